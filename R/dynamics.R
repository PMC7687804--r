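#' Aggregate per-protein, per-animal spectral counts
#'
#' Sums, for every protein in every (condition, layer, animal) cell, the
#' spectral counts of labeled peptides (`nsp_sc`, newly-synthesized protein
#' evidence), unlabeled peptides (`nnsp_sc`, pre-existing pool) and peptides
#' with at least one non-tryptic terminus (`nontryptic_sc`, turnover
#' evidence). Animals of a group without evidence for a protein are
#' zero-filled, so `nsp_sc + nnsp_sc` conserves the protein's total counts.
#'
#' @param classified A classified PSM table ([classify_psms()], with design).
#' @param design The design table (defines the animals to zero-fill).
#' @param shared_peptides `"unique"` (default) drops peptides claimed by more
#'   than one protein; `"all"` lets a shared peptide count towards its chosen
#'   (highest-specificity) mapping.
#' @return A data.frame with columns `accession`, `condition`, `layer`,
#'   `animal_id`, `nsp_sc`, `nnsp_sc`, `nontryptic_sc`.
#' @export
aggregate_counts <- function(classified, design,
                             shared_peptides = c("unique", "all")) {
  shared_peptides <- match.arg(shared_peptides)
  .needs_design_cols(classified)
  design <- validate_design(design)
  unknown <- setdiff(unique(classified$sample_id), design$sample_id)
  if (length(unknown)) stop("sample_id not in design: ", unknown[1])
  d <- classified[!is.na(classified$accession), , drop = FALSE]
  if (shared_peptides == "unique") d <- d[d$n_proteins == 1L, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(accession = character(0), condition = character(0),
                      layer = character(0), animal_id = character(0),
                      nsp_sc = integer(0), nnsp_sc = integer(0),
                      nontryptic_sc = integer(0)))
  }
  key <- paste(d$accession, d$condition, d$layer, d$animal_id, sep = "\r")
  nsp <- rowsum(d$spectral_count * d$labeled, key)
  nnsp <- rowsum(d$spectral_count * !d$labeled, key)
  ntr <- rowsum(d$spectral_count * d$nontryptic, key)
  parts <- do.call(rbind, strsplit(rownames(nsp), "\r", fixed = TRUE))
  obs <- data.frame(
    accession = parts[, 1], condition = parts[, 2], layer = parts[, 3],
    animal_id = parts[, 4],
    nsp_sc = as.integer(nsp[, 1]), nnsp_sc = as.integer(nnsp[, 1]),
    nontryptic_sc = as.integer(ntr[, 1]), stringsAsFactors = FALSE
  )
  # zero-fill: every animal of a group in which the protein's group appears
  prot_grp <- unique(obs[, c("accession", "condition", "layer")])
  anim <- unique(design[, c("condition", "layer", "animal_id")])
  full <- merge(prot_grp, anim, by = c("condition", "layer"))
  out <- merge(full, obs, by = c("accession", "condition", "layer", "animal_id"),
               all.x = TRUE)
  for (col in c("nsp_sc", "nnsp_sc", "nontryptic_sc")) {
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out <- out[, c("accession", "condition", "layer", "animal_id",
                 "nsp_sc", "nnsp_sc", "nontryptic_sc")]
  out <- out[order(out$accession, out$condition, out$layer, out$animal_id), ]
  rownames(out) <- NULL
  out
}

#' Two-sample t-test on per-animal spectral counts
#'
#' Student's pooled-variance two-sample t-test (Welch optional) on per-animal
#' summed spectral counts, the per-protein significance test of the pipeline.
#' Degenerate inputs are handled categorically: fewer than 2 animals on
#' either side gives `NA` (not testable); two identical constant groups give
#' p = 1; constant but different groups give p = 0 + machine epsilon.
#'
#' @param x,y Numeric vectors of per-animal counts for the two groups.
#' @param var_equal Pooled variance (default `TRUE`, the classic Student
#'   test); `FALSE` for Welch.
#' @return A p-value in (0, 1\], or `NA_real_` when not testable.
#' @export
#' @examples
#' test_protein(c(10, 11, 12), c(2, 1, 3))
test_protein <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else .Machine$double.eps)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

REGULATION_CALLS <- c("up", "down", "unchanged", "exclusive_LPS",
                      "exclusive_Control", "not_testable")

#' LPS/Control ratios, tests and regulation calls per protein
#'
#' For every protein of a layer, pools spectral counts across animals within
#' each condition and forms the LPS/Control ratio separately for
#' newly-synthesized (`nsp_ratio`) and pre-existing (`nnsp_ratio`) evidence;
#' per-animal sums feed Student's t-tests ([test_protein()]). Zero
#' denominators are categorical, never infinite: a protein with labeled
#' evidence only under LPS is `exclusive_LPS` (the Control side is N.D.),
#' only under Control `exclusive_Control`; both zero is not testable.
#' Regulation calls require the fold threshold and the p threshold jointly
#' (see [call_regulation()]).
#'
#' @param counts Output of [aggregate_counts()].
#' @param layer Layer to analyse (`"GC"`, `"EC"` or `"SMC"`).
#' @param min_animals Consistency filter: a protein is considered in a
#'   condition when detected (any evidence) in at least this many animals
#'   (default 2); testable proteins must pass it in both conditions.
#' @param fold_threshold,p_threshold Regulation thresholds (defaults 1.5 and
#'   0.05).
#' @param var_equal Passed to [test_protein()].
#' @return A data.frame with columns `accession`, `layer`, `nsp_lps_sc`,
#'   `nsp_control_sc`, `nnsp_lps_sc`, `nnsp_control_sc`, `nsp_ratio`,
#'   `nnsp_ratio`, `p_value_nsp`, `p_value_nnsp`, `call` (regulation call on
#'   the newly-synthesized evidence).
#' @export
compute_ratios <- function(counts, layer, min_animals = 2L,
                           fold_threshold = 1.5, p_threshold = 0.05,
                           var_equal = TRUE) {
  d <- counts[counts$layer == layer, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(accession = character(0), layer = character(0),
                      nsp_lps_sc = integer(0), nsp_control_sc = integer(0),
                      nnsp_lps_sc = integer(0), nnsp_control_sc = integer(0),
                      nsp_ratio = numeric(0), nnsp_ratio = numeric(0),
                      p_value_nsp = numeric(0), p_value_nnsp = numeric(0),
                      call = character(0)))
  }
  accs <- sort(unique(d$accession))
  rows <- lapply(accs, function(a) {
    da <- d[d$accession == a, , drop = FALSE]
    lps <- da[da$condition == "LPS", , drop = FALSE]
    ctl <- da[da$condition == "Control", , drop = FALSE]
    det_lps <- sum(lps$nsp_sc + lps$nnsp_sc > 0)
    det_ctl <- sum(ctl$nsp_sc + ctl$nnsp_sc > 0)
    # consistency filter: considered at all only when detected in at least
    # min_animals animals of at least one condition
    if (max(det_lps, det_ctl) < min_animals) return(NULL)
    nsp_l <- sum(lps$nsp_sc); nsp_c <- sum(ctl$nsp_sc)
    nnsp_l <- sum(lps$nnsp_sc); nnsp_c <- sum(ctl$nnsp_sc)
    nsp_ratio <- if (nsp_c > 0) nsp_l / nsp_c else NA_real_
    nnsp_ratio <- if (nnsp_c > 0) nnsp_l / nnsp_c else NA_real_
    testable <- det_lps >= min_animals && det_ctl >= min_animals
    p_nsp <- if (testable) test_protein(lps$nsp_sc, ctl$nsp_sc, var_equal) else NA_real_
    p_nnsp <- if (testable) test_protein(lps$nnsp_sc, ctl$nnsp_sc, var_equal) else NA_real_
    call <- if (nsp_c == 0 && nsp_l > 0) "exclusive_LPS"
      else if (nsp_l == 0 && nsp_c > 0) "exclusive_Control"
      else if (nsp_c == 0 && nsp_l == 0) "not_testable"
      else if (!testable || is.na(p_nsp)) "not_testable"
      else if (p_nsp <= p_threshold && nsp_ratio >= fold_threshold) "up"
      else if (p_nsp <= p_threshold && nsp_ratio <= 1 / fold_threshold) "down"
      else "unchanged"
    data.frame(accession = a, layer = layer,
               nsp_lps_sc = nsp_l, nsp_control_sc = nsp_c,
               nnsp_lps_sc = nnsp_l, nnsp_control_sc = nnsp_c,
               nsp_ratio = nsp_ratio, nnsp_ratio = nnsp_ratio,
               p_value_nsp = p_nsp, p_value_nnsp = p_nnsp,
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    return(data.frame(accession = character(0), layer = character(0),
                      nsp_lps_sc = integer(0), nsp_control_sc = integer(0),
                      nnsp_lps_sc = integer(0), nnsp_control_sc = integer(0),
                      nsp_ratio = numeric(0), nnsp_ratio = numeric(0),
                      p_value_nsp = numeric(0), p_value_nnsp = numeric(0),
                      call = character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Filter a regulation table to regulated and exclusive proteins
#'
#' Applies the joint threshold rule on the newly-synthesized evidence: `up`
#' requires ratio >= `fold_threshold` and p <= `p_threshold`, `down` ratio <=
#' 1/`fold_threshold` and p <= `p_threshold`; exclusive-synthesis proteins
#' (N.D. in one condition) are reported in a separate table.
#'
#' @param results Output of [compute_ratios()].
#' @return A list with data.frames `regulated` (up/down calls) and
#'   `exclusive` (exclusive_LPS / exclusive_Control).
#' @export
call_regulation <- function(results) {
  list(
    regulated = results[results$call %in% c("up", "down"), , drop = FALSE],
    exclusive = results[results$call %in% c("exclusive_LPS", "exclusive_Control"),
                        , drop = FALSE]
  )
}
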