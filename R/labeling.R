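K6_DELTA <- 6.0201

#' Call the Lys(6) label status of peptides
#'
#' A peptide is newly-synthesized evidence when it carries at least one
#' Lys(6) modification (`label-K6`, +6.0201 Da per labeled lysine). The call
#' is independent of modification order and idempotent.
#'
#' @param peptides Character vector of peptide sequences.
#' @param modifications Character vector of inline modification strings (see
#'   [parse_modifications()]), recycled against `peptides`.
#' @return A data.frame with columns `labeled`, `n_labeled_lysines`,
#'   `n_lysines`, `mass_shift` (Da).
#' @export
#' @examples
#' call_label("ASKLR", "3:K(+6.02)")
call_label <- function(peptides, modifications = "") {
  np <- max(length(peptides), length(modifications))
  peptides <- rep_len(peptides, np)
  modifications <- rep_len(modifications, np)
  # validates K6-on-K via residue check in the parser (distinct pairs only)
  u <- !duplicated(paste(modifications, peptides, sep = "\r"))
  invisible(parse_modifications(modifications[u], peptides[u]))
  n_lab <- count_mod_token(modifications, "K\\(\\+6\\.0[0-9]*\\)")
  n_lys <- nchar(peptides) - nchar(gsub("K", "", peptides, fixed = TRUE))
  if (any(n_lab > n_lys)) stop("more labeled lysines than lysines in peptide")
  data.frame(
    labeled = n_lab >= 1L,
    n_labeled_lysines = n_lab,
    n_lysines = n_lys,
    mass_shift = K6_DELTA * n_lab
  )
}

#' Classify a PSM table for label status and terminal specificity
#'
#' The central enrichment step: each PSM row gains the Lys(6) label call
#' ([call_label()]) and, against its claimed protein(s), the terminal
#' specificity call ([classify_specificity()]). For multi-protein peptides
#' the protein giving the highest specificity (ties: first listed) provides
#' the coordinates; `n_proteins` records the ambiguity so downstream policies
#' can act on it. Peptides matching none of their claimed proteins are
#' `unmapped`.
#'
#' @param psms A PSM data.frame (see [read_psm_table()]).
#' @param proteins A protein table (see [read_fasta()]).
#' @param design Optional design table; when given, `condition`, `layer` and
#'   `animal_id` columns are joined on.
#' @return The PSM table with added columns `labeled`, `n_labeled_lysines`,
#'   `n_lysines`, `mass_shift`, `accession` (chosen mapping), `n_proteins`,
#'   `specificity`, `n_term_tryptic`, `c_term_tryptic`, `missed_cleavages`,
#'   `start`, `end`, `multi_mapped`, `nontryptic` (at least one non-tryptic
#'   terminus) and, with a design, the design columns.
#' @export
classify_psms <- function(psms, proteins, design = NULL) {
  psms <- validate_psms(psms, design)
  # validate_psms has already vetted every modification, so the label
  # columns can be derived straight from the inline notation
  n_lab <- count_mod_token(psms$modifications, "K\\(\\+6\\.0[0-9]*\\)")
  n_lys <- nchar(psms$peptide) - nchar(gsub("K", "", psms$peptide, fixed = TRUE))
  psms$labeled <- n_lab >= 1L
  psms$n_labeled_lysines <- n_lab
  psms$n_lysines <- n_lys
  psms$mass_shift <- K6_DELTA * n_lab

  seq_by_acc <- setNames(proteins$sequence, proteins$accession)
  # classify each distinct (peptide, proteins-claim) once, expanding
  # multi-protein claims into candidate rows and taking, per claim, the
  # candidate with the highest specificity (ties: first listed protein)
  key <- paste(psms$peptide, psms$proteins, sep = "\r")
  uidx <- which(!duplicated(key))
  acc_list <- strsplit(psms$proteins[uidx], ";", fixed = TRUE)
  acc_list <- lapply(acc_list, function(a) a[nzchar(trimws(a))])
  n_claimed <- lengths(acc_list)
  cand_claim <- rep(seq_along(uidx), n_claimed)
  cand_acc <- unlist(acc_list, use.names = FALSE)
  known <- cand_acc %in% names(seq_by_acc)
  cl <- data.frame(specificity = rep("unmapped", length(cand_acc)),
                   n_term_tryptic = NA, c_term_tryptic = NA,
                   missed_cleavages = NA_integer_, start = NA_integer_,
                   end = NA_integer_, multi_mapped = FALSE,
                   stringsAsFactors = FALSE)
  if (any(known)) {
    cl[known, ] <- classify_specificity(
      psms$peptide[uidx][cand_claim[known]],
      unname(seq_by_acc[cand_acc[known]]))
  }
  lev <- match(cl$specificity, SPECIFICITY_LEVELS)
  ord <- order(cand_claim, lev)
  best <- ord[!duplicated(cand_claim[ord])]
  ucl <- cbind(
    data.frame(accession = ifelse(cl$specificity[best] == "unmapped",
                                  NA_character_, cand_acc[best]),
               n_proteins = n_claimed, stringsAsFactors = FALSE),
    cl[best, , drop = FALSE]
  )
  rownames(ucl) <- NULL
  cl_all <- ucl[match(key, key[uidx]), , drop = FALSE]
  rownames(cl_all) <- NULL
  psms <- cbind(psms, cl_all)
  psms$nontryptic <- psms$specificity %in% c("semi_tryptic", "non_tryptic")
  if (!is.null(design)) {
    m <- match(psms$sample_id, design$sample_id)
    psms$condition <- design$condition[m]
    psms$layer <- design$layer[m]
    psms$animal_id <- design$animal_id[m]
  }
  psms
}

group_key <- function(condition, layer) paste(condition, layer, sep = ":")

.needs_design_cols <- function(classified) {
  if (!all(c("condition", "layer", "animal_id") %in% names(classified))) {
    stop("classified PSMs lack design columns; run classify_psms() with a design")
  }
  invisible(classified)
}

#' Per-protein Lys(6) incorporation profiles
#'
#' For every protein in every group (condition x layer), sums spectral counts
#' of labeled and of all peptides and reports the incorporation fraction
#' `labeled_sc / total_sc` (spectral-count weighting, the default) together
#' with the distinct-peptide-weighted analogue.
#'
#' @param classified A classified PSM table ([classify_psms()], with design).
#' @param min_animals Consistency filter: a protein appears in a group's
#'   profile only if detected in at least this many animals of the group
#'   (default 2).
#' @return A data.frame with columns `accession`, `condition`, `layer`,
#'   `labeled_sc`, `total_sc`, `incorporation_fraction`, `labeled_peptides`,
#'   `total_peptides`, `incorporation_fraction_peptides`, `n_animals_detected`.
#' @export
incorporation_profiles <- function(classified, min_animals = 2L) {
  .needs_design_cols(classified)
  d <- classified[!is.na(classified$accession), , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(accession = character(0), condition = character(0),
                      layer = character(0), labeled_sc = integer(0),
                      total_sc = integer(0), incorporation_fraction = numeric(0),
                      labeled_peptides = integer(0), total_peptides = integer(0),
                      incorporation_fraction_peptides = numeric(0),
                      n_animals_detected = integer(0)))
  }
  key <- paste(d$accession, d$condition, d$layer, sep = "\r")
  labeled_sc <- rowsum(d$spectral_count * d$labeled, key)
  total_sc <- rowsum(d$spectral_count, key)
  pep_key <- !duplicated(paste(key, d$peptide, sep = "\r"))
  dk <- d[pep_key, , drop = FALSE]
  key_u <- paste(dk$accession, dk$condition, dk$layer, sep = "\r")
  # labeled distinct peptides: a sequence counts as labeled if any PSM of it
  # in the group is labeled
  lab_by_seq <- rowsum(as.integer(d$labeled),
                       paste(key, d$peptide, sep = "\r")) > 0
  labeled_pep <- rowsum(as.integer(lab_by_seq[paste(key_u, dk$peptide, sep = "\r"), 1]), key_u)
  total_pep <- rowsum(rep(1L, nrow(dk)), key_u)
  anim <- !duplicated(paste(key, d$animal_id, sep = "\r"))
  n_anim <- rowsum(rep(1L, sum(anim)),
                   paste(d$accession, d$condition, d$layer, sep = "\r")[anim])
  ks <- rownames(total_sc)
  parts <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
  out <- data.frame(
    accession = parts[, 1], condition = parts[, 2], layer = parts[, 3],
    labeled_sc = as.integer(labeled_sc[ks, 1]),
    total_sc = as.integer(total_sc[ks, 1]),
    incorporation_fraction = as.numeric(labeled_sc[ks, 1] / total_sc[ks, 1]),
    labeled_peptides = as.integer(labeled_pep[ks, 1]),
    total_peptides = as.integer(total_pep[ks, 1]),
    incorporation_fraction_peptides =
      as.numeric(labeled_pep[ks, 1] / total_pep[ks, 1]),
    n_animals_detected = as.integer(n_anim[ks, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_animals_detected >= min_animals, , drop = FALSE]
  out <- out[order(out$condition, out$layer, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeled-proteome fraction of a group
#'
#' Fraction of detected proteins that are newly synthesized: the numerator
#' counts proteins with Lys(6)-labeled peptide evidence in at least
#' `min_animals` animals of the group, the denominator counts proteins
#' detected (any peptide) in at least `min_animals` animals. Per-animal naive
#' fractions (within-animal evidence only) are reported with their mean and
#' SD.
#'
#' @param classified A classified PSM table with design columns.
#' @param condition,layer The group to evaluate.
#' @param min_animals Consistency filter (default 2).
#' @return A list with elements `fraction`, `n_labeled`, `n_detected`,
#'   `per_animal` (data.frame `animal_id`, `n_labeled`, `n_detected`,
#'   `fraction`), `mean`, `sd`.
#' @export
labeled_proteome_fraction <- function(classified, condition, layer,
                                      min_animals = 2L) {
  .needs_design_cols(classified)
  g <- classified[classified$condition == condition &
                    classified$layer == layer &
                    !is.na(classified$accession), , drop = FALSE]
  if (nrow(g) == 0L) stop("no PSMs for group ", condition, ":", layer)
  pa_key <- paste(g$accession, g$animal_id, sep = "\r")
  det <- rowsum(rep(1L, nrow(g)), pa_key) > 0
  lab <- rowsum(as.integer(g$labeled), pa_key) > 0
  parts <- do.call(rbind, strsplit(rownames(det), "\r", fixed = TRUE))
  acc <- parts[, 1]; animal <- parts[, 2]
  det_n <- rowsum(as.integer(det[, 1]), acc)
  lab_n <- rowsum(as.integer(lab[, 1]), acc)
  n_detected <- sum(det_n[, 1] >= min_animals)
  n_labeled <- sum(lab_n[, 1] >= min_animals)
  per_animal <- do.call(rbind, lapply(sort(unique(animal)), function(a) {
    sel <- animal == a
    data.frame(animal_id = a,
               n_labeled = sum(lab[sel, 1]),
               n_detected = sum(det[sel, 1]),
               stringsAsFactors = FALSE)
  }))
  per_animal$fraction <- per_animal$n_labeled / per_animal$n_detected
  list(
    fraction = if (n_detected > 0) n_labeled / n_detected else 0,
    n_labeled = n_labeled, n_detected = n_detected,
    per_animal = per_animal,
    mean = mean(per_animal$fraction), sd = sd(per_animal$fraction)
  )
}

#' Labeled fraction of the peptidome
#'
#' Fraction of distinct peptide sequences in a group carrying the Lys(6)
#' label (a sequence counts as labeled if any PSM of it is labeled), plus the
#' spectral-count-weighted analogue. Peptides without lysine are included in
#' the denominator by default.
#'
#' @param classified A classified PSM table with design columns.
#' @param condition,layer The group; `NULL` pools over that factor.
#' @param include_lysine_free Keep K-free peptides in denominators
#'   (default `TRUE`).
#' @return A list with `fraction` (distinct-peptide estimator),
#'   `fraction_sc` (spectral-count-weighted), `n_labeled`, `n_peptides`.
#' @export
labeled_peptidome_fraction <- function(classified, condition = NULL,
                                       layer = NULL,
                                       include_lysine_free = TRUE) {
  .needs_design_cols(classified)
  g <- classified
  if (!is.null(condition)) g <- g[g$condition == condition, , drop = FALSE]
  if (!is.null(layer)) g <- g[g$layer == layer, , drop = FALSE]
  if (!include_lysine_free) g <- g[g$n_lysines > 0L, , drop = FALSE]
  if (nrow(g) == 0L) stop("no PSMs in the requested group")
  lab_by_seq <- rowsum(as.integer(g$labeled), g$peptide) > 0
  n_pep <- nrow(lab_by_seq)
  n_lab <- sum(lab_by_seq[, 1])
  sc_tot <- sum(g$spectral_count)
  sc_lab <- sum(g$spectral_count[g$labeled])
  list(fraction = n_lab / n_pep,
       fraction_sc = sc_lab / sc_tot,
       n_labeled = n_lab, n_peptides = n_pep)
}

#' Cumulative incorporation-frequency distribution
#'
#' Builds the cumulative frequency curve of per-protein Lys(6) incorporation
#' fractions for each group, the standard view for comparing label uptake
#' between conditions; a left-shifted curve means reduced incorporation.
#'
#' @param profiles Output of [incorporation_profiles()].
#' @param weighting `"sc"` (spectral-count-weighted fractions, default) or
#'   `"peptides"`.
#' @return A data.frame with columns `condition`, `layer`, `fraction`
#'   (sorted), `cumulative` (non-decreasing proportion in (0, 1]).
#' @export
incorporation_distribution <- function(profiles, weighting = c("sc", "peptides")) {
  weighting <- match.arg(weighting)
  col <- if (weighting == "sc") "incorporation_fraction" else
    "incorporation_fraction_peptides"
  stopifnot(nrow(profiles) >= 1L)
  grp <- unique(profiles[, c("condition", "layer")])
  out <- lapply(seq_len(nrow(grp)), function(i) {
    sel <- profiles$condition == grp$condition[i] & profiles$layer == grp$layer[i]
    f <- sort(profiles[[col]][sel])
    data.frame(condition = grp$condition[i], layer = grp$layer[i],
               fraction = f, cumulative = seq_along(f) / length(f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov distance between two incorporation curves
#'
#' Plumbing for comparing per-group incorporation distributions: the
#' two-sample KS statistic on the underlying per-protein fractions.
#'
#' @param profiles Output of [incorporation_profiles()].
#' @param group_a,group_b Each a `c(condition, layer)` pair.
#' @param weighting See [incorporation_distribution()].
#' @return The KS distance (numeric scalar in \[0, 1\]).
#' @export
incorporation_ks_distance <- function(profiles, group_a, group_b,
                                      weighting = c("sc", "peptides")) {
  weighting <- match.arg(weighting)
  col <- if (weighting == "sc") "incorporation_fraction" else
    "incorporation_fraction_peptides"
  fa <- profiles[[col]][profiles$condition == group_a[1] & profiles$layer == group_a[2]]
  fb <- profiles[[col]][profiles$condition == group_b[1] & profiles$layer == group_b[2]]
  if (length(fa) == 0L || length(fb) == 0L) stop("empty group in KS comparison")
  unname(suppressWarnings(ks.test(fa, fb))$statistic)
}
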