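#' Score protein turnover from non-tryptic peptide evidence
#'
#' In a trypsin-digested sample, peptides whose termini do not coincide with
#' trypsin cleavage sites witness endogenous proteolysis; their summed
#' spectral counts per protein per group are the turnover score. Peptides
#' with at least one non-tryptic terminus (semi- or fully non-tryptic) count
#' by default. Proteins with evidence in at least one group are reported with
#' explicit zeros in the remaining groups.
#'
#' @param classified A classified PSM table ([classify_psms()], with design).
#' @param design The design table (defines the group universe for
#'   zero-filling).
#' @param include `"semi_or_non"` (default, any non-tryptic terminus) or
#'   `"non_only"` (both termini non-tryptic).
#' @param shared_peptides See [aggregate_counts()].
#' @return A data.frame with columns `accession`, `condition`, `layer`,
#'   `nontryptic_sc`, `nontryptic_distinct`.
#' @export
score_turnover <- function(classified, design,
                           include = c("semi_or_non", "non_only"),
                           shared_peptides = c("unique", "all")) {
  include <- match.arg(include)
  shared_peptides <- match.arg(shared_peptides)
  .needs_design_cols(classified)
  d <- classified[!is.na(classified$accession), , drop = FALSE]
  if (shared_peptides == "unique") d <- d[d$n_proteins == 1L, , drop = FALSE]
  hit <- if (include == "semi_or_non") d$nontryptic else
    d$specificity == "non_tryptic"
  empty <- data.frame(accession = character(0), condition = character(0),
                      layer = character(0), nontryptic_sc = integer(0),
                      nontryptic_distinct = integer(0))
  if (!any(hit)) return(empty)
  h <- d[hit, , drop = FALSE]
  key <- paste(h$accession, h$condition, h$layer, sep = "\r")
  sc <- rowsum(h$spectral_count, key)
  dis <- rowsum(as.integer(!duplicated(paste(key, h$peptide, sep = "\r"))), key)
  parts <- do.call(rbind, strsplit(rownames(sc), "\r", fixed = TRUE))
  obs <- data.frame(accession = parts[, 1], condition = parts[, 2],
                    layer = parts[, 3],
                    nontryptic_sc = as.integer(sc[, 1]),
                    nontryptic_distinct = as.integer(dis[, 1]),
                    stringsAsFactors = FALSE)
  groups <- unique(validate_design(design)[, c("condition", "layer")])
  full <- merge(data.frame(accession = unique(obs$accession)), groups)
  out <- merge(full, obs, by = c("accession", "condition", "layer"), all.x = TRUE)
  out$nontryptic_sc[is.na(out$nontryptic_sc)] <- 0L
  out$nontryptic_distinct[is.na(out$nontryptic_distinct)] <- 0L
  out <- out[order(out$accession, out$condition, out$layer), ]
  rownames(out) <- NULL
  out
}

#' Proteins-by-groups turnover matrix
#'
#' Arranges [score_turnover()] scores as a numeric matrix (rows: proteins
#' with non-zero evidence in at least one group, ordered by descending total
#' with accession as tie-break; columns: `condition:layer` groups). Values
#' are raw spectral counts; an optional per-sample total-count scaling is off
#' by default, matching the raw-count convention of spectral counting.
#'
#' @param scores Output of [score_turnover()].
#' @param normalize Divide each column by the group's total non-tryptic
#'   counts times the mean across groups (library-size scaling, default
#'   `FALSE`).
#' @return A numeric matrix, possibly 0-row.
#' @export
turnover_matrix <- function(scores, normalize = FALSE) {
  groups <- sort(unique(group_key(scores$condition, scores$layer)))
  accs <- sort(unique(scores$accession))
  m <- matrix(0, nrow = length(accs), ncol = length(groups),
              dimnames = list(accs, groups))
  if (length(accs)) {
    m[cbind(scores$accession, group_key(scores$condition, scores$layer))] <-
      scores$nontryptic_sc
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  ord <- order(-rowSums(m), rownames(m))
  m <- m[ord, , drop = FALSE]
  if (normalize && nrow(m)) {
    tot <- colSums(m)
    scale <- ifelse(tot > 0, mean(tot[tot > 0]) / tot, 1)
    m <- sweep(m, 2, scale, "*")
  }
  m
}

#' Map endogenous cleavage sites from non-tryptic termini
#'
#' Every non-tryptic peptide terminus pins an endogenous cleavage event to a
#' protein coordinate: a peptide starting at protein position `s` with a
#' non-tryptic N-terminus witnesses cleavage after residue `s - 1`
#' (`side = "N"`); a non-tryptic C-terminus at position `e` witnesses
#' cleavage after residue `e` (`side = "C"`). Observations of the same site
#' are aggregated with distinct-peptide and spectral-count tallies.
#'
#' @param classified A classified PSM table ([classify_psms()]).
#' @return A data.frame with columns `accession`, `position` (cleavage after
#'   this residue), `side`, `n_peptides`, `spectral_count`, sorted by
#'   accession then position.
#' @export
map_cleavage_sites <- function(classified) {
  d <- classified[!is.na(classified$accession) &
                    classified$specificity %in% c("semi_tryptic", "non_tryptic"),
                  , drop = FALSE]
  empty <- data.frame(accession = character(0), position = integer(0),
                      side = character(0), n_peptides = integer(0),
                      spectral_count = integer(0))
  if (nrow(d) == 0L) return(empty)
  recs <- list()
  nterm <- d[!d$n_term_tryptic & d$start > 1L, , drop = FALSE]
  if (nrow(nterm)) {
    recs[[length(recs) + 1L]] <- data.frame(
      accession = nterm$accession, position = nterm$start - 1L, side = "N",
      peptide = nterm$peptide, spectral_count = nterm$spectral_count,
      stringsAsFactors = FALSE)
  }
  cterm <- d[!d$c_term_tryptic, , drop = FALSE]
  if (nrow(cterm)) {
    recs[[length(recs) + 1L]] <- data.frame(
      accession = cterm$accession, position = cterm$end, side = "C",
      peptide = cterm$peptide, spectral_count = cterm$spectral_count,
      stringsAsFactors = FALSE)
  }
  r <- do.call(rbind, recs)
  if (is.null(r) || nrow(r) == 0L) return(empty)
  key <- paste(r$accession, r$position, r$side, sep = "\r")
  sc <- rowsum(r$spectral_count, key)
  npep <- rowsum(as.integer(!duplicated(paste(key, r$peptide, sep = "\r"))), key)
  parts <- do.call(rbind, strsplit(rownames(sc), "\r", fixed = TRUE))
  out <- data.frame(accession = parts[, 1],
                    position = as.integer(parts[, 2]),
                    side = parts[, 3],
                    n_peptides = as.integer(npep[, 1]),
                    spectral_count = as.integer(sc[, 1]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$position, out$side), ]
  rownames(out) <- NULL
  out
}
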