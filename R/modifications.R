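#' Controlled vocabulary of peptide modifications
#'
#' The modifications the pipeline understands, with their monoisotopic mass
#' deltas and the residues they are allowed to sit on. Inline PSM-table
#' notation prints rounded deltas (PEAKS style), so parsing matches a printed
#' delta to the vocabulary within +/- 0.01 Da.
#'
#' @return A data.frame with columns `name`, `delta_mass` (Da) and
#'   `residues` (allowed amino-acid letters, collapsed).
#' @export
#' @examples
#' modification_vocabulary()
modification_vocabulary <- function() {
  data.frame(
    name = c("label-K6", "phospho", "carbamidomethyl"),
    delta_mass = c(6.0201, 79.9663, 57.0215),
    residues = c("K", "STY", "C"),
    stringsAsFactors = FALSE
  )
}

# Delta tolerance (Da) when matching printed deltas to the vocabulary.
MOD_DELTA_TOL <- 0.01

#' Parse inline modification notation
#'
#' Parses semicolon-separated `"pos:RES(+delta)"` tokens (optionally with a
#' localization-score suffix `"@score"`, used for phosphosites) into one
#' modification table per input string. The printed delta is matched to the
#' controlled vocabulary within +/- 0.01 Da and replaced by the exact
#' vocabulary mass.
#'
#' @param x Character vector of modification strings; `""` or `NA` means no
#'   modifications.
#' @param peptides Optional character vector of peptide sequences (recycled
#'   against `x`); when given, positions are checked against peptide length
#'   and the stated residue must match the peptide.
#' @return A list (one element per input) of data.frames with columns
#'   `position`, `residue`, `name`, `delta_mass`, `localization_score`
#'   (`NA` when absent).
#' @export
#' @examples
#' parse_modifications("3:K(+6.02)", peptides = "ASKLR")[[1]]
parse_modifications <- function(x, peptides = NULL) {
  vocab <- modification_vocabulary()
  empty <- data.frame(
    position = integer(0), residue = character(0), name = character(0),
    delta_mass = numeric(0), localization_score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(peptides)) peptides <- rep_len(peptides, length(x))
  nonempty <- !is.na(x) & nzchar(x)
  out <- rep(list(empty), length(x))
  if (!any(nonempty)) return(out)
  # vectorized parse: explode all tokens, one regex pass over the lot
  tok_list <- strsplit(x[nonempty], ";", fixed = TRUE)
  idx <- rep(which(nonempty), lengths(tok_list))
  toks <- trimws(unlist(tok_list, use.names = FALSE))
  keep <- nzchar(toks)
  toks <- toks[keep]; idx <- idx[keep]
  pat <- "^([0-9]+):([A-Z])\\(\\+([0-9]+\\.?[0-9]*)\\)(@([0-9]+\\.?[0-9]*))?$"
  ok <- grepl(pat, toks)
  if (!all(ok)) {
    stop("unparseable modification token '", toks[!ok][1], "' in '",
         x[idx[!ok][1]], "'")
  }
  pos <- as.integer(sub(pat, "\\1", toks))
  res <- sub(pat, "\\2", toks)
  delta <- as.numeric(sub(pat, "\\3", toks))
  score_s <- sub(pat, "\\5", toks)
  score <- ifelse(nzchar(score_s), suppressWarnings(as.numeric(score_s)), NA_real_)
  vidx <- rep(NA_integer_, length(delta))
  for (j in seq_len(nrow(vocab))) {
    vidx[abs(delta - vocab$delta_mass[j]) <= MOD_DELTA_TOL] <- j
  }
  if (anyNA(vidx)) {
    stop("modification delta +", delta[is.na(vidx)][1],
         " matches no vocabulary entry within ", MOD_DELTA_TOL, " Da")
  }
  allowed <- vocab$residues[vidx]
  okres <- mapply(function(r, a) grepl(r, a, fixed = TRUE), res, allowed)
  if (!all(okres)) {
    k <- which(!okres)[1]
    stop("modification ", vocab$name[vidx[k]], " not allowed on residue ",
         res[k], " (allowed: ", allowed[k], ")")
  }
  if (!is.null(peptides)) {
    pep <- peptides[idx]
    if (any(pos < 1L | pos > nchar(pep))) {
      stop("modification position out of range for peptide '",
           pep[pos < 1L | pos > nchar(pep)][1], "'")
    }
    at <- substring(pep, pos, pos)
    if (any(at != res)) {
      k <- which(at != res)[1]
      stop("modification residue mismatch in peptide '", pep[k],
           "': stated ", res[k], " at position ", pos[k],
           ", peptide has ", at[k])
    }
  }
  long <- data.frame(
    position = pos, residue = res, name = vocab$name[vidx],
    delta_mass = vocab$delta_mass[vidx], localization_score = score,
    stringsAsFactors = FALSE
  )
  parts <- split(long, factor(idx, levels = unique(idx)))
  for (nmi in seq_along(parts)) {
    df <- parts[[nmi]]
    rownames(df) <- NULL
    out[[as.integer(names(parts)[nmi])]] <- df
  }
  out
}

#' Format a modification table back to inline notation
#'
#' Inverse of [parse_modifications()] up to delta rounding: deltas print with
#' two decimals, scores are appended as `@score` when present.
#'
#' @param mods A modification data.frame as returned by [parse_modifications()].
#' @return A single string (`""` when no modifications).
#' @export
format_modifications <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  tok <- sprintf("%d:%s(+%.2f)", mods$position, mods$residue, mods$delta_mass)
  has <- !is.na(mods$localization_score)
  tok[has] <- paste0(tok[has], "@", format(mods$localization_score[has],
                                           trim = TRUE, scientific = FALSE))
  paste(tok, collapse = ";")
}

# Fast vectorized helpers over raw modification strings. These avoid a full
# parse when only one modification class matters; validity is still enforced
# at read time by read_psm_table().
count_mod_token <- function(mod_strings, pattern) {
  n <- integer(length(mod_strings))
  has <- !is.na(mod_strings) & nzchar(mod_strings)
  if (any(has)) {
    n[has] <- vapply(gregexpr(pattern, mod_strings[has]), function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, integer(1))
  }
  n
}
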