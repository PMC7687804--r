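#' Trypsin cleavage sites of a protein sequence
#'
#' Positions `i` such that cleavage occurs after residue `i`: residue `i` is
#' K or R and residue `i+1` is not P (sequencing-grade trypsin rule). A
#' terminal K/R counts as a site.
#'
#' @param sequence Protein sequence (uppercase amino-acid string).
#' @return Sorted integer vector of cleavage positions (possibly empty).
#' @export
cleavage_sites <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L) return(integer(0))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  kr <- which(ch == "K" | ch == "R")
  kr[kr == n | ch[pmin(kr + 1L, n)] != "P"]
}

#' In-silico trypsin digestion
#'
#' Cleaves C-terminal to K/R except before P, emitting all peptides with
#' 0..`max_missed_cleavages` internal missed cleavage sites, with 1-based
#' inclusive protein coordinates, ordered by start position then length.
#'
#' @param sequence Protein sequence; an empty sequence yields an empty table.
#' @param max_missed_cleavages Maximum number of internal uncleaved K/R
#'   sites (default 2).
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`.
#' @export
#' @examples
#' digest("MAKRLSTKPE", max_missed_cleavages = 1)
digest <- function(sequence, max_missed_cleavages = 2L) {
  stopifnot(length(sequence) == 1L, max_missed_cleavages >= 0L)
  n <- nchar(sequence)
  empty <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  bounds <- unique(c(0L, cleavage_sites(sequence), n))
  nb <- length(bounds)  # bounds[j]..bounds[j+1] delimit the j-th base peptide
  starts <- integer(0); ends <- integer(0); mc <- integer(0)
  for (m in 0:max_missed_cleavages) {
    j <- seq_len(nb - 1L - m)
    if (length(j) == 0L) break
    starts <- c(starts, bounds[j] + 1L)
    ends <- c(ends, bounds[j + 1L + m])
    mc <- c(mc, rep.int(m, length(j)))
  }
  o <- order(starts, ends - starts)
  data.frame(
    peptide = substring(sequence, starts[o], ends[o]),
    start = starts[o], end = ends[o], missed_cleavages = mc[o],
    stringsAsFactors = FALSE
  )
}

SPECIFICITY_LEVELS <- c("fully_tryptic", "semi_tryptic", "non_tryptic", "unmapped")

#' Classify the terminal specificity of observed peptides
#'
#' For each peptide/protein pair, determines whether each terminus coincides
#' with a trypsin cleavage site or a protein terminus. Both termini tryptic
#' gives `fully_tryptic`, exactly one `semi_tryptic`, neither `non_tryptic`;
#' a peptide that is not a substring of the protein is `unmapped`. A peptide
#' starting at protein position 2 of a Met-initiated protein is given a
#' tryptic N-terminus (initiator-Met excision allowance). When a peptide
#' occurs at several positions, the occurrence maximizing specificity (fully
#' > semi > non) is reported and flagged `multi_mapped`. Missed cleavages
#' count internal uncleaved K/R (KP/RP excluded).
#'
#' @param peptides Character vector of peptide sequences.
#' @param protein_sequences Character vector of protein sequences, recycled
#'   against `peptides`.
#' @return A data.frame with columns `specificity`, `n_term_tryptic`,
#'   `c_term_tryptic`, `missed_cleavages`, `start`, `end`, `multi_mapped`
#'   (coordinates are `NA` for unmapped peptides).
#' @export
#' @examples
#' classify_specificity(c("LSTKPE", "STKPE", "ST"), "MAKRLSTKPE")
classify_specificity <- function(peptides, protein_sequences) {
  np <- max(length(peptides), length(protein_sequences))
  peptides <- rep_len(peptides, np)
  protein_sequences <- rep_len(protein_sequences, np)
  spec_i <- rep(4L, np)
  ntt_v <- rep(NA, np); ctt_v <- rep(NA, np)
  mc_v <- rep(NA_integer_, np)
  start_v <- rep(NA_integer_, np); end_v <- rep(NA_integer_, np)
  multi_v <- rep(FALSE, np)
  # cache per distinct protein: a site-membership lookup and the Met flag
  pidx <- match(protein_sequences, protein_sequences)
  first <- !duplicated(pidx)
  site_sets <- lapply(protein_sequences[first], function(p) {
    s <- cleavage_sites(p)
    is_site <- logical(nchar(p))
    is_site[s] <- TRUE
    is_site
  })
  site_of <- match(pidx, pidx[first])
  for (i in seq_len(np)) {
    prot <- protein_sequences[[i]]
    pep <- peptides[[i]]
    # lookahead so that overlapping occurrences are found too
    occ <- gregexpr(paste0("(?=", pep, ")"), prot, perl = TRUE)[[1]]
    if (occ[1] == -1L) next
    is_site <- site_sets[[site_of[i]]]
    n <- length(is_site)
    L <- nchar(pep)
    met <- substring(prot, 1L, 1L) == "M"
    b_spec <- 4L; b_s <- NA_integer_; b_e <- NA_integer_
    b_ntt <- NA; b_ctt <- NA
    for (s in as.integer(occ)) {
      e <- s + L - 1L
      ntt <- s == 1L || is_site[s - 1L] || (met && s == 2L)
      ctt <- e == n || is_site[e]
      spec <- if (ntt && ctt) 1L else if (ntt || ctt) 2L else 3L
      if (spec < b_spec) {
        b_spec <- spec; b_s <- s; b_e <- e; b_ntt <- ntt; b_ctt <- ctt
      }
      if (b_spec == 1L) break
    }
    spec_i[i] <- b_spec
    ntt_v[i] <- b_ntt; ctt_v[i] <- b_ctt
    mc_v[i] <- sum(is_site[b_s:b_e]) - is_site[b_e]
    start_v[i] <- b_s; end_v[i] <- b_e
    multi_v[i] <- length(occ) > 1L
  }
  data.frame(
    specificity = SPECIFICITY_LEVELS[spec_i],
    n_term_tryptic = ntt_v, c_term_tryptic = ctt_v,
    missed_cleavages = mc_v, start = start_v, end = end_v,
    multi_mapped = multi_v, stringsAsFactors = FALSE
  )
}
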