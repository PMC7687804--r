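# Brute-force oracles, written independently of the package internals:
# digestion is checked by enumerating every substring of the protein and
# testing the trypsin rule residue by residue.

oracle_is_site <- function(chars, i) {
  n <- length(chars)
  if (i < 1 || i > n) return(FALSE)
  if (!(chars[i] %in% c("K", "R"))) return(FALSE)
  if (i < n && chars[i + 1] == "P") return(FALSE)
  TRUE
}

# every substring whose termini both lie on cleavage boundaries and whose
# internal missed-cleavage count is within the allowance
oracle_digest <- function(sequence, mc) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  site <- vapply(seq_len(n), function(i) oracle_is_site(chars, i), logical(1))
  csum <- cumsum(site)
  starts <- integer(0); ends <- integer(0); mcs <- integer(0)
  for (s in seq_len(n)) {
    if (!(s == 1 || site[s - 1])) next
    for (e in s:n) {
      if (!(e == n || site[e])) next
      # a site at e is the C-terminal cleavage itself; only s..e-1 count
      internal <- csum[e] - site[e] - if (s > 1) csum[s - 1] else 0
      if (internal <= mc) {
        starts <- c(starts, s); ends <- c(ends, e); mcs <- c(mcs, internal)
      }
    }
  }
  data.frame(peptide = substring(sequence, starts, ends),
             start = starts, end = ends, missed_cleavages = as.integer(mcs),
             stringsAsFactors = FALSE)
}

# naive specificity call: scan every occurrence, apply the terminus rules
# (including the initiator-Met allowance), keep the best
oracle_classify <- function(peptide, protein) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  L <- nchar(peptide)
  best <- "unmapped"
  rank <- c(fully_tryptic = 1, semi_tryptic = 2, non_tryptic = 3, unmapped = 4)
  for (s in seq_len(max(n - L + 1, 0))) {
    if (substr(protein, s, s + L - 1) != peptide) next
    e <- s + L - 1
    n_ok <- s == 1 || oracle_is_site(chars, s - 1) ||
      (s == 2 && chars[1] == "M")
    c_ok <- e == n || oracle_is_site(chars, e)
    spec <- if (n_ok && c_ok) "fully_tryptic" else
      if (n_ok || c_ok) "semi_tryptic" else "non_tryptic"
    if (rank[spec] < rank[best]) best <- spec
  }
  best
}

random_protein <- function(len, met_start = TRUE) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  body <- paste(sample(aas, len - met_start, replace = TRUE), collapse = "")
  if (met_start) paste0("M", body) else body
}
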