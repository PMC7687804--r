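AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a protein FASTA database
#'
#' Reads an amino-acid FASTA file into a protein table. Sequences are
#' uppercased and must contain only the 20 canonical residues; duplicate
#' accessions are rejected. The accession is the first whitespace-delimited
#' token of the header, the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `description`, `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MAKR"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(accession = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(accession))) {
    stop("malformed FASTA header (empty accession) near line ",
         .fasta_header_line(path, which(!nzchar(accession))[1]))
  }
  if (anyDuplicated(accession)) {
    dup <- accession[duplicated(accession)][1]
    stop("duplicate accession in FASTA: ", dup, " (near line ",
         .fasta_header_line(path, which(accession == dup)[2]), ")")
  }
  sequence <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), sequence)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("illegal residue in record ", accession[i], " near line ",
         .fasta_header_line(path, i) + 1L)
  }
  if (any(!nzchar(sequence))) {
    i <- which(!nzchar(sequence))[1]
    stop("empty sequence for record ", accession[i])
  }
  data.frame(accession = accession, description = description,
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

# Line number of the k-th FASTA header; only used to decorate error messages.
.fasta_header_line <- function(path, k) {
  ln <- grep("^>", readLines(path, warn = FALSE))
  if (k <= length(ln)) ln[k] else NA_integer_
}

#' Write a protein table to FASTA
#'
#' @param proteins A data.frame with columns `accession`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  hdr <- ifelse(nzchar(desc), paste(proteins$accession, desc), proteins$accession)
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

DESIGN_COLUMNS <- c("sample_id", "condition", "layer", "animal_id")
PSM_COLUMNS <- c("sample_id", "peptide", "modifications", "proteins", "spectral_count")

#' Read a sample design table
#'
#' Tab-separated, UTF-8, `#`-comments ignored; required columns `sample_id`,
#' `condition` (Control/LPS), `layer` (GC/EC/SMC), `animal_id`. Each
#' (condition, layer, animal_id) combination must be unique.
#'
#' @param path Path to the design TSV.
#' @return A validated design data.frame.
#' @export
read_design <- function(path) {
  d <- read_tsv(path, DESIGN_COLUMNS)
  for (col in DESIGN_COLUMNS) d[[col]] <- as.character(d[[col]])
  validate_design(d)
}

#' Validate a sample design table
#'
#' @param design A design data.frame (see [read_design()]).
#' @return The design, invisibly unchanged, or an error.
#' @export
validate_design <- function(design) {
  miss <- setdiff(DESIGN_COLUMNS, names(design))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1])
  }
  bad <- !design$condition %in% c("Control", "LPS")
  if (any(bad)) stop("unknown condition: ", design$condition[bad][1])
  bad <- !design$layer %in% c("GC", "EC", "SMC")
  if (any(bad)) stop("unknown layer: ", design$layer[bad][1])
  key <- paste(design$condition, design$layer, design$animal_id)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, layer, animal_id) in design: ",
         key[duplicated(key)][1])
  }
  design
}

#' Read a PSM table
#'
#' Reads a tab-separated post-search PSM table with required columns
#' `sample_id`, `peptide`, `modifications` (semicolon-separated
#' `"pos:RES(+delta)"`, optional `"@score"` localization suffix), `proteins`
#' (semicolon-separated accessions) and `spectral_count`. All modifications
#' are parsed and validated against the controlled vocabulary
#' ([modification_vocabulary()]); every `sample_id` must resolve to a design
#' row.
#'
#' @param path Path to the PSM TSV.
#' @param design Optional design data.frame used to validate `sample_id`.
#' @return A data.frame with the five required columns.
#' @export
read_psm_table <- function(path, design = NULL) {
  d <- read_tsv(path, PSM_COLUMNS)
  d$sample_id <- as.character(d$sample_id)
  d$peptide <- as.character(d$peptide)
  d$modifications <- as.character(d$modifications)
  d$modifications[is.na(d$modifications)] <- ""
  d$proteins <- as.character(d$proteins)
  d$spectral_count <- as.numeric(d$spectral_count)
  validate_psms(d, design)
}

#' Validate a PSM table
#'
#' @param psms A PSM data.frame (see [read_psm_table()]).
#' @param design Optional design table; when given, unknown `sample_id`s are
#'   an error.
#' @return The PSM table (with integer counts), or an error.
#' @export
validate_psms <- function(psms, design = NULL) {
  miss <- setdiff(PSM_COLUMNS, names(psms))
  if (length(miss)) stop("PSM table is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(psms$peptide) | !nzchar(psms$peptide))) stop("empty peptide in PSM table")
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), psms$peptide)
  if (any(bad)) stop("illegal residue in peptide '", psms$peptide[bad][1], "'")
  if (any(is.na(psms$spectral_count) | psms$spectral_count < 0)) {
    stop("negative or missing spectral_count in PSM table")
  }
  if (any(psms$spectral_count != floor(psms$spectral_count))) {
    stop("non-integer spectral_count in PSM table")
  }
  psms$spectral_count <- as.integer(psms$spectral_count)
  # full parse of every distinct (mods, peptide) pair enforces the vocabulary
  key <- paste(psms$modifications, psms$peptide, sep = "\r")
  u <- !duplicated(key)
  invisible(parse_modifications(psms$modifications[u], psms$peptide[u]))
  if (!is.null(design)) {
    unknown <- setdiff(unique(psms$sample_id), design$sample_id)
    if (length(unknown)) stop("sample_id not in design: ", unknown[1])
  }
  psms
}

#' Read a tab-separated table
#'
#' UTF-8, tab-separated, decimal points only, `#`-prefixed comment lines
#' ignored.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return A data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8", na.strings = c("NA"))
  if (!is.null(required)) {
    miss <- setdiff(required, names(d))
    if (length(miss)) stop("missing column(s) in ", path, ": ",
                           paste(miss, collapse = ", "))
  }
  d
}

#' Write a tab-separated table
#'
#' Deterministic companion of [read_tsv()]: UTF-8, tab-separated, no quoting,
#' no row names, `\n` line endings.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n", na = "NA")
  invisible(path)
}

#' Write a set of result tables plus a JSON run summary
#'
#' Writes each table in `tables` as `<name>.tsv` (deterministic column order
#' as given) and `run_summary.json` holding `summary` (typically parameters,
#' seed, and per-table row counts). Tables round-trip through [read_tsv()].
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param summary Named list serialized to `run_summary.json`.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, summary = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths[nm] <- p
  }
  summary$tables <- lapply(tables, nrow)
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths["run_summary"] <- sp
  invisible(paths)
}
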