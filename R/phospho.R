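#' Collect phosphosites from classified PSMs
#'
#' Translates peptide-level phospho modifications to protein coordinates via
#' the peptide's mapped start position, filters by localization confidence
#' (Ascore; the search engine reports 1000 as maximal, and the default keeps
#' sites with score >= 1000), and merges duplicate observations of the same
#' (accession, position, residue) keeping the maximal score. Observation
#' provenance is kept for per-animal counting and specificity calls.
#'
#' @param classified A classified PSM table ([classify_psms()], with design).
#' @param proteins A protein table ([read_fasta()]) used to verify that the
#'   protein residue at each translated position matches the site residue.
#' @param min_score Minimum localization score (default 1000); observations
#'   without a score are dropped.
#' @return A data.frame of merged sites with columns `accession`, `residue`,
#'   `position`, `site` (e.g. `"Y113"`), `score` (max), `n_samples`,
#'   `groups_detected` (semicolon-joined `condition:layer`), plus an
#'   attribute `"observations"`: a data.frame with one row per
#'   (site, sample) observation (`accession`, `residue`, `position`,
#'   `sample_id`, `condition`, `layer`, `animal_id`, `score`,
#'   `spectral_count`).
#' @export
collect_sites <- function(classified, proteins, min_score = 1000) {
  .needs_design_cols(classified)
  has_phos <- count_mod_token(classified$modifications, "[STY]\\(\\+79\\.9[0-9]*\\)") > 0
  d <- classified[has_phos & !is.na(classified$accession), , drop = FALSE]
  obs_cols <- c("accession", "residue", "position", "sample_id", "condition",
                "layer", "animal_id", "score", "spectral_count")
  empty_obs <- data.frame(accession = character(0), residue = character(0),
                          position = integer(0), sample_id = character(0),
                          condition = character(0), layer = character(0),
                          animal_id = character(0), score = numeric(0),
                          spectral_count = integer(0))
  empty <- data.frame(accession = character(0), residue = character(0),
                      position = integer(0), site = character(0),
                      score = numeric(0), n_samples = integer(0),
                      groups_detected = character(0))
  if (nrow(d) == 0L) {
    attr(empty, "observations") <- empty_obs
    return(empty)
  }
  seq_by_acc <- setNames(proteins$sequence, proteins$accession)
  mods <- parse_modifications(d$modifications, d$peptide)
  obs <- list()
  for (i in seq_len(nrow(d))) {
    m <- mods[[i]]
    m <- m[m$name == "phospho", , drop = FALSE]
    if (nrow(m) == 0L) next
    prot_pos <- d$start[i] + m$position - 1L
    acc <- d$accession[i]
    at <- substring(seq_by_acc[[acc]], prot_pos, prot_pos)
    if (any(at != m$residue)) {
      stop("phosphosite residue mismatch for ", acc, " position ",
           prot_pos[at != m$residue][1])
    }
    obs[[length(obs) + 1L]] <- data.frame(
      accession = acc, residue = m$residue, position = prot_pos,
      sample_id = d$sample_id[i], condition = d$condition[i],
      layer = d$layer[i], animal_id = d$animal_id[i],
      score = m$localization_score, spectral_count = d$spectral_count[i],
      stringsAsFactors = FALSE)
  }
  obs <- if (length(obs)) do.call(rbind, obs) else empty_obs
  obs <- obs[!is.na(obs$score) & obs$score >= min_score, , drop = FALSE]
  if (nrow(obs) == 0L) {
    attr(empty, "observations") <- empty_obs
    return(empty)
  }
  # merge duplicate observations of a site within a sample
  okey <- paste(obs$accession, obs$position, obs$residue, obs$sample_id, sep = "\r")
  o <- order(okey, -obs$score)
  obs <- obs[o, , drop = FALSE]
  okey <- okey[o]
  sc <- rowsum(obs$spectral_count, okey)
  keep <- !duplicated(okey)
  obs <- obs[keep, , drop = FALSE]
  obs$spectral_count <- as.integer(sc[okey[keep], 1])
  obs <- obs[order(obs$accession, obs$position, obs$sample_id), , drop = FALSE]
  rownames(obs) <- NULL

  skey <- paste(obs$accession, obs$position, obs$residue, sep = "\r")
  usite <- !duplicated(skey)
  score_max <- tapply(obs$score, skey, max)
  n_samples <- tapply(obs$sample_id, skey, function(x) length(unique(x)))
  groups <- tapply(group_key(obs$condition, obs$layer), skey,
                   function(g) paste(sort(unique(g)), collapse = ";"))
  ks <- skey[usite]
  sites <- data.frame(
    accession = obs$accession[usite], residue = obs$residue[usite],
    position = obs$position[usite],
    site = paste0(obs$residue[usite], obs$position[usite]),
    score = as.numeric(score_max[ks]),
    n_samples = as.integer(n_samples[ks]),
    groups_detected = as.character(groups[ks]),
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "observations") <- obs
  sites
}

#' Per-animal and per-group phosphosite counts with a group test
#'
#' Counts distinct phosphosites per animal in every group and compares LPS
#' vs Control per layer with the pipeline's Student's t-test.
#'
#' @param sites Output of [collect_sites()] (its `"observations"` attribute
#'   is used).
#' @param design The design table; animals without site observations count 0.
#' @return A list with `per_animal` (data.frame `condition`, `layer`,
#'   `animal_id`, `n_sites`) and `tests` (data.frame `layer`, `mean_lps`,
#'   `mean_control`, `p_value`).
#' @export
count_sites_per_group <- function(sites, design) {
  obs <- attr(sites, "observations")
  design <- validate_design(design)
  anim <- unique(design[, c("condition", "layer", "animal_id")])
  anim <- anim[order(anim$condition, anim$layer, anim$animal_id), ]
  n <- integer(nrow(anim))
  if (!is.null(obs) && nrow(obs)) {
    for (i in seq_len(nrow(anim))) {
      sel <- obs$condition == anim$condition[i] &
        obs$layer == anim$layer[i] & obs$animal_id == anim$animal_id[i]
      n[i] <- length(unique(paste(obs$accession[sel], obs$position[sel])))
    }
  }
  per_animal <- cbind(anim, n_sites = n)
  rownames(per_animal) <- NULL
  layers <- sort(unique(design$layer))
  tests <- do.call(rbind, lapply(layers, function(ly) {
    x <- per_animal$n_sites[per_animal$layer == ly & per_animal$condition == "LPS"]
    y <- per_animal$n_sites[per_animal$layer == ly & per_animal$condition == "Control"]
    data.frame(layer = ly,
               mean_lps = if (length(x)) mean(x) else NA_real_,
               mean_control = if (length(y)) mean(y) else NA_real_,
               p_value = test_protein(x, y), stringsAsFactors = FALSE)
  }))
  list(per_animal = per_animal, tests = tests)
}

#' Call disease-specific (LPS-only) phosphosites
#'
#' A site is disease specific in a layer when observed in at least one LPS
#' sample and no Control sample of the same layer; the symmetric
#' control-specific flag is also reported (the two are mutually exclusive).
#' Output mirrors a disease-specific site table: one row per site and layer
#' with the gene (from an optional annotation map), accession, description
#' and the modified residue.
#'
#' @param sites Output of [collect_sites()].
#' @param design The design table.
#' @param proteins Optional protein table supplying descriptions.
#' @param annotation Optional data.frame with columns `accession`, `gene`
#'   (user-supplied identifier map).
#' @return A data.frame with columns `gene`, `accession`, `protein`,
#'   `layer`, `site`, `residue`, `position`, `score`, `disease_specific`,
#'   `control_specific`.
#' @export
call_disease_specific <- function(sites, design, proteins = NULL,
                                  annotation = NULL) {
  obs <- attr(sites, "observations")
  design <- validate_design(design)
  empty <- data.frame(gene = character(0), accession = character(0),
                      protein = character(0), layer = character(0),
                      site = character(0), residue = character(0),
                      position = integer(0), score = numeric(0),
                      disease_specific = logical(0),
                      control_specific = logical(0))
  if (is.null(obs) || nrow(obs) == 0L) return(empty)
  rows <- list()
  for (ly in sort(unique(obs$layer))) {
    oly <- obs[obs$layer == ly, , drop = FALSE]
    skey <- paste(oly$accession, oly$position, oly$residue, sep = "\r")
    in_lps <- tapply(oly$condition == "LPS", skey, any)
    in_ctl <- tapply(oly$condition == "Control", skey, any)
    score <- tapply(oly$score, skey, max)
    u <- !duplicated(skey)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = oly$accession[u], residue = oly$residue[u],
      position = oly$position[u], layer = ly,
      site = paste0(oly$residue[u], oly$position[u]),
      score = as.numeric(score[skey[u]]),
      disease_specific = as.logical(in_lps[skey[u]]) & !as.logical(in_ctl[skey[u]]),
      control_specific = as.logical(in_ctl[skey[u]]) & !as.logical(in_lps[skey[u]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$gene <- if (!is.null(annotation)) {
    as.character(annotation$gene[match(out$accession, annotation$accession)])
  } else NA_character_
  out$protein <- if (!is.null(proteins)) {
    as.character(proteins$description[match(out$accession, proteins$accession)])
  } else NA_character_
  out <- out[, c("gene", "accession", "protein", "layer", "site", "residue",
                 "position", "score", "disease_specific", "control_specific")]
  out <- out[order(out$layer, out$accession, out$position), ]
  rownames(out) <- NULL
  out
}
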