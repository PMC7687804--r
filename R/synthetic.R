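# Roughly mammalian residue frequencies; K+R >= 10% guarantees tryptic
# peptides of usable length.
AA_FREQS <- c(
  A = 0.070, C = 0.020, D = 0.050, E = 0.060, F = 0.040, G = 0.060,
  H = 0.030, I = 0.045, K = 0.090, L = 0.090, M = 0.025, N = 0.035,
  P = 0.045, Q = 0.040, R = 0.060, S = 0.070, T = 0.055, V = 0.060,
  W = 0.010, Y = 0.030
)

#' Configuration for the synthetic PSM-data generator
#'
#' Bundles and validates every generator parameter. Defaults encode the
#' study design the analysis targets: two conditions (Control, LPS) times
#' three vascular layers (GC, EC, SMC), three animals per condition,
#' per-protein newly-synthesized pool probabilities equal to the reported
#' per-layer labeled-proteome fractions (Control 0.31/0.29/0.34 and LPS
#' 0.16/0.18/0.16 for GC/EC/SMC), negative-binomial spectral counts (mean 3,
#' dispersion 0.5), and a 4-fold suppression of labeled-peptide counts in
#' LPS for 20% of proteins. See the methods vignette for the rationale
#' behind every default.
#'
#' @param n_proteins Number of proteins in the generated database.
#' @param protein_length_range Min/max protein length (residues).
#' @param n_animals Animals per condition (each animal contributes every
#'   layer).
#' @param conditions,layers Character vectors defining the groups.
#' @param protein_label_prob Probability that a protein belongs to the
#'   newly-synthesized pool of a group; scalar or named by `"condition:layer"`.
#' @param peptide_label_prob Per-peptide Bernoulli probability that a
#'   lysine-containing peptide of a pool protein is observed in labeled form.
#' @param peptidome_label_rate Optional marginal labeling rate over ALL
#'   distinct peptides; when set it replaces the pool model: every
#'   K-containing peptide is labeled with probability
#'   `rate / f_K` where `f_K` is the K-containing fraction of the generated
#'   peptide universe (only K-peptides can carry the label).
#' @param n_peptides_per_protein Peptides sampled per protein (capped by the
#'   available tryptic peptides).
#' @param peptide_length_range Usable tryptic peptide lengths.
#' @param sc_mean,sc_dispersion Negative-binomial spectral-count parameters
#'   (variance = mean + dispersion * mean^2; size = 1/dispersion).
#' @param endogenous_cleavage_prob Probability per protein per group that an
#'   endogenous cleavage generates a semi-tryptic fragment; scalar or named
#'   by condition or `"condition:layer"`.
#' @param fraction_modulated Fraction of proteins whose labeled-peptide
#'   counts are modulated in LPS.
#' @param nsp_fold_change LPS/Control fold applied to labeled-peptide count
#'   means of modulated proteins (0.25 = 4-fold suppression).
#' @param phospho_sites_per_protein Probability a protein carries one
#'   candidate phosphosite (on a covered S/T/Y residue).
#' @param phospho_detect_prob Named per-condition probabilities that a
#'   candidate site is observed in a given animal.
#' @param phospho_score_high_prob Probability an observation gets the
#'   maximal localization score (1000); otherwise uniform in \[200, 999\]
#'   (below the default filter).
#' @param protein_detect_prob Per-animal probability that a protein is
#'   present in the sample at all.
#' @param max_missed_cleavages Digestion depth for the sampled peptides.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param preset Optional preset name (`"fig1_fractions"` or `"null"`) or
#'   path to a YAML file; presets are data shipped under
#'   `inst/extdata/presets` and are applied before explicit arguments.
#' @return A validated list of class `"synthetic_config"`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_proteins = 20, seed = 1)
synthetic_config <- function(n_proteins = 500,
                             protein_length_range = c(200, 500),
                             n_animals = 3,
                             conditions = c("Control", "LPS"),
                             layers = c("GC", "EC", "SMC"),
                             protein_label_prob = c(
                               "Control:GC" = 0.31, "Control:EC" = 0.29,
                               "Control:SMC" = 0.34, "LPS:GC" = 0.16,
                               "LPS:EC" = 0.18, "LPS:SMC" = 0.16),
                             peptide_label_prob = 0.65,
                             peptidome_label_rate = NULL,
                             n_peptides_per_protein = 30,
                             peptide_length_range = c(6, 30),
                             sc_mean = 3, sc_dispersion = 0.5,
                             endogenous_cleavage_prob = 0.05,
                             fraction_modulated = 0.2,
                             nsp_fold_change = 0.25,
                             phospho_sites_per_protein = 0.2,
                             phospho_detect_prob = c(Control = 0.05, LPS = 0.3),
                             phospho_score_high_prob = 0.9,
                             protein_detect_prob = 1,
                             max_missed_cleavages = 2,
                             seed = 1,
                             preset = NULL) {
  cfg <- list(
    n_proteins = n_proteins, protein_length_range = protein_length_range,
    n_animals = n_animals, conditions = conditions, layers = layers,
    protein_label_prob = protein_label_prob,
    peptide_label_prob = peptide_label_prob,
    peptidome_label_rate = peptidome_label_rate,
    n_peptides_per_protein = n_peptides_per_protein,
    peptide_length_range = peptide_length_range,
    sc_mean = sc_mean, sc_dispersion = sc_dispersion,
    endogenous_cleavage_prob = endogenous_cleavage_prob,
    fraction_modulated = fraction_modulated,
    nsp_fold_change = nsp_fold_change,
    phospho_sites_per_protein = phospho_sites_per_protein,
    phospho_detect_prob = phospho_detect_prob,
    phospho_score_high_prob = phospho_score_high_prob,
    protein_detect_prob = protein_detect_prob,
    max_missed_cleavages = max_missed_cleavages,
    seed = seed
  )
  if (!is.null(preset)) {
    path <- if (file.exists(preset)) preset else
      system.file("extdata", "presets", paste0(preset, ".yaml"),
                  package = "silamdyn")
    if (!nzchar(path) || !file.exists(path)) stop("unknown preset: ", preset)
    pv <- yaml::read_yaml(path)
    for (nm in names(pv)) {
      v <- pv[[nm]]
      cfg[[nm]] <- if (is.list(v)) unlist(v) else v
    }
    # explicit arguments win over preset values
    supplied <- names(match.call())[-1]
    supplied <- setdiff(supplied, "preset")
    for (nm in supplied) cfg[[nm]] <- get(nm)
  }
  validate_synthetic_config(structure(cfg, class = "synthetic_config"))
}

#' Validate a synthetic_config
#' @param cfg A `synthetic_config` list.
#' @return `cfg`, or an error.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_proteins >= 1, cfg$n_animals >= 1,
            length(cfg$protein_length_range) == 2,
            cfg$protein_length_range[1] >= 20,
            diff(cfg$protein_length_range) >= 0,
            cfg$sc_mean > 0, cfg$sc_dispersion > 0,
            cfg$max_missed_cleavages >= 0,
            cfg$n_peptides_per_protein >= 1)
  probs <- c(cfg$protein_label_prob, cfg$peptide_label_prob,
             cfg$peptidome_label_rate, cfg$endogenous_cleavage_prob,
             cfg$fraction_modulated, cfg$phospho_sites_per_protein,
             cfg$phospho_detect_prob, cfg$phospho_score_high_prob,
             cfg$protein_detect_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(cfg$nsp_fold_change) <= 0) stop("nsp_fold_change must be positive")
  bad <- !cfg$conditions %in% c("Control", "LPS")
  if (any(bad)) stop("unknown condition: ", cfg$conditions[bad][1])
  bad <- !cfg$layers %in% c("GC", "EC", "SMC")
  if (any(bad)) stop("unknown layer: ", cfg$layers[bad][1])
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Resolve a scalar / per-condition / per-group parameter for one group.
.group_param <- function(p, condition, layer) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  key <- paste(condition, layer, sep = ":")
  if (!is.null(names(p))) {
    if (key %in% names(p)) return(unname(p[[key]]))
    if (condition %in% names(p)) return(unname(p[[condition]]))
  }
  if (length(p) == 1L) return(unname(p[[1]]))
  stop("cannot resolve parameter for group ", key)
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a random protein database
#'
#' Random sequences over the 20 canonical residues at roughly mammalian
#' frequencies (K+R about 15%), Met-initiated, with lengths uniform in the
#' configured range. Every protein is guaranteed to yield at least two
#' tryptic peptides of usable length (rejection sampling against
#' [digest()]). Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A protein data.frame (`accession`, `description`, `sequence`).
#' @export
generate_proteome <- function(config) {
  config <- validate_synthetic_config(config)
  with_local_seed(config$seed, .generate_proteome_impl(config))
}

.generate_proteome_impl <- function(config) {
  n <- config$n_proteins
  lr <- config$protein_length_range
  plr <- config$peptide_length_range
  aas <- names(AA_FREQS)
  freqs <- AA_FREQS / sum(AA_FREQS)
  width <- max(3L, nchar(as.character(n)))
  seqs <- character(n)
  for (i in seq_len(n)) {
    repeat {
      L <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
      s <- paste0("M", paste(sample(aas, L - 1L, replace = TRUE, prob = freqs),
                             collapse = ""))
      dg <- digest(s, config$max_missed_cleavages)
      len <- nchar(dg$peptide)
      if (sum(len >= plr[1] & len <= plr[2]) >= 2L) break
    }
    seqs[i] <- s
  }
  data.frame(
    accession = sprintf(paste0("SYN%0", width, "d"), seq_len(n)),
    description = sprintf("synthetic protein %d", seq_len(n)),
    sequence = seqs, stringsAsFactors = FALSE
  )
}

#' Generate synthetic PSM tables with ground truth
#'
#' Emulates post-search PSM tables for the configured design: per protein, a
#' fixed panel of tryptic peptides is sampled from the in-silico digest;
#' per group, pool proteins get Bernoulli Lys(6) labeling of K-containing
#' peptides (fixed across animals of the group); per animal, spectral counts
#' are drawn from a negative binomial (zeros drop the observation);
#' endogenous cleavage injects semi-tryptic fragments; candidate
#' phosphosites are observed per animal with condition-specific
#' probabilities and localization scores; modulated proteins have their
#' labeled-count means scaled by `nsp_fold_change` under LPS. The returned
#' truth is sufficient to recompute every generator-level quantity the
#' pipeline estimates.
#'
#' @param config A [synthetic_config()].
#' @param proteome Optional protein table; generated from `config` when
#'   `NULL`.
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `design.tsv`, `psms.tsv` and `truth.json`.
#' @return A list with `proteome`, `design`, `psms`, `truth` (and `paths`
#'   when `out_dir` is given).
#' @export
generate_psm_tables <- function(config, proteome = NULL, out_dir = NULL) {
  config <- validate_synthetic_config(config)
  res <- with_local_seed(config$seed, {
    if (is.null(proteome)) proteome <- .generate_proteome_impl(config)
    .generate_psms_impl(config, proteome)
  })
  res$proteome <- if (is.null(proteome)) res$proteome else proteome
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      fasta = write_fasta(res$proteome, file.path(out_dir, "proteins.fasta")),
      design = write_tsv(res$design, file.path(out_dir, "design.tsv")),
      psms = write_tsv(res$psms, file.path(out_dir, "psms.tsv"))
    )
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(res$truth, tp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths["truth"] <- tp
    res$paths <- paths
  }
  res
}

.generate_psms_impl <- function(config, proteome) {
  plr <- config$peptide_length_range
  size <- 1 / config$sc_dispersion
  n_prot <- nrow(proteome)

  # fixed per-protein peptide panels from the tryptic digest
  panels <- vector("list", n_prot)
  for (i in seq_len(n_prot)) {
    dg <- digest(proteome$sequence[i], config$max_missed_cleavages)
    len <- nchar(dg$peptide)
    dg <- dg[len >= plr[1] & len <= plr[2], , drop = FALSE]
    dg <- dg[!duplicated(dg$peptide), , drop = FALSE]
    k <- min(nrow(dg), config$n_peptides_per_protein)
    dg <- dg[sort(sample.int(nrow(dg), k)), , drop = FALSE]
    dg$accession <- proteome$accession[i]
    dg$has_k <- grepl("K", dg$peptide, fixed = TRUE)
    panels[[i]] <- dg
  }
  panel <- do.call(rbind, panels)
  rownames(panel) <- NULL
  upep <- !duplicated(panel$peptide)
  f_k <- sum(panel$has_k[upep]) / sum(upep)

  # design: each animal of a condition contributes every layer
  design <- do.call(rbind, lapply(config$conditions, function(cond) {
    off <- if (cond == "Control") 0L else config$n_animals
    do.call(rbind, lapply(config$layers, function(ly) {
      a <- seq_len(config$n_animals) + off
      data.frame(sample_id = sprintf("%s_%s_a%d", ly, cond, a),
                 condition = cond, layer = ly,
                 animal_id = sprintf("a%d", a), stringsAsFactors = FALSE)
    }))
  }))
  rownames(design) <- NULL

  # modulated proteins (shared across layers, applied under LPS)
  modulated <- proteome$accession[
    runif(n_prot) < config$fraction_modulated]

  # phospho candidate sites: one covered S/T/Y site per selected protein
  phospho_sites <- list()
  sel <- which(runif(n_prot) < config$phospho_sites_per_protein)
  for (i in sel) {
    pp <- panels[[i]]
    cand <- list()
    for (j in seq_len(nrow(pp))) {
      hits <- gregexpr("[STY]", pp$peptide[j])[[1]]
      if (hits[1] == -1L) next
      cand[[length(cand) + 1L]] <- data.frame(
        peptide = pp$peptide[j], start = pp$start[j],
        offset = as.integer(hits), stringsAsFactors = FALSE)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    res_letter <- substring(pick$peptide, pick$offset, pick$offset)
    phospho_sites[[length(phospho_sites) + 1L]] <- data.frame(
      accession = proteome$accession[i], peptide = pick$peptide,
      peptide_offset = pick$offset,
      position = pick$start + pick$offset - 1L,
      residue = res_letter, stringsAsFactors = FALSE)
  }
  phospho_sites <- if (length(phospho_sites)) do.call(rbind, phospho_sites) else NULL

  psm_rows <- list()
  truth_groups <- list()
  phospho_truth <- list()

  for (ly in config$layers) {
   # latent per-layer synthesis propensities, shared by both conditions so
   # that the LPS pool nests inside the Control pool (suppression, not
   # reshuffling) and the same peptides carry the label in both conditions
   u_prot <- runif(n_prot)
   u_pep <- runif(nrow(panel))
   for (cond in config$conditions) {
    gkey <- group_key(cond, ly)
    samples <- design[design$condition == cond & design$layer == ly, ]

    # pool membership and per-peptide labeling, fixed within the group
    if (is.null(config$peptidome_label_rate)) {
      p_pool <- .group_param(config$protein_label_prob, cond, ly)
      pool <- u_prot < p_pool
      pool_by_acc <- setNames(pool, proteome$accession)
      q <- config$peptide_label_prob
      labeled_pep <- panel$has_k & pool_by_acc[panel$accession] & u_pep < q
    } else {
      q <- config$peptidome_label_rate / f_k
      if (q > 1) stop("peptidome_label_rate ", config$peptidome_label_rate,
                      " not achievable: K-containing fraction is ",
                      signif(f_k, 3))
      pool_by_acc <- setNames(rep(TRUE, n_prot), proteome$accession)
      labeled_pep <- panel$has_k & u_pep < q
    }

    # semi-tryptic fragments from endogenous cleavage, fixed within group
    p_clv <- .group_param(config$endogenous_cleavage_prob, cond, ly)
    frag <- .make_fragments(panel, proteome, which(runif(n_prot) < p_clv))

    # per-peptide count means; labeled peptides of modulated proteins are
    # scaled under LPS
    mu <- rep(config$sc_mean, nrow(panel))
    if (cond == "LPS") {
      hit <- labeled_pep & panel$accession %in% modulated
      mu[hit] <- mu[hit] * config$nsp_fold_change
    }
    mods <- rep("", nrow(panel))
    if (any(labeled_pep)) {
      mods[labeled_pep] <- vapply(panel$peptide[labeled_pep], function(p) {
        kpos <- as.integer(gregexpr("K", p, fixed = TRUE)[[1]])
        paste(sprintf("%d:K(+6.02)", kpos), collapse = ";")
      }, character(1), USE.NAMES = FALSE)
    }

    for (s in seq_len(nrow(samples))) {
      sid <- samples$sample_id[s]
      present <- if (config$protein_detect_prob >= 1) rep(TRUE, n_prot) else
        runif(n_prot) < config$protein_detect_prob
      present_by_acc <- setNames(present, proteome$accession)
      ok <- present_by_acc[panel$accession]
      counts <- rnbinom(nrow(panel), mu = mu, size = size)
      keep <- ok & counts > 0L
      if (any(keep)) {
        psm_rows[[length(psm_rows) + 1L]] <- data.frame(
          sample_id = sid, peptide = panel$peptide[keep],
          modifications = mods[keep], proteins = panel$accession[keep],
          spectral_count = counts[keep], stringsAsFactors = FALSE)
      }
      if (!is.null(frag) && nrow(frag)) {
        fok <- present_by_acc[frag$accession]
        fc <- rnbinom(nrow(frag), mu = config$sc_mean, size = size)
        fkeep <- fok & fc > 0L
        if (any(fkeep)) {
          psm_rows[[length(psm_rows) + 1L]] <- data.frame(
            sample_id = sid, peptide = frag$peptide[fkeep],
            modifications = "", proteins = frag$accession[fkeep],
            spectral_count = fc[fkeep], stringsAsFactors = FALSE)
        }
      }
      if (!is.null(phospho_sites) && nrow(phospho_sites)) {
        p_det <- .group_param(config$phospho_detect_prob, cond, ly)
        det <- runif(nrow(phospho_sites)) < p_det
        det <- det & present_by_acc[phospho_sites$accession]
        if (any(det)) {
          ph <- phospho_sites[det, , drop = FALSE]
          score <- ifelse(runif(nrow(ph)) < config$phospho_score_high_prob,
                          1000, floor(runif(nrow(ph), 200, 1000)))
          pc <- pmax(1L, rnbinom(nrow(ph), mu = config$sc_mean, size = size))
          psm_rows[[length(psm_rows) + 1L]] <- data.frame(
            sample_id = sid, peptide = ph$peptide,
            modifications = sprintf("%d:%s(+79.97)@%d", ph$peptide_offset,
                                    ph$residue, as.integer(score)),
            proteins = ph$accession, spectral_count = pc,
            stringsAsFactors = FALSE)
          phospho_truth[[length(phospho_truth) + 1L]] <- data.frame(
            sample_id = sid, condition = cond, layer = ly,
            accession = ph$accession, position = ph$position,
            residue = ph$residue, score = as.numeric(score),
            stringsAsFactors = FALSE)
        }
      }
    }

    truth_groups[[gkey]] <- list(
      condition = cond, layer = ly,
      labeled_proteins = proteome$accession[pool_by_acc[proteome$accession]],
      n_labeled_peptides = sum(labeled_pep),
      endogenous_cleavage_prob = p_clv,
      n_fragments = if (is.null(frag)) 0L else nrow(frag)
    )
   }
  }

  psms <- do.call(rbind, psm_rows)
  rownames(psms) <- NULL
  psms <- psms[order(psms$sample_id, psms$proteins, psms$peptide,
                     psms$modifications), ]
  rownames(psms) <- NULL

  truth <- list(
    config = unclass(config),
    peptide_universe = sum(!duplicated(panel$peptide)),
    k_containing_fraction = f_k,
    modulated_proteins = modulated,
    nsp_fold_change = config$nsp_fold_change,
    groups = truth_groups,
    phospho_observations = if (length(phospho_truth))
      do.call(rbind, phospho_truth) else NULL
  )
  list(proteome = proteome, design = design, psms = psms, truth = truth)
}

# Build one semi-tryptic fragment per selected protein by truncating a
# sampled tryptic peptide at an internal, non-tryptic position. Fragments
# are verified against the parent sequence to classify semi-tryptic.
.make_fragments <- function(panel, proteome, protein_idx) {
  if (!length(protein_idx)) return(NULL)
  out <- list()
  for (i in protein_idx) {
    acc <- proteome$accession[i]
    prot <- proteome$sequence[i]
    pp <- panel[panel$accession == acc, , drop = FALSE]
    pp <- pp[nchar(pp$peptide) >= 8L, , drop = FALSE]
    if (!nrow(pp)) next
    done <- FALSE
    for (try in 1:10) {
      j <- sample.int(nrow(pp), 1L)
      s <- pp$start[j]; e <- pp$end[j]
      side <- sample(c("N", "C"), 1L)
      if (side == "N") {
        c_end <- sample((s + 5L):(e - 1L), 1L)
        fs <- s; fe <- c_end
      } else {
        c_start <- sample((s + 1L):(e - 5L), 1L)
        fs <- c_start; fe <- e
      }
      fragment <- substring(prot, fs, fe)
      cl <- classify_specificity(fragment, prot)
      if (cl$specificity == "semi_tryptic") {
        out[[length(out) + 1L]] <- data.frame(
          accession = acc, peptide = fragment, start = fs, end = fe,
          stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
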