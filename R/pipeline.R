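#' Pipeline run configuration
#'
#' Bundles input paths, analysis thresholds and policy switches. Thresholds
#' default to the study conventions: regulation fold 1.5, p 0.05,
#' localization score (Ascore) 1000, consistency across at least 2 animals,
#' digestion depth 2 missed cleavages.
#'
#' @param fasta,psms,design Input file paths (FASTA database, PSM TSV,
#'   design TSV). May be `NULL` when calling [proteome_dynamics()] on
#'   in-memory tables.
#' @param out_dir Output directory for [run_pipeline()].
#' @param p_threshold,fold_threshold,ascore_threshold,min_animals,max_missed_cleavages
#'   Analysis thresholds.
#' @param shared_peptides `"unique"` or `"all"` (see [aggregate_counts()]).
#' @param turnover_include `"semi_or_non"` or `"non_only"` (see
#'   [score_turnover()]).
#' @param var_equal Pooled-variance Student's t-test (default) or Welch.
#' @param seed Seed echoed into the run report (the analysis itself is
#'   deterministic).
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(fasta = NULL, psms = NULL, design = NULL,
                       out_dir = NULL,
                       p_threshold = 0.05, fold_threshold = 1.5,
                       ascore_threshold = 1000, min_animals = 2,
                       max_missed_cleavages = 2,
                       shared_peptides = c("unique", "all"),
                       turnover_include = c("semi_or_non", "non_only"),
                       var_equal = TRUE, seed = 1L) {
  cfg <- list(
    fasta = fasta, psms = psms, design = design, out_dir = out_dir,
    p_threshold = p_threshold, fold_threshold = fold_threshold,
    ascore_threshold = ascore_threshold, min_animals = as.integer(min_animals),
    max_missed_cleavages = as.integer(max_missed_cleavages),
    shared_peptides = match.arg(shared_peptides),
    turnover_include = match.arg(turnover_include),
    var_equal = isTRUE(var_equal), seed = as.integer(seed)
  )
  if (any(c(cfg$p_threshold, cfg$fold_threshold, cfg$ascore_threshold,
            cfg$min_animals) <= 0)) {
    stop("thresholds must be positive")
  }
  for (f in c("fasta", "psms", "design")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config error: ", f, " path not found: ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("config error: unknown key ", unknown[1])
  do.call(run_config, vals)
}

#' Full proteome-dynamics analysis of a PSM dataset
#'
#' The central analysis: classifies every PSM for Lys(6) label and trypsin
#' terminal specificity, then derives (i) per-protein incorporation profiles
#' and per-group labeled proteome/peptidome fractions, (ii) per-protein
#' newly-synthesized vs pre-existing spectral counts with LPS/Control
#' ratios, Student's t-tests, regulation and exclusive-synthesis calls per
#' layer, (iii) turnover scores from non-tryptic peptide evidence with
#' endogenous cleavage-site mapping, and (iv) phosphosite aggregation with
#' disease-specific (LPS-only) calls. Identical inputs give identical
#' results; all randomness lives in the synthetic generator.
#'
#' @param psms PSM data.frame ([read_psm_table()]).
#' @param design Design data.frame ([read_design()]).
#' @param proteins Protein data.frame ([read_fasta()]).
#' @param config A [run_config()] carrying thresholds and policies.
#' @param annotation Optional accession-to-gene map for phospho output.
#' @return An object of class `"proteome_dynamics"`: a list with elements
#'   `classified`, `profiles`, `proteome_fractions`, `peptidome_fractions`,
#'   `counts`, `regulation`, `turnover`, `turnover_mat`, `cleavage_sites`,
#'   `phospho_sites`, `phospho_counts`, `phospho_calls`, `config`, `report`.
#' @export
#' @examples
#' sim <- generate_psm_tables(synthetic_config(
#'   n_proteins = 20, layers = "EC", seed = 7))
#' fit <- proteome_dynamics(sim$psms, sim$design, sim$proteome)
#' fit
proteome_dynamics <- function(psms, design, proteins,
                              config = run_config(), annotation = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- validate_design(design)
  warnings <- character(0)

  classified <- classify_psms(psms, proteins, design)
  n_unmapped <- sum(classified$specificity == "unmapped")
  n_shared <- sum(classified$n_proteins > 1L &
                    classified$specificity != "unmapped")
  if (n_unmapped > 0) {
    warnings <- c(warnings, sprintf("%d PSMs unmapped to any claimed protein",
                                    n_unmapped))
  }

  profiles <- incorporation_profiles(classified, config$min_animals)
  groups <- unique(design[, c("condition", "layer")])
  proteome_fractions <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    pf <- labeled_proteome_fraction(classified, groups$condition[i],
                                    groups$layer[i], config$min_animals)
    data.frame(condition = groups$condition[i], layer = groups$layer[i],
               fraction = pf$fraction, n_labeled = pf$n_labeled,
               n_detected = pf$n_detected, per_animal_mean = pf$mean,
               per_animal_sd = pf$sd, stringsAsFactors = FALSE)
  }))
  peptidome_fractions <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    pf <- labeled_peptidome_fraction(classified, groups$condition[i],
                                     groups$layer[i])
    data.frame(condition = groups$condition[i], layer = groups$layer[i],
               fraction = pf$fraction, fraction_sc = pf$fraction_sc,
               n_labeled = pf$n_labeled, n_peptides = pf$n_peptides,
               stringsAsFactors = FALSE)
  }))

  counts <- aggregate_counts(classified, design, config$shared_peptides)
  both_conditions <- all(c("Control", "LPS") %in% design$condition)
  regulation <- if (both_conditions) {
    do.call(rbind, lapply(sort(unique(design$layer)), function(ly) {
      compute_ratios(counts, ly, config$min_animals, config$fold_threshold,
                     config$p_threshold, config$var_equal)
    }))
  } else NULL

  turnover <- score_turnover(classified, design, config$turnover_include,
                             config$shared_peptides)
  turnover_mat <- turnover_matrix(turnover)
  cleavage <- map_cleavage_sites(classified)

  phospho_sites <- collect_sites(classified, proteins, config$ascore_threshold)
  phospho_counts <- count_sites_per_group(phospho_sites, design)
  phospho_calls <- call_disease_specific(phospho_sites, design, proteins,
                                         annotation)

  n_attributed <- sum(!is.na(classified$accession) &
                        (config$shared_peptides == "all" |
                           classified$n_proteins == 1L))
  report <- list(
    package = "silamdyn",
    version = as.character(utils::packageVersion("silamdyn")),
    config = unclass(config),
    stages = list(
      ingest = list(n_psms = nrow(psms), n_samples = length(unique(psms$sample_id)),
                    n_proteins_db = nrow(proteins)),
      classify = list(n_classified = nrow(classified),
                      n_unmapped = n_unmapped, n_shared = n_shared,
                      n_attributed = n_attributed,
                      n_dropped = nrow(classified) - n_attributed,
                      drop_reasons = list(
                        unmapped = n_unmapped,
                        shared_peptide_policy =
                          if (config$shared_peptides == "unique") n_shared else 0L)),
      labeling = list(n_profiles = nrow(profiles)),
      dynamics = list(n_tested = if (is.null(regulation)) 0L else
        sum(!is.na(regulation$p_value_nsp)),
        n_regulated = if (is.null(regulation)) 0L else
          sum(regulation$call %in% c("up", "down")),
        n_exclusive = if (is.null(regulation)) 0L else
          sum(grepl("^exclusive", regulation$call))),
      turnover = list(n_proteins = nrow(turnover_mat),
                      n_cleavage_sites = nrow(cleavage)),
      phospho = list(n_sites = nrow(phospho_sites),
                     n_disease_specific = sum(phospho_calls$disease_specific))
    ),
    warnings = warnings
  )

  structure(list(
    classified = classified, profiles = profiles,
    proteome_fractions = proteome_fractions,
    peptidome_fractions = peptidome_fractions,
    counts = counts, regulation = regulation,
    turnover = turnover, turnover_mat = turnover_mat,
    cleavage_sites = cleavage,
    phospho_sites = phospho_sites, phospho_counts = phospho_counts,
    phospho_calls = phospho_calls,
    config = config, report = report
  ), class = "proteome_dynamics")
}

#' Run the pipeline end-to-end from files
#'
#' Reads the configured FASTA, PSM and design files, runs
#' [proteome_dynamics()], and writes every result table plus a JSON run
#' report to `config$out_dir`. Identical config and inputs produce
#' byte-identical outputs.
#'
#' @param config A [run_config()] with `fasta`, `psms`, `design` and
#'   `out_dir` set.
#' @param annotation Optional accession-to-gene map.
#' @return The `proteome_dynamics` object, invisibly, with an added
#'   `paths` element.
#' @export
run_pipeline <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("fasta", "psms", "design", "out_dir")) {
    if (is.null(config[[f]])) stop("config error: ", f, " is required")
  }
  stage <- "ingest"
  res <- tryCatch({
    proteins <- read_fasta(config$fasta)
    design <- read_design(config$design)
    psms <- read_psm_table(config$psms, design)
    stage <- "analysis"
    fit <- proteome_dynamics(psms, design, proteins, config, annotation)
    stage <- "write"
    fit$paths <- write_pipeline_results(fit, config$out_dir)
    fit
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Write all result tables of a proteome_dynamics object
#'
#' @param fit A `proteome_dynamics` object.
#' @param out_dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_pipeline_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "proteome_dynamics"))
  tm <- fit$turnover_mat
  tm_df <- data.frame(accession = rownames(tm), as.data.frame(tm),
                      check.names = FALSE, stringsAsFactors = FALSE)
  reg <- call_regulation(if (is.null(fit$regulation)) {
    compute_ratios(fit$counts, "EC")[0, ]
  } else fit$regulation)
  tables <- list(
    dynamics = fit$profiles,
    proteome_fractions = fit$proteome_fractions,
    peptidome_fractions = fit$peptidome_fractions,
    regulation = if (is.null(fit$regulation)) reg$regulated[0, ] else fit$regulation,
    regulated = reg$regulated,
    exclusive = reg$exclusive,
    turnover_matrix = tm_df,
    cleavage_sites = fit$cleavage_sites,
    phosphosites = fit$phospho_calls
  )
  write_results(tables, out_dir, summary = fit$report)
}

#' @export
print.proteome_dynamics <- function(x, ...) {
  cat("Proteome dynamics analysis (silamdyn)\n")
  cat(sprintf("  PSMs: %d in %d samples; proteins with profiles: %d\n",
              nrow(x$classified), length(unique(x$classified$sample_id)),
              length(unique(x$profiles$accession))))
  pf <- x$proteome_fractions
  for (i in seq_len(nrow(pf))) {
    cat(sprintf("  %s %s: labeled proteome %.1f%% (%d/%d)\n",
                pf$layer[i], pf$condition[i], 100 * pf$fraction[i],
                pf$n_labeled[i], pf$n_detected[i]))
  }
  if (!is.null(x$regulation)) {
    cat(sprintf("  Regulated proteins (|fold| >= %.2g, p <= %.2g): %d; exclusive: %d\n",
                x$config$fold_threshold, x$config$p_threshold,
                sum(x$regulation$call %in% c("up", "down")),
                sum(grepl("^exclusive", x$regulation$call))))
  }
  ds <- x$phospho_calls[x$phospho_calls$disease_specific, , drop = FALSE]
  cat(sprintf("  Turnover: %d proteins with non-tryptic evidence; phosphosites: %d (%d disease-specific site calls)\n",
              nrow(x$turnover_mat), nrow(x$phospho_sites),
              length(unique(paste(ds$accession, ds$position, ds$layer)))))
  invisible(x)
}

#' @export
summary.proteome_dynamics <- function(object, ...) {
  out <- list(
    proteome_fractions = object$proteome_fractions,
    peptidome_fractions = object$peptidome_fractions,
    regulation_calls = if (is.null(object$regulation)) NULL else
      table(object$regulation$layer, object$regulation$call),
    phospho_tests = object$phospho_counts$tests,
    report = object$report
  )
  class(out) <- "summary.proteome_dynamics"
  out
}

#' @export
print.summary.proteome_dynamics <- function(x, ...) {
  cat("Labeled proteome fractions:\n")
  print(x$proteome_fractions, row.names = FALSE)
  cat("\nLabeled peptidome fractions:\n")
  print(x$peptidome_fractions, row.names = FALSE)
  if (!is.null(x$regulation_calls)) {
    cat("\nRegulation calls by layer:\n")
    print(x$regulation_calls)
  }
  if (!is.null(x$phospho_tests) && nrow(x$phospho_tests)) {
    cat("\nPhosphosite counts, LPS vs Control:\n")
    print(x$phospho_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Plot incorporation curves or the turnover heatmap
#'
#' `type = "incorporation"` draws the per-group cumulative frequency curves
#' of per-protein Lys(6) incorporation fractions; `type = "turnover"` an
#' image of the turnover matrix (darker = lower turnover).
#'
#' @param x A `proteome_dynamics` object.
#' @param type `"incorporation"` or `"turnover"`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.proteome_dynamics <- function(x, type = c("incorporation", "turnover"),
                                   ...) {
  type <- match.arg(type)
  if (type == "incorporation") {
    curves <- incorporation_distribution(x$profiles)
    grp <- unique(curves[, c("condition", "layer")])
    cols <- hcl.colors(max(nrow(grp), 2L), "Dark 3")
    plot(NA, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "Lys(6) incorporation fraction",
         ylab = "Cumulative frequency",
         main = "Incorporation of Lys(6) in individual proteins")
    for (i in seq_len(nrow(grp))) {
      sel <- curves$condition == grp$condition[i] & curves$layer == grp$layer[i]
      lines(c(0, curves$fraction[sel], 1),
            c(0, curves$cumulative[sel], 1), type = "s", col = cols[i], lwd = 2)
    }
    legend("bottomright", legend = paste(grp$layer, grp$condition),
           col = cols[seq_len(nrow(grp))], lwd = 2, bty = "n")
  } else {
    m <- x$turnover_mat
    if (nrow(m) == 0L) stop("no non-tryptic evidence to plot")
    image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
          col = hcl.colors(64, "YlOrRd", rev = TRUE), axes = FALSE,
          main = "Protein turnover (non-tryptic spectral counts)")
    axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
         las = 2, cex.axis = 0.7)
  }
  invisible(x)
}
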