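test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_proteins = 15, layers = "EC", seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_psm_tables(cfg, out_dir = d1)
  generate_psm_tables(cfg, out_dir = d2)
  for (f in c("proteins.fasta", "design.tsv", "psms.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_proteome(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated proteins respect the length range and digest usefully", {
  cfg <- synthetic_config(n_proteins = 25, protein_length_range = c(120, 250),
                          seed = 5)
  prot <- generate_proteome(cfg)
  len <- nchar(prot$sequence)
  expect_true(all(len >= 120 & len <= 250))
  expect_false(any(duplicated(prot$accession)))
  for (s in prot$sequence) {
    dg <- digest(s, 2)
    usable <- nchar(dg$peptide) >= 6 & nchar(dg$peptide) <= 30
    expect_gte(sum(usable), 2)
  }
})

test_that("degenerate probabilities produce degenerate data", {
  sim <- small_sim(seed = 8, n_proteins = 30, protein_label_prob = 0,
                   conditions = "Control")
  expect_false(any(grepl("6.02", sim$psms$modifications, fixed = TRUE)))

  sim <- small_sim(seed = 9, n_proteins = 30, endogenous_cleavage_prob = 0,
                   conditions = "Control")
  cl <- classify_psms(sim$psms, sim$proteome, sim$design)
  expect_equal(nrow(score_turnover(cl, sim$design)), 0L)
})

test_that("labeled peptides always contain lysine and fragments classify semi-tryptic", {
  sim <- small_sim(seed = 10, n_proteins = 50, conditions = "Control",
                   endogenous_cleavage_prob = 0.4)
  lab <- sim$psms[grepl("K(+6.02)", sim$psms$modifications, fixed = TRUE), ]
  expect_gt(nrow(lab), 0)
  expect_true(all(grepl("K", lab$peptide, fixed = TRUE)))
  cl <- classify_psms(sim$psms, sim$proteome, sim$design)
  injected <- cl[cl$specificity != "fully_tryptic" & cl$modifications == "", ]
  expect_gt(nrow(injected), 0)
  expect_true(all(injected$specificity == "semi_tryptic"))
})

test_that("ground truth suffices to recompute generator-level quantities", {
  sim <- small_sim(seed = 11, n_proteins = 60, conditions = "Control",
                   phospho_sites_per_protein = 0.5)
  tr <- sim$truth
  expect_equal(sort(names(tr$groups)), sort(paste0("Control:", "EC")))
  g <- tr$groups[["Control:EC"]]
  # true labeled fraction recomputable from the pool list
  expect_equal(length(g$labeled_proteins) / nrow(sim$proteome),
               length(g$labeled_proteins) / tr$config$n_proteins)
  expect_true(all(g$labeled_proteins %in% sim$proteome$accession))
  # phospho truth rows describe real S/T/Y residues of the database
  ph <- tr$phospho_observations
  if (!is.null(ph)) {
    seqs <- setNames(sim$proteome$sequence, sim$proteome$accession)
    at <- substring(seqs[ph$accession], ph$position, ph$position)
    expect_equal(at, ph$residue, ignore_attr = TRUE)
    expect_true(all(at %in% c("S", "T", "Y")))
  }
})

test_that("the peptidome-rate mode hits the requested marginal rate", {
  cfg <- synthetic_config(n_proteins = 60, conditions = "Control",
                          layers = "EC", peptidome_label_rate = 0.051,
                          seed = 12)
  sim <- generate_psm_tables(cfg)
  cl <- classify_psms(sim$psms, sim$proteome, sim$design)
  pf <- labeled_peptidome_fraction(cl, "Control", "EC")
  expect_lt(abs(pf$fraction - 0.051), 0.03)
})

test_that("presets load as data and explicit arguments win", {
  cfg <- synthetic_config(preset = "fig1_fractions")
  expect_equal(unname(cfg$protein_label_prob[["Control:EC"]]), 0.29)
  expect_equal(unname(cfg$protein_label_prob[["LPS:GC"]]), 0.16)
  cfg <- synthetic_config(preset = "null", n_proteins = 77)
  expect_equal(cfg$fraction_modulated, 0)
  expect_equal(cfg$n_proteins, 77)
  expect_error(synthetic_config(preset = "does-not-exist"), "unknown preset")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(protein_label_prob = 1.2), "probabilities")
  expect_error(synthetic_config(sc_mean = -1))
  expect_error(synthetic_config(conditions = "Sham"), "unknown condition")
})
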