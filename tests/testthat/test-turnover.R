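turnover_fixture <- function() {
  d <- make_design(n_animals = 2)
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MAKRLSTKPEASKLR", stringsAsFactors = FALSE)
  # STKPE (6-10) is semi-tryptic; MAK and RLSTKPE... use fully vs semi mix
  psms <- rbind(
    make_psm("EC_LPS_a3", "STKPE", "", "P1", 2),
    make_psm("EC_LPS_a4", "STKPE", "", "P1", 3),
    make_psm("EC_Control_a1", "MAK", "", "P1", 5)
  )
  list(cl = classify_psms(psms, prot, d), design = d, prot = prot)
}

test_that("turnover scores sum non-tryptic spectral counts per group", {
  tf <- turnover_fixture()
  sc <- score_turnover(tf$cl, tf$design)
  lps <- sc[sc$condition == "LPS", ]
  expect_equal(lps$nontryptic_sc, 5L)      # 2 + 3 across animals
  expect_equal(lps$nontryptic_distinct, 1L)
  # protein present with zero evidence in the other group, not omitted
  ctl <- sc[sc$condition == "Control", ]
  expect_equal(ctl$nontryptic_sc, 0L)
})

test_that("fully tryptic evidence never contributes to turnover", {
  d <- make_design(conditions = "Control", n_animals = 2)
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MAKRLSTKPE", stringsAsFactors = FALSE)
  cl <- classify_psms(make_psm("EC_Control_a1", "LSTKPE", "", "P1", 7), prot, d)
  expect_equal(nrow(score_turnover(cl, d)), 0L)
})

test_that("turnover matrix is ordered, conservative, and input-order invariant", {
  tf <- turnover_fixture()
  sc <- score_turnover(tf$cl, tf$design)
  m <- turnover_matrix(sc)
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(unname(m["P1", "LPS:EC"]), 5)
  expect_equal(unname(m["P1", "Control:EC"]), 0)
  # column sums equal the groupwise totals
  for (g in colnames(m)) {
    cond <- strsplit(g, ":")[[1]][1]
    expect_equal(sum(m[, g]),
                 sum(sc$nontryptic_sc[sc$condition == cond]))
  }
  # permuting the PSM rows leaves the matrix unchanged
  cl2 <- tf$cl[rev(seq_len(nrow(tf$cl))), ]
  expect_identical(turnover_matrix(score_turnover(cl2, tf$design)), m)
})

test_that("turnover is invariant under relabeling of animal ids", {
  tf <- turnover_fixture()
  cl2 <- tf$cl
  d2 <- tf$design
  relabel <- c(a1 = "x1", a2 = "x2", a3 = "x3", a4 = "x4")
  cl2$animal_id <- unname(relabel[cl2$animal_id])
  d2$animal_id <- unname(relabel[d2$animal_id])
  expect_identical(turnover_matrix(score_turnover(cl2, d2)),
                   turnover_matrix(score_turnover(tf$cl, tf$design)))
})

test_that("cleavage sites map to the residue preceding a non-tryptic N-terminus", {
  d <- make_design(conditions = "Control", n_animals = 2)
  # STKPE starts at position 6, so the endogenous cut is after residue 5
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MAKRLSTKPEASKLR", stringsAsFactors = FALSE)
  psms <- rbind(
    make_psm("EC_Control_a1", "STKPE", "", "P1", 2),
    make_psm("EC_Control_a2", "STKPE", "", "P1", 1),
    make_psm("EC_Control_a1", "MAK", "", "P1", 5)   # fully tryptic: no site
  )
  cl <- classify_psms(psms, prot, d)
  sites <- map_cleavage_sites(cl)
  nsite <- sites[sites$side == "N", ]
  expect_equal(nsite$position, 5L)
  expect_equal(nsite$n_peptides, 1L)       # two PSMs of one peptide: one site
  expect_equal(nsite$spectral_count, 3L)
  # STKPE ends at 10 followed by A11, a non-tryptic C-terminus at 10
  csite <- sites[sites$side == "C", ]
  expect_equal(csite$position, 10L)
  expect_true(all(sites$position >= 1 & sites$position <= nchar(prot$sequence)))
})

test_that("turnover peptides are never products of the in-silico digest", {
  sim <- small_sim(seed = 650, n_proteins = 60, conditions = "Control",
                   endogenous_cleavage_prob = 0.5)
  cl <- classify_psms(sim$psms, sim$proteome, sim$design)
  hits <- cl[cl$nontryptic & !is.na(cl$accession), ]
  expect_gt(nrow(hits), 0)
  seqs <- setNames(sim$proteome$sequence, sim$proteome$accession)
  for (i in seq_len(nrow(hits))) {
    dg <- digest(seqs[[hits$accession[i]]], 2)
    expect_false(hits$peptide[i] %in% dg$peptide)
  }
})

test_that("mean turnover score increases with the endogenous cleavage rate", {
  mean_score <- function(p, seed) {
    sim <- small_sim(seed = seed, n_proteins = 60, conditions = "Control",
                     endogenous_cleavage_prob = p)
    cl <- classify_psms(sim$psms, sim$proteome, sim$design)
    sc <- score_turnover(cl, sim$design)
    sum(sc$nontryptic_sc) / nrow(sim$proteome)
  }
  wins <- sapply(1:5, function(s) {
    mean_score(0.2, 700 + s) > mean_score(0.02, 700 + s)
  })
  expect_true(all(wins))
})
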