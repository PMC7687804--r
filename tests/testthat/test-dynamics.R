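toy_classified <- function() {
  d <- make_design(n_animals = 3)
  psms <- rbind(
    make_psm("EC_Control_a1", "ASKLR", "3:K(+6.02)", "P1", 2),
    make_psm("EC_Control_a1", "ASKLR", "", "P1", 4),
    make_psm("EC_Control_a1", "LSTKPE", "4:K(+6.02)", "P1", 1),
    make_psm("EC_Control_a2", "ASKLR", "", "P1", 5),
    make_psm("EC_LPS_a4", "ASKLR", "3:K(+6.02)", "P1", 1),
    make_psm("EC_LPS_a5", "ASKLR", "", "P1", 2)
  )
  prot <- data.frame(accession = c("P1", "P2"), description = "",
                     sequence = c("MAKRLSTKPEASKLR", "MWWWKASKLR"),
                     stringsAsFactors = FALSE)
  list(cl = classify_psms(psms, prot, d), design = d)
}

test_that("aggregate_counts sums per animal and zero-fills missing animals", {
  tc <- toy_classified()
  counts <- aggregate_counts(tc$cl, tc$design)
  a1 <- counts[counts$animal_id == "a1" & counts$condition == "Control", ]
  expect_equal(a1$nsp_sc, 3L)   # labeled: 2 + 1
  expect_equal(a1$nnsp_sc, 4L)
  a3 <- counts[counts$animal_id == "a3" & counts$condition == "Control", ]
  expect_equal(a3$nsp_sc, 0L)   # zero-filled animal
  expect_equal(a3$nnsp_sc, 0L)
  # conservation: nsp + nnsp equals the protein's total spectral counts
  expect_equal(sum(counts$nsp_sc + counts$nnsp_sc),
               sum(tc$cl$spectral_count))
})

test_that("shared peptides are excluded under the unique-only policy", {
  d <- make_design(conditions = "Control", n_animals = 2)
  psms <- make_psm("EC_Control_a1", "ASKLR", "", "P1;P2", 3)
  prot <- data.frame(accession = c("P1", "P2"), description = "",
                     sequence = c("MAKRLSTKPEASKLR", "MWWWKASKLR"),
                     stringsAsFactors = FALSE)
  cl <- classify_psms(psms, prot, d)
  expect_equal(cl$n_proteins, 2L)
  expect_equal(nrow(aggregate_counts(cl, d, "unique")), 0L)
  all_counts <- aggregate_counts(cl, d, "all")
  expect_equal(sum(all_counts$nnsp_sc), 3L)
})

test_that("the per-protein t-test matches the closed-form Student statistic", {
  # hand oracle: means 11 vs 2, pooled s^2 = 1, t = 9 / sqrt(2/3), df = 4
  t_hand <- 9 / sqrt(2 / 3)
  p_hand <- 2 * pt(-t_hand, df = 4)
  expect_equal(test_protein(c(10, 11, 12), c(2, 1, 3)), p_hand)
  expect_lt(test_protein(c(10, 11, 12), c(2, 1, 3)), 0.05)
  # identical constant groups: no evidence at all
  expect_equal(test_protein(c(3, 3, 3), c(3, 3, 3)), 1)
  # one animal is not testable
  expect_true(is.na(test_protein(5, c(1, 2))))
})

test_that("ratios pool counts across animals and handle N.D. categorically", {
  tc <- toy_classified()
  counts <- aggregate_counts(tc$cl, tc$design)
  reg <- compute_ratios(counts, "EC")
  expect_equal(reg$nsp_ratio, 1 / 3)       # LPS 1 vs Control 3
  expect_equal(reg$nnsp_ratio, 2 / 9)
  # symmetry under group swap: swap condition labels and compare
  swapped <- counts
  swapped$condition <- ifelse(counts$condition == "LPS", "Control", "LPS")
  reg2 <- compute_ratios(swapped, "EC")
  expect_equal(reg2$nsp_ratio, 1 / reg$nsp_ratio)

  # zero Control nsp with nonzero LPS nsp is exclusive, never infinite
  d <- make_design(n_animals = 2)
  psms <- rbind(
    make_psm("EC_LPS_a3", "ASKLR", "3:K(+6.02)", "P1", 2),
    make_psm("EC_LPS_a4", "ASKLR", "3:K(+6.02)", "P1", 2),
    make_psm("EC_Control_a1", "LSTKPE", "", "P1", 1),
    make_psm("EC_Control_a2", "LSTKPE", "", "P1", 1)
  )
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MAKRLSTKPEASKLR", stringsAsFactors = FALSE)
  cl <- classify_psms(psms, prot, d)
  reg <- compute_ratios(aggregate_counts(cl, d), "EC")
  expect_equal(reg$call, "exclusive_LPS")
  expect_true(is.na(reg$nsp_ratio))

  # identical groups: ratio 1, unchanged
  psms <- rbind(
    make_psm("EC_LPS_a3", "ASKLR", "3:K(+6.02)", "P1", 2),
    make_psm("EC_LPS_a4", "ASKLR", "3:K(+6.02)", "P1", 3),
    make_psm("EC_Control_a1", "ASKLR", "3:K(+6.02)", "P1", 2),
    make_psm("EC_Control_a2", "ASKLR", "3:K(+6.02)", "P1", 3)
  )
  cl <- classify_psms(psms, prot, d)
  reg <- compute_ratios(aggregate_counts(cl, d), "EC")
  expect_equal(reg$nsp_ratio, 1)
  expect_equal(reg$call, "unchanged")
})

test_that("regulation calls require both the fold and the p threshold", {
  base <- data.frame(
    accession = c("A", "B", "C"), layer = "EC",
    nsp_lps_sc = c(14, 5, 1), nsp_control_sc = c(10, 10, 10),
    nnsp_lps_sc = 1, nnsp_control_sc = 1,
    nsp_ratio = c(1.4, 0.5, 2.0), nnsp_ratio = 1,
    p_value_nsp = c(0.01, 0.01, 0.5), p_value_nnsp = 0.5,
    call = c("unchanged", "down", "unchanged"), stringsAsFactors = FALSE
  )
  out <- call_regulation(base)
  expect_equal(out$regulated$accession, "B")
  expect_equal(nrow(out$exclusive), 0L)
})

test_that("null data keep the regulated fraction near the nominal level", {
  # scaled-down null check; the full 20 x 300 run lives in the acceptance suite
  fracs <- sapply(1:3, function(s) {
    sim <- small_sim(seed = 400 + s, n_proteins = 120, preset = "null")
    cl <- classify_psms(sim$psms, sim$proteome, sim$design)
    reg <- compute_ratios(aggregate_counts(cl, sim$design), "EC")
    sum(reg$call %in% c("up", "down")) / sum(!is.na(reg$p_value_nsp))
  })
  expect_lt(mean(fracs), 0.10)
})
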