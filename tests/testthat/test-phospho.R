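# protein with S/T/Y residues at known coordinates:
# MAKRLSTKPEASKLR -> S6, T7, S12; peptide LSTKPE maps to 5-10
phospho_protein <- function() {
  data.frame(accession = "P1", description = "toy",
             sequence = "MAKRLSTKPEASKLR", stringsAsFactors = FALSE)
}

test_that("peptide phospho positions translate to protein coordinates", {
  d <- make_design(n_animals = 2)
  # phospho at peptide position 2 of LSTKPE (starts at protein 5) -> S6
  psms <- make_psm("EC_LPS_a3", "LSTKPE", "2:S(+79.97)@1000", "P1", 1)
  cl <- classify_psms(psms, phospho_protein(), d)
  sites <- collect_sites(cl, phospho_protein(), min_score = 1000)
  expect_equal(sites$position, 6L)
  expect_equal(sites$residue, "S")
  expect_equal(sites$site, "S6")
  # round trip: protein position maps back to the peptide offset
  obs <- attr(sites, "observations")
  expect_equal(obs$position - cl$start + 1L, 2L)
})

test_that("sites below the localization threshold are discarded", {
  d <- make_design(n_animals = 2)
  psms <- rbind(
    make_psm("EC_LPS_a3", "LSTKPE", "2:S(+79.97)@999", "P1", 1),
    make_psm("EC_LPS_a4", "LSTKPE", "3:T(+79.97)@1000", "P1", 1)
  )
  cl <- classify_psms(psms, phospho_protein(), d)
  sites <- collect_sites(cl, phospho_protein(), min_score = 1000)
  expect_equal(sites$site, "T7")  # the 999-score S6 observation is dropped
})

test_that("duplicate observations merge with the maximal score", {
  d <- make_design(n_animals = 2)
  psms <- rbind(
    make_psm("EC_LPS_a3", "LSTKPE", "2:S(+79.97)@1000", "P1", 2),
    make_psm("EC_LPS_a4", "LSTKPE", "2:S(+79.97)@1200", "P1", 1)
  )
  cl <- classify_psms(psms, phospho_protein(), d)
  sites <- collect_sites(cl, phospho_protein())
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$score, 1200)
  expect_equal(sites$n_samples, 2L)
})

test_that("per-group site counts count distinct sites per animal", {
  d <- make_design(n_animals = 2)
  psms <- rbind(
    make_psm("EC_LPS_a3", "LSTKPE", "2:S(+79.97)@1000", "P1", 1),
    make_psm("EC_LPS_a3", "LSTKPE", "3:T(+79.97)@1000", "P1", 1),
    make_psm("EC_LPS_a4", "LSTKPE", "2:S(+79.97)@1000", "P1", 1)
  )
  cl <- classify_psms(psms, phospho_protein(), d)
  sites <- collect_sites(cl, phospho_protein())
  counts <- count_sites_per_group(sites, d)
  pa <- counts$per_animal
  expect_equal(pa$n_sites[pa$animal_id == "a3"], 2L)
  expect_equal(pa$n_sites[pa$animal_id == "a4"], 1L)
  expect_equal(pa$n_sites[pa$condition == "Control"], c(0L, 0L))
})

test_that("condition-specific phosphosite gain is detected at study scale", {
  sim <- small_sim(seed = 900, n_proteins = 200,
                   phospho_sites_per_protein = 1,
                   phospho_detect_prob = c(Control = 0.05, LPS = 0.3))
  cl <- classify_psms(sim$psms, sim$proteome, sim$design)
  sites <- collect_sites(cl, sim$proteome)
  counts <- count_sites_per_group(sites, sim$design)
  tst <- counts$tests[counts$tests$layer == "EC", ]
  expect_gt(tst$mean_lps, tst$mean_control)
  expect_lt(tst$p_value, 0.05)
})

test_that("disease-specific calls follow the same-layer LPS-only rule", {
  d <- make_design(n_animals = 2, layers = c("EC", "SMC"))
  psms <- rbind(
    # S6 in EC: LPS only -> disease specific
    make_psm("EC_LPS_a3", "LSTKPE", "2:S(+79.97)@1000", "P1", 1),
    # T7 in EC: both conditions -> neither flag
    make_psm("EC_LPS_a3", "LSTKPE", "3:T(+79.97)@1000", "P1", 1),
    make_psm("EC_Control_a1", "LSTKPE", "3:T(+79.97)@1000", "P1", 1),
    # S12 in EC: Control only -> control specific
    make_psm("EC_Control_a2", "ASKLR", "2:S(+79.97)@1000", "P1", 1),
    # S6 in SMC Control must not veto the EC call (same-layer rule)
    make_psm("SMC_Control_a1", "LSTKPE", "2:S(+79.97)@1000", "P1", 1)
  )
  cl <- classify_psms(psms, phospho_protein(), d)
  sites <- collect_sites(cl, phospho_protein())
  calls <- call_disease_specific(sites, d, phospho_protein())
  ec <- calls[calls$layer == "EC", ]
  expect_equal(ec$disease_specific[ec$site == "S6"], TRUE)
  expect_equal(ec$disease_specific[ec$site == "T7"], FALSE)
  expect_equal(ec$control_specific[ec$site == "T7"], FALSE)
  expect_equal(ec$control_specific[ec$site == "S12"], TRUE)
  expect_equal(ec$disease_specific[ec$site == "S12"], FALSE)
  smc <- calls[calls$layer == "SMC", ]
  expect_equal(smc$control_specific[smc$site == "S6"], TRUE)
  # mutual exclusion always holds
  expect_false(any(calls$disease_specific & calls$control_specific))
  expect_equal(unique(calls$protein), "toy")
})

test_that("phospho on a residue that cannot carry it is rejected", {
  d <- make_design(n_animals = 2)
  expect_error(classify_psms(
    make_psm("EC_LPS_a3", "LSTKPE", "1:L(+79.97)@1000", "P1", 1),
    phospho_protein(), d), "not allowed")
})
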