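test_that("expected bulk VAF follows the copy-weighted closed form", {
  het <- clonal_architecture(1, 2, 1)
  expect_equal(expected_vaf(het), 0.5)

  hemi <- clonal_architecture(c(0.5, 0.5), c(1, 2), c(1, 0))
  expect_equal(expected_vaf(hemi), 1 / 3)

  # 6% UPD-homozygous + 4% heterozygous + 90% WT: bulk VAF 8%, 6% of cells
  # biallelic -- a cryptic biallelic case
  cryptic <- clonal_architecture(c(0.06, 0.04, 0.90), c(2, 2, 2), c(2, 1, 0))
  expect_equal(expected_vaf(cryptic), 0.08)
  expect_equal(cryptic$truth_biallelic_fraction, 0.06)

  none <- clonal_architecture(c(0.3, 0.7), c(2, 2), c(0, 0))
  expect_equal(expected_vaf(none), 0)
  all_mut <- clonal_architecture(1, 2, 2)
  expect_equal(expected_vaf(all_mut), 1)

  expect_error(clonal_architecture(1, 2, 3))       # more mutant than copies
  expect_error(expected_vaf(clonal_architecture(1, 0, 0)), "zero TP53")
})

test_that("stored biallelic fractions are consistent with the states", {
  sim <- simulate_cohort(sim_params(n_patients = 300, seed = 61))
  for (a in sim$architectures) {
    inact <- rowSums(a$mutant_copies) + (2 - a$total_copies)
    expect_equal(a$truth_biallelic_fraction, sum(a$fractions[inact >= 2]))
    expect_equal(sum(a$fractions), 1, tolerance = 1e-9)
  }
})

test_that("bulk VAF sampling is binomial around the closed form", {
  set.seed(67)
  het <- clonal_architecture(1, 2, 1)
  expect_lt(abs(sample_bulk_vaf(het, 1, depth = 1e6) - 0.5), 0.002)

  cryptic <- clonal_architecture(c(0.06, 0.04, 0.90), c(2, 2, 2), c(2, 1, 0))
  draws <- replicate(1e4, sample_bulk_vaf(cryptic, 1, depth = 500))
  se <- sqrt(0.08 * 0.92 / 500)
  expect_lt(abs(mean(draws) - 0.08), 4 * se / sqrt(1e4))
  expect_lt(abs(var(draws) / (0.08 * 0.92 / 500) - 1), 0.2)

  none <- clonal_architecture(c(0.3, 0.7), c(2, 2), c(0, 0))
  expect_true(all(replicate(50, sample_bulk_vaf(none, 1, 500)) == 0))
})

test_that("del17p calls respect the detection floor", {
  set.seed(71)
  cryptic <- clonal_architecture(c(0.10, 0.90), c(1, 2), c(1, 0))
  res <- call_del17p(cryptic, 0.20)
  expect_false(res$del17p)
  expect_true(is.na(res$del17p_clonality))

  large <- clonal_architecture(c(0.60, 0.40), c(1, 2), c(1, 0))
  res2 <- call_del17p(large, 0.20)
  expect_true(res2$del17p)
  expect_lt(abs(res2$del17p_clonality - 0.60), 0.1)

  diploid <- clonal_architecture(1, 2, 1)
  expect_false(call_del17p(diploid, 0.20)$del17p)
})

test_that("survival strata reproduce the configured medians", {
  set.seed(73)
  params <- sim_params(censor_rate = 0)
  wt_draws <- replicate(1e4, sample_survival(0, 0, params)$os_months)
  expect_lt(abs(median(wt_draws) / 42 - 1), 0.05)

  # 34% biallelic cells lands in the high-hazard stratum
  s <- sample_survival(0.34, 2, params)
  expect_equal(s$stratum, "biallelic")
  expect_equal(sample_survival(0.005, 1, params)$stratum, "monoallelic")
  expect_equal(sample_survival(0.06, 1, params)$stratum, "biallelic")

  all_cens <- sim_params(censor_rate = 1)
  draws <- replicate(20, sample_survival(0, 1, all_cens)$os_event)
  expect_false(any(draws))
})

test_that("the realized censoring fraction tracks censor_rate", {
  sim <- simulate_cohort(sim_params(n_patients = 2000, censor_rate = 0.3,
                                    seed = 79))
  expect_lt(abs(mean(!sim$cohort$patients$os_event) - 0.3), 0.05)
})

test_that("single-cell sampling reproduces state fractions and bulk VAF", {
  set.seed(83)
  # 32% biallelic (compound heterozygous) cells beside monoallelic and WT clones
  arch <- clonal_architecture(c(0.32, 0.30, 0.38), c(2, 2, 2),
                              matrix(c(1, 1, 0, 1, 0, 0), 3, 2))
  sc <- sample_single_cells(arch, n_cells = 2000, ado_rate = 0)
  sd_b <- sqrt(0.32 * 0.68 / 2000)
  expect_lt(abs(mean(sc$biallelic_true) - 0.32), 3 * sd_b)

  for (j in 1:2) {
    bulk <- sum(sc$mutant_true[, j]) / sum(sc$total_true[, j])
    ev <- expected_vaf(arch, j)
    expect_lt(abs(bulk - ev), 3 * sqrt(ev * (1 - ev) / 2000))
  }

  dropped <- sample_single_cells(arch, n_cells = 200, ado_rate = 1)
  expect_true(all(dropped$total_obs == 0))
})

test_that("cohort simulation is seeded, composable and degenerates cleanly", {
  a <- simulate_cohort(sim_params(n_patients = 150, seed = 89))
  b <- simulate_cohort(sim_params(n_patients = 150, seed = 89))
  expect_identical(a$cohort$patients, b$cohort$patients)
  expect_identical(a$cohort$variants, b$cohort$variants)
  expect_identical(a$truth, b$truth)

  empty <- simulate_cohort(sim_params(n_patients = 0))
  expect_equal(nrow(empty$cohort$patients), 0L)
  expect_equal(nrow(empty$truth), 0L)

  # truth classes cover the mix and ids align
  expect_setequal(unique(a$truth$patient_id), a$cohort$patients$patient_id)
})

test_that("planted dominant-biallelic share is recovered by the classifier", {
  sim <- simulate_cohort(sim_params(n_patients = 2000, seed = 97))
  calls <- suppressWarnings(classify_allelic(sim$cohort))
  mut <- sim$truth$n_true_hits > 0
  planted <- mean(sim$truth$class[mut] %in%
                    c("dominant_biallelic", "del17p_involving"))
  observed <- mean(calls$label[mut] == "obligatory_biallelic")
  expect_lt(abs(observed - planted), 0.05)
})

test_that("the simulator produces cryptic biallelic discordance", {
  sim <- simulate_cohort(sim_params(n_patients = 1500, seed = 101))
  calls <- suppressWarnings(classify_allelic(sim$cohort))
  truth <- sim$truth
  cryptic <- truth$biallelic_fraction > 0 & truth$biallelic_fraction <= 0.1 &
    calls$combined_vaf < 0.23 & calls$combined_vaf > 0
  expect_gt(sum(cryptic), 0)
  # bulk classifier calls them monoallelic, yet they carry the high hazard
  expect_true(all(calls$label[cryptic] == "probable_monoallelic"))
  expect_true(all(truth$stratum[cryptic & truth$biallelic_fraction > 0.02] ==
                    "biallelic"))
})

test_that("change-point cohorts are seeded and respect their strata", {
  a <- simulate_changepoint_cohort(n = 200, changepoint = 0.25, seed = 103)
  b <- simulate_changepoint_cohort(n = 200, changepoint = 0.25, seed = 103)
  expect_identical(a, b)
  expect_true(all(a$truth$stratum[a$truth$true_vaf > 0.25] == "biallelic"))
  expect_true(all(a$truth$stratum[a$truth$true_vaf == 0] == "WT"))
})
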