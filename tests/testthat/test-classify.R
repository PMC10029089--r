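test_that("combined VAF sums, caps at 1, and handles the empty set", {
  expect_equal(combined_vaf(numeric()), 0)
  expect_equal(combined_vaf(c(0.30, 0.25)), 0.55)
  expect_equal(combined_vaf(c(0.12, 0.08)), 0.20)
  expect_warning(s <- combined_vaf(c(0.6, 0.6)), "capped")
  expect_equal(s, 1)
})

test_that("traditional single/double-hit rules enumerate correctly", {
  co <- make_cohort(
    vafs = list(c(0.3), numeric(), c(0.3), c(0.3, 0.2), numeric(), c(0.4)),
    del17p = c(NA, TRUE, FALSE, FALSE, FALSE, TRUE),
    upd = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  lab <- as.character(classify_traditional(co)$label)
  expect_equal(lab, c("single_hit",  # one mutation, no cytogenetics record
                      "single_hit",  # isolated del17p
                      "double_hit",  # mutation + UPD
                      "double_hit",  # two mutations
                      "WT",
                      "double_hit")) # mutation + del17p
})

test_that("allelic classification reproduces the worked single-cell cases", {
  cfg <- run_config(cutoff = 0.23)
  co <- make_cohort(vafs = list(c(0.08), c(0.33), c(0.12, 0.08)))
  calls <- classify_allelic(co, cfg)
  expect_equal(as.character(calls$label),
               c("probable_monoallelic", "probable_biallelic",
                 "probable_monoallelic"))
  expect_equal(calls$combined_vaf, c(0.08, 0.33, 0.20))
})

test_that("rule order and rule_fired are consistent", {
  cfg <- run_config(cutoff = 0.23)
  co <- make_cohort(
    vafs = list(c(0.60), c(0.30, 0.25), c(0.40), numeric(), numeric(),
                c(0.40)),
    del17p = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    clonality = c(NA, NA, 0.30, NA, 0.5, NA)
  )
  calls <- classify_allelic(co, cfg)
  expect_equal(as.character(calls$label),
               c("obligatory_biallelic", "obligatory_biallelic",
                 "obligatory_biallelic", "WT", "del17p_only",
                 "probable_biallelic"))
  expect_equal(as.character(calls$rule_fired),
               c("single_vaf_gt50", "combined_vaf_gt50",
                 "vaf_plus_del17p_gt50", "none", "none", "cutoff_above"))
  # del17p with unknown clonality skips the clonality rule and is flagged
  expect_match(calls$evidence_note[6], "clonality_unknown")
})

test_that("strict inequalities hold at the 50% and cutoff boundaries", {
  cfg <- run_config(cutoff = 0.23)
  co <- make_cohort(vafs = list(c(0.50), c(0.23), c(0.25, 0.25)))
  calls <- classify_allelic(co, cfg)
  expect_equal(as.character(calls$label),
               c("probable_biallelic",    # 50% exactly is not > 50%
                 "probable_monoallelic",  # at the cutoff stays monoallelic
                 "probable_biallelic"))   # combined exactly 50%
})

test_that("every patient gets exactly one label consistent with rule_fired", {
  vaf_grid <- seq(0, 1, by = 0.02)
  clon_grid <- c(NA, seq(0, 1, by = 0.1))
  cases <- expand.grid(v = vaf_grid, hits = 1:2, clon = seq_along(clon_grid))
  vafs <- lapply(seq_len(nrow(cases)), function(i) {
    if (cases$hits[i] == 1) cases$v[i]
    else c(0.7, 0.3) * cases$v[i]
  })
  clon <- clon_grid[cases$clon]
  co <- make_cohort(vafs, del17p = !is.na(clon) | seq_along(clon) %% 2 == 0,
                    clonality = clon)
  calls <- classify_allelic(co, run_config(cutoff = 0.23))
  expect_false(any(is.na(calls$label)))
  oblig <- calls$label == "obligatory_biallelic"
  expect_true(all(calls$rule_fired[oblig] %in%
                    c("single_vaf_gt50", "combined_vaf_gt50",
                      "vaf_plus_del17p_gt50")))
  probable <- calls$label %in% c("probable_biallelic", "probable_monoallelic")
  expect_true(all(calls$rule_fired[probable] %in%
                    c("cutoff_above", "cutoff_at_or_below")))
  expect_true(all(calls$rule_fired[!oblig & !probable] == "none"))
})

test_that("labels are monotone in combined VAF", {
  cfg <- run_config(cutoff = 0.23)
  rank_of <- c(probable_monoallelic = 1, probable_biallelic = 2,
               obligatory_biallelic = 3)
  vafs <- seq(0.005, 1, by = 0.005)
  for (hits in 1:2) {
    vl <- lapply(vafs, function(v) if (hits == 1) v else c(v / 2, v / 2))
    calls <- classify_allelic(make_cohort(vl), cfg)
    r <- rank_of[as.character(calls$label)]
    expect_true(all(diff(r) >= 0))
  }
})

test_that("boundary cutoffs collapse the probable classes as expected", {
  vafs <- lapply(seq(0.01, 0.49, by = 0.01), identity)
  co <- make_cohort(vafs)
  at_half <- classify_allelic(co, run_config(cutoff = 0.5))
  expect_false(any(at_half$label == "probable_biallelic"))
  near_zero <- classify_allelic(co, run_config(cutoff = 1e-9))
  expect_false(any(near_zero$label == "probable_monoallelic"))
})

test_that("wild-type agreement between the two schemes", {
  sim <- simulate_cohort(sim_params(n_patients = 300, seed = 21))
  trad <- classify_traditional(sim$cohort)$label
  novel <- suppressWarnings(classify_allelic(sim$cohort)$label)
  expect_equal(trad == "WT", novel %in% c("WT"))
  # del17p-only cases are single hits traditionally
  expect_true(all(trad[novel == "del17p_only"] == "single_hit"))
})

test_that("reclassification table conserves the cohort size", {
  co1 <- make_cohort(list(c(0.30)))
  t1 <- reclassification_table(co1, run_config())
  expect_equal(as.numeric(t1["single_hit", "probable_biallelic"]), 1)
  expect_equal(sum(t1), 1)

  co2 <- make_cohort(list(c(0.12, 0.08)))
  t2 <- reclassification_table(co2, run_config())
  expect_equal(as.numeric(t2["double_hit", "probable_monoallelic"]), 1)

  sim <- simulate_cohort(sim_params(n_patients = 200, seed = 5))
  t3 <- suppressWarnings(reclassification_table(sim$cohort))
  expect_equal(sum(t3), 200)
  expect_equal(as.numeric(rowSums(t3)),
               as.numeric(table(classify_traditional(sim$cohort)$label)))
})

test_that("upd17p does not by itself promote to obligatory biallelic", {
  co <- make_cohort(list(c(0.30)), del17p = FALSE, upd = TRUE)
  calls <- classify_allelic(co, run_config())
  expect_equal(as.character(calls$label), "probable_biallelic")
  expect_equal(as.character(classify_traditional(co)$label), "double_hit")
})
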