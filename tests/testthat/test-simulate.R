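test_that("the generator is deterministic under a seed and sensitive to it", {
  cfg <- simulation_config(n_chronic_hd = 10, n_transient_aki = 5, seed = 3)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_population(simulation_config(n_chronic_hd = 10,
                                              n_transient_aki = 5, seed = 4))
  expect_false(identical(s1$asv, s3$asv))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(simulate_population(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("zero counts give four empty tables and infeasible periods error", {
  cfg <- simulation_config(n_chronic_hd = 0, n_chronic_pd = 0, n_prevalent = 0,
                           n_transient_aki = 0, n_transient_short = 0,
                           n_nonresident = 0, n_death_in_hospital = 0,
                           n_fistula_only = 0)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$hdr), 0L)
  expect_equal(nrow(sim$asv), 0L)
  expect_equal(nrow(sim$registry), 0L)
  expect_equal(nrow(sim$truth), 0L)
  expect_error(simulation_config(index_period_end = as.Date("2014-01-10")),
               "at least 28 days")
})

test_that("a clean chronic starter is expected in every variant and in the registry", {
  sim <- simulate_population(simulation_config(
    n_chronic_hd = 1, n_chronic_pd = 0, n_prevalent = 0, n_transient_aki = 0,
    n_transient_short = 0, n_nonresident = 0, n_death_in_hospital = 0,
    n_fistula_only = 0, seed = 9))
  tr <- sim$truth
  expect_equal(nrow(tr), 1L)
  expect_true(all(tr$expected_alg1, tr$expected_alg2, tr$expected_asv_only))
  expect_true(tr$in_registry)
  expect_equal(format(tr$registry_inception_date, "%Y"), "2014")
  expect_equal(sim$registry$patient_id, tr$patient_id)
  # the first outpatient session sits exactly on the true index date
  expect_equal(min(sim$asv$service_date), tr$true_index_date)
})

test_that("transient AKI patients always span fewer than 90 days and are excluded", {
  sim <- simulate_population(simulation_config(
    n_chronic_hd = 0, n_chronic_pd = 0, n_prevalent = 0, n_transient_aki = 50,
    n_transient_short = 0, n_nonresident = 0, n_death_in_hospital = 0,
    n_fistula_only = 0, seed = 17))
  # recompute each patient's span from the emitted tables
  for (p in sim$truth$patient_id) {
    fe <- min(sim$hdr$admission_date[sim$hdr$patient_id == p])
    ev <- sim$asv$service_date[sim$asv$patient_id == p]
    span <- if (length(ev)) max(as.integer(ev - fe)) else 0L
    expect_lt(span, 90)
  }
  expect_equal(nrow(run_algorithm(sim$hdr, sim$asv, cfg2014())), 0L)
  expect_equal(nrow(sim$registry), 0L)  # never entered by the nephrologist
})

test_that("emitted tables satisfy the record invariants", {
  sim <- simulate_population(simulation_config(
    n_chronic_hd = 20, n_chronic_pd = 5, n_prevalent = 5, n_transient_aki = 5,
    n_transient_short = 5, n_nonresident = 3, n_death_in_hospital = 3,
    n_fistula_only = 3, p_year_boundary = 0.3, p_residence_miscode = 0.2,
    p_registry_only_short = 0.2, seed = 31))
  expect_true(all(sim$hdr$admission_date <= sim$hdr$discharge_date))
  for (j in 1:15) {
    pd <- sim$hdr[[paste0("proc", j, "_date")]]
    ok <- is.na(pd) | (pd >= sim$hdr$admission_date & pd <= sim$hdr$discharge_date)
    expect_true(all(ok))
  }
  expect_true(all(nzchar(sim$asv$service_code)))
  expect_false(anyNA(sim$asv$service_date))
  expect_true(all(sim$registry$modality %in% c("HD", "PD")))
  # and they survive a write/read round trip unchanged
  f <- withr::local_tempfile(fileext = ".csv")
  write_hdr(sim$hdr, f); expect_equal(read_hdr(f), sim$hdr)
  write_asv(sim$asv, f); expect_equal(read_asv(f), sim$asv)
  write_registry(sim$registry, f); expect_equal(read_registry(f), sim$registry)
})

test_that("expected_counts reflects each injected discordance mechanism", {
  clean <- simulate_population(simulation_config(n_chronic_hd = 20, seed = 5))
  cts <- expected_counts(clean$truth, "ALG1", 2014)
  expect_equal(cts$n_diff_year, 0L)
  expect_equal(cts$n_not_in_registry, 0L)
  expect_equal(cts$n_missed, 0L)

  yb <- simulate_population(simulation_config(n_chronic_hd = 40,
                                              p_year_boundary = 0.4, seed = 6))
  n_perturbed <- sum(format(yb$truth$registry_inception_date, "%Y") == "2013",
                     na.rm = TRUE)
  cts <- expected_counts(yb$truth, "ALG1", 2014)
  expect_gt(n_perturbed, 0)
  expect_equal(cts$n_diff_year, n_perturbed)
  # the perturbed patients leave the index-year registry denominator, so
  # sensitivity is untouched; the damage shows in PPV and agreement
  expect_equal(sensitivity(cts), 100)
  expect_lt(ppv(cts), 100)
  expect_lt(agreement(cts), 100)

  ro <- simulate_population(simulation_config(n_chronic_hd = 40,
                                              p_registry_only_short = 0.3, seed = 7))
  n_injected <- sum(ro$truth$archetype == "registry_only_short")
  expect_gt(n_injected, 0)
  expect_equal(expected_counts(ro$truth, "ALG1", 2014)$n_missed, n_injected)
})

test_that("discordance rates are recovered within binomial error at n >= 500", {
  for (seed in c(101, 202)) {
    sim <- simulate_population(simulation_config(
      n_chronic_hd = 450, n_chronic_pd = 50, n_prevalent = 0,
      n_transient_aki = 0, n_transient_short = 0, n_nonresident = 0,
      n_death_in_hospital = 0, n_fistula_only = 0,
      p_residence_miscode = 0.1, seed = seed))
    n_chronic <- 500
    phat <- sum(!sim$truth$expected_alg1[
      sim$truth$archetype %in% c("chronic_hd", "chronic_pd")]) / n_chronic
    expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / n_chronic))
  }
})
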