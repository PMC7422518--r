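cfg <- cfg2014()

test_that("hdr_index_candidates applies the diagnosis and procedure rules", {
  # rule 1: diagnosis-qualified admission, index at the admission date
  got <- hdr_index_candidates(adm1("A", "2014-03-10", "2014-03-20", dx = "585.6"), cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$event_date, d("2014-03-10"))
  expect_equal(got$source, "HDR_DX")
  expect_equal(got$modality_hint, "UNKNOWN")

  # fistula-only admission never qualifies through a diagnosis
  got <- hdr_index_candidates(
    adm1("A", "2014-03-10", "2014-03-20", dx = "585.6",
         proc_codes = "39.27", proc_dates = "2014-03-11"), cfg)
  expect_equal(nrow(got), 0L)
  # ... but under eskd_only scope a co-occurring encounter diagnosis rescues it
  got <- hdr_index_candidates(
    adm1("A", "2014-03-10", "2014-03-20", dx = c("585.6", "V56.0"),
         proc_codes = "39.27", proc_dates = "2014-03-11"),
    cfg2014(fistula_exclusion_scope = "eskd_only"))
  expect_equal(got$source, "HDR_DX")

  # rule 2: earliest dialysis procedure date wins, and procedure beats diagnosis
  got <- hdr_index_candidates(
    adm1("A", "2014-05-01", "2014-05-10", dx = "V56.0",
         proc_codes = c("39.95", "39.95"),
         proc_dates = c("2014-05-04", "2014-05-02")), cfg)
  expect_equal(got$event_date, d("2014-05-02"))
  expect_equal(got$source, "HDR_PROC")
  expect_equal(got$modality_hint, "HD")

  # missing procedure date falls back to the admission date
  got <- hdr_index_candidates(
    adm1("A", "2014-05-01", "2014-05-10", proc_codes = "54.98"), cfg)
  expect_equal(got$event_date, d("2014-05-01"))
  expect_equal(got$modality_hint, "PD")
})

test_that("an admission straddling the year boundary is indexed at its in-period procedure date", {
  hdr <- adm1("A", "2013-12-28", "2014-01-05", dx = "585.6",
              proc_codes = "39.95", proc_dates = "2014-01-02")
  got <- hdr_index_candidates(hdr, cfg)
  expect_equal(got$event_date, d("2014-01-02"))
  expect_equal(got$source, "HDR_PROC")

  # brute-force enumerator of all qualifying (rule, date) pairs on one record
  enumerate_pairs <- function(hdr_row, ps, pe) {
    pairs <- list()
    for (j in 1:15) {
      code <- hdr_row[[paste0("proc", j, "_code")]]
      if (is.na(code)) next
      date <- hdr_row[[paste0("proc", j, "_date")]]
      if (is.na(date)) date <- hdr_row$admission_date
      if (grepl("^(39\\.95|54\\.98)", code) && date >= ps && date <= pe)
        pairs[[length(pairs) + 1]] <- list(rule = "proc", date = date)
    }
    dx <- unlist(hdr_row[paste0("dx", 1:15)], use.names = FALSE)
    dx <- dx[!is.na(dx)]
    has_dial_dx <- any(dx == "585.6" | grepl("^V45\\.1", dx) | grepl("^V56\\.[0-8]", dx))
    if (!length(pairs) && has_dial_dx &&
        hdr_row$admission_date >= ps && hdr_row$admission_date <= pe)
      pairs[[length(pairs) + 1]] <- list(rule = "dx", date = hdr_row$admission_date)
    pairs
  }
  pairs <- enumerate_pairs(hdr[1, ], cfg$index_period_start, cfg$index_period_end)
  expect_equal(length(pairs), 1L)
  expect_equal(pairs[[1]]$rule, "proc")
  expect_equal(pairs[[1]]$date, got$event_date)

  # same record with the procedure dated before the period: only the
  # diagnosis rule could apply, and the admission date is outside the period
  hdr2 <- adm1("A", "2013-12-28", "2014-01-05", dx = "585.6",
               proc_codes = "39.95", proc_dates = "2013-12-30")
  expect_equal(nrow(hdr_index_candidates(hdr2, cfg)), 0L)
  expect_equal(length(enumerate_pairs(hdr2[1, ], cfg$index_period_start,
                                      cfg$index_period_end)), 0L)
})

test_that("asv_index_candidates keeps in-period dialysis services only", {
  asv <- asv_table(patient_id = c("A", "A", "A"),
                   service_date = d(c("2014-06-01", "2013-12-31", "2014-06-02")),
                   service_code = c("39.95.3", "54.98.1", "89.01"))
  got <- asv_index_candidates(asv, cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$event_date, d("2014-06-01"))
  expect_equal(got$source, "ASV")
  expect_equal(got$modality_hint, "HD")
})

test_that("assign_index_date takes the earliest candidate with documented tie-breaks", {
  cands <- data.frame(patient_id = "A",
                      event_date = d(c("2014-03-01", "2014-02-01")),
                      source = c("HDR_PROC", "ASV"),
                      modality_hint = c("HD", "HD"),
                      admission_id = c(1L, NA))
  expect_equal(assign_index_date(cands)$event_date, d("2014-02-01"))

  tie <- data.frame(patient_id = "A",
                    event_date = d(rep("2014-02-01", 3)),
                    source = c("HDR_DX", "ASV", "HDR_PROC"),
                    modality_hint = c("UNKNOWN", "HD", "PD"),
                    admission_id = c(2L, NA, 1L))
  for (perm in list(1:3, 3:1, c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2)))
    expect_equal(assign_index_date(tie[perm, ])$source, "HDR_PROC")

  single <- cands[1, ]
  expect_equal(assign_index_date(single)$event_date, single$event_date)
  expect_error(assign_index_date(cands[0, ]), "no index event")
  expect_error(assign_index_date(transform(cands, patient_id = c("A", "B"))),
               "single patient")
})

test_that("build_timeline respects each variant's treatment sources", {
  asv <- sess("A", c("2014-02-01", "2014-03-01"))
  hdr <- adm1("A", "2014-04-01", "2014-04-05", proc_codes = "39.95",
              proc_dates = "2014-04-02")
  tl1 <- build_timeline(hdr, asv, cfg2014(variant = "ALG1"))
  expect_equal(tl1$date, d(c("2014-02-01", "2014-03-01")))
  tl2 <- build_timeline(hdr, asv, cfg2014(variant = "ALG2"))
  expect_equal(tl2$date, d(c("2014-02-01", "2014-03-01", "2014-04-02")))
  expect_equal(tl2$source, c("ASV", "ASV", "HDR"))
  # diagnosis-only admissions never contribute treatments
  tl3 <- build_timeline(adm1("A", dx = "585.6"), empty_asv(),
                        cfg2014(variant = "ALG2"))
  expect_equal(nrow(tl3), 0L)
})

test_that("residence exclusion needs a present, differing region in the index period", {
  asv <- asv_table(patient_id = rep("A", 3),
                   service_date = d(c("2014-01-10", "2014-02-10", "2014-03-10")),
                   service_code = rep("39.95.1", 3),
                   region = c("080", "080", NA))
  expect_false(is_nonresident(empty_hdr(), asv, cfg)[["A"]])
  asv$region[2] <- "030"
  expect_true(is_nonresident(empty_hdr(), asv, cfg)[["A"]])
  # a differing region outside the index period does not exclude
  asv$region[2] <- "080"
  asv$service_date[1] <- d("2013-06-01"); asv$region[1] <- "030"
  expect_false(is_nonresident(empty_hdr(), asv, cfg)[["A"]])
})

test_that("prevalence window is the closed 365 days before the index date", {
  idx <- d("2014-06-01")
  # exhaustive boundary oracle: offsets -370..0 days around the index
  for (off in -370:0) {
    expected <- off >= -cfg$prevalence_lookback_days && off <= -1
    expect_identical(is_prevalent(idx, idx + off, cfg), expected,
                     label = paste("offset", off))
  }
  expect_true(is_prevalent(idx, d("2013-06-02"), cfg))   # 364 days before
  expect_false(is_prevalent(idx, d("2013-05-31"), cfg))  # 366 days before
  expect_false(is_prevalent(idx, idx, cfg))              # the index itself
  expect_false(is_prevalent(idx, as.Date(character()), cfg))
})

test_that("AKI is detected in the index admission or within 90 days before", {
  hdr <- adm1("A", "2014-03-01", "2014-03-10", dx = c("585.6", "584.9"),
              proc_codes = "39.95", proc_dates = "2014-03-02")
  idx <- hdr_index_candidates(hdr, cfg)
  expect_true(has_aki(hdr, idx, cfg))

  prior <- function(days_before) rbind(
    adm1("A", format(d("2014-06-01") - days_before), format(d("2014-06-01") - days_before + 2),
         dx = "584.5"))
  asv_idx <- assign_index_date(asv_index_candidates(sess("A", "2014-06-01"), cfg))
  expect_true(has_aki(prior(89), asv_idx, cfg))
  expect_false(has_aki(prior(95), asv_idx, cfg))
  expect_false(has_aki(prior(90), asv_idx, cfg))  # "less than 90" is strict
  expect_false(has_aki(empty_hdr(), asv_idx, cfg))
})

test_that("chronicity compares the treatment span against the AKI-specific threshold", {
  idx <- d("2014-03-01")
  # boundary oracle over all gaps 0..120 for both thresholds
  for (gap in 0:120) {
    tl <- if (gap == 0) as.Date(character()) else idx + gap
    expect_identical(is_chronic(idx, tl, FALSE, cfg), gap >= 30,
                     label = paste("non-AKI gap", gap))
    expect_identical(is_chronic(idx, tl, TRUE, cfg), gap >= 90,
                     label = paste("AKI gap", gap))
  }
  # only events inside (index, index + followup] count
  expect_false(is_chronic(idx, idx + 400, FALSE, cfg))
  expect_false(is_chronic(idx, idx - 10, FALSE, cfg))
  expect_true(is_chronic(idx, c(idx - 10, idx + 45), FALSE, cfg))
})

test_that("death at the index admission excludes only hospital-sourced index events", {
  hdr <- adm1("A", "2014-03-01", "2014-03-10", proc_codes = "39.95",
              proc_dates = "2014-03-02", dead = TRUE)
  idx <- hdr_index_candidates(hdr, cfg)
  expect_true(died_in_index_admission(hdr, idx))
  hdr$discharged_dead <- FALSE
  expect_false(died_in_index_admission(hdr, hdr_index_candidates(hdr, cfg)))
  # the patient dying in a later admission does not trigger the criterion
  asv_idx <- assign_index_date(asv_index_candidates(sess("A", "2014-02-01"), cfg))
  expect_false(died_in_index_admission(hdr, asv_idx))
})

test_that("modality comes from the index event, then the timeline, then defaults to HD", {
  pd_idx <- assign_index_date(
    asv_index_candidates(sess("A", "2014-02-01", code = "54.98.1"), cfg))
  expect_equal(assign_modality(pd_idx, data.frame()), "PD")

  dx_idx <- hdr_index_candidates(adm1("A", "2014-03-10", dx = "585.6"), cfg)
  tl <- build_timeline(empty_hdr(), sess("A", "2014-03-20"), cfg)
  expect_equal(assign_modality(dx_idx, tl), "HD")
  expect_warning(m <- assign_modality(dx_idx, tl[0, ]), "defaulting to HD")
  expect_equal(m, "HD")
})

test_that("run_algorithm composes inclusion, index assignment and exclusions", {
  # canonical incident: thrice-weekly sessions for a year, nothing before
  dates <- seq(d("2014-04-01"), d("2015-03-31"), by = 2)
  co <- run_algorithm(empty_hdr(), sess("A", format(dates)), cfg)
  expect_equal(nrow(co), 1L)
  expect_equal(co$index_date, d("2014-04-01"))
  expect_equal(co$modality, "HD")
  expect_false(co$aki_flag)

  # one session 93 days before the index makes the patient prevalent
  co <- run_algorithm(empty_hdr(), sess("A", format(c(d("2013-12-30"), dates))), cfg)
  expect_equal(nrow(co), 0L)
  audit <- attr(co, "audit")
  expect_equal(audit$excluded_by, "prevalent")

  # AKI admission + sessions ending 40 days after index: excluded under the
  # 90-day AKI threshold, included without the AKI diagnosis
  aki_hdr <- adm1("A", "2014-03-01", "2014-03-10", dx = "584.9",
                  proc_codes = "39.95", proc_dates = "2014-03-01")
  short <- sess("A", format(seq(d("2014-03-03"), d("2014-04-10"), by = 3)))
  co <- run_algorithm(aki_hdr, short, cfg)
  expect_equal(nrow(co), 0L)
  expect_equal(attr(co, "audit")$excluded_by, "non_chronic")
  non_aki_hdr <- adm1("A", "2014-03-01", "2014-03-10", dx = "585.6",
                      proc_codes = "39.95", proc_dates = "2014-03-01")
  co <- run_algorithm(non_aki_hdr, short, cfg)
  expect_equal(nrow(co), 1L)
  expect_true(co$index_date == d("2014-03-01"))

  # declared data windows that do not cover the required span are an error
  expect_error(
    run_algorithm(empty_hdr(), sess("A", format(dates)), cfg,
                  data_window = d(c("2014-01-01", "2015-12-31"))),
    "missing span")
  expect_silent(
    run_algorithm(empty_hdr(), sess("A", format(dates)), cfg,
                  data_window = d(c("2013-01-01", "2015-12-31"))))
})
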