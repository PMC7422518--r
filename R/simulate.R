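# Seeded generator of synthetic HDR/ASV/registry tables with a ground-truth
# label per patient, covering every archetype the case definition must
# handle: incident chronic HD/PD starters, prevalent patients, transient
# dialysis after acute kidney injury, short non-chronic courses, non-resident
# guests, in-hospital deaths at dialysis initiation, and access-creation-only
# admissions. Discordance injectors reproduce the known disagreement
# mechanisms between administrative data and a registry: year-boundary index
# dates, residence miscoding, and registry-only short-course patients.

#' Configuration of the synthetic population
#'
#' Defaults emulate the validation setting the case definition was designed
#' for: a one-calendar-year index period, thrice-weekly outpatient
#' hemodialysis sessions, one monthly peritoneal dialysis summary record,
#' about 85% hemodialysis among chronic incident starters, age 68 +/- 15 at
#' inception and 35% women. All discordance rates default to 0 (a clean
#' world in which algorithm and registry must agree perfectly).
#'
#' @param index_period_start,index_period_end `Date` bounds of the index
#'   period (default calendar year 2014). Must span at least 28 days.
#' @param n_chronic_hd,n_chronic_pd incident chronic hemodialysis /
#'   peritoneal dialysis starters (default 85 / 15).
#' @param n_prevalent patients already on dialysis before the index period
#'   (default 30).
#' @param n_transient_aki patients dialyzed transiently after acute kidney
#'   injury, treatment span < 90 days (default 10).
#' @param n_transient_short non-AKI short courses, span < 30 days (default 10).
#' @param n_nonresident guests resident in another region (default 5).
#' @param n_death_in_hospital patients dying during the admission in which
#'   dialysis started (default 5).
#' @param n_fistula_only admissions creating dialysis access only, no
#'   dialysis delivered in follow-up (default 5).
#' @param hd_sessions_per_week outpatient hemodialysis sessions per week
#'   (default 3; at most 7).
#' @param pd_records_per_month peritoneal dialysis summary records per month
#'   (default 1, dated the 1st).
#' @param kickoff_admission_fraction probability that a chronic starter's
#'   first dialysis happens during a hospital admission (585.6 diagnosis plus
#'   a dialysis procedure on the index date; default 0.3).
#' @param p_residence_miscode per chronic patient, probability that one
#'   in-period record's region of residence is miscoded to another region
#'   (makes the algorithm drop a true case).
#' @param p_year_boundary per chronic patient, probability that the registry
#'   inception is dated late December of the prior year while administrative
#'   events start in January of the index year.
#' @param p_registry_only_short per chronic patient, probability of spawning
#'   an additional registry-only patient: entered by the nephrologist with an
#'   index-year inception but treated for fewer than 30 days, so the
#'   algorithm correctly refuses them.
#' @param target_region,other_regions region codes (defaults `"080"` and
#'   `c("030","050","090")`).
#' @param age_mean,age_sd,female_fraction demographics at inception (defaults
#'   68, 15, 0.35).
#' @param seed integer; fixes the full output.
#' @return object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(index_period_start = as.Date("2014-01-01"),
                              index_period_end = as.Date("2014-12-31"),
                              n_chronic_hd = 85L, n_chronic_pd = 15L,
                              n_prevalent = 30L, n_transient_aki = 10L,
                              n_transient_short = 10L, n_nonresident = 5L,
                              n_death_in_hospital = 5L, n_fistula_only = 5L,
                              hd_sessions_per_week = 3L,
                              pd_records_per_month = 1L,
                              kickoff_admission_fraction = 0.3,
                              p_residence_miscode = 0,
                              p_year_boundary = 0,
                              p_registry_only_short = 0,
                              target_region = "080",
                              other_regions = c("030", "050", "090"),
                              age_mean = 68, age_sd = 15,
                              female_fraction = 0.35,
                              seed = 1L) {
  index_period_start <- as.Date(index_period_start)
  index_period_end <- as.Date(index_period_end)
  stopifnot(index_period_start <= index_period_end)
  if (as.integer(index_period_end - index_period_start) < 27L)
    stop("infeasible config: the index period must span at least 28 days ",
         "to hold the generated event patterns", call. = FALSE)
  counts <- c(n_chronic_hd, n_chronic_pd, n_prevalent, n_transient_aki,
              n_transient_short, n_nonresident, n_death_in_hospital,
              n_fistula_only)
  stopifnot(all(counts >= 0))
  rates <- c(p_residence_miscode, p_year_boundary, p_registry_only_short,
             kickoff_admission_fraction, female_fraction)
  stopifnot(all(rates >= 0 & rates <= 1))
  stopifnot(hd_sessions_per_week >= 1, hd_sessions_per_week <= 7,
            pd_records_per_month >= 1, length(other_regions) >= 1)
  structure(list(index_period_start = index_period_start,
                 index_period_end = index_period_end,
                 n_chronic_hd = as.integer(n_chronic_hd),
                 n_chronic_pd = as.integer(n_chronic_pd),
                 n_prevalent = as.integer(n_prevalent),
                 n_transient_aki = as.integer(n_transient_aki),
                 n_transient_short = as.integer(n_transient_short),
                 n_nonresident = as.integer(n_nonresident),
                 n_death_in_hospital = as.integer(n_death_in_hospital),
                 n_fistula_only = as.integer(n_fistula_only),
                 hd_sessions_per_week = as.integer(hd_sessions_per_week),
                 pd_records_per_month = as.integer(pd_records_per_month),
                 kickoff_admission_fraction = kickoff_admission_fraction,
                 p_residence_miscode = p_residence_miscode,
                 p_year_boundary = p_year_boundary,
                 p_registry_only_short = p_registry_only_short,
                 target_region = as.character(target_region),
                 other_regions = as.character(other_regions),
                 age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

.runif_date <- function(n, from, to) {
  from + floor(stats::runif(n) * (as.integer(to - from) + 1L))
}

# sample() treats a length-1 numeric vector as a range; never do that
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# thrice-weekly-style session schedule: `spw` distinct days in each 7-day
# block from `start` through `end`, jittered within the block; the first
# session is pinned to `start`.
.hd_session_dates <- function(start, end, spw) {
  if (end < start) return(as.Date(character()))
  n_blocks <- as.integer(end - start) %/% 7L + 1L
  offs <- lapply(seq_len(n_blocks) - 1L, function(b) {
    days <- if (b == 0L) c(0L, sample(1:6, spw - 1L)) else sample(0:6, spw)
    b * 7L + sort(days)
  })
  d <- start + unlist(offs)
  d[d <= end]
}

# monthly summary records dated the 1st, from `start` (itself a 1st) to `end`
.pd_record_dates <- function(start, end, per_month) {
  firsts <- seq(start, end, by = "month")
  firsts <- firsts[firsts <= end]
  rep(firsts, each = per_month)
}

# first day of a month lying within [from, to], chosen uniformly
.runif_month_first <- function(from, to) {
  first_candidates <- seq(as.Date(format(from, "%Y-%m-01")),
                          as.Date(format(to, "%Y-%m-01")), by = "month")
  first_candidates <- first_candidates[first_candidates >= from &
                                         first_candidates <= to]
  if (!length(first_candidates))
    stop("infeasible config: no first-of-month inside the index period")
  .sample1(first_candidates)
}

#' Simulate an administrative population with ground truth
#'
#' Generates the three flat tables (hospital discharge records, ambulatory
#' specialty visits, gold-standard registry) plus a truth table recording,
#' per patient, the archetype, the true index date and modality, whether the
#' nephrologist would enter the patient in the registry (chronic incident
#' starters only -- never transients, guests or in-hospital deaths), and
#' whether a correct implementation of each algorithm variant (at default
#' thresholds) must include the patient. The same seed yields byte-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `hdr`, `asv`, `registry`, `truth` (data.frames).
#' @seealso [expected_counts()] for the validation counts the truth table
#'   implies.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_population_impl(config))
}

.simulate_population_impl <- function(config) {
  ps <- config$index_period_start
  pe <- config$index_period_end
  index_year <- as.integer(format(ps, "%Y"))

  hdr_rows <- list()   # per-admission argument lists for hdr_table()
  asv_pid <- character(); asv_date <- as.Date(character())
  asv_code <- character(); asv_region <- character()
  asv_birth <- as.Date(character()); asv_sex <- character()
  reg_pid <- character(); reg_date <- as.Date(character()); reg_mod <- character()
  truth <- list()

  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("P%05d", counter)
  }
  demo <- function(ref_date) {
    age <- min(95, max(18, stats::rnorm(1L, config$age_mean, config$age_sd)))
    list(birth = ref_date - round(age * 365.25),
         sex = if (stats::runif(1L) < config$female_fraction) "F" else "M")
  }
  add_asv <- function(pid, dates, code, region, d) {
    n <- length(dates)
    if (!n) return(invisible())
    asv_pid <<- c(asv_pid, rep(pid, n))
    asv_date <<- c(asv_date, dates)
    asv_code <<- c(asv_code, rep(code, n))
    asv_region <<- c(asv_region, rep(region, n))
    asv_birth <<- c(asv_birth, rep(d$birth, n))
    asv_sex <<- c(asv_sex, rep(d$sex, n))
  }
  add_admission <- function(pid, adm, dis, dx, procs, region, dead, d) {
    hdr_rows[[length(hdr_rows) + 1L]] <<-
      list(pid = pid, adm = adm, dis = dis, dx = list(dx), procs = list(procs),
           region = region, dead = dead, birth = d$birth, sex = d$sex)
  }
  add_registry <- function(pid, date, mod) {
    reg_pid <<- c(reg_pid, pid); reg_date <<- c(reg_date, date)
    reg_mod <<- c(reg_mod, mod)
  }
  add_truth <- function(pid, archetype, index_date, mod, expected,
                        in_registry, inception) {
    truth[[length(truth) + 1L]] <<- data.frame(
      patient_id = pid, archetype = archetype,
      true_index_date = as.Date(index_date), true_modality = mod,
      expected_alg1 = expected[1L], expected_alg2 = expected[2L],
      expected_asv_only = expected[3L], in_registry = in_registry,
      registry_inception_date = as.Date(inception), stringsAsFactors = FALSE)
  }

  # -- chronic incident starters (the registry population) -------------------
  n_registry_only <- 0L
  for (mod in c("HD", "PD")) {
    n <- if (mod == "HD") config$n_chronic_hd else config$n_chronic_pd
    for (i in seq_len(n)) {
      pid <- next_id()
      yb <- stats::runif(1L) < config$p_year_boundary
      miscode <- stats::runif(1L) < config$p_residence_miscode
      if (stats::runif(1L) < config$p_registry_only_short)
        n_registry_only <- n_registry_only + 1L

      if (mod == "HD") {
        index <- if (yb) as.Date(sprintf("%d-01-%02d", index_year,
                                         sample(1:15, 1L))) else .runif_date(1L, ps, pe)
        dates <- .hd_session_dates(index, index + 365L, config$hd_sessions_per_week)
        code <- sprintf("39.95.%d", sample(1:9, 1L))
        proc <- "39.95"
      } else {
        index <- if (yb) as.Date(sprintf("%d-01-01", index_year))
          else .runif_month_first(ps, pe)
        dates <- .pd_record_dates(index, index + 365L, config$pd_records_per_month)
        code <- sample(c("54.98.1", "54.98.2"), 1L)
        proc <- "54.98"
      }
      d <- demo(index)
      regions <- rep(config$target_region, length(dates))
      if (miscode) {
        in_period <- which(dates >= ps & dates <= pe)
        flip <- if (length(in_period)) .sample1(in_period) else 1L
        regions[flip] <- .sample1(config$other_regions)
      }
      asv_pid <- c(asv_pid, rep(pid, length(dates)))
      asv_date <- c(asv_date, dates)
      asv_code <- c(asv_code, rep(code, length(dates)))
      asv_region <- c(asv_region, regions)
      asv_birth <- c(asv_birth, rep(d$birth, length(dates)))
      asv_sex <- c(asv_sex, rep(d$sex, length(dates)))

      if (stats::runif(1L) < config$kickoff_admission_fraction)
        add_admission(pid, index, index + 10L, "585.6",
                      data.frame(code = proc, date = index), config$target_region,
                      FALSE, d)
      inception <- if (yb)
        as.Date(sprintf("%d-12-%02d", index_year - 1L, sample(20:31, 1L)))
        else index
      add_registry(pid, inception, mod)
      add_truth(pid, paste0("chronic_", tolower(mod)), index, mod,
                rep(!miscode, 3L), TRUE, inception)
    }
  }

  # -- prevalent: on dialysis since before the index period ------------------
  for (i in seq_len(config$n_prevalent)) {
    pid <- next_id()
    start <- ps - sample(30:365, 1L)
    dates <- .hd_session_dates(start, ps + 180L, config$hd_sessions_per_week)
    d <- demo(start)
    add_asv(pid, dates, sprintf("39.95.%d", sample(1:9, 1L)),
            config$target_region, d)
    add_truth(pid, "prevalent", start, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- transient dialysis after acute kidney injury (span < 90 days) ---------
  for (i in seq_len(config$n_transient_aki)) {
    pid <- next_id()
    a <- .runif_date(1L, ps, pe)
    gap <- sample(0:89, 1L)
    d <- demo(a)
    add_admission(pid, a, a + 10L, c("584.9", "585.6"),
                  data.frame(code = "39.95", date = a), config$target_region,
                  FALSE, d)
    if (gap >= 1L) {
      dates <- unique(c(if (gap >= 2L) a + seq.int(2L, gap, by = 3L), a + gap))
      dates <- dates[dates > a]
      add_asv(pid, dates, "39.95.1", config$target_region, d)
    }
    add_truth(pid, "transient_aki", a, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- short non-chronic courses (span < 30 days, no AKI) --------------------
  for (i in seq_len(config$n_transient_short)) {
    pid <- next_id()
    s <- .runif_date(1L, ps, pe)
    gap <- sample(0:29, 1L)
    dates <- unique(c(s, if (gap >= 2L) s + seq.int(2L, gap, by = 3L), s + gap))
    d <- demo(s)
    add_asv(pid, dates, "39.95.2", config$target_region, d)
    add_truth(pid, "transient_short", s, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- guests: chronic pattern, resident elsewhere ---------------------------
  for (i in seq_len(config$n_nonresident)) {
    pid <- next_id()
    index <- .runif_date(1L, ps, pe)
    region <- .sample1(config$other_regions)
    dates <- .hd_session_dates(index, index + 365L, config$hd_sessions_per_week)
    d <- demo(index)
    add_asv(pid, dates, "39.95.1", region, d)
    add_truth(pid, "nonresident", index, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- death during the admission in which dialysis started -----------------
  # prolonged stay with repeated inpatient dialysis, no outpatient events:
  # ALG1 sees no follow-up treatments (non-chronic); ALG2 sees a chronic
  # course but excludes for in-hospital death
  for (i in seq_len(config$n_death_in_hospital)) {
    pid <- next_id()
    a <- .runif_date(1L, ps, pe)
    dis <- a + sample(40:60, 1L)
    proc_dates <- unique(c(seq(a, a + 36L, by = 4L), dis))
    d <- demo(a)
    add_admission(pid, a, dis, "585.6",
                  data.frame(code = "39.95", date = proc_dates),
                  config$target_region, TRUE, d)
    add_truth(pid, "death_in_hospital", a, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- access creation only, dialysis never started in follow-up ------------
  for (i in seq_len(config$n_fistula_only)) {
    pid <- next_id()
    a <- .runif_date(1L, ps, pe)
    d <- demo(a)
    add_admission(pid, a, a + 3L, "585.6",
                  data.frame(code = sample(c("39.27", "39.29", "54.93"), 1L),
                             date = a),
                  config$target_region, FALSE, d)
    add_truth(pid, "fistula_only", a, "HD", rep(FALSE, 3L), FALSE, NA)
  }

  # -- registry-only short courses (discordance mechanism c) -----------------
  for (i in seq_len(n_registry_only)) {
    pid <- next_id()
    s <- .runif_date(1L, ps, pe)
    gap <- sample(0:29, 1L)
    dates <- unique(c(s, if (gap >= 2L) s + seq.int(2L, gap, by = 3L), s + gap))
    d <- demo(s)
    add_asv(pid, dates, "39.95.1", config$target_region, d)
    add_registry(pid, s, "HD")
    add_truth(pid, "registry_only_short", s, "HD", rep(FALSE, 3L), TRUE, s)
  }

  hdr <- if (length(hdr_rows)) {
    hdr_table(patient_id = vapply(hdr_rows, `[[`, "", "pid"),
              admission_date = as.Date(vapply(hdr_rows, function(r) as.character(r$adm), "")),
              discharge_date = as.Date(vapply(hdr_rows, function(r) as.character(r$dis), "")),
              diagnoses = lapply(hdr_rows, function(r) r$dx[[1L]]),
              procedures = lapply(hdr_rows, function(r) r$procs[[1L]]),
              region = vapply(hdr_rows, `[[`, "", "region"),
              discharged_dead = vapply(hdr_rows, `[[`, NA, "dead"),
              birth_date = as.Date(vapply(hdr_rows, function(r) as.character(r$birth), "")),
              sex = vapply(hdr_rows, `[[`, "", "sex"))
  } else hdr_table()
  asv <- asv_table(asv_pid, asv_date, asv_code, asv_region, asv_birth, asv_sex)
  registry <- registry_table(reg_pid, reg_date, reg_mod)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), archetype = character(),
               true_index_date = as.Date(character()), true_modality = character(),
               expected_alg1 = logical(), expected_alg2 = logical(),
               expected_asv_only = logical(), in_registry = logical(),
               registry_inception_date = as.Date(character()),
               stringsAsFactors = FALSE)
  list(hdr = hdr, asv = asv, registry = registry, truth = truth)
}

#' Validation counts implied by the simulation truth table
#'
#' Derives, purely from truth labels, the cross-classification that a correct
#' implementation of the given variant must produce on the generated tables
#' when validated against the generated registry.
#'
#' @param truth truth table from [simulate_population()].
#' @param variant `"ALG1"`, `"ALG2"` or `"ASV_ONLY"`.
#' @param index_year integer calendar year.
#' @return a [validation_counts()] object.
#' @export
expected_counts <- function(truth, variant = c("ALG1", "ALG2", "ASV_ONLY"),
                            index_year) {
  variant <- match.arg(variant)
  col <- switch(variant, ALG1 = "expected_alg1", ALG2 = "expected_alg2",
                ASV_ONLY = "expected_asv_only")
  expc <- truth[[col]]
  reg_year <- as.integer(format(truth$registry_inception_date, "%Y"))
  reg_index <- truth$in_registry & !is.na(reg_year) & reg_year == as.integer(index_year)
  validation_counts(n_identified = sum(expc),
                    n_tp = sum(expc & reg_index),
                    n_diff_year = sum(expc & truth$in_registry & !reg_index),
                    n_not_in_registry = sum(expc & !truth$in_registry),
                    n_missed = sum(!expc & reg_index))
}
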