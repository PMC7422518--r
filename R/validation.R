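# Validation of an algorithm cohort against a gold-standard dialysis registry.
#
# The registry contains only patients who actually started chronic dialysis,
# so specificity/NPV cannot be computed; the comparison uses sensitivity,
# positive predictive value and percentage agreement, all derived from a
# five-cell cross-classification.

#' Cross-classify an algorithm cohort against the registry
#'
#' Matches on `patient_id`. A cohort entry is a true positive when the
#' registry holds an inception date in the index calendar year for that
#' patient (a patient re-entering the registry may have inceptions in several
#' years; one in the index year suffices). It is a different-year match when
#' the patient appears in the registry only with other inception years, and
#' not-in-registry otherwise. Missed cases are registry patients with an
#' index-year inception and no cohort entry.
#'
#' @param cohort data.frame with one row per identified patient (columns
#'   `patient_id` at minimum), e.g. from [run_algorithm()].
#' @param registry registry table ([registry_table()] schema).
#' @param index_year integer calendar year the cohort was built for.
#' @return object of class `validation_counts`: list with `n_identified`,
#'   `n_tp`, `n_diff_year`, `n_not_in_registry`, `n_missed`.
#' @export
classify_cases <- function(cohort, registry, index_year) {
  if (anyDuplicated(cohort$patient_id))
    stop("cohort must contain at most one entry per patient", call. = FALSE)
  index_year <- as.integer(index_year)
  reg_year <- as.integer(format(as.Date(registry$inception_date), "%Y"))
  reg_index <- unique(registry$patient_id[reg_year == index_year])
  reg_other <- unique(registry$patient_id[reg_year != index_year])

  tp <- cohort$patient_id %in% reg_index
  diff_year <- !tp & cohort$patient_id %in% reg_other
  validation_counts(n_identified = nrow(cohort),
                    n_tp = sum(tp),
                    n_diff_year = sum(diff_year),
                    n_not_in_registry = sum(!tp & !diff_year),
                    n_missed = sum(!reg_index %in% cohort$patient_id))
}

#' Construct a five-cell validation cross-classification
#'
#' @param n_identified cohort size; must equal
#'   `n_tp + n_diff_year + n_not_in_registry`.
#' @param n_tp cohort entries confirmed incident in the index year.
#' @param n_diff_year cohort entries in the registry with a different
#'   inception year only.
#' @param n_not_in_registry cohort entries absent from the registry.
#' @param n_missed index-year registry patients the cohort missed.
#' @return object of class `validation_counts`.
#' @export
validation_counts <- function(n_identified, n_tp, n_diff_year,
                              n_not_in_registry, n_missed) {
  x <- list(n_identified = as.integer(n_identified), n_tp = as.integer(n_tp),
            n_diff_year = as.integer(n_diff_year),
            n_not_in_registry = as.integer(n_not_in_registry),
            n_missed = as.integer(n_missed))
  if (any(vapply(x, function(v) is.na(v) || v < 0, logical(1L))))
    stop("counts must be non-negative integers")
  if (x$n_identified != x$n_tp + x$n_diff_year + x$n_not_in_registry)
    stop("n_identified must equal n_tp + n_diff_year + n_not_in_registry")
  structure(x, class = "validation_counts")
}

#' @export
print.validation_counts <- function(x, ...) {
  cat("Cohort vs registry cross-classification\n")
  cat("  identified by the algorithm :", x$n_identified, "\n")
  cat("    registry, index year      :", x$n_tp, "\n")
  cat("    registry, different year  :", x$n_diff_year, "\n")
  cat("    not in registry           :", x$n_not_in_registry, "\n")
  cat("  registry cases missed       :", x$n_missed, "\n")
  invisible(x)
}

# half-away-from-zero rounding (the reporting convention for percentages);
# the tiny epsilon guards exact halves against binary representation error
.round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

.pct <- function(num, den, digits = 1L) {
  if (is.na(den) || den == 0L) return(NA_real_)
  .round_half_up(100 * num / den, digits)
}

#' Validation metrics
#'
#' `sensitivity()` is `100 * TP / (TP + missed)`: the share of index-year
#' registry cases the algorithm found. `ppv()` is `100 * TP / identified`: the
#' share of algorithm cases confirmed incident in the index year. `agreement()`
#' is `100 * TP / (identified + missed)`. All are reported to 1 decimal,
#' rounding halves away from zero; a zero denominator yields `NA`.
#'
#' @param counts a `validation_counts` object.
#' @return numeric percentage in `[0, 100]`, or `NA` when undefined.
#' @examples
#' cts <- validation_counts(680, 571, 70, 39, 58)
#' sensitivity(cts)  # 90.8
#' ppv(cts)          # 84.0
#' agreement(cts)    # 77.4
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  .pct(counts$n_tp, counts$n_tp + counts$n_missed)
}

#' @rdname sensitivity
#' @export
ppv <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  .pct(counts$n_tp, counts$n_identified)
}

#' @rdname sensitivity
#' @export
agreement <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  .pct(counts$n_tp, counts$n_identified + counts$n_missed)
}

#' Full accuracy report
#'
#' Bundles the cross-classification with the three metrics, keeping both the
#' raw ratios and the rounded percentages.
#'
#' @inheritParams sensitivity
#' @return object of class `accuracy_report`: the counts plus
#'   `sensitivity_pct`, `ppv_pct`, `agreement_pct` (1 decimal) and the
#'   unrounded `sensitivity_raw`, `ppv_raw`, `agreement_raw`.
#' @export
accuracy_report <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  raw <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  structure(list(counts = counts,
                 sensitivity_pct = sensitivity(counts),
                 ppv_pct = ppv(counts),
                 agreement_pct = agreement(counts),
                 sensitivity_raw = raw(counts$n_tp, counts$n_tp + counts$n_missed),
                 ppv_raw = raw(counts$n_tp, counts$n_identified),
                 agreement_raw = raw(counts$n_tp, counts$n_identified + counts$n_missed)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  print(x$counts)
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", v)
  cat("  Percentage agreement        :", fmt(x$agreement_pct), "\n")
  cat("  Sensitivity                 :", fmt(x$sensitivity_pct), "\n")
  cat("  Positive predictive value   :", fmt(x$ppv_pct), "\n")
  invisible(x)
}

#' Descriptive characteristics of an identified cohort
#'
#' Summarizes an identified cohort the way registry reports do: size, age at
#' index (from birth dates found on the patient's records), percent female,
#' percent hemodialysis, number of dialysis treatments in the first year of
#' follow-up (median and interquartile range, counted on the variant's
#' timeline within `(index, index + followup]`) and number of hospital
#' admissions in that window (mean and SD). Statistics whose inputs are
#' entirely missing are reported as `NA`.
#'
#' @param cohort data.frame from [run_algorithm()].
#' @param hdr,asv the administrative tables the cohort was identified from.
#' @param config the [algorithm_config()] used.
#' @return one-row data.frame: `n`, `age_mean`, `age_sd`, `female_pct`,
#'   `hd_pct`, `treatments_median`, `treatments_p25`, `treatments_p75`,
#'   `admissions_mean`, `admissions_sd`.
#' @export
cohort_characteristics <- function(cohort, hdr, asv, config) {
  empty <- data.frame(n = 0L, age_mean = NA_real_, age_sd = NA_real_,
                      female_pct = NA_real_, hd_pct = NA_real_,
                      treatments_median = NA_real_, treatments_p25 = NA_real_,
                      treatments_p75 = NA_real_, admissions_mean = NA_real_,
                      admissions_sd = NA_real_)
  if (nrow(cohort) == 0L) return(empty)

  demo <- data.table::rbindlist(list(
    data.table::data.table(patient_id = hdr$patient_id,
                           birth_date = hdr$birth_date, sex = hdr$sex),
    data.table::data.table(patient_id = asv$patient_id,
                           birth_date = asv$birth_date, sex = asv$sex)))
  demo <- demo[patient_id %in% cohort$patient_id]
  first_known <- demo[, list(birth_date = birth_date[!is.na(birth_date)][1L],
                             sex = sex[!is.na(sex)][1L]), by = patient_id]
  co <- merge(data.table::as.data.table(cohort), first_known,
              by = "patient_id", all.x = TRUE)

  age <- as.numeric(co$index_date - co$birth_date) / 365.25
  tl <- data.table::as.data.table(build_timeline(hdr, asv, config))
  tl <- merge(co[, list(patient_id, index_date)], tl, by = "patient_id",
              allow.cartesian = TRUE)
  n_treat <- tl[date > index_date & date <= index_date + config$followup_days,
                list(k = .N), by = patient_id]
  treat <- merge(co[, list(patient_id)], n_treat, by = "patient_id", all.x = TRUE)
  treat[is.na(k), k := 0L]

  adm <- data.table::data.table(patient_id = hdr$patient_id,
                                admission_date = hdr$admission_date)
  adm <- merge(co[, list(patient_id, index_date)], adm, by = "patient_id",
               allow.cartesian = TRUE)
  n_adm <- adm[admission_date > index_date &
                 admission_date <= index_date + config$followup_days,
               list(k = .N), by = patient_id]
  adms <- merge(co[, list(patient_id)], n_adm, by = "patient_id", all.x = TRUE)
  adms[is.na(k), k := 0L]

  qs <- stats::quantile(treat$k, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = nrow(cohort),
             age_mean = if (all(is.na(age))) NA_real_ else mean(age, na.rm = TRUE),
             age_sd = if (all(is.na(age))) NA_real_ else stats::sd(age, na.rm = TRUE),
             female_pct = if (all(is.na(co$sex))) NA_real_ else
               100 * mean(co$sex == "F", na.rm = TRUE),
             hd_pct = 100 * mean(cohort$modality == "HD"),
             treatments_median = qs[2L], treatments_p25 = qs[1L],
             treatments_p75 = qs[3L],
             admissions_mean = mean(adms$k), admissions_sd = stats::sd(adms$k))
}
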