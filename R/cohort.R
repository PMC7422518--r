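# Incident chronic dialysis case definition.
#
# Inclusion: (1) an admission in the index period carrying a dialysis-related
# diagnosis (unless its only dialysis-related procedures create the access
# fistula/catheter); (2) an admission with a hemodialysis or peritoneal
# dialysis procedure dated inside the index period (procedure precedence over
# diagnosis is absolute within one record, and the earliest procedure date is
# used); (3) an outpatient dialysis session/summary in the index period.
# The index date is the earliest candidate date.
#
# Exclusion, in fixed order: (a) non-residents, (b) prevalent cases (any
# dialysis treatment in the 365 days before the index date), (c) non-chronic
# dialysis (less than 30 days -- 90 after acute kidney injury -- between the
# index date and the last dialysis within one year of follow-up), (d) death
# during the index admission (variant ALG2 only).
#
# The two main variants differ only in where previous/subsequent dialysis
# treatments are searched: ALG1 uses the outpatient (ASV) stream only, ALG2
# additionally counts inpatient dialysis procedures. ASV_ONLY further
# restricts the index search itself to the outpatient stream.

.SOURCE_PRECEDENCE <- c("HDR_PROC", "ASV", "HDR_DX")
.MODALITY_PRECEDENCE <- c("HD", "PD", "UNKNOWN")
.AKI_LOOKBACK_DAYS <- 90L  # admissions less than 90 days before the index date

#' Configuration of the case-definition algorithm
#'
#' @param index_period_start,index_period_end inclusive `Date` bounds of the
#'   calendar window in which incident cases are sought (e.g. one calendar
#'   year).
#' @param variant `"ALG1"` (default; previous/subsequent dialysis searched in
#'   the outpatient stream only), `"ALG2"` (inpatient dialysis procedures also
#'   count as treatments, and death during the index admission excludes), or
#'   `"ASV_ONLY"` (as ALG1 but the index event itself is searched only in the
#'   outpatient stream).
#' @param chronicity_days_non_aki minimum days between index date and the last
#'   observed dialysis within follow-up for the patient to count as chronic
#'   (default 30).
#' @param chronicity_days_aki the same threshold for patients whose dialysis
#'   followed acute kidney injury (default 90; must be >=
#'   `chronicity_days_non_aki`). The 60/90-day sensitivity-analysis variants
#'   are obtained by raising `chronicity_days_non_aki` and keeping this at
#'   `max(90, chronicity_days_non_aki)`.
#' @param prevalence_lookback_days lookback for the prevalence exclusion
#'   (default 365): a treatment in `[index - lookback, index - 1]` marks the
#'   patient prevalent.
#' @param followup_days follow-up horizon for the chronicity check (default
#'   365): only treatments in `(index, index + followup]` count.
#' @param target_region region-of-residence code of the population under
#'   study; any in-period record carrying a different (non-missing) region
#'   excludes the patient.
#' @param code_system `"ICD9"` (default) or `"ICD10"` for diagnosis codes.
#' @param fistula_exclusion_scope `"all_dx"` (default): an admission whose only
#'   dialysis-related procedures are access creation never qualifies through a
#'   diagnosis code; `"eskd_only"`: that block applies only when end-stage
#'   kidney disease is the sole qualifying diagnosis.
#' @return An object of class `algorithm_config` (a validated list).
#' @examples
#' cfg <- algorithm_config(as.Date("2014-01-01"), as.Date("2014-12-31"))
#' @export
algorithm_config <- function(index_period_start, index_period_end,
                             variant = c("ALG1", "ALG2", "ASV_ONLY"),
                             chronicity_days_non_aki = 30L,
                             chronicity_days_aki = max(90L, chronicity_days_non_aki),
                             prevalence_lookback_days = 365L,
                             followup_days = 365L,
                             target_region = "080",
                             code_system = c("ICD9", "ICD10"),
                             fistula_exclusion_scope = c("all_dx", "eskd_only")) {
  variant <- match.arg(variant)
  code_system <- match.arg(code_system)
  fistula_exclusion_scope <- match.arg(fistula_exclusion_scope)
  index_period_start <- as.Date(index_period_start)
  index_period_end <- as.Date(index_period_end)
  stopifnot(!is.na(index_period_start), !is.na(index_period_end),
            index_period_start <= index_period_end)
  days <- c(chronicity_days_non_aki, chronicity_days_aki,
            prevalence_lookback_days, followup_days)
  if (any(is.na(days)) || any(days <= 0))
    stop("all day-count parameters must be positive")
  if (chronicity_days_aki < chronicity_days_non_aki)
    stop("chronicity_days_aki must be >= chronicity_days_non_aki")
  structure(list(index_period_start = index_period_start,
                 index_period_end = index_period_end,
                 variant = variant,
                 chronicity_days_non_aki = as.integer(chronicity_days_non_aki),
                 chronicity_days_aki = as.integer(chronicity_days_aki),
                 prevalence_lookback_days = as.integer(prevalence_lookback_days),
                 followup_days = as.integer(followup_days),
                 target_region = as.character(target_region),
                 code_system = code_system,
                 fistula_exclusion_scope = fistula_exclusion_scope),
            class = "algorithm_config")
}

#' @export
print.algorithm_config <- function(x, ...) {
  cat("Incident chronic dialysis case definition (", x$variant, ")\n", sep = "")
  cat("  index period        : ", format(x$index_period_start), " .. ",
      format(x$index_period_end), "\n", sep = "")
  cat("  chronicity threshold: ", x$chronicity_days_non_aki, " days (",
      x$chronicity_days_aki, " after AKI)\n", sep = "")
  cat("  prevalence lookback : ", x$prevalence_lookback_days, " days; follow-up ",
      x$followup_days, " days\n", sep = "")
  cat("  target region       : ", x$target_region, " [", x$code_system, "]\n",
      sep = "")
  invisible(x)
}

.empty_candidates <- function() {
  data.table::data.table(patient_id = character(),
                         event_date = as.Date(character()),
                         source = character(), modality_hint = character(),
                         admission_id = integer())
}

#' Index-event candidates from hospital discharge records
#'
#' Applies inclusion rules 1 and 2 to each admission. Rule 2 (procedure): if
#' any hemodialysis/peritoneal dialysis procedure has its date (missing dates
#' fall back to the admission date) inside the index period, one candidate is
#' emitted at the earliest such date, with the procedure's modality. Rule 1
#' (diagnosis) applies only to admissions not emitting a rule-2 candidate:
#' admission date inside the index period, a dialysis-related diagnosis
#' present, and the admission is not a pure access-creation (fistula-only)
#' admission.
#'
#' @param hdr HDR table ([hdr_table()] schema).
#' @param config an [algorithm_config()].
#' @return data.frame of candidates: `patient_id`, `event_date`, `source`
#'   (`"HDR_PROC"`/`"HDR_DX"`), `modality_hint` (`"HD"`/`"PD"`/`"UNKNOWN"`),
#'   `admission_id` (row index into `hdr`).
#' @export
hdr_index_candidates <- function(hdr, config) {
  if (nrow(hdr) == 0L) return(as.data.frame(.empty_candidates()))
  procs <- .hdr_procedures_long(hdr, config$code_system)
  dxs <- .hdr_diagnoses_long(hdr, config$code_system)

  # rule 2: dialysis procedures dated inside the index period
  dial <- procs[category %in% c("HD_PROC", "PD_PROC") &
                  date >= config$index_period_start &
                  date <= config$index_period_end]
  rule2 <- .empty_candidates()
  if (nrow(dial)) {
    dial[, mod_rank := match(modality, .MODALITY_PRECEDENCE)]
    data.table::setorder(dial, admission_id, date, mod_rank)
    first <- dial[, .SD[1L], by = admission_id]
    rule2 <- first[, list(patient_id, event_date = date, source = "HDR_PROC",
                          modality_hint = modality, admission_id)]
  }

  # rule 1: diagnosis-qualified admissions (procedure precedence is absolute)
  qual_dx <- dxs[category %in% c("ESKD_DX", "DIALYSIS_STATUS_DX",
                                 "DIALYSIS_ENCOUNTER_DX")]
  rule1 <- .empty_candidates()
  if (nrow(qual_dx)) {
    adm <- qual_dx[, list(
      eskd_only = all(category == "ESKD_DX"),
      patient_id = patient_id[1L],
      admission_date = admission_date[1L]), by = admission_id]
    adm <- adm[admission_date >= config$index_period_start &
                 admission_date <= config$index_period_end]
    adm <- adm[!admission_id %in% rule2$admission_id]
    if (nrow(adm)) {
      dial_related <- procs[category %in% c("HD_PROC", "PD_PROC", "FISTULA_PROC"),
                            list(fistula_only = all(category == "FISTULA_PROC")),
                            by = admission_id]
      adm <- merge(adm, dial_related, by = "admission_id", all.x = TRUE)
      adm[is.na(fistula_only), fistula_only := FALSE]
      blocked <- if (config$fistula_exclusion_scope == "all_dx")
        adm$fistula_only else adm$fistula_only & adm$eskd_only
      adm <- adm[!blocked]
      if (nrow(adm))
        rule1 <- adm[, list(patient_id, event_date = admission_date,
                            source = "HDR_DX", modality_hint = "UNKNOWN",
                            admission_id)]
    }
  }
  as.data.frame(data.table::rbindlist(list(rule2, rule1)))
}

#' Index-event candidates from ambulatory specialty visits
#'
#' Inclusion rule 3: one candidate per outpatient hemodialysis session or
#' peritoneal dialysis summary whose service date lies in the index period.
#'
#' @param asv ASV table ([asv_table()] schema).
#' @inheritParams hdr_index_candidates
#' @return data.frame of candidates as in [hdr_index_candidates()], with
#'   source `"ASV"` and `admission_id` `NA`.
#' @export
asv_index_candidates <- function(asv, config) {
  if (nrow(asv) == 0L) return(as.data.frame(.empty_candidates()))
  cat_ <- classify_code(asv$service_code, "ASV_SERVICE", config$code_system)
  keep <- cat_ %in% c("HD_SERVICE", "PD_SERVICE") &
    asv$service_date >= config$index_period_start &
    asv$service_date <= config$index_period_end
  out <- data.table::data.table(patient_id = asv$patient_id[keep],
                                event_date = asv$service_date[keep],
                                source = "ASV",
                                modality_hint = .category_modality(cat_[keep]),
                                admission_id = NA_integer_)
  as.data.frame(unique(out))
}

.pick_index <- function(cand) {
  # deterministic first candidate per patient: earliest date, then source
  # precedence HDR_PROC > ASV > HDR_DX, then modality HD > PD > UNKNOWN
  cand <- data.table::as.data.table(cand)
  cand[, src_rank := match(source, .SOURCE_PRECEDENCE)]
  cand[, mod_rank := match(modality_hint, .MODALITY_PRECEDENCE)]
  data.table::setorder(cand, patient_id, event_date, src_rank, mod_rank,
                       admission_id, na.last = TRUE)
  idx <- cand[, .SD[1L], by = patient_id]
  idx[, c("src_rank", "mod_rank") := NULL]
  idx[]
}

#' Assign the index date from a patient's candidate events
#'
#' Returns the candidate with the earliest event date; date ties are broken by
#' source precedence (`HDR_PROC` > `ASV` > `HDR_DX`), then by modality
#' (`HD` > `PD` > `UNKNOWN`). Deterministic under any input ordering.
#'
#' @param candidates data.frame of one patient's candidate events.
#' @return one-row data.frame: the index event.
#' @export
assign_index_date <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("patient has no index event", call. = FALSE)
  if (length(unique(candidates$patient_id)) != 1L)
    stop("candidates must belong to a single patient", call. = FALSE)
  as.data.frame(.pick_index(candidates))
}

#' Build a patient-level timeline of actual dialysis treatments
#'
#' Collects the dated dialysis treatments the chosen variant recognizes:
#' outpatient sessions/summaries always; inpatient hemodialysis/peritoneal
#' dialysis procedures (at their dates, falling back to the admission date)
#' additionally under `ALG2`. Diagnosis-only admissions never contribute.
#'
#' @inheritParams hdr_index_candidates
#' @param asv ASV table.
#' @return data.frame: `patient_id`, `date`, `source` (`"ASV"`/`"HDR"`),
#'   `modality`; sorted, deduplicated at (patient, date, source, modality).
#' @export
build_timeline <- function(hdr, asv, config) {
  pieces <- list()
  if (nrow(asv)) {
    cat_ <- classify_code(asv$service_code, "ASV_SERVICE", config$code_system)
    keep <- cat_ %in% c("HD_SERVICE", "PD_SERVICE")
    pieces$asv <- data.table::data.table(patient_id = asv$patient_id[keep],
                                         date = asv$service_date[keep],
                                         source = "ASV",
                                         modality = .category_modality(cat_[keep]))
  }
  if (config$variant == "ALG2" && nrow(hdr)) {
    procs <- .hdr_procedures_long(hdr, config$code_system)
    dial <- procs[category %in% c("HD_PROC", "PD_PROC")]
    pieces$hdr <- dial[, list(patient_id, date, source = "HDR", modality)]
  }
  out <- data.table::rbindlist(pieces)
  if (is.null(out) || nrow(out) == 0L)
    out <- data.table::data.table(patient_id = character(),
                                  date = as.Date(character()),
                                  source = character(), modality = character())
  out <- unique(out)
  data.table::setorder(out, patient_id, date, source, modality)
  as.data.frame(out)
}

#' Residence exclusion (criterion a)
#'
#' A patient is flagged non-resident when at least one of their records dated
#' inside the index period (admission date for HDR, service date for ASV)
#' carries a present region of residence different from the target region.
#' Missing regions never trigger the exclusion.
#'
#' @inheritParams build_timeline
#' @return named logical vector over the patients appearing in either table.
#' @export
is_nonresident <- function(hdr, asv, config) {
  recs <- data.table::rbindlist(list(
    data.table::data.table(patient_id = hdr$patient_id, date = hdr$admission_date,
                           region = hdr$region),
    data.table::data.table(patient_id = asv$patient_id, date = asv$service_date,
                           region = asv$region)))
  if (nrow(recs) == 0L) return(stats::setNames(logical(), character()))
  in_period <- recs[date >= config$index_period_start &
                      date <= config$index_period_end]
  flag <- in_period[, list(nonres = any(!is.na(region) &
                                          region != config$target_region)),
                    by = patient_id]
  all_ids <- unique(recs$patient_id)
  out <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  out[flag$patient_id] <- flag$nonres
  out
}

#' Prevalence exclusion (criterion b)
#'
#' A patient is prevalent when any dialysis treatment on their timeline falls
#' in the closed lookback window `[index - lookback, index - 1]`; the index
#' day itself is not "before".
#'
#' @param index_date the patient's index `Date`.
#' @param timeline_dates `Date` vector of the patient's dialysis treatment
#'   dates (per variant, see [build_timeline()]).
#' @param config an [algorithm_config()].
#' @return logical scalar.
#' @export
is_prevalent <- function(index_date, timeline_dates, config) {
  d <- as.integer(as.Date(index_date) - as.Date(timeline_dates))
  any(d >= 1L & d <= config$prevalence_lookback_days)
}

#' Acute kidney injury at dialysis initiation
#'
#' TRUE when an AKI diagnosis appears (i) in the admission that generated the
#' index event (for HDR-sourced index events), or (ii) in any admission dated
#' less than 90 days before the index date (`0 <= index - admission < 90`).
#'
#' @param hdr HDR table covering the patient's admissions.
#' @param index_event one-row data.frame from [assign_index_date()].
#' @inheritParams is_prevalent
#' @return logical scalar.
#' @export
has_aki <- function(hdr, index_event, config) {
  pat <- hdr[hdr$patient_id == index_event$patient_id, , drop = FALSE]
  if (nrow(pat) == 0L) return(FALSE)
  dxs <- .hdr_diagnoses_long(hdr, config$code_system)
  aki <- dxs[category == "AKI_DX" & patient_id == index_event$patient_id]
  if (nrow(aki) == 0L) return(FALSE)
  if (index_event$source %in% c("HDR_DX", "HDR_PROC") &&
      !is.na(index_event$admission_id) &&
      any(aki$admission_id == index_event$admission_id)) return(TRUE)
  lag <- as.integer(as.Date(index_event$event_date) - aki$admission_date)
  any(lag >= 0L & lag < .AKI_LOOKBACK_DAYS)
}

#' Chronicity criterion (criterion c, inverted)
#'
#' Let `L` be the latest timeline treatment within `(index, index +
#' followup]`, and `gap = L - index` in days (0 when no such treatment). The
#' patient is chronic when `gap >= threshold`, with threshold
#' `chronicity_days_aki` after AKI and `chronicity_days_non_aki` otherwise
#' ("less than threshold" excludes).
#'
#' @inheritParams is_prevalent
#' @param aki_flag logical from [has_aki()].
#' @return logical scalar.
#' @export
is_chronic <- function(index_date, timeline_dates, aki_flag, config) {
  index_date <- as.Date(index_date)
  d <- as.integer(as.Date(timeline_dates) - index_date)
  d <- d[d >= 1L & d <= config$followup_days]
  gap <- if (length(d)) max(d) else 0L
  thr <- if (isTRUE(aki_flag)) config$chronicity_days_aki else config$chronicity_days_non_aki
  gap >= thr
}

#' In-hospital death at the index admission (criterion d)
#'
#' TRUE when the index event originates from an admission whose discharge
#' records death. Always FALSE for outpatient-sourced index events, even if
#' the patient later dies in hospital. Applied by variant `ALG2` only.
#'
#' @inheritParams has_aki
#' @return logical scalar.
#' @export
died_in_index_admission <- function(hdr, index_event) {
  if (!index_event$source %in% c("HDR_DX", "HDR_PROC")) return(FALSE)
  isTRUE(hdr$discharged_dead[index_event$admission_id])
}

#' Assign the dialysis modality of a cohort entry
#'
#' The index event's own modality when known; otherwise the modality of the
#' earliest timeline treatment on or after the index date; otherwise `"HD"`
#' (documented default, with a warning).
#'
#' @inheritParams has_aki
#' @param timeline the patient's timeline (data.frame from [build_timeline()]).
#' @return `"HD"` or `"PD"`.
#' @export
assign_modality <- function(index_event, timeline) {
  if (index_event$modality_hint %in% c("HD", "PD"))
    return(index_event$modality_hint)
  tl <- timeline[timeline$patient_id == index_event$patient_id &
                   timeline$date >= as.Date(index_event$event_date) &
                   timeline$modality %in% c("HD", "PD"), , drop = FALSE]
  if (nrow(tl)) {
    tl <- tl[order(tl$date, match(tl$modality, .MODALITY_PRECEDENCE)), , drop = FALSE]
    return(tl$modality[1L])
  }
  warning("no modality evidence for patient ", index_event$patient_id,
          "; defaulting to HD", call. = FALSE)
  "HD"
}

.empty_cohort <- function() {
  data.frame(patient_id = character(), index_date = as.Date(character()),
             modality = character(), aki_flag = logical(), source = character(),
             stringsAsFactors = FALSE)
}

.empty_audit <- function() {
  data.frame(patient_id = character(), index_date = as.Date(character()),
             source = character(), excluded_by = character(),
             exclusion_trace = character(), stringsAsFactors = FALSE)
}

#' Run the full case-definition algorithm
#'
#' Applies the inclusion rules, assigns per-patient index dates, and applies
#' the exclusion criteria in the fixed order residence -> prevalence ->
#' chronicity -> in-hospital death (the last under `ALG2` only). The result is
#' a pure function of its inputs: row order of the input tables never matters,
#' and duplicate records are dropped before processing.
#'
#' The input tables must cover all dialysis events from
#' `prevalence_lookback_days` before the index period to `followup_days` after
#' it; records outside that window are ignored. If `data_window` (the span the
#' extracts are known to cover) is supplied it is checked against this
#' requirement and an error names any missing span.
#'
#' @inheritParams build_timeline
#' @param data_window optional length-2 `Date` vector declaring the period the
#'   input extracts cover.
#' @return data.frame with one row per identified incident chronic dialysis
#'   patient (`patient_id`, `index_date`, `modality`, `aki_flag`, `source`),
#'   sorted by `patient_id`. The attribute `"audit"` holds one row per
#'   candidate patient with the exclusion checks evaluated (in order, stopping
#'   at the first failure) and `excluded_by` (`NA` for included patients).
#' @export
run_algorithm <- function(hdr, asv, config, data_window = NULL) {
  stopifnot(inherits(config, "algorithm_config"))
  win_lo <- config$index_period_start - config$prevalence_lookback_days
  win_hi <- config$index_period_end + config$followup_days
  if (!is.null(data_window)) {
    data_window <- as.Date(data_window)
    stopifnot(length(data_window) == 2L)
    miss <- character()
    if (data_window[1L] > win_lo)
      miss <- c(miss, paste0(format(win_lo), " .. ", format(data_window[1L] - 1)))
    if (data_window[2L] < win_hi)
      miss <- c(miss, paste0(format(data_window[2L] + 1), " .. ", format(win_hi)))
    if (length(miss))
      stop("input tables do not cover the required window (index period ± ",
           "lookback/follow-up); missing span(s): ", paste(miss, collapse = "; "),
           call. = FALSE)
  }

  hdr <- unique(hdr)
  asv <- unique(asv)
  # window conservation: nothing outside [start - lookback, end + followup]
  # can influence the result
  hdr <- hdr[hdr$admission_date <= win_hi & hdr$discharge_date >= win_lo, , drop = FALSE]
  asv <- asv[asv$service_date >= win_lo & asv$service_date <= win_hi, , drop = FALSE]
  rownames(hdr) <- NULL

  cand <- if (config$variant == "ASV_ONLY") {
    asv_index_candidates(asv, config)
  } else {
    rbind(hdr_index_candidates(hdr, config), asv_index_candidates(asv, config))
  }
  if (nrow(cand) == 0L) {
    out <- .empty_cohort()
    attr(out, "audit") <- .empty_audit()
    return(out)
  }

  idx <- .pick_index(cand)
  tl <- data.table::as.data.table(build_timeline(hdr, asv, config))

  # criterion a: residence
  nonres_map <- is_nonresident(hdr, asv, config)
  idx[, nonresident := unname(nonres_map[patient_id])]
  idx[is.na(nonresident), nonresident := FALSE]

  # criterion b: prevalence lookback on the variant's timeline
  lb <- merge(idx[, list(patient_id, event_date)], tl, by = "patient_id",
              allow.cartesian = TRUE)
  lb[, lag := as.integer(event_date - date)]
  prev <- lb[lag >= 1L & lag <= config$prevalence_lookback_days,
             list(prevalent = TRUE), by = patient_id]
  idx[, prevalent := patient_id %in% prev$patient_id]

  # criterion c: chronicity, with the AKI-specific threshold
  dxs <- .hdr_diagnoses_long(hdr, config$code_system)
  aki_adm <- dxs[category == "AKI_DX",
                 list(admission_id, patient_id, admission_date)]
  idx[, aki_flag := FALSE]
  if (nrow(aki_adm)) {
    same_adm <- aki_adm[idx[source != "ASV"],
                        on = c("patient_id", "admission_id"), nomatch = NULL]
    recent <- merge(idx[, list(patient_id, event_date)], aki_adm,
                    by = "patient_id", allow.cartesian = TRUE)
    recent[, lag := as.integer(event_date - admission_date)]
    recent <- recent[lag >= 0L & lag < .AKI_LOOKBACK_DAYS]
    idx[, aki_flag := patient_id %in% c(same_adm$patient_id, recent$patient_id)]
  }
  fu <- merge(idx[, list(patient_id, event_date)], tl, by = "patient_id",
              allow.cartesian = TRUE)
  fu[, ahead := as.integer(date - event_date)]
  gaps <- fu[ahead >= 1L & ahead <= config$followup_days,
             list(gap = max(ahead)), by = patient_id]
  idx <- merge(idx, gaps, by = "patient_id", all.x = TRUE)
  idx[is.na(gap), gap := 0L]
  idx[, threshold := data.table::fifelse(aki_flag, config$chronicity_days_aki,
                                         config$chronicity_days_non_aki)]
  idx[, chronic := gap >= threshold]

  # criterion d: death at the index admission (ALG2 only)
  idx[, died_index := FALSE]
  if (config$variant == "ALG2") {
    hdr_idx <- idx[source != "ASV" & !is.na(admission_id)]
    if (nrow(hdr_idx))
      idx[source != "ASV" & !is.na(admission_id),
          died_index := hdr$discharged_dead[admission_id]]
  }

  checks <- list(nonresident = idx$nonresident,
                 prevalent = idx$prevalent,
                 non_chronic = !idx$chronic)
  if (config$variant == "ALG2")
    checks$died_in_index_admission <- idx$died_index
  fail_mat <- do.call(cbind, checks)
  first_fail <- apply(fail_mat, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1L] else NA_integer_
  })
  idx[, excluded_by := data.table::fifelse(is.na(first_fail), NA_character_,
                                           names(checks)[first_fail])]
  trace <- vapply(seq_len(nrow(idx)), function(i) {
    upto <- if (is.na(first_fail[i])) length(checks) else first_fail[i]
    paste(paste0(names(checks)[seq_len(upto)], ":",
                 ifelse(fail_mat[i, seq_len(upto)], "fail", "pass")),
          collapse = ";")
  }, character(1L))
  idx[, exclusion_trace := trace]

  audit <- as.data.frame(idx[, list(patient_id, index_date = event_date, source,
                                    excluded_by, exclusion_trace)])
  audit <- audit[order(audit$patient_id), , drop = FALSE]
  rownames(audit) <- NULL

  inc <- idx[is.na(excluded_by)]
  if (nrow(inc) == 0L) {
    out <- .empty_cohort()
    attr(out, "audit") <- audit
    return(out)
  }
  tl_df <- as.data.frame(tl)
  modality <- vapply(seq_len(nrow(inc)), function(i)
    assign_modality(inc[i], tl_df), character(1L))
  out <- data.frame(patient_id = inc$patient_id, index_date = inc$event_date,
                    modality = modality, aki_flag = inc$aki_flag,
                    source = inc$source, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}
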