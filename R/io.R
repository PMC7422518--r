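# Flat-table schemas, constructors, readers and writers for the three
# administrative sources: hospital discharge records (HDR), ambulatory
# specialty visits (ASV) and the gold-standard dialysis registry.
#
# Files are delimited text (default comma), UTF-8, header row, ISO 8601 dates,
# empty cells for unused slots. In memory each table is a plain data.frame
# with Date columns, logical discharged_dead, and NA for absent values.

.DX_COLS <- paste0("dx", 1:15)
.PROC_CODE_COLS <- paste0("proc", 1:15, "_code")
.PROC_DATE_COLS <- paste0("proc", 1:15, "_date")
.HDR_COLS <- c("patient_id", "admission_date", "discharge_date",
               .DX_COLS,
               as.vector(rbind(.PROC_CODE_COLS, .PROC_DATE_COLS)),
               "region", "discharged_dead", "birth_date", "sex")
.ASV_COLS <- c("patient_id", "service_date", "service_code",
               "region", "birth_date", "sex")
.REGISTRY_COLS <- c("patient_id", "inception_date", "modality")

#' Build a hospital discharge record (HDR) table
#'
#' Constructs the wide HDR table (one row per admission, up to 15 diagnosis
#' codes and 15 dated procedures) from per-record lists. With no arguments,
#' returns an empty table with the full schema.
#'
#' @param patient_id character vector of patient identifiers.
#' @param admission_date,discharge_date `Date` vectors.
#' @param diagnoses list (one element per record) of character vectors of
#'   diagnosis codes, position 1 = main diagnosis; at most 15 each.
#' @param procedures list (one element per record) of data.frames with columns
#'   `code` and `date` (Date, `NA` allowed: a missing procedure date falls back
#'   to the admission date downstream); at most 15 rows each. `NULL` elements
#'   mean no procedures.
#' @param region character vector of region-of-residence codes (`NA` = unknown).
#' @param discharged_dead logical vector: died during this admission.
#' @param birth_date `Date` vector or `NA`.
#' @param sex `"F"`, `"M"` or `NA`.
#' @return data.frame in the HDR schema.
#' @export
hdr_table <- function(patient_id = character(),
                      admission_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      diagnoses = list(),
                      procedures = list(),
                      region = NA_character_,
                      discharged_dead = FALSE,
                      birth_date = as.Date(NA),
                      sex = NA_character_) {
  n <- length(patient_id)
  stopifnot(length(admission_date) == n, length(discharge_date) == n)
  if (length(diagnoses) == 0L) diagnoses <- rep(list(character()), n)
  if (length(procedures) == 0L) procedures <- rep(list(NULL), n)
  stopifnot(length(diagnoses) == n, length(procedures) == n)

  out <- data.frame(patient_id = as.character(patient_id),
                    admission_date = as.Date(admission_date),
                    discharge_date = as.Date(discharge_date),
                    stringsAsFactors = FALSE)
  dx <- matrix(NA_character_, nrow = n, ncol = 15L, dimnames = list(NULL, .DX_COLS))
  pc <- matrix(NA_character_, nrow = n, ncol = 15L, dimnames = list(NULL, .PROC_CODE_COLS))
  pd <- matrix(as.Date(NA), nrow = n, ncol = 15L)
  for (i in seq_len(n)) {
    d <- normalize_code(diagnoses[[i]])
    d <- d[nzchar(d)]
    if (length(d) > 15L) stop("record ", i, ": more than 15 diagnosis codes")
    if (length(d)) dx[i, seq_along(d)] <- d
    p <- procedures[[i]]
    if (!is.null(p) && nrow(p)) {
      if (nrow(p) > 15L) stop("record ", i, ": more than 15 procedures")
      pc[i, seq_len(nrow(p))] <- normalize_code(p$code)
      pd[i, seq_len(nrow(p))] <- as.Date(p$date)
    }
  }
  out <- cbind(out, as.data.frame(dx, stringsAsFactors = FALSE))
  for (j in 1:15) {
    out[[.PROC_CODE_COLS[j]]] <- pc[, j]
    out[[.PROC_DATE_COLS[j]]] <- as.Date(pd[, j], origin = "1970-01-01")
  }
  out$region <- rep_len(as.character(region), n)
  out$discharged_dead <- rep_len(as.logical(discharged_dead), n)
  out$birth_date <- rep_len(as.Date(birth_date), n)
  out$sex <- rep_len(as.character(sex), n)
  out[, .HDR_COLS]
}

#' Build an ambulatory specialty visit (ASV) table
#'
#' One row per outpatient service event (one per hemodialysis session, one
#' monthly summary record per peritoneal dialysis patient).
#'
#' @param patient_id character vector.
#' @param service_date `Date` vector.
#' @param service_code character vector of service codes (normalized).
#' @inheritParams hdr_table
#' @return data.frame in the ASV schema.
#' @export
asv_table <- function(patient_id = character(),
                      service_date = as.Date(character()),
                      service_code = character(),
                      region = NA_character_,
                      birth_date = as.Date(NA),
                      sex = NA_character_) {
  n <- length(patient_id)
  stopifnot(length(service_date) == n, length(service_code) == n)
  data.frame(patient_id = as.character(patient_id),
             service_date = as.Date(service_date),
             service_code = normalize_code(service_code),
             region = rep_len(as.character(region), n),
             birth_date = rep_len(as.Date(birth_date), n),
             sex = rep_len(as.character(sex), n),
             stringsAsFactors = FALSE)
}

#' Build a dialysis registry table
#'
#' Gold-standard incident entries: one row per (patient, inception date);
#' a patient may re-enter (e.g. returning to dialysis after a failed
#' transplant) with a later inception date.
#'
#' @param patient_id character vector.
#' @param inception_date `Date` vector: dialysis inception as assigned by the
#'   nephrologist in charge.
#' @param modality `"HD"` or `"PD"`.
#' @return data.frame in the registry schema.
#' @export
registry_table <- function(patient_id = character(),
                           inception_date = as.Date(character()),
                           modality = character()) {
  n <- length(patient_id)
  stopifnot(length(inception_date) == n, length(modality) == n)
  modality <- toupper(as.character(modality))
  if (n && !all(modality %in% c("HD", "PD")))
    stop("modality must be 'HD' or 'PD'")
  out <- data.frame(patient_id = as.character(patient_id),
                    inception_date = as.Date(inception_date),
                    modality = modality,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("patient_id", "inception_date")]))
    stop("registry has duplicate (patient_id, inception_date) entries")
  out
}

# -- parsing helpers ---------------------------------------------------------

.parse_iso_date <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  list(date = out, bad = nzchar(x) & (!ok | (ok & is.na(out))))
}

.blank_to_na <- function(x) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  x
}

.read_delim_raw <- function(path, delim, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw
}

.row_errors <- function(errors, on_error) {
  # errors: character vector, one message per bad row, already naming lines
  if (!length(errors)) return(integer())
  if (on_error == "stop")
    stop(paste(errors, collapse = "\n"), call. = FALSE)
  warning(length(errors), " malformed row(s) skipped:\n",
          paste(errors, collapse = "\n"), call. = FALSE)
}

#' Read a hospital discharge record file
#'
#' Reads and validates the wide HDR schema (see [hdr_table()] for the column
#' list). Every row must have a parseable ISO admission and discharge date with
#' `admission_date <= discharge_date`, any present procedure date inside the
#' stay, and `discharged_dead` coded 0/1. Codes are normalized on read.
#'
#' @param path file path.
#' @param delim field delimiter (default `","`).
#' @param on_error `"stop"` (default): fail listing every malformed row by line
#'   number; `"skip"`: drop malformed rows with a warning.
#' @return data.frame in the HDR schema.
#' @export
read_hdr <- function(path, delim = ",", on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  raw <- .read_delim_raw(path, delim, .HDR_COLS)
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  errs <- rep("", n)
  add_err <- function(bad, msg) {
    errs[bad & !nzchar(errs)] <<- paste0("line ", line[bad & !nzchar(errs)], ": ", msg)
  }

  adm <- .parse_iso_date(raw$admission_date)
  dis <- .parse_iso_date(raw$discharge_date)
  add_err(!nzchar(trimws(raw$patient_id)), "empty patient_id")
  add_err(adm$bad | is.na(adm$date), "malformed or missing admission_date")
  add_err(dis$bad | is.na(dis$date), "malformed or missing discharge_date")
  ord_bad <- !is.na(adm$date) & !is.na(dis$date) & adm$date > dis$date
  add_err(ord_bad, "admission_date after discharge_date")

  bd <- .parse_iso_date(raw$birth_date)
  add_err(bd$bad, "malformed birth_date")
  dd <- trimws(raw$discharged_dead)
  add_err(!dd %in% c("0", "1"), "discharged_dead must be 0 or 1")

  proc_dates <- vector("list", 15L)
  for (j in 1:15) {
    p <- .parse_iso_date(raw[[.PROC_DATE_COLS[j]]])
    add_err(p$bad, paste0("malformed ", .PROC_DATE_COLS[j]))
    in_stay_bad <- !is.na(p$date) & !is.na(adm$date) & !is.na(dis$date) &
      (p$date < adm$date | p$date > dis$date)
    add_err(in_stay_bad, paste0(.PROC_DATE_COLS[j], " outside the hospital stay"))
    proc_dates[[j]] <- p$date
  }

  .row_errors(errs[nzchar(errs)], on_error)
  keep <- !nzchar(errs)

  out <- data.frame(patient_id = trimws(raw$patient_id)[keep],
                    admission_date = adm$date[keep],
                    discharge_date = dis$date[keep],
                    stringsAsFactors = FALSE)
  for (cl in .DX_COLS) out[[cl]] <- .blank_to_na(normalize_code(raw[[cl]]))[keep]
  for (j in 1:15) {
    out[[.PROC_CODE_COLS[j]]] <- .blank_to_na(normalize_code(raw[[.PROC_CODE_COLS[j]]]))[keep]
    out[[.PROC_DATE_COLS[j]]] <- proc_dates[[j]][keep]
  }
  out$region <- .blank_to_na(raw$region)[keep]
  out$discharged_dead <- raw$discharged_dead[keep] == "1"
  out$birth_date <- bd$date[keep]
  out$sex <- .blank_to_na(toupper(raw$sex))[keep]
  out[, .HDR_COLS]
}

#' Read an ambulatory specialty visit file
#'
#' @inheritParams read_hdr
#' @return data.frame in the ASV schema (see [asv_table()]).
#' @export
read_asv <- function(path, delim = ",", on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  raw <- .read_delim_raw(path, delim, .ASV_COLS)
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  errs <- rep("", n)
  add_err <- function(bad, msg) {
    errs[bad & !nzchar(errs)] <<- paste0("line ", line[bad & !nzchar(errs)], ": ", msg)
  }
  sd <- .parse_iso_date(raw$service_date)
  bd <- .parse_iso_date(raw$birth_date)
  add_err(!nzchar(trimws(raw$patient_id)), "empty patient_id")
  add_err(sd$bad | is.na(sd$date), "malformed or missing service_date")
  add_err(!nzchar(normalize_code(raw$service_code)), "empty service_code")
  add_err(bd$bad, "malformed birth_date")
  .row_errors(errs[nzchar(errs)], on_error)
  keep <- !nzchar(errs)
  data.frame(patient_id = trimws(raw$patient_id)[keep],
             service_date = sd$date[keep],
             service_code = normalize_code(raw$service_code)[keep],
             region = .blank_to_na(raw$region)[keep],
             birth_date = bd$date[keep],
             sex = .blank_to_na(toupper(raw$sex))[keep],
             stringsAsFactors = FALSE)
}

#' Read a dialysis registry file
#'
#' @inheritParams read_hdr
#' @return data.frame in the registry schema (see [registry_table()]).
#' @export
read_registry <- function(path, delim = ",", on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  raw <- .read_delim_raw(path, delim, .REGISTRY_COLS)
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  errs <- rep("", n)
  add_err <- function(bad, msg) {
    errs[bad & !nzchar(errs)] <<- paste0("line ", line[bad & !nzchar(errs)], ": ", msg)
  }
  d <- .parse_iso_date(raw$inception_date)
  add_err(!nzchar(trimws(raw$patient_id)), "empty patient_id")
  add_err(d$bad | is.na(d$date), "malformed or missing inception_date")
  add_err(!toupper(trimws(raw$modality)) %in% c("HD", "PD"), "modality must be HD or PD")
  .row_errors(errs[nzchar(errs)], on_error)
  keep <- !nzchar(errs)
  registry_table(trimws(raw$patient_id)[keep], d$date[keep],
                 toupper(trimws(raw$modality))[keep])
}

.format_for_file <- function(x) {
  if (inherits(x, "Date")) x <- format(x, "%Y-%m-%d")
  if (is.logical(x)) x <- as.integer(x)
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

.write_delim <- function(x, path, delim) {
  out <- as.data.frame(lapply(x, .format_for_file), stringsAsFactors = FALSE,
                       check.names = FALSE)
  # preserve the header even for zero-row tables
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write administrative tables to delimited text
#'
#' Inverse of the corresponding readers: dates as ISO 8601, `discharged_dead`
#' as 0/1, `NA` as empty cells. A write-then-read round trip is the identity
#' on typed content.
#'
#' @param x a table in the matching schema.
#' @param path output file path.
#' @param delim field delimiter (default `","`).
#' @return the path, invisibly.
#' @export
write_hdr <- function(x, path, delim = ",") {
  stopifnot(all(.HDR_COLS %in% names(x)))
  .write_delim(x[, .HDR_COLS], path, delim)
}

#' @rdname write_hdr
#' @export
write_asv <- function(x, path, delim = ",") {
  stopifnot(all(.ASV_COLS %in% names(x)))
  .write_delim(x[, .ASV_COLS], path, delim)
}

#' @rdname write_hdr
#' @export
write_registry <- function(x, path, delim = ",") {
  stopifnot(all(.REGISTRY_COLS %in% names(x)))
  .write_delim(x[, .REGISTRY_COLS], path, delim)
}

# -- long-format views used by the algorithms --------------------------------

# One row per (admission, diagnosis position); adds a stable admission row id.
.hdr_diagnoses_long <- function(hdr, code_system = "ICD9") {
  dt <- data.table::as.data.table(hdr)
  dt[, admission_id := .I]
  long <- data.table::melt(
    dt[, c("admission_id", "patient_id", "admission_date", .DX_COLS), with = FALSE],
    id.vars = c("admission_id", "patient_id", "admission_date"),
    variable.name = "slot", value.name = "code")
  long <- long[!is.na(code) & nzchar(code)]
  long[, category := classify_code(code, "HDR_DIAGNOSIS", code_system)]
  long[]
}

# One row per (admission, procedure); missing procedure dates fall back to the
# admission date.
.hdr_procedures_long <- function(hdr, code_system = "ICD9") {
  dt <- data.table::as.data.table(hdr)
  dt[, admission_id := .I]
  pieces <- lapply(1:15, function(j) {
    code <- dt[[.PROC_CODE_COLS[j]]]
    keep <- !is.na(code) & nzchar(code)
    if (!any(keep)) return(NULL)
    data.table::data.table(
      admission_id = dt$admission_id[keep],
      patient_id = dt$patient_id[keep],
      admission_date = dt$admission_date[keep],
      code = code[keep],
      date = data.table::fifelse(is.na(dt[[.PROC_DATE_COLS[j]]][keep]),
                                 dt$admission_date[keep],
                                 dt[[.PROC_DATE_COLS[j]]][keep]))
  })
  out <- data.table::rbindlist(pieces)
  if (is.null(out) || nrow(out) == 0L)
    out <- data.table::data.table(admission_id = integer(), patient_id = character(),
                                  admission_date = as.Date(character()),
                                  code = character(), date = as.Date(character()))
  out[, category := classify_code(code, "HDR_PROCEDURE", code_system)]
  out[, modality := .category_modality(category)]
  out[]
}
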