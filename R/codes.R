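# Code sets: normalization, category classification, ICD-9-CM -> ICD-10-CM
# crosswalk. Matching is by normalized string with explicit prefix rules; dots
# are kept (Italian ambulatory nomenclature uses dotted sub-codes, e.g. 39.95.1).

#' Code categories recognized by the algorithms
#'
#' The closed set of categories into which [classify_code()] maps a code:
#' \describe{
#'   \item{ESKD_DX}{end-stage kidney disease diagnosis (ICD-9-CM 585.6 / ICD-10-CM N18.6)}
#'   \item{DIALYSIS_STATUS_DX}{renal dialysis status (V45.1x / Z99.2, Z91.15)}
#'   \item{DIALYSIS_ENCOUNTER_DX}{dialysis encounter (V56.0--V56.8 / Z49.x)}
#'   \item{HD_PROC}{inpatient hemodialysis procedure (39.95)}
#'   \item{PD_PROC}{inpatient peritoneal dialysis procedure (54.98)}
#'   \item{FISTULA_PROC}{vascular/peritoneal access creation (39.27, 39.29, 54.93)}
#'   \item{AKI_DX}{acute kidney injury diagnosis (584.x / N17.x)}
#'   \item{HD_SERVICE}{outpatient hemodialysis session (39.95.1--39.95.9)}
#'   \item{PD_SERVICE}{outpatient peritoneal dialysis summary (54.98.1, 54.98.2)}
#'   \item{OTHER}{anything else}
#' }
#' @format Character vector of the ten category names.
#' @export
code_categories <- c("ESKD_DX", "DIALYSIS_STATUS_DX", "DIALYSIS_ENCOUNTER_DX",
                     "HD_PROC", "PD_PROC", "FISTULA_PROC", "AKI_DX",
                     "HD_SERVICE", "PD_SERVICE", "OTHER")

#' Normalize a raw code string
#'
#' Strips surrounding whitespace and uppercases; internal dots are preserved.
#' Total and idempotent; `NA` and empty input yield `""`.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of canonical codes.
#' @examples
#' normalize_code(c(" v56.0 ", "39.95.1", ""))
#' @export
normalize_code <- function(raw) {
  out <- toupper(trimws(as.character(raw)))
  out[is.na(out)] <- ""
  out
}

# ICD-9-CM -> ICD-10-CM crosswalk (2020 edition), the ten rows used by the
# algorithms. Many-to-one on the ICD-10 side: V56.0 and V56.31 -> Z49.31;
# V56.32 and V56.8 -> Z49.32 (reproduced verbatim, not "improved").
.icd9_icd10_crosswalk <- data.frame(
  icd9  = c("584", "585.6", "V45.11", "V45.12", "V56.0",
            "V56.1", "V56.2", "V56.31", "V56.32", "V56.8"),
  icd10 = c("N17", "N18.6", "Z99.2", "Z91.15", "Z49.31",
            "Z49.01", "Z49.02", "Z49.31", "Z49.32", "Z49.32"),
  description = c(
    "Acute renal failure", "End stage renal disease",
    "Dependence on renal dialysis", "Patient's noncompliance with renal dialysis",
    "Encounter for adequacy testing for hemodialysis",
    "Encounter for fit/adjst of extracorporeal dialysis catheter",
    "Encounter for fit/adjst of peritoneal dialysis catheter",
    "Encounter for adequacy testing for hemodialysis",
    "Encounter for adequacy testing for peritoneal dialysis",
    "Encounter for adequacy testing for peritoneal dialysis"),
  stringsAsFactors = FALSE
)

#' ICD-9-CM to ICD-10-CM crosswalk table
#'
#' The conversion table for the ten ICD-9-CM codes the algorithms use, with
#' their ICD-10-CM (2020 edition) images. The mapping is many-to-one for some
#' targets.
#'
#' @return A data.frame with columns `icd9`, `icd10`, `description`.
#' @seealso [map_icd9_to_icd10()]
#' @export
icd9_icd10_crosswalk <- function() .icd9_icd10_crosswalk

#' Convert an ICD-9-CM code to its ICD-10-CM image(s)
#'
#' @param code a single ICD-9-CM code (normalized or not) present in the
#'   crosswalk table.
#' @return character vector of ICD-10-CM code(s) (always length 1 here; the
#'   interface allows one-to-many).
#' @examples
#' map_icd9_to_icd10("585.6")  # "N18.6"
#' map_icd9_to_icd10("V56.8")  # "Z49.32"
#' @export
map_icd9_to_icd10 <- function(code) {
  stopifnot(length(code) == 1L)
  code <- normalize_code(code)
  hit <- .icd9_icd10_crosswalk$icd10[.icd9_icd10_crosswalk$icd9 == code]
  if (length(hit) == 0L)
    stop("unmapped code: '", code, "' is not in the ICD-9-CM crosswalk table",
         call. = FALSE)
  unique(hit)
}

.has_prefix <- function(x, prefix) startsWith(x, prefix)

#' Classify a code into its algorithm category
#'
#' Deterministic, total classification of a (normalized) code given the field
#' it came from and the coding system. Diagnosis codes: 585.6 is end-stage
#' kidney disease; the V45.1 family (V45.11, V45.12) is dialysis status;
#' V56.0--V56.8 (prefix match, so sub-codes such as V56.31 qualify) is a
#' dialysis encounter; the 584 family is acute kidney injury. Procedure codes:
#' 39.95 hemodialysis, 54.98 peritoneal dialysis (prefix match), and 39.27,
#' 39.29, 54.93 create dialysis access (fistula/catheter). Outpatient service
#' codes: 39.95.1--39.95.9 are hemodialysis sessions, 54.98.1/54.98.2
#' peritoneal dialysis summaries. In ICD-10 mode the diagnosis images are
#' N18.6, Z99.2/Z91.15, Z49.01/Z49.02/Z49.31/Z49.32 and the N17 family;
#' procedure and service codes keep the ICD-9-CM rules (the Italian sources
#' code procedures in ICD-9-CM regardless).
#'
#' @param code character vector of codes (normalized internally).
#' @param context one of `"HDR_DIAGNOSIS"`, `"HDR_PROCEDURE"`, `"ASV_SERVICE"`:
#'   which field the code came from.
#' @param code_system `"ICD9"` (default) or `"ICD10"`.
#' @return character vector of categories (see [code_categories]).
#' @examples
#' classify_code("585.6", "HDR_DIAGNOSIS")        # ESKD_DX
#' classify_code("39.27", "HDR_PROCEDURE")        # FISTULA_PROC
#' classify_code("54.98.2", "ASV_SERVICE")        # PD_SERVICE
#' @export
classify_code <- function(code,
                          context = c("HDR_DIAGNOSIS", "HDR_PROCEDURE", "ASV_SERVICE"),
                          code_system = c("ICD9", "ICD10")) {
  context <- match.arg(context)
  code_system <- match.arg(code_system)
  x <- normalize_code(code)
  out <- rep("OTHER", length(x))

  if (context == "HDR_DIAGNOSIS") {
    if (code_system == "ICD9") {
      out[x == "585.6"] <- "ESKD_DX"
      out[.has_prefix(x, "V45.1")] <- "DIALYSIS_STATUS_DX"
      # V56.0 .. V56.8 as prefixes covers sub-codes (V56.31, V56.32, ...)
      v56 <- paste0("V56.", 0:8)
      hit <- Reduce(`|`, lapply(v56, function(p) .has_prefix(x, p)))
      out[hit] <- "DIALYSIS_ENCOUNTER_DX"
      out[.has_prefix(x, "584")] <- "AKI_DX"
    } else {
      out[x == "N18.6"] <- "ESKD_DX"
      out[x %in% c("Z99.2", "Z91.15")] <- "DIALYSIS_STATUS_DX"
      out[x %in% c("Z49.01", "Z49.02", "Z49.31", "Z49.32")] <- "DIALYSIS_ENCOUNTER_DX"
      out[.has_prefix(x, "N17")] <- "AKI_DX"
    }
  } else if (context == "HDR_PROCEDURE") {
    out[.has_prefix(x, "39.95")] <- "HD_PROC"
    out[.has_prefix(x, "54.98")] <- "PD_PROC"
    out[x %in% c("39.27", "39.29", "54.93")] <- "FISTULA_PROC"
  } else { # ASV_SERVICE
    out[x %in% paste0("39.95.", 1:9)] <- "HD_SERVICE"
    out[x %in% c("54.98.1", "54.98.2")] <- "PD_SERVICE"
  }
  out
}

# Modality implied by a dialysis code category; "UNKNOWN" when none.
.category_modality <- function(category) {
  out <- rep("UNKNOWN", length(category))
  out[category %in% c("HD_PROC", "HD_SERVICE")] <- "HD"
  out[category %in% c("PD_PROC", "PD_SERVICE")] <- "PD"
  out
}
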