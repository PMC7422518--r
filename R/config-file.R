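# Plain key = value configuration files and run manifests for the command-line
# interface (inst/cli/dialcohort.R). One file can drive the whole
# simulate -> identify -> validate chain; command-line flags override file keys.

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are kept as strings; comma-separated values become character
#' vectors. Later duplicate keys override earlier ones.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- list()
  for (i in seq_along(keys)) {
    v <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1L]])
    out[[keys[i]]] <- v
  }
  out
}

#' Build an [algorithm_config()] from a configuration list
#'
#' Recognized keys: `index_period_start`, `index_period_end`, `variant`,
#' `chronicity_days_non_aki`, `chronicity_days_aki`,
#' `prevalence_lookback_days`, `followup_days`, `target_region`,
#' `code_system`, `fistula_exclusion_scope`. Missing keys take the
#' [algorithm_config()] defaults; unknown keys are ignored (the same file may
#' carry simulation or file-path keys).
#'
#' @param conf named list, e.g. from [read_config_file()]; values may be
#'   strings.
#' @return an [algorithm_config()].
#' @export
algorithm_config_from <- function(conf) {
  pick <- function(key, default) if (!is.null(conf[[key]])) conf[[key]] else default
  algorithm_config(
    index_period_start = as.Date(pick("index_period_start", "2014-01-01")),
    index_period_end = as.Date(pick("index_period_end", "2014-12-31")),
    variant = pick("variant", "ALG1"),
    chronicity_days_non_aki = as.integer(pick("chronicity_days_non_aki", 30L)),
    chronicity_days_aki = as.integer(pick(
      "chronicity_days_aki",
      max(90L, as.integer(pick("chronicity_days_non_aki", 30L))))),
    prevalence_lookback_days = as.integer(pick("prevalence_lookback_days", 365L)),
    followup_days = as.integer(pick("followup_days", 365L)),
    target_region = pick("target_region", "080"),
    code_system = pick("code_system", "ICD9"),
    fistula_exclusion_scope = pick("fistula_exclusion_scope", "all_dx"))
}

#' Write a run manifest
#'
#' Records what a pipeline run did: timestamp, package version, the fully
#' resolved configuration, MD5 digests of the input files, output paths and
#' any warnings. Re-running with the same configuration and inputs reproduces
#' identical outputs.
#'
#' @param path output path for the manifest (JSON if the jsonlite package is
#'   available, `key = value` text otherwise).
#' @param config resolved configuration (a list; `Date`s are formatted).
#' @param inputs named character vector of input file paths (digested).
#' @param outputs named character vector of output file paths.
#' @param warnings character vector of warnings emitted during the run.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(),
                               outputs = character(), warnings = character()) {
  fmt <- function(x) if (inherits(x, "Date")) format(x, "%Y-%m-%d") else x
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dialcohort")),
    config = lapply(unclass(config), fmt),
    input_digests = as.list(if (length(inputs)) tools::md5sum(inputs) else character()),
    outputs = as.list(outputs),
    warnings = as.list(warnings))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    flat <- unlist(manifest)
    writeLines(paste(names(flat), "=", flat), path)
  }
  invisible(path)
}
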