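# Small builders shared across tests. All fixtures are constructed in code.

d <- function(x) as.Date(x)

cfg2014 <- function(...) {
  algorithm_config(d("2014-01-01"), d("2014-12-31"), ...)
}

# one-admission HDR table
adm1 <- function(patient_id = "A", admission = "2014-03-10",
                 discharge = "2014-03-20", dx = character(),
                 proc_codes = character(), proc_dates = NULL,
                 region = "080", dead = FALSE, birth = NA, sex = NA) {
  procs <- if (length(proc_codes)) {
    data.frame(code = proc_codes,
               date = if (is.null(proc_dates)) rep(d(NA), length(proc_codes))
                      else d(proc_dates))
  } else NULL
  hdr_table(patient_id = patient_id, admission_date = d(admission),
            discharge_date = d(discharge), diagnoses = list(dx),
            procedures = list(procs), region = region,
            discharged_dead = dead, birth_date = d(birth), sex = sex)
}

# ASV table of sessions for one patient
sess <- function(patient_id, dates, code = "39.95.1", region = "080") {
  asv_table(patient_id = rep(patient_id, length(dates)),
            service_date = d(dates), service_code = rep(code, length(dates)),
            region = region)
}

empty_hdr <- function() hdr_table()
empty_asv <- function() asv_table()
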