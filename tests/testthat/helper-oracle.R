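# Independent brute-force reference implementation of the case definition.
# Re-derives every code rule and every temporal criterion from first
# principles with per-patient loops; shares no code with the package beyond
# the input table schemas. Used to cross-check run_algorithm on randomly
# generated micro-datasets.

o_norm <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x)] <- ""
  x
}
o_hd_proc <- function(x) grepl("^39\\.95", x)
o_pd_proc <- function(x) grepl("^54\\.98", x)
o_fistula <- function(x) x %in% c("39.27", "39.29", "54.93")
o_dial_dx <- function(x) x == "585.6" | grepl("^V45\\.1", x) | grepl("^V56\\.[0-8]", x)
o_aki_dx <- function(x) grepl("^584", x)
o_hd_svc <- function(x) x %in% sprintf("39.95.%d", 1:9)
o_pd_svc <- function(x) x %in% c("54.98.1", "54.98.2")

oracle_run_algorithm <- function(hdr, asv, cfg) {
  ps <- cfg$index_period_start; pe <- cfg$index_period_end
  hdr <- unique(hdr); asv <- unique(asv)
  rownames(hdr) <- NULL
  src_rank <- c(HDR_PROC = 1, ASV = 2, HDR_DX = 3)
  mod_rank <- c(HD = 1, PD = 2, UNKNOWN = 3)

  pats <- sort(unique(c(hdr$patient_id, asv$patient_id)))
  out <- list()
  for (p in pats) {
    h <- hdr[hdr$patient_id == p, , drop = FALSE]
    a <- asv[asv$patient_id == p, , drop = FALSE]
    n_adm <- nrow(h)

    adm_dx <- lapply(seq_len(n_adm), function(i) {
      v <- o_norm(unlist(h[i, paste0("dx", 1:15)], use.names = FALSE))
      v[nzchar(v)]
    })
    adm_proc <- lapply(seq_len(n_adm), function(i) {
      codes <- o_norm(unlist(h[i, paste0("proc", 1:15, "_code")], use.names = FALSE))
      dates <- as.Date(vapply(1:15, function(j)
        as.numeric(h[[paste0("proc", j, "_date")]][i]), 0),
        origin = "1970-01-01")
      keep <- nzchar(codes)
      dates[is.na(dates)] <- h$admission_date[i]
      data.frame(code = codes[keep], date = dates[keep])
    })

    # candidates
    cand <- data.frame(date = as.Date(character()), source = character(),
                       mod = character(), adm = integer())
    if (cfg$variant != "ASV_ONLY") {
      for (i in seq_len(n_adm)) {
        pr <- adm_proc[[i]]
        dial <- pr[(o_hd_proc(pr$code) | o_pd_proc(pr$code)) &
                     pr$date >= ps & pr$date <= pe, , drop = FALSE]
        if (nrow(dial)) {
          dial$mod <- ifelse(o_hd_proc(dial$code), "HD", "PD")
          dial <- dial[order(dial$date, mod_rank[dial$mod]), , drop = FALSE]
          cand <- rbind(cand, data.frame(date = dial$date[1], source = "HDR_PROC",
                                         mod = dial$mod[1], adm = i))
        } else {
          dial_related <- pr[o_hd_proc(pr$code) | o_pd_proc(pr$code) |
                               o_fistula(pr$code), , drop = FALSE]
          fistula_only <- nrow(dial_related) > 0 &&
            all(o_fistula(dial_related$code))
          if (h$admission_date[i] >= ps && h$admission_date[i] <= pe &&
              any(o_dial_dx(adm_dx[[i]])) && !fistula_only)
            cand <- rbind(cand, data.frame(date = h$admission_date[i],
                                           source = "HDR_DX", mod = "UNKNOWN",
                                           adm = i))
        }
      }
    }
    for (j in seq_len(nrow(a))) {
      code <- o_norm(a$service_code[j])
      if ((o_hd_svc(code) || o_pd_svc(code)) &&
          a$service_date[j] >= ps && a$service_date[j] <= pe)
        cand <- rbind(cand, data.frame(date = a$service_date[j], source = "ASV",
                                       mod = if (o_hd_svc(code)) "HD" else "PD",
                                       adm = NA_integer_))
    }
    cand <- unique(cand)
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand$date, src_rank[cand$source], mod_rank[cand$mod],
                       cand$adm), , drop = FALSE]
    idx <- cand[1, ]

    # timeline of actual treatments, per variant
    tl <- data.frame(date = as.Date(character()), mod = character())
    for (j in seq_len(nrow(a))) {
      code <- o_norm(a$service_code[j])
      if (o_hd_svc(code)) tl <- rbind(tl, data.frame(date = a$service_date[j], mod = "HD"))
      if (o_pd_svc(code)) tl <- rbind(tl, data.frame(date = a$service_date[j], mod = "PD"))
    }
    if (cfg$variant == "ALG2") {
      for (i in seq_len(n_adm)) {
        pr <- adm_proc[[i]]
        dial <- pr[o_hd_proc(pr$code) | o_pd_proc(pr$code), , drop = FALSE]
        if (nrow(dial))
          tl <- rbind(tl, data.frame(date = dial$date,
                                     mod = ifelse(o_hd_proc(dial$code), "HD", "PD")))
      }
    }
    tl <- unique(tl)

    # (a) residence
    nonres <- FALSE
    for (i in seq_len(n_adm))
      if (h$admission_date[i] >= ps && h$admission_date[i] <= pe &&
          !is.na(h$region[i]) && h$region[i] != cfg$target_region) nonres <- TRUE
    for (j in seq_len(nrow(a)))
      if (a$service_date[j] >= ps && a$service_date[j] <= pe &&
          !is.na(a$region[j]) && a$region[j] != cfg$target_region) nonres <- TRUE
    if (nonres) next

    # (b) prevalence
    before <- as.integer(idx$date - tl$date)
    if (any(before >= 1 & before <= cfg$prevalence_lookback_days)) next

    # (c) chronicity with AKI threshold
    aki <- FALSE
    if (idx$source != "ASV" && any(o_aki_dx(adm_dx[[idx$adm]]))) aki <- TRUE
    for (i in seq_len(n_adm)) {
      lag <- as.integer(idx$date - h$admission_date[i])
      if (lag >= 0 && lag < 90 && any(o_aki_dx(adm_dx[[i]]))) aki <- TRUE
    }
    ahead <- as.integer(tl$date - idx$date)
    ahead <- ahead[ahead >= 1 & ahead <= cfg$followup_days]
    gap <- if (length(ahead)) max(ahead) else 0
    thr <- if (aki) cfg$chronicity_days_aki else cfg$chronicity_days_non_aki
    if (gap < thr) next

    # (d) in-hospital death at the index admission (ALG2 only)
    if (cfg$variant == "ALG2" && idx$source != "ASV" &&
        isTRUE(h$discharged_dead[idx$adm])) next

    modality <- idx$mod
    if (modality == "UNKNOWN") {
      after <- tl[tl$date >= idx$date, , drop = FALSE]
      if (nrow(after)) {
        after <- after[order(after$date, mod_rank[after$mod]), , drop = FALSE]
        modality <- after$mod[1]
      } else modality <- "HD"
    }
    out[[p]] <- data.frame(patient_id = p, index_date = idx$date,
                           modality = modality, aki_flag = aki,
                           source = idx$source, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(patient_id = character(), index_date = as.Date(character()),
                      modality = character(), aki_flag = logical(),
                      source = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random micro-dataset: <= 5 patients, <= 20 events each, codes drawn from a
# mix of qualifying and non-qualifying pools, dates concentrated around the
# 2014 index period so that criteria collide often
random_micro_data <- function() {
  dxpool <- c("585.6", "V45.11", "V45.12", "V56.0", "V56.31", "V56.8",
              "584.9", "584", "250.00", "401.9")
  procpool <- c("39.95", "39.95.1", "54.98", "39.27", "39.29", "54.93", "81.54")
  svcpool <- c("39.95.1", "39.95.9", "39.95.10", "54.98.1", "54.98.2",
               "54.98.3", "89.01")
  regions <- c("080", "080", "080", "030", NA)
  day0 <- as.Date("2013-01-01")
  rdate <- function(n) day0 + sample(0:1094, n, replace = TRUE)

  n_pat <- sample(1:5, 1)
  hdr <- hdr_table(); asv <- asv_table()
  for (p in paste0("M", seq_len(n_pat))) {
    for (k in seq_len(sample(0:3, 1))) {
      adm <- rdate(1)
      len <- sample(0:30, 1)
      m <- sample(0:3, 1)
      procs <- if (m > 0) {
        offs <- if (len == 0) rep(0L, m) else sample(0:len, m, replace = TRUE)
        data.frame(code = sample(procpool, m, replace = TRUE),
                   date = as.Date(ifelse(stats::runif(m) < 0.3, NA, adm + offs),
                                  origin = "1970-01-01"))
      } else NULL
      hdr <- rbind(hdr, hdr_table(
        patient_id = p, admission_date = adm, discharge_date = adm + len,
        diagnoses = list(sample(dxpool, sample(0:3, 1))),
        procedures = list(procs),
        region = sample(regions, 1),
        discharged_dead = stats::runif(1) < 0.15))
    }
    n_ev <- sample(0:12, 1)
    if (n_ev > 0)
      asv <- rbind(asv, asv_table(
        patient_id = rep(p, n_ev), service_date = rdate(n_ev),
        service_code = sample(svcpool, n_ev, replace = TRUE),
        region = sample(regions, n_ev, replace = TRUE)))
  }
  list(hdr = hdr, asv = asv)
}

random_micro_config <- function() {
  t_non_aki <- sample(c(30L, 60L, 90L), 1)
  algorithm_config(as.Date("2014-01-01"), as.Date("2014-12-31"),
                   variant = sample(c("ALG1", "ALG2", "ASV_ONLY"), 1),
                   chronicity_days_non_aki = t_non_aki,
                   chronicity_days_aki = max(90L, t_non_aki))
}

expect_matches_oracle <- function(hdr, asv, cfg) {
  got <- suppressWarnings(run_algorithm(hdr, asv, cfg))
  attr(got, "audit") <- NULL
  want <- suppressWarnings(oracle_run_algorithm(hdr, asv, cfg))
  expect_equal(got, want)
}
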