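# Independent brute-force oracles used across the suite. These deliberately
# use plain sequential loops and pairwise scans, not the package's vectorised
# code paths.

D0 <- as.Date("2015-01-01")

# Quick prescription rows at day offsets from D0 (supply recorded).
mk_rx <- function(patient_id, drug, day, supply = 30, dose = 50) {
  data.frame(patient_id = patient_id, drug = drug, issue_date = D0 + day,
             strength_mg = dose, quantity = supply,
             daily_dose_instruction_mg = dose, supply_days = supply,
             stringsAsFactors = FALSE)
}

mk_patient <- function(patient_id, birth_year = 2000, sex = "male",
                       start = D0 - 1000, end = D0 + 2000, source_id = "se_registry") {
  data.frame(patient_id = patient_id, birth_year = birth_year, sex = sex,
             enrolment_start = start, enrolment_end = end,
             source_id = source_id, stringsAsFactors = FALSE)
}

# Sequential stockpiling adjustment (scalar loop).
oracle_adjust <- function(issue, len) {
  o <- order(issue)
  issue <- issue[o]; len <- len[o]
  end <- numeric(length(issue))
  start <- numeric(length(issue))
  cur <- -Inf
  for (i in seq_along(issue)) {
    start[i] <- max(issue[i], cur)
    cur <- start[i] + len[i]
    end[i] <- cur
  }
  list(issue = issue, start = start, end = end, len = len)
}

# Episode partition by sequential scan over adjusted intervals.
oracle_episodes_one <- function(issue, len, gap) {
  a <- oracle_adjust(issue, len)
  eps <- list()
  cur <- NULL
  for (i in seq_along(a$issue)) {
    if (is.null(cur)) {
      cur <- list(start = a$start[i], end = a$end[i], n = 1L, covered = a$len[i])
    } else if (a$issue[i] - cur$end <= gap) {
      cur$end <- a$end[i]; cur$n <- cur$n + 1L; cur$covered <- cur$covered + a$len[i]
    } else {
      eps[[length(eps) + 1L]] <- cur
      cur <- list(start = a$start[i], end = a$end[i], n = 1L, covered = a$len[i])
    }
  }
  if (!is.null(cur)) eps[[length(eps) + 1L]] <- cur
  do.call(rbind, lapply(eps, as.data.frame))
}

# Pattern flags for one patient by exhaustive pairwise scan. `events` needs
# columns drug, day (issue offset), len.
oracle_patterns_one <- function(events, gap, wend, boundary = "inclusive") {
  within <- function(d) {
    if (boundary == "inclusive") d >= 0 & d <= gap else d >= 0 & d < gap
  }
  ev <- events[events$drug %in% c("LDX", "MPH", "ATX", "other_ADHD"), , drop = FALSE]
  issue <- numeric(nrow(ev)); endd <- numeric(nrow(ev)); startd <- numeric(nrow(ev))
  for (d in unique(ev$drug)) {
    k <- which(ev$drug == d)
    a <- oracle_adjust(ev$day[k], ev$len[k])
    issue[k[order(ev$day[k])]] <- a$issue
    endd[k[order(ev$day[k])]] <- a$end
    startd[k[order(ev$day[k])]] <- a$start
  }
  ldx <- ev$drug == "LDX"
  res <- list(switched_to_ldx = FALSE, switched_from_ldx = FALSE,
              discontinued = FALSE, discontinued_naive = FALSE, censored = FALSE)
  for (i in which(!ldx)) for (j in which(ldx)) {
    if (within(issue[j] - endd[i])) res$switched_to_ldx <- TRUE
  }
  for (i in which(ldx)) for (j in which(!ldx)) {
    if (within(issue[j] - endd[i])) res$switched_from_ldx <- TRUE
  }
  if (any(ldx)) {
    oth <- issue[!ldx]
    # An LDX period end e is an episode end when no other LDX period starts
    # within the grace window after it. Post-adjustment, an early or zero-gap
    # refill starts exactly at the running end, so "starts at or after e,
    # within the window, and supplies days beyond e" is the continuation test.
    ep_end <- c()
    for (i in which(ldx)) {
      e <- endd[i]
      cont <- FALSE
      for (j in which(ldx)) {
        if (j == i) next
        if (startd[j] >= e && within(startd[j] - e) && endd[j] > e) cont <- TRUE
      }
      if (!cont) ep_end <- c(ep_end, e)
    }
    for (e in ep_end) {
      switch_ev <- any(within(oth - e))
      if (!switch_ev) {
        res$discontinued_naive <- TRUE
        if (e + gap <= wend) res$discontinued <- TRUE
      }
    }
    last_e <- max(ep_end)
    res$censored <- (last_e + gap > wend) && !any(within(oth - last_e))
  }
  res
}

# Random event-sequence generator for the classifier equivalence suite:
# <= 6 prescriptions over {LDX, MPH}, inter-issue gaps 0..60 days.
random_sequence <- function() {
  n <- sample(1:6, 1L)
  drug <- sample(c("LDX", "MPH"), n, replace = TRUE)
  drug[sample.int(n, 1L)] <- "LDX"
  gaps <- if (n > 1L) sample(0:60, n - 1L, replace = TRUE) else integer(0)
  day <- cumsum(c(0L, gaps))
  data.frame(drug = drug, day = day, len = 30, stringsAsFactors = FALSE)
}

# Run the package classifier on a list of event sequences in one batch.
classify_batch <- function(seqs, gap = 30, wend_offset = NULL, boundary = "inclusive") {
  ids <- sprintf("S%06d", seq_along(seqs))
  rx <- do.call(rbind, Map(function(s, id) mk_rx(id, s$drug, s$day), seqs, ids))
  # window end: last issue + offset (drawn per sequence when NULL, so both
  # censored and adjudicable follow-up arise)
  offs <- if (is.null(wend_offset)) {
    sample(c(10, 31, 45, 120), length(seqs), replace = TRUE)
  } else {
    rep_len(wend_offset, length(seqs))
  }
  wend <- as.numeric(unclass(D0)) + vapply(seqs, function(s) max(s$day), 0) + offs
  names(wend) <- ids
  cov <- build_coverage(rx)
  got <- classify_patterns(cov, window_end = stats::setNames(as.Date(wend, origin = "1970-01-01"), ids),
                           gap_days = gap, boundary = boundary, patient_ids = ids)
  list(got = got, ids = ids, wend = wend)
}

# Brute-force cohort aggregation straight from raw event tables, using the
# loop-based oracles above (independent of dua()/summarize_cohort()).
oracle_summary <- function(co) {
  cc <- co$country_config
  pats <- co$patients; rx <- co$prescriptions; dx <- co$diagnoses
  ids <- unique(rx$patient_id[rx$drug == "LDX"])
  rx_len <- ifelse(!is.na(rx$supply_days), rx$supply_days,
                   ifelse(!is.na(rx$daily_dose_instruction_mg),
                          rx$quantity * rx$strength_mg / rx$daily_dose_instruction_mg,
                          30))
  per <- lapply(ids, function(pid) {
    sel <- rx$patient_id == pid
    r <- rx[sel, ]; len <- rx_len[sel]
    p <- pats[pats$patient_id == pid, ]
    l <- r$drug == "LDX"
    days <- as.numeric(unclass(r$issue_date))
    ep <- oracle_episodes_one(days[l], len[l], 30)
    wend <- min(as.numeric(unclass(p$enrolment_end)),
                as.numeric(unclass(cc$observation_end)))
    pt <- oracle_patterns_one(data.frame(drug = r$drug, day = days, len = len),
                              30, wend)
    first <- min(days[l])
    year_first <- as.integer(format(min(r$issue_date[l]), "%Y"))
    rx_years <- as.integer(format(r$issue_date[l], "%Y"))
    mg <- sum(r$quantity[l] * r$strength_mg[l])
    add <- mg / sum(len[l])
    doc <- if (!nrow(dx)) FALSE else {
      any(dx$patient_id == pid & dx$code_class == "ADHD" &
            as.numeric(unclass(dx$diagnosis_date)) <= first)
    }
    mph_ev <- (first - as.numeric(unclass(p$enrolment_start))) >= 365
    no_mph <- !any(r$drug == "MPH" & days < first)
    list(n_rx = sum(l), repeat_user = sum(l) > 1,
         exposure = sum(ep$end - ep$start), add = add,
         male = p$sex == "male", doc = doc,
         age_first = year_first - p$birth_year,
         under6 = if (is.na(p$birth_year)) NA else any(rx_years - p$birth_year < 6),
         mph_ev = mph_ev, no_mph = no_mph,
         discontinued = pt$discontinued, censored = pt$censored,
         switched_to = pt$switched_to_ldx, switched_from = pt$switched_from_ldx)
  })
  g <- function(f) sapply(per, function(x) x[[f]])
  add <- g("add"); add_ok <- add[!is.na(add) & add <= cc$max_daily_dose_mg]
  nrx <- g("n_rx"); expo <- g("exposure")
  list(
    n_patients = length(ids), n_prescriptions = sum(nrx),
    male_n = sum(g("male")), documented_adhd_n = sum(g("doc")),
    repeat_users_n = sum(g("repeat_user")),
    rx_mean = mean(nrx), rx_sd = stats::sd(nrx),
    rx_median = stats::median(nrx), rx_min = min(nrx), rx_max = max(nrx),
    exposure_mean = mean(expo), exposure_sd = stats::sd(expo),
    exposure_median = stats::median(expo),
    add_mean = mean(add_ok), add_denom = length(add_ok),
    add_exceeds_cap_n = sum(add > cc$max_daily_dose_mg, na.rm = TRUE),
    discontinued_n = sum(g("discontinued")), censored_n = sum(g("censored")),
    switched_to_n = sum(g("switched_to")), switched_from_n = sum(g("switched_from")),
    no_prior_mph_n = sum(g("no_mph")[g("mph_ev")]),
    no_prior_mph_denom = sum(g("mph_ev")),
    under_min_age_n = sum(g("under6"), na.rm = TRUE),
    age_denom = sum(!is.na(g("age_first")))
  )
}
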