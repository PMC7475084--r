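#' Per-prescription coverage intervals
#'
#' Maps each prescription to the interval of days it is assumed to supply
#' medication (its "prescription period"). The interval length is, in order
#' of preference: the recorded `supply_days`; else
#' `quantity * strength_mg / daily_dose_instruction_mg`; else
#' `default_supply_days`. The daily dose is the recorded instruction when
#' present, else `quantity * strength_mg / length`. Intervals are closed-open
#' `[start, end)` with `start = issue_date`.
#'
#' Records with no basis for an interval length (and no default configured)
#' or for a dose are returned in the `rejected` attribute rather than
#' silently dropped.
#'
#' @param prescriptions Prescription data.frame (see [read_cohort()]).
#' @param default_supply_days Fallback supply length in days; `NA` disables
#'   the fallback, making length-less records errors. Default 30.
#' @return Data.frame of coverage intervals: `patient_id`, `drug`,
#'   `issue_date`, `start`, `end` (Date, end exclusive), `days`,
#'   `dose_mg_per_day`, `total_mg`, `rx_id` (row index into the input).
#'   Attribute `rejected` holds unresolvable rows.
#' @export
build_coverage <- function(prescriptions, default_supply_days = 30) {
  rx <- prescriptions
  n <- nrow(rx)
  if (n == 0L) {
    out <- data.frame(patient_id = character(), drug = character(),
                      issue_date = as.Date(character()), start = as.Date(character()),
                      end = as.Date(character()), days = numeric(),
                      dose_mg_per_day = numeric(), total_mg = numeric(), rx_id = integer())
    attr(out, "rejected") <- out
    return(out)
  }
  instr <- rx$daily_dose_instruction_mg
  qs_mg <- rx$quantity * rx$strength_mg  # NA when either is missing

  days <- rx$supply_days
  need <- is.na(days)
  days[need] <- (qs_mg / instr)[need]
  need <- is.na(days)
  days[need] <- default_supply_days

  dose <- instr
  dose[is.na(dose)] <- (qs_mg / days)[is.na(dose)]

  bad <- is.na(days) | days <= 0 | is.na(dose) | dose <= 0
  total_mg <- ifelse(is.na(qs_mg), dose * days, qs_mg)

  out <- data.frame(
    patient_id = rx$patient_id, drug = rx$drug, issue_date = rx$issue_date,
    start = rx$issue_date, end = rx$issue_date + days, days = as.numeric(days),
    dose_mg_per_day = as.numeric(dose), total_mg = as.numeric(total_mg),
    rx_id = seq_len(n), stringsAsFactors = FALSE
  )
  rejected <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  out <- out[order(out$patient_id, out$drug, unclass(out$start), out$rx_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# Supply-conserving ("stockpiling") adjustment within each patient x drug
# stream: a refill issued before the previous interval has run out starts
# covering when that supply ends, so no dispensed days are discarded.
# Sequentially: adj_end[i] = max(issue[i], adj_end[i-1]) + days[i].
# Vectorised via adj_end[i] = cumdays[i] + cummax(issue[i] - cumdays[i-1]).
# overlap = "truncate" instead clips the earlier interval at the next issue.
adjust_coverage <- function(coverage, overlap = c("stockpile", "truncate")) {
  overlap <- match.arg(overlap)
  cov <- coverage
  if (nrow(cov) == 0L) {
    cov$adj_start <- as.Date(character())
    cov$adj_end <- as.Date(character())
    return(cov)
  }
  key <- paste(cov$patient_id, cov$drug, sep = "\r")
  o <- order(key, unclass(cov$start), cov$rx_id)
  cov <- cov[o, , drop = FALSE]
  key <- key[o]
  grp <- cumsum(!duplicated(key))
  issue <- as.numeric(unclass(cov$start))
  len <- cov$days

  if (overlap == "stockpile") {
    cumlen <- stats::ave(len, grp, FUN = cumsum)
    lag_cumlen <- cumlen - len
    adj_end <- cumlen + stats::ave(issue - lag_cumlen, grp, FUN = cummax)
    adj_start <- adj_end - len
  } else {
    first <- !duplicated(grp)
    nxt <- c(issue[-1], NA)
    nxt[c(first[-1], TRUE)] <- NA  # last in group has no successor
    adj_start <- issue
    adj_end <- issue + len
    clip <- !is.na(nxt) & nxt < adj_end
    adj_end[clip] <- pmax(nxt[clip], adj_start[clip] + 1)
    # truncation discards supply: shrink total_mg proportionally
    cov$total_mg <- cov$total_mg * (adj_end - adj_start) / len
    cov$days <- adj_end - adj_start
  }
  cov$adj_start <- as.Date(adj_start, origin = "1970-01-01")
  cov$adj_end <- as.Date(adj_end, origin = "1970-01-01")
  rownames(cov) <- NULL
  cov
}

#' Merge coverage intervals into treatment episodes
#'
#' A treatment episode is a maximal run of coverage intervals, per patient
#' and drug, in which each prescription is issued no more than `gap_days`
#' days after the running supply end; a gap greater than `gap_days` closes
#' the episode. Overlapping refills are handled by the stockpiling model
#' (remaining supply is appended, not discarded) or, optionally, truncation.
#'
#' @param coverage Output of [build_coverage()].
#' @param gap_days Grace period in days (default 30, the study definition).
#'   The boundary is inclusive: a gap of exactly `gap_days` continues the
#'   episode.
#' @param overlap `"stockpile"` (default) or `"truncate"`.
#' @return Data.frame of episodes: `patient_id`, `drug`, `episode_id` (1-based
#'   within patient x drug), `start`, `end` (Date, end exclusive),
#'   `n_prescriptions`, `total_mg`, `covered_days`, `span_days`
#'   (`end - start`; equals `covered_days` under stockpiling unless gaps
#'   <= `gap_days` occur inside the episode). Attribute `coverage` carries
#'   the adjusted intervals with their episode assignment.
#' @export
build_episodes <- function(coverage, gap_days = 30, overlap = c("stockpile", "truncate")) {
  if (!is.numeric(gap_days) || length(gap_days) != 1L || is.na(gap_days) || gap_days < 0) {
    stop("gap_days must be a single non-negative number")
  }
  cov <- adjust_coverage(coverage, overlap)
  if (nrow(cov) == 0L) {
    out <- data.frame(patient_id = character(), drug = character(), episode_id = integer(),
                      start = as.Date(character()), end = as.Date(character()),
                      n_prescriptions = integer(), total_mg = numeric(),
                      covered_days = numeric(), span_days = numeric())
    attr(out, "coverage") <- cov
    return(out)
  }
  key <- paste(cov$patient_id, cov$drug, sep = "\r")
  grp <- cumsum(!duplicated(key))
  issue <- as.numeric(unclass(cov$start))
  prev_end <- c(NA, as.numeric(unclass(cov$adj_end))[-length(issue)])
  new_stream <- !duplicated(grp)
  gap <- issue - prev_end
  breaks <- new_stream | (!is.na(gap) & gap > gap_days)
  epi <- factor(cumsum(breaks), levels = unique(cumsum(breaks)))
  cov$episode_id <- stats::ave(as.integer(breaks), grp, FUN = cumsum)

  agg_first <- function(x) x[!duplicated(epi)]
  start <- tapply(as.numeric(unclass(cov$adj_start)), epi, min)
  end <- tapply(as.numeric(unclass(cov$adj_end)), epi, max)
  out <- data.frame(
    patient_id = agg_first(cov$patient_id),
    drug = agg_first(cov$drug),
    episode_id = agg_first(cov$episode_id),
    start = as.Date(as.numeric(start), origin = "1970-01-01"),
    end = as.Date(as.numeric(end), origin = "1970-01-01"),
    n_prescriptions = as.integer(tapply(rep(1L, nrow(cov)), epi, sum)),
    total_mg = as.numeric(tapply(cov$total_mg, epi, sum)),
    covered_days = as.numeric(tapply(cov$days, epi, sum)),
    stringsAsFactors = FALSE
  )
  out$span_days <- as.numeric(unclass(out$end) - unclass(out$start))
  rownames(out) <- NULL
  attr(out, "coverage") <- cov
  out
}

#' Per-patient exposure measures
#'
#' Summarises one drug's episodes per patient: number of prescriptions,
#' repeat-user status (more than one prescription of the drug), number of
#' episodes, and two duration readings. The headline `duration_days` sums
#' episode spans (issue of first prescription to end of final coverage,
#' within each episode), consistent with gaps above the grace period ending
#' an episode; `followup_span_days` (first issue to last coverage end across
#' all episodes) is also reported.
#'
#' @param episodes Output of [build_episodes()].
#' @param patient_ids Optional character vector fixing the output universe
#'   (patients with no episodes of `drug` get zero rows of exposure).
#' @param drug Drug role to summarise (default `"LDX"`).
#' @return Data.frame keyed by `patient_id` with `n_prescriptions`,
#'   `repeat_user`, `n_episodes`, `duration_days`, `covered_days`,
#'   `followup_span_days`, `first_issue`, `last_end`.
#' @export
patient_exposure <- function(episodes, patient_ids = NULL, drug = "LDX") {
  ep <- episodes[episodes$drug == drug, , drop = FALSE]
  ids <- if (is.null(patient_ids)) unique(ep$patient_id) else unique(as.character(patient_ids))
  k <- length(ids)
  out <- data.frame(patient_id = ids, n_prescriptions = rep(0L, k),
                    repeat_user = rep(FALSE, k), n_episodes = rep(0L, k),
                    duration_days = rep(0, k), covered_days = rep(0, k),
                    followup_span_days = rep(0, k),
                    first_issue = rep(as.Date(NA), k), last_end = rep(as.Date(NA), k),
                    stringsAsFactors = FALSE)
  if (nrow(ep)) {
    agg <- function(v, fun) tapply(v, ep$patient_id, fun)
    m <- match(names(agg(ep$n_prescriptions, sum)), out$patient_id)
    out$n_prescriptions[m] <- as.integer(agg(ep$n_prescriptions, sum))
    out$n_episodes[m] <- as.integer(agg(ep$episode_id, length))
    out$duration_days[m] <- as.numeric(agg(ep$span_days, sum))
    out$covered_days[m] <- as.numeric(agg(ep$covered_days, sum))
    out$first_issue[m] <- as.Date(as.numeric(agg(unclass(ep$start), min)), origin = "1970-01-01")
    out$last_end[m] <- as.Date(as.numeric(agg(unclass(ep$end), max)), origin = "1970-01-01")
    out$followup_span_days[m] <- as.numeric(unclass(out$last_end[m]) - unclass(out$first_issue[m]))
    out$repeat_user <- out$n_prescriptions > 1L
  }
  rownames(out) <- NULL
  out
}

#' Average daily dose
#'
#' The average daily dose (ADD) is total milligrams dispensed divided by
#' total covered days, per patient, over one drug's coverage intervals.
#' Treatment gaps are excluded by construction (the denominator is covered
#' days, not calendar time), so long gaps cannot dilute the dose. A patient
#' `exceeds_cap` when ADD is strictly above `cap_mg`; cohort mean-dose
#' statistics pool only patients at or below the cap, while the flag feeds
#' the off-label audit.
#'
#' @param coverage Output of [build_coverage()].
#' @param cap_mg Label maximum in mg/day (default 70).
#' @param patient_ids Optional universe of patients, as in
#'   [patient_exposure()].
#' @param drug Drug role (default `"LDX"`).
#' @return Data.frame with `patient_id`, `add_mg_per_day`, `exceeds_cap`,
#'   `any_rx_dose_exceeds_cap` (any single prescription instructing above the
#'   cap). Patients with no coverage get `NA` dose.
#' @export
average_daily_dose <- function(coverage, cap_mg = 70, patient_ids = NULL, drug = "LDX") {
  cov <- coverage[coverage$drug == drug, , drop = FALSE]
  ids <- if (is.null(patient_ids)) unique(cov$patient_id) else unique(as.character(patient_ids))
  k <- length(ids)
  out <- data.frame(patient_id = ids, add_mg_per_day = rep(NA_real_, k),
                    exceeds_cap = rep(NA, k), any_rx_dose_exceeds_cap = rep(NA, k),
                    stringsAsFactors = FALSE)
  if (nrow(cov)) {
    if (any(cov$days <= 0)) stop("zero covered days in coverage")
    mg <- tapply(cov$total_mg, cov$patient_id, sum)
    dd <- tapply(cov$days, cov$patient_id, sum)
    anyhigh <- tapply(cov$dose_mg_per_day > cap_mg, cov$patient_id, any)
    m <- match(names(mg), out$patient_id)
    out$add_mg_per_day[m] <- as.numeric(mg) / as.numeric(dd)
    out$exceeds_cap[m] <- out$add_mg_per_day[m] > cap_mg
    out$any_rx_dose_exceeds_cap[m] <- as.logical(anyhigh)
  }
  rownames(out) <- NULL
  out
}
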