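#' Off-label audit of LDX prescribing
#'
#' Evaluates every LDX-treated patient against the operational off-label
#' criteria, under a country's [country_config()]:
#'
#' 1. **No prior diagnosis** — no ADHD diagnosis recorded strictly before
#'    the first LDX prescription. Not evaluable when the patient's source
#'    records no diagnoses (Swiss pharmacy panels).
#' 2. **No prior MPH** — no MPH prescription before the first LDX
#'    prescription. Not evaluable unless the patient has at least
#'    `mph_lookback_min_enrolment_days` (default 365) of enrolment history
#'    before first LDX.
#' 3. **Under minimum age** — younger than `min_label_age` (default 6) at
#'    the time of any LDX prescription. Ages are year-granular
#'    (event year minus birth year); not evaluable when birth year is
#'    missing.
#' 4. **Dose exceeds cap** — patient-level average daily dose strictly above
#'    `max_daily_dose_mg` (default 70). The per-prescription variant (any
#'    single instructed dose above the cap) is also reported as
#'    `any_rx_dose_exceeds_cap`.
#' 5. **Adult off-label** — any LDX prescription at age >= 19 is off-label
#'    unless (a) the treatment episode containing it began at age <= 18
#'    (continuation from adolescence into adulthood, using the same
#'    grace-period episodes as the rest of the analysis), or (b) the country
#'    has an adult approval, the prescription date is on/after it, and the
#'    patient's age does not exceed the country's adult age cap when one
#'    exists (Switzerland: 55).
#'
#' Not-evaluable results are returned as `NA` and never contribute to
#' `any_off_label`, which is the disjunction of the evaluable flags.
#'
#' @param patients,prescriptions,diagnoses Cohort tables (see
#'   [read_cohort()]).
#' @param config A [country_config()] (or key resolvable by it).
#' @param gap_days Grace period used for the continuation-exemption
#'   episodes; keep equal to the episode/pattern grace period (default 30).
#' @param default_supply_days Passed to [build_coverage()].
#' @return Data.frame with one row per LDX-treated patient:
#'   `no_prior_diagnosis`, `no_prior_mph` (NA = not evaluable),
#'   `mph_evaluable`, `under_min_age`, `dose_exceeds_cap`,
#'   `any_rx_dose_exceeds_cap`, `adult_off_label`, `any_off_label`, plus
#'   `first_ldx_date` and `age_first_ldx`.
#' @export
evaluate_offlabel <- function(patients, prescriptions, diagnoses, config,
                              gap_days = 30, default_supply_days = 30) {
  cfg <- country_config(config)
  cov <- build_coverage(prescriptions, default_supply_days)
  episodes <- build_episodes(cov[cov$drug == "LDX", , drop = FALSE], gap_days)
  add <- average_daily_dose(cov, cap_mg = cfg$max_daily_dose_mg)

  ldx <- prescriptions[prescriptions$drug == "LDX", , drop = FALSE]
  ids <- unique(ldx$patient_id)
  k <- length(ids)
  out <- data.frame(
    patient_id = ids, no_prior_diagnosis = rep(NA, k), no_prior_mph = rep(NA, k),
    mph_evaluable = rep(FALSE, k), under_min_age = rep(NA, k),
    dose_exceeds_cap = rep(NA, k), any_rx_dose_exceeds_cap = rep(NA, k),
    adult_off_label = rep(NA, k), any_off_label = rep(FALSE, k),
    first_ldx_date = rep(as.Date(NA), k), age_first_ldx = rep(NA_real_, k),
    stringsAsFactors = FALSE
  )
  if (length(ids) == 0L) return(out)

  pm <- match(ids, patients$patient_id)
  if (anyNA(pm)) stop("prescriptions reference unknown patients")
  birth <- patients$birth_year[pm]
  enrol_start <- patients$enrolment_start[pm]
  src <- cfg$sources[match(patients$source_id[pm], cfg$sources$source_id), , drop = FALSE]
  if (anyNA(src$source_id)) stop("patients reference sources absent from the country config")

  first_ldx <- as.Date(as.numeric(tapply(unclass(ldx$issue_date), ldx$patient_id, min)[ids]),
                       origin = "1970-01-01")
  out$first_ldx_date <- first_ldx
  first_year <- as.integer(format(first_ldx, "%Y"))
  out$age_first_ldx <- first_year - birth

  ## (1) prior recorded ADHD diagnosis ---------------------------------
  if (cfg$requires_recorded_diagnosis) {
    has_prior_dx <- rep(FALSE, length(ids))
    if (nrow(diagnoses)) {
      adhd <- diagnoses[diagnoses$code_class == "ADHD", , drop = FALSE]
      if (nrow(adhd)) {
        m <- match(adhd$patient_id, ids)
        ok <- !is.na(m) & unclass(adhd$diagnosis_date) < unclass(first_ldx[m])
        has_prior_dx[unique(m[ok])] <- TRUE
      }
    }
    out$no_prior_diagnosis <- !has_prior_dx
  }
  out$no_prior_diagnosis[!src$records_diagnoses] <- NA

  ## (2) prior MPH ------------------------------------------------------
  if (cfg$requires_prior_mph) {
    history <- as.numeric(unclass(first_ldx)) - as.numeric(unclass(enrol_start))
    out$mph_evaluable <- history >= cfg$mph_lookback_min_enrolment_days
    has_prior_mph <- rep(FALSE, length(ids))
    mph <- prescriptions[prescriptions$drug == "MPH", , drop = FALSE]
    if (nrow(mph)) {
      m <- match(mph$patient_id, ids)
      ok <- !is.na(m) & unclass(mph$issue_date) < unclass(first_ldx[m])
      has_prior_mph[unique(m[ok])] <- TRUE
    }
    out$no_prior_mph <- ifelse(out$mph_evaluable, !has_prior_mph, NA)
  }

  ## (3) minimum age at any prescription --------------------------------
  rx_year <- as.integer(format(ldx$issue_date, "%Y"))
  rx_age <- rx_year - birth[match(ldx$patient_id, ids)]
  young <- tapply(rx_age < cfg$min_label_age, ldx$patient_id, any)[ids]
  out$under_min_age <- as.logical(young)  # NA propagates from missing birth year

  ## (4) dose cap -------------------------------------------------------
  am <- match(ids, add$patient_id)
  out$dose_exceeds_cap <- add$exceeds_cap[am]
  out$any_rx_dose_exceeds_cap <- add$any_rx_dose_exceeds_cap[am]

  ## (5) adult use ------------------------------------------------------
  out$adult_off_label <- adult_off_label_flags(ldx, episodes, birth, ids, cfg)

  flags <- cbind(out$no_prior_diagnosis, out$no_prior_mph, out$under_min_age,
                 out$dose_exceeds_cap, out$adult_off_label)
  out$any_off_label <- apply(flags, 1L, function(f) any(f, na.rm = TRUE))
  rownames(out) <- NULL
  out
}

# Per-prescription adult check, folded to a patient flag. `episodes` must be
# LDX episodes built with the analysis grace period; the coverage attribute
# carries each prescription's episode assignment.
adult_off_label_flags <- function(ldx, episodes, birth, ids, cfg) {
  cov <- attr(episodes, "coverage")
  flag <- rep(NA, length(ids))
  if (is.null(cov) || nrow(cov) == 0L) return(flag)
  epi_start <- stats::setNames(as.numeric(unclass(episodes$start)),
                               paste(episodes$patient_id, episodes$episode_id, sep = "\r"))
  m <- match(cov$patient_id, ids)
  b <- birth[m]
  rx_year <- as.integer(format(cov$issue_date, "%Y"))
  age <- rx_year - b
  ep_key <- paste(cov$patient_id, cov$episode_id, sep = "\r")
  ep_start_year <- as.integer(format(as.Date(epi_start[ep_key], origin = "1970-01-01"), "%Y"))
  age_at_episode_start <- ep_start_year - b

  is_adult_rx <- !is.na(age) & age >= 19
  continuation <- !is.na(age_at_episode_start) & age_at_episode_start <= 18
  approved <- if (is.na(cfg$adult_approval_date)) {
    rep(FALSE, nrow(cov))
  } else {
    unclass(cov$issue_date) >= unclass(cfg$adult_approval_date) &
      (is.na(cfg$adult_age_cap) | age <= cfg$adult_age_cap)
  }
  off <- is_adult_rx & !continuation & !approved

  agg <- tapply(off, cov$patient_id, any)
  flag <- as.logical(agg[match(ids, names(agg))])
  flag[is.na(birth)] <- NA
  flag
}
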