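#' Simulation configuration for synthetic cohorts
#'
#' Bundles the parameters of the synthetic multi-country cohort generator.
#' The generator is a test harness emulating the *structure* of European
#' registry and prescription-panel data — per-country launch dates and
#' observation windows, age/sex mixes, diagnosis-recording completeness,
#' refill behaviour with a heavy late tail, per-refill discontinuation and
#' switching hazards, and source-specific missingness (pharmacy panels
#' without diagnoses; a self-dispensing panel without ages or durations). It
#' is not calibrated to any country's real results.
#'
#' @param n_patients Number of patients.
#' @param country Country key or [country_config()] object.
#' @param seed Integer RNG seed; the same config and seed always produce a
#'   byte-identical cohort.
#' @param age_mix Named probabilities over the age bands `0-5`, `6-12`,
#'   `13-18`, `19-25`, `>25` at first LDX prescription.
#' @param male_fraction Probability a patient is male.
#' @param p_adhd_recorded Probability a true ADHD diagnosis is recorded
#'   before the first LDX prescription (in sources that record diagnoses).
#' @param p_prior_mph Probability of at least one MPH prescription before
#'   the first LDX prescription.
#' @param p_switch_to Given prior MPH, probability the MPH supply runs out
#'   within the grace period before the first LDX issue (a switch-to event);
#'   otherwise the MPH history ends more than `gap_days` days earlier.
#' @param refill_gap Two-component refill-timing mixture: with probability
#'   `p_on_time` the next issue falls `on_time_min..on_time_max` days around
#'   the running supply end; otherwise the gap is lognormal
#'   (`late_meanlog`, `late_sdlog`), giving occasional gaps beyond the grace
#'   period (an episode break).
#' @param discontinuation_hazard Per-refill probability of stopping therapy.
#' @param switch_hazard Per-refill probability of switching to another ADHD
#'   drug (destination drawn uniformly from MPH/ATX/other ADHD).
#' @param dose_mix List with `dose_mg` and `prob`: the distribution of the
#'   per-patient instructed daily dose, including mass above 70 mg/day.
#' @param supply_days_nominal Days supplied per prescription (default 30).
#' @param p_adolescent_continuation Probability a patient is instead drawn
#'   as an age-18 starter whose episodes may cross the 19th birthday
#'   (feeds the adult continuation exemption).
#' @param mph_extra_mean Poisson mean of additional prior-MPH prescriptions
#'   beyond the first.
#' @param enrolment_history_max_days Enrolment may begin up to this many
#'   days before the observation window (registry history; default 1095).
#' @param gap_days Grace period used for the generator's own event
#'   bookkeeping; must match the analysis grace period (default 30).
#' @param source_weights Optional probabilities over the country's sources.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 500,
                              country = "sweden",
                              seed = 1L,
                              age_mix = c("0-5" = 0.003, "6-12" = 0.32,
                                          "13-18" = 0.28, "19-25" = 0.10,
                                          ">25" = 0.297),
                              male_fraction = 0.70,
                              p_adhd_recorded = 0.80,
                              p_prior_mph = 0.80,
                              p_switch_to = 0.50,
                              refill_gap = list(p_on_time = 0.85,
                                                on_time_min = -5, on_time_max = 5,
                                                late_meanlog = log(45),
                                                late_sdlog = 0.5),
                              discontinuation_hazard = 0.08,
                              switch_hazard = 0.03,
                              dose_mix = list(dose_mg = c(20, 30, 40, 50, 60, 70, 100),
                                              prob = c(0.05, 0.20, 0.20, 0.25, 0.10, 0.15, 0.05)),
                              supply_days_nominal = 30,
                              p_adolescent_continuation = 0.05,
                              mph_extra_mean = 1,
                              enrolment_history_max_days = 1095,
                              gap_days = 30,
                              source_weights = NULL) {
  cfg <- list(n_patients = as.integer(n_patients), country = country,
              seed = as.integer(seed), age_mix = age_mix,
              male_fraction = male_fraction, p_adhd_recorded = p_adhd_recorded,
              p_prior_mph = p_prior_mph, p_switch_to = p_switch_to,
              refill_gap = refill_gap,
              discontinuation_hazard = discontinuation_hazard,
              switch_hazard = switch_hazard, dose_mix = dose_mix,
              supply_days_nominal = supply_days_nominal,
              p_adolescent_continuation = p_adolescent_continuation,
              mph_extra_mean = mph_extra_mean,
              enrolment_history_max_days = enrolment_history_max_days,
              gap_days = gap_days, source_weights = source_weights)
  probs <- c(cfg$male_fraction, cfg$p_adhd_recorded, cfg$p_prior_mph,
             cfg$p_switch_to, cfg$discontinuation_hazard, cfg$switch_hazard,
             cfg$p_adolescent_continuation, cfg$refill_gap$p_on_time)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$age_mix) - 1) > 1e-8) stop("age_mix must sum to 1")
  if (abs(sum(cfg$dose_mix$prob) - 1) > 1e-8) stop("dose_mix$prob must sum to 1")
  if (cfg$supply_days_nominal < 1) stop("supply_days_nominal must be >= 1")
  class(cfg) <- "simulation_config"
  cfg
}

# Uniform integer draw on [lo, hi], safe against sample()'s scalar pitfall.
rint <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

age_band_range <- function(band) {
  switch(band,
         "0-5" = c(3, 5), "6-12" = c(6, 12), "13-18" = c(13, 18),
         "19-25" = c(19, 25), ">25" = c(26, 55),
         stop("unknown age band: ", band))
}

#' Simulate a synthetic cohort
#'
#' Generates the three event tables plus the generator's own ground-truth
#' event labels. Each patient's history is built forwards: a first LDX issue
#' date inside the country observation window; optionally a prior MPH
#' history (ending within the grace period before first LDX for switch-to
#' events, else more than a grace period earlier) and a recorded ADHD
#' diagnosis; then refills whose timing follows the refill-gap mixture until
#' a discontinuation or switch event fires or the window runs out. Because
#' gaps, stops and switches are *generated*, their labels are known exactly
#' and are returned in `truth` — the strongest end-to-end check of the
#' classifiers is recovering them.
#'
#' Events respect the grace-period definitions: a generated refill gap above
#' `gap_days` is itself an episode break and is booked as a discontinuation
#' when follow-up suffices; a final supply end too close to the window end
#' is booked as censored.
#'
#' @param config A [simulation_config()].
#' @return List with `patients`, `prescriptions`, `diagnoses` data.frames
#'   (interchange layout, see [read_cohort()]), `truth` (per-patient
#'   generated labels: `discontinued`, `switched_to_ldx`,
#'   `switched_from_ldx`, `censored`, `has_prior_mph`, `adhd_recorded`,
#'   `n_ldx_rx`, `first_ldx_date`, `dose_mg`), and the resolved
#'   `country_config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  cc <- country_config(cfg$country)
  obs_start <- as.numeric(unclass(cc$observation_start))
  obs_end <- as.numeric(unclass(cc$observation_end))
  supply <- cfg$supply_days_nominal
  gap_max <- cfg$gap_days
  if (obs_end - obs_start < supply) {
    stop("observation window shorter than one supply period")
  }
  last_issue_day <- obs_end - 1  # closed-open window

  set.seed(cfg$seed)
  n <- cfg$n_patients
  sources <- cc$sources
  sw <- cfg$source_weights
  if (is.null(sw)) sw <- rep(1 / nrow(sources), nrow(sources))

  pat <- vector("list", n); rx <- vector("list", n); dx <- vector("list", n)
  tru <- vector("list", n)

  draw_gap <- function() {
    if (stats::runif(1) < cfg$refill_gap$p_on_time) {
      rint(cfg$refill_gap$on_time_min, cfg$refill_gap$on_time_max)
    } else {
      round(stats::rlnorm(1, cfg$refill_gap$late_meanlog, cfg$refill_gap$late_sdlog))
    }
  }

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    src <- sources[sample.int(nrow(sources), 1L, prob = sw), ]
    sex <- if (stats::runif(1) < cfg$male_fraction) "male" else "female"
    enrol_start <- obs_start - rint(0L, cfg$enrolment_history_max_days)
    enrol_end <- obs_end

    first_ldx <- rint(obs_start, obs_end - supply)
    adolescent <- stats::runif(1) < cfg$p_adolescent_continuation
    if (adolescent) {
      age_first <- 18L
    } else {
      band <- sample(names(cfg$age_mix), 1L, prob = cfg$age_mix)
      r <- age_band_range(band)
      age_first <- rint(r[1], r[2])
    }
    first_ldx_year <- as.integer(format(as.Date(first_ldx, origin = "1970-01-01"), "%Y"))
    birth_year <- first_ldx_year - age_first

    dose <- sample(cfg$dose_mix$dose_mg, 1L, prob = cfg$dose_mix$prob)

    ## prior MPH history -------------------------------------------------
    has_mph <- stats::runif(1) < cfg$p_prior_mph
    switched_to <- FALSE
    mph_issue <- numeric(0)
    if (has_mph) {
      hist_days <- first_ldx - enrol_start
      feas_switch <- hist_days >= supply            # room for one MPH supply ending near first LDX
      feas_nonsw <- hist_days >= supply + gap_max + 1
      want_switch <- stats::runif(1) < cfg$p_switch_to
      mode <- if (want_switch && feas_switch) "switch"
      else if (!want_switch && feas_nonsw) "nonswitch"
      else if (feas_nonsw) "nonswitch"
      else if (feas_switch) "switch"
      else NA_character_
      if (is.na(mode)) {
        has_mph <- FALSE
      } else if (mode == "switch") {
        d2 <- rint(0, min(gap_max, hist_days - supply))
        mph_end <- first_ldx - d2
        mph_issue <- mph_end - supply
        switched_to <- TRUE
      } else {
        d3_max <- min(365, hist_days - supply)
        d3 <- rint(gap_max + 1, d3_max)
        mph_end <- first_ldx - d3
        mph_issue <- mph_end - supply
      }
      if (has_mph) {
        extra <- stats::rpois(1, cfg$mph_extra_mean)
        while (extra > 0) {
          g <- rint(0, gap_max)
          prev <- mph_issue[1] - g - supply
          if (prev < enrol_start) break
          mph_issue <- c(prev, mph_issue)
          extra <- extra - 1
        }
      }
    }

    ## ADHD diagnosis ----------------------------------------------------
    adhd_rec <- src$records_diagnoses && stats::runif(1) < cfg$p_adhd_recorded
    dx_date <- if (adhd_rec) first_ldx - rint(1, 1095) else NA_real_

    ## LDX refill process ------------------------------------------------
    ldx_issue <- first_ldx
    cur_end <- first_ldx + supply
    discontinued <- FALSE
    switched_from <- FALSE
    censored <- FALSE
    stop_type <- NULL
    repeat {
      u <- stats::runif(1)
      if (u < cfg$discontinuation_hazard) { stop_type <- "disc"; break }
      if (u < cfg$discontinuation_hazard + cfg$switch_hazard) { stop_type <- "switch"; break }
      g <- draw_gap()
      nxt <- cur_end + g
      if (nxt > last_issue_day) { stop_type <- "window"; break }
      if (g > gap_max) {
        # generated episode break; follow-up is guaranteed here because the
        # next issue itself lies inside the window
        discontinued <- TRUE
      }
      ldx_issue <- c(ldx_issue, nxt)
      cur_end <- max(nxt, cur_end) + supply
    }
    dest_issue <- NA_real_
    dest_drug <- NA_character_
    if (identical(stop_type, "switch")) {
      d <- rint(0, gap_max)
      if (cur_end + d <= last_issue_day) {
        dest_issue <- cur_end + d
        dest_drug <- sample(c("MPH", "ATX", "other_ADHD"), 1L)
        switched_from <- TRUE
      } else {
        stop_type <- "window"
      }
    }
    if (!identical(stop_type, "switch")) {
      if (cur_end + gap_max <= obs_end) discontinued <- TRUE else censored <- TRUE
    }

    ## assemble rows ------------------------------------------------------
    pat[[i]] <- data.frame(
      patient_id = pid,
      birth_year = if (src$records_ages) birth_year else NA_integer_,
      sex = sex,
      enrolment_start = as.Date(enrol_start, origin = "1970-01-01"),
      enrolment_end = as.Date(enrol_end, origin = "1970-01-01"),
      source_id = src$source_id, stringsAsFactors = FALSE
    )
    issues <- c(mph_issue, ldx_issue, if (!is.na(dest_issue)) dest_issue)
    drugs <- c(rep("MPH", length(mph_issue)), rep("LDX", length(ldx_issue)),
               if (!is.na(dest_issue)) dest_drug)
    doses <- c(rep(20, length(mph_issue)), rep(dose, length(ldx_issue)),
               if (!is.na(dest_issue)) 20)
    rx[[i]] <- data.frame(
      patient_id = pid, drug = drugs,
      issue_date = as.Date(issues, origin = "1970-01-01"),
      strength_mg = doses, quantity = supply,
      daily_dose_instruction_mg = if (src$records_durations) doses else NA_real_,
      supply_days = if (src$records_durations) supply else NA_real_,
      stringsAsFactors = FALSE
    )
    if (adhd_rec) {
      dx[[i]] <- data.frame(patient_id = pid, code_class = "ADHD",
                            diagnosis_date = as.Date(dx_date, origin = "1970-01-01"),
                            stringsAsFactors = FALSE)
    }
    tru[[i]] <- data.frame(
      patient_id = pid, discontinued = discontinued,
      switched_to_ldx = switched_to, switched_from_ldx = switched_from,
      censored = censored, has_prior_mph = has_mph, adhd_recorded = adhd_rec,
      n_ldx_rx = length(ldx_issue),
      first_ldx_date = as.Date(first_ldx, origin = "1970-01-01"),
      age_first_ldx = age_first, dose_mg = dose, stringsAsFactors = FALSE
    )
  }

  dxdf <- if (any(!vapply(dx, is.null, TRUE))) {
    do.call(rbind, dx[!vapply(dx, is.null, TRUE)])
  } else {
    data.frame(patient_id = character(), code_class = character(),
               diagnosis_date = as.Date(character()), stringsAsFactors = FALSE)
  }
  out <- list(patients = do.call(rbind, pat),
              prescriptions = do.call(rbind, rx),
              diagnoses = dxdf,
              truth = do.call(rbind, tru),
              country_config = cc,
              config = cfg)
  rownames(out$patients) <- rownames(out$prescriptions) <-
    rownames(out$diagnoses) <- rownames(out$truth) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients, %d prescriptions, %d diagnoses (%s, seed %d)>\n",
              nrow(x$patients), nrow(x$prescriptions), nrow(x$diagnoses),
              x$country_config$country, x$config$seed))
  invisible(x)
}
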