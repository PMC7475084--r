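AGE_BANDS <- c("0-5", "6-12", "13-18", "19-25", ">25")

age_band_of <- function(age) {
  cut(age, breaks = c(-Inf, 5, 12, 18, 25, Inf), labels = AGE_BANDS)
}

# Sample (n-1) SD; a single observation has zero spread by convention here,
# so degenerate one-patient cohorts print 0 rather than NA.
sdev <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L) return(0)
  stats::sd(x)
}

five_stats <- function(x, prefix) {
  x <- x[!is.na(x)]
  out <- if (length(x) == 0L) {
    c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
  } else {
    c(mean(x), sdev(x), stats::median(x), min(x), max(x))
  }
  stats::setNames(as.list(out), paste0(prefix, c("_mean", "_sd", "_median", "_min", "_max")))
}

pct_of <- function(n, denom) if (is.na(denom) || denom == 0) NA_real_ else 100 * n / denom

#' Drug utilization analysis (front door)
#'
#' Runs the full analysis on one country's cohort: coverage intervals,
#' treatment episodes (30-day grace period), exposure and average daily
#' dose, discontinuation/switching classification, off-label audit, and the
#' per-patient summary table. Returns a classed object with `print`,
#' `summary` and `plot` methods; `summary()` yields the cohort summary
#' shaped like the study's demographic and treatment-pattern tables.
#'
#' @param patients,prescriptions,diagnoses Cohort tables (see
#'   [read_cohort()]); `diagnoses` may be `NULL` for sources without
#'   diagnosis records.
#' @param config A [country_config()] or resolvable key.
#' @param gap_days Grace period in days shared by episode building,
#'   discontinuation and switching (default 30).
#' @param default_supply_days Fallback supply length (default 30).
#' @param overlap Overlapping-refill model: `"stockpile"` (default,
#'   supply-conserving) or `"truncate"`.
#' @param boundary Grace-window boundary convention (default
#'   `"inclusive"`: a gap of exactly `gap_days` is within the window).
#' @return An object of class `dua` with elements `patient_summary`,
#'   `episodes`, `coverage`, `cohort_summary`, `config` and `params`.
#' @export
dua <- function(patients, prescriptions, diagnoses = NULL, config,
                gap_days = 30, default_supply_days = 30,
                overlap = c("stockpile", "truncate"),
                boundary = c("inclusive", "exclusive")) {
  overlap <- match.arg(overlap)
  boundary <- match.arg(boundary)
  cfg <- country_config(config)
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(), code_class = character(),
                            diagnosis_date = as.Date(character()), stringsAsFactors = FALSE)
  }

  cov <- build_coverage(prescriptions, default_supply_days)
  ldx_cov <- cov[cov$drug == "LDX", , drop = FALSE]
  episodes <- build_episodes(ldx_cov, gap_days, overlap)
  ids <- unique(ldx_cov$patient_id)

  exposure <- patient_exposure(episodes, patient_ids = ids)
  add <- average_daily_dose(cov, cap_mg = cfg$max_daily_dose_mg, patient_ids = ids)

  wend <- pmin(as.numeric(unclass(patients$enrolment_end)),
               as.numeric(unclass(cfg$observation_end)))
  wend <- stats::setNames(as.Date(wend, origin = "1970-01-01"), patients$patient_id)
  pats <- classify_patterns(cov, window_end = wend[ids], gap_days = gap_days,
                            boundary = boundary, overlap = overlap, patient_ids = ids)
  ofl <- evaluate_offlabel(patients, prescriptions, diagnoses, cfg,
                           gap_days = gap_days, default_supply_days = default_supply_days)

  pm <- match(ids, patients$patient_id)
  om <- match(ids, ofl$patient_id)
  am <- match(ids, add$patient_id)
  xm <- match(ids, exposure$patient_id)
  tm <- match(ids, pats$patient_id)

  # documented diagnosis: any recorded ADHD diagnosis at or before first LDX
  first_ldx <- ofl$first_ldx_date[om]
  documented <- rep(FALSE, length(ids))
  adhd <- diagnoses[diagnoses$code_class == "ADHD", , drop = FALSE]
  if (nrow(adhd)) {
    m <- match(adhd$patient_id, ids)
    ok <- !is.na(m) & unclass(adhd$diagnosis_date) <= unclass(first_ldx[m])
    documented[unique(m[ok])] <- TRUE
  }
  src <- cfg$sources[match(patients$source_id[pm], cfg$sources$source_id), , drop = FALSE]
  documented[!src$records_diagnoses] <- NA

  ps <- data.frame(
    patient_id = ids,
    source_id = patients$source_id[pm],
    sex = patients$sex[pm],
    birth_year = patients$birth_year[pm],
    first_ldx_date = first_ldx,
    age_first_ldx = ofl$age_first_ldx[om],
    age_band = as.character(age_band_of(ofl$age_first_ldx[om])),
    documented_adhd = documented,
    n_prescriptions = exposure$n_prescriptions[xm],
    repeat_user = exposure$repeat_user[xm],
    n_episodes = exposure$n_episodes[xm],
    duration_days = exposure$duration_days[xm],
    covered_days = exposure$covered_days[xm],
    followup_span_days = exposure$followup_span_days[xm],
    add_mg_per_day = add$add_mg_per_day[am],
    discontinued = pats$discontinued[tm],
    discontinued_naive = pats$discontinued_naive[tm],
    switched_to_ldx = pats$switched_to_ldx[tm],
    switched_from_ldx = pats$switched_from_ldx[tm],
    censored = pats$censored[tm],
    no_prior_diagnosis = ofl$no_prior_diagnosis[om],
    no_prior_mph = ofl$no_prior_mph[om],
    mph_evaluable = ofl$mph_evaluable[om],
    under_min_age = ofl$under_min_age[om],
    dose_exceeds_cap = ofl$dose_exceeds_cap[om],
    any_rx_dose_exceeds_cap = ofl$any_rx_dose_exceeds_cap[om],
    adult_off_label = ofl$adult_off_label[om],
    any_off_label = ofl$any_off_label[om],
    stringsAsFactors = FALSE
  )

  obj <- list(
    patient_summary = ps,
    episodes = episodes,
    coverage = cov,
    cohort_summary = summarize_cohort(ps, cfg),
    config = cfg,
    params = list(gap_days = gap_days, default_supply_days = default_supply_days,
                  overlap = overlap, boundary = boundary)
  )
  class(obj) <- "dua"
  obj
}

#' Aggregate per-patient summaries into a cohort summary
#'
#' Deterministic aggregation of the per-patient table into the cohort-level
#' counts, percentages and distribution statistics (mean, sample SD, median,
#' min, max). Patients not evaluable for a field (`NA`) are excluded from
#' that field's numerator *and* denominator, and every percentage's
#' denominator is reported alongside it. Mean-dose statistics pool only
#' patients whose average daily dose is at or below the label cap; the
#' above-cap proportion is reported separately.
#'
#' @param patient_summary Per-patient table from [dua()].
#' @param config The [country_config()] used (dose cap and adult
#'   reportability).
#' @return Named list of class `cohort_summary`.
#' @export
summarize_cohort <- function(patient_summary, config) {
  cfg <- country_config(config)
  ps <- patient_summary
  n <- nrow(ps)
  s <- list(country = cfg$country, n_patients = n,
            n_prescriptions = sum(ps$n_prescriptions))

  cnt <- function(flag) {
    denom <- sum(!is.na(flag))
    nn <- sum(flag, na.rm = TRUE)
    list(n = nn, denom = denom, pct = pct_of(nn, denom))
  }

  male <- cnt(ps$sex == "male")
  s$male_n <- male$n; s$male_denom <- male$denom; s$male_pct <- male$pct
  doc <- cnt(ps$documented_adhd)
  s$documented_adhd_n <- doc$n; s$documented_adhd_denom <- doc$denom
  s$documented_adhd_pct <- doc$pct

  band <- factor(ps$age_band, levels = AGE_BANDS)
  bc <- table(band)
  s$age_0_5_n <- unname(bc["0-5"]); s$age_6_12_n <- unname(bc["6-12"])
  s$age_13_18_n <- unname(bc["13-18"]); s$age_19_25_n <- unname(bc["19-25"])
  s$age_gt25_n <- unname(bc[">25"]); s$age_denom <- sum(bc)

  ru <- cnt(ps$repeat_user)
  s$repeat_users_n <- ru$n; s$repeat_users_pct <- pct_of(ru$n, n)

  s <- c(s, five_stats(ps$n_prescriptions, "rx"),
         five_stats(ps$duration_days, "exposure"))

  add_ok <- ps$add_mg_per_day[!is.na(ps$add_mg_per_day) &
                                ps$add_mg_per_day <= cfg$max_daily_dose_mg]
  s <- c(s, five_stats(add_ok, "add"))
  s$add_denom <- length(add_ok)
  over <- cnt(ps$dose_exceeds_cap)
  s$add_exceeds_cap_n <- over$n; s$add_exceeds_cap_denom <- over$denom
  s$add_exceeds_cap_pct <- over$pct

  s$discontinued_n <- sum(ps$discontinued); s$discontinued_pct <- pct_of(s$discontinued_n, n)
  s$discontinued_naive_n <- sum(ps$discontinued_naive)
  s$censored_n <- sum(ps$censored)
  s$switched_to_n <- sum(ps$switched_to_ldx); s$switched_to_pct <- pct_of(s$switched_to_n, n)
  s$switched_from_n <- sum(ps$switched_from_ldx); s$switched_from_pct <- pct_of(s$switched_from_n, n)

  for (f in c("no_prior_diagnosis", "no_prior_mph", "under_min_age", "adult_off_label")) {
    x <- cnt(ps[[f]])
    s[[paste0(f, "_n")]] <- x$n
    s[[paste0(f, "_denom")]] <- x$denom
    s[[paste0(f, "_pct")]] <- x$pct
  }
  if (!cfg$adult_off_label_reportable) {
    # computed but not attributable to the approval timeline: report as
    # not evaluable in the comparison output
    s$adult_off_label_pct <- NA_real_
  }
  anyo <- cnt(ps$any_off_label)
  s$any_off_label_n <- anyo$n; s$any_off_label_pct <- pct_of(anyo$n, n)

  s <- lapply(s, function(v) if (is.table(v)) as.numeric(v) else v)
  class(s) <- "cohort_summary"
  s
}

#' Write / read a cohort summary
#'
#' The summary is written as a single-row tab-delimited file whose columns
#' mirror the demographic and treatment-pattern table rows
#' (`repeat_users_n`, `repeat_users_pct`, `rx_mean`, `rx_sd`, ...), at full
#' precision, so that write -> read is the identity. With
#' `suppress_small_cells = TRUE`, count cells between 1 and 5 (and their
#' percentages) are blanked, as practiced by EMR providers with small-cell
#' policies; default off.
#'
#' @param summary A `cohort_summary`.
#' @param path Output file.
#' @param suppress_small_cells Blank counts below 6 (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_cohort_summary <- function(summary, path, suppress_small_cells = FALSE) {
  stopifnot(inherits(summary, "cohort_summary"))
  s <- unclass(summary)
  if (suppress_small_cells) {
    for (f in grep("_n$", names(s), value = TRUE)) {
      v <- s[[f]]
      if (!is.na(v) && v >= 1 && v < 6) {
        s[[f]] <- NA_real_
        pf <- sub("_n$", "_pct", f)
        if (pf %in% names(s)) s[[pf]] <- NA_real_
      }
    }
  }
  df <- as.data.frame(s, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          fileEncoding = "UTF-8")
  s <- as.list(df[1, , drop = TRUE])
  s$country <- as.character(s$country)
  num <- setdiff(names(s), "country")
  s[num] <- lapply(s[num], as.numeric)
  class(s) <- "cohort_summary"
  s
}

#' Write the per-patient summary table
#'
#' @param patient_summary Per-patient table from [dua()].
#' @param path Output file (tab-delimited).
#' @return Invisibly, `path`.
#' @export
write_patient_summary <- function(patient_summary, path) {
  utils::write.table(patient_summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full pipeline on interchange files
#'
#' Executes read -> episodes -> patterns -> off-label -> summarise and
#' writes the per-patient summary, the cohort summary, the record rejection
#' log and a run log recording every analysis parameter. Outputs are
#' deterministic: the same inputs and configuration always produce
#' byte-identical files.
#'
#' @param input_dir Directory containing `patients.tsv`,
#'   `prescriptions.tsv`, `diagnoses.tsv` (see [write_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param config [country_config()] or resolvable key.
#' @param schema Optional schema override for [read_cohort()].
#' @param suppress_small_cells Passed to [write_cohort_summary()].
#' @param ... Analysis parameters passed to [dua()].
#' @return Invisibly, the `dua` object.
#' @export
run_pipeline <- function(input_dir, out_dir, config, schema = NULL,
                         suppress_small_cells = FALSE, ...) {
  cfg <- country_config(config)
  paths <- list(patients = file.path(input_dir, "patients.tsv"),
                prescriptions = file.path(input_dir, "prescriptions.tsv"),
                diagnoses = file.path(input_dir, "diagnoses.tsv"))
  cohort <- read_cohort(paths, schema = schema)
  res <- dua(cohort$patients, cohort$prescriptions, cohort$diagnoses, cfg, ...)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_patient_summary(res$patient_summary, file.path(out_dir, "patient_summary.tsv"))
  write_cohort_summary(res$cohort_summary, file.path(out_dir, "cohort_summary.tsv"),
                       suppress_small_cells = suppress_small_cells)
  utils::write.table(cohort$rejected, file.path(out_dir, "rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  p <- res$params
  log_lines <- c(
    sprintf("country: %s", cfg$country),
    sprintf("gap_days: %g", p$gap_days),
    sprintf("default_supply_days: %g", p$default_supply_days),
    sprintf("overlap: %s", p$overlap),
    sprintf("boundary: %s", p$boundary),
    sprintf("suppress_small_cells: %s", suppress_small_cells),
    sprintf("records read: %s", paste(sprintf("%s=%d", cohort$counts$file,
                                              cohort$counts$read), collapse = ", ")),
    sprintf("records kept: %s", paste(sprintf("%s=%d", cohort$counts$file,
                                              cohort$counts$kept), collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' @export
print.dua <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("<dua: %s — %d patients, %d LDX prescriptions>\n",
              s$country, s$n_patients, s$n_prescriptions))
  cat(sprintf("  grace period %g d, default supply %g d, %s overlap, %s boundary\n",
              x$params$gap_days, x$params$default_supply_days,
              x$params$overlap, x$params$boundary))
  cat("  use summary() for the cohort table, plot() for pattern charts\n")
  invisible(x)
}

#' @export
summary.dua <- function(object, ...) object$cohort_summary

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_pct <- function(p) if (is.na(p)) "n.e." else sprintf("%.1f%%", p)
  fmt_ms <- function(prefix) {
    sprintf("%.1f (%.1f); median %g (%g; %g)",
            x[[paste0(prefix, "_mean")]], x[[paste0(prefix, "_sd")]],
            x[[paste0(prefix, "_median")]], x[[paste0(prefix, "_min")]],
            x[[paste0(prefix, "_max")]])
  }
  cat(sprintf("Cohort summary — %s (n = %g patients, %g LDX prescriptions)\n",
              x$country, x$n_patients, x$n_prescriptions))
  if (x$n_patients == 0) {
    cat("  (empty cohort: counts 0, proportions undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("  Male:                   %g/%g (%s)\n", x$male_n, x$male_denom, fmt_pct(x$male_pct)))
  cat(sprintf("  Documented ADHD dx:     %g/%g (%s)\n", x$documented_adhd_n,
              x$documented_adhd_denom, fmt_pct(x$documented_adhd_pct)))
  cat(sprintf("  Age bands 0-5/6-12/13-18/19-25/>25: %g/%g/%g/%g/%g (denom %g)\n",
              x$age_0_5_n, x$age_6_12_n, x$age_13_18_n, x$age_19_25_n,
              x$age_gt25_n, x$age_denom))
  cat(sprintf("  Repeat users:           %g (%s)\n", x$repeat_users_n, fmt_pct(x$repeat_users_pct)))
  cat(sprintf("  Rx per patient:         mean (SD) %s\n", fmt_ms("rx")))
  cat(sprintf("  Exposure (days):        mean (SD) %s\n", fmt_ms("exposure")))
  cat(sprintf("  Avg daily dose (mg/d):  mean (SD) %s  [<= cap, n = %g]\n",
              fmt_ms("add"), x$add_denom))
  cat(sprintf("  ADD above cap:          %g/%g (%s)\n", x$add_exceeds_cap_n,
              x$add_exceeds_cap_denom, fmt_pct(x$add_exceeds_cap_pct)))
  cat(sprintf("  Discontinued:           %g (%s)  [naive %g; censored %g]\n",
              x$discontinued_n, fmt_pct(x$discontinued_pct),
              x$discontinued_naive_n, x$censored_n))
  cat(sprintf("  Switched to LDX:        %g (%s)\n", x$switched_to_n, fmt_pct(x$switched_to_pct)))
  cat(sprintf("  Switched from LDX:      %g (%s)\n", x$switched_from_n, fmt_pct(x$switched_from_pct)))
  cat(sprintf("  No prior diagnosis:     %g/%g (%s)\n", x$no_prior_diagnosis_n,
              x$no_prior_diagnosis_denom, fmt_pct(x$no_prior_diagnosis_pct)))
  cat(sprintf("  No prior MPH:           %g/%g (%s)\n", x$no_prior_mph_n,
              x$no_prior_mph_denom, fmt_pct(x$no_prior_mph_pct)))
  cat(sprintf("  Under minimum age:      %g/%g (%s)\n", x$under_min_age_n,
              x$under_min_age_denom, fmt_pct(x$under_min_age_pct)))
  cat(sprintf("  Adult off-label:        %g/%g (%s)\n", x$adult_off_label_n,
              x$adult_off_label_denom, fmt_pct(x$adult_off_label_pct)))
  cat(sprintf("  Any off-label:          %g (%s)\n", x$any_off_label_n, fmt_pct(x$any_off_label_pct)))
  invisible(x)
}

#' Plot treatment-pattern summaries
#'
#' Two base-graphics panels: the classified pattern proportions
#' (repeat use, discontinuation, switching, censoring) and the distribution
#' of the average daily dose with the label cap marked.
#'
#' @param x A `dua` object.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.dua <- function(x, ...) {
  ps <- x$patient_summary
  s <- x$cohort_summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  props <- c(`repeat user` = s$repeat_users_pct,
             discontinued = s$discontinued_pct,
             `switched to LDX` = s$switched_to_pct,
             `switched from LDX` = s$switched_from_pct,
             censored = pct_of(s$censored_n, s$n_patients))
  graphics::barplot(props, ylab = "% of patients", las = 2,
                    main = sprintf("Treatment patterns (%s)", s$country),
                    col = "steelblue")
  add <- ps$add_mg_per_day[!is.na(ps$add_mg_per_day)]
  if (length(add)) {
    graphics::hist(add, breaks = 20, xlab = "average daily dose (mg/day)",
                   main = "Average daily dose", col = "grey80")
    graphics::abline(v = x$config$max_daily_dose_mg, lty = 2, col = "red")
  }
  invisible(x)
}
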