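#' Country label configuration
#'
#' A `country_config` is the declarative description of one jurisdiction's
#' LDX label and observation setting: launch date, adult-approval status
#' (with an optional age cap, as in Switzerland's adults-up-to-55 approval),
#' the observation window, the paediatric label constraints (minimum age 6,
#' maximum 70 mg/day, prior-MPH requirement), and the data sources available
#' there with what each records. The eight shipped fixtures cover Denmark,
#' Finland, Germany, Norway, Spain, Sweden, Switzerland and the United
#' Kingdom over the 2013-2017 post-launch observation periods.
#'
#' All dates are ISO-8601; observation windows are closed-open
#' `[observation_start, observation_end)` in day units.
#'
#' @param x A file path to a YAML config, a country name matching a shipped
#'   fixture (case-insensitive, e.g. `"sweden"`), or a list with the config
#'   fields.
#' @return An object of class `country_config`.
#' @export
country_config <- function(x) {
  if (inherits(x, "country_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    path <- if (file.exists(x)) x else shipped_config_path(x)
    x <- yaml::read_yaml(path)
  }
  stopifnot(is.list(x))
  required <- c("country", "launch_date", "observation_start", "observation_end")
  missing <- setdiff(required, names(x))
  if (length(missing)) stop("country_config missing fields: ", paste(missing, collapse = ", "))

  cfg <- list(
    country = as.character(x$country),
    launch_date = parse_iso_date(x$launch_date),
    adult_approval_date = if (is.null(x$adult_approval_date)) as.Date(NA) else parse_iso_date(x$adult_approval_date),
    adult_age_cap = if (is.null(x$adult_age_cap)) NA_real_ else as.numeric(x$adult_age_cap),
    observation_start = parse_iso_date(x$observation_start),
    observation_end = parse_iso_date(x$observation_end),
    min_label_age = if (is.null(x$min_label_age)) 6 else as.numeric(x$min_label_age),
    max_daily_dose_mg = if (is.null(x$max_daily_dose_mg)) 70 else as.numeric(x$max_daily_dose_mg),
    requires_prior_mph = if (is.null(x$requires_prior_mph)) TRUE else isTRUE(x$requires_prior_mph),
    requires_recorded_diagnosis = if (is.null(x$requires_recorded_diagnosis)) TRUE else isTRUE(x$requires_recorded_diagnosis),
    mph_lookback_min_enrolment_days = if (is.null(x$mph_lookback_min_enrolment_days)) 365 else as.numeric(x$mph_lookback_min_enrolment_days),
    adult_off_label_reportable = if (is.null(x$adult_off_label_reportable)) TRUE else isTRUE(x$adult_off_label_reportable),
    sources = normalise_sources(x$sources)
  )
  if (is.na(cfg$launch_date) || is.na(cfg$observation_start) || is.na(cfg$observation_end)) {
    stop("country_config dates must be ISO-8601")
  }
  if (cfg$observation_end <= cfg$observation_start) {
    stop("observation_end must be after observation_start")
  }
  if (cfg$launch_date > cfg$observation_end) stop("launch_date after observation_end")
  class(cfg) <- "country_config"
  cfg
}

normalise_sources <- function(sources) {
  if (is.null(sources) || length(sources) == 0L) {
    sources <- list(list(source_id = "default", records_diagnoses = TRUE,
                         records_ages = TRUE, records_durations = TRUE,
                         description = "default source"))
  }
  do.call(rbind, lapply(sources, function(s) {
    data.frame(
      source_id = as.character(s$source_id),
      records_diagnoses = isTRUE(s$records_diagnoses),
      records_ages = isTRUE(s$records_ages),
      records_durations = isTRUE(s$records_durations),
      description = if (is.null(s$description)) "" else as.character(s$description),
      stringsAsFactors = FALSE
    )
  }))
}

shipped_config_path <- function(country) {
  fname <- paste0(tolower(gsub("[ _]", "", country)), ".yaml")
  path <- system.file("extdata", "countries", fname, package = "ldxdur")
  if (!nzchar(path)) stop("no shipped country config for '", country, "'")
  path
}

#' @return `list_country_configs()`: named list of all shipped
#'   `country_config` fixtures.
#' @rdname country_config
#' @export
list_country_configs <- function() {
  dir <- system.file("extdata", "countries", package = "ldxdur")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  cfgs <- lapply(files, country_config)
  stats::setNames(cfgs, vapply(cfgs, function(c) c$country, ""))
}

#' Write a country config to YAML
#'
#' Round-trip companion to [country_config()].
#'
#' @param cfg A `country_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_country_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "country_config"))
  out <- unclass(cfg)
  for (f in c("launch_date", "adult_approval_date", "observation_start", "observation_end")) {
    out[[f]] <- if (is.na(out[[f]])) NULL else format(out[[f]], "%Y-%m-%d")
  }
  if (is.na(out$adult_age_cap)) out$adult_age_cap <- NULL
  out$sources <- lapply(seq_len(nrow(cfg$sources)), function(i) as.list(cfg$sources[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.country_config <- function(x, ...) {
  cat(sprintf("<country_config: %s>\n", x$country))
  cat(sprintf("  launch: %s   observation: [%s, %s)\n",
              format(x$launch_date), format(x$observation_start), format(x$observation_end)))
  if (is.na(x$adult_approval_date)) {
    cat("  adult approval: none in window\n")
  } else {
    cat(sprintf("  adult approval: %s%s\n", format(x$adult_approval_date),
                if (!is.na(x$adult_age_cap)) sprintf(" (age cap %g)", x$adult_age_cap) else ""))
  }
  cat(sprintf("  label: age >= %g, dose <= %g mg/day, prior MPH %s\n",
              x$min_label_age, x$max_daily_dose_mg,
              if (x$requires_prior_mph) "required" else "not required"))
  cat(sprintf("  sources: %s\n", paste(x$sources$source_id, collapse = ", ")))
  invisible(x)
}
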