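#' Drug role vocabulary
#'
#' Prescriptions are classified into drug *roles* rather than product names:
#' `LDX` (the index drug, lisdexamfetamine), `MPH` (methylphenidate), `ATX`
#' (atomoxetine), `other_ADHD` (any other ADHD medication) and `non_ADHD`
#' (anything else; inert for all treatment-pattern logic). Input files may
#' carry arbitrary codes (e.g. ATC codes) which a schema-supplied `drug_map`
#' resolves to these roles.
#'
#' @return Character vector of the recognised drug roles.
#' @export
drug_levels <- function() c("LDX", "MPH", "ATX", "other_ADHD", "non_ADHD")

#' @rdname drug_levels
#' @return `adhd_drugs()`: the roles that count as ADHD medication.
#' @export
adhd_drugs <- function() c("LDX", "MPH", "ATX", "other_ADHD")

sex_levels <- function() c("male", "female", "unknown")

# Strict ISO-8601 parsing; anything else becomes NA (and is rejected upstream).
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  chr <- as.character(x)
  ok <- !is.na(chr) & grepl("^\\d{4}-\\d{2}-\\d{2}$", chr)
  out[ok] <- as.Date(chr[ok], format = "%Y-%m-%d")
  out
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Default interchange schema
#'
#' Maps canonical field names to the column names used in the delimited input
#' files, and maps raw drug codes to drug roles. A user schema (R list or YAML
#' file with the same shape) overrides any subset of it. The shipped
#' `drug_map` is a toy ATC mapping, not a dictionary.
#'
#' @return A list with elements `delimiter`, `columns` (per-table name maps)
#'   and `drug_map`.
#' @export
default_schema <- function() {
  list(
    delimiter = "\t",
    columns = list(
      patients = list(
        patient_id = "patient_id", birth_year = "birth_year", sex = "sex",
        enrolment_start = "enrolment_start", enrolment_end = "enrolment_end",
        source_id = "source_id"
      ),
      prescriptions = list(
        patient_id = "patient_id", drug = "drug", issue_date = "issue_date",
        strength_mg = "strength_mg", quantity = "quantity",
        daily_dose_instruction_mg = "daily_dose_instruction_mg",
        supply_days = "supply_days"
      ),
      diagnoses = list(
        patient_id = "patient_id", code_class = "code_class",
        diagnosis_date = "diagnosis_date"
      )
    ),
    drug_map = list(
      N06BA12 = "LDX", N06BA04 = "MPH", N06BA09 = "ATX",
      N06BA01 = "other_ADHD", N06BA02 = "other_ADHD", N06BA07 = "other_ADHD"
    )
  )
}

load_schema <- function(schema = NULL) {
  base <- default_schema()
  if (is.null(schema)) return(base)
  if (is.character(schema) && length(schema) == 1L) schema <- yaml::read_yaml(schema)
  stopifnot(is.list(schema))
  if (!is.null(schema$delimiter)) base$delimiter <- schema$delimiter
  for (tb in names(base$columns)) {
    if (!is.null(schema$columns[[tb]])) {
      base$columns[[tb]][names(schema$columns[[tb]])] <- schema$columns[[tb]]
    }
  }
  if (!is.null(schema$drug_map)) base$drug_map <- schema$drug_map
  base
}

# Pull canonical columns out of a raw data.frame; absent optional columns
# come back as NA.
extract_columns <- function(raw, colmap, optional = character()) {
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(colmap)) {
    src <- colmap[[canon]]
    if (src %in% names(raw)) {
      out[[canon]] <- raw[[src]]
    } else if (canon %in% optional) {
      out[[canon]] <- rep(NA, nrow(raw))
    } else {
      stop(sprintf("required column '%s' (mapped from '%s') not found", canon, src))
    }
  }
  out
}

new_rejection_log <- function() {
  data.frame(file = character(), line = integer(), patient_id = character(),
             reason = character(), stringsAsFactors = FALSE)
}

add_rejections <- function(log, file, lines, ids, reasons) {
  if (length(lines) == 0L) return(log)
  rbind(log, data.frame(file = file, line = as.integer(lines),
                        patient_id = as.character(ids),
                        reason = reasons, stringsAsFactors = FALSE))
}

#' Read a cohort from delimited interchange files
#'
#' Reads the three event tables (patients, prescriptions, diagnoses) from
#' UTF-8 delimited text with a header row, applies the schema's column and
#' drug-code mappings, type-checks every record, and separates invalid rows
#' into a rejection log instead of failing. Every input row is either kept or
#' logged (conservation of records). Line numbers in the log refer to the
#' physical file line (header is line 1).
#'
#' Checks applied: dates must be ISO-8601 and parseable; `strength_mg` and
#' `quantity` must be positive when present; prescriptions must fall inside
#' the patient's enrolment window; diagnoses must not postdate enrolment end
#' (historical diagnoses before enrolment are allowed); prescriptions and
#' diagnoses must reference a known patient. An implausible `birth_year`
#' (outside 1900..current year) is set to missing and logged, but the patient
#' is kept.
#'
#' @param paths Named list or vector with elements `patients`,
#'   `prescriptions`, `diagnoses` giving file paths. `diagnoses` may be `NA`
#'   or point to a file with no rows (sources that do not record diagnoses).
#' @param schema `NULL` for the default, or a list / YAML path overriding
#'   [default_schema()].
#' @param on_unknown_drug `"reject"` (default) drops rows whose drug code is
#'   neither a role nor in `drug_map`; `"map_non_adhd"` keeps them as
#'   `non_ADHD`.
#' @return A list with data.frames `patients`, `prescriptions`, `diagnoses`,
#'   the `rejected` log, and `counts` (rows read/kept per file).
#' @export
read_cohort <- function(paths, schema = NULL, on_unknown_drug = c("reject", "map_non_adhd")) {
  on_unknown_drug <- match.arg(on_unknown_drug)
  schema <- load_schema(schema)
  for (nm in c("patients", "prescriptions")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      stop(sprintf("input file for '%s' not found", nm))
    }
  }
  read_raw <- function(path) {
    utils::read.delim(path, sep = schema$delimiter, header = TRUE,
                      stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = c("NA", ""), fileEncoding = "UTF-8")
  }
  rej <- new_rejection_log()

  ## patients -----------------------------------------------------------
  raw <- read_raw(paths$patients)
  pat <- extract_columns(raw, schema$columns$patients, optional = c("birth_year", "sex"))
  line <- seq_len(nrow(pat)) + 1L
  pat$patient_id <- as.character(pat$patient_id)
  pat$birth_year <- num_or_na(pat$birth_year)
  pat$sex <- ifelse(is.na(pat$sex), "unknown", as.character(pat$sex))
  pat$enrolment_start <- parse_iso_date(pat$enrolment_start)
  pat$enrolment_end <- parse_iso_date(pat$enrolment_end)
  pat$source_id <- as.character(pat$source_id)

  bad_sex <- !pat$sex %in% sex_levels()
  pat$sex[bad_sex] <- "unknown"
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  implaus <- !is.na(pat$birth_year) & (pat$birth_year < 1900 | pat$birth_year > this_year)
  rej <- add_rejections(rej, "patients", line[implaus], pat$patient_id[implaus],
                        "implausible birth_year set to missing (record kept)")
  pat$birth_year[implaus] <- NA_real_

  drop <- is.na(pat$enrolment_start) | is.na(pat$enrolment_end)
  rej <- add_rejections(rej, "patients", line[drop], pat$patient_id[drop],
                        "malformed enrolment date")
  ok <- !drop
  bad_order <- ok & unclass(pat$enrolment_end) < unclass(pat$enrolment_start)
  rej <- add_rejections(rej, "patients", line[bad_order], pat$patient_id[bad_order],
                        "enrolment_end before enrolment_start")
  keep_pat <- ok & !bad_order
  n_pat_read <- nrow(pat)
  pat <- pat[keep_pat, , drop = FALSE]
  dup <- duplicated(pat$patient_id)
  if (any(dup)) {
    rej <- add_rejections(rej, "patients", line[keep_pat][dup], pat$patient_id[dup],
                          "duplicate patient_id")
    pat <- pat[!dup, , drop = FALSE]
  }
  rownames(pat) <- NULL

  enrol_start <- stats::setNames(pat$enrolment_start, pat$patient_id)
  enrol_end <- stats::setNames(pat$enrolment_end, pat$patient_id)

  ## prescriptions ------------------------------------------------------
  raw <- read_raw(paths$prescriptions)
  rx <- extract_columns(raw, schema$columns$prescriptions,
                        optional = c("strength_mg", "quantity",
                                     "daily_dose_instruction_mg", "supply_days"))
  line <- seq_len(nrow(rx)) + 1L
  rx$patient_id <- as.character(rx$patient_id)
  raw_drug <- as.character(rx$drug)
  mapped <- raw_drug
  in_map <- raw_drug %in% names(schema$drug_map)
  mapped[in_map] <- unlist(schema$drug_map[raw_drug[in_map]], use.names = FALSE)
  unknown <- !mapped %in% drug_levels()
  if (on_unknown_drug == "map_non_adhd") {
    mapped[unknown] <- "non_ADHD"
    unknown <- rep(FALSE, length(mapped))
  }
  rx$drug <- mapped
  rx$issue_date <- parse_iso_date(rx$issue_date)
  for (f in c("strength_mg", "quantity", "daily_dose_instruction_mg", "supply_days")) {
    rx[[f]] <- num_or_na(rx[[f]])
  }

  reason <- rep(NA_character_, nrow(rx))
  reason[unknown] <- paste0("unknown drug code '", raw_drug[unknown], "'")
  reason[is.na(reason) & is.na(rx$issue_date)] <- "malformed issue_date"
  known_pat <- rx$patient_id %in% pat$patient_id
  reason[is.na(reason) & !known_pat] <- "unknown patient_id"
  nonpos <- (!is.na(rx$strength_mg) & rx$strength_mg <= 0) |
    (!is.na(rx$quantity) & rx$quantity <= 0) |
    (!is.na(rx$daily_dose_instruction_mg) & rx$daily_dose_instruction_mg <= 0) |
    (!is.na(rx$supply_days) & rx$supply_days <= 0)
  reason[is.na(reason) & nonpos] <- "non-positive strength/quantity/dose/supply"
  in_window <- !is.na(rx$issue_date) & known_pat &
    unclass(rx$issue_date) >= unclass(enrol_start[rx$patient_id]) &
    unclass(rx$issue_date) <= unclass(enrol_end[rx$patient_id])
  reason[is.na(reason) & !in_window] <- "issue_date outside enrolment window"
  bad <- !is.na(reason)
  rej <- add_rejections(rej, "prescriptions", line[bad], rx$patient_id[bad], reason[bad])
  n_rx_read <- nrow(rx)
  rx <- rx[!bad, , drop = FALSE]
  rx <- rx[order(rx$patient_id, rx$issue_date), , drop = FALSE]
  rownames(rx) <- NULL

  ## diagnoses ----------------------------------------------------------
  if (!is.null(paths$diagnoses) && !is.na(paths$diagnoses) && file.exists(paths$diagnoses)) {
    raw <- read_raw(paths$diagnoses)
  } else {
    raw <- data.frame(patient_id = character(), code_class = character(),
                      diagnosis_date = character(), stringsAsFactors = FALSE)
  }
  dx <- extract_columns(raw, schema$columns$diagnoses)
  line <- seq_len(nrow(dx)) + 1L
  dx$patient_id <- as.character(dx$patient_id)
  dx$code_class <- ifelse(as.character(dx$code_class) == "ADHD", "ADHD", "other")
  dx$diagnosis_date <- parse_iso_date(dx$diagnosis_date)
  reason <- rep(NA_character_, nrow(dx))
  reason[is.na(dx$diagnosis_date)] <- "malformed diagnosis_date"
  known_pat <- dx$patient_id %in% pat$patient_id
  reason[is.na(reason) & !known_pat] <- "unknown patient_id"
  too_late <- !is.na(dx$diagnosis_date) & known_pat &
    unclass(dx$diagnosis_date) > unclass(enrol_end[dx$patient_id])
  reason[is.na(reason) & too_late] <- "diagnosis_date after enrolment end"
  bad <- !is.na(reason)
  rej <- add_rejections(rej, "diagnoses", line[bad], dx$patient_id[bad], reason[bad])
  n_dx_read <- nrow(dx)
  dx <- dx[!bad, , drop = FALSE]
  rownames(dx) <- NULL

  list(
    patients = pat, prescriptions = rx, diagnoses = dx, rejected = rej,
    counts = data.frame(
      file = c("patients", "prescriptions", "diagnoses"),
      read = c(n_pat_read, n_rx_read, n_dx_read),
      kept = c(nrow(pat), nrow(rx), nrow(dx)),
      stringsAsFactors = FALSE
    )
  )
}

#' Write a cohort to interchange files
#'
#' Inverse of [read_cohort()]: writes the three event tables as tab-delimited
#' UTF-8 text with canonical column names, so that read -> write -> read is
#' the identity.
#'
#' @param cohort List with `patients`, `prescriptions`, `diagnoses`
#'   data.frames (e.g. from [simulate_cohort()] or [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.tsv"),
             prescriptions = file.path(dir, "prescriptions.tsv"),
             diagnoses = file.path(dir, "diagnoses.tsv"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  }
  write_tsv(cohort$patients, paths["patients"])
  write_tsv(cohort$prescriptions, paths["prescriptions"])
  dx <- cohort$diagnoses
  if (is.null(dx)) {
    dx <- data.frame(patient_id = character(), code_class = character(),
                     diagnosis_date = character())
  }
  write_tsv(dx, paths["diagnoses"])
  invisible(paths)
}
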