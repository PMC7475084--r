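#' Classify treatment patterns: discontinuation and switching
#'
#' Applies the study's 30-day-window definitions to each patient's event
#' history:
#'
#' * **Discontinued**: some LDX treatment-episode end is followed by no new
#'   LDX prescription and no other-ADHD-drug prescription within `gap_days`,
#'   and the window extends at least `gap_days` beyond that end (otherwise
#'   the end is *censored* — there is not enough follow-up to adjudicate).
#' * **Switched to LDX**: an LDX prescription is issued within `gap_days`
#'   after the end of a prescription period of another ADHD medication.
#' * **Switched from LDX**: a prescription of another ADHD medication is
#'   issued within `gap_days` after the end of an LDX prescription period.
#'
#' Prescription-period ends are supply-conserving (stockpiling-adjusted)
#' coverage ends, matching the episode model. Switch flags are not exclusive
#' (a patient may switch to LDX and later from it); at any single episode
#' end, switch evidence and discontinuation are mutually exclusive. The
#' patient-level `discontinued` flag is "ever discontinued" at any episode
#' end; `discontinued_naive` ignores the censoring condition (the count a
#' follow-up-blind reading of the definition would give).
#'
#' @param coverage Output of [build_coverage()]; all ADHD drug roles are
#'   used, `non_ADHD` rows are ignored.
#' @param window_end Observation end (Date; closed-open window, exclusive),
#'   either a single date or a named Date vector keyed by `patient_id`.
#' @param gap_days Grace period (default 30).
#' @param boundary `"inclusive"` (default): "within `gap_days`" means
#'   `issue - end` in `[0, gap_days]`; `"exclusive"` uses `[0, gap_days)`.
#' @param overlap Overlap model passed to the coverage adjustment.
#' @param patient_ids Optional universe; defaults to patients with at least
#'   one LDX coverage interval.
#' @return Data.frame with one row per patient: logical flags
#'   `discontinued`, `discontinued_naive`, `switched_to_ldx`,
#'   `switched_from_ldx`, `censored`, and event dates `discontinuation_date`
#'   (first adjudicated discontinuation), `switch_to_date`,
#'   `switch_from_date` (first qualifying issue dates).
#' @export
classify_patterns <- function(coverage, window_end, gap_days = 30,
                              boundary = c("inclusive", "exclusive"),
                              overlap = c("stockpile", "truncate"),
                              patient_ids = NULL) {
  boundary <- match.arg(boundary)
  overlap <- match.arg(overlap)
  if (gap_days < 0) stop("gap_days must be non-negative")
  within_gap <- if (boundary == "inclusive") {
    function(d) !is.na(d) & d >= 0 & d <= gap_days
  } else {
    function(d) !is.na(d) & d >= 0 & d < gap_days
  }

  cov <- coverage[coverage$drug %in% adhd_drugs(), , drop = FALSE]
  cov <- adjust_coverage(cov, overlap)
  ids <- if (is.null(patient_ids)) {
    unique(cov$patient_id[cov$drug == "LDX"])
  } else {
    unique(as.character(patient_ids))
  }
  k <- length(ids)
  out <- data.frame(
    patient_id = ids, discontinued = rep(FALSE, k),
    discontinued_naive = rep(FALSE, k), switched_to_ldx = rep(FALSE, k),
    switched_from_ldx = rep(FALSE, k), censored = rep(FALSE, k),
    discontinuation_date = rep(as.Date(NA), k), switch_to_date = rep(as.Date(NA), k),
    switch_from_date = rep(as.Date(NA), k), stringsAsFactors = FALSE
  )
  if (nrow(cov) == 0L || length(ids) == 0L) return(out)

  wend <- resolve_window_end(window_end, ids)
  idx_by_pat <- split(seq_len(nrow(cov)), cov$patient_id)

  for (i in seq_along(ids)) {
    pid <- ids[i]
    rows <- idx_by_pat[[pid]]
    if (is.null(rows)) next
    pc <- cov[rows, , drop = FALSE]
    is_ldx <- pc$drug == "LDX"
    ldx_issue <- as.numeric(unclass(pc$issue_date[is_ldx]))
    ldx_end <- as.numeric(unclass(pc$adj_end[is_ldx]))
    oth_issue <- as.numeric(unclass(pc$issue_date[!is_ldx]))
    oth_end <- as.numeric(unclass(pc$adj_end[!is_ldx]))

    # switch to LDX: other-drug period end -> LDX issue within the window
    if (length(oth_end) && length(ldx_issue)) {
      d <- outer(ldx_issue, oth_end, "-")
      hit <- within_gap(d)
      if (any(hit)) {
        out$switched_to_ldx[i] <- TRUE
        out$switch_to_date[i] <- as.Date(min(ldx_issue[row(d)[hit]]), origin = "1970-01-01")
      }
    }
    # switch from LDX: LDX period end -> other-drug issue within the window
    if (length(ldx_end) && length(oth_issue)) {
      d <- outer(oth_issue, ldx_end, "-")
      hit <- within_gap(d)
      if (any(hit)) {
        out$switched_from_ldx[i] <- TRUE
        out$switch_from_date[i] <- as.Date(min(oth_issue[row(d)[hit]]), origin = "1970-01-01")
      }
    }
    # discontinuation / censoring at LDX episode ends
    if (length(ldx_end)) {
      # The LDX stream is in issue order and adjusted ends are strictly
      # increasing, so an end is an episode end exactly when the next issue
      # (if any) falls outside the grace period of that end.
      g <- ldx_issue[-1] - ldx_end[-length(ldx_end)]
      cont <- if (boundary == "inclusive") g <= gap_days else g < gap_days
      ep_end <- ldx_end[c(!cont, TRUE)]
      if (length(ep_end)) {
        has_switch_ev <- vapply(ep_end, function(e) any(within_gap(oth_issue - e)), TRUE)
        out$discontinued_naive[i] <- any(!has_switch_ev)
        adjudicable <- ep_end + gap_days <= wend[i]
        disc <- !has_switch_ev & adjudicable
        if (any(disc)) {
          out$discontinued[i] <- TRUE
          out$discontinuation_date[i] <- as.Date(min(ep_end[disc]), origin = "1970-01-01")
        }
        last_e <- max(ep_end)
        out$censored[i] <- (last_e + gap_days > wend[i]) &&
          !any(within_gap(oth_issue - last_e))
      }
    }
  }
  rownames(out) <- NULL
  out
}

resolve_window_end <- function(window_end, ids) {
  if (length(window_end) == 1L && is.null(names(window_end))) {
    rep(as.numeric(unclass(as.Date(window_end))), length(ids))
  } else {
    w <- as.numeric(unclass(as.Date(window_end)))[match(ids, names(window_end))]
    if (anyNA(w)) stop("window_end missing for some patients")
    w
  }
}
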