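#' @title Confirmed objective disability-progression detection
#' @description Detector for late-stage confirmed progression independent
#'   of relapse activity, defined on EDSS and functional-system (FS)
#'   scores: the candidate visit must reach EDSS >= 4.0 with pyramidal
#'   FS >= 2, show a threshold EDSS increase over the reference (>= 1.0
#'   when the reference EDSS is <= 5.5, >= 0.5 when it is >= 6), be
#'   confirmed stable in EDSS and in the leading functional system at
#'   least 3 months later, and have no relapse between the preceding
#'   evaluation and the candidate visit.
#' @name outcome_detection
NULL

.fs_names <- c("fs_pyramidal", "fs_cerebellar", "fs_brainstem", "fs_sensory",
               "fs_bowel_bladder", "fs_visual", "fs_cerebral")

#' Criteria governing objective progression detection
#'
#' @param edss_floor Minimum overall EDSS at the candidate visit (4.0).
#' @param pyramidal_min Minimum pyramidal FS at the candidate visit (2).
#' @param delta_low_baseline Required EDSS increase when the reference
#'   EDSS is <= 5.5 (1.0).
#' @param delta_high_baseline Required increase when the reference EDSS is
#'   >= 6 (0.5).
#' @param confirmation_days Minimum days between candidate and confirming
#'   visit; 3 months = 90 days.
#' @param require_leading_fs_confirmation Also require the leading
#'   functional system to be sustained at confirmation (default TRUE).
#' @param reference Comparator for the EDSS increase: `"nadir"` (minimum
#'   EDSS at or after baseline and strictly before the candidate; default)
#'   or `"baseline"` (EDSS at the baseline visit).
#' @return list of class `progression_criteria`.
#' @export
progression_criteria <- function(edss_floor = 4.0, pyramidal_min = 2L,
                                 delta_low_baseline = 1.0,
                                 delta_high_baseline = 0.5,
                                 confirmation_days = 90L,
                                 require_leading_fs_confirmation = TRUE,
                                 reference = c("nadir", "baseline")) {
  stopifnot(edss_floor > 0, pyramidal_min > 0, confirmation_days > 0,
            delta_high_baseline <= delta_low_baseline)
  # the half-point EDSS grid leaves no value strictly between 5.5 and 6,
  # so the two delta bands tile the reference range
  structure(list(edss_floor = edss_floor, pyramidal_min = pyramidal_min,
                 delta_low_baseline = delta_low_baseline,
                 delta_high_baseline = delta_high_baseline,
                 confirmation_days = as.integer(confirmation_days),
                 require_leading_fs_confirmation =
                   isTRUE(require_leading_fs_confirmation),
                 reference = match.arg(reference)),
            class = "progression_criteria")
}

## leading FS at a candidate: the system with the largest increase from its
## value at the reference visit; ties broken by the fixed order of .fs_names
.leading_fs <- function(visits, ref_idx, cand_idx) {
  ref <- as.numeric(visits[ref_idx, .fs_names])
  cand <- as.numeric(visits[cand_idx, .fs_names])
  inc <- cand - ref
  if (anyNA(inc)) return(NA_character_)
  .fs_names[which.max(inc)]   # which.max takes the first maximum in order
}

#' Detect the earliest confirmed objective progression event
#'
#' Scans a patient's visits in chronological order and returns the earliest
#' visit satisfying all four criteria (EDSS floor with pyramidal
#' involvement; threshold increase over the reference; >= 3-month
#' confirmation sustained in EDSS and leading FS at every visit up to the
#' confirming one; no relapse since the preceding evaluation). Candidates
#' needing a missing FS score are recorded as abstentions, never silently
#' passed or failed.
#'
#' @param record A patient record (list with `visits`, `relapses`,
#'   `baseline_date`), as returned by [patient_record()] or
#'   [make_fixture()].
#' @param criteria A [progression_criteria()] object.
#' @return `NULL` when no event is found, else a one-row data.frame with
#'   `patient_id`, `event_date`, `confirm_date`, `reference_edss`,
#'   `event_edss`, `leading_fs` and a `reason_trace` attribute listing the
#'   satisfied criteria. Abstained candidates surface through inclusion
#'   criterion I in [apply_inclusion_criteria()].
#' @export
detect_objective_progression <- function(record,
                                         criteria = progression_criteria()) {
  .scan_progression(record, criteria)$event
}

## full scan: the earliest qualifying event (or NULL) plus the dates of
## candidates skipped because a needed FS score was missing
.scan_progression <- function(record, criteria = progression_criteria()) {
  v <- record$visits
  v <- v[order(v$date), , drop = FALSE]
  v <- v[v$date >= record$baseline_date & !is.na(v$edss), , drop = FALSE]
  abstained <- as.Date(character())
  n <- nrow(v)
  if (n < 2L) return(list(event = NULL, abstentions = abstained))
  relapse_dates <- record$relapses$date

  for (ci in 2L:n) {
    prior <- v$edss[seq_len(ci - 1L)]
    if (criteria$reference == "nadir") {
      ref_edss <- min(prior)
      # reference visit: latest pre-candidate visit attaining the nadir
      ref_idx <- max(which(prior == ref_edss))
    } else {
      ref_edss <- v$edss[1L]
      ref_idx <- 1L
    }
    need <- if (ref_edss >= 6) criteria$delta_high_baseline else
      criteria$delta_low_baseline
    if (v$edss[ci] < criteria$edss_floor) next
    if (v$edss[ci] - ref_edss < need) next

    pyr <- v$fs_pyramidal[ci]
    if (is.na(pyr)) { abstained <- c(abstained, v$date[ci]); next }
    if (pyr < criteria$pyramidal_min) next

    # no relapse in (previous visit, candidate]
    if (length(relapse_dates) &&
        any(relapse_dates > v$date[ci - 1L] & relapse_dates <= v$date[ci])) next

    lead <- .leading_fs(v, ref_idx, ci)
    if (criteria$require_leading_fs_confirmation && is.na(lead)) {
      abstained <- c(abstained, v$date[ci]); next
    }

    # confirmation: first visit >= confirmation_days later; EDSS (and
    # leading FS) must be sustained at every visit up to and including it
    later <- which(v$date >= v$date[ci] + criteria$confirmation_days)
    later <- later[later > ci]
    if (length(later) == 0L) next
    confirm_idx <- later[1L]
    span <- (ci + 1L):confirm_idx
    if (any(v$edss[span] < v$edss[ci])) next
    if (criteria$require_leading_fs_confirmation) {
      lead_vals <- v[[lead]][span]
      if (anyNA(lead_vals)) { abstained <- c(abstained, v$date[ci]); next }
      if (any(lead_vals < v[[lead]][ci])) next
    }

    out <- data.frame(
      patient_id = record$patient_id,
      event_date = v$date[ci],
      confirm_date = v$date[confirm_idx],
      reference_edss = ref_edss,
      event_edss = v$edss[ci],
      leading_fs = if (is.na(lead)) NA_character_ else sub("^fs_", "", lead),
      stringsAsFactors = FALSE
    )
    attr(out, "reason_trace") <- c(
      "edss_floor_and_pyramidal", "threshold_increase",
      "sustained_confirmation", "relapse_free_interval")
    return(list(event = out, abstentions = abstained))
  }
  list(event = NULL, abstentions = abstained)
}

#' Detect objective progression events across a cohort
#'
#' @param registry An `ms_registry`.
#' @param criteria A [progression_criteria()].
#' @return data.frame with one row per detected event (columns as in
#'   [detect_objective_progression()]); patients without an event are
#'   absent.
#' @export
detect_progression_cohort <- function(registry,
                                      criteria = progression_criteria()) {
  evs <- lapply(.split_registry(registry), detect_objective_progression,
                criteria = criteria)
  evs <- evs[!vapply(evs, is.null, TRUE)]
  if (length(evs) == 0L) {
    return(data.frame(patient_id = character(),
                      event_date = as.Date(character()),
                      confirm_date = as.Date(character()),
                      reference_edss = numeric(), event_edss = numeric(),
                      leading_fs = character()))
  }
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Clinician-labelled progression within a fixed horizon
#'
#' @param record Patient record with `baseline_date` and (optionally)
#'   `spms_transition_date`.
#' @param horizon_years Prediction horizon; 5 years = 1826 days.
#' @return 1 if the clinician-assigned SPMS transition falls in
#'   `(baseline, baseline + horizon]`, else 0. A transition dated on or
#'   before baseline is an error (the patient was not relapsing-remitting
#'   at baseline).
#' @export
label_clinical_progression <- function(record, horizon_years = 5) {
  d <- record$spms_transition_date
  if (is.null(d) || length(d) == 0L || is.na(d)) return(0L)
  if (d <= record$baseline_date) {
    stop("patient ", record$patient_id,
         ": SPMS transition on or before baseline", call. = FALSE)
  }
  horizon_days <- round(horizon_years * 365.25)
  as.integer(d <= record$baseline_date + horizon_days)
}

#' Is the patient relapsing-remitting at baseline by objective criteria?
#'
#' Applies the objective detector to the history up to and including the
#' baseline visit; the patient qualifies when no confirmed event is dated
#' on or before baseline (inclusion criterion K).
#'
#' @inheritParams detect_objective_progression
#' @return logical.
#' @export
objective_rrms_at_baseline <- function(record,
                                       criteria = progression_criteria()) {
  pre <- record
  pre$visits <- record$visits[record$visits$date <= record$baseline_date, ,
                              drop = FALSE]
  # scan the full pre-baseline history, not just from baseline onwards
  pre$baseline_date <- if (nrow(pre$visits)) min(pre$visits$date) else
    record$baseline_date
  ev <- detect_objective_progression(pre, criteria)
  is.null(ev) || ev$event_date > record$baseline_date
}
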