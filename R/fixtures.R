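#' @title Hand-built fixture trajectories
#' @description A documented catalogue of small patient records, each
#'   instantiating one clause of the objective progression definition or
#'   one ELIE treatment-history category, together with the hand-derived
#'   expected detector/classifier output. Used throughout the test suite.
#' @name fixtures
NULL

## build a minimal patient record; months are 30-day months from baseline
.fixture_record <- function(id, months, edss, pyramidal,
                            relapse_months = numeric(),
                            treatments = NULL,
                            baseline = as.Date("2015-01-01")) {
  dates <- baseline + months * 30
  nv <- length(dates)
  visits <- data.frame(
    patient_id = id, date = dates, edss = edss,
    fs_pyramidal = as.integer(pyramidal),
    fs_cerebellar = 0L, fs_brainstem = 0L, fs_sensory = 0L,
    fs_bowel_bladder = 0L, fs_visual = 0L, fs_cerebral = 0L)
  relapses <- data.frame(patient_id = rep(id, length(relapse_months)),
                         date = baseline + relapse_months * 30)
  if (is.null(treatments)) {
    treatments <- data.frame(patient_id = character(),
                             dmt_name = character(),
                             start_date = as.Date(character()),
                             stop_date = as.Date(character()))
  } else {
    treatments <- data.frame(
      patient_id = id, dmt_name = treatments$dmt_name,
      start_date = baseline + treatments$start_month * 30,
      stop_date = baseline + ifelse(is.na(treatments$stop_month), NA,
                                    treatments$stop_month * 30))
    treatments$stop_date <- as.Date(treatments$stop_date,
                                    origin = "1970-01-01")
  }
  list(patient_id = id, sex = "female",
       birth_date = baseline - round(40 * 365.25),
       onset_date = baseline - round(5 * 365.25),
       baseline_date = baseline, course_at_baseline = "RRMS",
       spms_transition_date = as.Date(NA),
       other_neuro_disorder_flag = FALSE, prior_use_flag = FALSE,
       visits = visits, relapses = relapses, treatments = treatments)
}

#' Fixture case identifiers
#' @return Character vector of all catalogue case ids.
#' @export
fixture_catalogue <- function() {
  c("clean_delta10", "clean_high_base", "unconfirmed_spike",
    "relapse_block", "pyramidal_block", "edss_floor_block",
    "never_treated", "stable_low", "stable_intermediate", "stable_high",
    "switch_escalation", "switch_deescalation", "switch_bidirectional",
    "switch_initiation", "switch_discontinuation", "switch_complex")
}

#' Build a catalogue fixture and its expected outputs
#'
#' Detector cases (60-month records, 6-monthly visits unless noted):
#' `clean_delta10` a clean 1.0-step event from EDSS 3.5 confirmed 6 months
#' later; `clean_high_base` a 0.5-step event from EDSS 6.0;
#' `unconfirmed_spike` a worsening re-measured only 60 days later;
#' `relapse_block` the clean event contaminated by a relapse one month
#' before the candidate; `pyramidal_block` the worsening without pyramidal
#' involvement; `edss_floor_block` a 1.0 increase that never reaches
#' EDSS 4. The remaining cases hold EDSS flat and instantiate each ELIE
#' treatment-history category over the 5-year window.
#'
#' @param case_id One of [fixture_catalogue()].
#' @return list with `record` (a patient record) and `expected`: `n_events`
#'   (0 or 1), `event_month` (30-day months from baseline or `NA`) and
#'   `elie_category`.
#' @export
make_fixture <- function(case_id) {
  flat <- function(id, treatments, category) {
    rec <- .fixture_record(id, months = seq(0, 60, by = 6),
                           edss = rep(2, 11), pyramidal = rep(1, 11),
                           treatments = treatments)
    list(record = rec,
         expected = list(n_events = 0L, event_month = NA_real_,
                         elie_category = category))
  }
  tr <- function(name, start, stop) {
    data.frame(dmt_name = name, start_month = start, stop_month = stop)
  }
  switch(case_id,
    clean_delta10 = list(
      record = .fixture_record("fx01", c(0, 6, 12, 18), c(3.5, 3.5, 4.5, 4.5),
                               c(1, 1, 3, 3)),
      expected = list(n_events = 1L, event_month = 12,
                      elie_category = "never_treated")),
    clean_high_base = list(
      record = .fixture_record("fx02", c(0, 8, 12), c(6.0, 6.5, 6.5),
                               c(3, 3, 3)),
      expected = list(n_events = 1L, event_month = 8,
                      elie_category = "never_treated")),
    unconfirmed_spike = list(
      record = .fixture_record("fx03", c(0, 12, 14), c(3.5, 4.5, 3.5),
                               c(1, 3, 1)),
      expected = list(n_events = 0L, event_month = NA_real_,
                      elie_category = "never_treated")),
    relapse_block = list(
      record = .fixture_record("fx04", c(0, 6, 12, 18), c(3.5, 3.5, 4.5, 4.5),
                               c(1, 1, 3, 3), relapse_months = 11),
      expected = list(n_events = 0L, event_month = NA_real_,
                      elie_category = "never_treated")),
    pyramidal_block = list(
      record = .fixture_record("fx05", c(0, 6, 12, 18), c(3.5, 3.5, 4.5, 4.5),
                               c(1, 1, 1, 1)),
      expected = list(n_events = 0L, event_month = NA_real_,
                      elie_category = "never_treated")),
    edss_floor_block = list(
      record = .fixture_record("fx06", c(0, 6, 12, 18), c(2.0, 2.0, 3.0, 3.0),
                               c(1, 1, 3, 3)),
      expected = list(n_events = 0L, event_month = NA_real_,
                      elie_category = "never_treated")),
    never_treated = flat("fx07", NULL, "never_treated"),
    stable_low = flat("fx08", tr("dimethyl fumarate", -6, NA), "stable_low"),
    stable_intermediate = flat("fx09", tr("fingolimod", -6, NA),
                               "stable_intermediate"),
    stable_high = flat("fx10", tr("natalizumab", -6, NA), "stable_high"),
    switch_escalation = flat(
      "fx11", rbind(tr("interferon-beta", -6, 24), tr("natalizumab", 24, NA)),
      "switcher_escalation"),
    switch_deescalation = flat(
      "fx12", rbind(tr("natalizumab", -6, 24),
                    tr("glatiramer acetate", 24, NA)),
      "switcher_deescalation"),
    switch_bidirectional = flat(
      "fx13", rbind(tr("natalizumab", -6, 18), tr("teriflunomide", 18, 36),
                    tr("ocrelizumab", 36, NA)),
      "switcher_bidirectional"),
    switch_initiation = flat("fx14", tr("teriflunomide", 24, NA),
                             "switcher_initiation"),
    switch_discontinuation = flat("fx15", tr("interferon-beta", -6, 30),
                                  "switcher_discontinuation"),
    switch_complex = flat(
      "fx16", rbind(tr("interferon-beta", 6, 18),
                    tr("glatiramer acetate", 30, 42)),
      "switcher_complex"),
    stop("unknown fixture case_id: ", case_id, call. = FALSE)
  )
}
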