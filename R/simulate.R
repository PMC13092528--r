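#' @title Synthetic MS registry generator
#' @description Generates longitudinal registries with known ground truth:
#'   roughly 6-monthly visits over 3-7 years, EDSS as a bounded half-point
#'   random walk with upward drift after a latent progression date,
#'   functional-system scores co-generated with EDSS, Poisson relapses
#'   with age decay, dated DMT episodes drawn with indication bias from
#'   the named drug list, and clinician SPMS labels assigned with a
#'   recognition delay after the latent progression. The defaults emulate
#'   the cohort shape of a large adult RRMS registry (mean age 37.1 (SD
#'   10.8), disease duration 5.8 (7.3) years, median EDSS 2.0 (IQR 1-3),
#'   72.6% female, ~10% clinician-labelled progression over 5 years).
#' @name synthetic_registry
NULL

.dmt_by_class <- function() {
  list(low = c("interferon-beta", "glatiramer acetate", "teriflunomide",
               "dimethyl fumarate"),
       intermediate = c("fingolimod", "cladribine", "daclizumab",
                        "laquinimod", "siponimod"),
       high = c("natalizumab", "ocrelizumab", "rituximab", "alemtuzumab",
                "mitoxantrone", "ofatumumab"))
}

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed; the whole registry is deterministic in it.
#' @param visit_interval_days,visit_jitter_days Mean and SD of the
#'   inter-visit gap (truncated below at 100 days so consecutive
#'   evaluations stay more than 3 months apart).
#' @param followup_years Length-2 bounds of the uniform follow-up
#'   distribution; the lower bound dips below 3 so the follow-up
#'   inclusion criterion is exercised.
#' @param baseline_age_mean,baseline_age_sd Normal baseline age,
#'   truncated to 16-75 (a small tail below 18 exercises the age
#'   criterion).
#' @param duration_mean,duration_sd Gamma-distributed disease duration at
#'   baseline (years).
#' @param female_prop Proportion female.
#' @param edss_mean,edss_sd Baseline EDSS before rounding to the
#'   half-point grid (folded at 0, capped at 6.5).
#' @param relapse_rate Relapses per year at age 37; decays by
#'   `relapse_age_decay` per year of age.
#' @param relapse_age_decay See above.
#' @param hazard Named log-hazard coefficients of the latent progression
#'   process: `intercept` (log events/year for the reference patient) and
#'   slopes on standardized age, disease duration and EDSS.
#' @param efficacy_multipliers Hazard ratios applied while on a DMT class;
#'   must satisfy high <= intermediate <= low <= 1 (none).
#' @param treat_prob Probability of being on DMT at baseline.
#' @param indication_bias Strength of the dependence of high-efficacy
#'   assignment (and treatment at all) on baseline EDSS, age, duration
#'   and sex; 0 means treatment is assigned independently of covariates.
#' @param switch_rates Per-year rates of `escalation`, `deescalation`,
#'   `initiation`, `discontinuation`.
#' @param label_sensitivity Probability a latent progression is ever
#'   clinician-labelled as SPMS.
#' @param label_delay_mean_days Mean of the exponential recognition delay
#'   between latent progression and the clinician SPMS date (6 months).
#' @param missing_fs_rate,missing_edss_rate MCAR missingness rates for FS
#'   scores and (non-baseline) EDSS.
#' @param frac_non_rrms,frac_other_disorder,frac_prior_use Small
#'   contamination fractions exercising inclusion criteria A, B, G.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000, seed = 1,
                       visit_interval_days = 183, visit_jitter_days = 30,
                       followup_years = c(2.5, 7),
                       baseline_age_mean = 37.1, baseline_age_sd = 10.8,
                       duration_mean = 5.8, duration_sd = 7.3,
                       female_prop = 0.726,
                       edss_mean = 2.1, edss_sd = 1.5,
                       relapse_rate = 0.35, relapse_age_decay = 0.02,
                       hazard = c(intercept = -3.05, age = 0.45,
                                  duration = 0.25, edss = 0.55),
                       efficacy_multipliers = c(high = 0.45,
                                                intermediate = 0.65,
                                                low = 0.80, none = 1),
                       treat_prob = 0.65, indication_bias = 0.6,
                       switch_rates = c(escalation = 0.04,
                                        deescalation = 0.02,
                                        initiation = 0.06,
                                        discontinuation = 0.04),
                       label_sensitivity = 0.50,
                       label_delay_mean_days = 183,
                       missing_fs_rate = 0.02, missing_edss_rate = 0.01,
                       frac_non_rrms = 0.02, frac_other_disorder = 0.02,
                       frac_prior_use = 0.02) {
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (any(switch_rates < 0) || relapse_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  m <- efficacy_multipliers
  if (any(m <= 0) || any(m > 1) ||
      !(m[["high"]] <= m[["intermediate"]] &&
        m[["intermediate"]] <= m[["low"]] && m[["low"]] <= m[["none"]])) {
    stop("efficacy multipliers must lie in (0, 1] and be ordered ",
         "high <= intermediate <= low <= none", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.round_grid <- function(x) pmin(pmax(round(x * 2) / 2, 0), 10)

## assign baseline treatment class with indication bias: sicker (higher
## EDSS), longer-duration and male patients lean toward (high-efficacy)
## treatment; younger age also favors high-efficacy escalation.
.assign_baseline_class <- function(edss, age, dur, male, cfg) {
  b <- cfg$indication_bias
  p_treat <- stats::plogis(stats::qlogis(cfg$treat_prob) +
                             b * (0.5 * (edss - 2) + 0.3 * male -
                                    0.03 * (dur - 5.8)))
  if (stats::runif(1) > p_treat) return("none")
  lp_high <- -2.2 + b * (0.7 * (edss - 2) - 0.07 * (age - 37.1) +
                           0.7 * male + 0.06 * (dur - 5.8))
  p_high <- stats::plogis(lp_high)
  p_int <- 0.12
  u <- stats::runif(1)
  if (u < p_high) "high" else if (u < p_high + p_int) "intermediate" else
    "low"
}

#' Generate a synthetic registry with ground truth
#'
#' @param config A [sim_config()].
#' @return list with `registry` (an `ms_registry`) and `truth` (list with
#'   per-patient `patients`: latent progression date, clinician label
#'   status, baseline treatment class; and per-visit `visits`: the true
#'   log-hazard linear predictor at each visit).
#' @export
generate_registry <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  anchor <- as.Date("2010-01-01")
  drugs <- .dmt_by_class()
  rank <- c(low = 1L, intermediate = 2L, high = 3L)

  pats <- vector("list", cfg$n_patients)
  vis_l <- rel_l <- trt_l <- truth_l <- tlp_l <- vector("list",
                                                        cfg$n_patients)

  for (i in seq_len(cfg$n_patients)) {
    id <- sprintf("P%05d", i)
    male <- stats::runif(1) > cfg$female_prop
    age0 <- min(max(stats::rnorm(1, cfg$baseline_age_mean,
                                 cfg$baseline_age_sd), 16), 75)
    shp <- (cfg$duration_mean / cfg$duration_sd)^2
    dur0 <- max(stats::rgamma(1, shape = shp,
                              rate = shp / cfg$duration_mean), 0.1)
    dur0 <- min(dur0, age0 - 12)   # onset no earlier than age 12
    baseline <- anchor + round(stats::runif(1, -730, 730))
    birth <- baseline - round(age0 * 365.25)
    onset <- baseline - round(dur0 * 365.25)
    edss0 <- .round_grid(min(abs(stats::rnorm(1, cfg$edss_mean,
                                              cfg$edss_sd)), 6.5))

    fup_days <- round(stats::runif(1, cfg$followup_years[1],
                                   cfg$followup_years[2]) * 365.25)
    gaps <- pmax(round(stats::rnorm(ceiling(fup_days / 100) + 2,
                                    cfg$visit_interval_days,
                                    cfg$visit_jitter_days)), 100)
    offs <- c(0, cumsum(gaps))
    offs <- offs[offs <= fup_days]
    dates <- baseline + offs
    nv <- length(dates)

    ## --- treatment episode path, evolving at visits -------------------
    cls <- .assign_baseline_class(edss0, age0, dur0, male, cfg)
    cls_path <- character(nv); cls_path[1] <- cls
    if (nv > 1) for (k in 2:nv) {
      dt <- as.numeric(dates[k] - dates[k - 1]) / 365.25
      cur <- cls_path[k - 1]
      u <- stats::runif(1)
      if (cur == "none") {
        cls_path[k] <- if (u < 1 - exp(-cfg$switch_rates[["initiation"]] *
                                         dt)) {
          sample(c("low", "intermediate", "high"), 1,
                 prob = c(0.6, 0.15, 0.25))
        } else "none"
      } else {
        p_stop <- 1 - exp(-cfg$switch_rates[["discontinuation"]] * dt)
        p_up <- if (cur != "high")
          1 - exp(-cfg$switch_rates[["escalation"]] * dt) else 0
        p_down <- if (cur != "low")
          1 - exp(-cfg$switch_rates[["deescalation"]] * dt) else 0
        cls_path[k] <- if (u < p_stop) "none"
        else if (u < p_stop + p_up)
          names(rank)[min(rank[[cur]] + 1L, 3L)]
        else if (u < p_stop + p_up + p_down)
          names(rank)[max(rank[[cur]] - 1L, 1L)]
        else cur
      }
    }
    ## collapse the class path into dated episodes
    ep <- list()
    run_start <- 1L
    for (k in seq_len(nv)) {
      end_of_run <- k == nv || cls_path[k + 1L] != cls_path[k]
      if (end_of_run) {
        if (cls_path[run_start] != "none") {
          stop_d <- if (k == nv) as.Date(NA) else dates[k + 1L]
          ep[[length(ep) + 1L]] <- data.frame(
            patient_id = id,
            dmt_name = sample(drugs[[cls_path[run_start]]], 1),
            start_date = if (run_start == 1L) {
              baseline - round(stats::runif(1, 0, 365))
            } else dates[run_start],
            stop_date = stop_d)
        }
        run_start <- k + 1L
      }
    }
    trt_l[[i]] <- if (length(ep)) do.call(rbind, ep) else NULL

    ## --- latent progression hazard per inter-visit interval -----------
    hz <- cfg$hazard
    edss <- numeric(nv); edss[1] <- edss0
    lp <- numeric(nv)
    latent <- as.Date(NA)
    for (k in seq_len(nv)) {
      age_k <- age0 + as.numeric(dates[k] - baseline) / 365.25
      dur_k <- dur0 + as.numeric(dates[k] - baseline) / 365.25
      lp[k] <- hz[["intercept"]] +
        hz[["age"]] * (age_k - cfg$baseline_age_mean) / cfg$baseline_age_sd +
        hz[["duration"]] * (dur_k - cfg$duration_mean) / cfg$duration_sd +
        hz[["edss"]] * (edss[k] - 2) / 1.5
      if (k < nv && is.na(latent)) {
        dt <- as.numeric(dates[k + 1] - dates[k]) / 365.25
        rate <- exp(lp[k]) *
          cfg$efficacy_multipliers[[cls_path[k]]]
        if (stats::runif(1) < 1 - exp(-rate * dt)) {
          latent <- dates[k] + round(stats::runif(1) *
                                       as.numeric(dates[k + 1] - dates[k]))
        }
      }
      ## EDSS walk for the next visit: drift upward after progression
      if (k < nv) {
        progressed <- !is.na(latent) && dates[k + 1] > latent
        step <- if (progressed) {
          sample(c(0, 0.5, 1), 1, prob = c(0.20, 0.50, 0.30))
        } else {
          sample(c(-0.5, 0, 0.5), 1, prob = c(0.15, 0.70, 0.15))
        }
        edss[k + 1] <- min(max(edss[k] + step, 0), 9.5)
      }
    }

    ## --- functional systems, co-generated with EDSS -------------------
    progressed_at <- if (is.na(latent)) rep(FALSE, nv) else dates > latent
    pyr <- round(edss / 2 + 0.5 * progressed_at + stats::rnorm(nv, 0, 0.5))
    pyr <- pmin(pmax(pyr, 0), 6)
    pyr[progressed_at & edss >= 4 & pyr < 2] <- 2
    fs <- data.frame(
      fs_pyramidal = as.integer(pyr),
      fs_cerebellar = as.integer(pmin(pmax(round(edss / 3 +
        stats::rnorm(nv, 0, 0.6)), 0), 6)),
      fs_brainstem = as.integer(pmin(pmax(round(edss / 4 +
        stats::rnorm(nv, 0, 0.6)), 0), 6)),
      fs_sensory = as.integer(pmin(pmax(round(edss / 3 +
        stats::rnorm(nv, 0, 0.7)), 0), 6)),
      fs_bowel_bladder = as.integer(pmin(pmax(round(edss / 5 +
        stats::rnorm(nv, 0, 0.5)), 0), 6)),
      fs_visual = as.integer(pmin(pmax(round(edss / 5 +
        stats::rnorm(nv, 0, 0.6)), 0), 6)),
      fs_cerebral = as.integer(pmin(pmax(round(edss / 5 +
        stats::rnorm(nv, 0, 0.5)), 0), 6)))
    for (col in names(fs)) {
      miss <- stats::runif(nv) < cfg$missing_fs_rate
      fs[[col]][miss] <- NA
    }
    edss_rec <- edss
    if (nv > 1) {
      miss <- c(FALSE, stats::runif(nv - 1) < cfg$missing_edss_rate)
      edss_rec[miss] <- NA
    }
    vis_l[[i]] <- data.frame(patient_id = id, date = dates, edss = edss_rec,
                             fs)

    ## --- relapses ------------------------------------------------------
    rrate <- cfg$relapse_rate * exp(-cfg$relapse_age_decay * (age0 - 37))
    nrel <- stats::rpois(1, rrate * fup_days / 365.25)
    if (nrel > 0) {
      rel_l[[i]] <- data.frame(
        patient_id = id,
        date = baseline + sort(round(stats::runif(nrel, 1, fup_days))))
    }

    ## --- clinician SPMS label with recognition delay/noise -------------
    spms <- as.Date(NA)
    if (!is.na(latent) && stats::runif(1) < cfg$label_sensitivity) {
      cand <- latent + round(stats::rexp(1, 1 / cfg$label_delay_mean_days))
      if (cand <= dates[nv]) spms <- cand
    }

    pats[[i]] <- data.frame(
      patient_id = id,
      sex = if (male) "male" else "female",
      birth_date = birth, onset_date = onset, baseline_date = baseline,
      course_at_baseline = if (stats::runif(1) < cfg$frac_non_rrms) {
        sample(c("SPMS", "PPMS", "other"), 1)
      } else "RRMS",
      spms_transition_date = spms,
      other_neuro_disorder_flag =
        stats::runif(1) < cfg$frac_other_disorder,
      prior_use_flag = stats::runif(1) < cfg$frac_prior_use)
    truth_l[[i]] <- data.frame(patient_id = id, latent_date = latent,
                               labelled = !is.na(spms),
                               baseline_class = cls)
    tlp_l[[i]] <- data.frame(patient_id = id, date = dates, lp = lp)
  }

  empty_rel <- data.frame(patient_id = character(),
                          date = as.Date(character()))
  empty_trt <- data.frame(patient_id = character(), dmt_name = character(),
                          start_date = as.Date(character()),
                          stop_date = as.Date(character()))
  reg <- structure(list(
    patients = do.call(rbind, pats),
    visits = do.call(rbind, vis_l),
    relapses = if (any(!vapply(rel_l, is.null, TRUE)))
      do.call(rbind, rel_l[!vapply(rel_l, is.null, TRUE)]) else empty_rel,
    treatments = if (any(!vapply(trt_l, is.null, TRUE)))
      do.call(rbind, trt_l[!vapply(trt_l, is.null, TRUE)]) else empty_trt
  ), class = "ms_registry")
  rownames(reg$patients) <- rownames(reg$visits) <- NULL
  rownames(reg$relapses) <- rownames(reg$treatments) <- NULL
  list(registry = reg,
       truth = list(patients = do.call(rbind, truth_l),
                    visits = do.call(rbind, tlp_l)))
}
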