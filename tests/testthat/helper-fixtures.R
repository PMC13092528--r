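# Helpers shared across the suite: tiny in-code registries, random episode
# sets with a brute-force daily exposure oracle, and one modest shared
# synthetic registry reused by several files.

empty_relapses <- function() {
  data.frame(patient_id = character(), date = as.Date(character()))
}

empty_treatments <- function() {
  data.frame(patient_id = character(), dmt_name = character(),
             start_date = as.Date(character()),
             stop_date = as.Date(character()))
}

# a minimal hand-built registry: one row per patient definition, 6-monthly visits
tiny_registry <- function(specs) {
  pats <- vis <- list()
  for (s in specs) {
    b <- as.Date(s$baseline)
    if (!is.null(s$followup_days)) {
      dates <- c(b, b + s$followup_days)
      n <- 2L
    } else {
      n <- s$n_visits
      dates <- b + round(seq(0, by = 183, length.out = n))
    }
    pats[[s$id]] <- data.frame(
      patient_id = s$id, sex = if (is.null(s$sex)) "female" else s$sex,
      birth_date = b - round((if (is.null(s$age)) 40 else s$age) * 365.25),
      onset_date = b - round((if (is.null(s$dur)) 5 else s$dur) * 365.25),
      baseline_date = b,
      course_at_baseline = if (is.null(s$course)) "RRMS" else s$course,
      spms_transition_date = if (is.null(s$spms)) as.Date(NA) else
        as.Date(s$spms),
      other_neuro_disorder_flag = isTRUE(s$other_disorder),
      prior_use_flag = isTRUE(s$prior_use))
    vis[[s$id]] <- data.frame(
      patient_id = s$id, date = dates,
      edss = if (is.null(s$edss)) rep(2, n) else s$edss,
      fs_pyramidal = 1L, fs_cerebellar = 0L, fs_brainstem = 0L,
      fs_sensory = 0L, fs_bowel_bladder = 0L, fs_visual = 0L,
      fs_cerebral = 0L)
  }
  structure(list(patients = do.call(rbind, pats),
                 visits = do.call(rbind, vis),
                 relapses = empty_relapses(),
                 treatments = empty_treatments()),
            class = "ms_registry")
}

# random (possibly overlapping) episode sets over a fixed window
rand_episodes <- function(n, window_start, window_end) {
  if (n == 0L) return(empty_treatments())
  drugs <- names(dmt_efficacy_map())[1:15]
  span <- as.numeric(window_end - window_start)
  start <- window_start + round(stats::runif(n, -60, span))
  len <- round(stats::rexp(n, 1 / 300)) + 1
  stop <- start + len
  stop[stats::runif(n) < 0.15] <- NA   # some ongoing
  data.frame(patient_id = "X", dmt_name = sample(drugs, n, replace = TRUE),
             start_date = start, stop_date = as.Date(stop,
                                                     origin = "1970-01-01"))
}

# brute-force day-by-day exposure oracle on normalized episodes
daily_fraction_oracle <- function(episodes, window_start, window_end,
                                  map = dmt_efficacy_map()) {
  days <- seq(window_start, window_end - 1, by = "day")
  cls <- rep("none", length(days))
  if (nrow(episodes)) {
    ecls <- classify_efficacy(episodes$dmt_name, map)
    for (k in seq_len(nrow(episodes))) {
      stop <- if (is.na(episodes$stop_date[k])) window_end else
        episodes$stop_date[k]
      hit <- days >= episodes$start_date[k] & days < stop
      cls[hit] <- ecls[k]
    }
  }
  out <- vapply(c("low", "intermediate", "high", "none"),
                function(cc) mean(cls == cc), 0)
  out
}

# one shared synthetic registry, generated once per test run
shared_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_registry(sim_config(n_patients = 800, seed = 99))
    }
    val
  }
})
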