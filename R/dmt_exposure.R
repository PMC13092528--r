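#' DMT efficacy classification scheme
#'
#' Returns the default map from canonical (lower-case) disease-modifying
#' therapy names to efficacy classes. The three classes follow the
#' established grouping used in MS registry research:
#' \itemize{
#'   \item high: rituximab, ocrelizumab, mitoxantrone, alemtuzumab,
#'     natalizumab, ofatumumab
#'   \item intermediate: fingolimod, siponimod, daclizumab, laquinimod,
#'     cladribine
#'   \item low: interferon-beta, glatiramer acetate, teriflunomide,
#'     dimethyl fumarate
#' }
#'
#' @return Named character vector mapping drug name to one of
#'   `"low"`, `"intermediate"`, `"high"`.
#' @export
dmt_efficacy_map <- function() {
  c(
    "rituximab" = "high", "ocrelizumab" = "high", "mitoxantrone" = "high",
    "alemtuzumab" = "high", "natalizumab" = "high", "ofatumumab" = "high",
    "fingolimod" = "intermediate", "siponimod" = "intermediate",
    "daclizumab" = "intermediate", "laquinimod" = "intermediate",
    "cladribine" = "intermediate",
    "interferon-beta" = "low", "glatiramer acetate" = "low",
    "teriflunomide" = "low", "dimethyl fumarate" = "low",
    # registry spelling variants mapped onto the canonical entries
    "interferon beta" = "low", "interferon" = "low",
    "glatiramer" = "low"
  )
}

#' Efficacy class ordering used for escalation/de-escalation logic
#' @keywords internal
.efficacy_rank <- c(low = 1L, intermediate = 2L, high = 3L)

#' Classify a DMT name into an efficacy class
#'
#' @param dmt_name Character vector of drug names (case-insensitive;
#'   surrounding whitespace ignored).
#' @param map Named character vector as returned by [dmt_efficacy_map()].
#' @return Character vector of classes (`"low"`, `"intermediate"`, `"high"`).
#'   Unknown drugs are an error, never silently classified.
#' @export
classify_efficacy <- function(dmt_name, map = dmt_efficacy_map()) {
  key <- trimws(tolower(as.character(dmt_name)))
  cls <- unname(map[key])
  if (anyNA(cls)) {
    bad <- unique(key[is.na(cls)])
    stop("unknown DMT name(s): ", paste(bad, collapse = ", "),
         "; extend the efficacy map to classify them", call. = FALSE)
  }
  cls
}

#' Normalize treatment episodes to non-overlapping intervals
#'
#' Episodes are half-open `[start, stop)`; an open (ongoing) episode has
#' `stop_date = NA`. Overlaps within a patient are resolved by truncating
#' the earlier-starting episode at the later episode's start, so exposure
#' time is never double counted at a switch.
#'
#' @param episodes data.frame with columns `dmt_name`, `start_date`,
#'   `stop_date` (Date; `NA` stop = ongoing) for a single patient.
#' @return The same data.frame, sorted by start, with overlaps removed and
#'   zero-length episodes dropped.
#' @export
normalize_episodes <- function(episodes) {
  if (nrow(episodes) == 0L) return(episodes)
  stopifnot(inherits(episodes$start_date, "Date"))
  ep <- episodes[order(episodes$start_date, episodes$stop_date), , drop = FALSE]
  n <- nrow(ep)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      nxt <- ep$start_date[i + 1L]
      if (is.na(ep$stop_date[i]) || ep$stop_date[i] > nxt) {
        ep$stop_date[i] <- nxt
      }
    }
  }
  keep <- is.na(ep$stop_date) | ep$stop_date > ep$start_date
  ep[keep, , drop = FALSE]
}

## clip normalized episodes to a window; returns class, start, stop (Dates),
## all half-open [start, stop)
.clip_episodes <- function(episodes, window_start, window_end,
                           map = dmt_efficacy_map()) {
  if (nrow(episodes) == 0L) {
    return(data.frame(class = character(), start = as.Date(character()),
                      stop = as.Date(character())))
  }
  cls <- classify_efficacy(episodes$dmt_name, map)
  stop <- episodes$stop_date
  stop[is.na(stop)] <- window_end
  s <- pmax(episodes$start_date, window_start)
  e <- pmin(stop, window_end)
  keep <- e > s
  data.frame(class = cls[keep], start = s[keep], stop = e[keep])
}

#' Fraction of an observation window spent on each DMT efficacy class
#'
#' Intersects (normalized, non-overlapping) treatment episodes with the
#' half-open window `[window_start, window_end)` and returns the fraction
#' of window days spent in each efficacy class; `none` is the untreated
#' remainder. Fractions sum to 1.
#'
#' @param episodes data.frame of one patient's episodes (`dmt_name`,
#'   `start_date`, `stop_date`), already normalized.
#' @param window_start,window_end Dates; `window_start < window_end`.
#' @param map Efficacy map, see [dmt_efficacy_map()].
#' @return Named numeric vector with entries `low`, `intermediate`, `high`,
#'   `none`.
#' @export
exposure_fractions <- function(episodes, window_start, window_end,
                               map = dmt_efficacy_map()) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  total <- as.numeric(window_end - window_start)
  if (!is.finite(total) || total <= 0) {
    stop("empty or invalid observation window", call. = FALSE)
  }
  seg <- .clip_episodes(episodes, window_start, window_end, map)
  days <- c(low = 0, intermediate = 0, high = 0)
  if (nrow(seg)) {
    agg <- tapply(as.numeric(seg$stop - seg$start), seg$class, sum)
    days[names(agg)] <- agg
  }
  fr <- days / total
  c(fr, none = 1 - sum(fr))
}

#' Majority DMT class and switch flag over an observation window (DAAE-M)
#'
#' Majority class is the efficacy class covering strictly more than 50% of
#' the window (`none` if untreated time exceeds 50%, `no_majority` if no
#' class does). The switch flag is set when some other DMT efficacy class
#' covers strictly more than 25% of the whole window.
#'
#' @inheritParams exposure_fractions
#' @return list with `majority` (one of `"low"`, `"intermediate"`,
#'   `"high"`, `"none"`, `"no_majority"`), `switch_flag` (logical) and
#'   `fractions`.
#' @export
daae_exposure <- function(episodes, window_start, window_end,
                          map = dmt_efficacy_map()) {
  fr <- exposure_fractions(episodes, window_start, window_end, map)
  classes <- c("low", "intermediate", "high")
  majority <- if (any(fr[classes] > 0.5)) {
    classes[which(fr[classes] > 0.5)]
  } else if (fr[["none"]] > 0.5) "none" else "no_majority"
  other <- setdiff(classes, majority)
  switch_flag <- any(fr[other] > 0.25)
  list(majority = majority, switch_flag = switch_flag, fractions = fr)
}

#' DMT efficacy class in force at a given date
#'
#' @param episodes Normalized episode data.frame for one patient.
#' @param date Date of interest (typically baseline). Episodes are
#'   half-open, so an episode stopping on `date` does not count.
#' @param map Efficacy map.
#' @return `"low"`, `"intermediate"`, `"high"` or `"none"`.
#' @export
baseline_dmt <- function(episodes, date, map = dmt_efficacy_map()) {
  date <- as.Date(date)
  if (nrow(episodes) == 0L) return("none")
  stop <- episodes$stop_date
  covered <- episodes$start_date <= date & (is.na(stop) | stop > date)
  if (!any(covered)) return("none")
  classify_efficacy(episodes$dmt_name[covered][1L], map)
}

## Build the chronological sequence of exposure states (efficacy class or
## "none") over a window. Gaps <= gap_tolerance_days between episodes of the
## same class are bridged; longer untreated stretches (including leading and
## trailing ones) become explicit "none" states.
.exposure_states <- function(episodes, window_start, window_end,
                             map = dmt_efficacy_map(),
                             gap_tolerance_days = 0) {
  seg <- .clip_episodes(episodes, window_start, window_end, map)
  if (nrow(seg) == 0L) {
    return(data.frame(state = "none", start = window_start, stop = window_end))
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  states <- list()
  push <- function(state, start, stop) {
    states[[length(states) + 1L]] <<- data.frame(
      state = state, start = start, stop = stop)
  }
  if (as.numeric(seg$start[1L] - window_start) > gap_tolerance_days) {
    push("none", window_start, seg$start[1L])
  }
  cur <- seg[1L, ]
  if (nrow(seg) > 1L) {
    for (i in 2L:nrow(seg)) {
      gap <- as.numeric(seg$start[i] - cur$stop)
      if (seg$class[i] == cur$class && gap <= gap_tolerance_days) {
        cur$stop <- seg$stop[i]       # bridge same-class gap
      } else if (gap > gap_tolerance_days) {
        push(cur$class, cur$start, cur$stop)
        push("none", cur$stop, seg$start[i])
        cur <- seg[i, ]
      } else {                        # direct class switch
        push(cur$class, cur$start, cur$stop)
        cur <- seg[i, ]
      }
    }
  }
  push(cur$class, cur$start, cur$stop)
  if (as.numeric(window_end - cur$stop) > gap_tolerance_days) {
    push("none", cur$stop, window_end)
  }
  do.call(rbind, states)
}

#' Chronological efficacy-class transitions within a window
#'
#' @inheritParams exposure_fractions
#' @param gap_tolerance_days Untreated gaps of at most this many days
#'   between episodes of the same class are not transitions (default 0).
#' @return data.frame with columns `from`, `to` (class or `"none"`) and
#'   `date` (start of the new state), in chronological order.
#' @export
class_transitions <- function(episodes, window_start, window_end,
                              map = dmt_efficacy_map(),
                              gap_tolerance_days = 0) {
  st <- .exposure_states(episodes, as.Date(window_start), as.Date(window_end),
                         map, gap_tolerance_days)
  n <- nrow(st)
  if (n < 2L) {
    return(data.frame(from = character(), to = character(),
                      date = as.Date(character())))
  }
  data.frame(from = st$state[-n], to = st$state[-1L], date = st$start[-1L])
}

#' ELIE treatment-history category for a landmark window
#'
#' Assigns exactly one of the ten mutually exclusive treatment-history
#' categories to the window from baseline to the landmark date, applying a
#' fixed precedence: never treated; stable (single uninterrupted efficacy
#' class covering the window with at least 50% of time on it and no
#' transitions of any kind); bidirectional switching; escalation;
#' de-escalation; initiation; discontinuation; complex fallback.
#'
#' The separate switcher flag is set when at least 50% of the window is
#' spent on treatment and at least 25% of *treated* time falls on a
#' non-dominant efficacy class (a different denominator from the DAAE-M
#' switch rule, which uses the whole window).
#'
#' @inheritParams class_transitions
#' @return list with `category`, `switch_flag`, `fractions`,
#'   `treated_fraction` and `transitions`.
#' @export
elie_history_category <- function(episodes, window_start, window_end,
                                  map = dmt_efficacy_map(),
                                  gap_tolerance_days = 0) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  fr <- exposure_fractions(episodes, window_start, window_end, map)
  classes <- c("low", "intermediate", "high")
  treated <- 1 - fr[["none"]]
  tr <- class_transitions(episodes, window_start, window_end, map,
                          gap_tolerance_days)

  # switcher flag: >= 50% of window treated, >= 25% of treated time on a
  # non-dominant class
  switch_flag <- FALSE
  if (treated > 0) {
    dom <- classes[which.max(fr[classes])]
    nondom <- sum(fr[setdiff(classes, dom)]) / treated
    switch_flag <- treated >= 0.5 && nondom >= 0.25
  }

  cc <- tr$from %in% classes & tr$to %in% classes
  up <- cc & .efficacy_rank[tr$to] > .efficacy_rank[tr$from]
  down <- cc & .efficacy_rank[tr$to] < .efficacy_rank[tr$from]
  starts <- tr$from == "none" & tr$to %in% classes
  stops <- tr$from %in% classes & tr$to == "none"

  category <-
    if (treated == 0) {
      "never_treated"
    } else if (nrow(tr) == 0L && max(fr[classes]) >= 0.5) {
      paste0("stable_", classes[which.max(fr[classes])])
    } else if (any(up) && any(down)) {
      "switcher_bidirectional"
    } else if (any(up)) {
      "switcher_escalation"
    } else if (any(down)) {
      "switcher_deescalation"
    } else if (any(starts) && !any(stops)) {
      "switcher_initiation"
    } else if (any(stops) && !any(starts)) {
      "switcher_discontinuation"
    } else {
      "switcher_complex"
    }

  list(category = category, switch_flag = switch_flag, fractions = fr,
       treated_fraction = unname(treated), transitions = tr)
}

#' The ten ELIE treatment-history category labels
#' @return Character vector of the ten category names, reference level first.
#' @export
elie_categories <- function() {
  c("never_treated", "stable_low", "stable_intermediate", "stable_high",
    "switcher_escalation", "switcher_deescalation", "switcher_bidirectional",
    "switcher_initiation", "switcher_discontinuation", "switcher_complex")
}
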