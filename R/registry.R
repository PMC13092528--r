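#' @title Longitudinal MS registry: data model and file I/O
#' @description A registry is a set of four delimited tables sharing
#'   `patient_id`: patients (demographics, baseline, clinician SPMS
#'   label), visits (EDSS plus the seven functional-system scores),
#'   relapses (dates) and treatments (dated DMT episodes). All dates are
#'   ISO-8601; EDSS lives on the 0-10 half-point grid.
#' @name registry_core
NULL

.edss_on_grid <- function(x) {
  ok <- !is.na(x)
  ok & x >= 0 & x <= 10 & abs(x * 2 - round(x * 2)) < 1e-9
}

.parse_date <- function(x, what, file) {
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad)) {
    stop(file, ": malformed ", what, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  d
}

#' Load a registry from its four CSV tables
#'
#' @param patients_path,visits_path,relapses_path,treatments_path Paths to
#'   the four CSV files (see the package README for the schemas).
#' @return An object of class `ms_registry`: a list of the four validated
#'   data.frames with dates parsed, visits/relapses/treatments sorted by
#'   patient and date, and EDSS checked against the half-point grid.
#' @export
load_registry <- function(patients_path, visits_path, relapses_path,
                          treatments_path) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = "character")
  pat <- rd(patients_path); vis <- rd(visits_path)
  rel <- rd(relapses_path); trt <- rd(treatments_path)

  for (col in c("birth_date", "onset_date", "baseline_date",
                "spms_transition_date")) {
    pat[[col]] <- .parse_date(pat[[col]], col, patients_path)
  }
  for (col in c("other_neuro_disorder_flag", "prior_use_flag")) {
    pat[[col]] <- as.logical(pat[[col]])
  }
  if ("relapse_reporting_flag" %in% names(pat)) {
    pat$relapse_reporting_flag <- as.logical(pat$relapse_reporting_flag)
  }
  if (anyDuplicated(pat$patient_id)) {
    stop(patients_path, ": duplicated patient_id", call. = FALSE)
  }

  vis$date <- .parse_date(vis$date, "date", visits_path)
  vis$edss <- suppressWarnings(as.numeric(vis$edss))
  bad <- which(!is.na(vis$edss) & !.edss_on_grid(vis$edss))
  if (length(bad)) {
    stop(visits_path, ": EDSS off the 0-10 half-point grid at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  for (col in .fs_names) {
    vis[[col]] <- suppressWarnings(as.integer(vis[[col]]))
    badf <- which(!is.na(vis[[col]]) & (vis[[col]] < 0 | vis[[col]] > 6))
    if (length(badf)) {
      stop(visits_path, ": ", col, " outside 0-6 at row(s) ",
           paste(utils::head(badf, 5L), collapse = ", "), call. = FALSE)
    }
  }
  rel$date <- .parse_date(rel$date, "date", relapses_path)
  trt$start_date <- .parse_date(trt$start_date, "start_date", treatments_path)
  trt$stop_date <- .parse_date(trt$stop_date, "stop_date", treatments_path)
  badt <- which(!is.na(trt$stop_date) & trt$stop_date <= trt$start_date)
  if (length(badt)) {
    stop(treatments_path, ": stop_date not after start_date at row(s) ",
         paste(utils::head(badt, 5L), collapse = ", "), call. = FALSE)
  }

  for (nm in list(c("visits", visits_path), c("relapses", relapses_path),
                  c("treatments", treatments_path))) {
    tbl <- switch(nm[1L], visits = vis, relapses = rel, treatments = trt)
    unknown <- setdiff(unique(tbl$patient_id), pat$patient_id)
    if (length(unknown)) {
      stop(nm[2L], ": rows reference unknown patient(s) ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }

  vis <- vis[order(vis$patient_id, vis$date), , drop = FALSE]
  dup <- duplicated(vis[, c("patient_id", "date")])
  if (any(dup)) {
    stop(visits_path, ": duplicate visit date within a patient",
         call. = FALSE)
  }
  rel <- rel[order(rel$patient_id, rel$date), , drop = FALSE]
  trt <- trt[order(trt$patient_id, trt$start_date), , drop = FALSE]
  rownames(pat) <- rownames(vis) <- rownames(rel) <- rownames(trt) <- NULL

  structure(list(patients = pat, visits = vis, relapses = rel,
                 treatments = trt), class = "ms_registry")
}

#' Read a registry from a directory of standard-named CSVs
#'
#' Expects `patients.csv`, `visits.csv`, `relapses.csv`, `treatments.csv`.
#' @param dir Directory path.
#' @return An `ms_registry`.
#' @export
read_registry <- function(dir) {
  load_registry(file.path(dir, "patients.csv"), file.path(dir, "visits.csv"),
                file.path(dir, "relapses.csv"),
                file.path(dir, "treatments.csv"))
}

#' Write a registry to a directory as four CSVs
#'
#' Inverse of [read_registry()]; dates are written ISO-8601.
#' @param registry An `ms_registry`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "ms_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(registry$patients, "patients.csv")
  wr(registry$visits, "visits.csv")
  wr(registry$relapses, "relapses.csv")
  wr(registry$treatments, "treatments.csv")
  invisible(dir)
}

#' @export
print.ms_registry <- function(x, ...) {
  cat("MS registry:", nrow(x$patients), "patients,", nrow(x$visits),
      "visits,", nrow(x$relapses), "relapses,", nrow(x$treatments),
      "treatment episodes\n")
  invisible(x)
}

#' Extract one patient's record from a registry
#'
#' @param registry An `ms_registry`.
#' @param id Patient id.
#' @return list with the patient's demographic fields plus `visits`,
#'   `relapses` and (overlap-normalized) `treatments` data.frames.
#' @export
patient_record <- function(registry, id) {
  p <- registry$patients[registry$patients$patient_id == id, , drop = FALSE]
  if (nrow(p) != 1L) stop("unknown patient id: ", id, call. = FALSE)
  rec <- as.list(p)
  rec$visits <- registry$visits[registry$visits$patient_id == id, ,
                                drop = FALSE]
  rec$relapses <- registry$relapses[registry$relapses$patient_id == id, ,
                                    drop = FALSE]
  rec$treatments <- normalize_episodes(
    registry$treatments[registry$treatments$patient_id == id, , drop = FALSE])
  rec
}

## Split a registry into per-patient records in one pass (avoids repeated
## whole-table scans when iterating thousands of patients).
.split_registry <- function(registry) {
  ids <- registry$patients$patient_id
  fct <- function(df) factor(df$patient_id, levels = ids)
  vis <- split(registry$visits, fct(registry$visits))
  rel <- split(registry$relapses, fct(registry$relapses))
  trt <- split(registry$treatments, fct(registry$treatments))
  lapply(seq_along(ids), function(i) {
    rec <- as.list(registry$patients[i, , drop = FALSE])
    rec$visits <- vis[[i]]
    rec$relapses <- rel[[i]]
    rec$treatments <- normalize_episodes(trt[[i]])
    rec
  })
}

#' Restrict a registry to a set of patients
#' @param registry An `ms_registry`.
#' @param ids Patient ids to keep.
#' @return The filtered `ms_registry`.
#' @export
filter_registry <- function(registry, ids) {
  keep <- function(df) df[df$patient_id %in% ids, , drop = FALSE]
  structure(lapply(registry, keep), class = "ms_registry")
}

#' Apply the cohort inclusion criteria
#'
#' Base mode enforces: (A) relapsing-remitting course at baseline, (B) no
#' other neurological disorder (upstream flag), (C) age >= 18 at baseline,
#' (D) at least two clinical evaluations, (E) strictly more than
#' `min_followup_years` of follow-up (last visit minus baseline; target
#' 5 +/- 2 years), (F) EDSS recorded at the baseline visit, (G) data not
#' previously used (upstream flag). Objective mode additionally enforces:
#' (H) relapse reporting available, (I) functional-system scores present
#' at every visit the objective detector needs, (J) consecutive
#' evaluations more than `min_gap_days` apart, (K) no objective
#' progression event on or before baseline.
#'
#' Age and follow-up are computed in days and divided by 365.25.
#'
#' @param registry An `ms_registry`.
#' @param mode `"base"` or `"objective"`.
#' @param min_followup_years Strict lower bound on follow-up (default 3).
#' @param min_gap_days Criterion J gap, 3 months = 90 days.
#' @param criteria [progression_criteria()] used for criteria I and K.
#' @return data.frame of class `inclusion_report`: one row per patient,
#'   logical pass columns `A` ... (`K`), `included`, and `first_failed`
#'   (criterion code or `NA`).
#' @export
apply_inclusion_criteria <- function(registry, mode = c("base", "objective"),
                                     min_followup_years = 3,
                                     min_gap_days = 90,
                                     criteria = progression_criteria()) {
  mode <- match.arg(mode)
  pat <- registry$patients
  n <- nrow(pat)
  codes <- c("A", "B", "C", "D", "E", "F", "G")
  if (mode == "objective") codes <- c(codes, "H", "I", "J", "K")
  res <- matrix(TRUE, n, length(codes), dimnames = list(NULL, codes))
  recs <- .split_registry(registry)

  for (i in seq_len(n)) {
    rec <- recs[[i]]
    v <- rec$visits[rec$visits$date >= rec$baseline_date, , drop = FALSE]
    res[i, "A"] <- identical(rec$course_at_baseline, "RRMS")
    res[i, "B"] <- !isTRUE(rec$other_neuro_disorder_flag)
    res[i, "C"] <-
      as.numeric(rec$baseline_date - rec$birth_date) / 365.25 >= 18
    res[i, "D"] <- nrow(v) >= 2L
    res[i, "E"] <- nrow(v) >= 1L &&
      as.numeric(max(v$date) - rec$baseline_date) / 365.25 >
        min_followup_years
    res[i, "F"] <- any(v$date == rec$baseline_date & !is.na(v$edss))
    res[i, "G"] <- !isTRUE(rec$prior_use_flag)
    if (mode == "objective") {
      res[i, "H"] <- if ("relapse_reporting_flag" %in% names(rec)) {
        isTRUE(rec$relapse_reporting_flag)
      } else TRUE
      scan <- .scan_progression(rec, criteria)
      res[i, "I"] <- length(scan$abstentions) == 0L
      res[i, "J"] <- nrow(v) < 2L ||
        all(diff(as.numeric(v$date)) > min_gap_days)
      res[i, "K"] <- objective_rrms_at_baseline(rec, criteria)
    }
  }

  out <- data.frame(patient_id = pat$patient_id, res,
                    stringsAsFactors = FALSE)
  out$included <- apply(res, 1L, all)
  out$first_failed <- apply(res, 1L, function(r) {
    f <- which(!r)
    if (length(f)) codes[f[1L]] else NA_character_
  })
  class(out) <- c("inclusion_report", "data.frame")
  out
}

#' Included patient ids from an inclusion report
#' @param report An `inclusion_report`.
#' @return Character vector of included patient ids.
#' @export
included_ids <- function(report) report$patient_id[report$included]
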