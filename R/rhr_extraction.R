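# Wearable resting-heart-rate extraction.
#
# The algorithm: a minute's heart-rate sample is "resting" when the device
# certifies the absence of physical activity throughout a closed lookback
# window ending at that minute; the daily rHR is the median heart rate over
# those resting minutes; the visit-level wearable rHR is the mean of the
# daily values over the days strictly before the clinic visit.
#
# Unknown step data (non-wear) never certifies rest: a minute with any
# unrecorded step minute inside its lookback window is disqualified.

#' Rest-window extraction parameters
#'
#' @param lookback_min Length (minutes) of the activity-free lookback
#'   required before a minute qualifies as resting. The window is closed:
#'   minute `m` qualifies only if step counts are recorded and zero at every
#'   minute of `[m - lookback_min, m]`, so the current minute itself must
#'   also be activity-free. Default 15.
#' @param daily_stat Daily summary statistic; only `"median"` is supported
#'   (even-count median is the mean of the two central values).
#' @param previsit_days Number of calendar days strictly before the visit
#'   whose daily values are averaged into the visit-level rHR (the visit day
#'   itself is excluded). Default 5.
#' @param min_rest_minutes_per_day Minimum qualifying minutes for a day's
#'   rHR to be considered valid; otherwise the daily value is missing.
#'   Default 30.
#' @param min_valid_days_per_visit Minimum valid daily values in the
#'   pre-visit window for the visit-level rHR to be reported. Default 3.
#' @return An object of class `rest_params`.
#' @export
rest_params <- function(lookback_min = 15L,
                        daily_stat = "median",
                        previsit_days = 5L,
                        min_rest_minutes_per_day = 30L,
                        min_valid_days_per_visit = 3L) {
  daily_stat <- match.arg(daily_stat, "median")
  stopifnot(lookback_min >= 0, previsit_days >= 1,
            min_rest_minutes_per_day >= 1, min_valid_days_per_visit >= 1)
  structure(list(lookback_min = as.integer(lookback_min),
                 daily_stat = daily_stat,
                 previsit_days = as.integer(previsit_days),
                 min_rest_minutes_per_day = as.integer(min_rest_minutes_per_day),
                 min_valid_days_per_visit = as.integer(min_valid_days_per_visit)),
            class = "rest_params")
}

#' Minutes qualifying as resting in a day log
#'
#' A minute `m` qualifies iff (a) a heart-rate sample exists at `m`, and
#' (b) a step sample exists and equals zero at every minute of
#' `[m - lookback_min, m]`. Minutes whose lookback span contains any unknown
#' (unrecorded) step minute never qualify, and consequently minutes
#' `m < lookback_min` never qualify.
#'
#' @param log A [device_day_log()].
#' @param params A [rest_params()].
#' @return Sorted integer vector of qualifying minutes-of-day.
#' @export
qualifying_minutes <- function(log, params = rest_params()) {
  validate_day_log(log)
  vec <- as_minute_vectors(log)
  L <- params$lookback_min
  zero <- !is.na(vec$steps) & vec$steps == 0
  # closed window [m - L, m]: running count of activity-free recorded minutes
  cs <- c(0, cumsum(zero))
  m <- L:(MINUTES_PER_DAY - 1L)
  clean <- (cs[m + 2L] - cs[m - L + 1L]) == (L + 1L)
  qual <- m[clean]
  qual[!is.na(vec$hr[qual + 1L])]
}

#' Daily resting heart rate
#'
#' The median heart rate over [qualifying_minutes()]; missing when fewer
#' than `min_rest_minutes_per_day` minutes qualify.
#'
#' @inheritParams qualifying_minutes
#' @return A one-row tibble: `subject_id`, `date`, `rhr` (bpm or `NA`),
#'   `n_rest_minutes`.
#' @export
daily_rhr <- function(log, params = rest_params()) {
  qual <- qualifying_minutes(log, params)
  vec <- as_minute_vectors(log)
  n <- length(qual)
  rhr <- if (n >= params$min_rest_minutes_per_day) {
    stats::median(vec$hr[qual + 1L])
  } else {
    NA_real_
  }
  tibble::tibble(subject_id = log$subject_id, date = log$date,
                 rhr = rhr, n_rest_minutes = n)
}

#' Visit-level wearable resting heart rate
#'
#' Averages the non-missing daily rHR values over the `previsit_days`
#' calendar days strictly before `visit_date` (the visit day is excluded);
#' missing when fewer than `min_valid_days_per_visit` valid days fall in the
#' window.
#'
#' @param daily A tibble of [daily_rhr()] rows for one subject, sorted by
#'   date.
#' @param visit_date The clinic-visit date.
#' @param params A [rest_params()].
#' @return A one-row tibble: `subject_id`, `visit_date`, `wd_rhr` (bpm or
#'   `NA`), `n_days_used`.
#' @export
visit_wd_rhr <- function(daily, visit_date, params = rest_params()) {
  visit_date <- as.Date(visit_date)
  window <- daily$date >= visit_date - params$previsit_days &
    daily$date < visit_date & !is.na(daily$rhr)
  used <- daily$rhr[window]
  tibble::tibble(
    subject_id = if (nrow(daily)) daily$subject_id[1] else NA_character_,
    visit_date = visit_date,
    wd_rhr = if (length(used) >= params$min_valid_days_per_visit) mean(used) else NA_real_,
    n_days_used = length(used)
  )
}

#' Extract wearable rHR for every visit of a study
#'
#' Computes daily rHR for all device logs and joins the visit-level wearable
#' rHR onto the clinical visit table.
#'
#' @param logs A list of [device_day_log()] objects (any order), or a
#'   directory containing JSON device logs readable by [read_day_log()].
#' @param visits A visit table with at least `subject_id` and `visit_date`
#'   columns.
#' @param params A [rest_params()].
#' @return A list with `visits` (the input table plus `wd_rhr` and
#'   `n_days_used`) and `daily` (the per-day rHR table: `subject_id`,
#'   `date`, `rhr`, `n_rest_minutes`). Subjects with no logs get missing
#'   `wd_rhr` with a warning.
#' @export
extract_all <- function(logs, visits, params = rest_params()) {
  if (is.character(logs) && length(logs) == 1L) {
    files <- list.files(logs, pattern = "\\.json$", full.names = TRUE)
    logs <- lapply(files, read_day_log)
  }
  daily <- if (length(logs)) {
    dplyr::bind_rows(lapply(logs, daily_rhr, params = params))
  } else {
    tibble::tibble(subject_id = character(0), date = as.Date(character(0)),
                   rhr = numeric(0), n_rest_minutes = integer(0))
  }
  daily <- dplyr::arrange(daily, .data$subject_id, .data$date)

  missing_subjects <- setdiff(unique(visits$subject_id), unique(daily$subject_id))
  if (length(missing_subjects)) {
    warning("no device logs for subject(s): ",
            paste(missing_subjects, collapse = ", "),
            "; wearable rHR set to missing", call. = FALSE)
  }
  per_visit <- lapply(seq_len(nrow(visits)), function(i) {
    sub_daily <- daily[daily$subject_id == visits$subject_id[i], , drop = FALSE]
    row <- visit_wd_rhr(sub_daily, visits$visit_date[i], params)
    row$subject_id <- visits$subject_id[i]
    row
  })
  per_visit <- dplyr::bind_rows(per_visit)
  out <- visits
  out$wd_rhr <- per_visit$wd_rhr
  out$n_days_used <- per_visit$n_days_used
  list(visits = out, daily = daily)
}
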