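# Intraday device-log container and its JSON on-disk dialect.
#
# One document per subject-day: a heart-rate intraday array and a steps
# intraday array, each a list of {time, value} objects with "HH:MM" times.
# Internally times are minutes-of-day (0-1439). A missing step entry means
# "unknown activity" (e.g. non-wear) and is distinct from steps = 0.

MINUTES_PER_DAY <- 1440L
BPM_MIN <- 25
BPM_MAX <- 250

#' Construct a one-day device log
#'
#' A `device_day_log` holds one calendar day of intraday wearable data for
#' one subject: per-minute heart-rate samples and per-minute step counts.
#' Minutes without a step entry are treated as unknown activity (non-wear),
#' which is different from an explicit step count of zero.
#'
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param date Calendar date (`Date` or `"YYYY-MM-DD"` string).
#' @param heart Data frame with columns `time` (minute of day, 0-1439) and
#'   `bpm` (heart rate, must lie in 25-250). May be `NULL`/empty.
#' @param steps Data frame with columns `time` and `steps` (non-negative
#'   count in that minute). May be `NULL`/empty.
#'
#' @return An object of class `device_day_log`.
#' @details Sample times must be strictly increasing with at most one sample
#'   per minute per stream; violations raise an error naming the offending
#'   sample.
#' @seealso [write_day_log()], [read_day_log()]
#' @export
#' @examples
#' log <- device_day_log("S001", "2024-01-01",
#'                       heart = data.frame(time = 480, bpm = 70),
#'                       steps = data.frame(time = 480, steps = 0))
device_day_log <- function(subject_id, date, heart = NULL, steps = NULL) {
  stopifnot(length(subject_id) == 1L, length(date) == 1L)
  log <- structure(
    list(
      subject_id = as.character(subject_id),
      date = as.Date(date),
      heart = normalize_samples(heart, value_col = "bpm"),
      steps = normalize_samples(steps, value_col = "steps")
    ),
    class = "device_day_log"
  )
  validate_day_log(log)
  log
}

normalize_samples <- function(x, value_col) {
  if (is.null(x) || NROW(x) == 0L) {
    out <- tibble::tibble(time = integer(0), value = numeric(0))
    names(out)[2] <- value_col
    return(out)
  }
  x <- as.data.frame(x)
  if (!all(c("time", value_col) %in% names(x))) {
    stop("sample table must have columns 'time' and '", value_col, "'",
         call. = FALSE)
  }
  tibble::as_tibble(x[, c("time", value_col)])
}

validate_day_log <- function(log) {
  if (!inherits(log, "device_day_log")) stop("not a device_day_log")
  for (stream in c("heart", "steps")) {
    tab <- log[[stream]]
    tm <- tab$time
    if (anyNA(tm) || any(tm != floor(tm)) || any(tm < 0 | tm >= MINUTES_PER_DAY)) {
      bad <- tm[which(is.na(tm) | tm != floor(tm) | tm < 0 | tm >= MINUTES_PER_DAY)[1]]
      stop(sprintf("%s sample has invalid minute-of-day time %s (must be an integer in 0-%d)",
                   stream, format(bad), MINUTES_PER_DAY - 1L), call. = FALSE)
    }
    if (length(tm) > 1L && any(diff(tm) <= 0)) {
      i <- which(diff(tm) <= 0)[1]
      stop(sprintf("%s samples out of order or duplicated at minutes %d, %d (times must be strictly increasing, one sample per minute)",
                   stream, tm[i], tm[i + 1L]), call. = FALSE)
    }
  }
  bpm <- log$heart$bpm
  bad <- which(is.na(bpm) | bpm < BPM_MIN | bpm > BPM_MAX)
  if (length(bad)) {
    stop(sprintf("heart sample at minute %d has bpm %s outside [%d, %d]",
                 log$heart$time[bad[1]], format(bpm[bad[1]]), BPM_MIN, BPM_MAX),
         call. = FALSE)
  }
  st <- log$steps$steps
  bad <- which(is.na(st) | st < 0)
  if (length(bad)) {
    stop(sprintf("step sample at minute %d has negative or missing count %s",
                 log$steps$time[bad[1]], format(st[bad[1]])), call. = FALSE)
  }
  invisible(log)
}

#' @export
print.device_day_log <- function(x, ...) {
  cat(sprintf("<device_day_log> subject %s, %s: %d heart samples, %d step samples\n",
              x$subject_id, format(x$date), nrow(x$heart), nrow(x$steps)))
  invisible(x)
}

minute_to_hhmm <- function(m) sprintf("%02d:%02d", m %/% 60L, m %% 60L)

hhmm_to_minute <- function(s) {
  parts <- strsplit(as.character(s), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("malformed time string '", paste(p, collapse = ":"),
           "' (expected HH:MM or HH:MM:SS)", call. = FALSE)
    }
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

#' Write a device log as a JSON document
#'
#' Serializes a [device_day_log()] to the package's JSON dialect: top-level
#' keys `subject_id`, `date`, `heart_rate_intraday` and `steps_intraday`,
#' the intraday arrays holding `{time, value}` objects with `"HH:MM"` time
#' strings. The dialect is described by the schema shipped in
#' `system.file("extdata", "device-log-schema.json", package = "thyrowear")`.
#'
#' @param log A `device_day_log`.
#' @param path Destination file path. The conventional file name is
#'   `<subject_id>_<ISO-date>.json` (see [day_log_filename()]).
#' @return `path`, invisibly. Writing then reading the file reproduces the
#'   log exactly.
#' @export
write_day_log <- function(log, path) {
  validate_day_log(log)
  doc <- list(
    subject_id = log$subject_id,
    date = format(log$date, "%Y-%m-%d"),
    heart_rate_intraday = data.frame(
      time = minute_to_hhmm(log$heart$time), value = log$heart$bpm,
      stringsAsFactors = FALSE),
    steps_intraday = data.frame(
      time = minute_to_hhmm(log$steps$time), value = log$steps$steps,
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Conventional device-log file name
#'
#' @param log A `device_day_log`.
#' @return `"<subject_id>_<ISO-date>.json"`.
#' @export
day_log_filename <- function(log) {
  sprintf("%s_%s.json", log$subject_id, format(log$date, "%Y-%m-%d"))
}

#' Read a device log from a JSON document
#'
#' Parses a document in the dialect written by [write_day_log()] and
#' validates every type invariant (time ordering, one sample per minute,
#' heart-rate range, non-negative steps). Unknown top-level keys are ignored
#' with a warning. Sub-minute samples (`"HH:MM:SS"` times) are canonicalized
#' to the 1-minute grid at read time: heart-rate values are averaged and
#' step counts summed within each minute.
#'
#' @param path Path to a JSON file.
#' @return A validated [device_day_log()].
#' @export
read_day_log <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("subject_id", "date", "heart_rate_intraday", "steps_intraday")
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warning("ignoring unknown keys in device log '", path, "': ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(doc$subject_id) || is.null(doc$date)) {
    stop("device log '", path, "' lacks subject_id or date", call. = FALSE)
  }
  parse_stream <- function(arr, value_col, aggregate) {
    if (is.null(arr) || NROW(arr) == 0L) return(NULL)
    arr <- as.data.frame(arr)
    mins <- floor(hhmm_to_minute(arr$time))
    vals <- as.numeric(arr$value)
    if (anyDuplicated(mins)) {  # sub-minute data: canonicalize per minute
      vals <- as.numeric(tapply(vals, mins, aggregate))
      mins <- sort(unique(mins))
    }
    out <- data.frame(time = as.integer(mins), value = vals)
    names(out)[2] <- value_col
    out
  }
  device_day_log(
    subject_id = doc$subject_id,
    date = doc$date,
    heart = parse_stream(doc$heart_rate_intraday, "bpm", mean),
    steps = parse_stream(doc$steps_intraday, "steps", sum)
  )
}

# Dense per-minute view of a log: numeric vectors of length 1440 with NA
# where no sample exists. Internal workhorse for the rest-window algorithm.
as_minute_vectors <- function(log) {
  hr <- rep(NA_real_, MINUTES_PER_DAY)
  hr[log$heart$time + 1L] <- log$heart$bpm
  st <- rep(NA_real_, MINUTES_PER_DAY)
  st[log$steps$time + 1L] <- log$steps$steps
  list(hr = hr, steps = st)
}
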