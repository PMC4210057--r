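#' Parse dust-storm event intervals
#'
#' Converts a table of per-year interval strings (e.g. `"2/11-2/12, 3/6-3/9"`)
#' into a validated event table with one row per event. Intervals may cross a
#' month boundary (e.g. `"3/31-4/1"`) but not a year boundary.
#'
#' @param event_table data frame with columns `year` and `intervals`
#'   (comma-separated `"M/D-M/D"` tokens). Extra columns are ignored.
#' @return An object of class `ads_events`: a data frame with columns
#'   `start`, `end` (inclusive `Date`s), sorted by `start`.
#' @examples
#' parse_ads_events(data.frame(year = 2002, intervals = "2/11-2/12, 3/6-3/9"))
#' @export
parse_ads_events <- function(event_table) {
  stopifnot(is.data.frame(event_table))
  if (!all(c("year", "intervals") %in% names(event_table)))
    stop("event_table must have columns 'year' and 'intervals'")
  events <- list()
  for (i in seq_len(nrow(event_table))) {
    year <- as.integer(event_table$year[i])
    toks <- trimws(strsplit(as.character(event_table$intervals[i]), ",")[[1]])
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      m <- regmatches(tok, regexec("^([0-9]{1,2})/([0-9]{1,2})-([0-9]{1,2})/([0-9]{1,2})$", tok))[[1]]
      if (length(m) != 5L)
        stop(sprintf("malformed interval token '%s' (expected 'M/D-M/D')", tok))
      start <- .mk_date(year, m[2], m[3], tok)
      end <- .mk_date(year, m[4], m[5], tok)
      if (end < start)
        stop(sprintf("interval '%s' (%d): end precedes start", tok, year))
      events[[length(events) + 1L]] <- data.frame(start = start, end = end)
    }
  }
  if (!length(events)) stop("no events parsed")
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1L && any(ev$start[-1L] <= ev$end[-nrow(ev)]))
    stop("event intervals overlap")
  class(ev) <- c("ads_events", "data.frame")
  ev
}

.mk_date <- function(year, month, day, tok) {
  d <- tryCatch(as.Date(sprintf("%d-%02d-%02d", year, as.integer(month),
                                as.integer(day))),
                error = function(e) NA)
  if (is.na(d))
    stop(sprintf("invalid calendar date in token '%s' for year %d", tok, year))
  d
}

#' Packaged dust-storm event fixture, Taiwan 2002-2007
#'
#' Loads the packaged calendar of the 30 Taiwan EPA dust-storm events
#' declared between 2002 and 2007 (90 event days in total).
#'
#' @param parsed if `TRUE` (default) return parsed [ads_events][parse_ads_events];
#'   otherwise the raw fixture table (year, intervals, n_events, n_days).
#' @return `ads_events` data frame or the raw fixture table.
#' @export
ads_events_fixture <- function(parsed = TRUE) {
  path <- system.file("extdata", "ads_events_taiwan_2002_2007.csv",
                      package = "adstar", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!parsed) return(raw)
  parse_ads_events(raw)
}

#' Label study days as ADS / post-ADS / other
#'
#' Expands event intervals over a date range and labels every day. Event days
#' are `ADS`; the `post_window` days after an event's end are `POST_ADS`
#' unless they fall inside another event (ADS takes precedence); all
#' remaining days are `OTHER`. Windows are truncated at the range boundaries.
#'
#' @param start,end first and last study day (`Date` or coercible).
#' @param events an [ads_events][parse_ads_events] table.
#' @param post_window length of the post-event window in days (default 7,
#'   i.e. days end+1 .. end+7 inclusive).
#' @return An object of class `exposure_calendar`: data frame with columns
#'   `date`, `dow` (`Mon`..`Sun`), `period` (factor `ADS`, `POST_ADS`, `OTHER`).
#' @examples
#' ev <- parse_ads_events(data.frame(year = 2002, intervals = "2/11-2/12"))
#' cal <- label_periods("2002-02-01", "2002-02-28", ev)
#' table(cal$period)
#' @export
label_periods <- function(start, end, events, post_window = 7L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start)
    stop("invalid or empty date range")
  if (!inherits(events, "ads_events"))
    stop("events must be an 'ads_events' object from parse_ads_events()")
  post_window <- as.integer(post_window)
  if (post_window < 0L) stop("post_window must be >= 0")
  dates <- seq(start, end, by = "day")
  period <- rep("OTHER", length(dates))
  for (i in seq_len(nrow(events))) {
    if (post_window > 0L) {
      w0 <- events$end[i] + 1L
      w1 <- events$end[i] + post_window
      period[dates >= w0 & dates <= w1] <- "POST_ADS"
    }
  }
  for (i in seq_len(nrow(events)))  # second pass: ADS overrides post windows
    period[dates >= events$start[i] & dates <= events$end[i]] <- "ADS"
  dows <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  cal <- data.frame(
    date = dates,
    dow = factor(dows[as.integer(format(dates, "%u"))], levels = dows),
    period = factor(period, levels = c("ADS", "POST_ADS", "OTHER"))
  )
  class(cal) <- c("exposure_calendar", "data.frame")
  cal
}

#' Day-of-week dummy design
#'
#' Six indicator columns `I_MON` .. `I_SAT` (or, generally, all weekdays
#' except the reference) for each calendar day.
#'
#' @param calendar an [exposure_calendar][label_periods].
#' @param reference weekday treated as reference level (default `"Sun"`).
#' @return numeric matrix, one row per day, 6 columns.
#' @export
dow_design <- function(calendar, reference = "Sun") {
  stopifnot(inherits(calendar, "exposure_calendar"))
  dows <- levels(calendar$dow)
  if (!reference %in% dows)
    stop(sprintf("reference must be one of %s", paste(dows, collapse = ", ")))
  keep <- setdiff(dows, reference)
  X <- sapply(keep, function(d) as.numeric(calendar$dow == d))
  colnames(X) <- paste0("I_", toupper(keep))
  X
}

#' Export an exposure calendar to CSV
#'
#' @param calendar an [exposure_calendar][label_periods].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calendar <- function(calendar, path) {
  stopifnot(inherits(calendar, "exposure_calendar"))
  out <- data.frame(date = format(calendar$date, "%Y-%m-%d"),
                    dow = as.character(calendar$dow),
                    period = as.character(calendar$period))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
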