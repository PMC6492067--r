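#' Construct an activity log
#'
#' A log of app sightings: one row per (profile fingerprint, calendar
#' day) on which the profile was seen active.
#'
#' @param data data frame with columns `profile_id` (non-empty strings)
#'   and `date` (`Date` or ISO-8601 strings).
#' @param period_start,period_end observation window; defaults to the
#'   range of dates present.
#' @return object of class `activity_log` (a data frame).
#' @export
activity_log <- function(data, period_start = NULL, period_end = NULL) {
  data <- as.data.frame(data)
  if (!all(c("profile_id", "date") %in% names(data))) {
    stop("activity log needs columns `profile_id` and `date`", call. = FALSE)
  }
  data$date <- as.Date(data$date)
  data$profile_id <- as.character(data$profile_id)
  if (nrow(data) > 0 && any(is.na(data$profile_id) | data$profile_id == "")) {
    stop("empty profile fingerprints in activity log", call. = FALSE)
  }
  if (is.null(period_start)) {
    period_start <- if (nrow(data) > 0) min(data$date) else as.Date(NA)
  }
  if (is.null(period_end)) {
    period_end <- if (nrow(data) > 0) max(data$date) else as.Date(NA)
  }
  if (nrow(data) > 0 &&
    (any(data$date < period_start) || any(data$date > period_end))) {
    stop("sightings outside [period_start, period_end]", call. = FALSE)
  }
  structure(data,
    period_start = as.Date(period_start), period_end = as.Date(period_end),
    class = c("activity_log", "data.frame")
  )
}

#' Read an activity log from CSV
#'
#' @param path CSV with columns `profile_id`, `date` (ISO-8601).
#' @return an [activity_log()].
#' @export
read_activity_log <- function(path) {
  activity_log(utils::read.csv(path, colClasses = c(
    profile_id = "character",
    date = "character"
  )))
}

#' Write an activity log to CSV
#' @param log an [activity_log()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_activity_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

new_count_result <- function(count, method, ci = NULL, period_days = NA_integer_,
                             notes = character(0)) {
  structure(
    list(
      count = count, method = method, ci = ci,
      period_days = period_days, notes = notes
    ),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat("<count_result>", x$count, "active users [", x$method, "]")
  if (!is.null(x$ci)) {
    cat(sprintf(" 95%% CI %.0f-%.0f", x$ci[1], x$ci[2]))
  }
  if (!is.na(x$period_days)) cat(" over", x$period_days, "days")
  cat("\n")
  if (length(x$notes) > 0) cat(" note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Count active users by deduplicated enumeration
#'
#' Counts distinct profiles seen on at least `min_appearances` distinct
#' days, with at least two sightings `min_spacing_days` or more apart.
#' The spacing rule screens out short-term visitors whose profile
#' appears only in one burst.
#'
#' @param log an [activity_log()].
#' @param min_appearances minimum number of distinct active days.
#' @param min_spacing_days minimum gap in days between the earliest and
#'   latest sighting; 0 disables the spacing rule.
#' @return a `count_result` with `method = "dedup"` (no CI: the count is
#'   treated as a census of qualifying profiles).
#' @export
dedup_count <- function(log, min_appearances = 2, min_spacing_days = 3) {
  stopifnot(inherits(log, "activity_log"))
  assert_scalar(min_appearances, "min_appearances", lower = 1, integerish = TRUE)
  assert_scalar(min_spacing_days, "min_spacing_days", lower = 0, integerish = TRUE)
  period <- as.integer(attr(log, "period_end") - attr(log, "period_start")) + 1L
  if (nrow(log) == 0) {
    warning("empty activity log; count is 0", call. = FALSE)
    return(new_count_result(0L, "dedup", period_days = period))
  }
  u <- unique(data.frame(profile_id = log$profile_id, date = log$date))
  n_days <- tapply(u$date, u$profile_id, function(d) length(d))
  span <- tapply(u$date, u$profile_id, function(d) {
    as.integer(max(d) - min(d))
  })
  ok <- n_days >= min_appearances &
    (min_spacing_days == 0 | span >= min_spacing_days)
  new_count_result(sum(ok), "dedup", period_days = period)
}

#' Estimate active users by two-sample capture-recapture
#'
#' Matches the profiles active at two time points and applies the
#' Lincoln-Petersen estimator \eqn{\hat N = n_1 n_2 / m} or Chapman's
#' bias-corrected variant
#' \eqn{\hat N = (n_1+1)(n_2+1)/(m+1) - 1}, where \eqn{m} is the number
#' of profiles seen at both time points. The CI is a normal
#' approximation from the estimator's standard variance, floored at
#' \eqn{\max(n_1, n_2)}.
#'
#' @param capture1,capture2 character vectors of profile fingerprints
#'   seen at the two time points (duplicates within a capture ignored).
#' @param correction `"lincoln_petersen"` (default) or `"chapman"`.
#' @param level confidence level.
#' @param period_days length of the overall observation period in days.
#' @return a `count_result` with `method = "capture_recapture"`.
#' @export
capture_recapture_count <- function(capture1, capture2,
                                    correction = c("lincoln_petersen", "chapman"),
                                    level = 0.95, period_days = NA_integer_) {
  correction <- match.arg(correction)
  capture1 <- unique(as.character(capture1))
  capture2 <- unique(as.character(capture2))
  if (length(capture1) == 0 || length(capture2) == 0) {
    stop("both captures must be non-empty", call. = FALSE)
  }
  n1 <- length(capture1)
  n2 <- length(capture2)
  m <- length(intersect(capture1, capture2))
  if (correction == "lincoln_petersen") {
    if (m == 0) {
      stop(
        "no overlap between captures: Lincoln-Petersen is undefined; ",
        "use correction = \"chapman\"",
        call. = FALSE
      )
    }
    n_hat <- n1 * n2 / m
    v <- n1 * n2 * (n1 - m) * (n2 - m) / m^3
  } else {
    n_hat <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
    v <- (n1 + 1) * (n2 + 1) * (n1 - m) * (n2 - m) / ((m + 1)^2 * (m + 2))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(n_hat - z * sqrt(v), n1, n2)
  hi <- max(n_hat + z * sqrt(v), lo)
  new_count_result(round_half_up(n_hat), "capture_recapture",
    ci = c(lo, hi), period_days = period_days,
    notes = sprintf("%s on n1=%d, n2=%d, m=%d", correction, n1, n2, m)
  )
}

#' Wrap a provider-supplied aggregate user count
#'
#' For the case where the app administrator supplies the total
#' unduplicated number of active users directly.
#'
#' @param value non-negative integer count.
#' @param period_days period the count covers, in days.
#' @return a `count_result` with `method = "provider"`.
#' @export
provider_count <- function(value, period_days = 30) {
  assert_scalar(value, "value", lower = 0, integerish = TRUE)
  new_count_result(as.integer(value), "provider", period_days = period_days)
}
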