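#' Published provincial survey summary (Vietnam MSM, 2019)
#'
#' Per-province summary of the 12 RDS online surveys from the 2019
#' social-app multiplier study of the MSM population in Vietnam:
#' participants, eligible respondents, mean age, mean self-reported
#' network size, respondents qualifying by sexual preference rather
#' than recent behaviour, app account holders and 30-day app users.
#'
#' @return data frame with one row per province (no total row; see
#'   [survey_summary_totals()]).
#' @export
vn_survey_summary <- function() {
  utils::read.csv(
    system.file("extdata", "vn_msm_survey_summary_2019.csv",
      package = "appmultiplier", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
}

#' Column totals of the provincial survey summary
#'
#' @param summary data frame as returned by [vn_survey_summary()].
#' @return named list with `participants`, `eligible`, `jackd_account`,
#'   `jackd_30d`.
#' @export
survey_summary_totals <- function(summary = vn_survey_summary()) {
  list(
    participants = sum(summary$participants),
    eligible = sum(summary$eligible),
    jackd_account = sum(summary$jackd_account),
    jackd_30d = sum(summary$jackd_30d)
  )
}

#' Published provincial multiplier estimates (Vietnam MSM, 2019)
#'
#' The 11 reliable provincial rows of the same study: 30-day app-user
#' count (with counting method), RDS-I proportion of MSM using the app
#' in the last 30 days with 95% CI, estimated MSM population aged 18-49
#' with 95% CI, and the age-weighted percentage of males 15-49.
#'
#' @return data frame with one row per province.
#' @export
vn_provincial_estimates <- function() {
  utils::read.csv(
    system.file("extdata", "vn_msm_provincial_estimates_2019.csv",
      package = "appmultiplier", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
}

#' Provincial estimate table with a total row
#'
#' Builds the reporting table for a set of provincial rows and appends
#' the Total row: summed counts and population estimates (bound-wise
#' for the CI); the proportion columns are left blank in the total row
#' because a pooled proportion is not a column sum.
#'
#' @param estimates data frame shaped like [vn_provincial_estimates()].
#' @param path optional CSV path to write the table to.
#' @return the table including the `Total` row, invisibly if `path` is
#'   given.
#' @export
estimate_table <- function(estimates = vn_provincial_estimates(),
                           path = NULL) {
  total <- data.frame(
    province = "Total",
    count_30d = sum(estimates$count_30d),
    count_method = "",
    proportion = NA_real_, prop_lo = NA_real_, prop_hi = NA_real_,
    pop_estimate = sum(estimates$pop_estimate),
    pop_lo = sum(estimates$pop_lo),
    pop_hi = sum(estimates$pop_hi),
    weighted_pct = NA_real_
  )
  keep <- intersect(names(total), names(estimates))
  out <- rbind(estimates[keep], total[keep])
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}
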