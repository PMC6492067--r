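AGE_BANDS <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")

#' Multiplier population estimate
#'
#' Divides the app-user count (the multiplier's numerator, a census of
#' app users in the province) by the estimated proportion of the
#' population using the app. The CI divides the count by the
#' proportion's CI bounds; all figures are rounded half-up only at the
#' reporting step.
#'
#' @param count a `count_result` (or a plain non-negative number).
#' @param proportion a `proportion_estimate` (or a list with `p_hat`
#'   and optionally `ci`).
#' @param province optional province label carried into the result.
#' @return object of class `multiplier_estimate` with `N_hat` and `ci`.
#'   A zero lower proportion bound yields an infinite upper population
#'   bound, flagged in `notes`.
#' @export
#' @examples
#' multiplier_estimate(provider_count(260), list(p_hat = 0.35))$N_hat # 743
multiplier_estimate <- function(count, proportion, province = NA_character_) {
  if (is.numeric(count)) count <- provider_count(count)
  stopifnot(inherits(count, "count_result"))
  p <- proportion$p_hat
  if (is.null(p) || is.na(p)) {
    stop("proportion estimate is missing/unreliable: no multiplier estimate",
      call. = FALSE
    )
  }
  assert_scalar(p, "p_hat", lower = 0, upper = 1)
  if (p == 0) {
    stop("proportion is 0: population size undefined", call. = FALSE)
  }
  n_hat <- round_half_up(count$count / p)
  notes <- character(0)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(proportion$ci) && !any(is.na(proportion$ci))) {
    lo_p <- proportion$ci[1]
    hi_p <- proportion$ci[2]
    hi_n <- if (lo_p > 0) round_half_up(count$count / lo_p) else Inf
    if (!is.finite(hi_n)) {
      notes <- c(notes, "lower proportion bound is 0: upper bound infinite")
    }
    ci <- c(round_half_up(count$count / hi_p), hi_n)
  }
  structure(
    list(
      province = province, count = count, proportion = proportion,
      N_hat = n_hat, ci = ci, notes = notes
    ),
    class = "multiplier_estimate"
  )
}

#' @export
print.multiplier_estimate <- function(x, ...) {
  cat(sprintf(
    "<multiplier_estimate>%s N = %s",
    if (is.na(x$province)) "" else paste0(" ", x$province, ":"),
    format(x$N_hat, big.mark = ",")
  ))
  if (!any(is.na(x$ci))) {
    cat(sprintf(
      " (95%% CI %s-%s)", format(x$ci[1], big.mark = ","),
      format(x$ci[2], big.mark = ",")
    ))
  }
  cat("\n")
  invisible(x)
}

check_age_bands <- function(x, what) {
  miss <- setdiff(AGE_BANDS, names(x))
  if (length(miss) > 0) {
    stop(sprintf(
      "%s is missing age band(s): %s", what,
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  x[AGE_BANDS]
}

#' Age-weighted percentage of the population that is MSM
#'
#' Allocates an 18-49 population estimate to 5-year age bands in
#' proportion to the app users' age distribution, bridges the 18-19
#' share of the 15-19 band up to the full band under a uniform-age
#' assumption (factor 5/2), and expresses the result as a percentage of
#' the 15-49 male population.
#'
#' @param estimate a `multiplier_estimate` (or a plain number, taken as
#'   the 18-49 population size).
#' @param male_pop_by_age named vector of male population per band
#'   `"15-19"` ... `"45-49"`.
#' @param app_age_distribution named vector of app-user age-band
#'   fractions summing to 1.
#' @param bridge_15_17 apply the uniform-within-band rescaling of the
#'   15-19 band (set `FALSE` to report a pure 18-49 percentage of the
#'   15-49 denominator).
#' @return percentage (0-100 scale).
#' @export
weighted_msm_percentage <- function(estimate, male_pop_by_age,
                                    app_age_distribution,
                                    bridge_15_17 = TRUE) {
  n_hat <- if (inherits(estimate, "multiplier_estimate")) {
    estimate$N_hat
  } else {
    estimate
  }
  assert_scalar(n_hat, "estimate", lower = 0)
  pop <- check_age_bands(male_pop_by_age, "male_pop_by_age")
  if (any(pop <= 0)) stop("male populations must be positive", call. = FALSE)
  w <- check_age_bands(app_age_distribution, "app_age_distribution")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("app_age_distribution must sum to 1", call. = FALSE)
  }
  alloc <- n_hat * w
  if (bridge_15_17) {
    alloc["15-19"] <- alloc["15-19"] * 5 / 2
  }
  unname(sum(alloc) / sum(pop) * 100)
}

#' Extrapolation configuration
#'
#' @param provinces data frame with columns `name`, `region`, `observed`
#'   (logical) and one male-population column per age band (`"15-19"`
#'   ... `"45-49"`).
#' @param app_age_distribution named age-band fractions summing to 1.
#' @param pilot_estimates optional data frame `name`, `N_hat` (and
#'   optionally `lo`, `hi`) of previously piloted provinces to append
#'   to the national total. List pilot provinces in `provinces` with
#'   `observed = TRUE` (they are covered empirically, so they must not
#'   be extrapolated) and do not pass a multiplier estimate for them.
#' @return object of class `extrapolation_config`.
#' @export
extrapolation_config <- function(provinces, app_age_distribution,
                                 pilot_estimates = NULL) {
  provinces <- as.data.frame(provinces)
  need <- c("name", "region", "observed", AGE_BANDS)
  miss <- setdiff(need, names(provinces))
  if (length(miss) > 0) {
    stop("provinces table missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(as.matrix(provinces[AGE_BANDS]) <= 0)) {
    stop("male populations must be positive", call. = FALSE)
  }
  w <- check_age_bands(app_age_distribution, "app_age_distribution")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("app_age_distribution must sum to 1", call. = FALSE)
  }
  if (!is.null(pilot_estimates)) {
    pilot_estimates <- as.data.frame(pilot_estimates)
    if (!all(c("name", "N_hat") %in% names(pilot_estimates))) {
      stop("pilot_estimates needs columns `name` and `N_hat`", call. = FALSE)
    }
    if (is.null(pilot_estimates$lo)) pilot_estimates$lo <- pilot_estimates$N_hat
    if (is.null(pilot_estimates$hi)) pilot_estimates$hi <- pilot_estimates$N_hat
  }
  structure(
    list(
      provinces = provinces, app_age_distribution = w,
      pilot_estimates = pilot_estimates
    ),
    class = "extrapolation_config"
  )
}

#' Read an extrapolation configuration from YAML or JSON
#'
#' The file holds `provinces` (records with `name`, `region`,
#' `observed`, `population` mapping age bands to counts),
#' `app_age_distribution`, and optional `pilot_estimates`.
#'
#' @param path YAML or JSON file.
#' @return an [extrapolation_config()].
#' @export
read_extrapolation_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  prov <- do.call(rbind, lapply(raw$provinces, function(p) {
    pop <- unlist(p$population)
    df <- data.frame(
      name = p$name, region = p$region,
      observed = isTRUE(p$observed)
    )
    for (b in names(pop)) df[[b]] <- pop[[b]]
    df
  }))
  pilots <- if (!is.null(raw$pilot_estimates)) {
    do.call(rbind, lapply(raw$pilot_estimates, as.data.frame))
  } else {
    NULL
  }
  extrapolation_config(prov, unlist(raw$app_age_distribution), pilots)
}

#' National extrapolation of provincial estimates
#'
#' Converts each observed provincial estimate to an age-weighted
#' percentage of that province's 15-49 male population
#' ([weighted_msm_percentage()]), averages the percentages within each
#' region (population-weighted by default), applies the regional
#' percentage to the 15-49 male population of every unobserved province
#' of that region, and sums observed, extrapolated and pilot estimates
#' into a national total. The CI applies the identical procedure to the
#' provincial CI bounds (bound-wise, without an independence
#' assumption).
#'
#' @param provincial list of `multiplier_estimate` objects with
#'   `province` labels matching config rows.
#' @param config an [extrapolation_config()].
#' @param weighting how regional percentages are averaged across
#'   observed provinces: `"population"` (default), `"unweighted"` or
#'   `"median"`.
#' @param bridge_15_17 passed to [weighted_msm_percentage()].
#' @return object of class `national_estimate` with `total`, `ci`,
#'   `pct_adult_males`, `pct_ci` and a per-province `provenance` table.
#' @export
extrapolate_national <- function(provincial, config,
                                 weighting = c("population", "unweighted", "median"),
                                 bridge_15_17 = TRUE) {
  stopifnot(inherits(config, "extrapolation_config"))
  weighting <- match.arg(weighting)
  if (inherits(provincial, "multiplier_estimate")) provincial <- list(provincial)
  prov <- config$provinces
  pop15_49 <- rowSums(prov[AGE_BANDS])
  est_names <- vapply(provincial, function(e) e$province, character(1))
  if (anyNA(est_names)) {
    stop("every provincial estimate needs a `province` label", call. = FALSE)
  }
  miss <- setdiff(est_names, prov$name[prov$observed])
  if (length(miss) > 0) {
    stop(
      "estimate(s) for province(s) not marked observed in config: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  regions_needed <- unique(prov$region[!prov$observed])
  no_obs <- setdiff(regions_needed, prov$region[prov$observed])
  if (length(no_obs) > 0) {
    stop(
      "region(s) without any observed province: ",
      paste(no_obs, collapse = ", "),
      call. = FALSE
    )
  }

  pct_of <- function(value, row) {
    weighted_msm_percentage(
      value, unlist(prov[row, AGE_BANDS]),
      config$app_age_distribution,
      bridge_15_17 = bridge_15_17
    )
  }
  obs_rows <- match(est_names, prov$name)
  obs <- data.frame(
    name = est_names,
    region = prov$region[obs_rows],
    pop = pop15_49[obs_rows],
    N_hat = vapply(provincial, function(e) e$N_hat, numeric(1)),
    lo = vapply(provincial, function(e) e$ci[1], numeric(1)),
    hi = vapply(provincial, function(e) e$ci[2], numeric(1))
  )
  obs$lo[is.na(obs$lo)] <- obs$N_hat[is.na(obs$lo)]
  obs$hi[is.na(obs$hi)] <- obs$N_hat[is.na(obs$hi)]
  for (v in c("N_hat", "lo", "hi")) {
    obs[[paste0("pct_", v)]] <- vapply(
      seq_len(nrow(obs)),
      function(i) pct_of(obs[[v]][i], obs_rows[i]), numeric(1)
    )
  }

  regional_pct <- function(col) {
    vapply(split(obs, obs$region), function(g) {
      switch(weighting,
        population = sum(g[[col]] * g$pop) / sum(g$pop),
        unweighted = mean(g[[col]]),
        median = stats::median(g[[col]])
      )
    }, numeric(1))
  }
  r_pt <- regional_pct("pct_N_hat")
  r_lo <- regional_pct("pct_lo")
  r_hi <- regional_pct("pct_hi")

  unobs <- which(!prov$observed)
  ext <- data.frame(
    name = prov$name[unobs],
    region = prov$region[unobs],
    pop = pop15_49[unobs]
  )
  band_scale <- sum(config$app_age_distribution *
    ifelse(AGE_BANDS == "15-19", if (bridge_15_17) 5 / 2 else 1, 1))
  # regional pct already includes the age bridge; applying pct to the
  # unobserved 15-49 population gives its 15-49 MSM count directly
  ext$N_hat <- r_pt[ext$region] / 100 * ext$pop
  ext$lo <- r_lo[ext$region] / 100 * ext$pop
  ext$hi <- r_hi[ext$region] / 100 * ext$pop

  # observed provinces enter the national 15-49 total on the same
  # 15-49 scale as the extrapolated ones
  obs$N15 <- obs$N_hat * band_scale
  obs$lo15 <- obs$lo * band_scale
  obs$hi15 <- obs$hi * band_scale

  pilots <- config$pilot_estimates
  pilot_tot <- if (is.null(pilots)) c(0, 0, 0) else {
    c(sum(pilots$N_hat), sum(pilots$lo), sum(pilots$hi)) * band_scale
  }

  total <- sum(obs$N15) + sum(ext$N_hat) + pilot_tot[1]
  lo <- sum(obs$lo15) + sum(ext$lo) + pilot_tot[2]
  hi <- sum(obs$hi15) + sum(ext$hi) + pilot_tot[3]
  national_pop <- sum(pop15_49)

  provenance <- rbind(
    data.frame(name = obs$name, status = rep("observed", nrow(obs))),
    data.frame(name = ext$name, status = rep("extrapolated", nrow(ext))),
    if (!is.null(pilots)) {
      data.frame(name = pilots$name, status = rep("pilot", nrow(pilots)))
    }
  )
  structure(
    list(
      total = round_half_up(total),
      ci = round_half_up(c(lo, hi)),
      pct_adult_males = total / national_pop * 100,
      pct_ci = c(lo, hi) / national_pop * 100,
      observed = obs, extrapolated = ext,
      regional_pct = r_pt,
      provenance = provenance,
      age_bridge_note = if (bridge_15_17) {
        "18-49 estimates rescaled to 15-49 assuming uniform ages within the 15-19 band"
      } else {
        "no 15-17 bridge applied"
      }
    ),
    class = "national_estimate"
  )
}

#' @export
print.national_estimate <- function(x, ...) {
  cat(sprintf(
    "<national_estimate> total = %s (95%% CI %s-%s); %.2f%% of males 15-49 (%.2f-%.2f)\n",
    format(x$total, big.mark = ","), format(x$ci[1], big.mark = ","),
    format(x$ci[2], big.mark = ","), x$pct_adult_males,
    x$pct_ci[1], x$pct_ci[2]
  ))
  cat(" ", x$age_bridge_note, "\n")
  invisible(x)
}
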