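#' Recruitment homophily
#'
#' Ratio of observed same-group recruiter-recruit pairs to the number
#' expected under random mixing, where the expectation matches each
#' recruiter against the composition of the realised recruit pool.
#' 1 indicates random referral; values above 1 indicate assortative
#' recruitment (recruiters favouring their own group). Note that some
#' field reports read the statistic in the opposite direction; the
#' numeric selection rule in [select_estimator()] uses the printed
#' threshold either way.
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @return positive scalar.
#' @export
homophily <- function(sample, trait) {
  pr <- recruitment_pairs(sample, trait)
  if (nrow(pr) == 0) {
    stop("no recruitment pairs with observed trait: homophily undefined",
      call. = FALSE
    )
  }
  observed <- sum(pr$recruiter == pr$recruit)
  q_a <- mean(pr$recruit == 1)
  expected <- sum(ifelse(pr$recruiter == 1, q_a, 1 - q_a))
  observed / expected
}

# Cumulative estimate series in recruitment order. Because a recruiter
# always precedes its recruit, the transition counts, group sizes and
# inverse-degree sums of every prefix are cumulative sums, so the whole
# rds_i / crude series costs O(n). giles_ss is recomputed on a stride.
cumulative_series <- function(sample, trait, estimator = "rds_i",
                              smoothed = FALSE, N = NULL, sim_reps = 50,
                              max_iter = 3, tol = 5e-3, min_prefix = 10) {
  stopifnot(inherits(sample, "rds_sample"))
  ord <- order(sample$recruitment_order)
  t_v <- sample[[trait]][ord]
  d <- sample$degree[ord]
  rid <- sample$recruiter_id[ord]
  idx <- match(rid, sample$id[ord])
  n <- length(t_v)
  obs <- !is.na(t_v)

  if (estimator %in% c("rds_i", "crude")) {
    pair_ok <- !is.na(idx) & obs & !is.na(t_v[ifelse(is.na(idx), 1, idx)])
    rec_g <- ifelse(pair_ok, t_v[ifelse(is.na(idx), 1, idx)], NA)
    t_aa <- cumsum(ifelse(pair_ok & rec_g == 1 & t_v == 1, 1, 0))
    t_ab <- cumsum(ifelse(pair_ok & rec_g == 1 & t_v == 0, 1, 0))
    t_ba <- cumsum(ifelse(pair_ok & rec_g == 0 & t_v == 1, 1, 0))
    t_bb <- cumsum(ifelse(pair_ok & rec_g == 0 & t_v == 0, 1, 0))
    if (smoothed) {
      s <- (t_ab + t_ba) / 2
      t_ab <- s
      t_ba <- s
    }
    n_a <- cumsum(ifelse(obs & t_v == 1, 1, 0))
    n_b <- cumsum(ifelse(obs & t_v == 0, 1, 0))
    inv_a <- cumsum(ifelse(obs & t_v == 1, 1 / d, 0))
    inv_b <- cumsum(ifelse(obs & t_v == 0, 1 / d, 0))
    if (estimator == "crude") {
      est <- n_a / (n_a + n_b)
    } else {
      s_ab <- t_ab / (t_aa + t_ab)
      s_ba <- t_ba / (t_ba + t_bb)
      d_a <- n_a / inv_a
      d_b <- n_b / inv_b
      est <- s_ba * d_b / (s_ab * d_a + s_ba * d_b)
      est[(t_aa + t_ab) == 0 | (t_ba + t_bb) == 0] <- NA
      est[t_ab == 0 & t_ba == 0] <- NA
      est[n_a == 0] <- 0
      est[n_b == 0] <- 1
    }
    ks <- seq_len(n)
  } else if (estimator == "giles_ss") {
    if (is.null(N)) {
      stop("giles_ss series requires the assumed population size N",
        call. = FALSE
      )
    }
    ks <- unique(c(seq(min_prefix, n, by = max(1, floor(n / 50))), n))
    est <- vapply(ks, function(k) {
      tk <- t_v[seq_len(k)]
      dk <- d[seq_len(k)]
      ok <- !is.na(tk)
      if (sum(ok) < 2 || length(unique(tk[ok])) < 2) {
        return(NA_real_)
      }
      tryCatch(
        ss_point(dk[ok], tk[ok] == 1, N, sim_reps, max_iter, tol)$p,
        error = function(e) NA_real_
      )
    }, numeric(1))
  } else {
    stop("unknown estimator `", estimator, "`", call. = FALSE)
  }
  keep <- ks >= min_prefix & !is.na(est)
  data.frame(n = ks[keep], estimate = est[keep])
}

#' Convergence check for the cumulative RDS estimate
#'
#' Recomputes the estimator on every prefix of the sample in
#' recruitment order and declares convergence when every estimate in
#' the final `window_frac` of the series stays within `tol` of the
#' final estimate. The default tolerance is the 2-percentage-point
#' stability rule; `relative = TRUE` interprets `tol` as a fraction of
#' the final estimate instead.
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param estimator `"rds_i"`, `"giles_ss"` or `"crude"`.
#' @param tol stability tolerance (absolute by default).
#' @param window_frac fraction of the series forming the stability
#'   window.
#' @param relative interpret `tol` relative to the final estimate.
#' @param ... further arguments for the estimator (e.g. `N`, `smoothed`).
#' @return list with `converged` (logical), `series` (data frame `n`,
#'   `estimate`) and `notes`. Prefixes on which the estimator is
#'   undefined are omitted from the series.
#' @export
convergence_check <- function(sample, trait, estimator = "rds_i",
                              tol = 0.02, window_frac = 0.25,
                              relative = FALSE, ...) {
  stopifnot(inherits(sample, "rds_sample"))
  notes <- character(0)
  if (nrow(sample) < 50) {
    notes <- c(notes, sprintf(
      "only %d respondents; convergence assessment is weak below 50",
      nrow(sample)
    ))
  }
  series <- cumulative_series(sample, trait, estimator = estimator, ...)
  if (nrow(series) < 2) {
    return(list(
      converged = NA, series = series,
      notes = c(notes, "series too short to assess convergence")
    ))
  }
  n_final <- max(series$n)
  final <- series$estimate[which.max(series$n)]
  in_window <- series$n > (1 - window_frac) * n_final
  eff_tol <- if (relative) tol * final else tol
  converged <- all(abs(series$estimate[in_window] - final) <= eff_tol)
  dropped <- n_final - nrow(series) -
    (min(series$n) - 1) # prefixes omitted inside the assessed range
  if (dropped > 0) {
    notes <- c(notes, sprintf("%d undefined prefixes omitted", dropped))
  }
  list(converged = converged, series = series, notes = notes)
}

#' Per-seed bottleneck series
#'
#' Computes the cumulative estimate series separately within each
#' seed's recruitment subtree; large gaps between the final per-seed
#' estimates indicate chains trapped in different communities.
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param estimator passed to [cumulative_series()].
#' @param gap_flag gap above which the bottleneck flag is set.
#' @param ... further estimator arguments.
#' @return list with `series` (one data frame per seed with >= 2
#'   respondents), `final_estimates`, `gap` (max pairwise difference of
#'   final estimates, `NA` with a single usable seed) and `bottleneck`
#'   (logical flag, `gap > gap_flag`).
#' @export
bottleneck_series <- function(sample, trait, estimator = "crude",
                              gap_flag = 0.10, ...) {
  stopifnot(inherits(sample, "rds_sample"))
  seeds <- unique(sample$seed_id)
  series <- list()
  for (s in seeds) {
    sub <- sample[sample$seed_id == s, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub_sample <- rds_sample(as.data.frame(sub), traits = attr(sample, "traits"))
    ser <- cumulative_series(sub_sample, trait,
      estimator = estimator,
      min_prefix = 2, ...
    )
    if (nrow(ser) > 0) series[[as.character(s)]] <- ser
  }
  finals <- vapply(
    series,
    function(s) s$estimate[which.max(s$n)], numeric(1)
  )
  gap <- if (length(finals) >= 2) max(finals) - min(finals) else NA_real_
  list(
    series = series, final_estimates = finals, gap = gap,
    bottleneck = if (is.na(gap)) NA else gap > gap_flag
  )
}

#' Sensitivity screen on an estimated proportion
#'
#' An estimated app-use proportion outside `[low, high]` makes the
#' multiplier hypersensitive to small errors in the proportion; such
#' estimates are screened out. Bounds are inclusive.
#'
#' @param p_hat estimated proportion in `[0, 1]`.
#' @param low,high acceptance bounds (defaults 0.2 and 0.8).
#' @return `TRUE` when the estimator is *not* sensitive
#'   (`low <= p_hat <= high`).
#' @export
sensitivity_check <- function(p_hat, low = 0.2, high = 0.8) {
  assert_scalar(p_hat, "p_hat", lower = 0, upper = 1)
  p_hat >= low & p_hat <= high
}

#' Diagnostic battery for one province
#'
#' Bundles homophily, convergence, bottleneck and sensitivity into a
#' `diagnostics_report` consumable by [select_estimator()].
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param estimator estimator driving the convergence/bottleneck
#'   series.
#' @param p_hat optional proportion for the sensitivity screen
#'   (defaults to the final convergence-series value).
#' @param tol,window_frac convergence settings.
#' @param sensitivity_bounds length-2 vector of inclusive bounds.
#' @param gap_flag bottleneck flag threshold.
#' @param ... further estimator arguments.
#' @return object of class `diagnostics_report`.
#' @export
diagnose <- function(sample, trait, estimator = "rds_i", p_hat = NULL,
                     tol = 0.02, window_frac = 0.25,
                     sensitivity_bounds = c(0.2, 0.8), gap_flag = 0.10,
                     ...) {
  h <- homophily(sample, trait)
  conv <- convergence_check(sample, trait,
    estimator = estimator, tol = tol,
    window_frac = window_frac, ...
  )
  bn <- bottleneck_series(sample, trait, gap_flag = gap_flag)
  if (is.null(p_hat)) {
    p_hat <- conv$series$estimate[which.max(conv$series$n)]
  }
  sens <- sensitivity_check(p_hat, sensitivity_bounds[1], sensitivity_bounds[2])
  structure(
    list(
      homophily_value = h,
      converged = conv$converged,
      convergence_series = conv$series,
      bottleneck_series = bn$series,
      bottleneck_gap = bn$gap,
      bottleneck = bn$bottleneck,
      sensitive = !sens,
      p_hat = p_hat,
      notes = conv$notes
    ),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  homophily        %.3f\n", x$homophily_value))
  cat("  converged       ", x$converged, "\n")
  cat(sprintf(
    "  bottleneck gap   %s (flag: %s)\n",
    if (is.na(x$bottleneck_gap)) "NA" else sprintf("%.3f", x$bottleneck_gap),
    x$bottleneck
  ))
  cat(sprintf(
    "  sensitive        %s (p_hat = %.3f)\n", x$sensitive, x$p_hat
  ))
  if (length(x$notes) > 0) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Estimator selection across provinces
#'
#' RDS-I tends to underestimate when sampling has not converged, while
#' the successive-sampling bootstrap tends to underestimate when
#' homophily is below 1. The rule therefore counts, across provincial
#' reports, how many provinces have homophily below 1 and how many
#' failed to converge, and picks RDS-I exactly when the former count
#' exceeds the latter; ties go to Gile's SS.
#'
#' @param reports list of `diagnostics_report` objects (or a data frame
#'   with columns `homophily_value` and `converged`).
#' @return list with `estimator` (`"rds_i"` or `"giles_ss"`),
#'   `n_homophily_lt1`, `n_not_converged` and a `rationale` string.
#' @export
select_estimator <- function(reports) {
  if (inherits(reports, "diagnostics_report")) reports <- list(reports)
  if (is.data.frame(reports)) {
    h <- reports$homophily_value
    cv <- reports$converged
  } else {
    if (length(reports) < 1) stop("at least one report required", call. = FALSE)
    h <- vapply(reports, function(r) r$homophily_value, numeric(1))
    cv <- vapply(reports, function(r) isTRUE(r$converged), logical(1))
  }
  n_h <- sum(h < 1, na.rm = TRUE)
  n_nc <- sum(!cv, na.rm = TRUE)
  est <- if (n_h > n_nc) "rds_i" else "giles_ss"
  rationale <- sprintf(
    "%d province(s) with homophily < 1 vs %d without convergence: %s%s",
    n_h, n_nc, est,
    if (n_h == n_nc) " (tie, defaulting to giles_ss)" else ""
  )
  list(
    estimator = est, n_homophily_lt1 = n_h, n_not_converged = n_nc,
    rationale = rationale
  )
}

#' Compare app users and non-users on an outcome
#'
#' Equal-variance two-sample t test for continuous outcomes (pooled
#' degrees of freedom `n1 + n2 - 2`) and Pearson's chi-square without
#' continuity correction for binary outcomes.
#'
#' @param sample an [rds_sample()].
#' @param group_trait binary trait column defining the two groups.
#' @param outcome name of the outcome column (binary or continuous).
#' @return list with `test` (`"t"` or `"chisq"`), `statistic`, `df`,
#'   `p_value`.
#' @export
compare_groups <- function(sample, group_trait, outcome) {
  stopifnot(inherits(sample, "rds_sample"))
  g <- sample[[group_trait]]
  y <- sample[[outcome]]
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]
  y <- y[ok]
  if (length(unique(g)) < 2) {
    stop("grouping trait has a single level", call. = FALSE)
  }
  binary <- all(y %in% c(0, 1))
  if (binary) {
    tab <- table(factor(g, levels = c(1, 0)), factor(y, levels = c(1, 0)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop("degenerate 2x2 table", call. = FALSE)
    }
    ht <- stats::chisq.test(tab, correct = FALSE)
    list(
      test = "chisq", statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value
    )
  } else {
    if (stats::var(y) == 0) {
      stop("zero-variance outcome: t test undefined", call. = FALSE)
    }
    ht <- stats::t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    list(
      test = "t", statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value
    )
  }
}
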