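# Simulate `reps` pseudo-chains of length n over groups {A=1, B=0}
# using the observed transition proportions; returns an n x reps 0/1
# matrix. Undefined transition rows fall back to the marginal recruit
# composition (noted by the caller).
simulate_group_chains <- function(n, reps, p_a_given_a, p_a_given_b,
                                  start_groups) {
  g <- matrix(0L, n, reps)
  g[1, ] <- sample(start_groups, reps, replace = TRUE)
  if (n > 1) {
    for (k in 2:n) {
      u <- stats::runif(reps)
      prev <- g[k - 1, ]
      g[k, ] <- as.integer(ifelse(prev == 1L, u < p_a_given_a, u < p_a_given_b))
    }
  }
  g
}

# Vectorised RDS-I evaluation on a matrix of pseudo-chains (groups g,
# degrees d); returns one estimate per column, NA for degenerate
# replicates.
rds_i_on_chains <- function(g, d, smoothed = FALSE) {
  n <- nrow(g)
  prev <- g[-n, , drop = FALSE]
  cur <- g[-1, , drop = FALSE]
  t_aa <- colSums(prev & cur)
  t_ab <- colSums(prev & !cur)
  t_ba <- colSums(!prev & cur)
  t_bb <- colSums(!prev & !cur)
  if (smoothed) {
    s <- (t_ab + t_ba) / 2
    t_ab <- s
    t_ba <- s
  }
  row_a <- t_aa + t_ab
  row_b <- t_ba + t_bb
  s_ab <- t_ab / row_a
  s_ba <- t_ba / row_b
  inv_d <- 1 / d
  n_a <- colSums(g)
  n_b <- n - n_a
  d_a <- n_a / colSums(inv_d * g)
  d_b <- n_b / colSums(inv_d * (1 - g))
  p <- s_ba * d_b / (s_ab * d_a + s_ba * d_b)
  p[row_a == 0 | row_b == 0] <- NA # a group never recruited
  p[t_ab == 0 & t_ba == 0] <- NA # no cross-group recruitment
  p[n_a == 0] <- 0
  p[n_b == 0] <- 1
  p
}

#' Chain-structured bootstrap confidence interval for RDS estimators
#'
#' Each replicate regrows a pseudo-sample of the original size: the
#' chain starts from the group of a uniformly drawn seed, each
#' subsequent respondent's group is drawn from the observed recruitment
#' transition proportions, and the respondent's degree is resampled
#' with replacement from the empirical pool of that group. The chosen
#' estimator is applied to every replicate and the CI is the percentile
#' interval.
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param estimator `"rds_i"` or `"giles_ss"`.
#' @param reps bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param rng_seed integer seed; fixed seed gives identical intervals.
#' @param smoothed (rds_i) reciprocity-symmetrised transitions.
#' @param N,sim_reps,max_iter,tol (giles_ss) settings passed to the
#'   successive-sampling point estimator inside each replicate.
#' @return numeric `c(low, high)`. Attribute `failed` counts replicates
#'   on which the estimator was undefined; if more than 20% failed the
#'   interval carries attribute `unreliable = TRUE` and a warning is
#'   raised. A sample containing a single trait group returns the
#'   degenerate interval for that group's proportion.
#' @export
bootstrap_ci <- function(sample, trait, estimator = c("rds_i", "giles_ss"),
                         reps = 1000, level = 0.95, rng_seed = NULL,
                         smoothed = FALSE, N = NULL, sim_reps = 25,
                         max_iter = 2, tol = 5e-3) {
  stopifnot(inherits(sample, "rds_sample"))
  estimator <- match.arg(estimator)
  assert_scalar(reps, "reps", lower = 100, integerish = TRUE)
  assert_scalar(level, "level", lower = 0, upper = 1, strict_lower = TRUE,
    strict_upper = TRUE)
  t_v <- sample[[trait]]
  keep <- !is.na(t_v)
  t_v <- t_v[keep]
  d <- sample$degree[keep]
  is_seed <- is.na(sample$recruiter_id)[keep]
  n <- length(t_v)
  if (all(t_v == 1)) {
    return(structure(c(1, 1), failed = 0L))
  }
  if (all(t_v == 0)) {
    return(structure(c(0, 0), failed = 0L))
  }

  tm <- transition_matrix(sample, trait, smoothed = smoothed)
  # recruit-pool composition as fallback for a row whose group made no
  # recruitments
  pr <- recruitment_pairs(sample, trait)
  q_a <- mean(pr$recruit == 1)
  p_a_given_a <- if ("A" %in% tm$undefined_rows) q_a else tm$S["A", "A"]
  p_a_given_b <- if ("B" %in% tm$undefined_rows) q_a else tm$S["B", "A"]

  start_groups <- t_v[is_seed]
  if (length(start_groups) == 0) start_groups <- t_v
  pool_a <- d[t_v == 1]
  pool_b <- d[t_v == 0]
  if (!is.null(N)) assert_scalar(N, "N", lower = n + 1, integerish = TRUE)
  if (estimator == "giles_ss" && is.null(N)) {
    stop("giles_ss bootstrap requires the assumed population size N",
      call. = FALSE
    )
  }

  with_rng(rng_seed, {
    g <- simulate_group_chains(n, reps, p_a_given_a, p_a_given_b, start_groups)
    dm <- matrix(0, n, reps)
    n_in_a <- sum(g == 1L)
    dm[g == 1L] <- sample(pool_a, n_in_a, replace = TRUE)
    dm[g == 0L] <- sample(pool_b, length(g) - n_in_a, replace = TRUE)
    if (estimator == "rds_i") {
      p <- rds_i_on_chains(g, dm, smoothed = smoothed)
    } else {
      p <- vapply(seq_len(reps), function(r) {
        gr <- g[, r]
        if (all(gr == 1L)) return(1)
        if (all(gr == 0L)) return(0)
        tryCatch(
          ss_point(dm[, r], gr == 1L, N, sim_reps, max_iter, tol)$p,
          error = function(e) NA_real_
        )
      }, numeric(1))
    }
    failed <- sum(is.na(p))
    out <- percentile_interval(p, level)
    attr(out, "failed") <- failed
    if (failed > 0.2 * reps) {
      attr(out, "unreliable") <- TRUE
      warning(sprintf(
        "bootstrap CI unreliable: estimator failed on %d of %d replicates",
        failed, reps
      ), call. = FALSE)
    }
    out
  })
}
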