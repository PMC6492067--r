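#' Recruitment transition matrix
#'
#' Cross-tabulates recruiter group by recruit group for a binary trait
#' (group A = trait 1, group B = trait 0) and row-normalises to the
#' recruitment transition proportions S_XY used by the RDS-I
#' reciprocity identity. Seeds contribute only as recruiters; pairs with
#' a missing trait on either end are dropped.
#'
#' @param sample an [rds_sample()].
#' @param trait name of a binary trait column.
#' @param smoothed if `TRUE`, the off-diagonal counts are replaced by
#'   their mean `(t_AB + t_BA)/2` (reciprocity-symmetrised data
#'   smoothing) before normalising.
#' @return object of class `transition_matrix`: list with integer
#'   `counts` (2x2, rows = recruiter group), row-stochastic `S` (rows
#'   with zero recruitments are `NA` and listed in `undefined_rows`),
#'   `trait` and `smoothed`.
#' @export
transition_matrix <- function(sample, trait, smoothed = FALSE) {
  pr <- recruitment_pairs(sample, trait)
  if (nrow(pr) == 0) {
    stop("no recruitment pairs with observed trait `", trait, "`",
      call. = FALSE
    )
  }
  lv <- c(1, 0) # A, B
  counts <- table(
    factor(pr$recruiter, levels = lv),
    factor(pr$recruit, levels = lv)
  )
  counts <- matrix(as.integer(counts), 2, 2,
    dimnames = list(c("A", "B"), c("A", "B"))
  )
  eff <- counts
  if (smoothed) {
    s <- (counts["A", "B"] + counts["B", "A"]) / 2
    eff["A", "B"] <- s
    eff["B", "A"] <- s
  }
  rs <- rowSums(eff)
  S <- eff / ifelse(rs > 0, rs, NA)
  undefined <- rownames(S)[rs == 0]
  structure(
    list(
      counts = counts, S = S, trait = trait, smoothed = smoothed,
      undefined_rows = undefined
    ),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> trait:", x$trait,
    if (x$smoothed) "(smoothed)" else "", "\n"
  )
  print(round(x$S, 3))
  if (length(x$undefined_rows) > 0) {
    cat(
      " undefined row(s):", paste(x$undefined_rows, collapse = ", "),
      "(group made no recruitments)\n"
    )
  }
  invisible(x)
}

#' Harmonic mean degree of a trait group
#'
#' \eqn{D_X = n_X / \sum_{i \in X} 1/d_i}, the degree summary used by
#' the RDS-I estimator.
#'
#' @param sample an [rds_sample()], or a plain numeric vector of
#'   degrees (then `trait`/`group` are ignored).
#' @param trait name of the binary trait column.
#' @param group trait value selecting the group (1 = A, 0 = B).
#' @return positive scalar.
#' @export
harmonic_mean_degree <- function(sample, trait = NULL, group = 1) {
  if (is.numeric(sample)) {
    d <- sample
  } else {
    stopifnot(inherits(sample, "rds_sample"))
    d <- sample$degree[!is.na(sample[[trait]]) & sample[[trait]] == group]
  }
  if (length(d) == 0) stop("empty group: harmonic mean undefined", call. = FALSE)
  if (any(d < 1)) stop("degrees must be >= 1", call. = FALSE)
  length(d) / sum(1 / d)
}

new_proportion_estimate <- function(estimator, trait, p_hat, ci, n, reps,
                                    harmonic_degrees = c(NA_real_, NA_real_),
                                    reliable = TRUE, converged = NA,
                                    notes = character(0)) {
  structure(
    list(
      estimator = estimator, trait = trait, p_hat = p_hat, ci = ci,
      n = n, bootstrap_reps = reps, harmonic_degrees = harmonic_degrees,
      reliable = reliable, converged = converged, notes = notes
    ),
    class = "proportion_estimate"
  )
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf(
    "<proportion_estimate> %s of `%s`: %.4f", x$estimator, x$trait,
    x$p_hat
  ))
  if (!is.null(x$ci) && !any(is.na(x$ci))) {
    cat(sprintf(" (95%% CI %.4f-%.4f, %d bootstrap reps)", x$ci[1], x$ci[2],
      x$bootstrap_reps))
  }
  cat(sprintf(" [n = %d]\n", x$n))
  if (!x$reliable) cat(" ! flagged unreliable\n")
  if (length(x$notes) > 0) cat(" note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Point RDS-I estimate from pre-extracted vectors; returns NA when the
# reciprocity identity is undefined (a group absent from the recruiter
# pool or no cross-group recruitments at all).
rds_i_point <- function(sample, trait, smoothed = FALSE) {
  t_v <- sample[[trait]]
  keep <- !is.na(t_v)
  t_v <- t_v[keep]
  d <- sample$degree[keep]
  n_a <- sum(t_v == 1)
  n_b <- sum(t_v == 0)
  if (n_a == 0) return(0)
  if (n_b == 0) return(1)
  tm <- transition_matrix(sample, trait, smoothed = smoothed)
  if (length(tm$undefined_rows) > 0) return(NA_real_)
  s_ab <- tm$S["A", "B"]
  s_ba <- tm$S["B", "A"]
  if (s_ab + s_ba == 0) return(NA_real_)
  d_a <- n_a / sum(1 / d[t_v == 1])
  d_b <- n_b / sum(1 / d[t_v == 0])
  unname(s_ba * d_b / (s_ab * d_a + s_ba * d_b))
}

#' Salganik-Heckathorn (RDS-I) proportion estimator
#'
#' Estimates the population proportion of a binary trait from an RDS
#' sample through the tie-reciprocity balance
#' \deqn{\hat P_A = \frac{S_{BA} D_B}{S_{AB} D_A + S_{BA} D_B},}
#' where \eqn{S_{XY}} are recruitment transition proportions
#' ([transition_matrix()]) and \eqn{D_X} harmonic mean degrees
#' ([harmonic_mean_degree()]). The estimator is invariant to rescaling
#' all degrees by a common constant. Confidence intervals come from the
#' chain-structured bootstrap ([bootstrap_ci()]).
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param smoothed use reciprocity-symmetrised transition counts.
#' @param ci compute a bootstrap CI.
#' @param reps bootstrap replicates.
#' @param level confidence level.
#' @param rng_seed seed for the bootstrap.
#' @return a `proportion_estimate`. When a transition row is undefined
#'   (one group never recruited) the estimate is `NA` and flagged
#'   unreliable, mirroring provinces where the RDS estimator fails.
#' @export
rds_i_proportion <- function(sample, trait, smoothed = FALSE, ci = TRUE,
                             reps = 1000, level = 0.95, rng_seed = NULL) {
  stopifnot(inherits(sample, "rds_sample"))
  t_v <- sample[[trait]]
  keep <- !is.na(t_v)
  n_missing <- sum(!keep)
  n <- sum(keep)
  t_v <- t_v[keep]
  d <- sample$degree[keep]
  notes <- if (n_missing > 0) {
    sprintf("%d respondents with missing `%s` excluded", n_missing, trait)
  } else {
    character(0)
  }
  n_a <- sum(t_v == 1)
  n_b <- sum(t_v == 0)
  if (n_a == 0 || n_b == 0) {
    p <- as.numeric(n_a > 0)
    return(new_proportion_estimate("rds_i", trait, p, c(p, p), n, 0,
      notes = c(notes, "single-group sample")
    ))
  }
  d_a <- n_a / sum(1 / d[t_v == 1])
  d_b <- n_b / sum(1 / d[t_v == 0])
  p <- rds_i_point(sample, trait, smoothed = smoothed)
  reliable <- !is.na(p)
  if (!reliable) {
    notes <- c(notes, "transition matrix degenerate: estimate unreliable")
  }
  interval <- c(NA_real_, NA_real_)
  used_reps <- 0L
  if (ci && reliable) {
    interval <- bootstrap_ci(sample, trait,
      estimator = "rds_i", reps = reps,
      level = level, rng_seed = rng_seed, smoothed = smoothed
    )
    used_reps <- reps
    if (isTRUE(attr(interval, "unreliable"))) {
      reliable <- FALSE
      notes <- c(notes, "bootstrap unreliable (>20% replicate failures)")
    }
    interval <- c(min(interval[1], p), max(interval[2], p))
  }
  new_proportion_estimate("rds_i", trait, p, interval, n, used_reps,
    harmonic_degrees = c(D_A = d_a, D_B = d_b), reliable = reliable,
    notes = notes
  )
}

# Simulated per-degree-class inclusion probabilities under successive
# sampling (draws without replacement with probability proportional to
# degree). Unit-level exponential-race simulation for moderate
# populations; exact class-level sequential draws when the population
# is too large to materialise per-unit.
ss_inclusion_probs <- function(ud, n_d, n, reps) {
  k <- length(ud)
  n_pop <- sum(n_d)
  if (n >= n_pop) {
    return(rep(1, k))
  }
  cnt <- numeric(k)
  if (n_pop <= 2e5) {
    cls <- rep(seq_len(k), n_d)
    w <- rep(ud, n_d)
    for (r in seq_len(reps)) {
      t <- stats::rexp(n_pop) / w
      thr <- sort(t, partial = n)[n]
      sel <- which(t <= thr)
      if (length(sel) > n) sel <- sel[order(t[sel])][seq_len(n)]
      cnt <- cnt + tabulate(cls[sel], k)
    }
  } else {
    for (r in seq_len(reps)) {
      rem <- n_d
      for (i in seq_len(n)) {
        j <- sample.int(k, 1, prob = rem * ud)
        rem[j] <- rem[j] - 1
      }
      cnt <- cnt + (n_d - rem)
    }
  }
  pi_hat <- cnt / (reps * n_d)
  pmin(pmax(pi_hat, 0.5 / (reps * n_d)), 1)
}

# Successive-sampling point estimator: iterates between estimating the
# population degree distribution (weighting the sample distribution up
# to size N) and simulating inclusion probabilities under
# degree-proportional sampling without replacement from it.
ss_point <- function(d, is_a, N, sim_reps, max_iter, tol) {
  n <- length(d)
  ud <- sort(unique(d))
  n_d <- as.integer(table(factor(d, levels = ud)))
  w_d <- 1 / ud # initial weights proportional to 1/degree
  dist_old <- NULL
  converged <- FALSE
  pi_d <- NULL
  for (iter in seq_len(max_iter)) {
    mass <- n_d * w_d
    n_pop_d <- round_preserving_sum(N * mass / sum(mass), N)
    short <- n_pop_d < n_d
    if (any(short)) { # population must contain at least the sample
      n_pop_d[short] <- n_d[short]
      over <- sum(n_pop_d) - N
      if (over > 0) {
        slack <- n_pop_d - n_d
        take <- round_preserving_sum(slack * over / sum(slack), over)
        n_pop_d <- n_pop_d - pmin(take, slack)
      }
    }
    pi_d <- ss_inclusion_probs(ud, n_pop_d, n, sim_reps)
    w_d <- 1 / pi_d
    dist_new <- n_pop_d / sum(n_pop_d)
    if (!is.null(dist_old) && max(abs(dist_new - dist_old)) < tol) {
      converged <- TRUE
      break
    }
    dist_old <- dist_new
  }
  w_i <- w_d[match(d, ud)]
  list(
    p = sum(w_i[is_a]) / sum(w_i),
    pi_d = stats::setNames(pi_d, ud),
    converged = converged,
    iterations = iter
  )
}

#' Gile's successive-sampling (SS) proportion estimator
#'
#' Models RDS as sampling without replacement with probability
#' proportional to degree from a finite population of assumed size `N`.
#' Starting from weights proportional to `1/degree`, the estimator
#' alternates between (i) scaling the weighted sample degree
#' distribution up to a population of size `N` and (ii) estimating, by
#' Monte-Carlo simulation of successive sampling from that population,
#' the inclusion probability of each observed degree, until the
#' estimated degree distribution stabilises. The trait proportion is
#' the inclusion-probability-weighted sample proportion.
#'
#' @param sample an [rds_sample()].
#' @param trait binary trait column name.
#' @param N assumed population size (> sample size). In the multiplier
#'   workflow N is external (circular with the multiplier itself), so
#'   it is an explicit argument here; see [run_pipeline()] for the
#'   fixed-point option.
#' @param sim_reps successive-sampling simulation replicates per
#'   iteration.
#' @param max_iter maximum weight-refinement iterations.
#' @param tol convergence tolerance on the estimated population degree
#'   distribution (max absolute change in class proportions).
#' @param ci compute a chain-bootstrap CI (slower: the estimator is
#'   re-simulated inside every replicate, with `boot_sim_reps`
#'   replicates and at most `boot_max_iter` iterations each).
#' @param reps,level,rng_seed bootstrap settings.
#' @param boot_sim_reps,boot_max_iter reduced simulation effort used
#'   inside bootstrap replicates.
#' @return a `proportion_estimate` with the non-convergence flag in
#'   `converged`.
#' @export
giles_ss_proportion <- function(sample, trait, N, sim_reps = 200,
                                max_iter = 10, tol = 5e-3, ci = TRUE,
                                reps = 200, level = 0.95, rng_seed = NULL,
                                boot_sim_reps = 25, boot_max_iter = 2) {
  stopifnot(inherits(sample, "rds_sample"))
  t_v <- sample[[trait]]
  keep <- !is.na(t_v)
  n_missing <- sum(!keep)
  t_v <- t_v[keep]
  d <- sample$degree[keep]
  n <- length(d)
  assert_scalar(N, "N", integerish = TRUE)
  if (N <= n) stop("population size N must exceed the sample size", call. = FALSE)
  notes <- if (n_missing > 0) {
    sprintf("%d respondents with missing `%s` excluded", n_missing, trait)
  } else {
    character(0)
  }
  n_a <- sum(t_v == 1)
  if (n_a == 0 || n_a == n) {
    p <- as.numeric(n_a > 0)
    return(new_proportion_estimate("giles_ss", trait, p, c(p, p), n, 0,
      notes = c(notes, "single-group sample")
    ))
  }
  fit <- with_rng(rng_seed, ss_point(d, t_v == 1, N, sim_reps, max_iter, tol))
  if (!fit$converged) {
    notes <- c(notes, sprintf(
      "degree-distribution iteration did not converge in %d iterations",
      max_iter
    ))
  }
  interval <- c(NA_real_, NA_real_)
  used_reps <- 0L
  reliable <- TRUE
  if (ci) {
    interval <- bootstrap_ci(sample, trait,
      estimator = "giles_ss", reps = reps, level = level,
      rng_seed = if (is.null(rng_seed)) NULL else rng_seed + 1L,
      N = N, sim_reps = boot_sim_reps, max_iter = boot_max_iter, tol = tol
    )
    used_reps <- reps
    if (isTRUE(attr(interval, "unreliable"))) {
      reliable <- FALSE
      notes <- c(notes, "bootstrap unreliable (>20% replicate failures)")
    }
    interval <- c(min(interval[1], fit$p), max(interval[2], fit$p))
  }
  new_proportion_estimate("giles_ss", trait, fit$p, interval, n, used_reps,
    reliable = reliable, converged = fit$converged, notes = notes
  )
}
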