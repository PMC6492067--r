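#' Specification of a synthetic two-group population
#'
#' Defines the study conditions for the simulator: a population of `N`
#' individuals split into group A (app users, fraction `prevalence`) and
#' group B, connected by a degree-corrected two-group mixing network,
#' sampled by coupon-limited RDS recruitment.
#'
#' @param N population size.
#' @param prevalence fraction of the population in group A, strictly
#'   between 0 and 1.
#' @param degree_mean mean of the negative-binomial degree distribution
#'   (>= 1).
#' @param degree_dispersion negative-binomial size (dispersion)
#'   parameter; smaller values give heavier tails.
#' @param homophily_w within-group tie preference: the odds of a
#'   within-group tie relative to random mixing. 1 = random mixing.
#' @param seed_count number of RDS seeds.
#' @param coupon_limit recruitment coupons per respondent (0 allowed for
#'   a seeds-only sample; surveys of this design hand out 3).
#' @param sample_target desired RDS sample size (< N).
#' @param seed_bias optional fraction of seeds forced into group A;
#'   `NULL` draws seeds uniformly from the population.
#' @param rng_seed integer seed driving every random draw downstream.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(N, prevalence, degree_mean = 10,
                            degree_dispersion = 2, homophily_w = 1,
                            seed_count = 6, coupon_limit = 3,
                            sample_target = 400, seed_bias = NULL,
                            rng_seed = 1L) {
  assert_scalar(N, "N", lower = 2, integerish = TRUE)
  assert_scalar(prevalence, "prevalence",
    lower = 0, upper = 1,
    strict_lower = TRUE, strict_upper = TRUE
  )
  assert_scalar(degree_mean, "degree_mean", lower = 1)
  if (degree_mean >= N) {
    stop("infeasible spec: degree_mean must be smaller than N", call. = FALSE)
  }
  assert_scalar(degree_dispersion, "degree_dispersion",
    lower = 0, strict_lower = TRUE
  )
  assert_scalar(homophily_w, "homophily_w", lower = 0, strict_lower = TRUE)
  assert_scalar(seed_count, "seed_count", lower = 1, integerish = TRUE)
  assert_scalar(coupon_limit, "coupon_limit", lower = 0, integerish = TRUE)
  assert_scalar(sample_target, "sample_target", lower = 1, integerish = TRUE)
  if (sample_target >= N) {
    stop("sample_target must be smaller than N", call. = FALSE)
  }
  if (!is.null(seed_bias)) {
    assert_scalar(seed_bias, "seed_bias", lower = 0, upper = 1)
  }
  assert_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(
    list(
      N = as.integer(N), prevalence = prevalence,
      degree_mean = degree_mean, degree_dispersion = degree_dispersion,
      homophily_w = homophily_w, seed_count = as.integer(seed_count),
      coupon_limit = as.integer(coupon_limit),
      sample_target = as.integer(sample_target), seed_bias = seed_bias,
      rng_seed = as.integer(rng_seed)
    ),
    class = "population_spec"
  )
}

#' Generate a two-group social network
#'
#' Draws target degrees from a zero-truncated negative binomial, assigns
#' exactly `round(N * prevalence)` nodes to group A, and places edges by
#' degree-weighted stub matching in which the probability mass of the
#' within-group edge categories (A-A and B-B) is multiplied by
#' `homophily_w` relative to random mixing. Self-loops and duplicate
#' edges are discarded; nodes left isolated are re-attached to one
#' partner so the realised minimum degree is 1.
#'
#' @param spec a [population_spec()].
#' @return object of class `sim_network`: list with `group` (factor
#'   A/B per node), `adjacency` (list of integer neighbour vectors),
#'   `degree` (realised degrees), `edges` (2-column matrix) and `truth`
#'   (realised prevalence, mean degree per group, edge count,
#'   within-group edge fraction).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_rng(spec$rng_seed, {
    N <- spec$N
    deg <- stats::rnbinom(N, mu = spec$degree_mean, size = spec$degree_dispersion)
    deg[deg < 1] <- 1

    n_a <- round(N * spec$prevalence)
    if (n_a < 1 || n_a > N - 1) {
      stop("prevalence leaves one group empty at this N", call. = FALSE)
    }
    group <- factor(rep("B", N), levels = c("A", "B"))
    group[sample.int(N, n_a)] <- "A"
    a_nodes <- which(group == "A")
    b_nodes <- which(group == "B")

    m_a <- sum(deg[a_nodes])
    m_b <- sum(deg[b_nodes])
    n_edges <- round(sum(deg) / 2)
    w <- spec$homophily_w
    cat_w <- c(aa = w * m_a^2, bb = w * m_b^2, ab = 2 * m_a * m_b)
    n_cat <- stats::rmultinom(1, n_edges, cat_w / sum(cat_w))[, 1]

    draw <- function(nodes, k) {
      sample(nodes, k, replace = TRUE, prob = deg[nodes])
    }
    edges <- rbind(
      matrix(draw(a_nodes, 2 * n_cat[["aa"]]), ncol = 2),
      matrix(draw(b_nodes, 2 * n_cat[["bb"]]), ncol = 2),
      cbind(draw(a_nodes, n_cat[["ab"]]), draw(b_nodes, n_cat[["ab"]]))
    )
    lo <- pmin(edges[, 1], edges[, 2])
    hi <- pmax(edges[, 1], edges[, 2])
    keep <- lo != hi & !duplicated(lo * (N + 1) + hi)
    edges <- cbind(lo[keep], hi[keep])

    # guarantee minimum realised degree 1
    touched <- unique(c(edges))
    isolated <- setdiff(seq_len(N), touched)
    if (length(isolated) > 0) {
      extra <- vapply(isolated, function(i) {
        own <- if (group[i] == "A") a_nodes else b_nodes
        oth <- if (group[i] == "A") b_nodes else a_nodes
        m_own <- sum(deg[own])
        m_oth <- sum(deg[oth])
        if (stats::runif(1) < w * m_own / (w * m_own + m_oth)) {
          p <- draw(setdiff(own, i), 1)
        } else {
          p <- draw(oth, 1)
        }
        p
      }, numeric(1))
      edges <- rbind(edges, cbind(
        pmin(isolated, extra),
        pmax(isolated, extra)
      ))
      edges <- edges[!duplicated(edges[, 1] * (N + 1) + edges[, 2]), ,
        drop = FALSE
      ]
    }

    adjacency <- vector("list", N)
    nb <- split(
      c(edges[, 2], edges[, 1]),
      factor(c(edges[, 1], edges[, 2]), levels = seq_len(N))
    )
    adjacency <- unname(lapply(nb, as.integer))
    degree <- unname(lengths(adjacency))

    same <- group[edges[, 1]] == group[edges[, 2]]
    truth <- list(
      true_N = N,
      true_prevalence_A = n_a / N,
      true_mean_degree_by_group = c(
        A = mean(degree[a_nodes]),
        B = mean(degree[b_nodes])
      ),
      network_edge_count = nrow(edges),
      within_group_edge_fraction = mean(same)
    )
    structure(
      list(
        group = group, adjacency = adjacency, degree = degree,
        edges = edges, spec = spec, truth = truth
      ),
      class = "sim_network"
    )
  })
}

#' @export
print.sim_network <- function(x, ...) {
  cat(
    "<sim_network> N =", length(x$group), "| edges =",
    x$truth$network_edge_count, "| prevalence A =",
    signif(x$truth$true_prevalence_A, 3), "| within-group edge fraction =",
    signif(x$truth$within_group_edge_fraction, 3), "\n"
  )
  invisible(x)
}

#' Simulate coupon-limited RDS recruitment on a network
#'
#' Seeds are drawn (optionally biased toward group A), then respondents
#' recruit uniformly at random among their not-yet-sampled neighbours,
#' up to `coupon_limit` recruits each, in first-come-first-served wave
#' order, without replacement, until `sample_target` respondents are
#' reached or every chain has died.
#'
#' @param network a `sim_network` from [generate_network()].
#' @param spec the [population_spec()]; `spec$rng_seed + 1` seeds the
#'   recruitment draws so network and chains are independently
#'   reproducible.
#' @param province label stored on every respondent.
#' @param degree_noise_sd standard deviation of optional multiplicative
#'   log-normal noise on reported degrees (0 = truthful reporting).
#' @param ever_use_rate_b fraction of group-B members reporting having
#'   ever used the app (group A always reports ever-use).
#' @return an [rds_sample()] with traits `app_30d` (group A membership)
#'   and `app_ever`, plus `age` and `province`; the network truth is
#'   attached as attribute `"truth"`. A warning is raised if recruitment
#'   dies before reaching half of `sample_target`.
#' @export
simulate_rds <- function(network, spec = network$spec,
                         province = "SimProvince", degree_noise_sd = 0,
                         ever_use_rate_b = 0.28) {
  stopifnot(inherits(network, "sim_network"))
  stopifnot(inherits(spec, "population_spec"))
  N <- length(network$group)
  if (spec$sample_target > N) {
    stop("sample_target exceeds network size", call. = FALSE)
  }
  with_rng(spec$rng_seed + 1L, {
    n_seed <- min(spec$seed_count, spec$sample_target)
    if (!is.null(spec$seed_bias)) {
      n_a_seed <- round(n_seed * spec$seed_bias)
      a_pool <- which(network$group == "A")
      b_pool <- which(network$group == "B")
      seeds <- c(
        sample(a_pool, min(n_a_seed, length(a_pool))),
        sample(b_pool, min(n_seed - n_a_seed, length(b_pool)))
      )
    } else {
      seeds <- sample.int(N, n_seed)
    }

    sampled <- logical(N)
    sampled[seeds] <- TRUE
    node <- integer(spec$sample_target)
    recruiter <- integer(spec$sample_target)
    node[seq_along(seeds)] <- seeds
    recruiter[seq_along(seeds)] <- NA_integer_
    n_got <- length(seeds)
    head <- 1L
    while (head <= n_got && n_got < spec$sample_target) {
      r <- node[head]
      nbrs <- network$adjacency[[r]]
      free <- nbrs[!sampled[nbrs]]
      k <- min(spec$coupon_limit, length(free), spec$sample_target - n_got)
      if (k > 0) {
        rec <- if (length(free) == 1) free else sample(free, k)
        rec <- rec[seq_len(k)]
        sampled[rec] <- TRUE
        node[n_got + seq_len(k)] <- rec
        recruiter[n_got + seq_len(k)] <- r
        n_got <- n_got + k
      }
      head <- head + 1L
    }
    node <- node[seq_len(n_got)]
    recruiter <- recruiter[seq_len(n_got)]
    if (n_got < spec$sample_target / 2) {
      warning(sprintf(
        "recruitment chains died at n = %d (< 50%% of target %d); partial sample returned",
        n_got, spec$sample_target
      ), call. = FALSE)
    }

    deg <- network$degree[node]
    if (degree_noise_sd > 0) {
      deg <- pmax(1, round(deg * stats::rlnorm(n_got, 0, degree_noise_sd)))
    }
    app_30d <- as.integer(network$group[node] == "A")
    app_ever <- pmax(
      app_30d,
      as.integer(stats::runif(n_got) < ever_use_rate_b)
    )
    age <- pmin(49, pmax(18, round(18 + stats::rgamma(n_got, shape = 2, scale = 3.5))))

    out <- rds_sample(
      data.frame(
        id = node,
        recruiter_id = recruiter,
        recruitment_order = seq_len(n_got),
        degree = deg,
        app_30d = app_30d,
        app_ever = app_ever,
        age = age,
        province = province
      ),
      traits = c("app_30d", "app_ever")
    )
    attr(out, "truth") <- network$truth
    out
  })
}

#' Simulate a multi-day app activity log
#'
#' Each resident member logs in independently on each day with a
#' group-specific probability (by default only group A, the app users,
#' generate sightings); transient "visitor" profiles, which should be
#' removed by deduplication, each appear on exactly one day.
#'
#' @param network a `sim_network`.
#' @param spec the [population_spec()]; `spec$rng_seed + 2` seeds the
#'   log.
#' @param days observation window length in days (>= 2).
#' @param daily_login_prob_by_group length-2 vector of daily login
#'   probabilities for groups A and B.
#' @param visitor_rate expected number of new one-day visitor profiles
#'   per day (Poisson).
#' @param period_start first calendar day of the window.
#' @return an [activity_log()] with one row per (profile, active day).
#' @export
simulate_activity_log <- function(network, spec = network$spec, days = 30,
                                  daily_login_prob_by_group = c(0.3, 0),
                                  visitor_rate = 2,
                                  period_start = as.Date("2024-06-01")) {
  stopifnot(inherits(network, "sim_network"))
  assert_scalar(days, "days", lower = 2, integerish = TRUE)
  if (length(daily_login_prob_by_group) != 2 ||
    any(daily_login_prob_by_group < 0 | daily_login_prob_by_group > 1)) {
    stop("daily_login_prob_by_group must be two probabilities in [0, 1]",
      call. = FALSE
    )
  }
  assert_scalar(visitor_rate, "visitor_rate", lower = 0)
  with_rng(spec$rng_seed + 2L, {
    rows <- list()
    for (g in c("A", "B")) {
      p <- daily_login_prob_by_group[if (g == "A") 1 else 2]
      if (p <= 0) next
      members <- which(network$group == g)
      hit <- which(stats::runif(length(members) * days) < p) - 1L
      rows[[g]] <- data.frame(
        profile_id = sprintf("u%06d", members[hit %% length(members) + 1L]),
        date = period_start + hit %/% length(members)
      )
    }
    n_vis <- stats::rpois(1, visitor_rate * days)
    if (n_vis > 0) {
      rows[["v"]] <- data.frame(
        profile_id = sprintf("v%06d", seq_len(n_vis)),
        date = period_start + sample.int(days, n_vis, replace = TRUE) - 1L
      )
    }
    df <- if (length(rows) > 0) {
      do.call(rbind, rows)
    } else {
      data.frame(profile_id = character(0), date = as.Date(character(0)))
    }
    df <- df[order(df$date, df$profile_id), , drop = FALSE]
    rownames(df) <- NULL
    activity_log(df,
      period_start = period_start,
      period_end = period_start + days - 1
    )
  })
}

#' Ground truth of a simulated network or sample
#'
#' @param x a `sim_network` or a simulated [rds_sample()].
#' @return list with `true_N`, `true_prevalence_A`,
#'   `true_mean_degree_by_group`, `network_edge_count`.
#' @export
sim_truth <- function(x) {
  t <- if (inherits(x, "sim_network")) x$truth else attr(x, "truth")
  if (is.null(t)) stop("no simulation truth attached", call. = FALSE)
  t
}
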