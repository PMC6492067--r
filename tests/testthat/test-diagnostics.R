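test_that("homophily matches hand computation and its limits", {
  # fixture pairs: (A->A) x4, (A->B) x1, (B->B) x1, (B->A) x4
  pairs <- data.frame(
    recruiter = c(rep(1, 5), rep(0, 5)),
    recruit = c(rep(1, 4), 0, 0, rep(1, 4))
  )
  s <- sample_from_pairs(pairs)
  # hand: observed same = 5; recruit pool 8 A of 10 -> expected
  # 5 * 0.8 + 5 * 0.2 = 5
  expect_equal(homophily(s, "trait"), 5 / 5)
  # perfectly assortative recruitment exceeds 1
  pairs_h <- data.frame(
    recruiter = c(1, 1, 1, 0, 0),
    recruit = c(1, 1, 1, 0, 0)
  )
  expect_gt(homophily(sample_from_pairs(pairs_h), "trait"), 1)
  # random referral in a large simulated sample sits near 1
  st <- sim_setup(31)
  expect_lt(abs(homophily(st$sample, "app_30d") - 1), 0.1)
  expect_error(homophily(chain_sample(1), "trait"), "undefined")
})

test_that("homophily has mean 1 under a permutation null", {
  st <- sim_setup(32, N = 2000, sample_target = 300)
  df <- as.data.frame(st$sample)
  vals <- vapply(1:200, function(i) {
    d2 <- df
    d2$trait_perm <- sample(df$app_30d)
    homophily(rds_sample(d2), "trait_perm")
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se + 0.01)
})

test_that("convergence rule follows the stability window", {
  # constant series converges
  s <- chain_sample(rep(c(1, 0), 40), degree = rep(3, 80))
  cc <- convergence_check(s, "trait", estimator = "crude")
  expect_true(cc$converged)
  # a late jump larger than the tolerance fails
  tr <- c(rep(c(1, 0), 30), rep(1, 20)) # drifts upward at the end
  s2 <- chain_sample(tr, degree = rep(3, 80))
  cc2 <- convergence_check(s2, "trait", estimator = "crude", tol = 0.02)
  expect_false(cc2$converged)
  # tol = 1 accepts anything; tol = 0 only an exactly constant window
  expect_true(convergence_check(s2, "trait", estimator = "crude", tol = 1)$converged)
  expect_false(convergence_check(s2, "trait", estimator = "crude", tol = 0)$converged)
  s_const <- chain_sample(rep(1, 60), degree = rep(3, 60))
  expect_true(
    convergence_check(s_const, "trait", estimator = "crude", tol = 0)$converged
  )
  expect_true(all(cc$series$estimate >= 0 & cc$series$estimate <= 1))
})

test_that("cumulative series equals per-prefix recomputation", {
  st <- sim_setup(33, N = 2000, sample_target = 150)
  ser <- convergence_check(st$sample, "app_30d", estimator = "rds_i")$series
  df <- as.data.frame(st$sample)
  for (k in c(60, 100, 150)) {
    direct <- rds_i_proportion(
      rds_sample(df[seq_len(k), , drop = FALSE]),
      "app_30d",
      ci = FALSE
    )$p_hat
    expect_equal(ser$estimate[ser$n == k], direct, tolerance = 1e-10)
  }
})

test_that("strong homophily with opposed seeds disrupts convergence", {
  conv <- function(w, i) {
    spec <- population_spec(
      N = 4000, prevalence = 0.5, homophily_w = w,
      seed_count = 2, seed_bias = 0.5, sample_target = 250,
      rng_seed = 6000 + i
    )
    s <- suppressWarnings(simulate_rds(generate_network(spec)))
    if (nrow(s) < 50) {
      return(NA)
    }
    isTRUE(convergence_check(s, "app_30d", estimator = "crude")$converged)
  }
  base <- vapply(1:30, function(i) conv(1, i), logical(1))
  homo <- vapply(1:30, function(i) conv(12, i), logical(1))
  expect_lt(mean(homo, na.rm = TRUE), mean(base, na.rm = TRUE))
})

test_that("bottleneck gap separates mixed and segregated seeds", {
  # two seeds with identical subtree composition -> gap 0
  df <- data.frame(
    id = 1:8,
    recruiter_id = c(NA, NA, 1, 2, 3, 4, 5, 6),
    degree = 2,
    trait = c(1, 1, 0, 0, 1, 1, 0, 0)
  )
  bn <- bottleneck_series(rds_sample(df), "trait")
  expect_equal(unname(bn$gap), 0)
  expect_false(bn$bottleneck)
  # pure-A and pure-B subtrees -> gap 1
  df2 <- data.frame(
    id = 1:8,
    recruiter_id = c(NA, NA, 1, 2, 3, 4, 5, 6),
    degree = 2,
    trait = c(1, 0, 1, 0, 1, 0, 1, 0)
  )
  bn2 <- bottleneck_series(rds_sample(df2), "trait")
  expect_equal(unname(bn2$gap), 1)
  expect_true(bn2$bottleneck)
})

test_that("community structure widens the bottleneck gap", {
  gap <- function(w, i) {
    spec <- population_spec(
      N = 4000, prevalence = 0.5, homophily_w = w,
      seed_count = 2, seed_bias = 0.5, sample_target = 250,
      rng_seed = 7000 + i
    )
    s <- suppressWarnings(simulate_rds(generate_network(spec)))
    bottleneck_series(s, "app_30d")$gap
  }
  base <- vapply(1:15, function(i) gap(1, i), numeric(1))
  homo <- vapply(1:15, function(i) gap(12, i), numeric(1))
  expect_gt(mean(homo, na.rm = TRUE), mean(base, na.rm = TRUE))
})

test_that("sensitivity screen uses inclusive bounds", {
  expect_true(sensitivity_check(0.35))
  expect_false(sensitivity_check(0.15))
  expect_true(sensitivity_check(0.2))
  expect_true(sensitivity_check(0.8))
  expect_false(sensitivity_check(0.81))
  # widening the bounds never flips not-sensitive into sensitive
  for (p in seq(0, 1, by = 0.05)) {
    if (sensitivity_check(p, 0.2, 0.8)) {
      expect_true(sensitivity_check(p, 0.1, 0.9))
    }
  }
})

test_that("estimator selection follows the homophily vs convergence rule", {
  mk <- function(h, conv) {
    list(homophily_value = h, converged = conv)
  }
  # 4 provinces homophily < 1, 2 not converged -> rds_i
  reports <- c(
    lapply(c(0.8, 0.9, 0.7, 0.95), mk, conv = TRUE),
    lapply(c(1.2, 1.1), mk, conv = FALSE)
  )
  sel <- select_estimator(reports)
  expect_equal(sel$estimator, "rds_i")
  expect_equal(sel$n_homophily_lt1, 4)
  expect_equal(sel$n_not_converged, 2)
  # tie (0, 0) -> giles_ss
  sel0 <- select_estimator(list(mk(1.5, TRUE)))
  expect_equal(sel0$estimator, "giles_ss")
  expect_match(sel0$rationale, "tie")
  # 1 vs 3 -> giles_ss
  reports2 <- c(
    list(mk(0.9, FALSE)),
    lapply(1:2, function(i) mk(1.2, FALSE)),
    list(mk(1.3, TRUE))
  )
  expect_equal(select_estimator(reports2)$estimator, "giles_ss")
})

test_that("group comparisons reproduce the textbook statistics", {
  # identical group means -> t = 0, pooled df = n1 + n2 - 2
  df <- data.frame(
    id = 1:12, recruiter_id = c(NA, 1:11), degree = 2,
    g = rep(c(1, 0), 6), y = rep(c(3, 5, 7), 4)
  )
  s <- rds_sample(df, traits = "g")
  tt <- compare_groups(s, "g", "y")
  expect_equal(tt$test, "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$df, 10)
  # chi-square on table ((30,70),(60,40)) vs direct sum((O-E)^2/E)
  g <- rep(c(1, 0), c(100, 100))
  y <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(60, 40)))
  df2 <- data.frame(
    id = 1:200, recruiter_id = c(NA, 1:199), degree = 2,
    g = g, y = y
  )
  s2 <- rds_sample(df2)
  ct <- compare_groups(s2, "g", "y")
  o <- c(30, 70, 60, 40)
  e <- c(45, 55, 45, 55)
  expect_equal(ct$test, "chisq")
  expect_equal(ct$statistic, sum((o - e)^2 / e))
  expect_equal(ct$df, 1)
  # identical row proportions -> chi-square 0
  df3 <- df2
  df3$y <- rep(c(1, 0, 1, 0), c(30, 70, 30, 70))
  expect_equal(compare_groups(rds_sample(df3), "g", "y")$statistic, 0)
  # zero-variance continuous outcome is an error
  df4 <- df
  df4$y <- 5
  expect_error(compare_groups(rds_sample(df4, traits = "g"), "g", "y"), "variance")
})

test_that("diagnose bundles the battery into one report", {
  st <- sim_setup(61)
  rep <- diagnose(st$sample, "app_30d")
  expect_s3_class(rep, "diagnostics_report")
  expect_true(is.numeric(rep$homophily_value))
  expect_true(is.logical(rep$converged) || is.na(rep$converged))
  expect_true(all(rep$convergence_series$estimate >= 0 &
    rep$convergence_series$estimate <= 1))
  expect_gte(length(rep$bottleneck_series), 2)
})
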