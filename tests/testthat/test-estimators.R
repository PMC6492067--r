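test_that("transition matrix counts and normalises recruitment pairs", {
  # all recruits in the recruiter's own group
  s <- chain_sample(c(1, 1, 1, 0, 0), n_seeds = 4)
  # build explicit same-group pairs instead
  pairs <- data.frame(recruiter = c(1, 1, 0, 0), recruit = c(1, 1, 0, 0))
  tm <- transition_matrix(sample_from_pairs(pairs), "trait")
  expect_equal(unname(tm$S["A", "A"]), 1)
  expect_equal(unname(tm$S["B", "B"]), 1)

  pairs2 <- data.frame(
    recruiter = c(rep(1, 4), rep(0, 4)),
    recruit = c(1, 1, 1, 0, 1, 1, 0, 0)
  ) # counts ((3,1),(2,2))
  tm2 <- transition_matrix(sample_from_pairs(pairs2), "trait")
  expect_equal(unname(tm2$S["A", "B"]), 0.25)
  expect_equal(unname(tm2$S["B", "A"]), 0.5)
  expect_equal(unname(rowSums(tm2$counts)), c(4, 4))

  # a group with no recruitments is flagged undefined
  pairs3 <- data.frame(recruiter = c(1, 1), recruit = c(1, 0))
  tm3 <- transition_matrix(sample_from_pairs(pairs3), "trait")
  expect_equal(tm3$undefined_rows, "B")
  expect_true(all(is.na(tm3$S["B", ])))
})

test_that("transition proportions reflect pool composition without homophily", {
  st <- sim_setup(17)
  tm <- transition_matrix(st$sample, "app_30d")
  prev_b <- 1 - sim_truth(st$net)$true_prevalence_A
  expect_lt(abs(unname(tm$S["A", "B"]) - prev_b), 0.1)
})

test_that("harmonic mean degree follows its formula", {
  expect_equal(harmonic_mean_degree(c(2, 2, 2)), 2)
  expect_equal(harmonic_mean_degree(c(1, 4)), 1.6)
  d <- c(1, 3, 7, 12)
  expect_lte(harmonic_mean_degree(d), mean(d))
  s <- worked_sample_12()
  expect_equal(
    harmonic_mean_degree(s, "app_30d", 1),
    harmonic_mean_degree(s$degree[s$app_30d == 1])
  )
  expect_error(harmonic_mean_degree(numeric(0)), "empty")
})

test_that("RDS-I matches independent hand evaluation on the worked sample", {
  s <- worked_sample_12()
  # hand-tallied recruitment pairs: A->A 4, A->B 1, B->A 2, B->B 3
  s_ab <- 1 / 5
  s_ba <- 2 / 5
  d_a <- 7 / sum(1 / c(2, 3, 8, 4, 10, 2, 6))
  d_b <- 5 / sum(1 / c(4, 6, 2, 5, 4))
  expected <- s_ba * d_b / (s_ab * d_a + s_ba * d_b)
  est <- rds_i_proportion(s, "app_30d", ci = FALSE)
  expect_equal(est$p_hat, expected, tolerance = 1e-12)
  expect_equal(unname(est$harmonic_degrees), c(d_a, d_b), tolerance = 1e-12)
})

test_that("RDS-I honours symmetry, degeneracy and scale invariance", {
  # single group
  s1 <- chain_sample(rep(1, 6), degree = c(2, 5, 3, 8, 1, 4))
  expect_equal(rds_i_proportion(s1, "trait", ci = FALSE)$p_hat, 1)
  # symmetric transitions with equal constant degrees -> 0.5
  pairs <- data.frame(
    recruiter = c(1, 1, 0, 0),
    recruit = c(1, 0, 0, 1)
  )
  s2 <- sample_from_pairs(pairs, degree = 3)
  expect_equal(rds_i_proportion(s2, "trait", ci = FALSE)$p_hat, 0.5)
  # rescaling all degrees by a common constant leaves the estimate alone
  s <- worked_sample_12()
  s_scaled <- as.data.frame(s)
  s_scaled$degree <- s_scaled$degree * 7
  expect_equal(
    rds_i_proportion(rds_sample(s_scaled), "app_30d", ci = FALSE)$p_hat,
    rds_i_proportion(s, "app_30d", ci = FALSE)$p_hat
  )
  # complement trait: estimates sum to one
  s_c <- as.data.frame(s)
  s_c$not_app <- 1 - s_c$app_30d
  s_c <- rds_sample(s_c)
  expect_equal(
    rds_i_proportion(s_c, "app_30d", ci = FALSE)$p_hat +
      rds_i_proportion(s_c, "not_app", ci = FALSE)$p_hat,
    1
  )
  # perfectly homophilous recruitment leaves the identity undefined
  pairs_h <- data.frame(recruiter = c(1, 1, 0, 0), recruit = c(1, 1, 0, 0))
  est_h <- rds_i_proportion(sample_from_pairs(pairs_h), "trait", ci = FALSE)
  expect_true(is.na(est_h$p_hat))
  expect_false(est_h$reliable)
})

test_that("Gile's SS reduces to known limits", {
  # equal degrees: inclusion probabilities constant, crude proportion
  s <- chain_sample(c(1, 0, 1, 1, 0, 0, 1, 0), degree = rep(4, 8))
  est <- giles_ss_proportion(s, "trait", N = 500, ci = FALSE, rng_seed = 1)
  expect_equal(est$p_hat, 0.5)
  # huge N: approaches the degree-weighted Hajek estimate
  set.seed(99)
  n <- 200
  d <- pmax(1, stats::rnbinom(n, mu = 10, size = 2))
  tr <- stats::rbinom(n, 1, stats::plogis((d - mean(d)) / stats::sd(d)))
  s2 <- chain_sample(tr, degree = d, n_seeds = 3)
  hajek <- sum((1 / d)[tr == 1]) / sum(1 / d)
  est2 <- giles_ss_proportion(s2, "trait",
    N = 1e6, sim_reps = 200, ci = FALSE,
    rng_seed = 2
  )
  expect_lt(abs(est2$p_hat - hajek), 0.02)
  # complement trait sums to one
  s3 <- as.data.frame(s2)
  s3$not_trait <- 1 - s3$trait
  s3 <- rds_sample(s3)
  pa <- giles_ss_proportion(s3, "trait", N = 5000, ci = FALSE, rng_seed = 4)$p_hat
  pb <- giles_ss_proportion(s3, "not_trait", N = 5000, ci = FALSE, rng_seed = 4)$p_hat
  expect_equal(pa + pb, 1, tolerance = 1e-10)
  expect_error(
    giles_ss_proportion(s, "trait", N = 8, ci = FALSE),
    "exceed"
  )
})

test_that("both estimators recover the true prevalence under random mixing", {
  nrun <- 50
  rdsi <- ss <- numeric(nrun)
  for (i in seq_len(nrun)) {
    st <- sim_setup(2000 + i)
    rdsi[i] <- rds_i_proportion(st$sample, "app_30d", ci = FALSE)$p_hat
    ss[i] <- giles_ss_proportion(st$sample, "app_30d",
      N = 10000,
      sim_reps = 100, max_iter = 5, ci = FALSE, rng_seed = i
    )$p_hat
  }
  expect_lt(abs(mean(rdsi) - 0.35), 0.03)
  expect_lt(abs(mean(ss) - 0.35), 0.03)
})

test_that("degree-adjusted estimators beat the crude proportion on a degree-linked trait", {
  # chain-referral sampling reaches high-degree nodes first, so the
  # crude proportion of a degree-linked trait is badly biased; the
  # degree-adjusted estimators should correct most of that bias
  nrun <- 30
  err <- matrix(NA_real_, nrun, 3)
  for (i in seq_len(nrun)) {
    st <- sim_setup(4000 + i, N = 5000, sample_target = 300)
    cutoff <- stats::quantile(st$net$degree, 0.65)
    truth <- mean(st$net$degree > cutoff)
    df <- as.data.frame(st$sample)
    df$high_degree <- as.integer(st$net$degree[df$id] > cutoff)
    s <- rds_sample(df)
    err[i, ] <- abs(c(
      rds_i_proportion(s, "high_degree", ci = FALSE)$p_hat,
      giles_ss_proportion(s, "high_degree",
        N = 5000, sim_reps = 100,
        max_iter = 5, ci = FALSE, rng_seed = i
      )$p_hat,
      mean(df$high_degree)
    ) - truth)
  }
  expect_lt(mean(err[, 1]), mean(err[, 3]))
  expect_lt(mean(err[, 2]), mean(err[, 3]))
})
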