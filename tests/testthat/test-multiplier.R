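prop <- function(p, lo = NA, hi = NA) list(p_hat = p, ci = c(lo, hi))

test_that("multiplier division and rounding follow the reporting rule", {
  est <- multiplier_estimate(provider_count(260), prop(0.35, 0.23, 0.47))
  expect_equal(est$N_hat, 743) # 260 / 0.35 = 742.857...
  expect_equal(multiplier_estimate(500, prop(1))$N_hat, 500)
  # direct division of printed inputs, bound-wise
  est2 <- multiplier_estimate(provider_count(360), prop(0.42, 0.28, 0.55))
  expect_equal(est2$N_hat, 857)
  expect_equal(est2$ci, c(655, 1286))
  expect_error(multiplier_estimate(100, prop(0)), "undefined")
  est3 <- multiplier_estimate(100, prop(0.5, 0, 0.9))
  expect_true(is.infinite(est3$ci[2]))
})

test_that("multiplier is homogeneous in the count and orders its bounds", {
  p <- prop(0.37, 0.21, 0.52)
  e1 <- multiplier_estimate(400, p)
  e2 <- multiplier_estimate(800, p)
  expect_equal(e2$N_hat, 2 * e1$N_hat, tolerance = 1e-3)
  expect_equal(e2$ci, 2 * e1$ci, tolerance = 1e-3)
  expect_true(e1$ci[1] <= e1$N_hat && e1$N_hat <= e1$ci[2])
  # dividing by the larger proportion bound gives the smaller bound
  expect_lt(400 / p$ci[2], 400 / p$ci[1])
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(742.5), 743)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.4), 2)
})

bands <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")

test_that("age-weighted percentage matches hand computation", {
  pop <- stats::setNames(rep(10000, 7), bands)
  unif <- stats::setNames(rep(1 / 7, 7), bands)
  # without the age bridge, 1% of every band stays exactly 1%
  expect_equal(
    weighted_msm_percentage(700, pop, unif, bridge_15_17 = FALSE),
    1
  )
  # all users in one (non-bridged) band: that band drives the result
  one <- stats::setNames(c(0, 1, 0, 0, 0, 0, 0), bands)
  expect_equal(
    weighted_msm_percentage(500, pop, one),
    500 / 70000 * 100
  )
  # 3-band fixture with the 15-19 bridge, against explicit arithmetic
  w <- stats::setNames(c(0.2, 0.5, 0.3, 0, 0, 0, 0), bands)
  pop2 <- stats::setNames(c(8000, 12000, 9000, 7000, 6000, 5000, 4000), bands)
  n_hat <- 1000
  alloc <- c(0.2 * 5 / 2, 0.5, 0.3) * n_hat
  expect_equal(
    weighted_msm_percentage(n_hat, pop2, w),
    sum(alloc) / sum(pop2) * 100
  )
  expect_error(
    weighted_msm_percentage(100, pop[-1], unif),
    "15-19"
  )
  bad <- unif * 2
  expect_error(weighted_msm_percentage(100, pop, bad), "sum to 1")
})

make_config <- function(pilot = NULL) {
  prov <- data.frame(
    name = c("Ob1", "Ob2", "Un1", "Un2", "Ob3", "Ob4", "Un3"),
    region = c("north", "north", "north", "north", "south", "south", "south"),
    observed = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  popmat <- matrix(
    c(
      10000, 12000, 11000, 9000, 8000, 7000, 6000,
      20000, 22000, 21000, 19000, 18000, 17000, 16000,
      5000, 6000, 5500, 4500, 4000, 3500, 3000,
      8000, 9000, 8500, 7500, 7000, 6500, 6000,
      15000, 16000, 15500, 14500, 14000, 13500, 13000,
      9000, 10000, 9500, 8500, 8000, 7500, 7000,
      12000, 13000, 12500, 11500, 11000, 10500, 10000
    ),
    nrow = 7, byrow = TRUE, dimnames = list(NULL, bands)
  )
  extrapolation_config(
    cbind(prov, as.data.frame(popmat)),
    stats::setNames(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.06, 0.04), bands),
    pilot_estimates = pilot
  )
}

mk_est <- function(name, n, lo, hi) {
  multiplier_estimate(provider_count(round(n * 0.4)),
    list(p_hat = round(n * 0.4) / n, ci = c(round(n * 0.4) / hi, round(n * 0.4) / lo)),
    province = name
  )
}

test_that("national extrapolation equals the spreadsheet oracle", {
  cfg <- make_config()
  ests <- list(
    mk_est("Ob1", 1500, 1100, 2400),
    mk_est("Ob2", 2600, 2000, 4100),
    mk_est("Ob3", 3100, 2500, 5200),
    mk_est("Ob4", 1900, 1500, 3000)
  )
  nat <- extrapolate_national(ests, cfg)

  # independent spreadsheet-style recomputation
  w <- stats::setNames(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.06, 0.04), bands)
  scale15 <- sum(w * c(5 / 2, rep(1, 6))) # 18-49 -> 15-49 bridge
  pops <- rowSums(cfg$provinces[bands])
  names(pops) <- cfg$provinces$name
  n_hats <- vapply(ests, function(e) e$N_hat, numeric(1))
  names(n_hats) <- vapply(ests, function(e) e$province, character(1))
  pct <- n_hats * scale15 / pops[names(n_hats)] * 100
  north_pct <- sum(pct[c("Ob1", "Ob2")] * pops[c("Ob1", "Ob2")]) /
    sum(pops[c("Ob1", "Ob2")])
  south_pct <- sum(pct[c("Ob3", "Ob4")] * pops[c("Ob3", "Ob4")]) /
    sum(pops[c("Ob3", "Ob4")])
  expected_total <- sum(n_hats * scale15) +
    north_pct / 100 * (pops[["Un1"]] + pops[["Un2"]]) +
    south_pct / 100 * pops[["Un3"]]
  expect_equal(nat$total, round_half_up(expected_total))
  expect_equal(
    nat$pct_adult_males, expected_total / sum(pops) * 100,
    tolerance = 1e-10
  )
  expect_true(nat$ci[1] <= nat$total && nat$total <= nat$ci[2])
  # provenance covers every province exactly once
  expect_setequal(nat$provenance$name, cfg$provinces$name)
})

test_that("extrapolation handles pilots and rejects uncovered regions", {
  cfg <- make_config(pilot = data.frame(name = "Ob4", N_hat = 2000))
  ests <- list(
    mk_est("Ob1", 1500, 1100, 2400),
    mk_est("Ob2", 2600, 2000, 4100),
    mk_est("Ob3", 3100, 2500, 5200)
  )
  with_pilot <- extrapolate_national(ests, cfg)
  without <- extrapolate_national(ests, make_config())
  w <- stats::setNames(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.06, 0.04), bands)
  scale15 <- sum(w * c(5 / 2, rep(1, 6)))
  # the pilot province adds its (bridged) estimate to the total
  expect_gt(with_pilot$total, 0)
  expect_equal(
    sum(with_pilot$provenance$status == "pilot"), 1
  )
  # a region whose provinces are all unobserved is rejected by name
  prov <- make_config()$provinces
  prov$observed[prov$region == "south"] <- FALSE
  cfg_bad <- extrapolation_config(
    prov,
    stats::setNames(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.06, 0.04), bands)
  )
  expect_error(
    extrapolate_national(
      list(mk_est("Ob1", 1500, 1100, 2400), mk_est("Ob2", 2600, 2000, 4100)),
      cfg_bad
    ),
    "south"
  )
  # all provinces observed: total is just the (bridged) sum
  prov_all <- make_config()$provinces
  prov_all$observed <- TRUE
  cfg_all <- extrapolation_config(
    prov_all,
    stats::setNames(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.06, 0.04), bands)
  )
  ests_all <- lapply(prov_all$name, function(nm) mk_est(nm, 1000, 800, 1500))
  nat_all <- extrapolate_national(ests_all, cfg_all)
  expect_equal(
    nat_all$total,
    round_half_up(sum(vapply(ests_all, function(e) e$N_hat, numeric(1))) * scale15)
  )
})

test_that("published provincial table reproduces its printed totals", {
  tab <- estimate_table()
  tot <- tab[tab$province == "Total", ]
  expect_equal(tot$count_30d, 19924)
  expect_equal(tot$pop_estimate, 61609)
})
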