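test_that("sliding windows advance one week and count n - width + 1", {
  w <- sliding_windows(20)
  expect_equal(nrow(w), 17L)
  expect_equal(w$first_week, 1:17)
  expect_equal(w$last_week, 4:20)

  expect_equal(nrow(sliding_windows(4)), 1L)
  w2 <- sliding_windows(5)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$first_week, c(1L, 2L)) # weeks 1-4 then 2-5
  expect_equal(w2$last_week, c(4L, 5L))
  expect_error(sliding_windows(3), "shorter than window width")
})

test_that("repeatability is 1 with zero within-group and 0 with equal means", {
  expect_equal(estimate_repeatability(list(a = c(1, 1), b = c(2, 2),
                                           c = c(3, 3)))$R, 1)
  expect_equal(estimate_repeatability(list(a = c(1, 2), b = c(1, 2),
                                           c = c(1, 2)))$R, 0)
  expect_error(estimate_repeatability(list(a = c(1, 2))), ">= 2 groups")
  expect_error(estimate_repeatability(list(a = 1, b = 2)),
               ">= 2 observations")
})

test_that("ANOVA estimator agrees with brute force and lme4 on balanced data", {
  set.seed(5)
  for (rep in 1:10) {
    groups <- lapply(1:8, function(i) rnorm(6, mean = rnorm(1, 0, 1), sd = 1))
    names(groups) <- paste0("g", 1:8)
    est <- estimate_repeatability(groups)
    expect_equal(est$R, icc_brute_force(groups), tolerance = 1e-10)
    expect_gte(est$R, 0)
    expect_lte(est$R, 1)
  }
  # unbalanced groups against the brute-force oracle
  set.seed(6)
  ub <- lapply(sample(2:9, 7, replace = TRUE), function(n) rnorm(n, rnorm(1), 1))
  expect_equal(estimate_repeatability(ub)$R, icc_brute_force(ub),
               tolerance = 1e-10)

  skip_if_not_installed("lme4")
  d <- simulate_re_series(10, 8, 0.5, seed = 3)
  est <- estimate_repeatability(data.frame(animal_id = d$animal_id,
                                           value = d$re))
  m <- lme4::lmer(re ~ 1 + (1 | animal_id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(est$R, vc$vcov[1] / (vc$vcov[1] + vc$vcov[2]),
               tolerance = 1e-6)
})

test_that("parametric simulation recovers R near 0.5 for equal variance components", {
  # sigma2_a = sigma2_e = 1 at 19 groups x 28 obs; mean over 200 sims ~ 0.5
  est <- vapply(1:200, function(r) {
    set.seed(900 + r)
    u <- rnorm(19, 0, 1)
    values <- rep(u, each = 28) + rnorm(19 * 28, 0, 1)
    estimate_repeatability(split(values, rep(1:19, each = 28)))$R
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("cluster bootstrap intervals are seeded and degenerate data give (1,1)", {
  groups <- list(a = c(1, 1), b = c(2, 2), c = c(3, 3), d = c(4, 4))
  ci <- bootstrap_ci(groups, n_boot = 50, seed = 1)
  expect_equal(ci$ci, c(1, 1))

  d <- simulate_re_series(12, 10, 0.5, seed = 2)
  grp <- data.frame(animal_id = d$animal_id, value = d$re)
  ci1 <- bootstrap_ci(grp, n_boot = 100, seed = 99)
  ci2 <- bootstrap_ci(grp, n_boot = 100, seed = 99)
  expect_identical(ci1$ci, ci2$ci)
  expect_lte(ci1$ci[1], ci1$ci[2])
  expect_error(bootstrap_ci(grp, n_boot = 0, seed = 1), "n_boot")
  expect_error(bootstrap_ci(grp, n_boot = 10), "seed")
})

test_that("bootstrap intervals cover a known variance ratio", {
  # sigma2_a = sigma2_e = 1 -> true R = 0.5. Percentile intervals from a
  # cluster bootstrap over only 19 animals undercover somewhat (their
  # long-run coverage here is ~85%, not the nominal 95%), so the bound
  # asserts the interval is informative rather than nominally calibrated.
  covered <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    u <- rnorm(19, 0, 1)
    values <- rep(u, each = 28) + rnorm(19 * 28, 0, 1)
    grp <- split(values, rep(1:19, each = 28))
    ci <- bootstrap_ci(grp, n_boot = 200, seed = 4000 + r)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.80)
})

test_that("permutation p-values behave at the extremes and are exchange-invariant", {
  # groups big enough that no random shuffle reconstructs the separation
  sep <- list(a = 0 + (1:5) / 100, b = 10 + (1:5) / 100, c = 20 + (1:5) / 100)
  pp <- permutation_pvalue(sep, n_perm = 100, seed = 1)
  expect_equal(pp$p, 1 / 101)

  flat <- list(a = c(5, 5), b = c(5, 5), c = c(5, 5))
  expect_equal(permutation_pvalue(flat, n_perm = 50, seed = 1)$p, 1)

  # relabeling animals leaves the observed R and the null distribution
  # unchanged (the latter up to Monte-Carlo error of the realized draws)
  d <- simulate_re_series(8, 6, 0.4, seed = 10)
  grp <- split(d$re, d$animal_id)
  p1 <- permutation_pvalue(grp, n_perm = 400, seed = 7)
  p2 <- permutation_pvalue(grp[c(3, 1, 8, 5, 2, 7, 4, 6)], n_perm = 400,
                           seed = 7)
  expect_equal(p2$R_obs, p1$R_obs, tolerance = 1e-12)
  expect_lt(abs(mean(p1$replicates) - mean(p2$replicates)), 0.02)
  expect_error(permutation_pvalue(grp, n_perm = 0, seed = 1), "n_perm")
})

test_that("window repeatability tracks a constructed stability increase", {
  # RE series whose between-animal spread grows relative to noise over time
  set.seed(21)
  n_animals <- 12
  n_nights <- 7 * 8
  u <- rnorm(n_animals, 0, 1)
  rows <- lapply(1:n_animals, function(i) {
    wk <- rep(1:8, each = 7)
    sig_a <- seq(0.2, 1.4, length.out = 8)[wk] # animal signal ramps up
    tibble::tibble(
      animal_id = sprintf("M%02d", i),
      date = as.Date("2019-06-01") + 0:(n_nights - 1),
      re = 0.5 + sig_a * u[i] / 10 + rnorm(n_nights, 0, 0.03)
    )
  })
  re_data <- do.call(rbind, rows)
  rw <- repeatability_windows(re_data, n_boot = 50, n_perm = 20, seed = 5)
  expect_equal(nrow(rw), 5L) # 8 weeks -> 5 windows of 4 weeks
  expect_true(all(rw$R >= 0 & rw$R <= 1))
  expect_true(all(rw$ci_low <= rw$ci_high))
  tr <- repeatability_trend(rw)
  expect_gt(tr$slope, 0)

  # trend degenerate cases
  expect_equal(repeatability_trend(c(0.4, 0.4, 0.4, 0.4))$slope, 0)
  lin <- repeatability_trend(seq(0.3, 0.6, length.out = 6))
  expect_equal(lin$adj_r2, 1, tolerance = 1e-10)
  expect_error(repeatability_trend(c(0.3, 0.4)), ">= 3 windows")
})
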