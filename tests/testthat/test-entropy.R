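test_that("contact distributions tally and normalize per animal", {
  log <- make_log(
    c("M01", "M01", "M01", "M02"), c(5, 5, 7, 1),
    rep("2019-06-01 21:00:00", 4)
  )
  d <- contact_distribution(log, "M01", k = 27)
  expect_equal(d$counts[c(5, 7)], c(2L, 1L))
  expect_equal(sum(d$counts), 3L)
  expect_equal(d$p[c(5, 7)], c(2 / 3, 1 / 3))
  expect_equal(sum(d$p), 1)
  expect_false(d$empty)

  absent <- contact_distribution(log, "M99", k = 27)
  expect_true(absent$empty)
  expect_true(is.na(roaming_entropy(absent)))

  full <- make_log(rep("M01", 27), 1:27, rep("2019-06-01 21:00:00", 27))
  u <- contact_distribution(full, "M01", k = 27)
  expect_equal(u$p, rep(1 / 27, 27))

  expect_error(contact_distribution(log, "M01", k = 4), "smaller than max")
})

test_that("roaming entropy matches its defining formula and bounds", {
  expect_equal(roaming_entropy(rep(1 / 27, 27)), 1)
  expect_equal(roaming_entropy(c(1, rep(0, 26))), 0)

  # two equally used antennas out of 27: high-precision oracle log(2)/log(27)
  p <- c(0.5, 0.5, rep(0, 25))
  expect_equal(roaming_entropy(p), log(2) / log(27), tolerance = 1e-12)
  expect_equal(roaming_entropy(p), 0.2103099, tolerance = 1e-6)

  # counts and probabilities give the same entropy
  expect_equal(roaming_entropy(c(2, 1, rep(0, 25))),
               roaming_entropy(c(2, 1, rep(0, 25)) / 3))

  expect_error(roaming_entropy(c(0.5, 0.5), k = 1), "k > 1")
  expect_error(roaming_entropy(rep(0, 27)), "positive sum")
})

test_that("entropy is symmetric, base-free, bounded, and coarsening never raises it", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:40, 1)
    p <- as.numeric(stats::rgamma(k, 1))
    p <- p / sum(p)
    re <- roaming_entropy(p)
    expect_gte(re, 0)
    expect_lte(re, 1)
    # label permutation invariance
    expect_equal(roaming_entropy(sample(p)), re)
    # base invariance: recompute with log2
    nz <- p > 0
    expect_equal(re, -sum(p[nz] * log2(p[nz])) / log2(k), tolerance = 1e-12)
    # merging two antennas (coarsening onto the same k slots) reduces RE
    q <- p
    q[1] <- q[1] + q[2]
    q[2] <- 0
    expect_lte(roaming_entropy(q), re + 1e-12)
  }
})

test_that("cumulative RE is a running sum with missing nights adding zero", {
  expect_equal(as.numeric(cumulative_re(c(0.5, 0.3))), c(0.5, 0.8))
  expect_length(cumulative_re(numeric()), 0)

  cre <- cumulative_re(rep(0.06, 136))
  expect_equal(cre[136], 136 * 0.06) # arithmetic oracle: 8.16
  expect_true(all(diff(cre) >= 0))
  # conservation: cRE equals the sum of its increments
  expect_equal(sum(diff(c(0, cre))), cre[136])

  with_na <- cumulative_re(c(0.5, NA, 0.25))
  expect_equal(as.numeric(with_na), c(0.5, 0.5, 0.75))
  expect_equal(attr(with_na, "missing"), c(FALSE, TRUE, FALSE))

  expect_error(cumulative_re(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(cumulative_re(0.5, missing_policy = "zero-fill"), "arg")
})

test_that("group summaries report mean, sd, CV%, extremes and n", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv_percent, 50)
  expect_equal(s$max, 3)
  expect_equal(s$min, 1)
  expect_equal(s$n, 3L)

  const <- group_summary(c(4, 4, 4))
  expect_equal(const$sd, 0)
  expect_equal(const$cv_percent, 0)

  expect_equal(group_summary(c(1, NA, 3))$n, 2L)
  expect_error(group_summary(c(NA_real_, NA_real_)), "missing")
})

test_that("variance trajectory recovers a constructed linear variance trend", {
  # all animals identical: zero variance, zero slope
  flat <- matrix(rep(0.07, 5 * 10), nrow = 5)
  vt <- variance_trajectory(flat)
  expect_equal(vt$variance, rep(0, 10))
  expect_equal(vt$trend$slope, 0)

  # construct nights whose cross-animal variance is exactly linear in t:
  # animals at +/- c(t) with c(t) = sqrt(v(t)), v(t) = 2e-4 * t
  nights <- 1:12
  v_true <- 2e-4 * nights
  m <- rbind(0.08 + sqrt(v_true / 2), 0.08 - sqrt(v_true / 2))
  vt2 <- variance_trajectory(m)
  expect_equal(vt2$variance, v_true, tolerance = 1e-12)
  expect_equal(vt2$trend$slope, 2e-4, tolerance = 1e-10)
  expect_equal(vt2$trend$adj_r2, 1, tolerance = 1e-8)

  # simulated heterogeneous decline: recovered slope sign matches construction
  set.seed(8)
  sd_t <- sqrt(seq(4e-4, 1e-4, length.out = 20))
  sim <- vapply(seq_along(sd_t), function(t) rnorm(30, 0.07, sd_t[t]),
                numeric(30))
  expect_lt(variance_trajectory(sim)$trend$slope, 0)

  expect_error(variance_trajectory(matrix(1:2, ncol = 1)), ">= 2 animals|nights")
  expect_error(variance_trajectory(matrix(runif(4), 2, 2)), "3 nights")
})

test_that("roaming_series assembles nightly RE and cRE per animal", {
  sched <- summer_schedule()
  log <- make_log(
    c("A", "A", "A", "B", "A"),
    c(5, 5, 7, 3, 2),
    c("2019-06-01 21:00:00", "2019-06-01 21:10:00", "2019-06-01 22:00:00",
      "2019-06-01 21:00:00", "2019-06-02 23:00:00")
  )
  rs <- roaming_series(log, sched, nights = c("2019-06-01", "2019-06-02"))
  a <- rs[rs$animal_id == "A", ]
  expect_equal(a$re[1], roaming_entropy(c(2, 1, rep(0, 25)) / 3))
  expect_equal(a$re[2], 0) # single antenna night
  expect_equal(a$cre, cumsum(a$re))
  b <- rs[rs$animal_id == "B", ]
  expect_equal(b$re[1], 0)
  expect_true(b$missing[2])
  expect_equal(b$cre[2], b$cre[1]) # missing night adds nothing
  expect_equal(a$n_contacts, c(3L, 1L))
})
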