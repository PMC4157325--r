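test_that("site scores match direct arithmetic on small occupancies", {
  # 1/(1 + 2^-3) and 1/(1 + 2^0)
  expect_equal(site_scores(decision_params(s = 2, a = 1, k = 0), c(3, 0, 0, 0)),
               c(8 / 9, 0.5, 0.5, 0.5), tolerance = 1e-12)
  # general cases against an independently written scalar evaluation
  cases <- list(
    list(con = c(3, 0, 0, 0), het = c(0, 0, 0, 0), s_c = 2, s_h = 2,
         a = 1, k = 0),
    list(con = c(1, 2, 0, 1), het = c(0, 1, 1, 0), s_c = 12.64, s_h = 2.10,
         a = 13.48, k = 0.01),
    list(con = c(0, 0, 5, 0), het = c(2, 0, 0, 1), s_c = 3.63, s_h = 4.05,
         a = 9.99, k = 0.02)
  )
  for (cs in cases) {
    got <- site_scores(
      decision_params(s_c = cs$s_c, s_h = cs$s_h, a = cs$a, k = cs$k),
      list(conspecific = cs$con, heterospecific = cs$het))
    expect_equal(got, direct_scores(cs$con, cs$het, cs$s_c, cs$s_h,
                                    cs$a, cs$k),
                 tolerance = 1e-12)
  }
})

test_that("s = 1 gives exactly uniform choice for arbitrary occupancies", {
  withr::local_seed(7)
  for (i in 1:25) {
    counts <- rpois(4, 5)
    a <- runif(1, 0.2, 5)
    k <- runif(1, 0, 2)
    p1 <- choice_probabilities(decision_params(s = 1, a = a, k = k), counts)
    expect_equal(p1$probabilities, rep(0.25, 4), tolerance = 1e-12)
    # all scores collapse to 1/(1+a)
    expect_equal(p1$raw_scores, rep(1 / (1 + a), 4), tolerance = 1e-12)
    p2 <- choice_probabilities(
      decision_params(s_c = 1, s_h = 1, a = a, k = k),
      list(conspecific = counts, heterospecific = rpois(4, 3)))
    expect_equal(p2$probabilities, rep(0.25, 4), tolerance = 1e-12)
  }
})

test_that("probability matching yields a strictly positive distribution", {
  withr::local_seed(11)
  for (i in 1:50) {
    params <- decision_params(s_c = exp(runif(1, -2, 4)),
                              s_h = exp(runif(1, -2, 4)),
                              a = exp(runif(1, -1, 3)), k = runif(1, 0, 1))
    counts <- list(conspecific = rpois(4, 4), heterospecific = rpois(4, 2))
    p <- choice_probabilities(params, counts)$probabilities
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("two-rate variant with equal rates collapses to the single rate", {
  withr::local_seed(3)
  for (i in 1:20) {
    s <- exp(runif(1, -1, 3)); a <- exp(runif(1, -1, 2)); k <- runif(1, 0, 1)
    con <- rpois(4, 4); het <- rpois(4, 3)
    expect_equal(
      site_scores(decision_params(s_c = s, s_h = s, a = a, k = k),
                  list(conspecific = con, heterospecific = het)),
      site_scores(decision_params(s = s, a = a, k = k), con + het),
      tolerance = 1e-12)
  }
})

test_that("choice of the most occupied feeder is non-decreasing in s", {
  # all other feeders empty: their scores stay fixed while the occupied
  # feeder's score grows with s
  counts <- c(4, 0, 0, 0)
  s_grid <- c(1, 1.5, 2, 4, 8, 20)
  p_busy <- vapply(s_grid, function(s) {
    choice_probabilities(decision_params(s = s, a = 1.5, k = 0),
                         counts)$probabilities[1]
  }, numeric(1))
  expect_true(all(diff(p_busy) >= -1e-12))
  expect_gt(p_busy[length(p_busy)], 0.25)
})

test_that("larger a penalizes empty feeders relative to occupied ones", {
  counts <- c(5, 0, 0, 0)
  ratio <- vapply(c(1, 2, 5, 10), function(a) {
    p <- choice_probabilities(decision_params(s = 3, a = a), counts)$probabilities
    p[2] / p[1]
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
})

test_that("scores stay finite in log-space at extreme rates and counts", {
  p <- decision_params(s = exp(6), a = exp(6), k = 0)
  sc <- site_scores(p, c(400, 0, 0, 0))
  # occupied-feeder score saturates to 1 in double precision, but nothing
  # overflows and empty feeders keep strictly positive scores
  expect_true(all(is.finite(sc)) && all(sc > 0) && all(sc <= 1))
  cp <- choice_probabilities(p, c(400, 0, 0, 0))$probabilities
  expect_true(all(cp > 0))
  expect_equal(sum(cp), 1, tolerance = 1e-12)
})

test_that("choice surface is flat at 0.25 for s = 1 and monotone for s > 1", {
  flat <- choice_surface(decision_params(s = 1, a = 2), 6, 6)
  expect_equal(flat$grid$p_choose, rep(0.25, nrow(flat$grid)),
               tolerance = 1e-12)
  surf <- choice_surface(decision_params(s_c = 4, s_h = 2, a = 3, k = 0.01),
                         8, 8)
  z <- matrix(surf$grid$p_choose, nrow = 9)
  expect_true(all(apply(z, 2, function(col) all(diff(col) >= -1e-12))))
  expect_true(all(apply(z, 1, function(row) all(diff(row) >= -1e-12))))
  expect_true(length(surf$contour_25) >= 1)
})

test_that("threshold counts behave per the attraction rule", {
  # s = 1: every feeder sits exactly at 0.25, threshold 0
  expect_identical(
    threshold_count(decision_params(s = 1, a = 3), "conspecific",
                    c(n_c = 10, n_h = 0)), 0L)
  # reference great-tit rule: ~3 conspecifics needed out of 10 (qualitative)
  gt <- great_tit_params()
  expect_equal(threshold_count(gt, "conspecific", c(n_c = 10, n_h = 0)), 3)
  # thresholds scale with flock size for attractive rules
  t10 <- threshold_count(gt, "conspecific", c(n_c = 10, n_h = 0))
  t20 <- threshold_count(gt, "conspecific", c(n_c = 20, n_h = 0))
  expect_gte(t20, t10)
})

test_that("parameter validation rejects invalid values", {
  expect_error(decision_params(s = -1), "positive")
  expect_error(decision_params(s = 2, s_c = 3, s_h = 1), "not both")
  expect_error(decision_params(s_c = 2), "both")
  expect_error(decision_params(s = 2, k = -0.1), "k")
  expect_error(decision_params(s = 2, a = 0), "a")
  expect_error(site_scores(decision_params(s = 2), c(-1, 0, 0, 0)),
               "non-negative")
})
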