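test_that("the asocial rule gives every move probability 1/3", {
  st <- generate_dataset(small_config(seed = 29L))
  ev <- extract_movements(st)
  ev <- filter_events(ev, ev$arr_total > 0)
  ll <- event_log_likelihood(decision_params(s = 1, a = 4, k = 0.3), ev)
  expect_equal(ll, rep(log(1 / 3), nrow(ev)), tolerance = 1e-12)
  # unconditional convention: probability 1/4 including "stay"
  ll4 <- event_log_likelihood(decision_params(s = 1), ev,
                              convention = "unconditional")
  expect_equal(ll4, rep(log(1 / 4), nrow(ev)), tolerance = 1e-12)
})

test_that("total log-likelihood equals the brute-force per-event product", {
  rho <- matrix(c(0.6, 0.2, 0.2, 0,
                  0.25, 0.25, 0.25, 0.25,
                  0, 0.5, 0.5, 0,
                  1, 0, 0, 0,
                  0.1, 0.3, 0.4, 0.2), nrow = 5, byrow = TRUE)
  ev <- fake_events(rho, from = c(1, 2, 2, 1, 4), to = c(2, 3, 3, 3, 1))
  params <- decision_params(s_c = 3, s_h = 2, a = 1.5, k = 0.1)
  # direct multiplication with independently coded scores
  probs <- vapply(1:5, function(i) {
    con <- unlist(ev[i, sprintf("arr_nc_%d", 1:4)], use.names = FALSE)
    het <- unlist(ev[i, sprintf("arr_nh_%d", 1:4)], use.names = FALSE)
    sc <- direct_scores(con, het, 3, 2, 1.5, 0.1)
    sc[ev$to_feeder[i]] / sum(sc[-ev$from_feeder[i]])
  }, numeric(1))
  expect_equal(sum(event_log_likelihood(params, ev)), log(prod(probs)),
               tolerance = 1e-10)
})

test_that("moves toward overwhelming occupancy approach certainty as s grows", {
  rho <- matrix(c(0, 1, 0, 0), nrow = 1)
  ev <- fake_events(rho, from = 1L, to = 2L, n_per_feeder = 12L)
  # the empty alternatives keep score 1/(1+a), so certainty needs a large
  # low-density penalty a as well as a large s
  lls <- vapply(c(2, 8, 50, 400), function(s) {
    event_log_likelihood(decision_params(s = s, a = 1e4), ev)
  }, numeric(1))
  expect_true(all(diff(lls) >= 0))
  expect_gt(lls[2], lls[1])
  expect_gt(lls[4], -1e-3)
  expect_true(all(lls < 0))
})

test_that("fits recover the asocial null from asocial decisions", {
  cfg <- synthetic_config(seed = 1L)
  ev <- simulate_decisions(decision_params(s = 1, a = 2), 2000, cfg, seed = 33)
  fit <- fit_decision_model(ev, variant = "single")
  expect_true(fit$converged)
  expect_gt(fit$params$s, 0.8)
  expect_lt(fit$params$s, 1.25)
})

test_that("likelihood is additive and order-invariant", {
  cfg <- synthetic_config(seed = 1L)
  ev <- simulate_decisions(great_tit_params(), 400, cfg,
                           focal_species = "great_tit", seed = 44)
  fit1 <- fit_decision_model(ev, variant = "two_species")
  # duplicated events: identical estimates, doubled log-likelihood
  dup <- flockdecide:::new_movement_events(
    rbind(as.data.frame(ev), as.data.frame(ev)),
    n_feeders = 4L, window = 30L, logging_interval = 15L)
  fit2 <- fit_decision_model(dup, variant = "two_species")
  expect_equal(fit2$params$s_c, fit1$params$s_c, tolerance = 1e-4)
  expect_equal(fit2$log_likelihood, 2 * fit1$log_likelihood,
               tolerance = 1e-6)
  # permuted events: identical fit
  perm <- filter_events(ev, rep(TRUE, nrow(ev)))
  perm <- flockdecide:::new_movement_events(
    as.data.frame(perm)[rev(seq_len(nrow(perm))), ],
    n_feeders = 4L, window = 30L, logging_interval = 15L)
  fit3 <- fit_decision_model(perm, variant = "two_species")
  expect_equal(fit3$params$s_c, fit1$params$s_c, tolerance = 1e-8)
  expect_equal(fit3$log_likelihood, fit1$log_likelihood, tolerance = 1e-8)
})

test_that("fitted models always dominate the nested asocial null", {
  cfg <- synthetic_config(seed = 1L)
  for (sd in c(101, 102)) {
    ev <- simulate_decisions(blue_tit_params(), 600, cfg,
                             focal_species = "blue_tit", seed = sd)
    fit <- fit_decision_model(ev, variant = "two_species")
    expect_gte(fit$log_likelihood, fit$null_log_likelihood)
    expect_lte(fit$log_likelihood, 0)
  }
})

test_that("the two likelihood conventions are both available and disagree", {
  # movement-only data cannot identify the stay-included convention (the
  # dropped stays carry the information), so the two conventions are
  # exposed side by side as a sensitivity analysis rather than as
  # interchangeable estimators
  cfg <- synthetic_config(seed = 1L)
  ev <- simulate_decisions(decision_params(s = 3, a = 3, k = 0), 1500, cfg,
                           seed = 55)
  fit_c <- fit_decision_model(ev, variant = "single")
  fit_u <- fit_decision_model(ev, variant = "single",
                              convention = "unconditional")
  expect_true(fit_c$converged && fit_u$converged)
  expect_gt(fit_c$params$s, 2.2)
  expect_lt(fit_c$params$s, 4)
  expect_false(isTRUE(all.equal(fit_c$params$s, fit_u$params$s)))
  expect_gte(fit_u$log_likelihood, fit_u$null_log_likelihood)
})

test_that("profile intervals bracket estimates and flag bounds", {
  cfg <- synthetic_config(seed = 1L)
  ev <- simulate_decisions(great_tit_params(), 1200, cfg,
                           focal_species = "great_tit", seed = 66)
  fit <- fit_decision_model(ev, variant = "two_species")
  ci <- profile_ci(fit, "s_c")
  expect_lt(ci$lower, fit$params$s_c)
  expect_gt(ci$upper, fit$params$s_c)
  # k generated at 0.01 frequently profiles down to the k >= 0 bound
  ci_k <- profile_ci(fit, "k")
  expect_gte(ci_k$lower, 0)
  expect_lte(ci_k$lower, fit$params$k)
  expect_error(profile_ci(fit, "s"), "not in this fit")
})

test_that("profile intervals cover the generating value", {
  cfg <- synthetic_config(seed = 1L)
  hits <- vapply(1:50, function(r) {
    ev <- simulate_decisions(great_tit_params(), 300, cfg,
                             focal_species = "great_tit", seed = 700 + r)
    fit <- fit_decision_model(ev, variant = "two_species")
    ci <- profile_ci(fit, "s_c", tol = 5e-3)
    ci$lower <= 12.64 && 12.64 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sparse event sets trigger the stability warning", {
  cfg <- synthetic_config(seed = 1L)
  ev <- simulate_decisions(blue_tit_params(), 10, cfg,
                           focal_species = "blue_tit", seed = 77)
  expect_warning(fit_decision_model(ev, variant = "single"), "unstable")
})
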