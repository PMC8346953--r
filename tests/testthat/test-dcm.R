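test_that("expected utility is the probability-weighted utility sum", {
  for (cv in list(prelec_s, utility_curve("scdf2", c(2, 0.4)))) {
    expect_equal(expected_utility(gamble(0, 0.5), cv, dist_low), 0.5)
  }
  expect_equal(expected_utility(safe(0.5), linear_curve, dist_low), 1.0)
  # arithmetic oracle under linear utility: EU = p1 m1 + p2 m2 (normalized)
  expect_equal(expected_utility(gamble(0.2, 0.6), linear_curve, dist_full),
               0.5 * 0.2 + 0.5 * 0.6)
  expect_error(expected_utility(safe(0.9), linear_curve, dist_low),
               "outside")
})

test_that("the likelihood matches a per-trial loop oracle", {
  ag <- s_shaped_agent(lambda = 6, seed = 13)
  tr <- generate_choice_trials(ag, dist_full, 300)
  cv <- utility_curve("prelec2", c(1.4, 0.9))
  lambda <- 7; theta <- 0.3
  # independent loop oracle
  oracle <- 0
  for (i in seq_len(nrow(tr))) {
    left <- utiladapt:::row_option(tr[i, ], "left")
    right <- utiladapt:::row_option(tr[i, ], "right")
    pl <- stats::plogis(lambda * (expected_utility(left, cv, dist_full) -
                                    expected_utility(right, cv, dist_full)) +
                          theta)
    oracle <- oracle - log(if (tr$chosen[i] == "left") pl else 1 - pl)
  }
  expect_equal(neg_log_likelihood(tr, cv, lambda, theta, dist_full), oracle,
               tolerance = 1e-10)
  # lambda = 0, theta = 0: every trial contributes ln 2
  expect_equal(neg_log_likelihood(tr[1:100, ], cv, 0, 0, dist_full),
               100 * log(2), tolerance = 1e-10)
  expect_error(neg_log_likelihood(tr[0, ], cv, 1, 0, dist_full), "no trials")
})

test_that("BIC applies the k ln(n) penalty to the log-likelihood", {
  fit <- structure(list(family = "prelec2", k = 4, n_trials = 100,
                        neg_ll = 69.31), class = "dcm_fit")
  expect_equal(bic(fit), 4 * log(100) + 2 * 69.31)
  fit$k <- 3
  expect_equal(bic(fit), 3 * log(100) + 138.62, tolerance = 1e-10)
})

test_that("fitting recovers generating parameters and is deterministic", {
  truth <- utility_curve("power1", 1)
  ag <- agent_config(truth, lambda = 10, theta = 0, seed = 303)
  tr <- generate_choice_trials(ag, dist_full, 5000)
  fit <- fit_dcm(tr, "power1", dist_full, n_starts = 4, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$utility$params[["alpha"]] - 1), 0.05)
  expect_lt(abs(fit$theta), 0.1)
  expect_lt(abs(fit$lambda - 10) / 10, 0.2)
  fit2 <- fit_dcm(tr, "power1", dist_full, n_starts = 4, seed = 1)
  expect_identical(fit$utility$params, fit2$utility$params)
  expect_identical(fit$neg_ll, fit2$neg_ll)
})

test_that("likelihood at the truth beats perturbed parameters (large n)", {
  ag <- s_shaped_agent(lambda = 10, seed = 99)
  tr <- generate_choice_trials(ag, dist_full, 4000)
  nll_true <- neg_log_likelihood(tr, prelec_s, 10, 0, dist_full)
  worse <- c(
    neg_log_likelihood(tr, utility_curve("prelec2", c(3, 1)), 10, 0,
                       dist_full),
    neg_log_likelihood(tr, utility_curve("prelec2", c(2, 1.5)), 10, 0,
                       dist_full),
    neg_log_likelihood(tr, prelec_s, 15, 0, dist_full),
    neg_log_likelihood(tr, prelec_s, 10, 0.5, dist_full))
  expect_true(all(worse > nll_true))
})

test_that("BIC ordering is invariant to trial order", {
  ag <- s_shaped_agent(lambda = 8, seed = 41)
  tr <- generate_choice_trials(ag, dist_full, 400)
  f_a <- fit_dcm(tr, "prelec2", dist_full, n_starts = 3, seed = 2)
  f_b <- fit_dcm(tr, "power1", dist_full, n_starts = 3, seed = 2)
  set.seed(9); shuf <- tr[sample(nrow(tr)), ]
  g_a <- fit_dcm(shuf, "prelec2", dist_full, n_starts = 3, seed = 2)
  g_b <- fit_dcm(shuf, "power1", dist_full, n_starts = 3, seed = 2)
  expect_equal(f_a$bic, g_a$bic, tolerance = 1e-4)
  expect_identical(f_a$bic < f_b$bic, g_a$bic < g_b$bic)
})

test_that("cross-validation is seeded, fold-complete and unbiased", {
  ag <- s_shaped_agent(lambda = 8, seed = 52)
  tr <- generate_choice_trials(ag, dist_full, 400)
  cv1 <- crossvalidate(tr, "prelec2", dist_full, seed = 4, n_starts = 2)
  cv2 <- crossvalidate(tr, "prelec2", dist_full, seed = 4, n_starts = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$cv_negll, cv2$cv_negll)
  expect_equal(sort(unique(cv1$folds)), 1:10)
  # held-out score no better than the training fit per trial, within noise
  fit <- fit_dcm(tr, "prelec2", dist_full, n_starts = 3, seed = 4)
  expect_gt(cv1$per_trial_negll, fit$neg_ll / fit$n_trials - 0.02)
  expect_error(crossvalidate(tr[1:10, ], "prelec2", dist_full), "20 trials")
})

test_that("random choices leave nothing to learn across families", {
  ag0 <- agent_config(linear_curve, lambda = 0, seed = 61)
  tr <- generate_choice_trials(ag0, dist_full, 400)
  for (fam in c("power1", "prelec2")) {
    cv <- crossvalidate(tr, fam, dist_full, seed = 6, n_starts = 2)
    expect_lt(abs(cv$per_trial_negll - log(2)), 0.03)
  }
})

test_that("the pooled ln-parameter rule flags planted outliers only", {
  mk <- function(a, b) {
    structure(list(family = "prelec2",
                   utility = utility_curve("prelec2", c(a, b))),
              class = "dcm_fit")
  }
  set.seed(7)
  pool <- lapply(1:50, function(i) mk(exp(rnorm(1, 0, 0.1)),
                                      exp(rnorm(1, 0, 0.1))))
  res <- flag_outliers(pool)
  expect_true(all(res$keep))
  pool[[7]] <- mk(8, 1)  # ln(8) is ~20 pooled SDs from the ln-alpha mean
  res <- flag_outliers(pool)
  expect_false(res$keep[7])
  expect_equal(sum(!res$keep), 1)
  # identical fits: SD = 0, nothing excluded
  same <- lapply(1:5, function(i) mk(2, 1))
  expect_true(all(flag_outliers(same)$keep))
})

test_that("recovery error shrinks with the number of trials", {
  err <- vapply(c(200, 1000, 5000), function(n) {
    e <- vapply(1:8, function(r) {
      ag <- agent_config(prelec_s, lambda = 10, seed = 7000 + 17 * r + n)
      tr <- generate_choice_trials(ag, dist_full, n)
      fit <- fit_dcm(tr, "prelec2", dist_full, n_starts = 2, seed = r)
      abs(fit$utility$params[["alpha"]] - 2)
    }, numeric(1))
    stats::median(e)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
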