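test_that("schedules expand blocks into ordered day sequences", {
  s <- build_schedule(list(list(distribution = "low", n_days = 22),
                           list(distribution = "full", n_days = 31),
                           list(distribution = "high", n_days = 17)))
  expect_equal(nrow(s), 70)
  expect_equal(s$day_index, 0:69)
  expect_equal(unique(s$distribution), c("low", "full", "high"))
  expect_equal(sum(s$distribution == "low"), 22)
  s1 <- build_schedule(list(list(distribution = "full", n_days = 1)))
  expect_equal(nrow(s1), 1)
  s2 <- build_schedule(list(list(distribution = "low", n_days = 2),
                            list(distribution = "high", n_days = 2)))
  expect_equal(s2$distribution[s2$day_index %in% 0:1], rep("low", 2))
  expect_equal(s2$distribution[s2$day_index %in% 2:3], rep("high", 2))
  expect_error(build_schedule(list()), "empty")
})

test_that("choice probabilities follow the logit rule exactly", {
  ag0 <- agent_config(linear_curve, lambda = 0, theta = 0)
  expect_equal(choice_probability(ag0, gamble(0, 1), safe(0.2), dist_full),
               0.5)
  # bias saturation: lambda = 0, huge theta
  ag_b <- agent_config(linear_curve, lambda = 0, theta = 9.9)
  expect_gt(choice_probability(ag_b, safe(0.1), safe(0.9), dist_full),
            0.9999)
  # closed-form oracle: linear utility, lambda = 10, EVs 0.6 vs 0.4
  ag <- agent_config(linear_curve, lambda = 10, theta = 0)
  p <- choice_probability(ag, safe(0.6), safe(0.4), dist_full)
  expect_equal(p, 1 / (1 + exp(-10 * (0.6 - 0.4))), tolerance = 1e-12)
  # strictly increasing in the EU difference
  evs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(evs, function(v)
    choice_probability(ag, safe(v), safe(0.5), dist_full), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("simulated choices are reproducible and match the analytic rule", {
  ag <- agent_config(prelec_s, lambda = 8, theta = 0, seed = 5)
  set.seed(1); a <- replicate(50, simulate_choice(ag, gamble(0, 1),
                                                  safe(0.4), dist_full))
  set.seed(1); b <- replicate(50, simulate_choice(ag, gamble(0, 1),
                                                  safe(0.4), dist_full))
  expect_identical(a, b)
  # deterministic limit
  ag_hi <- agent_config(linear_curve, lambda = 1000)
  set.seed(2)
  ch <- replicate(200, simulate_choice(ag_hi, safe(0.9), safe(0.1),
                                       dist_full))
  expect_true(all(ch == "left"))
  # fair coin at lambda = 0
  ag0 <- agent_config(linear_curve, lambda = 0)
  set.seed(3)
  ch0 <- replicate(10000, simulate_choice(ag0, safe(0.9), safe(0.1),
                                          dist_full))
  expect_lt(abs(mean(ch0 == "left") - 0.5), 0.02)
  # empirical frequency matches choice_probability within 3 binomial SE
  p <- choice_probability(ag, gamble(0, 1), safe(0.4), dist_full)
  set.seed(4)
  f <- mean(replicate(4000, simulate_choice(ag, gamble(0, 1), safe(0.4),
                                            dist_full)) == "left")
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("fractile sessions implement the three-step chained design", {
  ag <- s_shaped_agent(lambda = 30, seed = 21)
  tr <- generate_fractile_session(ag, dist_low)
  expect_setequal(unique(tr$sequence_tag),
                  c("fractile_step1", "fractile_step2", "fractile_step3"))
  # all magnitudes inside the distribution
  mags <- c(tr$left_m1, tr$left_m2, tr$right_m1, tr$right_m2)
  mags <- mags[!is.na(mags)]
  expect_true(all(mags >= dist_low$min_ml - 1e-9 &
                    mags <= dist_low$max_ml + 1e-9))
  # step-1 gamble is the min/max equiprobable gamble
  s1 <- tr[tr$sequence_tag == "fractile_step1", ]
  g_m1 <- ifelse(is.na(s1$left_m2), s1$right_m1, s1$left_m1)
  g_m2 <- ifelse(is.na(s1$left_m2), s1$right_m2, s1$left_m2)
  expect_true(all(abs(pmin(g_m1, g_m2) - 0) < 1e-9))
  expect_true(all(abs(pmax(g_m1, g_m2) - 0.5) < 1e-9))
  # safe ladder on the 0.05 ml grid, never outside the distribution
  safes <- ifelse(is.na(s1$left_m2), s1$left_m1, s1$right_m1)
  expect_true(all(abs(safes / 0.05 - round(safes / 0.05)) < 1e-9))
  expect_true(all(safes <= 0.5 + 1e-9))
  # step 2 interweaves two gambles chained on the step-1 CE
  s2 <- tr[tr$sequence_tag == "fractile_step2", ]
  g2 <- unique(paste(
    pmin(ifelse(is.na(s2$left_m2), s2$right_m1, s2$left_m1),
         ifelse(is.na(s2$left_m2), s2$right_m2, s2$left_m2)),
    pmax(ifelse(is.na(s2$left_m2), s2$right_m1, s2$left_m1),
         ifelse(is.na(s2$left_m2), s2$right_m2, s2$left_m2))))
  expect_length(g2, 2)
  ce1 <- attr(tr, "ce")[["0.5"]]
  expect_true(any(grepl(paste0("^0 ", ce1), g2)))
})

test_that("same seed regenerates bitwise-identical sessions", {
  ag <- s_shaped_agent(seed = 33)
  t1 <- generate_fractile_session(ag, dist_high, day_index = 3)
  t2 <- generate_fractile_session(ag, dist_high, day_index = 3)
  expect_identical(t1, t2)
  t3 <- generate_fractile_session(ag, dist_high, day_index = 4)
  expect_false(identical(t1$chosen, t3$chosen))
})

test_that("a sharp risk-neutral agent's step-1 CE sits at the gamble's EV", {
  ag <- risk_neutral_agent(lambda = 100, seed = 44)
  tr <- generate_fractile_session(ag, dist_low, repeats = 8)
  ce <- attr(tr, "ce")
  expect_false(attr(tr, "flagged"))
  expect_lt(abs(ce[["0.5"]] - 0.25), 0.05)  # EV of (0, 0.5) within one step
})

test_that("validation sessions pair the four equivariant gambles", {
  ag <- s_shaped_agent(seed = 55)
  tr <- generate_validation_session(ag, dist_full)
  expect_true(all(tr$sequence_tag == "validation"))
  g_m1 <- ifelse(is.na(tr$left_m2), tr$right_m1, tr$left_m1)
  g_m2 <- ifelse(is.na(tr$left_m2), tr$right_m2, tr$left_m2)
  spreads <- unique(round(abs(g_m2 - g_m1), 9))
  expect_equal(spreads, 0.30)
  centers <- sort(unique(round((g_m1 + g_m2) / 2, 9)))
  expect_equal(centers, c(0.25, 0.45, 0.65, 0.85))
})
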