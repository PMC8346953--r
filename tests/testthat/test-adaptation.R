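test_that("median curves take parameter-wise medians of daily fits", {
  mk <- function(a) structure(list(family = "power1",
                                   utility = utility_curve("power1", a)),
                              class = "dcm_fit")
  expect_equal(median_curve(list(mk(3)))$params[["alpha"]], 3)
  expect_equal(median_curve(list(mk(1), mk(2), mk(9)))$params[["alpha"]], 2)
  expect_error(median_curve(list(mk(1), structure(list(family = "prelec2"),
                                                  class = "dcm_fit"))),
               "mix")
  # the median curve's CR lies inside the daily CR range
  set.seed(15)
  fits <- lapply(runif(9, 0.5, 3), mk)
  crs <- vapply(fits, function(f) curvature_ratio(f$utility), numeric(1))
  cr_med <- curvature_ratio(median_curve(fits))
  expect_gte(cr_med, min(crs)); expect_lte(cr_med, max(crs))
})

test_that("SAC is the relative change in curvature ratio", {
  expect_equal(sac(prelec_s, prelec_s), 0)
  # closed form: power alpha 1 -> 2 gives (1/3 - 1/2)/(1/2) = -1/3
  expect_equal(sac(utility_curve("power1", 2), linear_curve), -1 / 3,
               tolerance = 1e-6)
  # arithmetic: CR 0.5 -> 0.6 is +20%
  f06 <- function(m) 1 - (1 - m)^1.5  # concave curve with CR = 0.6
  expect_equal(curvature_ratio(f06), 0.6, tolerance = 1e-6)
  expect_equal(sac(f06, linear_curve), 0.2, tolerance = 1e-5)
})

test_that("the rescaled full template hits its domain and image anchors", {
  # linear full curve: the template degenerates to the segment itself
  f_lin <- build_adapted_template(linear_curve, dist_low, dist_full)
  x <- seq(0, 0.5, length.out = 21)
  expect_equal(f_lin(x), x, tolerance = 1e-12)
  # construction identity for the lower half range: U_adapt(b*t) =
  # U_full(b) * U_full(t) when U_full(0) = 0
  f_ad <- build_adapted_template(prelec_s, dist_low, dist_full)
  t <- seq(0, 1, length.out = 41)
  expect_equal(f_ad(0.5 * t),
               eval_utility(prelec_s, 0.5) * eval_utility(prelec_s, t),
               tolerance = 1e-12)
  # upper half range: endpoints pinned to the full curve and to 1
  f_hi <- build_adapted_template(prelec_s, dist_high, dist_full)
  expect_equal(f_hi(0.5), eval_utility(prelec_s, 0.5), tolerance = 1e-12)
  expect_equal(f_hi(1), 1, tolerance = 1e-12)
  expect_error(build_adapted_template(prelec_s, dist_alt, dist_full),
               "nested")
})

test_that("GAC identities hold across families and both narrow ranges", {
  curves <- list(prelec_s,
                 utility_curve("prelec2", c(0.7, 1.3)),
                 utility_curve("scdf2", c(2.5, 0.4)),
                 utility_curve("tversky1", 0.6))
  for (cv in curves) {
    for (nd in list(dist_low, dist_high)) {
      # narrow curve = same normalized shape -> full adaptation, GAC 1
      expect_equal(gac(cv, cv, nd, dist_full), 1, tolerance = 1e-5)
      # narrow curve = segment of the full curve -> no adaptation, GAC 0
      seg <- segment_curve(cv, nd, dist_full)
      expect_equal(gac(seg, cv, nd, dist_full), 0, tolerance = 1e-5)
    }
  }
  # a pure power law fits the non-lower-half range too
  pw <- utility_curve("power1", 2)
  expect_equal(gac(pw, pw, dist_high, dist_full), 1, tolerance = 1e-5)
  # linear full curve: denominator vanishes, GAC undefined; likewise a power
  # law on a lower half-range, whose segment is its own rescaled template
  # (power laws are scale-free at the origin)
  expect_error(gac(linear_curve, linear_curve, dist_low, dist_full),
               class = "utiladapt_undefined_gac")
  expect_error(gac(pw, pw, dist_low, dist_full),
               class = "utiladapt_undefined_gac")
})

test_that("partial-adaptation agents land strictly between the GAC poles", {
  full_curve <- prelec_s
  ag <- agent_config(full_curve, lambda = 30, adaptation_mode = "partial",
                     adapt_weight = 0.5, reference = dist_full, seed = 66)
  fits <- lapply(0:2, function(day) {
    tr <- generate_fractile_session(ag, dist_low, day_index = day)
    fit_dcm(tr, "prelec2", dist_low, n_starts = 3, seed = day + 1)
  })
  g <- gac(median_curve(fits), full_curve, dist_low, dist_full)
  expect_gt(g, 0.05)
  expect_lt(g, 0.95)
})

test_that("the Monte-Carlo null separates non- from fully-adapting agents", {
  ag <- agent_config(prelec_s, lambda = 30, seed = 10)
  templates <- rbind(
    generate_fractile_session(ag, dist_low, day_index = 0),
    generate_fractile_session(ag, dist_high, day_index = 1))
  dists <- list(low = dist_low, high = dist_high)
  mc0 <- monte_carlo_no_adaptation(prelec_s, templates, dists, dist_full,
                                   n_reps = 8, seed = 3, lambda = 30,
                                   adaptation_mode = "none")
  mc1 <- monte_carlo_no_adaptation(prelec_s, templates, dists, dist_full,
                                   n_reps = 8, seed = 3, lambda = 30,
                                   adaptation_mode = "full")
  for (lab in c("low", "high")) {
    expect_lt(abs(stats::median(mc0$gac[mc0$distribution == lab])), 0.25)
    expect_lt(abs(stats::median(mc1$gac[mc1$distribution == lab]) - 1), 0.25)
  }
  # determinism
  mc0b <- monte_carlo_no_adaptation(prelec_s, templates, dists, dist_full,
                                    n_reps = 8, seed = 3, lambda = 30,
                                    adaptation_mode = "none")
  expect_identical(mc0$gac, mc0b$gac)
})

test_that("adaptation reports collect metrics, SAC, GAC and predictions", {
  ag <- agent_config(prelec_s, lambda = 30, seed = 20)
  fits_by_dist <- list()
  for (lab in c("low", "full")) {
    d <- reward_distribution(lab)
    fits_by_dist[[lab]] <- lapply(0:1, function(day) {
      tr <- generate_fractile_session(ag, d, day_index = day)
      fit_dcm(tr, "prelec2", d, n_starts = 3, seed = day + 5)
    })
  }
  rep <- adaptation_report(fits_by_dist,
                           list(low = dist_low, full = dist_full))
  expect_s3_class(rep, "adaptation_report")
  expect_equal(rep$metrics$distribution, c("low", "full"))
  expect_equal(nrow(rep$sac), 1)
  expect_equal(rep$gac$distribution, "low")
  # fully adapting agent: same normalized shape, so SAC near 0, GAC near 1
  expect_lt(abs(rep$sac$sac), 0.15)
  expect_gt(rep$gac$gac, 0.7)
  expect_false(rep$predicted_inflections$clipped)
})
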