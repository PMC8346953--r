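# parameter draws used by the property-style checks
sample_params <- function(family, n = 8, seed = 101) {
  set.seed(seed)
  b <- utility_param_bounds(family)
  lapply(seq_len(n), function(i) {
    vapply(seq_along(b$names), function(j) {
      nm <- b$names[j]
      if (nm %in% c("alpha", "beta") && b$upper[j] > 1) {
        exp(stats::runif(1, log(0.3), log(4)))      # curvature/elevation
      } else if (family == "tversky1") {
        exp(stats::runif(1, log(0.35), log(3)))
      } else {
        stats::runif(1, 0.1, 0.9)                   # interval knots
      }
    }, numeric(1))
  })
}

test_that("anchored families hit exactly 0 and 1 at the domain ends", {
  for (family in utility_families()) {
    for (p in sample_params(family)) {
      cv <- utility_curve(family, p)
      expect_lt(abs(eval_utility(cv, 0)), 1e-9)
      expect_lt(abs(eval_utility(cv, 1) - 1), 1e-9)
    }
  }
})

test_that("all in-bounds curves are monotone non-decreasing", {
  m <- seq(0, 1, length.out = 1e4)
  for (family in utility_families()) {
    for (p in sample_params(family, seed = 202)) {
      u <- eval_utility(utility_curve(family, p), m)
      expect_true(all(diff(u) >= -1e-10),
                  label = sprintf("%s(%s) monotone", family,
                                  paste(round(p, 3), collapse = ",")))
    }
  }
})

test_that("Prelec with alpha = 1 coincides with a power law", {
  m <- seq(0, 1, length.out = 1001)
  for (b in c(0.4, 1, 2.5)) {
    d <- max(abs(eval_utility(utility_curve("prelec2", c(1, b)), m) - m^b))
    expect_lt(d, 1e-12)
  }
})

test_that("the two-sided-power branches agree at the knot", {
  for (p in sample_params("scdf2", seed = 303)) {
    a <- p[1]; b <- p[2]
    below <- b * (b / b)^a
    above <- 1 - (1 - b) * ((1 - b) / (1 - b))^a
    expect_equal(below, above, tolerance = 1e-12)
    expect_equal(eval_utility(utility_curve("scdf2", p), b), b,
                 tolerance = 1e-12)
  }
})

test_that("two-sided-power curvature follows its alpha (S vs inverse-S)", {
  for (a in c(2, 3)) {
    cv <- utility_curve("scdf2", c(a, 0.5))
    u <- eval_utility(cv, seq(0.01, 0.49, length.out = 201))
    expect_true(all(diff(diff(u)) > 0))  # convex below the knot
    u2 <- eval_utility(cv, seq(0.51, 0.99, length.out = 201))
    expect_true(all(diff(diff(u2)) < 0))  # concave above
  }
  cv <- utility_curve("scdf2", c(0.5, 0.5))
  u <- eval_utility(cv, seq(0.01, 0.49, length.out = 201))
  expect_true(all(diff(diff(u)) < 0))  # inverse-S: concave below the knot
})

test_that("inflection points match the dense-grid oracle", {
  expect_true(is.na(inflection_point(utility_curve("power1", 2))))
  expect_true(is.na(inflection_point(utility_curve("power1", 0.5))))
  # kinked families: inflection at the knot
  expect_equal(inflection_point(utility_curve("scdf2", c(3, 0.35))), 0.35)
  expect_equal(inflection_point(utility_curve("power3", c(0.6, 1, 0.4))), 0.4)
  # smooth families: within 1e-4 of a brute-force second-difference scan
  for (p in list(c(2, 1), c(3, 0.8), c(1.6, 1.4))) {
    cv <- utility_curve("prelec2", p)
    oracle <- grid_inflection_oracle(function(m) eval_utility(cv, m))
    expect_equal(inflection_point(cv), oracle, tolerance = 1e-4)
  }
  cv <- utility_curve("tversky1", 0.6)
  oracle <- grid_inflection_oracle(function(m) eval_utility(cv, m))
  expect_equal(inflection_point(cv), oracle, tolerance = 1e-4)
})

test_that("curvature ratio: closed forms, symmetry and continuity", {
  expect_equal(curvature_ratio(utility_curve("power1", 1)), 0.5)
  # closed form: int m^a = 1/(a+1)
  for (a in c(0.5, 2, 3)) {
    expect_equal(curvature_ratio(utility_curve("power1", a)), 1 / (a + 1),
                 tolerance = 1e-5)
  }
  # point-symmetric curve about (0.5, 0.5): CR + reflected CR = 1
  cv <- utility_curve("scdf2", c(2, 0.5))
  f <- function(m) eval_utility(cv, m)
  refl <- function(m) 1 - f(1 - m)
  expect_equal(curvature_ratio(f) + curvature_ratio(refl), 1,
               tolerance = 1e-9)
  # small parameter perturbations move CR by little
  for (family in c("prelec2", "scdf2")) {
    p <- c(1.7, if (family == "scdf2") 0.4 else 1.2)
    cr0 <- curvature_ratio(utility_curve(family, p))
    cr1 <- curvature_ratio(utility_curve(family, p + 1e-6))
    expect_lt(abs(cr1 - cr0), 1e-4)
  }
})

test_that("parameter bounds are enforced and curves serialize losslessly", {
  expect_error(utility_curve("scdf2", c(2, 1.5)), "outside bounds")
  expect_error(utility_curve("prelec2", 2), "takes 2")
  expect_error(eval_utility(prelec_s, 1.2), "domain")
  js <- curve_to_json(prelec_s, dist_low)
  cv <- curve_from_json(js)
  expect_equal(cv$params, prelec_s$params)
  expect_equal(attr(cv, "distribution")$max_ml, 0.5)
})
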