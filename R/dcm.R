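#' Expected utility of a reward option
#'
#' Expected utility under objective probabilities: the probability-weighted
#' sum of the utilities of an option's outcomes, with magnitudes normalized
#' to the option's reward distribution.  Probability distortion is
#' deliberately absent: every gamble here is equiprobable (p = 0.5), where
#' distortion is negligible, so option value is plain EU.
#'
#' @param option a [gamble()] or [safe()] option.
#' @param curve a [utility_curve()].
#' @param distribution the [reward_distribution()] anchoring the utility.
#' @return EU in `[0, 1]`.
#' @examples
#' d <- reward_distribution("low")
#' expected_utility(gamble(0, 0.5), utility_curve("prelec2", c(2, 1)), d)
#' # 0.5 utils for any anchored curve: 0.5 * U(0) + 0.5 * U(1)
#' @export
expected_utility <- function(option, curve, distribution) {
  stopifnot(inherits(option, "reward_option"))
  sum(option$p * eval_utility(curve, normalize_ce(option$m, distribution)))
}

# wide trial columns -> matrices of normalized magnitudes and probabilities
# (safe options become a single outcome with the second slot zero-weighted)
trial_matrices <- function(trials, distribution) {
  grab <- function(side) {
    m1 <- trials[[paste0(side, "_m1")]]
    p1 <- trials[[paste0(side, "_p1")]]
    m2 <- trials[[paste0(side, "_m2")]]
    p2 <- trials[[paste0(side, "_p2")]]
    p2[is.na(p2)] <- 0
    m2[is.na(m2)] <- distribution$min_ml
    list(m1 = normalize_ce(m1, distribution), p1 = p1,
         m2 = normalize_ce(m2, distribution), p2 = p2)
  }
  list(left = grab("left"), right = grab("right"),
       chose_left = trials$chosen == "left")
}

eu_side <- function(side, curve) {
  side$p1 * eval_utility(curve, side$m1) +
    side$p2 * eval_utility(curve, side$m2)
}

nll_from_matrices <- function(mats, curve, lambda, theta, clamp = 1e-12) {
  eu_l <- eu_side(mats$left, curve)
  eu_r <- eu_side(mats$right, curve)
  p_left <- stats::plogis(lambda * (eu_l - eu_r) + theta)
  p_left <- pmin(pmax(p_left, clamp), 1 - clamp)
  -sum(log(ifelse(mats$chose_left, p_left, 1 - p_left)))
}

#' Negative log-likelihood of trial-level choices under the logit model
#'
#' The choice rule is a logit on the expected-utility difference:
#' `P(left) = 1 / (1 + exp(-lambda * (EU_left - EU_right) - theta))`, with
#' temperature `lambda` (steeper = more deterministic) and additive side
#' bias `theta` (positive biases toward the left option).  The likelihood
#' is the left/right Bernoulli over trials; probabilities are clamped away
#' from 0/1 by 1e-12 to keep the log finite.
#'
#' @param trials trial data frame in the canonical layout (see
#'   [read_trials()]).
#' @param curve a [utility_curve()].
#' @param lambda,theta choice-noise and side-bias parameters.
#' @param distribution the session's [reward_distribution()].
#' @return cumulative negative log-likelihood (>= 0).
#' @export
neg_log_likelihood <- function(trials, curve, lambda, theta, distribution) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trials supplied", call. = FALSE)
  }
  if (any(is.na(trials$chosen))) stop("every trial needs a recorded choice",
                                      call. = FALSE)
  nll_from_matrices(trial_matrices(trials, distribution), curve,
                    lambda, theta)
}

# --- fast fitting core ----------------------------------------------------
# Bare-metal per-family evaluators used inside the optimizer: no input
# validation, utilities computed once per unique normalized magnitude (the
# fractile ladders repeat few distinct values), analytic parameter gradients
# for the smooth one/two-parameter families.

fast_u <- function(family) {
  switch(family,
    power1 = function(m, p) m^p[1],
    tversky1 = function(m, p) {
      g <- p[1]
      mm <- pmin(pmax(m, 1e-12), 1 - 1e-12)
      u <- mm^g / (mm^g + (1 - mm)^g)^(1 / g)
      u[m <= 0] <- 0; u[m >= 1] <- 1
      u
    },
    prelec2 = function(m, p) {
      mm <- pmax(m, 1e-12)
      u <- exp(-p[2] * (-log(mm))^p[1])
      u[m <= 0] <- 0
      u
    },
    scdf2 = function(m, p) {
      a <- p[1]; b <- p[2]
      ifelse(m <= b, b * (m / b)^a, 1 - (1 - b) * ((1 - m) / (1 - b))^a)
    },
    power3 = function(m, p) {
      a <- p[1]; b <- p[2]; g <- p[3]
      raw <- ifelse(m >= g, (m - g)^a, -b * (g - m)^a)
      r0 <- -b * g^a
      (raw - r0) / ((1 - g)^a - r0)
    })
}

# dU/dparam (matrix: length(m) x n_params), or NULL when no tractable form
fast_du <- function(family) {
  switch(family,
    power1 = function(m, p, u) {
      d <- u * log(pmax(m, 1e-300))
      d[m <= 0] <- 0
      matrix(d, ncol = 1)
    },
    prelec2 = function(m, p, u) {
      t <- -log(pmax(m, 1e-12))
      ta <- t^p[1]
      lt <- ifelse(t > 0, log(t), 0)
      da <- -p[2] * u * ta * lt
      db <- -u * ta
      da[m <= 0] <- 0; db[m <= 0] <- 0
      cbind(da, db)
    },
    NULL)
}

# objective/gradient pair on the free parameter vector c(par_u, lambda, theta)
make_dcm_objective <- function(trials, distribution, family,
                               fix_beta = TRUE, clamp = 1e-12) {
  mats <- trial_matrices(trials, distribution)
  mm <- c(mats$left$m1, mats$left$m2, mats$right$m1, mats$right$m2)
  uv <- unique(mm)
  n <- nrow(trials)
  idx <- matrix(match(mm, uv), ncol = 4)
  p1l <- mats$left$p1; p2l <- mats$left$p2
  p1r <- mats$right$p1; p2r <- mats$right$p2
  y <- mats$chose_left
  fp <- dcm_free_params(family, fix_beta)
  k_u <- length(fp$names)
  expand <- function(par_u) {
    if (family == "power3" && fix_beta) c(par_u[1], 1, par_u[2]) else par_u
  }
  u_of <- fast_u(family)
  du_of <- fast_du(family)
  fn <- function(par) {
    pu <- expand(par[seq_len(k_u)])
    u <- u_of(uv, pu)
    deu <- p1l * u[idx[, 1]] + p2l * u[idx[, 2]] -
           p1r * u[idx[, 3]] - p2r * u[idx[, 4]]
    p <- stats::plogis(par[k_u + 1] * deu + par[k_u + 2])
    p <- pmin(pmax(p, clamp), 1 - clamp)
    v <- -(sum(log(p[y])) + sum(log1p(-p[!y])))
    if (!is.finite(v)) 1e12 else v
  }
  gr <- if (is.null(du_of) || (family == "power3" && !fix_beta)) NULL else
    function(par) {
      pu <- expand(par[seq_len(k_u)])
      lambda <- par[k_u + 1]
      u <- u_of(uv, pu)
      du <- du_of(uv, pu, u)
      deu <- p1l * u[idx[, 1]] + p2l * u[idx[, 2]] -
             p1r * u[idx[, 3]] - p2r * u[idx[, 4]]
      p <- stats::plogis(lambda * deu + par[k_u + 2])
      p <- pmin(pmax(p, clamp), 1 - clamp)
      w <- p - y   # dNLL/dz per trial
      g_u <- vapply(seq_len(k_u), function(j) {
        dj <- du[, j]
        ddeu <- p1l * dj[idx[, 1]] + p2l * dj[idx[, 2]] -
                p1r * dj[idx[, 3]] - p2r * dj[idx[, 4]]
        lambda * sum(w * ddeu)
      }, numeric(1))
      c(g_u, sum(w * deu), sum(w))
    }
  list(fn = fn, gr = gr, k_u = k_u, fp = fp)
}

dcm_free_params <- function(family, fix_beta = TRUE) {
  info <- utility_param_bounds(family)
  free <- info$names
  if (family == "power3" && fix_beta) free <- setdiff(free, "beta")
  i <- match(free, info$names)
  list(names = free, lower = info$lower[i], upper = info$upper[i])
}

build_curve <- function(family, free_values, free_names, fix_beta = TRUE) {
  info <- utility_param_bounds(family)
  params <- stats::setNames(rep(NA_real_, length(info$names)), info$names)
  params[free_names] <- free_values
  if (family == "power3" && fix_beta) params[["beta"]] <- 1
  utility_curve(family, params)
}

# Latin-hypercube start points: positive curvature/elevation parameters are
# sampled log-uniformly on a moderate subrange, interval-bounded knots
# uniformly away from their edges, lambda log-uniform, theta uniform.
dcm_starts <- function(family, n_starts, fix_beta = TRUE) {
  fp <- dcm_free_params(family, fix_beta)
  k_u <- length(fp$names)
  heur <- switch(family,
    power1 = 1, tversky1 = 1, prelec2 = c(1, 1), scdf2 = c(1, 0.5),
    power3 = if (fix_beta) c(1, 0.5) else c(1, 1, 0.5))
  starts <- matrix(c(heur, 5, 0), nrow = 1)
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1, k_u + 2)
    pts <- matrix(NA_real_, n_starts - 1, k_u + 2)
    for (j in seq_len(k_u)) {
      nm <- fp$names[j]
      if (nm %in% c("alpha", "beta") && fp$upper[j] > 1) {
        lo <- max(fp$lower[j], 0.2); hi <- min(fp$upper[j], 5)
        pts[, j] <- exp(log(lo) + u[, j] * (log(hi) - log(lo)))
      } else if (nm == "gamma" && family == "tversky1") {
        pts[, j] <- exp(log(0.35) + u[, j] * (log(5) - log(0.35)))
      } else {
        pts[, j] <- 0.1 + u[, j] * 0.8  # interval knots (scdf beta, p3 gamma)
      }
    }
    pts[, k_u + 1] <- exp(log(0.5) + u[, k_u + 1] * (log(100) - log(0.5)))
    pts[, k_u + 2] <- -2 + u[, k_u + 2] * 4
    starts <- rbind(starts, pts)
  }
  starts
}

#' Fit the discrete choice model to one session's trials
#'
#' Maximum-likelihood estimation of a utility family's parameters plus the
#' logit temperature and side bias, by bounded local optimization
#' (`L-BFGS-B`) from multiple start points (one heuristic start plus
#' Latin-hypercube draws inside the parameter bounds); the best converged
#' start is retained.  The free-parameter count `k` includes `lambda` and
#' `theta`; for the three-parameter power family the loss-aversion weight
#' `beta` is fixed at 1 by default (all magnitudes here are gains), leaving
#' two free utility parameters.
#'
#' @param trials trial data frame for one session/distribution.
#' @param family one of `utility_families()`.
#' @param distribution the session's [reward_distribution()].
#' @param n_starts number of optimizer starts.
#' @param seed optional integer; makes the start draws reproducible.
#' @param fix_beta fix the `power3` loss-aversion weight at 1.
#' @param lambda_bounds,theta_bounds box constraints on the choice
#'   parameters.
#' @param init optional start vector `c(utility params, lambda, theta)`
#'   replacing the heuristic start (e.g. warm starts in cross-validation).
#' @return an object of class `dcm_fit`: the fitted [utility_curve()],
#'   `lambda`, `theta`, `neg_ll`, `n_trials`, `k`, `bic`, `converged`.
#' @export
fit_dcm <- function(trials, family, distribution, n_starts = 10,
                    seed = NULL, fix_beta = TRUE,
                    lambda_bounds = c(0, 1000), theta_bounds = c(-10, 10),
                    init = NULL) {
  family <- match.arg(family, utility_families())
  fp <- dcm_free_params(family, fix_beta)
  n <- nrow(trials)
  if (n < length(fp$names) + 2 + 10) {
    stop("too few trials to fit '", family, "' (need at least k + 10)",
         call. = FALSE)
  }
  core <- make_dcm_objective(trials, distribution, family, fix_beta)
  k_u <- core$k_u
  if (!is.null(seed)) set.seed(seed)
  starts <- dcm_starts(family, n_starts, fix_beta)
  if (!is.null(init)) starts <- rbind(init, starts[-1, , drop = FALSE])
  lower <- c(fp$lower, lambda_bounds[1], theta_bounds[1])
  upper <- c(fp$upper, lambda_bounds[2], theta_bounds[2])
  best <- NULL
  diagnostics <- character(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], core$fn, gr = core$gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e6, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) {
      diagnostics[s] <- "optimizer error"
      next
    }
    diagnostics[s] <- sprintf("value %.4f (convergence %d)", res$value,
                              res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e12) {
    stop("all optimizer starts failed:\n",
         paste(diagnostics, collapse = "\n"), call. = FALSE)
  }
  curve <- build_curve(family, best$par[seq_len(k_u)], fp$names, fix_beta)
  k <- k_u + 2
  fit <- structure(list(
    family = family,
    utility = curve,
    lambda = unname(best$par[k_u + 1]),
    theta = unname(best$par[k_u + 2]),
    neg_ll = best$value,
    n_trials = n,
    k = k,
    bic = k * log(n) + 2 * best$value,
    cv_negll = NA_real_,
    converged = best$convergence == 0,
    distribution = distribution$label
  ), class = "dcm_fit")
  fit
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf(
    "<dcm_fit %s(%s), lambda = %.3g, theta = %.3g; -LL = %.2f, BIC = %.2f, n = %d>\n",
    x$family, paste(sprintf("%.3g", x$utility$params), collapse = ", "),
    x$lambda, x$theta, x$neg_ll, x$bic, x$n_trials))
  invisible(x)
}

#' Bayesian information criterion of a discrete-choice fit
#'
#' `BIC = k * ln(n) - 2 * LogLikelihood`, i.e. `k * ln(n) + 2 * neg_ll`;
#' `k` counts the utility parameters plus `lambda` and `theta`.
#'
#' @param fit a `dcm_fit`.
#' @return the BIC (lower is better).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "dcm_fit"))
  fit$k * log(fit$n_trials) + 2 * fit$neg_ll
}

#' K-fold cross-validation of a discrete-choice fit
#'
#' Trials are split into `k_folds` random folds (stratified by
#' `sequence_tag` when present, so each fold sees every gamble type); the
#' model is refit on each training set and scored by the held-out negative
#' log-likelihood.  The reported score is the mean of the fold scores;
#' lower means better out-of-sample prediction.
#'
#' @inheritParams fit_dcm
#' @param k_folds number of folds.
#' @param n_starts optimizer starts per refit.
#' @param init optional warm-start vector for the refits, typically the
#'   full-data fit's parameters.
#' @return list with `cv_negll` (mean held-out NLL per fold),
#'   `per_trial_negll`, `fold_negll`, and the fold assignment.
#' @export
crossvalidate <- function(trials, family, distribution, k_folds = 10,
                          seed = NULL, n_starts = 3, fix_beta = TRUE,
                          init = NULL) {
  n <- nrow(trials)
  if (n < 20) stop("need at least 20 trials for cross-validation",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  strat <- if (!is.null(trials$sequence_tag)) trials$sequence_tag
           else rep("all", n)
  for (tag in unique(strat)) {
    idx <- which(strat == tag)
    folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  if (any(tabulate(folds, k_folds) < 1)) {
    stop("a fold received no trials; use fewer folds", call. = FALSE)
  }
  fold_nll <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    train <- trials[folds != f, , drop = FALSE]
    test <- trials[folds == f, , drop = FALSE]
    fit <- fit_dcm(train, family, distribution, n_starts = n_starts,
                   fix_beta = fix_beta, init = init)
    fold_nll[f] <- neg_log_likelihood(test, fit$utility, fit$lambda,
                                      fit$theta, distribution)
  }
  list(cv_negll = mean(fold_nll),
       per_trial_negll = sum(fold_nll) / n,
       fold_negll = fold_nll,
       folds = folds)
}

#' Flag implausible fits by the pooled ln-parameter rule
#'
#' Pools the ln-transformed utility parameters of all supplied fits (all
#' days, all subjects) and excludes any fit whose ln-parameter lies more
#' than `n_sd` standard deviations from the pooled mean.  A degenerate pool
#' (zero SD) excludes nothing; non-positive parameter values, whose log is
#' undefined, are excluded with an explicit reason.
#'
#' @param fits list of `dcm_fit` objects (same family).
#' @param n_sd exclusion threshold in pooled standard deviations.
#' @return list with `kept`, `excluded`, logical `keep`, and `reasons`.
#' @export
flag_outliers <- function(fits, n_sd = 3) {
  stopifnot(length(fits) >= 3)
  fam <- unique(vapply(fits, function(f) f$family, character(1)))
  if (length(fam) != 1) stop("fits mix utility families", call. = FALSE)
  par_mat <- do.call(rbind, lapply(fits, function(f) f$utility$params))
  reasons <- character(length(fits))
  keep <- rep(TRUE, length(fits))
  nonpos <- apply(par_mat <= 0, 1, any)
  keep[nonpos] <- FALSE
  reasons[nonpos] <- "non-positive parameter (ln undefined)"
  lp <- log(par_mat[!nonpos, , drop = FALSE])
  for (j in seq_len(ncol(lp))) {
    mu <- mean(lp[, j]); sdv <- stats::sd(lp[, j])
    if (!is.finite(sdv) || sdv == 0) next
    out <- abs(lp[, j] - mu) > n_sd * sdv
    idx <- which(!nonpos)[out]
    keep[idx] <- FALSE
    reasons[idx] <- paste0("ln(", colnames(par_mat)[j],
                           ") beyond ", n_sd, " pooled SD")
  }
  list(kept = fits[keep], excluded = fits[!keep], keep = keep,
       reasons = reasons)
}
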