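# Lower-triangular-ish factor L with L L' = Sigma for a PSD matrix,
# via (pivoted) Cholesky. The Monte Carlo draw is T0 = T + L z, z ~ N(0, I6),
# with z drawn as rnorm(6) per plot in plot order -- this draw order is part
# of the reproducibility contract.
psd_factor <- function(Sigma) {
  Sigma <- (Sigma + t(Sigma)) / 2
  if (all(Sigma == 0)) return(matrix(0, nrow(Sigma), ncol(Sigma)))
  L <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  R <- suppressWarnings(chol(Sigma, pivot = TRUE))
  piv <- attr(R, "pivot")
  t(R[, order(piv), drop = FALSE])
}

#' Monte Carlo covariance of the NDES limit
#'
#' Propagates parameter uncertainty to the limit composition: for each plot,
#' one parameter vector \eqn{T^0 \sim N(T, \Sigma)} is drawn (Cholesky
#' factor of \eqn{\Sigma}, seeded), the map's limit is computed with
#' \eqn{T^0} as parameters starting the iteration from that plot's latter
#' observed abundance, and \eqn{\Sigma^*} is the sample covariance of the
#' `n` simulated limit vectors. Draws violating \eqn{t_1 > 0, t_2 > 0} or
#' failing to converge are redrawn (up to `max_redraws` per plot); if more
#' than 10% of the nominal draws need redrawing the parameter covariance is
#' too wide for the positivity constraint and an error is raised.
#'
#' Because each simulated limit lies on the simplex, the nine entries of
#' \eqn{\Sigma^*} sum to zero.
#'
#' @param fit an `ndes_fit` (or a list with elements `par` and `cov`).
#' @param initial_abundances `n x 3` matrix of latter observed abundance
#'   triples, one row per plot.
#' @param seed integer seed for the parameter draws.
#' @param draws_per_plot draws per plot (default 1, the reference scheme;
#'   larger values are a variance-of-variance diagnostic).
#' @param max_redraws redraw cap per draw slot (default 100).
#' @param tol,max_iter fixed-point iteration control for each draw.
#' @param ... passed to [ndes_fixed_point()] for the point estimate `y_star`
#'   (e.g. `start =` to resolve a multistable fitted map to the attractor of
#'   the observed basin).
#' @return an object of class `"ndes_limit_estimate"`: list with `y_star`
#'   (limit at the fitted parameters, multi-start checked), `sigma_star`
#'   (3x3 covariance), `limits` (`draws x 3` simulated limits), `n`,
#'   `draws`, `redraws`, `seed`.
#' @export
mc_limit_covariance <- function(fit, initial_abundances, seed = 1L,
                                draws_per_plot = 1L, max_redraws = 100L,
                                tol = 1e-10, max_iter = 1e5L, ...) {
  T <- as_params(fit$par)
  Sigma <- fit$cov
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == 6L))
  Y0 <- as.matrix(initial_abundances)
  if (ncol(Y0) != 3L || nrow(Y0) < 2L)
    stop("initial_abundances must be an n x 3 matrix with n >= 2")
  apply(Y0, 1, assert_simplex, what = "initial abundance")
  n <- nrow(Y0)
  L <- psd_factor(Sigma)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(child_seed(seed, "mc"))
  n_draws <- n * as.integer(draws_per_plot)
  lims <- matrix(NA_real_, n_draws, 3, dimnames = list(NULL, GROUPS))
  redraws <- 0L
  slot <- 0L
  for (i in seq_len(n)) {
    for (d in seq_len(draws_per_plot)) {
      slot <- slot + 1L
      ok <- FALSE
      for (try in 0:max_redraws) {
        T0 <- as.numeric(T) + as.vector(L %*% stats::rnorm(6))
        if (T0[1] <= 0 || T0[2] <= 0) { redraws <- redraws + 1L; next }
        it <- iterate_fixed_point(Y0[i, ], T0, tol = tol, max_iter = max_iter)
        if (!it$converged) { redraws <- redraws + 1L; next }
        lims[slot, ] <- it$y
        ok <- TRUE
        break
      }
      if (!ok) stop("plot ", i, ": no valid parameter draw within ",
                    max_redraws, " redraws", call. = FALSE)
    }
  }
  if (redraws > 0.10 * n_draws)
    stop("more than 10% of Monte Carlo draws were invalid (", redraws, "/",
         n_draws, "); the parameter covariance is too wide for the ",
         "t1, t2 > 0 constraint", call. = FALSE)
  structure(list(y_star = ndes_fixed_point(T, seed = seed, ...)$y_star,
                 sigma_star = stats::cov(lims),
                 limits = lims, n = n, draws = n_draws,
                 redraws = redraws, seed = seed),
            class = "ndes_limit_estimate")
}

#' @export
print.ndes_limit_estimate <- function(x, ...) {
  cat("NDES limit with Monte Carlo uncertainty (", x$draws, " draws, ",
      x$redraws, " redraws)\n", sep = "")
  print(round(x$y_star, 4))
  cat("Sigma* (limit covariance):\n")
  print(signif(x$sigma_star, 4))
  invisible(x)
}

# Normal distribution truncated to [0, 1]: distribution function and
# quantile by analytic inversion of the CDF (exact; equivalent to
# root-finding on the CDF at machine precision).
ptruncnorm01 <- function(q, mean, sd) {
  Fa <- stats::pnorm(0, mean, sd); Fb <- stats::pnorm(1, mean, sd)
  pmin(1, pmax(0, (stats::pnorm(q, mean, sd) - Fa) / (Fb - Fa)))
}

qtruncnorm01 <- function(p, mean, sd) {
  Fa <- stats::pnorm(0, mean, sd); Fb <- stats::pnorm(1, mean, sd)
  pmin(1, pmax(0, stats::qnorm(Fa + p * (Fb - Fa), mean, sd)))
}

#' Truncated-normal interval for one limit component
#'
#' Central (equal-tail) confidence interval for a single species group's
#' abundance limit under a normal density truncated and renormalised to
#' \eqn{[0, 1]}: \eqn{p_{tr}(y) = p(y; y^*, \sigma^2) / \tau} with
#' \eqn{\tau = \int_0^1 p(y; y^*, \sigma^2)\,dy}. Each tail carries
#' \eqn{(1 - level)/2} of the truncated mass.
#'
#' @param point point estimate \eqn{y^*} of the limit component, in
#'   \eqn{[0, 1]}.
#' @param sigma standard deviation of the untruncated normal (> 0).
#' @param level confidence level in (0, 1), default 0.95.
#' @return an object of class `"truncnorm_interval"`: list with `point`,
#'   `sigma`, `level`, `lower`, `upper`.
#' @examples
#' truncnorm_interval(0.0408, 0.00273, 0.95)
#' @export
truncnorm_interval <- function(point, sigma, level = 0.95) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  if (point < 0 || point > 1) stop("point must lie in [0, 1]")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  structure(list(point = point, sigma = sigma, level = level,
                 lower = qtruncnorm01(a, point, sigma),
                 upper = qtruncnorm01(1 - a, point, sigma)),
            class = "truncnorm_interval")
}

#' @export
print.truncnorm_interval <- function(x, ...) {
  cat(sprintf("%.0f%% truncated-normal interval: [%.4f, %.4f] (point %.4f, sigma %.5f)\n",
              100 * x$level, x$lower, x$upper, x$point, x$sigma))
  invisible(x)
}

#' Calibrate the truncated-normal sigma to a reported interval
#'
#' Solves for the standard deviation whose equal-tail interval at `level`
#' has the width of a reported interval `[lower, upper]` around `point`.
#' Interval width is strictly increasing in sigma, so the root is unique.
#'
#' @param point point estimate in \eqn{[0, 1]}.
#' @param lower,upper reported interval endpoints.
#' @param level level of the reported interval (default 0.95).
#' @return the calibrated sigma.
#' @export
calibrate_truncnorm_sigma <- function(point, lower, upper, level = 0.95) {
  stopifnot(lower < upper)
  a <- (1 - level) / 2
  width <- function(s) qtruncnorm01(1 - a, point, s) - qtruncnorm01(a, point, s)
  stats::uniroot(function(s) width(s) - (upper - lower),
                 interval = c(1e-8, 10), tol = 1e-12)$root
}

#' F-test of a hypothesized limit composition
#'
#' Hotelling-style test of \eqn{H_0: Y^* = Y_0} on the first two limit
#' components (pine, fir); the third is determined by the sum-to-one
#' constraint, which also makes the full 3x3 limit covariance rank 2. The
#' statistic is
#' \deqn{F = \frac{n - p}{(n - 1) p} (Y^{*(2)} - Y_0^{(2)})' (\Sigma^{*(2)})^{-1}
#'   (Y^{*(2)} - Y_0^{(2)}) \sim F(p, n - p), \quad p = 2.}
#'
#' @param y_star_2 first two components of the estimated limit.
#' @param y0_2 first two components of the hypothesized limit (e.g.
#'   `c(0, 0)` for joint pine-and-fir extinction).
#' @param sigma_2 2x2 top-left block of the limit covariance \eqn{\Sigma^*}.
#' @param n number of plots behind \eqn{\Sigma^*}.
#' @return an object of class `"ndes_f_test"`: list with `F`, `df1`, `df2`,
#'   `p_value`, `hypothesis`.
#' @examples
#' limit_f_test(c(0.3, 0.2), c(0, 0), diag(0.01, 2), n = 100)
#' @export
limit_f_test <- function(y_star_2, y0_2, sigma_2, n) {
  p <- 2L
  stopifnot(length(y_star_2) == 2L, length(y0_2) == 2L,
            is.matrix(sigma_2), all(dim(sigma_2) == 2L))
  if (n <= p) stop("need n > 2 plots")
  inv <- tryCatch(solve(sigma_2), error = function(e)
    stop("singular 2x2 limit covariance", call. = FALSE))
  d <- as.numeric(y_star_2 - y0_2)
  F <- (n - p) / ((n - 1) * p) * as.numeric(t(d) %*% inv %*% d)
  structure(list(F = F, df1 = p, df2 = n - p,
                 p_value = stats::pf(F, p, n - p, lower.tail = FALSE),
                 hypothesis = as.numeric(y0_2)),
            class = "ndes_f_test")
}

#' @export
print.ndes_f_test <- function(x, ...) {
  cat(sprintf("limit F-test vs Y0(2) = (%.4f, %.4f): F(%d, %d) = %.2f, p = %.6f\n",
              x$hypothesis[1], x$hypothesis[2], x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Full inference report for a limit estimate
#'
#' Assembles the limit point estimate, its Monte Carlo covariance, per-group
#' truncated-normal intervals at the requested levels, and the three
#' extinction-hypothesis F-tests (pine to zero, fir to zero, both to zero,
#' in each case reallocating the lost share to broadleaf).
#'
#' @param est an `ndes_limit_estimate` from [mc_limit_covariance()].
#' @param levels confidence levels for the intervals.
#' @return a named list (JSON-ready): `y_star`, `sigma_star`, `intervals`
#'   (data frame), `f_tests` (data frame with 6-decimal p-values), `n`,
#'   `draws`.
#' @export
inference_report <- function(est, levels = c(0.95, 0.99)) {
  stopifnot(inherits(est, "ndes_limit_estimate"))
  y <- est$y_star
  sds <- sqrt(diag(est$sigma_star))
  iv <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(group = GROUPS, level = lv, point = as.numeric(y),
               sigma = sds,
               lower = vapply(1:3, function(i)
                 truncnorm_interval(y[i], sds[i], lv)$lower, 0),
               upper = vapply(1:3, function(i)
                 truncnorm_interval(y[i], sds[i], lv)$upper, 0))
  }))
  hyps <- list(pine_extinct = c(0, y[2]),
               fir_extinct = c(y[1], 0),
               both_extinct = c(0, 0))
  s2 <- est$sigma_star[1:2, 1:2]
  ft <- do.call(rbind, lapply(names(hyps), function(h) {
    r <- limit_f_test(y[1:2], hyps[[h]], s2, est$n)
    data.frame(hypothesis = h, F = r$F, df1 = r$df1, df2 = r$df2,
               p_value = as.numeric(sprintf("%.6f", r$p_value)))
  }))
  list(y_star = as.list(y), sigma_star = unname(est$sigma_star),
       intervals = iv, f_tests = ft, n = est$n, draws = est$draws)
}
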