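make_fit_stub <- function(T, cov) list(par = as_params_stub(T), cov = cov)
as_params_stub <- function(T) structure(stats::setNames(as.numeric(T),
  paste0("t", 1:6)), class = "ndes_params")

test_that("zero parameter covariance gives identical limits and zero Sigma*", {
  T <- zhejiang_params("2014-2019")
  inits <- random_simplex(25, seed = 201)
  est <- mc_limit_covariance(make_fit_stub(T, matrix(0, 6, 6)), inits, seed = 1)
  expect_equal(max(abs(est$sigma_star)), 0)
  # every plot's limit is the same despite different initial values
  expect_lt(max(apply(est$limits, 2, function(z) diff(range(z)))), 1e-9)
  expect_equal(est$redraws, 0L)
})

test_that("Sigma* rows, columns and total sum to zero (simplex constraint)", {
  cfg <- synthetic_config(n_plots = 120, noise_concentration = 200, seed = 202)
  p <- generate_plot_pairs(cfg)
  fit <- fit_ndes(p)
  est <- mc_limit_covariance(fit, as.matrix(p[c("y11", "y21", "y31")]), seed = 7)
  expect_lt(max(abs(rowSums(est$sigma_star))), 1e-10)
  expect_lt(max(abs(colSums(est$sigma_star))), 1e-10)
  expect_lt(abs(sum(est$sigma_star)), 1e-10)
  expect_gt(min(eigen(est$sigma_star, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-12)
})

test_that("seeded Monte Carlo matches an independently coded loop oracle draw-for-draw", {
  T <- as.numeric(zhejiang_params("2014-2019"))
  Sigma <- diag(c(0, 0, rep(1e-4, 4)))
  inits <- random_simplex(500, seed = 203)
  seed <- 11L
  est <- mc_limit_covariance(make_fit_stub(T, Sigma), inits, seed = seed)

  # oracle: re-derives the draw scheme from its documented contract --
  # child seed (seed * 97 + 53) mod (2^31 - 1), one rnorm(6) per plot in
  # plot order, T0 = T + L z with L the (pivoted) Cholesky factor of Sigma,
  # plain Picard iteration
  R <- suppressWarnings(chol(Sigma, pivot = TRUE))
  L <- t(R[, order(attr(R, "pivot")), drop = FALSE])
  set.seed((seed * 97 + 53) %% 2147483647)
  olims <- matrix(NA_real_, 500, 3)
  for (i in 1:500) {
    T0 <- T + as.vector(L %*% rnorm(6))
    y <- as.numeric(inits[i, ])
    repeat {
      a <- y[1]; b <- y[2]
      l <- c(0, log(T0[1]) + T0[3] * a + T0[4] * b,
             log(T0[2]) + T0[5] * a + T0[6] * b)
      w <- exp(l - max(l))
      fy <- w / sum(w)
      if (max(abs(fy - y)) <= 1e-10) { y <- fy; break }
      y <- fy
    }
    olims[i, ] <- y
  }
  expect_identical(unname(est$limits), olims)
  # manual covariance oracle
  ocov <- matrix(0, 3, 3)
  cm <- colMeans(olims)
  for (i in 1:500) ocov <- ocov + tcrossprod(olims[i, ] - cm)
  ocov <- ocov / 499
  expect_equal(unname(est$sigma_star), ocov, tolerance = 1e-14)
})

test_that("overly wide parameter covariance triggers the invalid-draw error", {
  T <- c(0.01, 0.01, 0, 0, 0, 0)
  Sigma <- diag(c(1, 1, 0, 0, 0, 0))  # t1, t2 go negative in most draws
  inits <- random_simplex(30, seed = 204)
  expect_error(mc_limit_covariance(make_fit_stub(T, Sigma), inits, seed = 3),
               "10%|redraws")
})

test_that("truncated-normal quantiles match a quadrature-and-root-finding oracle", {
  point <- 0.5; sigma <- 0.2
  iv <- truncnorm_interval(point, sigma, 0.95)
  tau <- integrate(function(y) dnorm(y, point, sigma), 0, 1,
                   rel.tol = 1e-13)$value
  cdf <- function(x) integrate(function(y) dnorm(y, point, sigma), 0, x,
                               rel.tol = 1e-13)$value / tau
  lo <- uniroot(function(x) cdf(x) - 0.025, c(0, 1), tol = 1e-12)$root
  hi <- uniroot(function(x) cdf(x) - 0.975, c(0, 1), tol = 1e-12)$root
  expect_equal(iv$lower, lo, tolerance = 1e-8)
  expect_equal(iv$upper, hi, tolerance = 1e-8)
})

test_that("with negligible truncation the interval reduces to plain normal quantiles", {
  iv <- truncnorm_interval(0.5, 0.05, 0.95)
  expect_equal(iv$lower, qnorm(0.025, 0.5, 0.05), tolerance = 1e-10)
  expect_equal(iv$upper, qnorm(0.975, 0.5, 0.05), tolerance = 1e-10)
})

test_that("intervals collapse as sigma vanishes and widen with level and sigma", {
  iv0 <- truncnorm_interval(0.3, 1e-12, 0.95)
  expect_lt(iv0$upper - iv0$lower, 1e-9)
  w <- function(s, l) { iv <- truncnorm_interval(0.2, s, l); iv$upper - iv$lower }
  expect_true(w(0.01, 0.95) < w(0.02, 0.95))
  expect_true(w(0.01, 0.95) < w(0.01, 0.99))
  iv95 <- truncnorm_interval(0.2, 0.01, 0.95)
  iv99 <- truncnorm_interval(0.2, 0.01, 0.99)
  expect_lt(iv99$lower, iv95$lower)
  expect_gt(iv99$upper, iv95$upper)
  expect_error(truncnorm_interval(0.5, 0), "positive")
})

test_that("sigma calibration inverts the reported-interval construction", {
  ref <- zhejiang_reference_limits()
  for (i in 1:3) {
    s <- calibrate_truncnorm_sigma(ref$point[i], ref$lower95[i], ref$upper95[i])
    iv <- truncnorm_interval(ref$point[i], s, 0.95)
    expect_equal(iv$upper - iv$lower, ref$upper95[i] - ref$lower95[i],
                 tolerance = 1e-9)
  }
})

test_that("F-test matches hand-evaluated matrix arithmetic and is zero at the estimate", {
  r0 <- limit_f_test(c(0.3, 0.2), c(0.3, 0.2), diag(0.01, 2), n = 100)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  r <- limit_f_test(c(0.3, 0.2), c(0, 0), diag(0.01, 2), n = 100)
  expect_equal(r$F, (98 / 198) * (0.09 / 0.01 + 0.04 / 0.01), tolerance = 1e-12)
  expect_equal(r$df1, 2L)
  expect_equal(r$df2, 98L)
  # invariance under (difference, covariance) -> (c d, c^2 Sigma)
  for (c0 in c(0.1, 3)) {
    r2 <- limit_f_test(c0 * c(0.3, 0.2), c(0, 0), c0^2 * diag(0.01, 2), n = 100)
    expect_equal(r2$F, r$F, tolerance = 1e-12)
  }
  expect_error(limit_f_test(c(.3, .2), c(0, 0), matrix(0, 2, 2), 100), "singular")
})

test_that("95% limit intervals cover the true limit in most seeded replicates", {
  T_true <- zhejiang_params("2014-2019")
  y_true <- ndes_fixed_point(T_true)$y_star
  n_rep <- 200
  covered <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(n_plots = 800, noise_concentration = 200,
                            seed = 2000 + r)
    p <- generate_plot_pairs(cfg)
    fit <- fit_ndes(p)
    est <- mc_limit_covariance(fit, as.matrix(p[c("y11", "y21", "y31")]),
                               seed = 3000 + r)
    sds <- sqrt(diag(est$sigma_star))
    for (i in 1:3) {
      iv <- truncnorm_interval(est$y_star[i], sds[i], 0.95)
      covered[r, i] <- y_true[i] >= iv$lower && y_true[i] <= iv$upper
    }
  }
  expect_true(all(colMeans(covered) >= 0.90))
})

test_that("the full pipeline recovers the generating limit within Monte Carlo spread", {
  cfg <- synthetic_config(n_plots = 1500, noise_concentration = 200, seed = 205)
  p <- generate_plot_pairs(cfg)
  fit <- fit_ndes(p)
  est <- mc_limit_covariance(fit, as.matrix(p[c("y11", "y21", "y31")]), seed = 6)
  y_true <- ndes_fixed_point(zhejiang_params("2014-2019"))$y_star
  sds <- sqrt(diag(est$sigma_star))
  expect_true(all(abs(est$y_star - y_true) <= 4 * sds))
  rep <- inference_report(est)
  expect_equal(nrow(rep$f_tests), 3L)
  expect_true(all(rep$f_tests$p_value < 1e-6))
})
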