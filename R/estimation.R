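# Internal parameterisation used by the optimizer: theta = (log t1, log t2,
# t3, t4, t5, t6). Optimizing the logs enforces t1, t2 > 0.

theta_from_params <- function(T) c(log(T[1]), log(T[2]), T[3], T[4], T[5], T[6])
params_from_theta <- function(th) {
  structure(c(t1 = exp(th[1]), t2 = exp(th[2]), t3 = th[3], t4 = th[4],
              t5 = th[5], t6 = th[6]), class = "ndes_params")
}

pairs_matrices <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("y10", "y20", "y11", "y21", "y31")
  if (!all(need %in% names(pairs)))
    stop("pairs must carry columns ", paste(need, collapse = ", "),
         " (see pair_surveys)")
  list(A = as.matrix(pairs[c("y10", "y20")]),
       Y1 = as.matrix(pairs[c("y11", "y21", "y31")]))
}

# Vectorized one-step predictions for all pairs: n x 3 matrix.
predict_theta <- function(theta, A) {
  l2 <- theta[1] + theta[3] * A[, 1] + theta[4] * A[, 2]
  l3 <- theta[2] + theta[5] * A[, 1] + theta[6] * A[, 2]
  m <- pmax(0, l2, l3)
  w1 <- exp(-m); w2 <- exp(l2 - m); w3 <- exp(l3 - m)
  s <- w1 + w2 + w3
  cbind(w1, w2, w3) / s
}

# Analytic Jacobian of the predicted components with respect to theta.
# d p_i / d theta_k = c_k * p_i * (1{i == m_k} - p_{m_k}) where theta_k
# enters only log-weight m_k with coefficient c_k (1, y10 or y20).
# Returns a (n * length(comps)) x 6 matrix, rows stacked component-major.
jac_theta <- function(theta, A, comps = 1:3) {
  P <- predict_theta(theta, A)
  n <- nrow(A)
  targets <- c(2L, 3L, 2L, 2L, 3L, 3L)
  coefs <- cbind(1, 1, A[, 1], A[, 2], A[, 1], A[, 2])
  J <- matrix(NA_real_, n * length(comps), 6L)
  for (k in 1:6) {
    m <- targets[k]
    dk <- coefs[, k] * P[, comps, drop = FALSE] *
      (outer(rep(1, n), comps == m) - P[, m])
    J[, k] <- as.vector(dk)
  }
  J
}

#' Log-ratio initial values for NDES estimation
#'
#' On noiseless data the model implies the exact linear identities
#' \deqn{\log(y_{21}/y_{11}) = \log t_1 + t_3 y_{10} + t_4 y_{20}}
#' \deqn{\log(y_{31}/y_{11}) = \log t_2 + t_5 y_{10} + t_6 y_{20}}
#' so ordinary least squares on the two log-ratios of the latter abundances
#' against the former pine and fir abundances yields starting values for the
#' nonlinear fit (and the exact parameters when the data are noiseless).
#' Latter components are floored at `floor` before taking logs; the floor
#' affects only this initializer, never the nonlinear loss.
#'
#' @param pairs an `ndes_pairs` data frame (see [pair_surveys()]).
#' @param floor lower bound applied to latter abundances before the log
#'   (default `1e-6`).
#' @return an [ndes_params()] vector.
#' @export
init_params_logratio <- function(pairs, floor = 1e-6) {
  m <- pairs_matrices(pairs)
  if (nrow(m$A) < 6) stop("need at least 6 pairs to initialize 6 parameters")
  Y1 <- pmax(m$Y1, floor)
  X <- cbind(1, m$A)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design: former abundances do not vary enough ",
         "to identify the parameters", call. = FALSE)
  b2 <- qr.solve(X, log(Y1[, 2] / Y1[, 1]))
  b3 <- qr.solve(X, log(Y1[, 3] / Y1[, 1]))
  ndes_params(exp(b2[1]), exp(b3[1]), b2[2], b2[3], b3[2], b3[3])
}

#' Per-group coefficients of determination
#'
#' For each species group, \eqn{R^2 = 1 - SSE/SST} with the total sum of
#' squares about that group's observed mean. A group whose observed values
#' do not vary has no defined \eqn{R^2} and is reported `NA`.
#'
#' @param observed,predicted `n x 3` matrices of latter abundance triples.
#' @return named numeric triple (pine, fir, broadleaf).
#' @export
r_squared <- function(observed, predicted) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(ncol(observed) == 3L, ncol(predicted) == 3L)
  if (nrow(observed) != nrow(predicted) || nrow(observed) < 2L)
    stop("observed and predicted must have the same number of rows (>= 2)")
  sse <- colSums((observed - predicted)^2)
  sst <- colSums(sweep(observed, 2, colMeans(observed))^2)
  out <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  stats::setNames(out, GROUPS)
}

#' Gauss-Newton covariance of the fitted NDES parameters
#'
#' Covariance \eqn{\hat\sigma^2 (J'J)^{-1}} of the least-squares estimate,
#' where `J` stacks the derivatives of the first two predicted components
#' per plot with respect to \eqn{(\log t_1, \log t_2, t_3, \dots, t_6)} and
#' is mapped back to the \eqn{t_1 \dots t_6} scale by the delta method. Only
#' two of the three per-plot residuals are informative (the triple sums to
#' one, so the third residual is minus the sum of the first two); using all
#' three would make the information matrix singular. Correspondingly
#' \eqn{\hat\sigma^2 = RSS_2 / (2n - 6)} with the residual sum of squares
#' taken over the first two components.
#'
#' @param pairs an `ndes_pairs` data frame.
#' @param T the fitted parameters ([ndes_params()] or an `ndes_fit`).
#' @param dof residual degrees of freedom; default `2 * n - 6`.
#' @return symmetric positive semi-definite 6x6 matrix on the `t` scale.
#' @export
param_covariance <- function(pairs, T, dof = NULL) {
  T <- as_params(T)
  m <- pairs_matrices(pairs)
  n <- nrow(m$A)
  if (is.null(dof)) dof <- 2 * n - 6
  if (dof <= 0) stop("need more than 3 pairs for a residual variance")
  theta <- theta_from_params(T)
  J <- jac_theta(theta, m$A, comps = 1:2)
  P <- predict_theta(theta, m$A)
  rss2 <- sum((m$Y1[, 1:2] - P[, 1:2])^2)
  sigma2 <- rss2 / dof
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e)
    stop("singular information matrix (J'J); the former abundances are ",
         "not varied enough to identify all six parameters", call. = FALSE))
  D <- diag(c(T[1], T[2], 1, 1, 1, 1))  # delta method: t1 = exp(theta1) etc.
  V <- D %*% (sigma2 * inv) %*% D
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(T), names(T))
  V
}

#' Fit the NDES map to paired plot abundances
#'
#' Minimizes the residual sum of squares
#' \eqn{\sum_{plots} \sum_{i=1}^{3} (y_{i1} - F(Y_0)_i)^2}
#' over the six parameters by Levenberg-Marquardt with an analytic Jacobian,
#' optimizing \eqn{\log t_1, \log t_2} so the positivity constraint holds by
#' construction. Starting values come from [init_params_logratio()] unless
#' supplied; up to `max_restarts` seeded 10%-jittered restarts are tried and
#' the best optimum kept.
#'
#' @param pairs an `ndes_pairs` data frame with at least 6 rows.
#' @param init optional [ndes_params()] starting values.
#' @param max_restarts jittered restarts after the initial attempt
#'   (default 5).
#' @param seed seed for the restart jitter.
#' @param dof residual degrees of freedom passed to [param_covariance()].
#' @return an object of class `"ndes_fit"`: list with `par`
#'   ([ndes_params()]), `cov` (6x6, `t` scale), `se`, `r2` (per-group
#'   \eqn{R^2}), `n_pairs`, `objective` (RSS over all three components),
#'   `sigma2`, `converged`, `info`, `message`.
#' @examples
#' cfg <- synthetic_config(n_plots = 50, noise_concentration = Inf, seed = 1)
#' fit <- fit_ndes(generate_plot_pairs(cfg))
#' fit$par
#' @export
fit_ndes <- function(pairs, init = NULL, max_restarts = 5L, seed = 1L,
                     dof = NULL) {
  m <- pairs_matrices(pairs)
  n <- nrow(m$A)
  if (n < 6) stop("need at least 6 pairs to fit 6 parameters")
  if (is.null(init)) init <- init_params_logratio(pairs)
  theta0 <- theta_from_params(as_params(init))
  resid_fn <- function(th) as.vector(m$Y1 - predict_theta(th, m$A))
  jac_fn <- function(th) -jac_theta(th, m$A, comps = 1:3)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  run_one <- function(th) {
    tryCatch(minpack.lm::nls.lm(par = th, fn = resid_fn, jac = jac_fn,
                                control = ctrl),
             error = function(e) NULL)
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(child_seed(seed, "restart"))
  best <- NULL
  tried <- 0L
  for (r in 0:max_restarts) {
    th <- if (r == 0) theta0 else
      theta0 + 0.1 * pmax(abs(theta0), 0.1) * stats::rnorm(6)
    res <- run_one(th)
    tried <- tried + 1L
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
    if (r == 0 && res$info %in% 1:4) break  # clean convergence from init
  }
  if (is.null(best))
    stop("NDES optimizer failed after ", tried, " attempt(s); check that ",
         "the former abundances vary and the pairs are on the simplex",
         call. = FALSE)
  theta <- best$par
  T <- params_from_theta(theta)
  P <- predict_theta(theta, m$A)
  converged <- best$info %in% 1:4
  fit <- list(par = T,
              cov = param_covariance(pairs, T, dof = dof),
              r2 = r_squared(m$Y1, P),
              n_pairs = n,
              objective = best$deviance,
              sigma2 = sum((m$Y1[, 1:2] - P[, 1:2])^2) /
                (if (is.null(dof)) 2 * n - 6 else dof),
              converged = converged,
              info = best$info,
              message = best$message,
              init = as_params(init))
  fit$se <- stats::setNames(sqrt(diag(fit$cov)), names(T))
  class(fit) <- "ndes_fit"
  fit
}

#' @export
print.ndes_fit <- function(x, ...) {
  cat("NDES fit on", x$n_pairs, "paired plots\n")
  tab <- cbind(estimate = unclass(x$par), std.error = x$se)
  print(round(tab, 4))
  cat("R^2 (pine, fir, broadleaf):", paste(round(x$r2, 4), collapse = ", "), "\n")
  cat(sprintf("RSS %.6g; %s\n", x$objective,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  invisible(x)
}

#' Serialize an NDES fit report
#'
#' Flattens an `ndes_fit` into a list of plain vectors/matrices with fixed
#' field names (`parameters`, `std_errors`, `covariance`, `r_squared`,
#' `n_pairs`, `objective`, `converged`) ready for JSON serialization.
#'
#' @param fit an `ndes_fit`.
#' @return a named list.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "ndes_fit"))
  list(parameters = as.list(unclass(fit$par)),
       std_errors = as.list(fit$se),
       covariance = unname(apply(fit$cov, 1, as.list, simplify = FALSE)),
       r_squared = as.list(fit$r2),
       n_pairs = fit$n_pairs,
       objective = fit$objective,
       converged = fit$converged)
}
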