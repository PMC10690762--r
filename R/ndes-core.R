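#' Construct and validate an NDES parameter vector
#'
#' The nonlinear difference equation system (NDES) maps the abundance triple
#' \eqn{Y_k = (y_1, y_2, y_3)} (pine, fir, broadleaf shares of plot biomass)
#' at one survey to the triple one survey interval (five years) later:
#' \deqn{Y_{k+1} = F(Y_k), \quad F_i(Y) = w_i / (w_1 + w_2 + w_3)}
#' with unnormalised weights
#' \deqn{w_1 = 1,\; w_2 = t_1 e^{t_3 y_1 + t_4 y_2},\; w_3 = t_2 e^{t_5 y_1 + t_6 y_2}.}
#' The scales \eqn{t_1, t_2} must be strictly positive; the exponents
#' \eqn{t_3,\dots,t_6} are unconstrained reals (units: per unit abundance).
#'
#' @param t1,t2 positive weight scales for the fir and broadleaf equations.
#' @param t3,t4,t5,t6 real exponents coupling the outcome to the former pine
#'   (`t3`, `t5`) and fir (`t4`, `t6`) abundances.
#' @return a named numeric vector of class `"ndes_params"`.
#' @examples
#' ndes_params(1.5, 33, -3.4, 2.8, -5.6, -2.9)
#' @export
ndes_params <- function(t1, t2, t3, t4, t5, t6) {
  T <- c(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5, t6 = t6)
  validate_params(T)
  structure(T, class = "ndes_params")
}

validate_params <- function(T) {
  T <- as.numeric(T)
  if (length(T) != 6L || !all(is.finite(T)))
    stop("NDES parameters must be 6 finite numbers (t1..t6)", call. = FALSE)
  if (T[1] <= 0 || T[2] <= 0)
    stop("t1 and t2 must be strictly positive (they scale, and divide, ",
         "the weight terms)", call. = FALSE)
  invisible(T)
}

as_params <- function(T) {
  if (inherits(T, "ndes_fit")) T <- T$par
  T <- as.numeric(T)
  validate_params(T)
  T
}

#' @export
print.ndes_params <- function(x, ...) {
  cat("NDES parameters (t1..t6):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' One five-year step of the NDES map
#'
#' Evaluates \eqn{F(Y_0)} in the numerically safe softmax form: the three
#' log-weights \eqn{0}, \eqn{\log t_1 + t_3 y_{10} + t_4 y_{20}} and
#' \eqn{\log t_2 + t_5 y_{10} + t_6 y_{20}} are shifted by their maximum
#' before exponentiation, which is algebraically identical to the three
#' reciprocal expressions of the model (see [ndes_step_literal()]) but cannot
#' overflow for extreme parameter draws. The output is strictly interior to
#' the simplex and sums to 1 by construction.
#'
#' @param y0 abundance triple (pine, fir, broadleaf) on the simplex.
#' @param T parameters, see [ndes_params()]; a plain numeric 6-vector is
#'   accepted.
#' @return the abundance triple one survey interval (5 years) later.
#' @seealso [ndes_trajectory()], [ndes_fixed_point()]
#' @export
ndes_step <- function(y0, T) {
  T <- as_params(T)
  assert_simplex(y0)
  step_unsafe(as.numeric(y0), T)
}

# core step without validation; used in inner loops
step_unsafe <- function(y0, T) {
  l <- c(0,
         log(T[1]) + T[3] * y0[1] + T[4] * y0[2],
         log(T[2]) + T[5] * y0[1] + T[6] * y0[2])
  w <- exp(l - max(l))
  out <- w / sum(w)
  names(out) <- GROUPS
  out
}

#' Literal term-by-term evaluation of the NDES map
#'
#' Transcribes the model's three reciprocal expressions
#' \deqn{f_1 = \frac{1}{1 + t_1 e^{t_3 y_{10} + t_4 y_{20}} + t_2 e^{t_5 y_{10} + t_6 y_{20}}}}
#' \deqn{f_2 = \frac{1}{(1/t_1) e^{-t_3 y_{10} - t_4 y_{20}} + 1 + (t_2/t_1) e^{(t_5-t_3) y_{10} + (t_6-t_4) y_{20}}}}
#' \deqn{f_3 = \frac{1}{(1/t_2) e^{-t_5 y_{10} - t_6 y_{20}} + (t_1/t_2) e^{(t_3-t_5) y_{10} + (t_4-t_6) y_{20}} + 1}}
#' exactly as written. Serves as the independent oracle for [ndes_step()]:
#' the two agree to machine precision wherever neither form over- or
#' underflows.
#'
#' @inheritParams ndes_step
#' @return the abundance triple one survey interval later.
#' @export
ndes_step_literal <- function(y0, T) {
  T <- as_params(T)
  assert_simplex(y0)
  a <- y0[1]; b <- y0[2]
  f1 <- 1 / (1 + T[1] * exp(T[3] * a + T[4] * b) + T[2] * exp(T[5] * a + T[6] * b))
  f2 <- 1 / ((1 / T[1]) * exp(-T[3] * a - T[4] * b) + 1 +
               (T[2] / T[1]) * exp((T[5] - T[3]) * a + (T[6] - T[4]) * b))
  f3 <- 1 / ((1 / T[2]) * exp(-T[5] * a - T[6] * b) +
               (T[1] / T[2]) * exp((T[3] - T[5]) * a + (T[4] - T[6]) * b) + 1)
  c(pine = f1, fir = f2, broadleaf = f3)
}

#' Iterate the NDES map over several survey intervals
#'
#' @inheritParams ndes_step
#' @param k number of steps (each step spans one 5-year survey interval).
#' @return a `(k + 1) x 3` matrix of simplex points; row 1 is `y0`, row
#'   `j + 1` is the state `5 * j` years after the start.
#' @export
ndes_trajectory <- function(y0, T, k) {
  T <- as_params(T)
  assert_simplex(y0)
  if (length(k) != 1L || k < 0 || k != round(k)) stop("k must be a nonnegative integer")
  out <- matrix(NA_real_, k + 1, 3, dimnames = list(NULL, GROUPS))
  y <- as.numeric(y0)
  out[1, ] <- y
  if (k > 0) for (j in seq_len(k)) {
    y <- step_unsafe(y, T)
    out[j + 1, ] <- y
  }
  out
}

# Picard iteration to a fixed point from one start. Damped iteration
# y <- (y + F(y))/2 kicks in automatically if the residual fails to decrease
# over a 100-iteration window (guards oscillatory parameter draws).
iterate_fixed_point <- function(y, T, tol = 1e-12, max_iter = 1e6L) {
  damped <- FALSE
  res_ref <- Inf
  for (i in seq_len(max_iter)) {
    fy <- step_unsafe(y, T)
    r <- max(abs(fy - y))
    if (r <= tol)
      return(list(y = fy, iterations = i, residual = r, converged = TRUE))
    y <- if (damped) (y + fy) / 2 else fy
    if (i %% 100L == 0L) {
      if (!damped && r >= res_ref) damped <- TRUE
      res_ref <- r
    }
  }
  list(y = y, iterations = max_iter, residual = r, converged = FALSE)
}

#' Equilibrium (limit) of the NDES map
#'
#' Locates a fixed point \eqn{Y^* = F(Y^*)}, the theoretical ultimate species
#' composition, by Picard iteration \eqn{Y \leftarrow F(Y)} from `n_starts`
#' points spread over the simplex: the three vertices, the barycenter, and
#' seeded uniform interior points. All starts must converge to the same
#' point (within `10 * tol`); if they do not, the map has several coexisting
#' attractors and an error lists the distinct limits found, because a single
#' "limit composition" is then not defined.
#'
#' @param T parameters, see [ndes_params()].
#' @param tol convergence tolerance on \eqn{\max_i |F(Y)_i - Y_i|}
#'   (default `1e-12`).
#' @param n_starts number of starting points (default 16; values below 4
#'   drop random starts first, then the barycenter and vertices).
#' @param seed integer seed for the random interior starts.
#' @param start optional single simplex start; when given, only this start is
#'   used (no multi-start check).
#' @param max_iter iteration cap per start.
#' @return an object of class `"ndes_fixed_point"`: list with `y_star`
#'   (simplex triple), `iterations`, `residual`, and `starts_agreeing`.
#' @examples
#' ndes_fixed_point(ndes_params(1, 1, 0, 0, 0, 0))$y_star  # (1/3, 1/3, 1/3)
#' @export
ndes_fixed_point <- function(T, tol = 1e-12, n_starts = 16L, seed = 1L,
                             start = NULL, max_iter = 1e6L) {
  T <- as_params(T)
  if (tol <= 0) stop("tol must be positive")
  if (!is.null(start)) {
    assert_simplex(start)
    starts <- matrix(as.numeric(start), 1, 3)
  } else {
    fixed <- rbind(diag(3), rep(1 / 3, 3))
    n_rand <- max(0L, as.integer(n_starts) - nrow(fixed))
    rand <- if (n_rand > 0) {
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(child_seed(seed, "starts"))
      rdirichlet(n_rand, c(1, 1, 1))
    }
    starts <- utils::head(rbind(rand, fixed[c(4, 1, 2, 3), ]), as.integer(n_starts))
  }
  runs <- apply(starts, 1, iterate_fixed_point, T = T, tol = tol,
                max_iter = max_iter, simplify = FALSE)
  bad <- !vapply(runs, `[[`, logical(1), "converged")
  if (any(bad))
    stop("fixed-point iteration did not converge within ", max_iter,
         " iterations for ", sum(bad), " start(s)", call. = FALSE)
  lims <- t(vapply(runs, `[[`, numeric(3), "y"))
  ref <- lims[1, ]
  agree <- apply(lims, 1, function(z) max(abs(z - ref)) <= 10 * tol)
  if (!all(agree)) {
    distinct <- unique(round(lims, max(1L, ceiling(-log10(10 * tol)) - 2L)))
    stop("multi-start iteration found ", nrow(distinct),
         " distinct limits; the map is multistable for these parameters:\n",
         paste(utils::capture.output(print(distinct)), collapse = "\n"),
         call. = FALSE)
  }
  best <- which.min(vapply(runs, `[[`, numeric(1), "residual"))
  structure(list(y_star = as_triple(lims[best, ]),
                 iterations = runs[[best]]$iterations,
                 residual = runs[[best]]$residual,
                 starts_agreeing = sum(agree),
                 n_starts = nrow(starts)),
            class = "ndes_fixed_point")
}

#' @export
print.ndes_fixed_point <- function(x, ...) {
  cat("NDES limit (fixed point Y* = F(Y*)):\n")
  print(round(x$y_star, 6))
  cat(sprintf("residual %.2e after %d iterations; %d/%d starts agree\n",
              x$residual, x$iterations, x$starts_agreeing, x$n_starts))
  invisible(x)
}
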