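#' Plot-wise projection averaged over plots
#'
#' Projects species composition forward by iterating the NDES map for each
#' plot independently from its own initial abundance, then averaging across
#' plots at each step ("iterate, then average" -- the reverse order gives a
#' different, incorrect series because the map is nonlinear). One step spans
#' one 5-year survey interval; a predicted state depends only on the
#' previous state.
#'
#' @param fit an `ndes_fit` or an [ndes_params()] vector.
#' @param initial `n x 3` matrix of initial abundance triples (one row per
#'   plot), typically the latter observed abundances of the fitting data.
#' @param start_year calendar year of the initial state.
#' @param horizon_year final projected year; `start_year + 100` by default
#'   (a century, e.g. 2019 to 2119). Must exceed `start_year` by a multiple
#'   of `step_years`.
#' @param step_years years per map application (default 5).
#' @param keep_plots retain the per-plot trajectories (default `FALSE`).
#' @return an object of class `"ndes_projection"`: list with `series` (data
#'   frame `year`, `pine`, `fir`, `broadleaf` of plot-mean abundances),
#'   `n_plots`, and optionally `per_plot` (`n x (k+1) x 3` array).
#' @examples
#' T <- zhejiang_params("2014-2019")
#' predict_average_trajectory(T, rbind(c(.3, .3, .4), c(.5, .2, .3)), 2019, 2069)
#' @export
predict_average_trajectory <- function(fit, initial, start_year,
                                       horizon_year = start_year + 100,
                                       step_years = 5L, keep_plots = FALSE) {
  T <- as_params(if (inherits(fit, "ndes_fit")) fit$par else fit)
  Y <- as.matrix(initial)
  if (ncol(Y) != 3L || nrow(Y) < 1L) stop("initial must be a nonempty n x 3 matrix")
  apply(Y, 1, assert_simplex, what = "initial abundance")
  span <- horizon_year - start_year
  if (span < 0 || span %% step_years != 0)
    stop("horizon_year - start_year must be a nonnegative multiple of ",
         step_years, " years")
  k <- span %/% step_years
  n <- nrow(Y)
  traj <- array(NA_real_, c(n, k + 1, 3))
  for (i in seq_len(n)) traj[i, , ] <- ndes_trajectory(Y[i, ], T, k)
  mean_ab <- apply(traj, c(2, 3), mean)
  colnames(mean_ab) <- GROUPS
  series <- data.frame(year = start_year + step_years * (0:k), mean_ab)
  out <- list(series = series, n_plots = n, start_year = start_year,
              horizon_year = horizon_year, step_years = step_years)
  if (keep_plots) out$per_plot <- traj
  structure(out, class = "ndes_projection")
}

#' @export
print.ndes_projection <- function(x, ...) {
  cat("NDES projection,", x$n_plots, "plots,", x$start_year, "to",
      x$horizon_year, "\n")
  s <- x$series
  pick <- unique(c(1, round(seq(1, nrow(s), length.out = 6))))
  print(round(s[pick, ], 4), row.names = FALSE)
  invisible(x)
}

#' Signed relative prediction error, in percent
#'
#' \eqn{100 (\hat y - y) / y} per species group: positive when the
#' prediction exceeds the actual value. A zero actual component leaves that
#' group's error undefined (`NA`).
#'
#' @param predicted,actual abundance triples (pine, fir, broadleaf).
#' @return named numeric triple of percentages.
#' @examples
#' relative_error(c(0.2, 0.3, 0.5), c(0.1, 0.3, 0.6))
#' @export
relative_error <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  stopifnot(length(predicted) == 3L, length(actual) == 3L)
  out <- ifelse(actual > 0, 100 * (predicted - actual) / actual, NA_real_)
  stats::setNames(out, GROUPS)
}
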