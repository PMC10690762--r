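#' @keywords internal
"_PACKAGE"

GROUPS <- c("pine", "fir", "broadleaf")

#' Check whether a numeric triple lies on the probability simplex
#'
#' @param y numeric vector of length 3.
#' @param tol tolerance on the sum-to-one constraint and on small negative
#'   components (default `1e-9`).
#' @return `TRUE` or `FALSE`.
#' @export
is_simplex <- function(y, tol = 1e-9) {
  is.numeric(y) && length(y) == 3L && all(is.finite(y)) &&
    all(y >= -tol) && all(y <= 1 + tol) && abs(sum(y) - 1) <= tol
}

assert_simplex <- function(y, what = "abundance triple", tol = 1e-9) {
  if (!is_simplex(y, tol)) {
    stop(what, " must be a length-3 nonnegative vector summing to 1 (got: ",
         paste(signif(y, 6), collapse = ", "), ")", call. = FALSE)
  }
  invisible(y)
}

# Dirichlet sampler via independent gammas; rows sum to 1.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(x)
  # all-underflow rows (tiny alphas) fall back to the mean
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) x[bad, ] <- matrix(alpha / sum(alpha), sum(bad), k, byrow = TRUE)
  x / rowSums(x)
}

# Deterministic child seeds from one master seed: every randomised stage of
# the package draws from its own stream, child = (master * 97 + offset) mod
# (2^31 - 1), so any stage is reproducible in isolation.
STAGE_OFFSETS <- c(initial = 11L, noise = 23L, drop = 37L, trees = 41L,
                   mc = 53L, starts = 67L, restart = 71L, panel = 83L)

child_seed <- function(master, stage) {
  off <- STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(master) * 97 + off) %% 2147483647)
}

as_triple <- function(x, what = "triple") {
  x <- as.numeric(x)
  if (length(x) != 3L) stop(what, " must have length 3", call. = FALSE)
  names(x) <- GROUPS
  x
}
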