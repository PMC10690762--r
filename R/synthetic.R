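#' Configuration for the synthetic paired-plot generator
#'
#' Describes an inventory-like study: `n_plots` permanent plots surveyed
#' `n_surveys` times at 5-year intervals, each successive survey's abundance
#' a noisy image of the previous one under a known NDES map. Defaults match
#' the study conditions of the most recent Zhejiang reexamination period:
#' the 2014--2019 reference parameters, 1712 plots, and a mixture of initial
#' compositions whose dominance tallies mirror the reference
#' pine:fir:broadleaf mix 478:402:832.
#'
#' Observation noise is Dirichlet with mean equal to the model prediction
#' and concentration `noise_concentration` (kappa): larger kappa puts the
#' observed latter abundance closer to the prediction, and
#' `noise_concentration = Inf` is exact mode (no noise). The default
#' kappa = 25 is a heuristic calibration: it puts synthetic per-group
#' R-squared in the 0.81--0.98 band typical of real inventory fits. A logistic-normal noise family with a
#' comparable dispersion is available as an alternative.
#'
#' @param T_true generating parameters ([ndes_params()]); default the
#'   2014--2019 reference set.
#' @param n_plots number of plots (default 1712).
#' @param n_surveys number of surveys (>= 2, default 2).
#' @param start_year calendar year of the first survey (default 2014).
#' @param interval years between surveys (default 5).
#' @param mix_weights mixture weights over the three dominance components
#'   (default the 2014 reference tallies 478:402:832).
#' @param mix_means 3x3 matrix; row g is the mean initial composition of a
#'   plot dominated by group g.
#' @param mix_concentration Dirichlet concentration of each mixture
#'   component (spread of initial plot compositions around the component
#'   mean).
#' @param noise_concentration observation-noise concentration kappa
#'   (> 0, or `Inf` for exact mode).
#' @param noise_family `"dirichlet"` (default) or `"logistic-normal"`.
#' @param drop_fraction fraction of plots relocated (dropped and replaced by
#'   a fresh plot) between consecutive surveys, emulating inventory plot
#'   relocation (default 0).
#' @param seed master seed; all stages derive child seeds from it.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(T_true = zhejiang_params("2014-2019"),
                             n_plots = 1712L, n_surveys = 2L,
                             start_year = 2014L, interval = 5L,
                             mix_weights = c(478, 402, 832),
                             mix_means = rbind(c(0.70, 0.15, 0.15),
                                               c(0.15, 0.70, 0.15),
                                               c(0.12, 0.13, 0.75)),
                             mix_concentration = 12,
                             noise_concentration = 25,
                             noise_family = c("dirichlet", "logistic-normal"),
                             drop_fraction = 0, seed = 1L) {
  noise_family <- match.arg(noise_family)
  T_true <- as_params(T_true)
  stopifnot(n_plots >= 0, n_surveys >= 2, interval >= 1,
            length(mix_weights) == 3, all(mix_weights > 0),
            all(dim(as.matrix(mix_means)) == 3), mix_concentration > 0,
            noise_concentration > 0,
            drop_fraction >= 0, drop_fraction < 1)
  apply(mix_means, 1, assert_simplex, what = "mixture component mean")
  structure(list(T_true = T_true, n_plots = as.integer(n_plots),
                 n_surveys = as.integer(n_surveys),
                 start_year = as.integer(start_year),
                 interval = as.integer(interval),
                 mix_weights = mix_weights / sum(mix_weights),
                 mix_means = as.matrix(mix_means),
                 mix_concentration = mix_concentration,
                 noise_concentration = noise_concentration,
                 noise_family = noise_family,
                 drop_fraction = drop_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw n initial plot compositions from the dominance mixture.
draw_initials <- function(cfg, n) {
  if (n == 0) return(matrix(numeric(0), 0, 3, dimnames = list(NULL, GROUPS)))
  comp <- sample.int(3L, n, replace = TRUE, prob = cfg$mix_weights)
  y <- matrix(NA_real_, n, 3, dimnames = list(NULL, GROUPS))
  for (g in 1:3) {
    idx <- which(comp == g)
    if (length(idx))
      y[idx, ] <- rdirichlet(length(idx),
                             cfg$mix_concentration * cfg$mix_means[g, ])
  }
  y
}

# Noisy observation of the one-step-ahead prediction, rowwise.
observe_step <- function(cfg, former) {
  if (nrow(former) == 0L) return(former)
  mu <- t(apply(former, 1, step_unsafe, T = cfg$T_true))
  if (!is.finite(cfg$noise_concentration)) return(mu)
  k <- cfg$noise_concentration
  if (cfg$noise_family == "dirichlet") {
    out <- mu
    for (i in seq_len(nrow(mu))) out[i, ] <- rdirichlet(1, k * mu[i, ])
    out
  } else {
    # logistic-normal: additive Gaussian noise on the log-ratio scale with
    # sd 1/sqrt(k), roughly matching the Dirichlet dispersion at the same k
    z <- log(pmax(mu, 1e-12)) +
      matrix(stats::rnorm(length(mu), sd = 1 / sqrt(k)), nrow(mu))
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  }
}

#' Generate synthetic paired observations
#'
#' Former abundances are drawn from the configured dominance mixture; the
#' latter abundance of each plot is a simplex-valued noisy observation
#' centred on the NDES prediction `step(former, T_true)`. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return an `ndes_pairs` data frame (see [pair_surveys()]).
#' @examples
#' pairs <- generate_plot_pairs(synthetic_config(n_plots = 20, seed = 7))
#' @export
generate_plot_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(child_seed(cfg$seed, "initial"))
  y0 <- draw_initials(cfg, cfg$n_plots)
  set.seed(child_seed(cfg$seed, "noise"))
  y1 <- observe_step(cfg, y0)
  out <- data.frame(plot_id = sprintf("P%05d", seq_len(cfg$n_plots)),
                    year_start = rep(cfg$start_year, cfg$n_plots),
                    year_end = rep(cfg$start_year + cfg$interval, cfg$n_plots),
                    y10 = y0[, 1], y20 = y0[, 2], y30 = y0[, 3],
                    y11 = y1[, 1], y21 = y1[, 2], y31 = y1[, 3])
  attr(out, "exclusions") <- c(missing_latter = 0L, nonforested_former = 0L,
                               nonforested_latter = 0L)
  attr(out, "T_true") <- cfg$T_true
  class(out) <- c("ndes_pairs", "data.frame")
  out
}

#' Generate a multi-survey synthetic plot panel
#'
#' A panel of `n_surveys` consecutive surveys where each survey's abundance
#' is the noisy NDES image of the previous one. Between consecutive surveys
#' a fraction `drop_fraction` of plots is relocated: the old plot stops
#' being measured and a fresh plot (new id, new initial composition) enters,
#' so those plots cannot be paired across that period -- emulating inventory
#' plot relocation.
#'
#' @param cfg a [synthetic_config()].
#' @return a plot survey data frame (`plot_id`, `year`, `pine`, `fir`,
#'   `broadleaf`) accepted by [pair_surveys()] and [write_plot_table()].
#' @examples
#' panel <- generate_panel(synthetic_config(n_plots = 10, n_surveys = 3))
#' table(panel$year)
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  years <- cfg$start_year + cfg$interval * (seq_len(cfg$n_surveys) - 1L)
  set.seed(child_seed(cfg$seed, "panel"))
  ids <- sprintf("P%05d", seq_len(cfg$n_plots))
  next_id <- cfg$n_plots
  y <- draw_initials(cfg, cfg$n_plots)
  chunks <- list(data.frame(plot_id = ids, year = years[1], y))
  for (s in seq_len(cfg$n_surveys - 1L)) {
    y <- observe_step(cfg, y)
    if (cfg$drop_fraction > 0 && cfg$n_plots > 0) {
      drop <- stats::runif(cfg$n_plots) < cfg$drop_fraction
      if (any(drop)) {
        ids[drop] <- sprintf("P%05d", next_id + seq_len(sum(drop)))
        next_id <- next_id + sum(drop)
        y[drop, ] <- draw_initials(cfg, sum(drop))
      }
    }
    chunks[[s + 1L]] <- data.frame(plot_id = ids, year = years[s + 1L], y)
  }
  out <- do.call(rbind, chunks)
  names(out) <- c("plot_id", "year", GROUPS)
  rownames(out) <- NULL
  out
}

#' Generate synthetic tree-level records for target plot compositions
#'
#' Expands plot-level target abundances into individual tree records whose
#' per-group biomass shares reproduce the targets exactly: each group with
#' positive target share receives at least one tree, species names are
#' sampled from that group's list, and the group biomass is split over its
#' trees with random positive weights that are rescaled to the target share.
#' A stand-in for allometric biomass, not a biological allometry.
#'
#' @param targets `n x 3` matrix of target abundance triples (rownames, if
#'   present, become plot ids).
#' @param trees_per_plot trees per plot (>= 3 recommended).
#' @param map a [species_group_map()] supplying species names.
#' @param total_biomass plot total biomass (arbitrary units, default 100).
#' @param seed seed.
#' @return data frame with columns `plot_id`, `species`, `biomass`.
#' @export
generate_tree_level <- function(targets, trees_per_plot = 30L,
                                map = species_group_map(),
                                total_biomass = 100, seed = 1L) {
  targets <- as.matrix(targets)
  stopifnot(ncol(targets) == 3L, trees_per_plot >= 1L)
  apply(targets, 1, assert_simplex, what = "target abundance")
  ids <- if (!is.null(rownames(targets))) rownames(targets) else
    sprintf("P%05d", seq_len(nrow(targets)))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(child_seed(seed, "trees"))
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    y <- targets[i, ]
    present <- which(y > 0)
    # at least one tree per present group, remaining trees by target share
    n_g <- integer(3)
    n_g[present] <- 1L
    extra <- trees_per_plot - length(present)
    if (extra > 0) {
      add <- table(factor(sample(present, extra, replace = TRUE,
                                 prob = y[present]), levels = 1:3))
      n_g <- n_g + as.integer(add)
    }
    sp <- bm <- vector("list", 3)
    for (g in present) {
      w <- stats::runif(n_g[g], 0.5, 1.5)
      bm[[g]] <- total_biomass * y[g] * w / sum(w)
      sp[[g]] <- sample(map$groups[[GROUPS[g]]], n_g[g], replace = TRUE)
    }
    rows[[i]] <- data.frame(plot_id = ids[i],
                            species = unlist(sp),
                            biomass = unlist(bm))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
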