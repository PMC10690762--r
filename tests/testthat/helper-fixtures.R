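# Fixtures built in code; no stored data.

# Noiseless pairs: latter = F(former) exactly under T, at given former points.
exact_pairs <- function(T, formers) {
  latters <- t(apply(formers, 1, ndes_step, T = T))
  out <- data.frame(plot_id = sprintf("X%03d", seq_len(nrow(formers))),
                    year_start = 2014L, year_end = 2019L)
  out[c("y10", "y20", "y30")] <- formers
  out[c("y11", "y21", "y31")] <- latters
  class(out) <- c("ndes_pairs", "data.frame")
  out
}

# A spread of interior simplex points, deterministic.
simplex_grid <- function(by = 0.15, margin = 0.05) {
  pts <- NULL
  for (a in seq(margin, 1 - margin, by = by))
    for (b in seq(margin, 1 - a, by = by))
      if (1 - a - b >= margin) pts <- rbind(pts, c(a, b, 1 - a - b))
  pts
}

random_simplex <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rgamma(3 * n, 1), n, 3)
  x / rowSums(x)
}

ref_periods <- function() zhejiang_params()$period
stable_periods <- c("1999-2004", "2004-2009", "2009-2014", "2014-2019")
multistable_periods <- c("1989-1994", "1994-1999")
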