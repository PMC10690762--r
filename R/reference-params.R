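#' Reference NDES parameter estimates for Zhejiang Province
#'
#' Parameter estimates of the six-parameter NDES map reported for each of the
#' six five-year reexamination periods of the Zhejiang provincial continuous
#' forest inventory (permanent plots, surveys 1989--2019), together with the
#' per-group coefficients of determination of those fits. These are treated
#' as given inputs: the plot data behind them are not public, so they serve
#' as reference dynamics for limit analysis, projection and as defaults for
#' the synthetic generator -- not as estimation targets.
#'
#' Note that the 1989--1994 and 1994--1999 parameter sets make the map
#' multistable (three coexisting stable equilibria); [ndes_fixed_point()]
#' reports this explicitly. The four post-1999 sets each have a unique
#' attractor.
#'
#' @param period optional period label like `"2014-2019"`; when given, the
#'   parameter vector for that period is returned as an [ndes_params()]
#'   object, otherwise the full table.
#' @return a data frame with columns `period`, `t1`..`t6`, `r2_pine`,
#'   `r2_fir`, `r2_broadleaf`, `n_plots`; or a single `ndes_params` vector.
#' @examples
#' zhejiang_params("2014-2019")
#' @export
zhejiang_params <- function(period = NULL) {
  tab <- data.frame(
    period = c("1989-1994", "1994-1999", "1999-2004",
               "2004-2009", "2009-2014", "2014-2019"),
    t1 = c(0.7220, 1.0682, 0.8203, 1.3904, 1.1641, 1.5110),
    t2 = c(35.8226, 20.4263, 32.2185, 42.8872, 32.1222, 33.1472),
    t3 = c(-2.8635, -2.7597, -2.3495, -3.1068, -2.9822, -3.3836),
    t4 = c(3.5865, 2.7024, 3.1429, 2.5992, 2.8834, 2.8001),
    t5 = c(-6.9519, -5.7101, -5.6925, -5.8867, -5.4936, -5.5520),
    t6 = c(-4.4867, -3.8109, -3.3400, -3.1080, -2.9301, -2.8888),
    r2_pine = c(0.9803, 0.9203, 0.9123, 0.9298, 0.9118, 0.9117),
    r2_fir = c(0.9695, 0.8727, 0.9150, 0.9070, 0.9071, 0.9095),
    r2_broadleaf = c(0.9516, 0.8180, 0.8156, 0.9014, 0.9387, 0.9581),
    n_plots = c(842L, 824L, 909L, 1582L, 1657L, 1712L))
  if (is.null(period)) return(tab)
  i <- match(period, tab$period)
  if (is.na(i)) stop("unknown period '", period, "'; available: ",
                     paste(tab$period, collapse = ", "))
  do.call(ndes_params, as.list(tab[i, paste0("t", 1:6)]))
}

#' Reference limit estimates and 95% intervals for the 2014--2019 period
#'
#' Point estimates of the limit composition under the 2014--2019 reference
#' parameters together with their reported equal-tail 95% truncated-normal
#' intervals. Used for interval self-consistency checks: given the point and
#' the 95% interval, [calibrate_truncnorm_sigma()] recovers the implied
#' standard deviation, from which intervals at other levels follow.
#'
#' @return a data frame with columns `group`, `point`, `lower95`, `upper95`.
#' @export
zhejiang_reference_limits <- function() {
  data.frame(
    group = GROUPS,
    point = c(0.0408, 0.0642, 0.8950),
    lower95 = c(0.0354, 0.0561, 0.8847),
    upper95 = c(0.0461, 0.0723, 0.9053))
}

#' Reference dominant-group plot counts per reexamination period
#'
#' Numbers of paired plots per period, tallied by the dominant species group
#' at the former survey. Used to calibrate the synthetic generator's mixture
#' of initial plot compositions.
#'
#' @return a data frame with columns `period`, `pine`, `fir`, `broadleaf`,
#'   `total`.
#' @export
zhejiang_dominance_counts <- function() {
  data.frame(
    period = c("1989-1994", "1994-1999", "1999-2004",
               "2004-2009", "2009-2014", "2014-2019"),
    pine = c(493L, 498L, 481L, 683L, 575L, 478L),
    fir = c(236L, 211L, 294L, 483L, 432L, 402L),
    broadleaf = c(113L, 115L, 134L, 416L, 650L, 832L),
    total = c(842L, 824L, 909L, 1582L, 1657L, 1712L))
}
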