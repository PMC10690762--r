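#' Default species-to-group assignments
#'
#' The default grouping used in subtropical Chinese forest management: pines,
#' firs (Cupressaceae/Taxaceae conifers other than pines), and broadleaves.
#' Entries are editable; see [species_group_map()] and [read_species_map()].
#'
#' @return named list with elements `pine`, `fir`, `broadleaf`, each a
#'   character vector of species or genus names.
#' @export
default_species_groups <- function() {
  list(
    pine = c("Pinus massoniana", "Pinus thunbergii", "Pinus taiwanensis",
             "Pinus elliottii"),
    fir = c("Cunninghamia lanceolata", "Cryptomeria fortunei",
            "Metasequoia glyptostroboides", "Taxodium ascendens",
            "Taxus wallichiana var. chinensis"),
    broadleaf = c("Quercus", "Castanopsis", "Liquidambar", "Schima superba",
                  "Cinnamomum camphora", "Lauraceae"))
}

normalize_species <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Build a species-to-group lookup map
#'
#' @param groups named list mapping each of `pine`, `fir`, `broadleaf` to a
#'   character vector of species names; defaults to
#'   [default_species_groups()]. Lookup is case-insensitive after whitespace
#'   normalisation.
#' @return an object of class `"species_group_map"`.
#' @export
species_group_map <- function(groups = default_species_groups()) {
  if (!all(names(groups) %in% GROUPS) || length(groups) == 0)
    stop("groups must be a named list with names among: ",
         paste(GROUPS, collapse = ", "))
  species <- normalize_species(unlist(groups, use.names = FALSE))
  group <- rep(names(groups), lengths(groups))
  if (anyDuplicated(species)) {
    d <- species[duplicated(species)]
    stop("species mapped to more than one group: ", paste(d, collapse = ", "))
  }
  if (length(species) == 0) stop("species map is empty")
  structure(list(lookup = stats::setNames(group, species), groups = groups),
            class = "species_group_map")
}

#' Classify species names into the three species groups
#'
#' @param species character vector of species names.
#' @param map a [species_group_map()].
#' @return character vector of group labels (`"pine"`, `"fir"`,
#'   `"broadleaf"`). Unknown species raise an error naming them -- never a
#'   silent default.
#' @examples
#' classify_species_group("Pinus massoniana", species_group_map())
#' @export
classify_species_group <- function(species, map = species_group_map()) {
  stopifnot(inherits(map, "species_group_map"))
  g <- unname(map$lookup[normalize_species(species)])
  if (anyNA(g)) {
    unknown <- unique(species[is.na(g)])
    stop("species not in the group map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Plot abundance from group biomass
#'
#' The abundance of a species group in a plot is its share of the plot's
#' total tree biomass, so the three abundances lie on the probability
#' simplex.
#'
#' @param biomass nonnegative triple (pine, fir, broadleaf), or an `n x 3`
#'   matrix of such triples; units cancel.
#' @return abundance triple (or matrix of triples) summing to 1 per plot.
#'   A plot with zero total biomass is non-forested and has no defined
#'   abundance: error.
#' @examples
#' compute_plot_abundance(c(20, 30, 50))
#' @export
compute_plot_abundance <- function(biomass) {
  if (is.null(dim(biomass))) {
    b <- as.numeric(biomass)
    if (length(b) != 3L || any(!is.finite(b)) || any(b < 0))
      stop("biomass must be a nonnegative triple")
    tot <- sum(b)
    if (tot <= 0) stop("plot has zero total biomass (non-forested); ",
                       "abundance is undefined", call. = FALSE)
    return(as_triple(b / tot))
  }
  b <- as.matrix(biomass)
  stopifnot(ncol(b) == 3L)
  if (any(!is.finite(b)) || any(b < 0)) stop("biomass must be nonnegative")
  tot <- rowSums(b)
  if (any(tot <= 0)) stop("plot(s) with zero total biomass (non-forested); ",
                          "abundance is undefined: rows ",
                          paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  sweep(b, 1, tot, "/")
}

# Normalize a survey table to columns plot_id, year, pine, fir, broadleaf
# (abundance). Biomass columns win over abundance columns; rows with zero
# total biomass get NA abundance (excluded later, counted as non-forested).
normalize_surveys <- function(surveys, mismatch_tol = 1e-6) {
  stopifnot(is.data.frame(surveys))
  if (!all(c("plot_id", "year") %in% names(surveys)))
    stop("survey table needs columns plot_id and year")
  bm_cols <- paste0(GROUPS, "_biomass")
  has_bm <- all(bm_cols %in% names(surveys))
  has_ab <- all(GROUPS %in% names(surveys))
  if (!has_bm && !has_ab)
    stop("survey table needs either biomass columns (",
         paste(bm_cols, collapse = ", "), ") or abundance columns (",
         paste(GROUPS, collapse = ", "), ")")
  out <- data.frame(plot_id = as.character(surveys$plot_id),
                    year = as.integer(surveys$year))
  if (has_bm) {
    b <- as.matrix(surveys[bm_cols])
    if (any(b < 0, na.rm = TRUE)) stop("negative biomass")
    tot <- rowSums(b)
    ab <- matrix(NA_real_, nrow(b), 3)
    ok <- is.finite(tot) & tot > 0
    ab[ok, ] <- b[ok, , drop = FALSE] / tot[ok]
    if (has_ab) {
      given <- as.matrix(surveys[GROUPS])
      mis <- ok & apply(abs(given - ab), 1, max) > mismatch_tol
      if (any(mis, na.rm = TRUE))
        stop("abundance columns disagree with biomass-derived abundance ",
             "beyond ", mismatch_tol, " in rows: ",
             paste(which(mis), collapse = ", "), call. = FALSE)
    }
  } else {
    ab <- as.matrix(surveys[GROUPS])
    bad <- apply(ab, 1, function(y) !is_simplex(y))
    if (any(bad)) stop("abundance rows off the simplex: ",
                       paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out[GROUPS] <- ab
  out
}

#' Pair plot surveys across one reexamination period
#'
#' Matches plots measured at both endpoint years of a reexamination period
#' into former/latter abundance pairs. A plot is kept only if it appears at
#' both endpoints and is forested (positive total biomass, hence defined
#' abundance) at both; plots missing the latter survey, or non-forested at
#' either endpoint, are excluded and counted.
#'
#' @param surveys data frame with columns `plot_id`, `year` and either
#'   biomass columns `pine_biomass`, `fir_biomass`, `broadleaf_biomass` or
#'   abundance columns `pine`, `fir`, `broadleaf` (if both are present the
#'   biomass columns win and a disagreement beyond `1e-6` is an error).
#' @param period length-2 integer vector `(year_start, year_end)`.
#' @param interval expected survey interval in years (default 5); the period
#'   endpoints must differ by exactly this.
#' @return a data frame of class `"ndes_pairs"` with columns `plot_id`,
#'   `year_start`, `year_end`, `y10`, `y20`, `y30` (former triple) and
#'   `y11`, `y21`, `y31` (latter triple), and an `"exclusions"` attribute:
#'   named counts `missing_latter`, `nonforested_former`,
#'   `nonforested_latter`.
#' @examples
#' s <- data.frame(plot_id = c("A", "A", "B"), year = c(1994, 1999, 1994),
#'                 pine = c(.6, .5, 1), fir = c(.3, .3, 0),
#'                 broadleaf = c(.1, .2, 0))
#' pair_surveys(s, c(1994, 1999))
#' @export
pair_surveys <- function(surveys, period, interval = 5L) {
  period <- as.integer(period)
  if (length(period) != 2L || diff(period) != interval)
    stop("period endpoints must differ by the survey interval (", interval,
         " years)")
  s <- normalize_surveys(surveys)
  s <- s[s$year %in% period, , drop = FALSE]
  if (anyDuplicated(s[c("plot_id", "year")])) {
    d <- s[duplicated(s[c("plot_id", "year")]), ]
    stop("duplicate (plot_id, year) rows: ",
         paste(unique(paste0(d$plot_id, "@", d$year)), collapse = ", "),
         call. = FALSE)
  }
  former <- s[s$year == period[1], , drop = FALSE]
  latter <- s[s$year == period[2], , drop = FALSE]
  i <- match(former$plot_id, latter$plot_id)
  f_ok <- !is.na(former$pine)
  l_present <- !is.na(i)
  l_ok <- l_present & !is.na(latter$pine[i])
  keep <- f_ok & l_ok
  # disjoint reasons so kept + excluded = plots present at the former year
  excl <- c(missing_latter = sum(!l_present),
            nonforested_former = sum(l_present & !f_ok),
            nonforested_latter = sum(l_present & f_ok & !l_ok))
  out <- data.frame(plot_id = former$plot_id[keep],
                    year_start = period[1], year_end = period[2])
  out[c("y10", "y20", "y30")] <- as.matrix(former[keep, GROUPS])
  out[c("y11", "y21", "y31")] <- as.matrix(latter[i[keep], GROUPS])
  attr(out, "exclusions") <- excl
  class(out) <- c("ndes_pairs", "data.frame")
  out
}

#' Tally dominant species groups over paired plots
#'
#' The dominant group of a plot is the one with the largest abundance.
#' Exact ties are resolved by the fixed priority pine > fir > broadleaf and
#' counted in the `ties` field so tallies are reproducible.
#'
#' @param pairs an `ndes_pairs` data frame (see [pair_surveys()]).
#' @param stage `"former"` or `"latter"` survey of each pair.
#' @return list with `counts` (named integer triple), `total` and `ties`.
#' @export
tally_dominant_groups <- function(pairs, stage = c("former", "latter")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  cols <- if (stage == "former") c("y10", "y20", "y30") else c("y11", "y21", "y31")
  y <- as.matrix(pairs[cols])
  mx <- apply(y, 1, max)
  n_at_max <- rowSums(y == mx)
  dom <- apply(y, 1, which.max)  # which.max: first max wins = pine > fir > broadleaf
  counts <- stats::setNames(tabulate(dom, 3L), GROUPS)
  list(counts = counts, total = nrow(y), ties = sum(n_at_max > 1L))
}
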