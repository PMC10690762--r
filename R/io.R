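#' Read a delimited plot survey table
#'
#' Reads a UTF-8 delimited text file with a header row, one row per plot per
#' survey year. The delimiter (comma or tab) is auto-detected from the
#' header. Expected columns: `plot_id`, `year`, and either per-group biomass
#' (`pine_biomass`, `fir_biomass`, `broadleaf_biomass`) or abundance
#' proportions (`pine`, `fir`, `broadleaf`).
#'
#' @param path file path.
#' @return a data frame of plot surveys (validated lazily by
#'   [pair_surveys()]).
#' @export
read_plot_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = TRUE,
                         fileEncoding = "UTF-8")
  if (!all(c("plot_id", "year") %in% names(x)))
    stop("plot table must have columns plot_id and year: ", path)
  x
}

#' Write a plot survey table
#'
#' @param surveys data frame as produced by [generate_panel()] or accepted
#'   by [pair_surveys()].
#' @param path destination; `sep` `","` (default) or `"\t"`.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(surveys, path, sep = ",") {
  utils::write.table(surveys, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a species group map config
#'
#' The config is a YAML file mapping each group (`pine`, `fir`,
#' `broadleaf`) to a list of species names, e.g.
#' ```yaml
#' pine: ["Pinus massoniana", "Pinus taiwanensis"]
#' fir: ["Cunninghamia lanceolata"]
#' broadleaf: ["Quercus", "Schima superba"]
#' ```
#'
#' @param path file path.
#' @return [read_species_map()]: a [species_group_map()].
#' @export
read_species_map <- function(path) {
  groups <- yaml::read_yaml(path)
  groups <- lapply(groups, as.character)
  species_group_map(groups)
}

#' @rdname read_species_map
#' @param map a [species_group_map()] (or the named list form).
#' @export
write_species_map <- function(map, path) {
  groups <- if (inherits(map, "species_group_map")) map$groups else map
  yaml::write_yaml(groups, path)
  invisible(path)
}
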