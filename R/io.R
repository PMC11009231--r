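## CSV round-trips for generated tables --------------------------------------
##
## Plain-CSV schemas so every synthetic input (species table, plot/tree
## records, landscape, suitability maps, plans, ratio series) can be written
## to disk and read back identically.

#' Write / read a species table
#' @param tab species table; `path` a CSV file path.
#' @return `read_species_csv` returns the validated table.
#' @export
write_species_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_csv
#' @param path CSV file path.
#' @export
read_species_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$replacement_target[tab$replacement_target == ""] <- NA_character_
  validate_species_table(tab)
  tab
}

#' Write / read a landscape (two CSVs: cells and cohorts)
#' @param landscape an `fc_landscape`.
#' @param dir directory for `cells.csv` and `cohorts.csv`.
#' @export
write_landscape_csv <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(landscape$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$cohorts, file.path(dir, "cohorts.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(dir) {
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  cohorts <- utils::read.csv(file.path(dir, "cohorts.csv"),
                             stringsAsFactors = FALSE)
  structure(list(cells = cells, cohorts = cohorts,
                 grid = c(nrow = max(cells$row) + 1L,
                          ncol = max(cells$col) + 1L)),
            class = "fc_landscape")
}

#' Write / read a suitability matrix
#' @param m cell x species suitability matrix.
#' @param path CSV file path.
#' @export
write_suitability_csv <- function(m, path) {
  utils::write.csv(data.frame(cell_id = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_suitability_csv
#' @export
read_suitability_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$cell_id
  m
}

#' Read a scenario configuration from a YAML file
#'
#' Keys match the [scenario_config()] arguments exactly; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return an `fc_scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_input("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(scenario_config)))
  if (length(unknown))
    stop_input("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(scenario_config, vals)
}

#' @export
print.fc_landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d cells (%d x %d grid), %d cohorts (1 km2 each)\n",
              nrow(x$cells), x$grid[1], x$grid[2], nrow(x$cohorts)))
  cat(sprintf("  standing carbon: %.2f Tg C; grass/shrub budget: %.0f km2\n",
              sum(x$cohorts$carbon_density) * HA_PER_KM2 * 1e-6,
              sum(x$cells$grassland_shrubland_km2)))
  invisible(x)
}
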