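# Scenario projection: continuous suitability maps and their binarization at
# the sensitivity+specificity-maximizing threshold.

#' Project an ensemble onto a scenario's climate grid
#'
#' @param ensemble an `ensemble_niche_model`.
#' @param grid a [climate_grid()] with all 24 variables.
#' @return a `suitability_map`: values matrix in \[0, 1\] plus scenario id.
#' @export
project_ensemble <- function(ensemble, grid) {
  x <- extract_climate(grid)  # errors if a variable is missing, naming it
  p <- predict(ensemble, x)
  structure(list(scenario_id = grid$scenario_id,
                 values = matrix(p, grid$n_rows, grid$n_cols),
                 n_rows = grid$n_rows, n_cols = grid$n_cols,
                 cell_size = grid$cell_size, origin = grid$origin),
            class = "suitability_map")
}

#' Binarize a suitability map
#'
#' A cell is suitable when its value is >= `threshold` (inclusive). The
#' threshold is chosen once per species from recent-scenario held-out
#' evaluation (the ensemble's `eval$threshold`) and reused unchanged for all
#' six scenarios.
#'
#' @param map a `suitability_map`.
#' @param threshold numeric in (0, 1).
#' @param species_id optional species label carried on the result.
#' @return a `binary_niche_map`: logical mask, threshold, `range_size` (count
#'   of suitable cells) and grid geometry.
#' @export
binarize <- function(map, threshold, species_id = NA_character_) {
  stopifnot(inherits(map, "suitability_map"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  mask <- map$values >= threshold
  structure(list(species_id = species_id, scenario_id = map$scenario_id,
                 mask = mask, threshold = threshold, range_size = sum(mask),
                 n_rows = map$n_rows, n_cols = map$n_cols,
                 cell_size = map$cell_size, origin = map$origin),
            class = "binary_niche_map")
}

#' @export
print.binary_niche_map <- function(x, ...) {
  cat(sprintf("<binary_niche_map> %s / %s: %d suitable cells (threshold %.3f)\n",
              x$species_id, x$scenario_id, x$range_size, x$threshold))
  invisible(x)
}

#' Binary map from a logical matrix
#'
#' Convenience constructor used when the mask comes from somewhere other
#' than [binarize()] (e.g. a virtual species' true niche).
#'
#' @param mask logical matrix.
#' @param scenario_id,species_id labels.
#' @param cell_size,origin grid geometry (km).
#' @param threshold value recorded on the map.
#' @return a `binary_niche_map`.
#' @export
binary_niche_map <- function(mask, scenario_id = "recent",
                             species_id = NA_character_, cell_size = 1,
                             origin = c(0, 0), threshold = 0.5) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(species_id = species_id, scenario_id = scenario_id,
                 mask = mask, threshold = threshold, range_size = sum(mask),
                 n_rows = nrow(mask), n_cols = ncol(mask),
                 cell_size = cell_size, origin = origin),
            class = "binary_niche_map")
}
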