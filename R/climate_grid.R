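#' Climate grid container
#'
#' A `climate_grid` holds the 24 monthly climate layers (12 mean monthly
#' temperatures in degrees C, 12 mean monthly precipitations in mm) plus an
#' elevation layer, on a regular planar grid in an equal-area km coordinate
#' system. Layers are matrices with `n_rows` rows and `n_cols` columns; row
#' `r`, column `c` covers the square cell whose center is at
#' `x = origin[1] + (c - 0.5) * cell_size`,
#' `y = origin[2] + (r - 0.5) * cell_size`. y increases northward.
#'
#' @param scenario_id one of `scenario_labels()`.
#' @param layers named list of 24 matrices (`tmean_01`..`tmean_12`,
#'   `prec_01`..`prec_12`), all with identical dimensions.
#' @param elevation elevation matrix (m), same dimensions as the layers.
#' @param cell_size cell edge length in km.
#' @param origin numeric length-2, (x, y) of the grid's lower-left corner (km).
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(scenario_id, layers, elevation,
                         cell_size = 1, origin = c(0, 0)) {
  scenario_id <- match.arg(scenario_id, scenario_labels())
  expected <- climate_variable_names()
  if (!setequal(names(layers), expected)) {
    missing <- setdiff(expected, names(layers))
    extra <- setdiff(names(layers), expected)
    stop("layers must be exactly the 24 monthly variables; missing: ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  layers <- layers[expected]
  dims <- dim(layers[[1]])
  for (nm in expected) {
    if (!identical(dim(layers[[nm]]), dims)) {
      stop("layer ", nm, " does not match grid dimensions")
    }
  }
  if (!identical(dim(elevation), dims)) stop("elevation does not match grid dimensions")
  for (m in sprintf("prec_%02d", 1:12)) {
    if (any(layers[[m]] < 0)) stop("precipitation layer ", m, " has negative values")
  }
  structure(
    list(scenario_id = scenario_id, layers = layers, elevation = elevation,
         n_rows = dims[1], n_cols = dims[2],
         cell_size = cell_size, origin = as.numeric(origin)),
    class = "climate_grid"
  )
}

#' The six time-by-climate scenario labels
#'
#' Past, recent, and four futures: mid- and late-century under a moderate
#' (RCP 4.5 analogue) and a high (RCP 8.5 analogue) emission pathway.
#' @return character vector of length 6.
#' @export
scenario_labels <- function() {
  c("past", "recent", "mid45", "mid85", "late45", "late85")
}

#' Names of the 24 monthly climate variables
#' @return character vector: `tmean_01`..`tmean_12`, `prec_01`..`prec_12`.
#' @export
climate_variable_names <- function() {
  c(sprintf("tmean_%02d", 1:12), sprintf("prec_%02d", 1:12))
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("<climate_grid> scenario:", x$scenario_id,
      sprintf("| %d x %d cells of %g km | origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  jul <- x$layers$tmean_07
  cat(sprintf("  tmean_07 mean %.2f C | prec_07 mean %.1f mm | elev %d-%d m\n",
              mean(jul), mean(x$layers$prec_07),
              round(min(x$elevation)), round(max(x$elevation))))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a `climate_grid`.
#' @return integer count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-center coordinates
#'
#' @param grid a `climate_grid`.
#' @param cells optional integer vector of cell indices (column-major, as
#'   produced by `cell_index()`); default all cells.
#' @return data.frame with columns `cell`, `row`, `col`, `x`, `y` (km).
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(grid))
  row <- ((cells - 1L) %% grid$n_rows) + 1L
  col <- ((cells - 1L) %/% grid$n_rows) + 1L
  data.frame(
    cell = cells, row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size
  )
}

#' Map point coordinates to cell indices
#'
#' Points outside the grid extent get `NA`.
#'
#' @param grid a `climate_grid`.
#' @param x,y point coordinates (km).
#' @return integer vector of column-major cell indices (NA = off-grid).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  # points exactly on the top/right edge belong to the last cell
  col[x == grid$origin[1] + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin[2] + grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    is.na(x) | is.na(y)
  idx <- (col - 1L) * grid$n_rows + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Extract the 24-variable climate matrix for a set of cells
#'
#' @param grid a `climate_grid`.
#' @param cells integer cell indices; default all cells.
#' @param variables which variables to extract; default all 24.
#' @return numeric matrix, one row per cell, one named column per variable.
#' @export
extract_climate <- function(grid, cells = NULL, variables = climate_variable_names()) {
  unknown <- setdiff(variables, names(grid$layers))
  if (length(unknown)) {
    stop("variable(s) not in grid: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cells)) cells <- seq_len(n_cells(grid))
  out <- vapply(variables, function(v) grid$layers[[v]][cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, variables))
  out
}
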