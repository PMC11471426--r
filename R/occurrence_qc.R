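# Occurrence quality control: year window, distance-to-range, centroid
# proximity, taxon grouping, per-cell deduplication, and the modelable gate.
# Filters run in a fixed order and the report conserves record counts.

#' Filter records to a year window
#'
#' Records with a missing year, or a year outside the closed window, are
#' removed.
#'
#' @param table occurrence data.frame with at least species, x, y, year.
#' @param window inclusive year bounds, default 1981-2018.
#' @return the retained rows.
#' @export
filter_year_window <- function(table, window = c(1981, 2018)) {
  if (nrow(table) == 0) stop("empty occurrence table")
  keep <- !is.na(table$year) & table$year >= window[1] & table$year <= window[2]
  table[keep, , drop = FALSE]
}

#' Remove records far from a species' documented range
#'
#' Records at `max_km` or more (inclusive) from the range polygon are
#' removed; points inside the polygon have distance 0. Species without a
#' polygon in `range_polygons` pass through untouched, mirroring
#' "when available" range products.
#'
#' @param table occurrence data.frame.
#' @param range_polygons named list (by species) of two-column vertex
#'   matrices, or a single matrix applied to all species; NULL = no-op.
#' @param max_km removal distance (km), inclusive.
#' @return the retained rows.
#' @export
filter_far_from_range <- function(table, range_polygons = NULL, max_km = 200) {
  if (is.null(range_polygons)) return(table)
  if (is.matrix(range_polygons) || is.data.frame(range_polygons)) {
    range_polygons <- stats::setNames(
      rep(list(as.matrix(range_polygons)), length(unique(table$species))),
      unique(table$species))
  }
  keep <- rep(TRUE, nrow(table))
  for (sp in unique(table$species)) {
    poly <- range_polygons[[sp]]
    if (is.null(poly)) next
    i <- which(table$species == sp)
    d <- point_polygon_distance(table$x[i], table$y[i], poly)
    keep[i] <- d < max_km
  }
  table[keep, , drop = FALSE]
}

#' Remove records snapped to jurisdiction centroids
#'
#' Records strictly within `max_m` of any centroid are removed; such
#' coordinates are typically polygon centers substituted for unknown true
#' locations.
#'
#' @param table occurrence data.frame.
#' @param centroids data.frame with x, y columns (km), one row per centroid.
#' @param max_m removal radius in meters (strict <).
#' @return the retained rows.
#' @export
filter_centroid_proximity <- function(table, centroids, max_m = 300) {
  if (is.null(centroids) || nrow(centroids) == 0) stop("centroid list is empty")
  if (nrow(table) == 0) return(table)
  max_km <- max_m / 1000
  dmin <- rep(Inf, nrow(table))
  for (j in seq_len(nrow(centroids))) {
    dmin <- pmin(dmin, sqrt((table$x - centroids$x[j])^2 +
                            (table$y - centroids$y[j])^2))
  }
  table[dmin >= max_km, , drop = FALSE]
}

#' Relabel species into taxon groups
#'
#' Species listed in `grouping` are renamed to their group id (e.g., four
#' congeners collapsed into one genus-level group). Cell deduplication must
#' be (re-)applied afterwards; [qc_pipeline()] does this.
#'
#' @param table occurrence data.frame.
#' @param grouping named character: species -> group id. Names absent from
#'   the table are ignored; a species mapped to two groups is an error.
#' @return the relabeled table.
#' @export
group_taxa <- function(table, grouping = character()) {
  if (!length(grouping)) return(table)
  if (anyDuplicated(names(grouping))) {
    dup <- names(grouping)[duplicated(names(grouping))]
    stop("species mapped to more than one group: ", paste(unique(dup), collapse = ", "))
  }
  hit <- table$species %in% names(grouping)
  table$species[hit] <- unname(grouping[table$species[hit]])
  table
}

#' Deduplicate records by species and grid cell
#'
#' Retains exactly one record per (species, cell). Ties break to the record
#' with the earliest year (missing years sort last), then the
#' lexicographically smallest source, then original order, so the choice is
#' deterministic and auditable. Records outside the grid extent are removed
#' (out of range).
#'
#' @param table occurrence data.frame.
#' @param grid a [climate_grid()] supplying the cell geometry.
#' @return the retained rows, with a `cell` column.
#' @export
dedupe_by_cell <- function(table, grid) {
  if (nrow(table) == 0) return(table)
  table$cell <- cell_index(grid, table$x, table$y)
  table <- table[!is.na(table$cell), , drop = FALSE]
  if (nrow(table) == 0) return(table)
  yr <- ifelse(is.na(table$year), Inf, table$year)
  ord <- order(table$species, table$cell, yr, as.character(table$source))
  table <- table[ord, , drop = FALSE]
  keep <- !duplicated(table[, c("species", "cell")])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species with enough records to model
#'
#' @param table QC'd occurrence data.frame.
#' @param min_points threshold; a species is modelable with strictly more
#'   than this many retained records (default 50).
#' @return character vector of modelable species ids.
#' @export
select_modelable <- function(table, min_points = 50) {
  counts <- table(table$species)
  names(counts)[counts > min_points]
}

#' Run the full occurrence QC pipeline
#'
#' Fixed filter order: year window, far-from-range, centroid proximity,
#' taxon grouping, cell deduplication, modelable gate. The report conserves
#' counts per species (input = retained + sum of removals) and the pipeline
#' is idempotent.
#'
#' @param table raw occurrence data.frame (species, x, y, year, source).
#' @param grid a [climate_grid()].
#' @param jurisdictions a `jurisdiction_set` (its centroids feed the
#'   centroid-proximity filter); NULL skips that filter.
#' @param range_polygons optional named list of range polygons (see
#'   [filter_far_from_range()]).
#' @param grouping optional species -> group map.
#' @param year_window inclusive year bounds.
#' @param max_range_km far-from-range removal distance.
#' @param centroid_m centroid-proximity removal radius (meters).
#' @param min_points modelable gate.
#' @return list with `table` (retained records), `modelable` (species ids),
#'   and `report` (a data.frame of per-species, per-stage attrition).
#' @export
qc_pipeline <- function(table, grid, jurisdictions = NULL, range_polygons = NULL,
                        grouping = character(), year_window = c(1981, 2018),
                        max_range_km = 200, centroid_m = 300, min_points = 50) {
  count_by <- function(t) {
    if (nrow(t) == 0) return(integer())
    c(table(t$species))
  }
  all_species <- unique(table$species)
  tally <- function(before, after) {
    b <- count_by(before); a <- count_by(after)
    sapply(all_species, function(s) {
      bs <- if (s %in% names(b)) b[[s]] else 0L
      as <- if (s %in% names(a)) a[[s]] else 0L
      bs - as
    })
  }

  t0 <- table
  t1 <- filter_year_window(t0, year_window)
  rm_year <- tally(t0, t1)
  t2 <- filter_far_from_range(t1, range_polygons, max_range_km)
  rm_range <- tally(t1, t2)
  t3 <- if (is.null(jurisdictions)) t2 else
    filter_centroid_proximity(t2, jurisdictions$centroids, centroid_m)
  rm_centroid <- tally(t2, t3)
  t4 <- group_taxa(t3, grouping)
  t5 <- dedupe_by_cell(t4, grid)
  # grouping relabels species, so attribute grouping+dedupe attrition to the
  # post-grouping labels; pre-grouping labels close their ledger at grouping
  grouped_species <- unique(t4$species)
  rm_dedupe <- sapply(grouped_species, function(s) {
    sum(t4$species == s) - sum(t5$species == s)
  })
  modelable <- select_modelable(t5, min_points)

  retained <- sapply(grouped_species, function(s) sum(t5$species == s))
  report <- data.frame(
    species = grouped_species,
    removed_dedupe_or_offgrid = as.integer(rm_dedupe),
    retained = as.integer(retained),
    modelable = grouped_species %in% modelable,
    row.names = NULL
  )
  pre_report <- data.frame(
    species = all_species,
    input = as.integer(sapply(all_species, function(s) sum(t0$species == s))),
    removed_year = as.integer(rm_year),
    removed_far_from_range = as.integer(rm_range),
    removed_centroid = as.integer(rm_centroid),
    row.names = NULL
  )
  list(table = t5, modelable = modelable,
       report = report, stage_report = pre_report)
}
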