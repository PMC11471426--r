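# Range-change accounting between scenario pairs: pixel gain/loss/maintain
# counts, the derived percentages, expand/shift/contract/stable
# classification, centroid shifts, and stacked richness.

#' Range-change summary from pixel counts
#'
#' The percentage conventions follow the published pixel table: percent lost
#' = 100 * Loss / (Loss + Maintain); percent gained = 100 * Gain /
#' (Loss + Maintain); range change = percent gained - percent lost, computed
#' from the unrounded ratios (never from the rounded percentages) and equal
#' to the net percent change in range size. Rounding to 2 decimals happens
#' only at export.
#'
#' @param loss,gain,maintain non-negative pixel counts.
#' @param species_id,scenario_from,scenario_to labels.
#' @param centroid_from,centroid_to optional (x, y) centroids (km).
#' @return a `range_change_summary`.
#' @export
range_change_summary <- function(loss, gain, maintain,
                                 species_id = NA_character_,
                                 scenario_from = NA_character_,
                                 scenario_to = NA_character_,
                                 centroid_from = NULL, centroid_to = NULL) {
  stopifnot(loss >= 0, gain >= 0, maintain >= 0)
  current <- loss + maintain
  future <- gain + maintain
  if (current > 0) {
    percent_lost <- 100 * loss / current
    percent_gained <- 100 * gain / current
  } else {
    percent_lost <- NA_real_
    percent_gained <- NA_real_
  }
  shift <- if (!is.null(centroid_from) && !is.null(centroid_to)) {
    centroid_shift_xy(centroid_from, centroid_to)
  } else {
    list(shift_km = NA_real_, bearing_deg = NA_real_)
  }
  structure(list(
    species_id = species_id,
    scenario_pair = c(from = scenario_from, to = scenario_to),
    loss = loss, gain = gain, maintain = maintain,
    current_size = current, future_size = future,
    percent_lost = percent_lost, percent_gained = percent_gained,
    range_change = percent_gained - percent_lost,
    net_change_pct = if (current > 0) 100 * (future - current) / current else NA_real_,
    turnover_pct = percent_lost,
    centroid_from = centroid_from, centroid_to = centroid_to,
    shift_km = shift$shift_km, bearing_deg = shift$bearing_deg,
    class = NA_character_
  ), class = "range_change_summary")
}

#' @export
print.range_change_summary <- function(x, ...) {
  cat(sprintf(
    "<range_change_summary> %s %s->%s | current %d future %d | lost %.2f%% gained %.2f%% change %.2f%%%s\n",
    x$species_id, x$scenario_pair[["from"]], x$scenario_pair[["to"]],
    x$current_size, x$future_size, x$percent_lost, x$percent_gained,
    x$range_change,
    if (!is.na(x$class)) paste0(" | ", x$class) else ""))
  invisible(x)
}

#' Compare two binary niche maps
#'
#' Loss = cells suitable in `from_map` only; gain = suitable in `to_map`
#' only; maintain = suitable in both. Grids must match.
#'
#' @param from_map,to_map `binary_niche_map`s of the same species and grid.
#' @return a [range_change_summary()] including both centroids and the
#'   centroid shift.
#' @export
compare_ranges <- function(from_map, to_map) {
  stopifnot(inherits(from_map, "binary_niche_map"),
            inherits(to_map, "binary_niche_map"))
  if (!identical(dim(from_map$mask), dim(to_map$mask)) ||
      !identical(from_map$cell_size, to_map$cell_size) ||
      !identical(from_map$origin, to_map$origin)) {
    stop("binary maps are on mismatched grids")
  }
  loss <- sum(from_map$mask & !to_map$mask)
  gain <- sum(!from_map$mask & to_map$mask)
  maintain <- sum(from_map$mask & to_map$mask)
  range_change_summary(
    loss, gain, maintain,
    species_id = from_map$species_id,
    scenario_from = from_map$scenario_id, scenario_to = to_map$scenario_id,
    centroid_from = if (from_map$range_size > 0) niche_centroid(from_map) else NULL,
    centroid_to = if (to_map$range_size > 0) niche_centroid(to_map) else NULL
  )
}

#' Classify a range change
#'
#' Rules on the net size change (dead band +/- `net_thresh`), the turnover
#' (percent of originally suitable cells lost), and the centroid movement:
#' net >= +10% with turnover <= 50% is `expand`; net >= +10% with turnover
#' > 50% is `shift`; net <= -10% is `contract`; within the dead band,
#' a centroid displacement beyond `centroid_thresh_km` is `stable_shift`,
#' otherwise `stable`. An empty current range is `undefined`.
#'
#' @param summary a `range_change_summary`.
#' @param net_thresh net-change dead band half-width (percent, default 10).
#' @param turnover_thresh turnover cut separating expand from shift
#'   (percent, default 50).
#' @param centroid_thresh_km centroid displacement separating stable from
#'   stable_shift (default 100 km).
#' @return the summary with its `class` field set.
#' @export
classify_change <- function(summary, net_thresh = 10, turnover_thresh = 50,
                            centroid_thresh_km = 100) {
  stopifnot(inherits(summary, "range_change_summary"))
  if (summary$current_size == 0) {
    summary$class <- "undefined"
    return(summary)
  }
  net <- summary$net_change_pct
  turn <- summary$turnover_pct
  summary$class <- if (net >= net_thresh && turn <= turnover_thresh) {
    "expand"
  } else if (net >= net_thresh) {
    "shift"
  } else if (net <= -net_thresh) {
    "contract"
  } else if (!is.na(summary$shift_km) && summary$shift_km > centroid_thresh_km) {
    "stable_shift"
  } else {
    "stable"
  }
  summary
}

#' Centroid (center of gravity) of a binary niche map
#'
#' Unweighted arithmetic mean of the suitable cells' center coordinates.
#'
#' @param map a `binary_niche_map` with at least one suitable cell.
#' @return named numeric (x, y) in km.
#' @export
niche_centroid <- function(map) {
  stopifnot(inherits(map, "binary_niche_map"))
  if (map$range_size < 1) stop("centroid undefined: empty niche map")
  idx <- which(map$mask)
  row <- ((idx - 1L) %% map$n_rows) + 1L
  col <- ((idx - 1L) %/% map$n_rows) + 1L
  c(x = map$origin[1] + mean(col - 0.5) * map$cell_size,
    y = map$origin[2] + mean(row - 0.5) * map$cell_size)
}

centroid_shift_xy <- function(from, to) {
  dx <- to[["x"]] - from[["x"]]
  dy <- to[["y"]] - from[["y"]]
  list(shift_km = sqrt(dx^2 + dy^2),
       bearing_deg = (atan2(dx, dy) * 180 / pi) %% 360)
}

#' Centroid shift between two binary maps
#'
#' Euclidean distance (km) and bearing clockwise from grid north
#' (0 = north, 90 = east).
#'
#' @param from_map,to_map `binary_niche_map`s with non-empty niches.
#' @return list: shift_km, bearing_deg.
#' @export
centroid_shift <- function(from_map, to_map) {
  centroid_shift_xy(niche_centroid(from_map), niche_centroid(to_map))
}

#' Stacked species richness
#'
#' Per-cell count of species whose binary niche map marks the cell suitable.
#'
#' @param maps list of `binary_niche_map`s on one shared grid (one scenario).
#' @param n_rows,n_cols grid dimensions, required only when `maps` is empty.
#' @return a `richness_map`: integer values matrix plus the species set.
#' @export
richness_stack <- function(maps, n_rows = NULL, n_cols = NULL) {
  if (!length(maps)) {
    if (is.null(n_rows) || is.null(n_cols)) {
      stop("empty species set: supply n_rows and n_cols")
    }
    return(structure(list(scenario_id = NA_character_,
                          values = matrix(0L, n_rows, n_cols),
                          species = character()),
                     class = "richness_map"))
  }
  dims <- dim(maps[[1]]$mask)
  vals <- matrix(0L, dims[1], dims[2])
  for (m in maps) {
    if (!identical(dim(m$mask), dims)) stop("richness stack: grid mismatch")
    vals <- vals + m$mask
  }
  structure(list(scenario_id = maps[[1]]$scenario_id, values = vals,
                 species = vapply(maps, `[[`, "", "species_id")),
            class = "richness_map")
}

#' Richness change between scenarios under a dispersal assumption
#'
#' Full dispersal counts every newly suitable cell; no dispersal masks each
#' species' gains outside its recent range (losses always count), so the
#' change layer is nowhere positive.
#'
#' @param recent_maps,future_maps lists of `binary_niche_map`s with matching
#'   species sets, on one shared grid.
#' @param dispersal `"full"` or `"none"`.
#' @return signed integer matrix (future minus recent richness).
#' @export
richness_change <- function(recent_maps, future_maps, dispersal = c("full", "none")) {
  dispersal <- match.arg(dispersal)
  rs <- vapply(recent_maps, `[[`, "", "species_id")
  fs <- vapply(future_maps, `[[`, "", "species_id")
  if (!identical(sort(rs), sort(fs))) stop("species sets differ between stacks")
  future_maps <- future_maps[match(rs, fs)]
  dims <- dim(recent_maps[[1]]$mask)
  delta <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(recent_maps)) {
    r <- recent_maps[[i]]$mask; f <- future_maps[[i]]$mask
    if (!identical(dim(r), dims) || !identical(dim(f), dims)) {
      stop("richness change: grid mismatch")
    }
    eff <- if (dispersal == "none") f & r else f
    delta <- delta + (eff - r)
  }
  delta
}
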