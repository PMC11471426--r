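# Synthetic jurisdictions and occurrence sampling, including the data
# defects the QC pipeline is built to catch.

# sample() treats a length-1 x as 1:x; this does not
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a jurisdiction partition of a grid
#'
#' Discrete Voronoi tessellation: `n` seed points are scattered uniformly and
#' every cell is assigned to its nearest seed, so jurisdictions are irregular
#' but tile the grid exactly (every cell belongs to exactly one).
#'
#' @param grid a [climate_grid()].
#' @param n number of jurisdictions.
#' @param seed integer seed.
#' @return a `jurisdiction_set`: integer assignment matrix (values 1..n),
#'   jurisdiction ids, and centroids (mean suitable cell-center per region).
#' @export
generate_jurisdictions <- function(grid, n = 9, seed = 1) {
  stopifnot(n >= 1, n <= n_cells(grid))
  with_seed(seed, {
    xmax <- grid$origin[1] + grid$n_cols * grid$cell_size
    ymax <- grid$origin[2] + grid$n_rows * grid$cell_size
    sx <- stats::runif(n, grid$origin[1], xmax)
    sy <- stats::runif(n, grid$origin[2], ymax)
    cc <- cell_centers(grid)
    d2 <- outer(cc$x, sx, "-")^2 + outer(cc$y, sy, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    assignment <- matrix(nearest, grid$n_rows, grid$n_cols)
    ids <- sprintf("J%02d", seq_len(n))
    centroids <- data.frame(
      jurisdiction = ids,
      x = tapply(cc$x, factor(nearest, levels = seq_len(n)), mean),
      y = tapply(cc$y, factor(nearest, levels = seq_len(n)), mean),
      row.names = NULL
    )
    structure(list(assignment = assignment, ids = ids, centroids = centroids,
                   n = n, seed = seed),
              class = "jurisdiction_set")
  })
}

#' @export
print.jurisdiction_set <- function(x, ...) {
  cat("<jurisdiction_set>", x$n, "regions tiling a",
      nrow(x$assignment), "x", ncol(x$assignment), "grid\n")
  invisible(x)
}

#' Sample occurrence records for a virtual species
#'
#' Clean records are cells drawn without replacement with probability
#' proportional to true suitability within the true-suitable region
#' (suitability >= 0.5), jittered within their cell; years are uniform on
#' 1981-2018. Artifact records emulating real data defects are injected at
#' the given rates: `duplicate` (a second record in an already-sampled cell),
#' `missing_year`, `centroid_snap` (placed within 300 m of a jurisdiction
#' centroid), and `far_outlier` (placed at least 200 km outside the species'
#' true-suitable hull). The `artifact` column stores the ground-truth label.
#'
#' @param species a [virtual_species()].
#' @param grid a [climate_grid()].
#' @param n total number of records (>= 1).
#' @param artifact_rates named numeric rates in \[0, 1\] summing to <= 1, with
#'   any of the names duplicate, missing_year, centroid_snap, far_outlier.
#' @param jurisdictions a `jurisdiction_set`; required when
#'   `centroid_snap > 0`, and used to keep clean records away from centroids.
#' @param seed integer seed.
#' @return data.frame: species, x, y, year, source, artifact, cell.
#' @export
sample_occurrences <- function(species, grid, n,
                               artifact_rates = c(duplicate = 0, missing_year = 0,
                                                  centroid_snap = 0, far_outlier = 0),
                               jurisdictions = NULL, seed = 1) {
  if (n < 1) stop("n must be at least 1")
  rates <- c(duplicate = 0, missing_year = 0, centroid_snap = 0, far_outlier = 0)
  unknown <- setdiff(names(artifact_rates), names(rates))
  if (length(unknown)) stop("unknown artifact rate(s): ", paste(unknown, collapse = ", "))
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("artifact rates must lie in [0, 1] and sum to at most 1")
  }
  if (rates[["centroid_snap"]] > 0 && is.null(jurisdictions)) {
    stop("centroid_snap artifacts require a jurisdiction_set")
  }

  with_seed(seed, {
    suit <- true_suitability(species, grid)
    suitable <- which(suit >= 0.5)
    if (!length(suitable)) stop("species has no true-suitable cells on this grid")
    n_art <- floor(n * rates)
    # rounding remainder goes to clean records
    n_clean <- n - sum(n_art)
    if (n_clean > length(suitable)) {
      stop("n exceeds the number of true-suitable cells (", length(suitable), ")")
    }

    jitter_xy <- function(cells) {
      cc <- cell_centers(grid, cells)
      h <- 0.49 * grid$cell_size
      x <- cc$x + stats::runif(length(cells), -h, h)
      y <- cc$y + stats::runif(length(cells), -h, h)
      if (!is.null(jurisdictions)) {
        # keep non-snapped records clear of centroids so QC removal counts
        # equal the injected artifact counts exactly
        for (i in seq_along(x)) {
          tries <- 0
          while (min(sqrt((x[i] - jurisdictions$centroids$x)^2 +
                          (y[i] - jurisdictions$centroids$y)^2)) < 0.35 &&
                 tries < 50) {
            x[i] <- cc$x[i] + stats::runif(1, -h, h)
            y[i] <- cc$y[i] + stats::runif(1, -h, h)
            tries <- tries + 1
          }
        }
      }
      cbind(x, y)
    }
    sources <- c("museum", "gbif", "agency")
    draw_years <- function(k) sample(1981:2018, k, replace = TRUE)
    mk <- function(cells, xy, year, artifact) {
      data.frame(species = species$species_id, x = xy[, 1], y = xy[, 2],
                 year = year, source = sample(sources, length(cells), replace = TRUE),
                 artifact = artifact, cell = cells, stringsAsFactors = FALSE)
    }

    clean_cells <- resample(suitable, n_clean, prob = suit[suitable])
    recs <- mk(clean_cells, jitter_xy(clean_cells), draw_years(n_clean), "none")

    if (n_art[["duplicate"]] > 0) {
      dup_cells <- resample(clean_cells, n_art[["duplicate"]], replace = TRUE)
      recs <- rbind(recs, mk(dup_cells, jitter_xy(dup_cells),
                             draw_years(n_art[["duplicate"]]), "duplicate"))
    }
    if (n_art[["missing_year"]] > 0) {
      my_pool <- setdiff(suitable, unique(recs$cell))
      if (length(my_pool) < n_art[["missing_year"]]) my_pool <- suitable
      my_cells <- resample(my_pool, n_art[["missing_year"]])
      recs <- rbind(recs, mk(my_cells, jitter_xy(my_cells),
                             rep(NA_integer_, n_art[["missing_year"]]), "missing_year"))
    }
    if (n_art[["centroid_snap"]] > 0) {
      k <- n_art[["centroid_snap"]]
      ci <- sample(nrow(jurisdictions$centroids), k, replace = TRUE)
      ang <- stats::runif(k, 0, 2 * pi)
      rad <- stats::runif(k, 0, 0.25)  # strictly inside 300 m
      x <- jurisdictions$centroids$x[ci] + rad * sin(ang)
      y <- jurisdictions$centroids$y[ci] + rad * cos(ang)
      snap_cells <- cell_index(grid, x, y)
      recs <- rbind(recs, mk(snap_cells, cbind(x, y), draw_years(k), "centroid_snap"))
    }
    if (n_art[["far_outlier"]] > 0) {
      k <- n_art[["far_outlier"]]
      cc <- cell_centers(grid, suitable)
      hull <- convex_hull(cc$x, cc$y)
      cx <- mean(hull[, 1]); cy <- mean(hull[, 2])
      span <- max(dist(rbind(c(cx, cy), hull)))
      ang <- stats::runif(k, 0, 2 * pi)
      rad <- span + 200 + stats::runif(k, 5, 100)
      x <- cx + rad * sin(ang); y <- cy + rad * cos(ang)
      recs <- rbind(recs, mk(cell_index(grid, x, y), cbind(x, y),
                             draw_years(k), "far_outlier"))
    }
    rownames(recs) <- NULL
    recs
  })
}
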