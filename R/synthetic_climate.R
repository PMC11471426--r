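# Synthetic climate generator: smooth monthly temperature/precipitation
# surfaces with seasonal structure on a planar km grid, plus an elevation
# surface, across the six time-by-climate scenarios.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Spatially autocorrelated Gaussian random field
#'
#' White noise convolved (circularly, via FFT) with a separable Gaussian
#' kernel whose standard deviation is `autocorr_length` cells, then
#' standardized to mean 0, sd 1. The torus topology keeps the variance
#' uniform; on grids much wider than the autocorrelation length the
#' wrap-around correlation is negligible.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param autocorr_length kernel standard deviation, in cells (> 0).
#' @return matrix with unit variance.
#' @export
smooth_gaussian_field <- function(n_rows, n_cols, autocorr_length) {
  if (autocorr_length <= 0) stop("autocorr_length must be > 0")
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  wrapped_kernel <- function(n) {
    pos <- 0:(n - 1)
    k <- stats::dnorm(pmin(pos, n - pos), sd = autocorr_length)
    k / sum(k)
  }
  kern <- outer(wrapped_kernel(n_rows), wrapped_kernel(n_cols))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Configuration for the synthetic climate generator
#'
#' Scenario deltas are applied to the recent-scenario surfaces: each future
#' (or past) scenario's monthly temperatures are the recent layer plus a
#' constant offset (degrees C), and its precipitation layers are the recent
#' layer times a multiplier. Defaults emulate RCP 4.5 / 8.5-like warming
#' magnitudes with mild drying.
#'
#' @param n_rows,n_cols grid dimensions (each >= 10).
#' @param cell_size cell edge (km).
#' @param origin lower-left corner (km).
#' @param autocorr_length autocorrelation length of the random fields, km.
#' @param temp_offsets named numeric, one finite offset per scenario (deg C).
#' @param prec_multipliers named numeric, one non-negative multiplier per scenario.
#' @param base_tmean July mean temperature at sea level and southern edge (deg C).
#' @param seasonal_amp amplitude of the annual temperature cycle (deg C);
#'   January sits `2 * seasonal_amp` below July.
#' @param lat_gradient cooling rate northward (deg C per km).
#' @param lapse_rate cooling rate with elevation (deg C per m).
#' @param temp_noise_sd sd of the shared + monthly temperature noise fields (deg C).
#' @param prec_base mean monthly precipitation scale (mm).
#' @param prec_seasonal_amp relative amplitude of the annual precipitation
#'   cycle (winter-wet regime).
#' @param elev_range elevation span (m): a west-east ramp plus smooth relief.
#' @return a `climate_sim_config` list.
#' @export
climate_sim_config <- function(n_rows = 100, n_cols = 100, cell_size = 1,
                               origin = c(0, 0), autocorr_length = 10,
                               temp_offsets = c(past = -0.5, recent = 0,
                                                mid45 = 1.5, mid85 = 2.0,
                                                late45 = 2.0, late85 = 3.0),
                               prec_multipliers = c(past = 1, recent = 1,
                                                    mid45 = 0.98, mid85 = 0.95,
                                                    late45 = 0.95, late85 = 0.90),
                               base_tmean = 24, seasonal_amp = 11,
                               lat_gradient = 0.05, lapse_rate = 0.0065,
                               temp_noise_sd = 1.5, prec_base = 40,
                               prec_seasonal_amp = 0.5, elev_range = c(100, 1600)) {
  if (n_rows < 10 || n_cols < 10) stop("grid must be at least 10 x 10")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (autocorr_length <= 0) stop("autocorr_length must be > 0")
  labs <- scenario_labels()
  if (!all(labs %in% names(temp_offsets)) || any(!is.finite(temp_offsets[labs]))) {
    stop("temp_offsets must give a finite value for each of the six scenarios")
  }
  if (!all(labs %in% names(prec_multipliers)) || any(prec_multipliers[labs] < 0)) {
    stop("prec_multipliers must be non-negative for each of the six scenarios")
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size, origin = origin,
    autocorr_length = autocorr_length,
    temp_offsets = temp_offsets[labs], prec_multipliers = prec_multipliers[labs],
    base_tmean = base_tmean, seasonal_amp = seasonal_amp,
    lat_gradient = lat_gradient, lapse_rate = lapse_rate,
    temp_noise_sd = temp_noise_sd, prec_base = prec_base,
    prec_seasonal_amp = prec_seasonal_amp, elev_range = elev_range
  ), class = "climate_sim_config")
}

#' Generate one climate grid per scenario
#'
#' The recent scenario is built from smooth random fields: temperature is a
#' sinusoidal annual cycle (July warmest) over a northward-cooling,
#' elevation-lapsed mean surface plus shared and month-specific
#' autocorrelated noise; precipitation is a winter-wet log-normal surface.
#' Every other scenario differs from recent only by its configured constant
#' temperature offset and precipitation multiplier, so the geography is held
#' fixed across scenarios. Pure function of (config, seed).
#'
#' @param config a [climate_sim_config()].
#' @param seed integer seed.
#' @return named list of six [climate_grid()] objects.
#' @export
generate_climate_grids <- function(config = climate_sim_config(), seed = 1) {
  stopifnot(inherits(config, "climate_sim_config"))
  with_seed(seed, {
    nr <- config$n_rows; nc <- config$n_cols
    acl_cells <- config$autocorr_length / config$cell_size
    # elevation: west-east ramp + smooth relief, floored at 0
    relief <- smooth_gaussian_field(nr, nc, acl_cells)
    ramp <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    elev <- config$elev_range[1] +
      (config$elev_range[2] - config$elev_range[1]) * (0.7 * ramp + 0.3 * (relief - min(relief)) / diff(range(relief)))
    elev <- pmax(elev, 0)

    ycoord <- matrix(rep(config$origin[2] + (seq_len(nr) - 0.5) * config$cell_size, nc), nr, nc)
    shared_t <- smooth_gaussian_field(nr, nc, acl_cells)
    shared_p <- smooth_gaussian_field(nr, nc, acl_cells)

    layers <- vector("list", 24)
    names(layers) <- climate_variable_names()
    for (m in 1:12) {
      month_t <- smooth_gaussian_field(nr, nc, acl_cells)
      month_p <- smooth_gaussian_field(nr, nc, acl_cells)
      seas <- config$seasonal_amp * cos(2 * pi * (m - 7) / 12)
      layers[[sprintf("tmean_%02d", m)]] <-
        config$base_tmean + seas -
        config$lat_gradient * (ycoord - config$origin[2]) -
        config$lapse_rate * elev +
        config$temp_noise_sd * (0.7 * shared_t + 0.3 * month_t)
      pseas <- 1 + config$prec_seasonal_amp * cos(2 * pi * (m - 1) / 12)
      layers[[sprintf("prec_%02d", m)]] <-
        config$prec_base * pseas * exp(0.35 * shared_p + 0.15 * month_p)
    }

    out <- lapply(scenario_labels(), function(sc) {
      sl <- layers
      off <- config$temp_offsets[[sc]]
      mult <- config$prec_multipliers[[sc]]
      for (m in 1:12) {
        sl[[sprintf("tmean_%02d", m)]] <- sl[[sprintf("tmean_%02d", m)]] + off
        sl[[sprintf("prec_%02d", m)]] <- sl[[sprintf("prec_%02d", m)]] * mult
      }
      climate_grid(sc, sl, elev, config$cell_size, config$origin)
    })
    names(out) <- scenario_labels()
    out
  })
}
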