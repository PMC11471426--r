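# Fixtures built in code: toy grids, mock model fits, and small occurrence
# tables used across the test files.

# climate_grid with constant layers, overridable per variable
uniform_grid <- function(n_rows = 10, n_cols = 10, scenario = "recent",
                         tmean = 15, prec = 50, elevation = 100,
                         overrides = list(), cell_size = 1, origin = c(0, 0)) {
  layers <- list()
  for (m in sprintf("tmean_%02d", 1:12)) layers[[m]] <- matrix(tmean, n_rows, n_cols)
  for (m in sprintf("prec_%02d", 1:12)) layers[[m]] <- matrix(prec, n_rows, n_cols)
  for (nm in names(overrides)) layers[[nm]] <- overrides[[nm]]
  climate_grid(scenario, layers, matrix(elevation, n_rows, n_cols),
               cell_size = cell_size, origin = origin)
}

# single_model_fit whose prediction is a fixed constant, with a preset TSS
mock_fit <- function(tss, value, technique = "mock") {
  m <- structure(list(v = value), class = "nichecast_mock")
  attr(m, "nichecast_predict") <- function(model, newx) rep(model$v, nrow(newx))
  structure(list(technique = technique, model = m,
                 eval = list(tss = tss, sensitivity = NA_real_,
                             specificity = NA_real_, threshold = 0.5,
                             degenerate = FALSE)),
            class = "single_model_fit")
}

# occurrence table from vectors, with defaults
occ_table <- function(species, x, y, year = 2000, source = "museum") {
  data.frame(species = species, x = x, y = y, year = year, source = source,
             stringsAsFactors = FALSE)
}

# binary map from a 0/1 matrix literal
mask_map <- function(m, species = "sp", scenario = "recent", cell_size = 1,
                     origin = c(0, 0)) {
  binary_niche_map(m > 0, scenario_id = scenario, species_id = species,
                   cell_size = cell_size, origin = origin)
}

# safe sampler (length-1 x is not expanded)
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# random logical matrix
rand_mask <- function(n_rows, n_cols, p = 0.4) {
  matrix(stats::runif(n_rows * n_cols) < p, n_rows, n_cols)
}

# shared mid-size synthetic world for the heavier integration tests
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grids <- generate_climate_grids(
        climate_sim_config(n_rows = 80, n_cols = 80), seed = 42)
      jur <- generate_jurisdictions(grids$recent, n = 6, seed = 7)
      sp <- calibrate_virtual_species(grids$recent, prevalence_target = 0.2,
                                      species_id = "shared_vs", seed = 3)
      cache <<- list(grids = grids, jur = jur, species = sp)
    }
    cache
  }
})
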