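# End-to-end orchestration: configuration, the qc -> fit -> project ->
# change -> jurisdiction sequence, run manifests, and the range-change
# summary table export.

#' Model-run accounting for a study design
#'
#' Each species gets `techniques * pa_replicates * split_repeats` single
#' models plus one ensemble. With the full design (8 techniques, 2
#' pseudo-absence replicates, 2 splits) that is 33 runs per species.
#'
#' @param n_species number of modeled species.
#' @param techniques number of techniques.
#' @param pa_replicates pseudo-absence replicates.
#' @param split_repeats evaluation splits per replicate.
#' @return list: single_models_per_species, runs_per_species, total_runs.
#' @export
plan_model_runs <- function(n_species, techniques = 8, pa_replicates = 2,
                            split_repeats = 2) {
  single <- techniques * pa_replicates * split_repeats
  list(single_models_per_species = single,
       runs_per_species = single + 1,
       total_runs = n_species * (single + 1))
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' QC year window 1981-2018, 200 km range-distance filter, 300 m centroid
#' filter, > 50 records to model; two pseudo-absence replicates and two
#' 70/30 splits; TSS > 0.7 ensemble cutoff; SRE tail quantile 0.025;
#' +/- 10% net-change dead band, 50% turnover cut, 100 km centroid
#' threshold; > 50 pixels for state presence. All values land in the run
#' manifest.
#'
#' @param n_species virtual species to simulate (demo mode).
#' @param sim synthetic-climate configuration, a [climate_sim_config()].
#' @param n_occurrences records sampled per species.
#' @param artifact_rates defect rates passed to [sample_occurrences()].
#' @param n_jurisdictions jurisdictions tiling the grid.
#' @param techniques modeling technique ids.
#' @param n_pa pseudo-absences per replicate.
#' @param pa_replicates,split_repeats,holdout evaluation design.
#' @param tss_cutoff,sre_q,min_members ensemble settings.
#' @param year_window,max_range_km,centroid_m,min_points QC settings.
#' @param net_thresh,turnover_thresh,centroid_thresh_km classification.
#' @param state_min_pixels jurisdiction presence threshold.
#' @param scenario_to future scenario compared against recent.
#' @param seed master seed; stage seeds derive from it.
#' @return a `nichecast_config` list.
#' @export
nichecast_config <- function(n_species = 3,
                             sim = climate_sim_config(),
                             n_occurrences = 300,
                             artifact_rates = c(duplicate = 0.05,
                                                missing_year = 0.05,
                                                centroid_snap = 0.05,
                                                far_outlier = 0.02),
                             n_jurisdictions = 9,
                             techniques = c("glm", "rf", "sre"),
                             n_pa = 2000, pa_replicates = 2,
                             split_repeats = 2, holdout = 0.30,
                             tss_cutoff = 0.7, sre_q = 0.025, min_members = 3,
                             year_window = c(1981, 2018), max_range_km = 200,
                             centroid_m = 300, min_points = 50,
                             net_thresh = 10, turnover_thresh = 50,
                             centroid_thresh_km = 100, state_min_pixels = 50,
                             scenario_to = "late85", seed = 1) {
  structure(as.list(environment()), class = "nichecast_config")
}

#' Run the full demo pipeline on synthetic data
#'
#' Stages, in order: simulate (climate grids, jurisdictions, virtual species,
#' occurrence records with defects), qc, fit (ensemble per modelable
#' species), project (all six scenarios, one fixed threshold per species),
#' change (recent vs `scenario_to` accounting, classification, centroid
#' shifts), jurisdiction (presence, turnover, elevation shifts), richness.
#' Deterministic for a fixed config.
#'
#' @param config a [nichecast_config()].
#' @return list with the per-stage outputs and a `manifest` recording seeds,
#'   thresholds and record counts.
#' @export
run_pipeline <- function(config = nichecast_config()) {
  stopifnot(inherits(config, "nichecast_config"))
  seed <- config$seed

  grids <- generate_climate_grids(config$sim, seed = seed)
  jur <- generate_jurisdictions(grids$recent, n = config$n_jurisdictions,
                                seed = seed + 1L)
  species <- lapply(seq_len(config$n_species), function(i) {
    calibrate_virtual_species(grids$recent,
                              prevalence_target = 0.15 + 0.05 * (i %% 3),
                              species_id = sprintf("virtual_sp_%02d", i),
                              seed = seed + 10L + i)
  })
  occ <- do.call(rbind, lapply(seq_along(species), function(i) {
    sample_occurrences(species[[i]], grids$recent, n = config$n_occurrences,
                       artifact_rates = config$artifact_rates,
                       jurisdictions = jur, seed = seed + 100L + i)
  }))
  range_polygons <- stats::setNames(lapply(species, function(sp) {
    cc <- cell_centers(grids$recent, which(true_suitable_mask(sp, grids$recent)))
    convex_hull(cc$x, cc$y)
  }), vapply(species, `[[`, "", "species_id"))

  qc <- qc_pipeline(occ[, c("species", "x", "y", "year", "source")],
                    grids$recent, jurisdictions = jur,
                    range_polygons = range_polygons,
                    year_window = config$year_window,
                    max_range_km = config$max_range_km,
                    centroid_m = config$centroid_m,
                    min_points = config$min_points)

  ensembles <- list(); binary <- list(); summaries <- list()
  non_ensembleable <- character()
  for (sp in qc$modelable) {
    cells <- qc$table$cell[qc$table$species == sp]
    ens <- tryCatch(
      fit_ensemble_sdm(cells, grids$recent, techniques = config$techniques,
                       n_pa = config$n_pa, pa_replicates = config$pa_replicates,
                       split_repeats = config$split_repeats,
                       holdout = config$holdout, tss_cutoff = config$tss_cutoff,
                       sre_q = config$sre_q, min_members = config$min_members,
                       seed = seed + 1000L + match(sp, qc$modelable)),
      nichecast_non_ensembleable = function(e) NULL)
    if (is.null(ens)) {
      non_ensembleable <- c(non_ensembleable, sp)
      next
    }
    ensembles[[sp]] <- ens
    thr <- min(max(ens$eval$threshold, 1e-6), 1 - 1e-6)
    binary[[sp]] <- lapply(grids, function(g)
      binarize(project_ensemble(ens, g), thr, species_id = sp))
    summ <- compare_ranges(binary[[sp]]$recent, binary[[sp]][[config$scenario_to]])
    summaries[[sp]] <- classify_change(summ, net_thresh = config$net_thresh,
                                       turnover_thresh = config$turnover_thresh,
                                       centroid_thresh_km = config$centroid_thresh_km)
  }

  fitted <- names(ensembles)
  recent_maps <- lapply(fitted, function(sp) binary[[sp]]$recent)
  future_maps <- lapply(fitted, function(sp) binary[[sp]][[config$scenario_to]])
  richness <- list(
    recent = richness_stack(recent_maps, config$sim$n_rows, config$sim$n_cols),
    future = richness_stack(future_maps, config$sim$n_rows, config$sim$n_cols),
    change_full = if (length(fitted)) richness_change(recent_maps, future_maps, "full"),
    change_none = if (length(fitted)) richness_change(recent_maps, future_maps, "none")
  )
  turnover <- if (length(fitted)) {
    state_turnover(recent_maps, future_maps, jur,
                   min_pixels = config$state_min_pixels)
  }

  manifest <- list(
    seed = seed,
    thresholds = config[c("year_window", "max_range_km", "centroid_m",
                          "min_points", "tss_cutoff", "sre_q", "holdout",
                          "net_thresh", "turnover_thresh",
                          "centroid_thresh_km", "state_min_pixels")],
    design = list(techniques = config$techniques, n_pa = config$n_pa,
                  pa_replicates = config$pa_replicates,
                  split_repeats = config$split_repeats),
    counts = list(
      occurrences_raw = nrow(occ), occurrences_retained = nrow(qc$table),
      species_simulated = config$n_species,
      species_modelable = length(qc$modelable),
      species_fitted = length(fitted),
      non_ensembleable = non_ensembleable),
    model_runs = plan_model_runs(length(fitted),
                                 techniques = length(config$techniques),
                                 pa_replicates = config$pa_replicates,
                                 split_repeats = config$split_repeats)
  )
  list(grids = grids, jurisdictions = jur, species = species,
       occurrences = occ, qc = qc, ensembles = ensembles, binary = binary,
       summaries = summaries, richness = richness, turnover = turnover,
       manifest = manifest)
}

#' Export range-change summaries as the published-table layout
#'
#' One row per species with columns in the fixed order species, current,
#' future, loss, gain, maintain, percent_lost, percent_gained, range_change;
#' percentages rounded to 2 decimals here (and only here); rows sorted by
#' range change ascending, so the strongest contractions come first.
#'
#' @param summaries list of `range_change_summary` objects.
#' @param path optional file; when given the table is also written as CSV.
#' @return the data.frame, invisibly when `path` is given.
#' @export
export_table1 <- function(summaries, path = NULL) {
  df <- if (!length(summaries)) {
    data.frame(species = character(), current = integer(), future = integer(),
               loss = integer(), gain = integer(), maintain = integer(),
               percent_lost = numeric(), percent_gained = numeric(),
               range_change = numeric())
  } else {
    rows <- lapply(summaries, function(s) data.frame(
      species = s$species_id, current = s$current_size, future = s$future_size,
      loss = s$loss, gain = s$gain, maintain = s$maintain,
      percent_lost = round(s$percent_lost, 2),
      percent_gained = round(s$percent_gained, 2),
      range_change = round(s$range_change, 2)))
    out <- do.call(rbind, rows)
    out <- out[order(out$range_change), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Published range-change pixel counts for the 21 contracting species
#'
#' The pixel accounting table shipped with the package (plain-text CSV in
#' `inst/extdata`): per species, the current and future range sizes, the
#' loss/gain/maintain pixel counts, and the printed percent-lost,
#' percent-gained and range-change values for the recent vs late-century
#' high-emission comparison.
#'
#' @return data.frame with one row per species.
#' @export
published_range_change_table <- function() {
  path <- system.file("extdata", "table1_range_change.csv",
                      package = "nichecast", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
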