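# Virtual-species validation experiments: niche recovery on synthetic grids
# and directional (northward/upslope) recovery under warming. These drive
# the package's own end-to-end checks and are reusable at other scales.

#' Niche-recovery experiment on a synthetic landscape
#'
#' For each seed: generate climate grids, calibrate a virtual species
#' (prevalence drawn in `prevalence_range`), sample clean presences, fit the
#' ensemble, and score (a) the ensemble's pooled held-out TSS and (b) the
#' Jaccard overlap between the recovered binary map and the species'
#' true-suitable region on the recent scenario.
#'
#' @param seeds integer vector, one experiment per seed.
#' @param n_rows,n_cols grid size (default 200 x 200).
#' @param n_presences clean occurrence records per species.
#' @param n_pa pseudo-absences per replicate.
#' @param techniques technique ids.
#' @param prevalence_range range the species' prevalence target is drawn from.
#' @return data.frame: seed, prevalence, ensemble_tss, jaccard.
#' @export
recovery_experiment <- function(seeds = 1:5, n_rows = 200, n_cols = 200,
                                n_presences = 500, n_pa = 2000,
                                techniques = c("glm", "rf", "sre"),
                                prevalence_range = c(0.1, 0.3)) {
  rows <- lapply(seeds, function(s) {
    grids <- generate_climate_grids(
      climate_sim_config(n_rows = n_rows, n_cols = n_cols), seed = s)
    prev <- with_seed(s, stats::runif(1, prevalence_range[1], prevalence_range[2]))
    sp <- calibrate_virtual_species(grids$recent, prevalence_target = prev,
                                    species_id = sprintf("vs_%03d", s),
                                    seed = s + 500L)
    occ <- sample_occurrences(sp, grids$recent, n = n_presences, seed = s + 900L)
    cells <- unique(occ$cell)
    ens <- fit_ensemble_sdm(cells, grids$recent, techniques = techniques,
                            n_pa = n_pa, seed = s + 1300L)
    thr <- min(max(ens$eval$threshold, 1e-6), 1 - 1e-6)
    rec <- binarize(project_ensemble(ens, grids$recent), thr, sp$species_id)
    truth <- true_suitable_mask(sp, grids$recent)
    data.frame(seed = s, prevalence = prev, ensemble_tss = ens$eval$tss,
               jaccard = sum(rec$mask & truth) / sum(rec$mask | truth))
  })
  do.call(rbind, rows)
}

#' Directional-recovery experiment: a cold-limited species under warming
#'
#' For each seed, a virtual species with its thermal optimum in the cooler
#' part of the landscape is fitted on the recent scenario and projected to
#' the late-century high-emission scenario (+3 degrees C by default). The
#' experiment records whether the recovered niche's centroid moved toward
#' colder (more northerly) cells and whether the elevation distribution of
#' suitable cells shifted significantly upward on the sloped synthetic DEM.
#'
#' The elevation shift is judged within state boundaries, where the
#' interquartile test has resolution: among jurisdictions where the species
#' is present (more than `min_pixels` suitable cells) in both scenarios, the
#' seed's `elevation_class` is `"increase"` when at least one state shifts
#' significantly upward and none shifts downward, `"decrease"` for the
#' converse, and `"similar"` otherwise.
#'
#' @param seeds integer vector.
#' @param n_rows,n_cols grid size (default 100 x 100).
#' @param n_presences,n_pa,techniques as in [recovery_experiment()].
#' @param scenario_to future scenario (default `"late85"`).
#' @param n_jurisdictions states tiling the grid.
#' @param min_pixels within-state presence floor for a comparison to count.
#' @return data.frame: seed, shift_km, bearing_deg, northward (dy > 0),
#'   states_increase, states_decrease, states_compared, elevation_class,
#'   median_elevation_change_m (median over compared states).
#' @export
directional_experiment <- function(seeds = 1:10, n_rows = 100, n_cols = 100,
                                   n_presences = 300, n_pa = 1000,
                                   techniques = c("glm", "rf", "sre", "gam"),
                                   scenario_to = "late85",
                                   n_jurisdictions = 16, min_pixels = 50) {
  rows <- lapply(seeds, function(s) {
    grids <- generate_climate_grids(
      climate_sim_config(n_rows = n_rows, n_cols = n_cols), seed = s)
    sp <- calibrate_virtual_species(grids$recent,
                                    variables = c("tmean_07", "tmean_01"),
                                    prevalence_target = 0.2,
                                    optimum_quantiles = 0.3,
                                    species_id = sprintf("cold_vs_%03d", s),
                                    seed = s + 500L)
    occ <- sample_occurrences(sp, grids$recent, n = n_presences, seed = s + 900L)
    ens <- fit_ensemble_sdm(unique(occ$cell), grids$recent,
                            techniques = techniques, n_pa = n_pa,
                            seed = s + 1300L)
    thr <- min(max(ens$eval$threshold, 1e-6), 1 - 1e-6)
    rec <- binarize(project_ensemble(ens, grids$recent), thr, sp$species_id)
    fut <- binarize(project_ensemble(ens, grids[[scenario_to]]), thr, sp$species_id)
    jur <- generate_jurisdictions(grids$recent, n = n_jurisdictions, seed = s)
    pres_r <- state_presence(rec, jur, min_pixels)
    pres_f <- state_presence(fut, jur, min_pixels)
    comparable <- jur$ids[pres_r$present & pres_f$present]
    shifts <- lapply(comparable, function(j)
      elevation_shift(rec, fut, jur, j, grids$recent$elevation))
    classes <- vapply(shifts, `[[`, "", "class")
    n_up <- sum(classes == "increase"); n_dn <- sum(classes == "decrease")
    cls <- if (n_up > 0 && n_dn == 0) "increase" else
           if (n_dn > 0 && n_up == 0) "decrease" else "similar"
    med <- if (length(shifts)) {
      stats::median(vapply(shifts, `[[`, numeric(1), "median_change_m"))
    } else NA_real_
    shift <- centroid_shift(rec, fut)
    dy <- niche_centroid(fut)[["y"]] - niche_centroid(rec)[["y"]]
    data.frame(seed = s, shift_km = shift$shift_km,
               bearing_deg = shift$bearing_deg, northward = dy > 0,
               states_increase = n_up, states_decrease = n_dn,
               states_compared = length(comparable), elevation_class = cls,
               median_elevation_change_m = med)
  })
  do.call(rbind, rows)
}
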