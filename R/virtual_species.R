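# Virtual species: known bell-shaped climate responses used as ground truth
# for niche-recovery experiments.

#' Define a virtual species
#'
#' A virtual species responds to a handful of named climate variables with
#' Gaussian (bell-shaped) curves; per-variable responses combine by product,
#' so suitability is 1 exactly where every variable sits at its optimum and
#' decays monotonically away from each optimum.
#'
#' @param species_id character name.
#' @param response named list; each element is `c(optimum =, breadth =)` for
#'   one climate variable. Breadths must be strictly positive.
#' @param prevalence_target intended fraction of recent-scenario cells in the
#'   true-suitable region (suitability >= 0.5), in (0, 1). Informational
#'   unless set by [calibrate_virtual_species()].
#' @param seed integer carried for provenance.
#' @return a `virtual_species` object.
#' @export
virtual_species <- function(species_id, response, prevalence_target = NA_real_,
                            seed = NA_integer_) {
  stopifnot(length(response) >= 1, !is.null(names(response)))
  for (v in names(response)) {
    r <- response[[v]]
    if (!all(c("optimum", "breadth") %in% names(r)) || r[["breadth"]] <= 0) {
      stop("response for ", v, " needs a finite optimum and strictly positive breadth")
    }
  }
  if (!is.na(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1)) {
    stop("prevalence_target must lie in (0, 1)")
  }
  structure(list(species_id = species_id, response = response,
                 interaction_rule = "product",
                 prevalence_target = prevalence_target, seed = seed),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("<virtual_species>", x$species_id, "| responds to:",
      paste(names(x$response), collapse = ", "), "\n")
  invisible(x)
}

#' True suitability surface of a virtual species
#'
#' @param species a [virtual_species()].
#' @param grid a [climate_grid()] containing every response variable.
#' @return matrix in \[0, 1\] with the grid's dimensions.
#' @export
true_suitability <- function(species, grid) {
  missing <- setdiff(names(species$response), names(grid$layers))
  if (length(missing)) {
    stop("response variable(s) not present in grid: ",
         paste(missing, collapse = ", "))
  }
  suit <- matrix(1, grid$n_rows, grid$n_cols)
  for (v in names(species$response)) {
    r <- species$response[[v]]
    suit <- suit * exp(-0.5 * ((grid$layers[[v]] - r[["optimum"]]) / r[["breadth"]])^2)
  }
  suit
}

#' True-suitable region of a virtual species
#'
#' Cells whose true suitability is at least `threshold` (default 0.5); this
#' is the ground-truth binary niche used by recovery experiments.
#'
#' @inheritParams true_suitability
#' @param threshold suitability cutoff.
#' @return logical matrix.
#' @export
true_suitable_mask <- function(species, grid, threshold = 0.5) {
  true_suitability(species, grid) >= threshold
}

#' Calibrate a virtual species to a target prevalence
#'
#' Places each response optimum at a chosen quantile of the recent-scenario
#' distribution of its variable, then scales a common breadth factor by
#' bisection until the fraction of cells in the true-suitable region
#' (suitability >= 0.5) matches `prevalence_target`.
#'
#' @param grid the recent-scenario [climate_grid()].
#' @param variables climate variables the niche uses (2-3 is typical).
#' @param prevalence_target fraction of suitable cells, in (0, 1).
#' @param optimum_quantiles quantile of each variable's distribution at which
#'   to place the optimum (recycled). 0.35 puts the species in the cooler,
#'   cold-limited part of the landscape with room to track warming northward.
#' @param species_id name.
#' @param seed integer; perturbs the optimum quantiles slightly so replicate
#'   species differ.
#' @return a calibrated `virtual_species`.
#' @export
calibrate_virtual_species <- function(grid, variables = c("tmean_07", "prec_06"),
                                      prevalence_target = 0.2,
                                      optimum_quantiles = 0.35,
                                      species_id = "virtual_sp", seed = 1) {
  stopifnot(prevalence_target > 0, prevalence_target < 1)
  optimum_quantiles <- rep_len(optimum_quantiles, length(variables))
  with_seed(seed, {
    q <- pmin(0.95, pmax(0.05, optimum_quantiles + stats::runif(length(variables), -0.05, 0.05)))
    response <- list()
    for (i in seq_along(variables)) {
      v <- variables[i]
      vals <- grid$layers[[v]]
      if (is.null(vals)) stop("variable not in grid: ", v)
      response[[v]] <- c(optimum = unname(stats::quantile(vals, q[i])),
                         breadth = stats::sd(vals))
    }
    base <- virtual_species(species_id, response, prevalence_target, seed)
    prev_at <- function(scale) {
      sp <- base
      for (v in names(sp$response)) sp$response[[v]][["breadth"]] <-
          response[[v]][["breadth"]] * scale
      mean(true_suitable_mask(sp, grid))
    }
    lo <- 1e-3; hi <- 50
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (prev_at(mid) < prevalence_target) lo <- mid else hi <- mid
    }
    scale <- sqrt(lo * hi)
    for (v in names(base$response)) base$response[[v]][["breadth"]] <-
        response[[v]][["breadth"]] * scale
    base
  })
}
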