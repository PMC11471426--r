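# TSS-weighted ensembles of single models, plus permutation variable
# importance and the per-species fitting driver.

#' Build a TSS-weighted ensemble from evaluated single models
#'
#' Members are the single models with evaluation TSS strictly above `cutoff`
#' (default 0.7). Member weights are proportional to their TSS and sum to 1;
#' the ensemble prediction is the weighted mean of member suitabilities
#' (envelope members contribute their 0/1 scores).
#'
#' @param fits list of evaluated `single_model_fit` objects.
#' @param cutoff TSS inclusion cutoff.
#' @param min_members minimum members required (default 3); fewer raises a
#'   `nichecast_non_ensembleable` error so callers can flag the species.
#' @return an `ensemble_niche_model` with members, weights and member TSS.
#' @export
build_ensemble <- function(fits, cutoff = 0.7, min_members = 3) {
  evaluated <- Filter(function(f) !is.null(f$eval), fits)
  tss <- vapply(evaluated, function(f) f$eval$tss, numeric(1))
  keep <- tss > cutoff
  if (sum(keep) < min_members) {
    stop(structure(class = c("nichecast_non_ensembleable", "error", "condition"),
                   list(message = sprintf(
                     "only %d of %d single models exceed TSS %g (need >= %d)",
                     sum(keep), length(evaluated), cutoff, min_members),
                     call = sys.call())))
  }
  members <- evaluated[keep]
  w <- tss[keep] / sum(tss[keep])
  structure(list(members = members, weights = w, member_tss = tss[keep],
                 cutoff = cutoff, eval = NULL, variable_importance = NULL),
            class = "ensemble_niche_model")
}

#' @export
print.ensemble_niche_model <- function(x, ...) {
  cat("<ensemble_niche_model>", length(x$members), "members (TSS >",
      x$cutoff, "), techniques:",
      paste(unique(vapply(x$members, `[[`, "", "technique")), collapse = ", "), "\n")
  if (!is.null(x$eval)) {
    cat(sprintf("  ensemble TSS %.3f (sens %.3f, spec %.3f, threshold %.3f)\n",
                x$eval$tss, x$eval$sensitivity, x$eval$specificity,
                x$eval$threshold))
  }
  invisible(x)
}

#' Ensemble suitability prediction
#'
#' @param object an `ensemble_niche_model`.
#' @param x numeric predictor matrix.
#' @param ... unused.
#' @return weighted-mean suitability in \[0, 1\].
#' @export
predict.ensemble_niche_model <- function(object, x, ...) {
  p <- numeric(nrow(x))
  for (i in seq_along(object$members)) {
    p <- p + object$weights[i] * predict_suitability(object$members[[i]], x)
  }
  p
}

#' Permutation variable importance
#'
#' For each predictor, its column is permuted `n_perm` times; the score is
#' `1 - cor(original predictions, permuted predictions)` averaged over
#' permutations and clipped to \[0, 1\]. Variables the model ignores score ~0.
#' Constant predictions give all-zero scores.
#'
#' @param model an `ensemble_niche_model` or `single_model_fit`.
#' @param x predictor matrix on which to measure importance.
#' @param n_perm permutations per variable (>= 1).
#' @param seed integer seed.
#' @return named numeric vector, one score per column of `x`.
#' @export
variable_importance <- function(model, x, n_perm = 3, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  pred_fun <- if (inherits(model, "ensemble_niche_model")) {
    function(m, newx) predict(m, newx)
  } else {
    function(m, newx) predict_suitability(m, newx)
  }
  base <- pred_fun(model, x)
  out <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (stats::sd(base) == 0) return(out)
  with_seed(seed, {
    for (v in colnames(x)) {
      s <- 0
      for (k in seq_len(n_perm)) {
        xp <- x
        xp[, v] <- xp[sample.int(nrow(x)), v]
        pp <- pred_fun(model, xp)
        r <- if (stats::sd(pp) == 0) 0 else stats::cor(base, pp)
        s <- s + (1 - r)
      }
      out[v] <- min(1, max(0, s / n_perm))
    }
  })
  out
}

#' Fit the full single-model set and ensemble for one species
#'
#' Drives the per-species workflow: pseudo-absence replicates, repeated
#' 70/30 evaluation splits, one fit per technique per run (so
#' `length(techniques) * pa_replicates * split_repeats` single models),
#' TSS evaluation of each on its held-out split, and a TSS-weighted ensemble
#' of the models above the cutoff. The ensemble itself is evaluated on the
#' pooled held-out data, which also fixes the binarization threshold reused
#' for every scenario projection.
#'
#' @param presence_cells integer presence cell indices on `grid`.
#' @param grid the training-scenario [climate_grid()].
#' @param techniques technique ids (default glm, rf, sre).
#' @param n_pa pseudo-absences per replicate.
#' @param pa_replicates pseudo-absence replicates (default 2).
#' @param split_repeats evaluation splits per replicate (default 2).
#' @param holdout evaluation holdout fraction (default 0.30).
#' @param tss_cutoff ensemble inclusion cutoff (default 0.7).
#' @param sre_q envelope tail quantile (default 0.025).
#' @param min_members minimum members for an ensemble (default 3).
#' @param importance compute permutation variable importance (default TRUE);
#'   skip for bulk experiments that only need the ensemble map.
#' @param seed integer seed.
#' @return an `ensemble_niche_model` with `eval` (pooled held-out TSS,
#'   sensitivity, specificity, threshold), `variable_importance`, an
#'   `eval_table` data.frame over all single models, and the run bookkeeping.
#' @export
fit_ensemble_sdm <- function(presence_cells, grid,
                             techniques = c("glm", "rf", "sre"),
                             n_pa = 2000, pa_replicates = 2, split_repeats = 2,
                             holdout = 0.30, tss_cutoff = 0.7, sre_q = 0.025,
                             min_members = 3, importance = TRUE, seed = 1) {
  presence_cells <- unique(presence_cells)
  pa_sets <- generate_pseudo_absences(grid, presence_cells, n = n_pa,
                                      replicates = pa_replicates, seed = seed)
  runs <- make_eval_splits(presence_cells, pa_sets, holdout = holdout,
                           repeats = split_repeats, seed = seed + 1L)
  climate <- extract_climate(grid)

  fits <- list()
  eval_rows <- list()
  for (run in runs) {
    x_train <- climate[c(run$train_pres, run$train_pa), , drop = FALSE]
    y_train <- rep(c(1, 0), c(length(run$train_pres), length(run$train_pa)))
    x_test <- climate[c(run$test_pres, run$test_pa), , drop = FALSE]
    y_test <- rep(c(1, 0), c(length(run$test_pres), length(run$test_pa)))
    for (tech in techniques) {
      fit <- if (tech == "sre") {
        fit_single_model(tech, x_train, y_train, q = sre_q)
      } else {
        fit_single_model(tech, x_train, y_train)
      }
      fit$pa_replicate <- run$pa_replicate
      fit$split_replicate <- run$split_replicate
      fit <- evaluate_tss(fit, x_test, y_test)
      fits[[length(fits) + 1]] <- fit
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        technique = tech, pa_replicate = run$pa_replicate,
        split_replicate = run$split_replicate, tss = fit$eval$tss,
        sensitivity = fit$eval$sensitivity, specificity = fit$eval$specificity
      )
    }
  }

  ens <- build_ensemble(fits, cutoff = tss_cutoff, min_members = min_members)

  # pooled held-out evaluation fixes the projection threshold
  pooled_x <- do.call(rbind, lapply(runs, function(run)
    climate[c(run$test_pres, run$test_pa), , drop = FALSE]))
  pooled_y <- unlist(lapply(runs, function(run)
    rep(c(1, 0), c(length(run$test_pres), length(run$test_pa)))))
  ens$eval <- tss_stats(predict(ens, pooled_x), pooled_y)

  if (importance) {
    # importance is measured on a capped, seeded subsample of the modeling
    # data; permutation scores stabilize well below the full background size
    vi_cells <- c(presence_cells, pa_sets[[1]]$cells)
    if (length(vi_cells) > 1000) {
      vi_cells <- with_seed(seed + 3L, resample(vi_cells, 1000))
    }
    ens$variable_importance <- variable_importance(
      ens, climate[vi_cells, , drop = FALSE], n_perm = 2, seed = seed + 2L)
  }
  ens$eval_table <- do.call(rbind, eval_rows)
  ens$presence_cells <- presence_cells
  ens$seed <- seed
  ens
}
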