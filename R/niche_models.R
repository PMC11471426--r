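# Single-model fitting: pseudo-absence sampling, repeated evaluation splits,
# a pluggable technique registry (logistic GLM, random forest, bespoke
# surface range envelope, optional GAM), and TSS evaluation.

#' Sample pseudo-absence replicates
#'
#' Background cells drawn uniformly at random without replacement from the
#' grid, excluding presence cells. Replicates use sequential draws from one
#' seeded stream, so they are reproducible and mutually independent.
#'
#' @param grid a [climate_grid()].
#' @param presence_cells integer cell indices of presences.
#' @param n pseudo-absences per replicate.
#' @param replicates number of replicates (default 2).
#' @param seed integer seed.
#' @return list of pseudo-absence sets: `list(replicate_id, cells, n)`.
#' @export
generate_pseudo_absences <- function(grid, presence_cells, n = 50000,
                                     replicates = 2, seed = 1) {
  pool <- setdiff(seq_len(n_cells(grid)), unique(presence_cells))
  if (n > length(pool)) {
    stop("n = ", n, " exceeds the ", length(pool), " available background cells")
  }
  with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      list(replicate_id = r, cells = resample(pool, n), n = n)
    })
  })
}

#' Build repeated train/test evaluation splits
#'
#' For every pseudo-absence replicate, presences and pseudo-absences are each
#' split `repeats` times into 70/30 train/test partitions (default holdout
#' 0.30), yielding `length(pa_sets) * repeats` runs per technique.
#'
#' @param presence_cells integer presence cell indices (>= 10).
#' @param pa_sets list from [generate_pseudo_absences()].
#' @param holdout fraction withheld for evaluation.
#' @param repeats splits per pseudo-absence replicate (default 2).
#' @param seed integer seed.
#' @return list of runs: `list(pa_replicate, split_replicate, train_pres,
#'   test_pres, train_pa, test_pa)` (cell indices).
#' @export
make_eval_splits <- function(presence_cells, pa_sets, holdout = 0.30,
                             repeats = 2, seed = 1) {
  np <- length(presence_cells)
  if (np < 10) stop("too few presences to split (need >= 10, got ", np, ")")
  n_test <- round(np * holdout)
  if (n_test < 1 || n_test >= np) stop("holdout fraction leaves an empty partition")
  with_seed(seed, {
    runs <- list()
    for (pa in pa_sets) {
      n_pa_test <- round(pa$n * holdout)
      for (s in seq_len(repeats)) {
        ti <- resample(seq_len(np), n_test)
        pi <- resample(seq_len(pa$n), n_pa_test)
        runs[[length(runs) + 1]] <- list(
          pa_replicate = pa$replicate_id, split_replicate = s,
          train_pres = presence_cells[-ti], test_pres = presence_cells[ti],
          train_pa = pa$cells[-pi], test_pa = pa$cells[pi]
        )
      }
    }
    runs
  })
}

# --- technique registry ------------------------------------------------------

.technique_registry <- new.env(parent = emptyenv())

#' Register a modeling technique
#'
#' A technique is a fit function `function(x, y, ...)` taking a numeric
#' predictor matrix and a 0/1 response, returning an object for which
#' [predict_suitability()] yields scores in \[0, 1\].
#'
#' @param name technique id.
#' @param fit_fun fitting function.
#' @export
register_technique <- function(name, fit_fun) {
  assign(name, fit_fun, envir = .technique_registry)
  invisible(name)
}

#' List registered techniques
#' @return character vector of technique ids.
#' @export
registered_techniques <- function() sort(ls(.technique_registry))

#' Fit one single-technique model
#'
#' @param technique a registered technique id (see [registered_techniques()]).
#' @param x numeric predictor matrix (named columns).
#' @param y 0/1 response; both classes must be present.
#' @param ... passed to the technique's fit function (e.g. `q` for `sre`).
#' @return a `single_model_fit` with elements technique, model, and (after
#'   [evaluate_tss()]) eval.
#' @export
fit_single_model <- function(technique, x, y, ...) {
  if (!technique %in% registered_techniques()) {
    stop("technique not registered: ", technique)
  }
  if (length(unique(y)) < 2) stop("training data has a single class")
  model <- get(technique, envir = .technique_registry)(x, y, ...)
  structure(list(technique = technique, model = model, eval = NULL),
            class = "single_model_fit")
}

#' Predict suitability scores from a fitted single model
#'
#' @param fit a `single_model_fit`.
#' @param x numeric predictor matrix.
#' @return numeric scores in \[0, 1\].
#' @export
predict_suitability <- function(fit, x) {
  stopifnot(inherits(fit, "single_model_fit"))
  p <- attr(fit$model, "nichecast_predict")(fit$model, x)
  pmin(1, pmax(0, as.numeric(p)))
}

technique_glm <- function(x, y, ...) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  m <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  attr(m, "nichecast_predict") <- function(model, newx) {
    suppressWarnings(stats::predict(model, newdata = as.data.frame(newx),
                                    type = "response"))
  }
  m
}

technique_rf <- function(x, y, num.trees = 300, ...) {
  m <- ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                      num.trees = num.trees, probability = TRUE,
                      seed = 1, num.threads = 1)
  attr(m, "nichecast_predict") <- function(model, newx) {
    stats::predict(model, data = as.data.frame(newx),
                   num.threads = 1)$predictions[, "1"]
  }
  m
}

technique_gam <- function(x, y, max_smooths = 6, ...) {
  if (!requireNamespace("mgcv", quietly = TRUE)) {
    stop("the gam technique needs the mgcv package")
  }
  # smooth the predictors most correlated with the response; the rest enter
  # linearly would add little at background prevalence, so they are dropped
  cors <- abs(suppressWarnings(stats::cor(x, y)))
  cors[is.na(cors)] <- 0
  vars <- colnames(x)[order(-cors)][seq_len(min(max_smooths, ncol(x)))]
  fml <- stats::as.formula(paste(".y ~",
    paste(sprintf("s(`%s`, k = 4)", vars), collapse = " + ")))
  df <- data.frame(.y = y, x, check.names = FALSE)
  m <- mgcv::gam(fml, data = df, family = stats::binomial(), method = "REML")
  attr(m, "nichecast_predict") <- function(model, newx) {
    as.numeric(mgcv::predict.gam(model, newdata = as.data.frame(newx),
                                 type = "response"))
  }
  m
}

#' Fit a surface range envelope
#'
#' The SRE is a rectilinear climate envelope: for each predictor it keeps the
#' `[q, 1 - q]` quantile interval of the training presences; a cell scores 1
#' iff every predictor falls inside its interval, else 0.
#'
#' @param x_pres predictor matrix of training presences (>= 2 rows).
#' @param q tail quantile trimmed from each end, in \[0, 0.5).
#' @return an `sre_envelope` with per-variable lower/upper bounds.
#' @export
fit_sre <- function(x_pres, q = 0.025) {
  if (q < 0 || q >= 0.5) stop("q must lie in [0, 0.5)")
  if (nrow(x_pres) < 2) stop("SRE needs at least 2 presences")
  lo <- apply(x_pres, 2, stats::quantile, probs = q)
  hi <- apply(x_pres, 2, stats::quantile, probs = 1 - q)
  structure(list(lower = lo, upper = hi, q = q), class = "sre_envelope")
}

#' Predict from a surface range envelope
#' @param object an `sre_envelope`.
#' @param x predictor matrix.
#' @param ... unused.
#' @return 0/1 scores.
#' @export
predict.sre_envelope <- function(object, x, ...) {
  inside <- rep(TRUE, nrow(x))
  for (v in names(object$lower)) {
    inside <- inside & x[, v] >= object$lower[[v]] & x[, v] <= object$upper[[v]]
  }
  as.numeric(inside)
}

technique_sre <- function(x, y, q = 0.025, ...) {
  m <- fit_sre(x[y == 1, , drop = FALSE], q = q)
  attr(m, "nichecast_predict") <- function(model, newx) predict(model, newx)
  m
}

register_technique("glm", technique_glm)
register_technique("rf", technique_rf)
register_technique("gam", technique_gam)
register_technique("sre", technique_sre)

# --- evaluation --------------------------------------------------------------

#' True-skill-statistic evaluation of scores
#'
#' Sweeps candidate thresholds (the sorted unique scores) and keeps the one
#' maximizing sensitivity + specificity, with a cell scored present when its
#' score is >= the threshold. Ties break toward the smaller threshold. TSS =
#' sensitivity + specificity - 1. Degenerate score vectors (all equal) give
#' TSS 0 with `degenerate = TRUE`.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 observed classes (both present).
#' @return list: tss, sensitivity, specificity, threshold, degenerate.
#' @export
tss_stats <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("evaluation data has a single class")
  if (length(unique(scores)) < 2) {
    warning("degenerate predictions: all scores identical")
    return(list(tss = 0, sensitivity = NA_real_, specificity = NA_real_,
                threshold = scores[1], degenerate = TRUE))
  }
  thr <- sort(unique(scores))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best <- NULL
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / npos
    spec <- sum(!pred & labels == 0) / nneg
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity + 1e-12) {
      best <- list(tss = sens + spec - 1, sensitivity = sens,
                   specificity = spec, threshold = t, degenerate = FALSE)
    }
  }
  best
}

#' Evaluate a fitted single model on held-out data
#'
#' @param fit a `single_model_fit`.
#' @param x_test,y_test held-out predictors and 0/1 labels.
#' @return the fit, with its `eval` slot filled (tss, sensitivity,
#'   specificity, threshold).
#' @export
evaluate_tss <- function(fit, x_test, y_test) {
  scores <- predict_suitability(fit, x_test)
  fit$eval <- tss_stats(scores, y_test)
  fit
}
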