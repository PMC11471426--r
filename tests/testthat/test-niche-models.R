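# Pseudo-absences, evaluation splits, the technique registry, TSS scoring,
# ensembles and permutation importance.

test_that("pseudo-absence replicates exclude presences and differ in membership", {
  g <- uniform_grid(100, 100)
  pres <- 1:50
  pa <- generate_pseudo_absences(g, pres, n = 500, replicates = 2, seed = 4)
  expect_length(pa, 2)
  for (set in pa) {
    expect_length(set$cells, 500)
    expect_false(any(set$cells %in% pres))
    expect_false(anyDuplicated(set$cells) > 0)
  }
  expect_false(identical(sort(pa[[1]]$cells), sort(pa[[2]]$cells)))
  expect_error(generate_pseudo_absences(g, pres, n = 9951), "exceeds")
  expect_identical(generate_pseudo_absences(g, pres, n = 500, seed = 4), pa)
})

test_that("pseudo-absence sampling is uniform over background cells", {
  g <- uniform_grid(10, 10)
  pres <- 1:20
  freq <- integer(100)
  for (r in 1:500) {
    pa <- generate_pseudo_absences(g, pres, n = 20, replicates = 1, seed = r)
    freq[pa[[1]]$cells] <- freq[pa[[1]]$cells] + 1L
  }
  expect_true(all(freq[pres] == 0))
  p <- 20 / 80
  expect_true(all(abs(freq[-(1:20)] - 500 * p) < 6 * sqrt(500 * p * (1 - p))))
})

test_that("evaluation splits withhold 30% and produce four runs per technique", {
  g <- uniform_grid(50, 50)
  pres <- 101:200
  pa <- generate_pseudo_absences(g, pres, n = 400, replicates = 2, seed = 1)
  runs <- make_eval_splits(pres, pa, seed = 2)
  expect_length(runs, 4)  # 2 PA replicates x 2 splits
  for (run in runs) {
    expect_length(run$test_pres, 30)
    expect_length(run$train_pres, 70)
    expect_length(run$test_pa, 120)
    expect_setequal(c(run$train_pres, run$test_pres), pres)
  }
  expect_error(make_eval_splits(1:9, pa), "too few presences")
  # full design: 8 techniques x 4 runs = 32 single models, 33 with ensemble
  plan <- plan_model_runs(1, techniques = 8)
  expect_equal(plan$single_models_per_species, 32)
  expect_equal(plan$runs_per_species, 33)
})

test_that("surface range envelope reproduces hand-computed quantile boxes", {
  x <- cbind(v1 = c(1, 2, 3, 4, 5), v2 = c(5, 4, 3, 2, 1))
  env <- fit_sre(x, q = 0.2)
  # independent quantile oracle: linear interpolation on sorted values
  qhand <- function(v, p) { v <- sort(v); h <- (length(v) - 1) * p + 1
    v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)]) }
  expect_equal(unname(env$lower), c(qhand(1:5, .2), qhand(1:5, .2)))
  expect_equal(unname(env$upper), c(qhand(1:5, .8), qhand(1:5, .8)))
  expect_equal(predict(env, cbind(v1 = 3, v2 = 5)), 0)  # one variable outside
  expect_equal(predict(env, cbind(v1 = 3, v2 = 3)), 1)
  # q = 0 keeps the min-max box, so every training presence scores 1
  expect_equal(predict(fit_sre(x, q = 0), x), rep(1, 5))
  expect_error(fit_sre(x[1, , drop = FALSE]), "at least 2")
  expect_error(fit_sre(x, q = 0.5), "q must lie")
})

test_that("single-model fitting validates inputs and nails separable data", {
  x <- cbind(a = c(rnorm(50, 0), rnorm(50, 6)), b = rnorm(100))
  y <- rep(c(0, 1), each = 50)
  expect_error(fit_single_model("nope", x, y), "not registered")
  expect_error(fit_single_model("glm", x, rep(1, 100)), "single class")
  rf <- evaluate_tss(fit_single_model("rf", x, y), x, y)
  expect_equal(rf$eval$tss, 1.0)  # training TSS on separable toy
  sre <- evaluate_tss(fit_single_model("sre", x, y, q = 0), x, y)
  expect_equal(sre$eval$sensitivity, 1.0)
})

test_that("TSS is near zero under a permutation null", {
  set.seed(99)
  x_test <- matrix(rnorm(400 * 4), 400, 4, dimnames = list(NULL, letters[1:4]))
  y_test <- rep(c(0, 1), each = 200)
  tss <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, letters[1:4]))
    y <- sample(rep(c(0, 1), each = 50))  # labels shuffled: no signal
    fit <- evaluate_tss(fit_single_model("glm", x, y), x_test, y_test)
    fit$eval$tss
  }, numeric(1))
  expect_lt(mean(abs(tss)), 0.15)
})

test_that("tss_stats matches a brute-force threshold sweep and its arithmetic", {
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  res <- tss_stats(scores, labels)
  # brute-force oracle over every candidate threshold
  cand <- sort(unique(scores))
  oracle <- sapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t); spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  })
  expect_equal(res$tss, max(oracle))
  expect_equal(res$threshold, cand[which.max(oracle)])  # ties -> smallest
  expect_gt(res$threshold, 0.3)
  expect_lte(res$threshold, 0.4)
  expect_equal(res$tss, 1.0)  # perfectly separable toy
  expect_equal(res$sensitivity + res$specificity - 1, res$tss)
  # sens 0.8 + spec 0.9 - 1 = TSS 0.7 arithmetic
  s2 <- c(rep(0.9, 4), 0.01, 0.9, rep(0.05, 9))
  l2 <- c(rep(1, 5), rep(0, 10))
  r2 <- tss_stats(s2, l2)
  expect_equal(r2$sensitivity, 0.8)
  expect_equal(r2$specificity, 0.9)
  expect_equal(r2$tss, 0.7)
  expect_warning(d <- tss_stats(rep(0.5, 6), labels), "degenerate")
  expect_equal(d$tss, 0)
  expect_true(d$degenerate)
  expect_error(tss_stats(scores, rep(1, 6)), "single class")
})

test_that("ensemble weighting follows TSS proportionality and the inclusion cutoff", {
  w <- build_ensemble(list(mock_fit(0.8, 0.6), mock_fit(0.75, 0.5),
                           mock_fit(0.72, 0.4)), min_members = 3)$weights
  expect_equal(round(w, 4), c(0.3524, 0.3304, 0.3172))
  expect_equal(sum(w), 1)
  # equal TSS members average their predictions
  ens <- build_ensemble(list(mock_fit(0.8, 0.6), mock_fit(0.8, 0.8)), min_members = 2)
  expect_equal(predict(ens, matrix(0, 3, 1)), rep(0.7, 3))
  # members at or below the cutoff are excluded
  ens2 <- build_ensemble(list(mock_fit(0.9, 1), mock_fit(0.45, 0)), min_members = 1)
  expect_length(ens2$members, 1)
  expect_equal(predict(ens2, matrix(0, 2, 1)), c(1, 1))
  expect_error(build_ensemble(list(mock_fit(0.9, 1), mock_fit(0.45, 0))),
               class = "nichecast_non_ensembleable")
})

test_that("permutation importance finds used variables and ignores unused ones", {
  w <- shared_world()
  grid <- w$grids$recent
  suit <- true_suitability(w$species, grid)  # niche uses tmean_07 and prec_06
  ranks_first <- logical(6)
  unused_max <- numeric(6)
  for (s in 1:6) {
    set.seed(s)
    pres <- resample(which(suit >= 0.5), 200)
    bg <- resample(which(suit < 0.5), 200)
    x <- extract_climate(grid, c(pres, bg))
    fit <- fit_single_model("rf", x, rep(c(1, 0), each = 200))
    vi <- variable_importance(fit, x, n_perm = 2, seed = s)
    used <- names(w$species$response)
    ranks_first[s] <- names(which.max(vi)) %in% used
    unused_max[s] <- max(vi[setdiff(sprintf("prec_%02d", 1:12), used)])
  }
  expect_gte(mean(ranks_first), 0.9)
  expect_lt(stats::median(unused_max), 0.05)
  # determinism under a fixed seed
  x <- extract_climate(grid, 1:100)
  fit <- mock_fit(0.9, 0.5)
  expect_identical(variable_importance(fit, x, seed = 3),
                   variable_importance(fit, x, seed = 3))
  # constant predictions give all-zero scores
  expect_true(all(variable_importance(fit, x, seed = 1) == 0))
})

test_that("stored fits satisfy the TSS identity, recomputed from their confusion matrices", {
  w <- shared_world()
  occ <- sample_occurrences(w$species, w$grids$recent, n = 150, seed = 8)
  ens <- fit_ensemble_sdm(unique(occ$cell), w$grids$recent, n_pa = 300,
                          importance = FALSE, seed = 8)
  for (fit in ens$members) {
    e <- fit$eval
    expect_equal(e$tss, e$sensitivity + e$specificity - 1, tolerance = 1e-12)
    expect_true(e$sensitivity >= 0 && e$sensitivity <= 1)
    expect_true(e$specificity >= 0 && e$specificity <= 1)
    expect_true(e$tss >= -1 && e$tss <= 1)
  }
  expect_true(all(ens$weights >= 0))
  expect_equal(sum(ens$weights), 1)
  expect_true(all(ens$member_tss > ens$cutoff))
})
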