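# Synthetic climate, virtual species, jurisdictions and occurrence sampling.

test_that("scenario deltas are applied exactly and precipitation multiplier 1 is the identity", {
  cfg <- climate_sim_config(n_rows = 20, n_cols = 20,
                            temp_offsets = c(past = -0.5, recent = 0, mid45 = 1.5,
                                             mid85 = 2, late45 = 2, late85 = 3),
                            prec_multipliers = c(past = 1, recent = 1, mid45 = 1,
                                                 mid85 = 1, late45 = 1, late85 = 1))
  grids <- generate_climate_grids(cfg, seed = 42)
  expect_equal(mean(grids$late85$layers$tmean_07) - mean(grids$recent$layers$tmean_07),
               3.0, tolerance = 1e-12)
  expect_identical(grids$late85$layers$prec_03, grids$recent$layers$prec_03)
  expect_identical(grids$past$layers$prec_11, grids$recent$layers$prec_11)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- climate_sim_config(n_rows = 15, n_cols = 15)
  a <- generate_climate_grids(cfg, seed = 42)
  b <- generate_climate_grids(cfg, seed = 42)
  c <- generate_climate_grids(cfg, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$recent$layers$tmean_01, c$recent$layers$tmean_01))
})

test_that("recent climate has seasonal structure and warming is monotone across scenarios", {
  grids <- generate_climate_grids(climate_sim_config(n_rows = 30, n_cols = 30), seed = 5)
  # winter colder than summer, everywhere
  expect_true(all(grids$recent$layers$tmean_01 < grids$recent$layers$tmean_07))
  # spatial-mean July temperature strictly increases recent -> mid -> late
  for (m in sprintf("tmean_%02d", 1:12)) {
    means <- vapply(grids[c("recent", "mid85", "late85")],
                    function(g) mean(g$layers[[m]]), numeric(1))
    expect_true(all(diff(means) > 0))
  }
  # precipitation never negative in any scenario
  for (g in grids) {
    expect_true(all(vapply(sprintf("prec_%02d", 1:12),
                           function(v) all(g$layers[[v]] >= 0), logical(1))))
  }
})

test_that("generator configuration is validated", {
  expect_error(climate_sim_config(n_rows = 5), "at least 10")
  expect_error(climate_sim_config(autocorr_length = 0), "autocorr_length")
  expect_error(climate_sim_config(prec_multipliers = c(past = 1, recent = 1,
    mid45 = 1, mid85 = 1, late45 = 1, late85 = -0.2)), "non-negative")
  expect_error(climate_sim_config(temp_offsets = c(past = NA, recent = 0,
    mid45 = 1, mid85 = 1, late45 = 1, late85 = 1)), "finite")
})

test_that("true suitability is 1 at the joint optimum and vanishes in the tails", {
  g <- uniform_grid(5, 5, tmean = 20, prec = 50)
  sp <- virtual_species("vs", list(tmean_07 = c(optimum = 20, breadth = 2),
                                   prec_06 = c(optimum = 50, breadth = 10)))
  expect_equal(unname(true_suitability(sp, g)[1, 1]), 1.0)
  far <- uniform_grid(5, 5, tmean = 40, prec = 50)  # 10 breadths away
  expect_true(all(true_suitability(sp, far) < 1e-3))
  expect_error(true_suitability(
    virtual_species("vs", list(nope = c(optimum = 1, breadth = 1))), g), "nope")
})

test_that("widening a response breadth never decreases suitability anywhere", {
  grids <- generate_climate_grids(climate_sim_config(n_rows = 20, n_cols = 20), seed = 9)
  sp <- virtual_species("vs", list(tmean_07 = c(optimum = 22, breadth = 2),
                                   prec_06 = c(optimum = 40, breadth = 15)))
  wide <- sp
  wide$response$tmean_07[["breadth"]] <- 4
  s1 <- true_suitability(sp, grids$recent)
  s2 <- true_suitability(wide, grids$recent)
  expect_true(all(s2 >= s1 - 1e-15))  # exhaustive over all 400 cells
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("virtual species validation rejects bad parameters", {
  expect_error(virtual_species("v", list(tmean_01 = c(optimum = 1, breadth = 0))),
               "positive breadth")
  expect_error(virtual_species("v", list(tmean_01 = c(optimum = 1, breadth = 1)),
                               prevalence_target = 1.2), "prevalence_target")
})

test_that("prevalence calibration hits its target", {
  w <- shared_world()
  for (target in c(0.1, 0.2, 0.3)) {
    sp <- calibrate_virtual_species(w$grids$recent, prevalence_target = target,
                                    seed = 11)
    expect_equal(mean(true_suitable_mask(sp, w$grids$recent)), target,
                 tolerance = 0.02)
  }
})

test_that("jurisdictions tile the grid exactly and centroids sit inside it", {
  w <- shared_world()
  jur <- w$jur
  expect_true(all(jur$assignment %in% seq_len(jur$n)))
  expect_identical(dim(jur$assignment), c(80L, 80L))
  expect_equal(sum(tabulate(jur$assignment, jur$n)), n_cells(w$grids$recent))
  expect_true(all(jur$centroids$x > 0 & jur$centroids$x < 80))
  expect_identical(generate_jurisdictions(w$grids$recent, n = 6, seed = 7)$assignment,
                   jur$assignment)
})

test_that("clean occurrence sampling stays in the true-suitable region with complete years", {
  w <- shared_world()
  occ <- sample_occurrences(w$species, w$grids$recent, n = 100, seed = 21)
  expect_equal(nrow(occ), 100)
  expect_true(all(!is.na(occ$year)))
  expect_true(all(occ$year >= 1981 & occ$year <= 2018))
  truth <- true_suitable_mask(w$species, w$grids$recent)
  expect_true(all(truth[occ$cell]))
  expect_identical(occ, sample_occurrences(w$species, w$grids$recent, n = 100, seed = 21))
})

test_that("artifact records are injected at the stated rates and geometries", {
  w <- shared_world()
  occ <- sample_occurrences(w$species, w$grids$recent, n = 1000,
                            artifact_rates = c(duplicate = 0.05, missing_year = 0.05,
                                               centroid_snap = 0.1, far_outlier = 0.02),
                            jurisdictions = w$jur, seed = 33)
  counts <- table(occ$artifact)
  expect_equal(unname(counts[["centroid_snap"]]), 100)
  expect_equal(unname(counts[["duplicate"]]), 50)
  expect_equal(unname(counts[["missing_year"]]), 50)
  expect_equal(unname(counts[["far_outlier"]]), 20)
  snap <- occ[occ$artifact == "centroid_snap", ]
  dmin <- vapply(seq_len(nrow(snap)), function(i)
    min(sqrt((snap$x[i] - w$jur$centroids$x)^2 + (snap$y[i] - w$jur$centroids$y)^2)),
    numeric(1))
  expect_true(all(dmin < 0.3))  # within 300 m
  dup <- occ[occ$artifact == "duplicate", ]
  expect_true(all(dup$cell %in% occ$cell[occ$artifact == "none"]))
  expect_true(all(is.na(occ$year[occ$artifact == "missing_year"])))
  # far outliers sit >= 200 km from the true-suitable hull
  cc <- cell_centers(w$grids$recent, which(true_suitable_mask(w$species, w$grids$recent)))
  hull <- convex_hull(cc$x, cc$y)
  out <- occ[occ$artifact == "far_outlier", ]
  expect_true(all(point_polygon_distance(out$x, out$y, hull) >= 200))
})

test_that("occurrence sampling validates its inputs", {
  w <- shared_world()
  expect_error(sample_occurrences(w$species, w$grids$recent, n = 0), "at least 1")
  expect_error(sample_occurrences(w$species, w$grids$recent, n = 10,
                                  artifact_rates = c(duplicate = 0.8, missing_year = 0.5)),
               "sum to at most 1")
  expect_error(sample_occurrences(w$species, w$grids$recent, n = 10,
                                  artifact_rates = c(centroid_snap = 0.5)),
               "jurisdiction_set")
})

test_that("occurrence density increases with suitability decile", {
  w <- shared_world()
  occ <- sample_occurrences(w$species, w$grids$recent, n = 1000, seed = 55)
  suit <- true_suitability(w$species, w$grids$recent)
  suitable <- which(true_suitable_mask(w$species, w$grids$recent))
  dec <- cut(suit[suitable], stats::quantile(suit[suitable], 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  sampled <- suitable %in% occ$cell
  dens <- tapply(sampled, dec, mean)
  expect_gt(stats::cor(seq_along(dens), as.numeric(dens), method = "spearman"), 0)
})
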