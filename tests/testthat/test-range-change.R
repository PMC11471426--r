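# Pixel accounting between scenario pairs, change classification, centroid
# shifts, and stacked richness.

test_that("range-change percentages follow the published pixel conventions", {
  # worked examples from the published contraction table
  s <- range_change_summary(loss = 184792, gain = 1039, maintain = 3858)
  expect_equal(s$percent_lost, 100 * 184792 / 188650)   # formula identity
  expect_lt(abs(s$percent_lost - 97.96), 0.011)         # printed value, final digit free
  expect_equal(round(s$percent_gained, 2), 0.55)
  expect_equal(round(s$range_change, 2), -97.40)
  expect_equal(s$current_size, 188650)
  expect_equal(s$future_size, 4897)
  s2 <- range_change_summary(loss = 4322, gain = 0, maintain = 0)
  expect_equal(round(s2$percent_lost, 2), 100.00)
  expect_equal(round(s2$range_change, 2), -100.00)
  # range change must come from unrounded ratios, not rounded percentages
  s3 <- range_change_summary(loss = 58877, gain = 1535, maintain = 17423)
  expect_equal(round(s3$range_change, 2), -75.15)
  expect_false(isTRUE(all.equal(round(s3$range_change, 2),
                                round(round(s3$percent_gained, 2) -
                                      round(s3$percent_lost, 2), 2))))
  # net change identity: percent gained - percent lost = net size change
  expect_equal(s3$range_change, s3$net_change_pct, tolerance = 1e-12)
})

test_that("comparing binary maps counts loss/gain/maintain and is antisymmetric", {
  a <- mask_map(matrix(c(1, 1, 0, 0, 1, 0), 2, 3))
  b <- mask_map(matrix(c(1, 0, 1, 0, 1, 0), 2, 3))
  s <- compare_ranges(a, b)
  expect_equal(c(s$loss, s$gain, s$maintain), c(1, 1, 2))
  expect_equal(s$current_size, a$range_size)
  expect_equal(s$future_size, b$range_size)
  # identity comparison
  si <- compare_ranges(a, a)
  expect_equal(c(si$loss, si$gain), c(0, 0))
  expect_equal(si$range_change, 0)
  expect_equal(si$shift_km, 0)
  # antisymmetry under swapped scenarios
  r <- compare_ranges(b, a)
  expect_equal(c(r$loss, r$gain), c(s$gain, s$loss))
  set.seed(12)
  for (i in 1:5) {
    m1 <- mask_map(rand_mask(6, 6)); m2 <- mask_map(rand_mask(6, 6))
    f <- compare_ranges(m1, m2); g <- compare_ranges(m2, m1)
    expect_equal(f$loss, g$gain)
    expect_equal(f$maintain, g$maintain)
  }
  expect_error(compare_ranges(a, mask_map(matrix(1, 3, 3))), "mismatched")
})

test_that("change classification applies the dead band, turnover and centroid rules", {
  cls <- function(loss, gain, maintain, shift = NULL) {
    s <- range_change_summary(loss, gain, maintain)
    if (!is.null(shift)) s$shift_km <- shift
    classify_change(s)$class
  }
  expect_equal(cls(184792, 1039, 3858), "contract")   # net -97.4, turnover 98
  expect_equal(cls(20, 40, 80), "expand")             # net +20%, turnover 20%
  expect_equal(cls(60, 80, 40), "shift")              # net +20%, turnover 60%
  expect_equal(cls(5, 10, 95), "stable")              # net +5%, no movement
  expect_equal(cls(5, 10, 95, shift = 150), "stable_shift")
  expect_equal(cls(10, 20, 90), "expand")             # net exactly +10% counts
  expect_equal(cls(21, 10, 89), "contract")           # net exactly -10% counts
  s0 <- classify_change(range_change_summary(0, 5, 0))
  expect_equal(s0$class, "undefined")
})

test_that("centroids are suitable-cell means and shifts have distance and bearing", {
  one <- mask_map(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(niche_centroid(one), c(x = 1.5, y = 1.5))
  sym <- mask_map(matrix(c(1, 0, 0, 1), 2, 2), origin = c(-1, -1))
  expect_equal(niche_centroid(sym), c(x = 0, y = 0))
  # five listed cells, mean by hand: cols {1,2,3,1,5}, rows {1,1,2,4,3}
  m <- matrix(0, 4, 5)
  m[1, 1] <- 1; m[1, 2] <- 1; m[2, 3] <- 1; m[4, 1] <- 1; m[3, 5] <- 1
  expect_equal(niche_centroid(mask_map(m)),
               c(x = mean(c(1, 2, 3, 1, 5)) - 0.5, y = mean(c(1, 1, 2, 4, 3)) - 0.5))
  expect_error(niche_centroid(mask_map(matrix(0, 2, 2))), "empty")
  # bearings: north 0, east 90, 3-4-5 triangle 36.87
  expect_equal(nichecast:::centroid_shift_xy(c(x = 0, y = 0), c(x = 0, y = 100)),
               list(shift_km = 100, bearing_deg = 0))
  expect_equal(nichecast:::centroid_shift_xy(c(x = 0, y = 0), c(x = 100, y = 0)),
               list(shift_km = 100, bearing_deg = 90))
  tri <- nichecast:::centroid_shift_xy(c(x = 0, y = 0), c(x = 30, y = 40))
  expect_equal(tri$shift_km, 50)
  expect_equal(tri$bearing_deg, atan2(30, 40) * 180 / pi, tolerance = 1e-10)
  expect_equal(round(tri$bearing_deg, 2), 36.87)
})

test_that("richness stacks sum per-cell and respect dispersal assumptions", {
  set.seed(77)
  maps <- lapply(1:3, function(i) mask_map(rand_mask(5, 5), species = paste0("s", i)))
  rich <- richness_stack(maps)
  brute <- maps[[1]]$mask + maps[[2]]$mask + maps[[3]]$mask
  expect_equal(rich$values, brute + 0L)
  all_on <- richness_stack(lapply(1:3, function(i)
    mask_map(matrix(1, 2, 2), species = paste0("s", i))))
  expect_true(all(all_on$values == 3))
  empty <- richness_stack(list(), n_rows = 4, n_cols = 4)
  expect_true(all(empty$values == 0))
  expect_error(richness_stack(list(maps[[1]], mask_map(matrix(1, 3, 3)))), "mismatch")
})

test_that("no-dispersal richness change masks gains and keeps losses", {
  rec <- mask_map(matrix(c(1, 1, 0, 0), 2, 2), species = "s1")
  fut <- mask_map(matrix(c(0, 1, 1, 0), 2, 2), species = "s1")
  full <- richness_change(list(rec), list(fut), "full")
  none <- richness_change(list(rec), list(fut), "none")
  expect_equal(as.numeric(full), c(-1, 0, 1, 0))  # gain counted under full dispersal
  expect_equal(as.numeric(none), c(-1, 0, 0, 0))  # gain masked, loss kept
  # property: no-dispersal change is nowhere positive, any stack
  set.seed(41)
  for (i in 1:10) {
    r <- lapply(1:4, function(k) mask_map(rand_mask(6, 6), species = paste0("s", k)))
    f <- lapply(1:4, function(k) mask_map(rand_mask(6, 6), species = paste0("s", k)))
    expect_true(all(richness_change(r, f, "none") <= 0))
    # full dispersal equals the sum of per-species gain-loss indicators
    per_sp <- Reduce(`+`, lapply(1:4, function(k) f[[k]]$mask - r[[k]]$mask))
    expect_equal(richness_change(r, f, "full"), per_sp)
  }
  expect_error(richness_change(list(rec), list(mask_map(matrix(1, 2, 2), species = "zz")),
                               "full"), "species sets")
})
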