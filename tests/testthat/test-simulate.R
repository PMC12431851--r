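test_that("generators are pure functions of their seed", {
  c1 <- sim_force_curves(3, 4000, seed = 5)
  c2 <- sim_force_curves(3, 4000, seed = 5)
  expect_identical(c1, c2)
  f1 <- sim_stiffness_field("fibrotic", seed = 5)
  f2 <- sim_stiffness_field("fibrotic", seed = 5)
  expect_identical(f1, f2)
  p <- shallow_pattern()
  t1 <- sim_tracks(p, n_tracks = 10, duration = 3600, seed = 5)
  t2 <- sim_tracks(p, n_tracks = 10, duration = 3600, seed = 5)
  expect_identical(t1, t2)
  x1 <- sim_flux_table(5, 0.2, seed = 5)
  x2 <- sim_flux_table(5, 0.2, seed = 5)
  expect_identical(x1, x2)
  fb1 <- sim_fibers("curly", n = 5, seed = 5)
  fb2 <- sim_fibers("curly", n = 5, seed = 5)
  expect_identical(fb1, fb2)
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(sim_force_curves(1, 4000, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("derived seeds separate generator streams", {
  s <- vapply(0:20, function(k) derive_seed(7, k), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
})

test_that("generated objects satisfy the consuming types' invariants", {
  cvs <- sim_force_curves(5, 4000, seed = 2)
  for (cv in cvs) expect_s3_class(cv, "force_curve")
  fld <- sim_stiffness_field("fibrotic", seed = 2)
  expect_s3_class(fld, "stiffness_map")
  expect_true(all(fld$grid > 0))
  tr <- sim_tracks(shallow_pattern(), n_tracks = 8, duration = 3600,
                   seed = 2)
  expect_s3_class(as_track_table(tr), "track_table")
  ext <- shallow_pattern()$extent
  expect_true(all(tr$x >= 0 & tr$x <= ext[1] & tr$y >= 0 & tr$y <= ext[2]))
  fx <- sim_flux_table(4, 0.3, seed = 2)
  expect_true(all(fx$flux$photon_flux >= 0))
  for (f in sim_fibers("straight_aligned", n = 4, seed = 2)) {
    expect_gte(nrow(f), 2)
  }
})

test_that("healthy fields are near-uniform, fibrotic fields carry foci", {
  h <- sim_stiffness_field("healthy", seed = 30)
  expect_lt(average_slope(h, n_slopes = 50, seed = 1)$average_slope, 100)
  flat <- sim_stiffness_field("healthy", healthy_amp = 0, seed = 30)
  expect_true(all(flat$grid == flat$grid[1, 1]))
  expect_equal(average_slope(flat, 50, seed = 1)$average_slope, 0)
  fb <- sim_stiffness_field("fibrotic", seed = 30)
  foci <- attr(fb, "foci")
  expect_equal(nrow(foci), 5)
  expect_setequal(unique(foci$kind), c("peak", "valley"))
})

test_that("planted fibrotic foci are recovered within one pixel", {
  recall <- vapply(1:10, function(s) {
    fld <- sim_stiffness_field("fibrotic", seed = s)
    foci <- attr(fld, "foci")
    det <- detect_peaks_valleys(fld, min_prominence = 500)
    hits <- vapply(seq_len(nrow(foci)), function(i) {
      same <- det[det$kind == foci$kind[i], , drop = FALSE]
      nrow(same) > 0 &&
        min(sqrt((same$x - foci$x[i])^2 + (same$y - foci$y[i])^2)) <=
          fld$pitch
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(mean(recall), 0.9)
})

test_that("unbiased walkers show no forward migration", {
  tr <- sim_tracks(shallow_pattern(extent = c(5000, 5000)),
                   n_tracks = 1000, duration = 7200, dt = 600,
                   bias_strength = 0, seed = 19)
  m <- track_metrics(tr, "+x")
  se <- sd(m$fmi_parallel) / sqrt(nrow(m))
  expect_lt(abs(mean(m$fmi_parallel)), 3 * se)
})

test_that("gradient-biased walkers migrate up the gradient", {
  tr <- sim_tracks(shallow_pattern(), n_tracks = 200, duration = 21600,
                   bias_strength = 4, seed = 19)
  m <- track_metrics(tr, "+x")
  expect_gt(mean(m$fmi_parallel), 0.3)
  rh <- rose_histogram(tr, "+x")
  # modal bin flanks 0 degrees
  centre <- (rh$bin_edges[-1] + rh$bin_edges[-length(rh$bin_edges)]) / 2
  expect_lt(abs(centre[which.max(rh$counts)]), 20)
})

test_that("bias has no effect where the gradient is zero", {
  u <- substrate_pattern("uniform", 4000, extent = c(2000, 2000))
  t0 <- sim_tracks(u, n_tracks = 50, duration = 7200, bias_strength = 0,
                   seed = 23)
  t5 <- sim_tracks(u, n_tracks = 50, duration = 7200, bias_strength = 5,
                   seed = 23)
  expect_identical(t0$x, t5$x)
  expect_identical(t0$y, t5$y)
})

test_that("flux tables reproduce their ground-truth indices exactly", {
  sim <- sim_flux_table(10, 0.25, seed = 41)
  r <- metastatic_index(sim$flux)
  expect_equal(r$metastatic_index, sim$truth$index)
  zero <- sim_flux_table(6, 0, seed = 41)
  expect_true(all(metastatic_index(zero$flux)$metastatic_index == 0))
})

test_that("fibre styles separate in curvature and alignment", {
  st <- fiber_population_summary(sim_fibers("straight_aligned", n = 100,
                                            seed = 37))
  cu <- fiber_population_summary(sim_fibers("curly", n = 100, seed = 37))
  expect_gt(median(st$curvature_ratios), 0.95)
  expect_gt(st$alignment_score, 0.8)
  expect_lt(median(cu$curvature_ratios), median(st$curvature_ratios))
  expect_lt(cu$alignment_score, 0.3)
  # zero wiggle: exactly straight
  one <- sim_fibers("straight_aligned", n = 1, wiggle = 0, seed = 1)
  expect_equal(curvature_ratio(one[[1]]), 1)
})
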