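test_that("the durotactic index is the stiff/soft count ratio", {
  p <- step_pattern()
  # equal occupancy -> index 1 (the plating-time baseline)
  pos <- rbind(c(290, 10), c(290, 50), c(100, 10), c(100, 50))
  r <- durotactic_index(pos, p)
  expect_equal(r$index_raw, 1)
  expect_equal(r$n_excluded, 0)
  # 60 stiff / 20 soft -> 3; with a baseline of 1.5 -> normalized 2
  stiff_pts <- cbind(290, seq(1, 399, length.out = 60))
  soft_pts <- cbind(100, seq(1, 399, length.out = 20))
  r3 <- durotactic_index(rbind(stiff_pts, soft_pts), p)
  expect_equal(r3$index_raw, 3)
  base <- rbind(cbind(290, seq(1, 399, length.out = 30)),
                cbind(100, seq(1, 399, length.out = 20)))
  rn <- durotactic_index(rbind(stiff_pts, soft_pts), p, baseline = base)
  expect_equal(rn$normalization_baseline, 1.5)
  expect_equal(rn$index_normalized, 2)
})

test_that("transition cells are excluded by default, split under midpoint", {
  p <- step_pattern()
  pos <- rbind(c(290, 10), c(100, 10), c(225, 10))  # one mid-band cell
  r <- durotactic_index(pos, p)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n_stiff + r$n_soft, 2)
  r2 <- durotactic_index(pos, p, rule = "midpoint")
  expect_equal(r2$n_excluded, 0)
})

test_that("zero soft counts saturate instead of dividing by zero", {
  p <- step_pattern()
  r <- durotactic_index(rbind(c(290, 10), c(290, 50)), p)
  expect_true(r$saturated)
  expect_true(is.na(r$index_raw))
  expect_equal(r$n_stiff, 2)
})

test_that("uniform seeding on an equal-area pattern gives index near 1", {
  p <- equal_stripe_pattern()  # 150/150 um stripes, period 380, extent 760
  set.seed(99)
  n <- 10000
  pos <- cbind(runif(n, 0, 760), runif(n, 0, 400))
  r <- durotactic_index(pos, p)
  # index -> 1 as n grows; 3 SE band on the ratio via delta method
  se <- r$index_raw * sqrt(1 / r$n_stiff + 1 / r$n_soft)
  expect_lt(abs(r$index_raw - 1), 3 * se)
})

test_that("density normalization cancels unequal stripe areas", {
  p <- step_pattern(extent = c(760, 400))  # 100 um stiff vs 200 um soft
  set.seed(123)
  pos <- cbind(runif(10000, 0, 760), runif(10000, 0, 400))
  raw <- durotactic_index(pos, p)
  # raw ratio tracks the 1:2 area ratio
  expect_equal(raw$index_raw, 0.5, tolerance = 0.15)
  dens <- durotactic_index(pos, p, density_normalize = TRUE)
  se <- dens$index_raw * sqrt(1 / dens$n_stiff + 1 / dens$n_soft)
  expect_lt(abs(dens$index_raw - 1), 3 * se)
})

test_that("durotaxis classification follows the conventional thresholds", {
  expect_equal(classify_durotaxis(6.5), "strong")
  expect_equal(classify_durotaxis(2.5), "moderate")
  expect_equal(classify_durotaxis(1.0), "none")
  expect_equal(classify_durotaxis(4.5, confluent = TRUE),
               "confluence_dependent")
  expect_equal(classify_durotaxis(4.5, confluent = FALSE), "moderate")
  expect_error(classify_durotaxis(-1), "non-negative")
  # monotone in the index: labels only ever move up the ordering
  ord <- c(none = 0, moderate = 1, confluence_dependent = 2, strong = 3)
  idx <- seq(0, 8, by = 0.25)
  for (conf in c(FALSE, TRUE)) {
    lv <- ord[vapply(idx, classify_durotaxis, character(1),
                     confluent = conf)]
    expect_true(all(diff(lv) >= 0))
  }
})

test_that("time courses normalize every timepoint to the earliest", {
  p <- step_pattern()
  pos <- rbind(c(290, 10), c(100, 10))
  tc <- assay_timecourse(list(`4` = pos, `24` = pos), p)
  expect_equal(tc$index_normalized, c(1, 1))
  expect_equal(tc$timepoint_h, c(4, 24))
  # all-on-stiff endpoint saturates rather than dividing by zero
  stiff_only <- rbind(c(290, 10), c(290, 50))
  tc2 <- assay_timecourse(list(`4` = pos, `24` = stiff_only), p)
  expect_true(tc2$saturated[2])
  expect_true(is.na(tc2$index_normalized[2]))
})

test_that("strongly biased walkers raise the normalized 24-h index above 1", {
  p <- equal_stripe_pattern(extent = c(760, 760))
  walks <- sim_tracks(p, n_tracks = 300, duration = 86400, dt = 1800,
                      speed_mean = 0.5, bias_strength = 4, seed = 13)
  start <- walks[!duplicated(walks$track_id), c("x", "y")]
  end <- walks[!duplicated(walks$track_id, fromLast = TRUE), c("x", "y")]
  tc <- durotactic_index(end, p, baseline = start)
  expect_gt(tc$index_normalized, 1)
})
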