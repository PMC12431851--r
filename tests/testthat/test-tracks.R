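test_that("track metrics match hand-computed values", {
  # path (0,0) -> (3,0) -> (3,4): 3-4-5 triangle
  tr <- data.frame(track_id = "a", t = c(0, 60, 120),
                   x = c(0, 3, 3), y = c(0, 0, 4))
  m <- track_metrics(tr, "+x")
  expect_equal(m$path_length, 7)
  expect_equal(m$net_displacement, 5)
  expect_equal(m$mean_speed, 7 / 2)  # um/min over 2 min
  expect_equal(m$directionality, 5 / 7)
  expect_equal(m$fmi_parallel, 3 / 7)
  expect_equal(m$fmi_perpendicular, 4 / 7)
  expect_equal(m$end_angle, atan2(4, 3) * 180 / pi)
})

test_that("straight monotone paths score directionality and FMI of 1", {
  m <- track_metrics(straight_track(), "+x")
  expect_identical(m$directionality, 1)
  expect_identical(m$fmi_parallel, 1)
  expect_equal(m$end_angle, 0)
  # along -x against a +x axis: FMI = -1, angle 180
  m2 <- track_metrics(straight_track(ux = -2), "+x")
  expect_identical(m2$fmi_parallel, -1)
  expect_equal(m2$end_angle, 180)
})

test_that("closed loops have zero directionality and FMI by definition", {
  loop <- data.frame(track_id = "l", t = 0:4 * 60,
                     x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  m <- track_metrics(loop)
  expect_equal(m$directionality, 0)
  expect_equal(m$fmi_parallel, 0)
  expect_true(is.na(m$end_angle))
})

test_that("directionality bounds and the Pythagorean FMI decomposition hold", {
  tracks <- sim_tracks(shallow_pattern(), n_tracks = 60, duration = 7200,
                       bias_strength = 1.5, seed = 42)
  m <- track_metrics(tracks, "+x")
  expect_true(all(m$directionality >= 0 & m$directionality <= 1))
  expect_true(all(abs(m$fmi_parallel) <= m$directionality + 1e-12))
  expect_true(all(m$fmi_parallel^2 + m$fmi_perpendicular^2 <=
                    m$directionality^2 + 1e-12))
})

test_that("metrics are invariant under joint rotation of tracks and axis", {
  tracks <- sim_tracks(substrate_pattern("uniform", 4000,
                                         extent = c(400, 400)),
                       n_tracks = 20, duration = 7200, seed = 8)
  m0 <- track_metrics(tracks, "+x")
  for (ang in c(30, 90, 137.5)) {
    mr <- track_metrics(rotate_tracks(tracks, ang), ang)
    for (col in c("path_length", "net_displacement", "directionality",
                  "fmi_parallel", "fmi_perpendicular", "end_angle")) {
      expect_equal(mr[[col]], m0[[col]], tolerance = 1e-9)
    }
  }
})

test_that("coverage filtering applies a strict 10% rule", {
  # 120-frame recording at dt = 1 s: 13-frame track kept, 12-frame dropped
  mk <- function(id, n) data.frame(track_id = id, t = 0:(n - 1),
                                   x = 0:(n - 1), y = 0)
  tracks <- rbind(mk("keep", 13), mk("drop", 12))
  kept <- filter_tracks(tracks, recording_duration = 120)
  expect_equal(unique(kept$track_id), "keep")
  # min_coverage = 0 keeps everything
  all_kept <- filter_tracks(tracks, 120, min_coverage = 0)
  expect_setequal(unique(all_kept$track_id), c("keep", "drop"))
  empty <- tracks[0, ]
  expect_equal(nrow(filter_tracks(empty, 120)), 0L)
})

test_that("rose histograms conserve counts and respect symmetry", {
  tracks <- do.call(rbind, lapply(1:3, function(k) {
    straight_track(id = paste0("t", k))
  }))
  rh <- rose_histogram(tracks, "+x")
  expect_equal(sum(rh$counts), 3)
  # all mass in the bin whose right edge is 0 degrees
  expect_equal(rh$counts[which(rh$bin_edges == 0) - 1], 3)
  # mirrored pairs give a histogram symmetric about 0
  up <- straight_track("u", ux = 1, uy = 0.5)
  dn <- straight_track("d", ux = 1, uy = -0.5)
  rh2 <- rose_histogram(rbind(up, dn))
  expect_equal(rh2$counts, rev(rh2$counts))
  # zero-net tracks are excluded with a count
  loop <- data.frame(track_id = "loop", t = 0:2 * 60,
                     x = c(0, 1, 0), y = c(0, 1, 0))
  rh3 <- rose_histogram(rbind(up, loop))
  expect_equal(sum(rh3$counts), 1)
  expect_equal(rh3$n_excluded, 1)
})

test_that("step-mode rose histograms pool per-step displacement angles", {
  tr <- data.frame(track_id = "z", t = 0:3 * 60,
                   x = c(0, 1, 1, 2), y = c(0, 0, 1, 1))
  rh <- rose_histogram(tr, "+x", mode = "step")
  expect_equal(sum(rh$counts), 3)  # two +x steps and one +y step
  centre <- (rh$bin_edges[-1] + rh$bin_edges[-19]) / 2
  expect_equal(sum(rh$counts[abs(centre - (-10)) < 1e-9]), 2)
  expect_equal(sum(rh$counts[abs(centre - 90) < 15]), 1)
})

test_that("unbiased walker angles are circularly uniform", {
  tracks <- sim_tracks(substrate_pattern("uniform", 4000,
                                         extent = c(5000, 5000)),
                       n_tracks = 1000, duration = 7200, dt = 600,
                       bias_strength = 0, seed = 77)
  m <- track_metrics(tracks)
  ang <- m$end_angle[!is.na(m$end_angle)] * pi / 180
  resultant <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  expect_lt(resultant, 0.1)
})

test_that("drift correction removes a rigid common translation exactly", {
  # three tracks whose per-frame displacements are (+s, 0), (0, +s),
  # (-s, -s): the median ensemble displacement is exactly zero per frame
  frames <- 0:10 * 300
  mk <- function(id, dx, dy) {
    data.frame(track_id = id, t = frames,
               x = 50 + cumsum(c(0, rep(dx, 10))),
               y = 50 + cumsum(c(0, rep(dy, 10))))
  }
  base <- rbind(mk("a", 2, 0), mk("b", 0, 2), mk("c", -2, -2))
  drift <- apply(cbind(c(0, rep(1, 10)), c(0, rep(-2, 10))), 2, cumsum)
  shifted <- as_track_table(base)
  idx <- match(shifted$t, frames)
  shifted$x <- shifted$x + drift[idx, 1]
  shifted$y <- shifted$y + drift[idx, 2]
  fixed <- drift_correct(shifted)
  expected <- as_track_table(base)
  expect_equal(fixed$x, expected$x, tolerance = 1e-9)
  expect_equal(fixed$y, expected$y, tolerance = 1e-9)
  # no drift: output equals input when the median displacement is zero
  same <- drift_correct(expected)
  expect_equal(same$x, expected$x, tolerance = 1e-9)
  # single track: warning, unchanged
  single <- expected[expected$track_id == "a", ]
  expect_warning(out <- drift_correct(single), "2 simultaneous")
  expect_equal(out$x, single$x)
})

test_that("random-walk drift is removed to near zero ensemble motion", {
  base <- sim_tracks(substrate_pattern("uniform", 4000,
                                       extent = c(400, 400)),
                     n_tracks = 20, duration = 7200, dt = 300, seed = 6)
  frames <- sort(unique(base$t))
  set.seed(31)
  steps <- cbind(c(0, rnorm(length(frames) - 1, 0, 3)),
                 c(0, rnorm(length(frames) - 1, 0, 3)))
  drift <- apply(steps, 2, cumsum)
  shifted <- base
  idx <- match(shifted$t, frames)
  shifted$x <- shifted$x + drift[idx, 1]
  shifted$y <- shifted$y + drift[idx, 2]
  fixed <- drift_correct(shifted)
  # per-frame median ensemble displacement after correction ~ 0
  resid <- attr(drift_correct(fixed), "drift")
  expect_lt(max(abs(c(resid$dx, resid$dy))), 1e-6)
})

test_that("invasion index counts start-to-end boundary crossings", {
  boundary <- rbind(c(50, -10), c(50, 110))  # vertical line x = 50
  mk <- function(id, x0, x1) data.frame(track_id = id, t = c(0, 600),
                                        x = c(x0, x1), y = c(50, 50))
  confined <- rbind(mk("a", 10, 20), mk("b", 30, 40))
  expect_equal(invasion_index(confined, boundary, "right"), 0)
  crossing <- rbind(mk("a", 10, 80), mk("b", 30, 90))
  expect_equal(invasion_index(crossing, boundary, "right"), 1)
  mixed <- do.call(rbind, lapply(1:10, function(k) {
    mk(paste0("t", k), 10, if (k <= 3) 90 else 40)
  }))
  expect_equal(invasion_index(mixed, boundary, "right"), 0.3)
  expect_error(invasion_index(mixed, rbind(c(0, 0), c(0, 0)), "right"),
               "degenerate")
})

test_that("malformed track tables are rejected with located errors", {
  bad <- data.frame(track_id = "a", t = c(0, 60, 60), x = 0:2, y = 0)
  expect_error(as_track_table(bad), "not strictly increasing")
  expect_error(as_track_table(data.frame(track_id = 1, t = 1, x = 1)),
               "missing columns")
  short <- data.frame(track_id = "a", t = 0, x = 0, y = 0)
  expect_error(as_track_table(short), "fewer than 2")
})
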