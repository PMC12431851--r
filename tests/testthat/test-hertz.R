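test_that("Hertz forward model matches the closed form", {
  expect_equal(hertz_force(0, 4000), 0)
  # direct evaluation: delta = 500 nm, E = 4 kPa, nu = 0.4, R = 2.5 um
  f <- hertz_force(500e-9, 4000, 0.4, 2.5e-6)
  expect_equal(f, (4 / 3) * 4000 / (1 - 0.16) * sqrt(2.5e-6) * (5e-7)^1.5)
  expect_equal(f * 1e9, 3.549, tolerance = 1e-3)
  # linear in E at fixed indentation
  expect_equal(hertz_force(500e-9, 40000, 0.4, 2.5e-6), 10 * f)
  expect_error(hertz_force(-1e-9, 4000), "non-negative")
})

test_that("the printed inverse formula recovers E from the forward model", {
  for (E in c(500, 4000, 40000)) {
    for (delta in c(1e-8, 1e-7, 1e-6)) {
      F <- hertz_force(delta, E, 0.4, 2.5e-6)
      E_back <- 0.75 * (1 - 0.4^2) * F / (sqrt(2.5e-6) * delta^1.5)
      expect_equal(E_back, E)
    }
  }
})

test_that("hertz_force is strictly increasing in delta, E and R", {
  d <- seq(1e-8, 1e-6, length.out = 20)
  expect_true(all(diff(hertz_force(d, 4000)) > 0))
  Es <- seq(500, 50000, length.out = 20)
  expect_true(all(diff(vapply(Es, function(E) hertz_force(5e-7, E),
                              numeric(1))) > 0))
  Rs <- seq(1e-6, 5e-6, length.out = 20)
  expect_true(all(diff(vapply(Rs, function(R) hertz_force(5e-7, 4000,
                                                          R = R),
                              numeric(1))) > 0))
})

test_that("noiseless curves are fit back to machine precision", {
  for (E in c(500, 10000, 64000)) {
    cv <- sim_force_curves(1, E, noise_frac = 0, seed = 1)[[1]]
    fit <- fit_hertz(cv)
    expect_true(fit$valid)
    expect_equal(fit$E, E, tolerance = 1e-9)
    expect_lt(fit$residual_rms, 1e-15)
  }
})

test_that("mean fitted modulus recovers truth under 2% force noise", {
  cvs <- sim_force_curves(200, 4000, noise_frac = 0.02, seed = 101)
  Es <- vapply(cvs, function(cv) fit_hertz(cv)$E, numeric(1))
  expect_lt(abs(mean(Es) - 4000) / 4000, 0.05)
})

test_that("estimator error shrinks with noise and sample count", {
  med_err <- function(noise, n_samples) {
    cvs <- sim_force_curves(60, 4000, noise_frac = noise,
                            n_samples = n_samples, seed = 55)
    Es <- vapply(cvs, function(cv) fit_hertz(cv)$E, numeric(1))
    median(abs(Es - 4000) / 4000)
  }
  errs_noise <- c(med_err(0.10, 50), med_err(0.02, 50), med_err(0.001, 50))
  expect_true(all(diff(errs_noise) < 0))
  expect_lt(med_err(0.05, 400), med_err(0.05, 16))
})

test_that("degenerate curves are flagged invalid, not errors", {
  cv <- sim_force_curves(1, 4000, noise_frac = 0, seed = 1)[[1]]
  # truncate the usable range to 3 samples via the force cap
  fit <- fit_hertz(cv, max_force = cv$force[4])
  expect_false(fit$valid)
  expect_true(is.na(fit$E))
  expect_error(force_curve(c(0, 2, 1, 3, 4, 5, 6, 7) * 1e-8, rep(1e-9, 8)),
               "non-decreasing")
})

test_that("contact point is recovered on synthetic approach traces", {
  # noiseless: contact at 1.0 um within one sample
  trc <- sim_indentation_trace(4000, 1.0e-6, 2e-6, noise_frac = 0,
                               seed = 1)
  dz <- diff(trc$z)[1]
  cp <- estimate_contact_point(trc$z, trc$force)
  expect_true(cp$valid)
  expect_lt(abs(cp$contact_z - 1.0e-6), dz + 1e-12)
  # 1% noise: contact at 0.5 um within 2 samples
  trc <- sim_indentation_trace(4000, 0.5e-6, 1.5e-6, noise_frac = 0.01,
                               seed = 9)
  cp <- estimate_contact_point(trc$z, trc$force)
  expect_lt(abs(cp$contact_z - 0.5e-6), 2 * diff(trc$z)[1] + 1e-12)
  # baseline-only trace: invalid flag, no exception
  flat <- estimate_contact_point(seq(0, 1e-6, length.out = 50),
                                 rep(0, 50))
  expect_false(flat$valid)
  expect_true(is.na(flat$contact_z))
})

test_that("stiffness maps assemble from gridded fits", {
  xs <- seq(0, 80, by = 5)
  fits <- list()
  k <- 0
  for (y in xs) for (x in xs) {
    k <- k + 1
    cv <- sim_force_curves(1, 10000, noise_frac = 0, seed = 1)[[1]]
    cv$position <- c(x, y)
    fits[[k]] <- fit_hertz(cv)
  }
  m <- build_stiffness_map(fits, pitch = 5)
  expect_equal(dim(m$grid), c(17, 17))
  expect_equal(map_extent(m), c(80, 80))
  expect_true(all(abs(m$grid - 10000) < 1e-6))
})

test_that("invalid fits become missing map entries and duplicates error", {
  cv <- sim_force_curves(1, 10000, noise_frac = 0, seed = 1)[[1]]
  f_ok <- fit_hertz(cv)
  f_bad <- fit_hertz(cv, max_force = cv$force[3])
  f_ok$position <- c(0, 0)
  f_bad$position <- c(5, 0)
  m <- build_stiffness_map(list(f_ok, f_bad), pitch = 5)
  expect_equal(m$grid[1, 1], f_ok$E)
  expect_true(is.na(m$grid[1, 2]))
  # all invalid -> all missing, not an error
  f_bad2 <- f_bad
  f_bad2$position <- c(0, 0)
  m2 <- build_stiffness_map(list(f_bad2, f_bad), pitch = 5)
  expect_true(all(is.na(m2$grid)))
  # single fit -> 1 x 1 map
  m3 <- build_stiffness_map(list(f_ok), pitch = 5)
  expect_equal(dim(m3$grid), c(1, 1))
  expect_equal(m3$grid[1, 1], f_ok$E)
  dup <- f_ok
  expect_error(build_stiffness_map(list(f_ok, dup), pitch = 5),
               "duplicate")
})
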