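#' AFM force-indentation curve
#'
#' One nanoindentation record: ordered (indentation, force) samples plus
#' the probe constants needed for Hertz fitting. Units are SI throughout
#' (metres, newtons); conversion to/from um and nN happens only at the
#' file I/O edge.
#'
#' @param delta Indentation depths in m, non-decreasing, length >= 8.
#' @param force Measured forces in N (same length).
#' @param tip_radius Sphere tip radius in m (default 2.5e-6, a 5 um
#'   diameter probe).
#' @param poisson Poisson's ratio, in `[0, 0.5)` (default 0.4, the usual
#'   assumption for soft tissue).
#' @param spring_constant Cantilever spring constant in N/m, metadata
#'   only (default 0.06, i.e. ~60 pN/nm).
#' @param position Optional grid position `c(x, y)` in um.
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(delta, force, tip_radius = 2.5e-6, poisson = 0.4,
                        spring_constant = 0.06, position = NULL) {
  stopifnot(length(delta) == length(force), length(delta) >= 8L,
            tip_radius > 0, poisson >= 0, poisson < 0.5)
  if (any(diff(delta) < 0)) {
    stop("indentation must be non-decreasing along the curve",
         call. = FALSE)
  }
  structure(
    list(delta = as.numeric(delta), force = as.numeric(force),
         tip_radius = tip_radius, poisson = poisson,
         spring_constant = spring_constant, position = position),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve: %d samples, delta <= %.3g um, F <= %.3g nN, R = %.2g um>\n",
    length(x$delta), max(x$delta) * 1e6, max(x$force) * 1e9,
    x$tip_radius * 1e6))
  invisible(x)
}

#' Hertz spherical-contact force
#'
#' Forward model for a rigid sphere indenting an elastic half-space:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`. Its inverse,
#' `E = (3/4) * (1 - nu^2) * F / (sqrt(R) * delta^(3/2))`, recovers the
#' Young's modulus from a force-indentation pair.
#'
#' @param delta Indentation in m (>= 0, vectorized).
#' @param E Young's modulus in Pa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @param R Tip radius in m (> 0).
#' @return Force in N.
#' @examples
#' hertz_force(500e-9, 4000, 0.4, 2.5e-6) * 1e9  # ~3.55 nN
#' @export
hertz_force <- function(delta, E, nu = 0.4, R = 2.5e-6) {
  stopifnot(E > 0, R > 0, nu >= 0, nu < 0.5)
  if (any(delta < 0)) stop("indentation must be non-negative", call. = FALSE)
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

#' Estimate the tip-sample contact point of a raw approach trace
#'
#' Locates the piezo position past which the measured force rises above
#' the pre-contact baseline noise. The baseline mean and standard
#' deviation are estimated from the first `baseline_frac` of samples;
#' the force's first sustained crossing of `mean + c * sd` marks the
#' rise, and the estimate is then refined by a piecewise-model grid
#' search around the crossing: each candidate contact sample z0 models
#' the trace as a flat baseline followed by a Hertzian (z - z0)^(3/2)
#' rise, and the candidate minimizing the total squared error wins (the
#' raw threshold crossing alone is systematically late because the
#' Hertzian force grows only as delta^(3/2) near contact). Subtracting
#' the returned z from the z axis yields the indentation axis used for
#' fitting.
#'
#' @param z Piezo/approach positions in m (increasing).
#' @param force Measured force in N.
#' @param baseline_frac Fraction of leading samples treated as baseline.
#' @param c Threshold in baseline standard deviations (default 3).
#' @return List with `contact_z` (m, `NA` if undetectable), `valid` flag
#'   and `threshold` (N).
#' @export
estimate_contact_point <- function(z, force, baseline_frac = 0.2, c = 3) {
  stopifnot(length(z) == length(force), length(z) >= 8L, c > 0,
            baseline_frac > 0, baseline_frac < 1)
  nb <- max(4L, floor(length(z) * baseline_frac))
  mu <- mean(force[seq_len(nb)])
  sd0 <- stats::sd(force[seq_len(nb)])
  thr <- mu + c * max(sd0, .Machine$double.eps)
  above <- force > thr
  # first index from which the force stays above threshold
  run <- rev(cumprod(rev(above)))
  first <- which(run == 1)[1]
  if (is.na(first)) {
    return(list(contact_z = NA_real_, valid = FALSE, threshold = thr))
  }
  # refine by piecewise fit: baseline then beta * (z - z0)^(3/2)
  n <- length(z)
  cand <- max(2L, first - 40L):min(n - 4L, first + 5L)
  best <- Inf
  j <- cand[1]
  for (k in cand) {
    mu_k <- mean(force[seq_len(k)])
    xk <- (z[(k + 1L):n] - z[k])^1.5
    fk <- force[(k + 1L):n] - mu_k
    beta <- sum(xk * fk) / sum(xk * xk)
    if (!is.finite(beta) || beta < 0) beta <- 0
    sse <- sum((force[seq_len(k)] - mu_k)^2) + sum((fk - beta * xk)^2)
    if (sse < best) {
      best <- sse
      j <- k
    }
  }
  list(contact_z = z[j], valid = TRUE, threshold = thr)
}

#' Fit the Hertz model to a force curve
#'
#' Least-squares estimate of the Young's modulus from samples with force
#' at most `max_force`. The model is linear in the reduced modulus when
#' parameterized as `F = beta * delta^(3/2)`, so the fit is the
#' closed-form no-intercept regression of F on `delta^(3/2)` and
#' `E = (3/4) * beta * (1 - nu^2) / sqrt(R)` -- no iterative optimizer is
#' involved. Curves with fewer than `min_points` usable samples return an
#' invalid fit rather than an error.
#'
#' @param curve A [force_curve()].
#' @param max_force Upper force bound in N for the fitted range (default
#'   16e-9, i.e. the ~16 nN setpoint).
#' @param nu Poisson's ratio; defaults to the curve's.
#' @param min_points Minimum usable samples (default 8).
#' @return Object of class `elasticity_fit`: list with `E` (Pa),
#'   `contact_point` (m, 0 for pre-aligned curves), `residual_rms` (N),
#'   `n_points_used`, `valid`, `position`.
#' @export
fit_hertz <- function(curve, max_force = 16e-9, nu = NULL,
                      min_points = 8L) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(nu)) nu <- curve$poisson
  stopifnot(nu >= 0, nu < 0.5)
  keep <- is.finite(curve$force) & is.finite(curve$delta) &
    curve$force <= max_force & curve$delta >= 0
  d <- curve$delta[keep]
  f <- curve$force[keep]
  x <- d^1.5
  usable <- sum(x > 0)
  if (usable < min_points) {
    return(invalid_fit(curve, sum(keep)))
  }
  beta <- sum(x * f) / sum(x * x)
  E <- 0.75 * beta * (1 - nu^2) / sqrt(curve$tip_radius)
  if (!is.finite(E) || E <= 0) {
    return(invalid_fit(curve, sum(keep)))
  }
  res <- f - beta * x
  structure(
    list(E = E, contact_point = 0, residual_rms = sqrt(mean(res^2)),
         n_points_used = length(f), valid = TRUE,
         position = curve$position),
    class = "elasticity_fit"
  )
}

invalid_fit <- function(curve, n) {
  structure(
    list(E = NA_real_, contact_point = NA_real_, residual_rms = NA_real_,
         n_points_used = n, valid = FALSE, position = curve$position),
    class = "elasticity_fit"
  )
}

#' @export
print.elasticity_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<elasticity_fit: E = %.4g kPa, %d points, rms %.2g nN>\n",
                x$E / 1000, x$n_points_used, x$residual_rms * 1e9))
  } else {
    cat("<elasticity_fit: invalid>\n")
  }
  invisible(x)
}

#' Assemble a stiffness map from gridded Hertz fits
#'
#' Places per-point fits on a regular lattice; invalid fits become
#' missing map entries.
#'
#' @param fits List of [fit_hertz()] results, each carrying a `position`
#'   `c(x, y)` in um on a regular lattice.
#' @param pitch Lattice spacing in um.
#' @return A [stiffness_map()].
#' @export
build_stiffness_map <- function(fits, pitch) {
  stopifnot(length(fits) >= 1L, pitch > 0)
  pos <- t(vapply(fits, function(f) {
    if (is.null(f$position)) {
      stop("every fit needs a grid `position` to build a map",
           call. = FALSE)
    }
    as.numeric(f$position)
  }, numeric(2)))
  key <- paste(round(pos[, 1] / pitch), round(pos[, 2] / pitch))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate grid positions: ", paste(dups, collapse = "; "),
         call. = FALSE)
  }
  ox <- min(pos[, 1]); oy <- min(pos[, 2])
  j <- round((pos[, 1] - ox) / pitch) + 1
  i <- round((pos[, 2] - oy) / pitch) + 1
  if (max(abs(pos[, 1] - (ox + (j - 1) * pitch))) > 1e-6 * pitch ||
      max(abs(pos[, 2] - (oy + (i - 1) * pitch))) > 1e-6 * pitch) {
    stop("fit positions do not lie on a regular lattice of the given pitch",
         call. = FALSE)
  }
  grid <- matrix(NA_real_, nrow = max(i), ncol = max(j))
  E <- vapply(fits, function(f) if (isTRUE(f$valid)) f$E else NA_real_,
              numeric(1))
  grid[cbind(i, j)] <- E
  stiffness_map(grid, pitch = pitch, origin = c(ox, oy),
                provenance = sprintf("Hertz fits, %d points", length(fits)))
}
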