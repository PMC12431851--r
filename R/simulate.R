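#' Simulate Hertzian force-indentation curves
#'
#' Generates seeded synthetic AFM force curves from the forward Hertz
#' model ([hertz_force()]) with multiplicative Gaussian force noise.
#' Indentation is sampled uniformly from zero to the depth at which the
#' noiseless force reaches `max_force` (the ~16 nN setpoint), so curves
#' resemble constant-force acquisitions. Ground truth is attached as the
#' `"truth"` attribute.
#'
#' @param n_curves Number of curves.
#' @param E_true True Young's modulus in Pa.
#' @param R Tip radius in m (default 2.5e-6).
#' @param nu Poisson's ratio (default 0.4).
#' @param n_samples Samples per curve (default 100).
#' @param noise_frac Multiplicative force noise SD (default 0.02).
#' @param max_force Force setpoint in N (default 16e-9).
#' @param seed Integer seed; identical seeds give identical curves.
#' @return List of [force_curve()] objects with a `"truth"` attribute
#'   (list of `E_true`, `R`, `nu`, `noise_frac`, `seed`).
#' @export
sim_force_curves <- function(n_curves, E_true, R = 2.5e-6, nu = 0.4,
                             n_samples = 100L, noise_frac = 0.02,
                             max_force = 16e-9, seed = 1L) {
  stopifnot(n_curves >= 1L, E_true > 0, noise_frac >= 0, n_samples >= 8L)
  beta <- (4 / 3) * E_true / (1 - nu^2) * sqrt(R)
  delta_max <- (max_force / beta)^(2 / 3)
  delta <- seq(0, delta_max, length.out = n_samples)
  f0 <- hertz_force(delta, E_true, nu, R)
  curves <- with_seed(seed, {
    lapply(seq_len(n_curves), function(k) {
      f <- f0 * (1 + stats::rnorm(n_samples, 0, noise_frac))
      force_curve(delta, f, tip_radius = R, poisson = nu)
    })
  })
  attr(curves, "truth") <- list(E_true = E_true, R = R, nu = nu,
                                noise_frac = noise_frac, seed = seed)
  curves
}

#' Simulate a raw approach trace with a pre-contact baseline
#'
#' Produces a z/force trace as acquired before contact-point alignment:
#' flat baseline noise before `contact_z`, Hertzian rise after. Used to
#' exercise [estimate_contact_point()] against known ground truth.
#'
#' @param E_true Young's modulus in Pa.
#' @param contact_z Tip-sample contact position in m.
#' @param z_max Final approach position in m.
#' @param n_samples Trace length.
#' @param noise_frac Noise SD as a fraction of the final force.
#' @param R,nu Probe constants.
#' @param seed Integer seed.
#' @return List with `z`, `force` (SI units) and `contact_z`.
#' @export
sim_indentation_trace <- function(E_true, contact_z, z_max,
                                  n_samples = 200L, noise_frac = 0.01,
                                  R = 2.5e-6, nu = 0.4, seed = 1L) {
  stopifnot(z_max > contact_z, contact_z >= 0, E_true > 0)
  z <- seq(0, z_max, length.out = n_samples)
  delta <- pmax(z - contact_z, 0)
  f <- hertz_force(delta, E_true, nu, R)
  fmax <- max(f)
  f <- with_seed(seed, f + stats::rnorm(n_samples, 0, noise_frac * fmax))
  list(z = z, force = f, contact_z = contact_z)
}

#' Simulate a healthy or fibrotic stiffness field
#'
#' Healthy fields are a uniform baseline plus a smooth low-amplitude
#' random undulation (broad Gaussian bumps), emulating the relatively
#' uniform stiffness of uninjured tissue. Fibrotic fields add focal
#' Gaussian peaks rising towards `peak_E` and valleys dropping towards
#' `valley_E`, emulating the focal stiff niches and soft pockets of
#' fibrotic tissue; focus centres are drawn with a minimum mutual
#' separation and border margin so each focus is an isolated extremum.
#' Planted foci are returned in the `"foci"` attribute.
#'
#' @param kind `"healthy"` or `"fibrotic"`.
#' @param extent Field extent `c(width, height)` um (default 80 x 80).
#' @param pitch Node spacing um (default 5, the AFM mapping pitch).
#' @param baseline Baseline modulus Pa (default 2000).
#' @param healthy_amp Amplitude of the smooth healthy undulation in Pa
#'   (default 300; 0 gives an exactly uniform map).
#' @param n_peaks,n_valleys Focus counts for fibrotic fields (3 and 2).
#' @param peak_E Peak ceiling in Pa (default 40000).
#' @param valley_E Valley floor in Pa (default 500).
#' @param focus_sigma Gaussian focus width in um (default 6).
#' @param noise_frac Multiplicative node noise SD (default 0.01).
#' @param seed Integer seed.
#' @return A [stiffness_map()] with attribute `"foci"`: data frame of
#'   `x`, `y`, `E`, `kind` for each planted focus (empty for healthy).
#' @export
sim_stiffness_field <- function(kind = c("healthy", "fibrotic"),
                                extent = c(80, 80), pitch = 5,
                                baseline = 2000, healthy_amp = 300,
                                n_peaks = 3L, n_valleys = 2L,
                                peak_E = 40000, valley_E = 500,
                                focus_sigma = 6, noise_frac = 0.01,
                                seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(all(extent > 0), pitch > 0, baseline > 0,
            valley_E > 0, peak_E > baseline)
  xs <- seq(0, extent[1], by = pitch)
  ys <- seq(0, extent[2], by = pitch)
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  with_seed(seed, {
    g <- matrix(baseline, nrow = length(ys), ncol = length(xs))
    foci <- data.frame(x = numeric(0), y = numeric(0), E = numeric(0),
                       kind = character(0))
    if (kind == "healthy") {
      if (healthy_amp > 0) {
        for (k in seq_len(4)) {
          cx <- stats::runif(1, 0, extent[1])
          cy <- stats::runif(1, 0, extent[2])
          amp <- stats::runif(1, -healthy_amp, healthy_amp)
          sg <- max(extent) / 3
          g <- g + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
        }
      }
    } else {
      n_foci <- n_peaks + n_valleys
      ctr <- place_separated(n_foci, extent,
                             margin = 1.5 * focus_sigma,
                             min_sep = 3 * focus_sigma)
      kinds <- c(rep("peak", n_peaks), rep("valley", n_valleys))
      for (k in seq_len(n_foci)) {
        if (kinds[k] == "peak") {
          amp <- stats::runif(1, 0.6, 1) * (peak_E - baseline)
        } else {
          amp <- -stats::runif(1, 0.6, 1) * (baseline - valley_E)
        }
        g <- g + amp *
          exp(-((X - ctr[k, 1])^2 + (Y - ctr[k, 2])^2) / (2 * focus_sigma^2))
        foci <- rbind(foci, data.frame(x = ctr[k, 1], y = ctr[k, 2],
                                       E = baseline + amp,
                                       kind = kinds[k]))
      }
    }
    if (noise_frac > 0 && !(kind == "healthy" && healthy_amp == 0)) {
      g <- g * (1 + matrix(stats::rnorm(length(g), 0, noise_frac),
                           nrow = nrow(g)))
    }
    g <- pmax(g, valley_E / 2)
    out <- stiffness_map(g, pitch = pitch,
                         provenance = sprintf("simulated %s field, seed %d",
                                              kind, seed))
    attr(out, "foci") <- foci
    out
  })
}

# rejection-sample n points with a border margin and minimum separation
place_separated <- function(n, extent, margin, min_sep,
                            max_tries = 2000L) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  for (k in seq_len(max_tries)) {
    p <- c(stats::runif(1, margin, extent[1] - margin),
           stats::runif(1, margin, extent[2] - margin))
    ok <- got == 0L ||
      min(sqrt(rowSums((pts[seq_len(got), , drop = FALSE] -
                          matrix(p, got, 2, byrow = TRUE))^2))) >= min_sep
    if (ok) {
      got <- got + 1L
      pts[got, ] <- p
      if (got == n) return(pts)
    }
  }
  stop("could not place ", n, " separated foci in the given extent",
       call. = FALSE)
}

#' Simulate persistent (optionally gradient-biased) random-walk tracks
#'
#' A persistent random walk with Ornstein-Uhlenbeck-style heading
#' persistence: each frame the heading receives Gaussian rotational
#' noise of variance `2 * dt / persistence_time` plus a deterministic
#' torque towards the local stiffness-gradient direction,
#' `w * sin(phi_grad - theta)` with saturating weight
#' `w = bias_strength / (1 + bias_strength) * |grad| / (grad_half +
#' |grad|)` (both factors saturate below 1, keeping the heading
#' relaxation stable at any gain). On plateaus and
#' uniform substrates the gradient is zero, so any `bias_strength`
#' reduces to the unbiased walk. Walkers reflect at the substrate
#' boundary. The bias coupling is an explicit phenomenological stand-in
#' for mechanosensing, not a molecular-clutch model.
#'
#' @param pattern A [substrate_pattern()] the walkers move on.
#' @param n_tracks Number of walkers (default 75, a typical tracked-cell
#'   count per field).
#' @param duration Recording duration in s (default 21600, i.e. 6 h).
#' @param dt Frame interval in s (default 300, i.e. 5 min).
#' @param speed_mean Mean instantaneous speed in um/min (default 0.5).
#' @param speed_cv Coefficient of variation of per-step speeds (0.1).
#' @param persistence_time Heading persistence time in s (default 1800).
#' @param bias_strength Dimensionless gradient-coupling strength (>= 0;
#'   0 gives an unbiased persistent walk).
#' @param grad_half Gradient magnitude at half-saturation, Pa/um (10).
#' @param seed Integer seed.
#' @return Tidy track table (`track_id`, `t`, `x`, `y`) with a `"truth"`
#'   attribute recording the generator configuration.
#' @export
sim_tracks <- function(pattern, n_tracks = 75L, duration = 21600,
                       dt = 300, speed_mean = 0.5, speed_cv = 0.1,
                       persistence_time = 1800, bias_strength = 0,
                       grad_half = 10, seed = 1L) {
  stopifnot(inherits(pattern, "substrate_pattern"), n_tracks >= 1L,
            duration > dt, dt > 0, speed_mean > 0, persistence_time > 0,
            bias_strength >= 0)
  n_steps <- floor(duration / dt)
  ext <- pattern$extent
  sig_theta <- sqrt(2 * dt / persistence_time)
  with_seed(seed, {
    x <- stats::runif(n_tracks, 0, ext[1])
    y <- stats::runif(n_tracks, 0, ext[2])
    theta <- stats::runif(n_tracks, -pi, pi)
    X <- matrix(NA_real_, n_steps + 1L, n_tracks)
    Y <- matrix(NA_real_, n_steps + 1L, n_tracks)
    X[1, ] <- x; Y[1, ] <- y
    for (s in seq_len(n_steps)) {
      grad <- local_gradient(pattern, cbind(x, y))
      gmag <- sqrt(grad[, 1]^2 + grad[, 2]^2)
      # both factors saturate in [0, 1); w < 1 keeps the heading
      # relaxation contractive (no overshoot past the gradient direction)
      w <- bias_strength / (1 + bias_strength) * gmag / (grad_half + gmag)
      phi <- atan2(grad[, 2], grad[, 1])
      torque <- ifelse(gmag > 0, w * sin(phi - theta), 0)
      theta <- theta + torque + stats::rnorm(n_tracks, 0, sig_theta)
      sp <- speed_mean * pmax(1 + stats::rnorm(n_tracks, 0, speed_cv), 0.05)
      step <- sp * dt / 60
      x <- x + step * cos(theta)
      y <- y + step * sin(theta)
      # reflecting boundaries
      fx <- x < 0 | x > ext[1]
      fy <- y < 0 | y > ext[2]
      x[x < 0] <- -x[x < 0]
      x[x > ext[1]] <- 2 * ext[1] - x[x > ext[1]]
      y[y < 0] <- -y[y < 0]
      y[y > ext[2]] <- 2 * ext[2] - y[y > ext[2]]
      theta[fx] <- pi - theta[fx]
      theta[fy] <- -theta[fy]
      X[s + 1L, ] <- x; Y[s + 1L, ] <- y
    }
    out <- data.frame(
      track_id = rep(sprintf("w%03d", seq_len(n_tracks)),
                     each = n_steps + 1L),
      t = rep((0:n_steps) * dt, times = n_tracks),
      x = as.numeric(X), y = as.numeric(Y))
    out <- as_track_table(out)
    attr(out, "truth") <- list(bias_strength = bias_strength,
                               speed_mean = speed_mean, dt = dt,
                               persistence_time = persistence_time,
                               grad_half = grad_half, seed = seed)
    out
  })
}

#' Simulate a per-animal photon-flux table
#'
#' Log-normal primary-tumour fluxes; each animal's total metastatic flux
#' is a gamma-distributed fraction of its primary (mean
#' `metastatic_fraction_mean`), split across the metastatic sites by
#' uniform random proportions. The realized per-animal index (metastatic
#' over primary flux) is returned as ground truth.
#'
#' @param n_animals Number of animals (>= 1).
#' @param metastatic_fraction_mean Mean metastatic/primary flux ratio
#'   (0 gives all-zero metastatic flux).
#' @param fraction_cv Coefficient of variation of the ratio (0.5).
#' @param sites Metastatic site labels (default `c("liver", "lung")`).
#' @param primary_meanlog,primary_sdlog Log-normal parameters of the
#'   primary flux (defaults `log(1e7)` and 0.5).
#' @param seed Integer seed.
#' @return List with `flux` (data frame `animal_id`, `site`,
#'   `photon_flux`) and `truth` (data frame `animal_id`, `index`).
#' @export
sim_flux_table <- function(n_animals = 8L, metastatic_fraction_mean = 0.2,
                           fraction_cv = 0.5, sites = c("liver", "lung"),
                           primary_meanlog = log(1e7),
                           primary_sdlog = 0.5, seed = 1L) {
  stopifnot(n_animals >= 1L, metastatic_fraction_mean >= 0)
  with_seed(seed, {
    ids <- sprintf("m%02d", seq_len(n_animals))
    prim <- stats::rlnorm(n_animals, primary_meanlog, primary_sdlog)
    if (metastatic_fraction_mean > 0) {
      shape <- 1 / fraction_cv^2
      frac <- stats::rgamma(n_animals, shape = shape,
                            rate = shape / metastatic_fraction_mean)
    } else {
      frac <- rep(0, n_animals)
    }
    rows <- lapply(seq_len(n_animals), function(k) {
      met_total <- frac[k] * prim[k]
      prop <- stats::runif(length(sites))
      prop <- prop / sum(prop)
      data.frame(animal_id = ids[k],
                 site = c("primary", sites),
                 photon_flux = c(prim[k], met_total * prop))
    })
    list(flux = do.call(rbind, rows),
         truth = data.frame(animal_id = ids, index = frac))
  })
}

#' Simulate collagen-fibre centerlines
#'
#' `"straight_aligned"` fibres are near-linear polylines sharing a
#' dominant axis with a small per-fibre angular jitter and larger widths
#' (the stiff, aligned phenotype of an invasive front);
#' `"curly"` fibres are random-walk polylines with dispersed initial
#' orientations and thinner widths (the wavy, anisotropic phenotype of a
#' tumour core). Generator parameters are attached as `"truth"`.
#'
#' @param style `"curly"` or `"straight_aligned"`.
#' @param n Number of fibres.
#' @param length_um Contour length per fibre in um (default 50).
#' @param n_points Points per centerline (default 40).
#' @param axis_deg Dominant axis for aligned fibres, degrees (default 0).
#' @param axis_jitter_deg SD of per-fibre axis jitter, degrees (5).
#' @param wiggle Per-step heading noise SD in radians
#'   (default 0.02 aligned / 0.6 curly; 0 gives exactly straight fibres).
#' @param width_mean,width_sd Fibre width distribution in um (defaults
#'   3 +- 0.5 aligned, 1.5 +- 0.3 curly).
#' @param seed Integer seed.
#' @return List of fibre data frames (`x`, `y`, `width` attribute) with
#'   a `"truth"` attribute.
#' @export
sim_fibers <- function(style = c("curly", "straight_aligned"), n = 100L,
                       length_um = 50, n_points = 40L, axis_deg = 0,
                       axis_jitter_deg = 5, wiggle = NULL,
                       width_mean = NULL, width_sd = NULL, seed = 1L) {
  style <- match.arg(style)
  stopifnot(n >= 1L, length_um > 0, n_points >= 2L)
  if (is.null(wiggle)) wiggle <- if (style == "curly") 0.6 else 0.02
  if (is.null(width_mean)) width_mean <- if (style == "curly") 1.5 else 3
  if (is.null(width_sd)) width_sd <- if (style == "curly") 0.3 else 0.5
  step <- length_um / (n_points - 1L)
  with_seed(seed, {
    fibers <- lapply(seq_len(n), function(k) {
      th0 <- if (style == "curly") {
        stats::runif(1, -pi, pi)
      } else {
        deg2rad(axis_deg + stats::rnorm(1, 0, axis_jitter_deg))
      }
      dth <- if (wiggle > 0) {
        stats::rnorm(n_points - 1L, 0, wiggle)
      } else {
        rep(0, n_points - 1L)
      }
      th <- th0 + cumsum(dth)
      x <- c(0, cumsum(step * cos(th)))
      y <- c(0, cumsum(step * sin(th)))
      f <- data.frame(x = x, y = y)
      f$width <- max(0.1, stats::rnorm(1, width_mean, width_sd))
      f
    })
    attr(fibers, "truth") <- list(style = style, wiggle = wiggle,
                                  axis_deg = axis_deg,
                                  axis_jitter_deg = axis_jitter_deg,
                                  width_mean = width_mean, seed = seed)
    fibers
  })
}
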