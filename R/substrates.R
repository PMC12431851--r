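#' Parametric stiffness-patterned substrate
#'
#' Constructs an in-silico model of a mechanically patterned hydrogel as a
#' continuous stiffness field E(x, y) in pascals over a rectangular extent
#' in micrometres. Five kinds are supported:
#'
#' * `"step_stripes"`: alternating soft and stiff stripes along x with a
#'   linear transition ramp of width `transition_width` between them (the
#'   photolithographic "step" hydrogel; with 4 and 40 kPa stripes and a
#'   40 um transition the nominal gradient is 900 Pa/um).
#' * `"linear_gradient"`: a single linear ramp from `E_soft` to `E_stiff`
#'   over `transition_width` starting at x = 0 (the microfluidic shallow
#'   gradient; 4-40 kPa over 1000 um gives 36 Pa/um), clamped to the
#'   plateau moduli outside the ramp.
#' * `"island"`: a circular soft island of radius `island_radius` centred
#'   in the extent, blended over `transition_width` into a surrounding
#'   striped field (tumour-stroma interface mimic).
#' * `"uniform"`: constant `E_soft` everywhere.
#' * `"field"`: stiffness interpolated bilinearly from a measured
#'   [stiffness_map()] given in `field_grid`.
#'
#' Coordinates are continuous 2-D micrometres, origin at the lower-left
#' corner, with the gradient axis along +x by convention.
#'
#' @param kind One of `"step_stripes"`, `"linear_gradient"`, `"island"`,
#'   `"uniform"`, `"field"`.
#' @param E_soft,E_stiff Soft and stiff plateau Young's moduli in Pa
#'   (`E_stiff >= E_soft > 0`).
#' @param stripe_width_stiff,stripe_width_soft Plateau stripe widths in um
#'   (defaults 100 and 200, the photomask geometry).
#' @param transition_width Width of the linear stiffness ramp in um
#'   (default 40; for `"linear_gradient"` this is the full ramp length).
#' @param extent Numeric length-2, substrate width and height in um.
#' @param island_radius Island radius in um (island kind only).
#' @param field_grid A [stiffness_map()] (field kind only).
#' @return An object of class `substrate_pattern`.
#' @examples
#' p <- substrate_pattern("step_stripes", E_soft = 4000, E_stiff = 40000)
#' nominal_gradient(p)  # 900 Pa/um
#' @export
substrate_pattern <- function(kind = c("step_stripes", "linear_gradient",
                                       "island", "uniform", "field"),
                              E_soft = 4000, E_stiff = 40000,
                              stripe_width_stiff = 100,
                              stripe_width_soft = 200,
                              transition_width = 40,
                              extent = c(1000, 1000),
                              island_radius = NULL,
                              field_grid = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") E_stiff <- E_soft
  stopifnot(E_soft > 0, E_stiff >= E_soft, transition_width > 0,
            stripe_width_stiff > 0, stripe_width_soft > 0,
            length(extent) == 2L, all(extent > 0))
  if (kind == "island") {
    if (is.null(island_radius) || island_radius <= 0) {
      stop("island kind requires a positive `island_radius`", call. = FALSE)
    }
  }
  if (kind == "field") {
    if (!inherits(field_grid, "stiffness_map")) {
      stop("field kind requires `field_grid` to be a stiffness_map",
           call. = FALSE)
    }
  }
  structure(
    list(kind = kind, E_soft = E_soft, E_stiff = E_stiff,
         stripe_width_stiff = stripe_width_stiff,
         stripe_width_soft = stripe_width_soft,
         transition_width = transition_width,
         extent = as.numeric(extent),
         island_radius = island_radius,
         field_grid = field_grid),
    class = "substrate_pattern"
  )
}

#' @export
print.substrate_pattern <- function(x, ...) {
  cat(sprintf("<substrate_pattern: %s>\n", x$kind))
  cat(sprintf("  E: %.3g - %.3g kPa over %g x %g um\n",
              x$E_soft / 1000, x$E_stiff / 1000, x$extent[1], x$extent[2]))
  if (x$kind %in% c("step_stripes", "island")) {
    cat(sprintf("  stripes: stiff %g um / soft %g um, transition %g um\n",
                x$stripe_width_stiff, x$stripe_width_soft,
                x$transition_width))
  }
  if (x$kind %in% c("step_stripes", "linear_gradient")) {
    cat(sprintf("  nominal gradient: %g Pa/um\n", nominal_gradient(x)))
  }
  invisible(x)
}

# points as n x 2 matrix
as_points <- function(point) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2, byrow = TRUE)
  stopifnot(ncol(point) == 2L)
  point
}

check_in_extent <- function(pattern, pts) {
  bad <- pts[, 1] < 0 | pts[, 1] > pattern$extent[1] |
    pts[, 2] < 0 | pts[, 2] > pattern$extent[2]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) is outside the pattern extent %g x %g um",
                 pts[i, 1], pts[i, 2], pattern$extent[1], pattern$extent[2]),
         call. = FALSE)
  }
}

stripe_period <- function(pattern) {
  pattern$stripe_width_soft + pattern$stripe_width_stiff +
    2 * pattern$transition_width
}

# stripe profile value and x-derivative at phase positions (vectorized)
stripe_profile <- function(pattern, x) {
  p <- stripe_period(pattern)
  ws <- pattern$stripe_width_soft
  wt <- pattern$transition_width
  wf <- pattern$stripe_width_stiff
  dE <- pattern$E_stiff - pattern$E_soft
  ph <- x %% p
  E <- numeric(length(ph))
  g <- numeric(length(ph))
  soft <- ph < ws
  rise <- ph >= ws & ph < ws + wt
  stiff <- ph >= ws + wt & ph < ws + wt + wf
  fall <- ph >= ws + wt + wf
  E[soft] <- pattern$E_soft
  E[rise] <- pattern$E_soft + dE * (ph[rise] - ws) / wt
  E[stiff] <- pattern$E_stiff
  E[fall] <- pattern$E_stiff - dE * (ph[fall] - ws - wt - wf) / wt
  g[rise] <- dE / wt
  g[fall] <- -dE / wt
  list(E = E, g = g, phase = ph)
}

#' Stiffness at a point of a patterned substrate
#'
#' @param pattern A [substrate_pattern()].
#' @param point Numeric `c(x, y)` in um, or an n x 2 matrix of points.
#' @return Young's modulus in Pa (vector of length n). Always within
#'   `[E_soft, E_stiff]` for in-extent points.
#' @examples
#' p <- substrate_pattern("linear_gradient", 4000, 40000,
#'                        transition_width = 1000)
#' stiffness_at(p, c(250, 50))  # 13 kPa
#' @export
stiffness_at <- function(pattern, point) {
  stopifnot(inherits(pattern, "substrate_pattern"))
  pts <- as_points(point)
  check_in_extent(pattern, pts)
  switch(pattern$kind,
    uniform = rep(pattern$E_soft, nrow(pts)),
    step_stripes = stripe_profile(pattern, pts[, 1])$E,
    linear_gradient = {
      g <- (pattern$E_stiff - pattern$E_soft) / pattern$transition_width
      pmin(pattern$E_stiff, pmax(pattern$E_soft,
                                 pattern$E_soft + g * pts[, 1]))
    },
    island = island_value(pattern, pts),
    field = map_interp(pattern$field_grid, pts[, 1], pts[, 2])
  )
}

island_value <- function(pattern, pts) {
  base <- stripe_profile(pattern, pts[, 1])$E
  ctr <- pattern$extent / 2
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  r <- pattern$island_radius
  wt <- pattern$transition_width
  # blend weight: 0 inside the island core, 1 outside the rim
  w <- pmin(1, pmax(0, (d - (r - wt)) / wt))
  pattern$E_soft + w * (base - pattern$E_soft)
}

#' Nominal stiffness gradient of a patterned substrate
#'
#' The engineered gradient magnitude `(E_stiff - E_soft) / transition
#' distance` in Pa/um: 900 Pa/um for the 4-40 kPa step stripes with a
#' 40 um transition, 36 Pa/um for the 4-40 kPa ramp over 1000 um.
#'
#' @param pattern A [substrate_pattern()] with a defined transition
#'   (`step_stripes`, `linear_gradient` or `island`).
#' @return Gradient in Pa/um.
#' @export
nominal_gradient <- function(pattern) {
  stopifnot(inherits(pattern, "substrate_pattern"))
  if (pattern$kind %in% c("uniform", "field")) {
    stop(sprintf("nominal_gradient is undefined for kind '%s'",
                 pattern$kind), call. = FALSE)
  }
  (pattern$E_stiff - pattern$E_soft) / pattern$transition_width
}

#' Local spatial gradient of the stiffness field
#'
#' Analytic gradient of E at a point for the parametric kinds; central
#' finite differences for `island` and `field` kinds. Zero on plateaus;
#' magnitude equals [nominal_gradient()] inside a transition band.
#'
#' @param pattern A [substrate_pattern()].
#' @param point `c(x, y)` um or n x 2 matrix.
#' @param h Finite-difference half-step in um for non-analytic kinds.
#' @return n x 2 matrix of (dE/dx, dE/dy) in Pa/um (a length-2 vector for
#'   a single point is returned as a 1 x 2 matrix).
#' @export
local_gradient <- function(pattern, point, h = 0.05) {
  stopifnot(inherits(pattern, "substrate_pattern"))
  pts <- as_points(point)
  check_in_extent(pattern, pts)
  n <- nrow(pts)
  out <- switch(pattern$kind,
    uniform = matrix(0, n, 2),
    step_stripes = cbind(stripe_profile(pattern, pts[, 1])$g, 0),
    linear_gradient = {
      g <- (pattern$E_stiff - pattern$E_soft) / pattern$transition_width
      gx <- ifelse(pts[, 1] <= pattern$transition_width, g, 0)
      cbind(gx, 0)
    },
    fd_gradient(pattern, pts, h)
  )
  colnames(out) <- c("dx", "dy")
  out
}

fd_gradient <- function(pattern, pts, h) {
  clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))
  gx <- gy <- numeric(nrow(pts))
  x1 <- clamp(pts[, 1] - h, 0, pattern$extent[1])
  x2 <- clamp(pts[, 1] + h, 0, pattern$extent[1])
  y1 <- clamp(pts[, 2] - h, 0, pattern$extent[2])
  y2 <- clamp(pts[, 2] + h, 0, pattern$extent[2])
  gx <- (stiffness_at(pattern, cbind(x2, pts[, 2])) -
           stiffness_at(pattern, cbind(x1, pts[, 2]))) / (x2 - x1)
  gy <- (stiffness_at(pattern, cbind(pts[, 1], y2)) -
           stiffness_at(pattern, cbind(pts[, 1], y1))) / (y2 - y1)
  cbind(gx, gy)
}

#' Region label of a point on a patterned substrate
#'
#' Assigns each point to the soft plateau, the stiff plateau or the
#' transition band. Under the default rule (`"exclude"`) transition points
#' keep the label `"transition"` so that downstream counts can exclude
#' them; under `"midpoint"` a transition point is labelled `"stiff"` iff
#' its stiffness lies strictly past the midpoint `(E_soft + E_stiff)/2`.
#'
#' @param pattern A [substrate_pattern()].
#' @param point `c(x, y)` um or n x 2 matrix.
#' @param rule `"exclude"` (default) or `"midpoint"`.
#' @return Character vector of labels in `{"soft", "stiff", "transition"}`.
#' @export
region_of <- function(pattern, point, rule = c("exclude", "midpoint")) {
  stopifnot(inherits(pattern, "substrate_pattern"))
  rule <- match.arg(rule)
  pts <- as_points(point)
  E <- stiffness_at(pattern, pts)  # checks extent
  eps <- 1e-9 * max(pattern$E_stiff, 1)
  lab <- rep("transition", length(E))
  lab[E <= pattern$E_soft + eps] <- "soft"
  lab[E >= pattern$E_stiff - eps] <- "stiff"
  if (pattern$kind == "uniform") lab[] <- "soft"
  if (rule == "midpoint") {
    mid <- (pattern$E_soft + pattern$E_stiff) / 2
    tr <- lab == "transition"
    lab[tr] <- ifelse(E[tr] > mid, "stiff", "soft")
  }
  lab
}

#' Rasterize a substrate pattern to a stiffness map
#'
#' Samples E(x, y) on a regular lattice of node spacing `pitch` um
#' (nodes at `origin + i * pitch`, 0-based), returning a
#' [stiffness_map()].
#'
#' @param pattern A [substrate_pattern()].
#' @param pitch Lattice spacing in um.
#' @return A [stiffness_map()] spanning the pattern extent.
#' @export
rasterize_pattern <- function(pattern, pitch) {
  stopifnot(inherits(pattern, "substrate_pattern"), pitch > 0)
  xs <- seq(0, pattern$extent[1], by = pitch)
  ys <- seq(0, pattern$extent[2], by = pitch)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  E <- stiffness_at(pattern, pts)
  grid <- matrix(E, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  stiffness_map(grid, pitch = pitch,
                provenance = sprintf("rasterized %s pattern", pattern$kind))
}
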