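#' Stiffness profile along a transect
#'
#' Samples a [stiffness_map()] by bilinear interpolation at regular steps
#' along the segment from `start` to `end`. Cells with missing values
#' propagate as `NA` gaps in the profile.
#'
#' @param map A [stiffness_map()].
#' @param start,end Transect endpoints `c(x, y)` in um, inside the map
#'   extent.
#' @param step Sampling interval along the transect in um (default half
#'   the map pitch).
#' @return A `gradient_profile`: data frame with columns `distance` (um)
#'   and `E` (Pa), plus `start`/`end` attributes.
#' @export
profile_along_transect <- function(map, start, end, step = map$pitch / 2) {
  stopifnot(inherits(map, "stiffness_map"), length(start) == 2L,
            length(end) == 2L, step > 0)
  len <- sqrt(sum((end - start)^2))
  if (len == 0) {
    d <- 0
  } else {
    d <- seq(0, len, by = step)
    if (d[length(d)] < len - 1e-9) d <- c(d, len)
  }
  u <- if (len > 0) (end - start) / len else c(0, 0)
  xs <- start[1] + d * u[1]
  ys <- start[2] + d * u[2]
  E <- map_interp(map, xs, ys)  # errors if outside extent
  out <- data.frame(distance = d, E = E)
  attr(out, "start") <- as.numeric(start)
  attr(out, "end") <- as.numeric(end)
  class(out) <- c("gradient_profile", "data.frame")
  out
}

#' Extract transect slopes between consecutive profile extrema
#'
#' Splits a stiffness-distance profile into its maximal monotone runs
#' (flat stretches break runs; `NA` gaps split the profile) and returns
#' one least-squares slope magnitude per run, in Pa/um. A constant
#' profile yields an empty vector. Runs shorter than 3 points are
#' discarded.
#'
#' @param profile A [profile_along_transect()] result, or any data frame
#'   with `distance` and `E` columns.
#' @param smooth Odd moving-average window for optional pre-smoothing
#'   (default 1 = off).
#' @return Numeric vector of slope magnitudes (Pa/um).
#' @export
extract_slopes <- function(profile, smooth = 1L) {
  stopifnot(all(c("distance", "E") %in% names(profile)))
  d <- profile$distance
  E <- profile$E
  if (length(d) < 3L) return(numeric(0))
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    Es <- stats::filter(E, k, sides = 2)
    E <- ifelse(is.na(Es), E, as.numeric(Es))
  }
  # split at NA gaps
  ok <- is.finite(E)
  grp <- cumsum(!ok)
  slopes <- numeric(0)
  for (g in unique(grp[ok])) {
    sel <- ok & grp == g
    slopes <- c(slopes, run_slopes(d[sel], E[sel]))
  }
  slopes
}

run_slopes <- function(d, E) {
  n <- length(E)
  if (n < 3L) return(numeric(0))
  dif <- diff(E)
  tol <- 1e-12 * max(abs(E), 1)
  s <- sign(dif)
  s[abs(dif) <= tol] <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(s)) {
    if (s[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
    # run covers points i .. j+1
    if (j + 1L - i + 1L >= 3L) {
      dd <- d[i:(j + 1L)]
      ee <- E[i:(j + 1L)]
      b <- stats::cov(dd, ee) / stats::var(dd)
      out <- c(out, abs(b))
    }
    i <- j + 1L
  }
  out
}

#' Average stiffness-gradient slope of an elastograph
#'
#' The per-sample gradient statistic: seeded random transects are drawn
#' across the map, each anchored at a uniform random in-extent point and
#' oriented along the local steepest-ascent direction of the interpolated
#' field, extended to the map boundary in both directions. Slopes are
#' extracted per monotone run ([extract_slopes()]) and pooled until
#' `n_slopes` are collected (or the transect budget is exhausted); the
#' summary is the mean slope magnitude. Fully reproducible given `seed`.
#' A map with no spatial variation returns an average of 0 with zero
#' slopes collected.
#'
#' @param map A [stiffness_map()].
#' @param n_slopes Number of slopes to accumulate (default 50, the
#'   per-sample count used for tissue elastographs).
#' @param seed Integer RNG seed.
#' @param step Profile sampling interval in um (default `pitch / 2`).
#' @param max_transects Transect budget (default `20 * n_slopes`).
#' @return A `slope_summary`: list with `slopes` (Pa/um), `average_slope`
#'   (mean magnitude), `n_slopes`, `n_transects_used` and `seed`.
#' @export
average_slope <- function(map, n_slopes = 50L, seed = 1L,
                          step = map$pitch / 2,
                          max_transects = 20L * n_slopes) {
  stopifnot(inherits(map, "stiffness_map"), n_slopes >= 1L)
  if (sum(is.finite(map$grid)) < 2L) {
    stop("map needs at least 2 finite cells", call. = FALSE)
  }
  ext <- map_extent(map)
  o <- map$origin
  gscale <- max(abs(range(map$grid, na.rm = TRUE)))
  slopes <- numeric(0)
  used <- 0L
  with_seed(seed, {
    while (length(slopes) < n_slopes && used < max_transects) {
      used <- used + 1L
      a <- o + stats::runif(2) * ext
      g <- map_gradient_fd(map, a, h = map$pitch / 2)
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < 1e-9 * max(gscale, 1) / max(ext)) next
      u <- g / gn
      ends <- clip_ray_to_rect(a, u, o, o + ext)
      prof <- try(profile_along_transect(map, ends$p1, ends$p2, step),
                  silent = TRUE)
      if (inherits(prof, "try-error")) next
      slopes <- c(slopes, extract_slopes(prof))
    }
  })
  if (length(slopes) > n_slopes) slopes <- slopes[seq_len(n_slopes)]
  structure(
    list(slopes = slopes,
         average_slope = if (length(slopes)) mean(slopes) else 0,
         n_slopes = length(slopes), n_transects_used = used,
         seed = as.integer(seed)),
    class = "slope_summary"
  )
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf(
    "<slope_summary: average %.4g Pa/um from %d slopes (%d transects, seed %d)>\n",
    x$average_slope, x$n_slopes, x$n_transects_used, x$seed))
  invisible(x)
}

# central-difference gradient of the interpolated field at point p (um)
map_gradient_fd <- function(map, p, h) {
  ext <- map_extent(map)
  o <- map$origin
  cl <- function(v, lo, hi) min(max(v, lo), hi)
  x1 <- cl(p[1] - h, o[1], o[1] + ext[1]); x2 <- cl(p[1] + h, o[1], o[1] + ext[1])
  y1 <- cl(p[2] - h, o[2], o[2] + ext[2]); y2 <- cl(p[2] + h, o[2], o[2] + ext[2])
  gx <- if (x2 > x1) {
    (map_interp(map, x2, p[2]) - map_interp(map, x1, p[2])) / (x2 - x1)
  } else 0
  gy <- if (y2 > y1) {
    (map_interp(map, p[1], y2) - map_interp(map, p[1], y1)) / (y2 - y1)
  } else 0
  c(gx, gy)
}

# intersect the line through `a` with direction `u` with rectangle
# [lo, hi]; returns the two boundary points
clip_ray_to_rect <- function(a, u, lo, hi) {
  ts <- c()
  for (dim in 1:2) {
    if (abs(u[dim]) > 1e-12) {
      ts <- c(ts, (lo[dim] - a[dim]) / u[dim], (hi[dim] - a[dim]) / u[dim])
    }
  }
  pts <- lapply(ts, function(t) a + t * u)
  inside <- vapply(pts, function(p) {
    all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
  }, logical(1))
  ts <- ts[inside]
  t1 <- min(ts); t2 <- max(ts)
  clamp <- function(p) pmin(pmax(p, lo), hi)
  list(p1 = clamp(a + t1 * u), p2 = clamp(a + t2 * u))
}

#' Detect focal stiffness peaks and valleys
#'
#' Local maxima ("peaks") and minima ("valleys") of the (optionally
#' smoothed) stiffness field whose deviation from the map median exceeds
#' `min_prominence`. A node is a local extremum when it is strictly more
#' extreme than all of its 8 neighbours. Results are sorted by decreasing
#' `|E - median|`.
#'
#' @param map A [stiffness_map()] with at least 9 finite cells.
#' @param min_prominence Minimum `|E - median(map)|` in Pa (default 0).
#' @param smooth Odd moving-average window applied to the grid before
#'   detection (default 1 = off).
#' @return Data frame with columns `x`, `y` (um), `E` (Pa), `kind`
#'   (`"peak"`/`"valley"`); zero rows when no extremum qualifies.
#' @export
detect_peaks_valleys <- function(map, min_prominence = 0, smooth = 1L) {
  stopifnot(inherits(map, "stiffness_map"))
  g <- map$grid
  if (sum(is.finite(g)) < 9L) {
    stop("map needs at least 9 finite cells", call. = FALSE)
  }
  if (smooth > 1L) g <- smooth_grid(g, smooth)
  nr <- nrow(g); nc <- ncol(g)
  med <- stats::median(g, na.rm = TRUE)
  res <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- g[i, j]
      if (!is.finite(v)) next
      ni <- max(1, i - 1):min(nr, i + 1)
      nj <- max(1, j - 1):min(nc, j + 1)
      nbv <- setdiff_once(g[ni, nj], v)
      if (!length(nbv)) next
      kind <- if (all(v > nbv)) "peak" else if (all(v < nbv)) "valley" else NA
      if (is.na(kind)) next
      if (abs(v - med) < min_prominence) next
      res[[length(res) + 1L]] <- data.frame(
        x = map$origin[1] + (j - 1) * map$pitch,
        y = map$origin[2] + (i - 1) * map$pitch,
        E = map$grid[i, j], kind = kind, prominence = abs(v - med))
    }
  }
  if (!length(res)) {
    return(data.frame(x = numeric(0), y = numeric(0), E = numeric(0),
                      kind = character(0), prominence = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(-out$prominence), , drop = FALSE]
}

# neighbourhood values with the centre value removed exactly once
setdiff_once <- function(block, v) {
  vals <- as.numeric(block)
  vals <- vals[is.finite(vals)]
  hit <- which(vals == v)[1]
  if (!is.na(hit)) vals <- vals[-hit]
  vals
}

smooth_grid <- function(g, k) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1) / 2
  nr <- nrow(g); nc <- ncol(g)
  out <- g
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- g[max(1, i - half):min(nr, i + half),
               max(1, j - half):min(nc, j + half)]
      out[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  out
}
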