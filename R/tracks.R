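#' Validate a tidy track table
#'
#' Tracks are stored tidily: one data frame with columns `track_id`,
#' `t` (s), `x`, `y` (um), one row per observation, times strictly
#' increasing within each track and at least two points per track.
#'
#' @param tracks Data frame with columns `track_id`, `t`, `x`, `y`.
#' @return The validated data frame (invisibly classed `track_table`).
#' @export
as_track_table <- function(tracks) {
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    stop("track table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tracks) == 0) {
    class(tracks) <- unique(c("track_table", class(tracks)))
    return(tracks)
  }
  tracks <- tracks[order(tracks$track_id, tracks$t), , drop = FALSE]
  for (id in unique(tracks$track_id)) {
    tt <- tracks$t[tracks$track_id == id]
    if (length(tt) < 2L) {
      stop(sprintf("track '%s' has fewer than 2 points", id), call. = FALSE)
    }
    if (any(diff(tt) <= 0)) {
      row <- which(diff(tt) <= 0)[1] + 1L
      stop(sprintf("track '%s': time not strictly increasing at point %d",
                   id, row), call. = FALSE)
    }
  }
  class(tracks) <- unique(c("track_table", class(tracks)))
  tracks
}

split_tracks <- function(tracks) split(tracks, tracks$track_id)

#' Per-track migration metrics
#'
#' For every track computes: total path length (um), net start-to-end
#' displacement (um), mean speed (um/min, path length over elapsed time),
#' directionality (straightness: net/path, in `[0, 1]`, 1 for a straight
#' path), the signed forward migration indices parallel and perpendicular
#' to the gradient axis (net displacement component divided by path
#' length, in `[-1, 1]`), and the end-to-end angle relative to the axis
#' in degrees, in `(-180, 180]`.
#'
#' A track that returns exactly to its start has directionality and FMI
#' defined as 0 and an `NA` angle.
#'
#' @param tracks A tidy track table (see [as_track_table()]).
#' @param gradient_axis Reference direction: `"+x"` (default), `"-x"`,
#'   `"+y"`, `"-y"`, an angle in degrees, or a numeric 2-vector.
#' @return Data frame, one row per track: `track_id`, `path_length`,
#'   `net_displacement`, `mean_speed`, `directionality`, `fmi_parallel`,
#'   `fmi_perpendicular`, `end_angle`.
#' @examples
#' tr <- data.frame(track_id = 1, t = 0:2 * 60,
#'                  x = c(0, 3, 3), y = c(0, 0, 4))
#' track_metrics(tr)  # path 7, net 5, directionality 5/7
#' @export
track_metrics <- function(tracks, gradient_axis = "+x") {
  tracks <- as_track_table(tracks)
  axis <- as_unit_axis(gradient_axis)
  perp <- c(-axis[2], axis[1])
  rows <- lapply(split_tracks(tracks), function(tr) {
    dx <- diff(tr$x); dy <- diff(tr$y)
    path <- sum(sqrt(dx^2 + dy^2))
    netv <- c(tr$x[nrow(tr)] - tr$x[1], tr$y[nrow(tr)] - tr$y[1])
    net <- sqrt(sum(netv^2))
    elapsed <- tr$t[nrow(tr)] - tr$t[1]
    if (elapsed <= 0) stop("zero elapsed time in track ", tr$track_id[1],
                           call. = FALSE)
    speed <- path / (elapsed / 60)
    if (path > 0) {
      dir <- net / path
      fmi_par <- sum(netv * axis) / path
      fmi_perp <- sum(netv * perp) / path
    } else {
      dir <- fmi_par <- fmi_perp <- 0
    }
    ang <- if (net > 0) {
      wrap_angle(rad2deg(atan2(sum(netv * perp), sum(netv * axis))))
    } else {
      NA_real_
    }
    data.frame(track_id = tr$track_id[1], path_length = path,
               net_displacement = net, mean_speed = speed,
               directionality = dir, fmi_parallel = fmi_par,
               fmi_perpendicular = fmi_perp, end_angle = ang)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter tracks by recording-time coverage
#'
#' Keeps tracks observed for strictly more than `min_coverage` of the
#' recording. A track seen in k frames of an N-frame recording covers
#' k/N of it, so coverage is measured as `(span + dt) / recording
#' duration` with `dt` the track's median sampling interval; with the
#' default 10% threshold a 13-frame track of a 120-frame recording is
#' kept and a 12-frame track is dropped.
#'
#' @param tracks A tidy track table.
#' @param recording_duration Total recording duration in s (frames times
#'   frame interval).
#' @param min_coverage Coverage threshold, default 0.10.
#' @return The filtered track table.
#' @export
filter_tracks <- function(tracks, recording_duration, min_coverage = 0.10) {
  stopifnot(recording_duration > 0, min_coverage >= 0)
  tracks <- as_track_table(tracks)
  if (nrow(tracks) == 0) return(tracks)
  keep <- vapply(split_tracks(tracks), function(tr) {
    dt <- stats::median(diff(tr$t))
    span <- tr$t[nrow(tr)] - tr$t[1] + dt
    span > min_coverage * recording_duration
  }, logical(1))
  ids <- names(keep)[keep]
  out <- tracks[tracks$track_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rose histogram of track end-to-end angles
#'
#' Bins one end-to-end angle per track, measured relative to the
#' gradient axis, into `n_bins` half-open bins `(a, b]` partitioning
#' `(-180, 180]`, with bin edges at multiples of the bin width so the
#' default is 18 bins of 20 degrees with an edge at 0. Tracks with zero
#' net displacement contribute no angle and are counted in the
#' `n_excluded` attribute.
#'
#' @param tracks Tidy track table.
#' @param gradient_axis Reference direction (see [track_metrics()]).
#' @param n_bins Number of angular bins (>= 4, default 18).
#' @param mode `"track"` (default): one end-to-end angle per track;
#'   `"step"`: every per-step displacement angle, pooled over tracks
#'   (zero-length steps are excluded).
#' @return A `rose_histogram`: list with `bin_edges` (degrees, length
#'   `n_bins + 1`), `counts`, `reference_axis` and `n_excluded`.
#' @export
rose_histogram <- function(tracks, gradient_axis = "+x", n_bins = 18L,
                           mode = c("track", "step")) {
  stopifnot(n_bins >= 4L)
  mode <- match.arg(mode)
  if (mode == "track") {
    m <- track_metrics(tracks, gradient_axis)
    ang <- m$end_angle
  } else {
    axis <- as_unit_axis(gradient_axis)
    perp <- c(-axis[2], axis[1])
    tracks <- as_track_table(tracks)
    ang <- unlist(lapply(split_tracks(tracks), function(tr) {
      dx <- diff(tr$x); dy <- diff(tr$y)
      keep <- dx != 0 | dy != 0
      a <- wrap_angle(rad2deg(atan2(dx * perp[1] + dy * perp[2],
                                    dx * axis[1] + dy * axis[2])))
      ifelse(keep, a, NA_real_)
    }), use.names = FALSE)
  }
  excl <- sum(is.na(ang))
  ang <- ang[!is.na(ang)]
  edges <- seq(-180, 180, length.out = n_bins + 1)
  # half-open (a, b]: shift angles at exactly -180 into the top bin
  ang[ang <= -180] <- ang[ang <= -180] + 360
  idx <- findInterval(ang, edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = edges, counts = counts,
         reference_axis = as_unit_axis(gradient_axis), n_excluded = excl),
    class = "rose_histogram"
  )
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat(sprintf("<rose_histogram: %d tracks in %d bins (%d excluded)>\n",
              sum(x$counts), length(x$counts), x$n_excluded))
  invisible(x)
}

#' Remove common stage drift from a track ensemble
#'
#' Estimates the per-frame median displacement over all tracks present in
#' consecutive frames and subtracts the accumulated drift from every
#' point, so a rigid common translation is removed exactly. With a single
#' track the input is returned unchanged with a warning.
#'
#' @param tracks Tidy track table; tracks must share frame timestamps.
#' @return Drift-corrected track table. The cumulative drift per frame is
#'   attached as the `"drift"` attribute (data frame `t`, `dx`, `dy`).
#' @export
drift_correct <- function(tracks) {
  tracks <- as_track_table(tracks)
  ids <- unique(tracks$track_id)
  if (length(ids) < 2L) {
    warning("drift correction needs >= 2 simultaneous tracks; ",
            "returning input unchanged")
    return(tracks)
  }
  frames <- sort(unique(tracks$t))
  drift <- matrix(0, nrow = length(frames), ncol = 2)
  for (k in seq_along(frames)[-1]) {
    t0 <- frames[k - 1]; t1 <- frames[k]
    a <- tracks[tracks$t == t0, c("track_id", "x", "y")]
    b <- tracks[tracks$t == t1, c("track_id", "x", "y")]
    common <- intersect(a$track_id, b$track_id)
    if (length(common) >= 1L) {
      ai <- a[match(common, a$track_id), ]
      bi <- b[match(common, b$track_id), ]
      step <- c(stats::median(bi$x - ai$x), stats::median(bi$y - ai$y))
    } else {
      step <- c(0, 0)
    }
    drift[k, ] <- drift[k - 1, ] + step
  }
  idx <- match(tracks$t, frames)
  out <- tracks
  out$x <- tracks$x - drift[idx, 1]
  out$y <- tracks$y - drift[idx, 2]
  attr(out, "drift") <- data.frame(t = frames, dx = drift[, 1],
                                   dy = drift[, 2])
  out
}

#' Boundary-crossing invasion fraction
#'
#' Fraction of tracks that start on the non-invaded side of a boundary
#' polyline and end on the invaded side. Side assignment uses the signed
#' cross product relative to the nearest boundary segment, so the
#' polyline must partition the field of view (an open curve spanning it).
#' This boundary-crossing fraction is a declared operationalization of an
#' invasion index; it is not a uniquely defined literature quantity.
#'
#' @param tracks Tidy track table.
#' @param boundary n x 2 matrix of polyline vertices (um), n >= 2.
#' @param invaded_side `"left"` or `"right"` of the polyline's direction
#'   of travel.
#' @return Fraction in `[0, 1]`.
#' @export
invasion_index <- function(tracks, boundary, invaded_side = c("left", "right")) {
  invaded_side <- match.arg(invaded_side)
  boundary <- as_points(boundary)
  if (nrow(boundary) < 2L) {
    stop("boundary needs at least 2 vertices", call. = FALSE)
  }
  if (sum(sqrt(rowSums(diff(boundary)^2))) == 0) {
    stop("boundary polyline is degenerate and cannot partition the field",
         call. = FALSE)
  }
  tracks <- as_track_table(tracks)
  trs <- split_tracks(tracks)
  if (!length(trs)) return(NA_real_)
  side_of <- function(p) {
    # nearest segment, then sign of the cross product
    best <- Inf; s <- 0
    for (k in seq_len(nrow(boundary) - 1L)) {
      a <- boundary[k, ]; b <- boundary[k + 1L, ]
      ab <- b - a
      tt <- sum((p - a) * ab) / sum(ab^2)
      tt <- min(max(tt, 0), 1)
      proj <- a + tt * ab
      d2 <- sum((p - proj)^2)
      if (d2 < best) {
        best <- d2
        s <- sign(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1]))
      }
    }
    if (s >= 0) "left" else "right"
  }
  crossed <- vapply(trs, function(tr) {
    s0 <- side_of(c(tr$x[1], tr$y[1]))
    s1 <- side_of(c(tr$x[nrow(tr)], tr$y[nrow(tr)]))
    s0 != invaded_side && s1 == invaded_side
  }, logical(1))
  mean(crossed)
}
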