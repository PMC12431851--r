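#' Bioluminescence metastatic index
#'
#' Normalized metastatic tumour burden per animal: the summed photon
#' flux of the selected metastatic sites divided by the photon flux of
#' the animal's primary tumour. The index is invariant to rescaling all
#' of an animal's fluxes (exposure conditions cancel) and to row order.
#'
#' @param flux Data frame with columns `animal_id`, `site` (one
#'   `"primary"` row per animal; metastatic sites e.g. `"liver"`,
#'   `"lung"`, `"GI"`) and `photon_flux` (a.u., >= 0).
#' @param sites Character vector of metastatic sites to sum (default
#'   `c("liver", "lung")`; use e.g. `c("liver", "GI")` for
#'   gastrointestinal readouts).
#' @return Data frame, one row per animal: `animal_id`,
#'   `metastatic_flux`, `primary_flux`, `metastatic_index`, `error`
#'   (`NA` or a message for animals with a missing/zero primary; their
#'   index is `NA` while other animals are still computed).
#' @examples
#' fx <- data.frame(animal_id = "m1",
#'                  site = c("primary", "liver", "lung"),
#'                  photon_flux = c(1e7, 2e6, 1e6))
#' metastatic_index(fx)$metastatic_index  # 0.3
#' @export
metastatic_index <- function(flux, sites = c("liver", "lung")) {
  need <- c("animal_id", "site", "photon_flux")
  miss <- setdiff(need, names(flux))
  if (length(miss)) {
    stop("flux table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(flux$photon_flux < 0, na.rm = TRUE)) {
    stop("photon flux must be non-negative", call. = FALSE)
  }
  rows <- lapply(unique(flux$animal_id), function(id) {
    sub <- flux[flux$animal_id == id, , drop = FALSE]
    prim <- sub$photon_flux[sub$site == "primary"]
    met <- sum(sub$photon_flux[sub$site %in% sites])
    if (length(prim) == 0L) {
      return(data.frame(animal_id = id, metastatic_flux = met,
                        primary_flux = NA_real_,
                        metastatic_index = NA_real_,
                        error = "no primary row"))
    }
    if (length(prim) > 1L) {
      return(data.frame(animal_id = id, metastatic_flux = met,
                        primary_flux = NA_real_,
                        metastatic_index = NA_real_,
                        error = "multiple primary rows"))
    }
    if (prim <= 0) {
      return(data.frame(animal_id = id, metastatic_flux = met,
                        primary_flux = prim,
                        metastatic_index = NA_real_,
                        error = "primary flux is zero"))
    }
    data.frame(animal_id = id, metastatic_flux = met, primary_flux = prim,
               metastatic_index = met / prim, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# fibres ------------------------------------------------------------------

as_fiber_matrix <- function(fiber) {
  if (is.data.frame(fiber)) fiber <- cbind(fiber$x, fiber$y)
  fiber <- as_points(fiber)
  if (nrow(fiber) < 2L) stop("fibre needs >= 2 points", call. = FALSE)
  seg <- sqrt(rowSums((fiber[-1, , drop = FALSE] -
                         fiber[-nrow(fiber), , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("fibre has consecutive duplicate points", call. = FALSE)
  }
  fiber
}

#' Fibre curvature ratio (straightness)
#'
#' End-to-end chord length of a fibre centerline divided by its contour
#' (arc) length: 1 for a straight fibre, small for curly fibres, 0 for a
#' closed loop. Refining the polyline by midpoint insertion leaves the
#' ratio unchanged.
#'
#' @param fiber n x 2 matrix or `x`/`y` data frame of ordered centerline
#'   points (um), consecutive points distinct.
#' @return Ratio in `[0, 1]`.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' curvature_ratio(cbind(cos(th), sin(th)))  # ~ 2 / pi
#' @export
curvature_ratio <- function(fiber) {
  f <- as_fiber_matrix(fiber)
  chord <- sqrt(sum((f[nrow(f), ] - f[1, ])^2))
  arc <- sum(sqrt(rowSums((f[-1, , drop = FALSE] -
                             f[-nrow(f), , drop = FALSE])^2)))
  chord / arc
}

#' Axial fibre orientation
#'
#' Orientation of the fibre's end-to-end chord as an axial angle in
#' degrees in `[0, 180)` (a fibre has no head or tail, so theta and
#' theta + 180 are identified). With `mode = "segments"` the
#' length-weighted axial mean of per-segment tangents is used instead.
#' Closed loops have no chord orientation and return `NA`.
#'
#' @param fiber n x 2 matrix or `x`/`y` data frame (um).
#' @param mode `"chord"` (default) or `"segments"`.
#' @return Angle in degrees in `[0, 180)`, or `NA` for a closed loop.
#' @export
fiber_orientation <- function(fiber, mode = c("chord", "segments")) {
  mode <- match.arg(mode)
  f <- as_fiber_matrix(fiber)
  if (mode == "chord") {
    v <- f[nrow(f), ] - f[1, ]
    if (all(v == 0)) return(NA_real_)
    ang <- rad2deg(atan2(v[2], v[1])) %% 180
  } else {
    seg <- f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    th2 <- 2 * atan2(seg[, 2], seg[, 1])  # doubled angles: axial mean
    mx <- sum(len * cos(th2)); my <- sum(len * sin(th2))
    if (mx == 0 && my == 0) return(NA_real_)
    ang <- (rad2deg(atan2(my, mx) / 2)) %% 180
  }
  ang
}

#' Population summary of fibre geometry
#'
#' Aggregates a set of fibre centerlines into width and orientation
#' histograms, per-fibre curvature ratios and an alignment score. The
#' alignment score is the mean resultant length of the doubled axial
#' orientation angles, in `[0, 1]`: 1 when all fibres are parallel, near
#' 0 for uniformly dispersed orientations.
#'
#' @param fibers List of fibres (each an n x 2 matrix or data frame with
#'   `x`, `y` and optionally a `width` column or `"width"` attribute), or
#'   a tidy data frame with `fiber_id`, `x`, `y` and optionally `width`.
#' @param width_breaks,orientation_breaks Histogram break specifications
#'   (defaults: widths via Sturges, orientations in 15-degree bins over
#'   `[0, 180]`).
#' @return A `fiber_summary`: list with `n_fibers`, `curvature_ratios`,
#'   `orientations` (degrees), `alignment_score`, `width_hist` and
#'   `orientation_hist` (both `hist` objects, `width_hist` `NULL` when
#'   no widths are available).
#' @export
fiber_population_summary <- function(fibers,
                                     width_breaks = "Sturges",
                                     orientation_breaks = seq(0, 180, 15)) {
  if (is.data.frame(fibers)) {
    stopifnot(all(c("fiber_id", "x", "y") %in% names(fibers)))
    fibers <- split(fibers, fibers$fiber_id)
  }
  stopifnot(length(fibers) >= 1L)
  widths <- unlist(lapply(fibers, function(f) {
    if (is.data.frame(f) && "width" %in% names(f)) {
      mean(f$width)
    } else {
      attr(f, "width")
    }
  }))
  curv <- vapply(fibers, curvature_ratio, numeric(1))
  ori <- vapply(fibers, fiber_orientation, numeric(1))
  ori_ok <- ori[!is.na(ori)]
  th2 <- deg2rad(2 * ori_ok)
  align <- if (length(ori_ok)) {
    sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  } else {
    NA_real_
  }
  structure(
    list(n_fibers = length(fibers),
         curvature_ratios = unname(curv),
         orientations = unname(ori),
         alignment_score = align,
         width_hist = if (length(widths)) {
           graphics::hist(widths, breaks = width_breaks, plot = FALSE)
         } else NULL,
         orientation_hist = graphics::hist(
           ori_ok, breaks = orientation_breaks, plot = FALSE,
           include.lowest = TRUE)),
    class = "fiber_summary"
  )
}

#' @export
print.fiber_summary <- function(x, ...) {
  cat(sprintf(
    "<fiber_summary: %d fibres, median curvature ratio %.3f, alignment %.3f>\n",
    x$n_fibers, stats::median(x$curvature_ratios, na.rm = TRUE),
    x$alignment_score))
  invisible(x)
}
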