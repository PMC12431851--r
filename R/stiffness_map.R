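#' Gridded stiffness map (elastograph)
#'
#' A rectangular lattice of Young's moduli in Pa with a physical node
#' spacing (`pitch`, um). Rows index y and columns index x; node (i, j)
#' (1-based) sits at physical position `origin + c((j-1), (i-1)) * pitch`,
#' so an n x n grid spans `(n-1) * pitch` um per side -- a 17 x 17 grid at
#' 5 um pitch covers an 80 x 80 um area, the standard AFM mapping
#' protocol. Missing (unfittable) nodes are `NA`.
#'
#' @param grid Numeric matrix of moduli in Pa; `NA` allowed, finite
#'   entries must be positive.
#' @param pitch Node spacing in um (> 0).
#' @param origin Physical position of node (1, 1) in um.
#' @param provenance Free-text acquisition/processing metadata.
#' @return Object of class `stiffness_map`.
#' @export
stiffness_map <- function(grid, pitch, origin = c(0, 0), provenance = "") {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  stopifnot(is.numeric(pitch), length(pitch) == 1L, pitch > 0,
            length(origin) == 2L)
  fin <- grid[is.finite(grid)]
  if (any(fin <= 0)) {
    stop("stiffness map entries must be positive (Pa)", call. = FALSE)
  }
  structure(
    list(grid = grid, pitch = as.numeric(pitch),
         origin = as.numeric(origin), provenance = provenance),
    class = "stiffness_map"
  )
}

#' @export
print.stiffness_map <- function(x, ...) {
  ext <- map_extent(x)
  fin <- x$grid[is.finite(x$grid)]
  cat(sprintf("<stiffness_map: %d x %d nodes, pitch %g um, extent %g x %g um>\n",
              nrow(x$grid), ncol(x$grid), x$pitch, ext[1], ext[2]))
  if (length(fin)) {
    cat(sprintf("  E: %.3g - %.3g kPa (median %.3g), %d missing\n",
                min(fin) / 1000, max(fin) / 1000, stats::median(fin) / 1000,
                sum(!is.finite(x$grid))))
  }
  invisible(x)
}

#' Physical extent of a stiffness map
#' @param map A [stiffness_map()].
#' @return `c(width, height)` in um spanned by the lattice nodes.
#' @export
map_extent <- function(map) {
  stopifnot(inherits(map, "stiffness_map"))
  c(ncol(map$grid) - 1, nrow(map$grid) - 1) * map$pitch
}

#' Bilinear interpolation of a stiffness map
#'
#' Interpolates moduli at arbitrary in-extent positions; any query whose
#' enclosing cell touches a missing node returns `NA` (gaps propagate).
#'
#' @param map A [stiffness_map()].
#' @param x,y Physical coordinates in um (vectors).
#' @return Numeric vector of moduli in Pa.
#' @export
map_interp <- function(map, x, y) {
  stopifnot(inherits(map, "stiffness_map"))
  ext <- map_extent(map)
  px <- (x - map$origin[1]) / map$pitch
  py <- (y - map$origin[2]) / map$pitch
  bad <- px < -1e-9 | px > ncol(map$grid) - 1 + 1e-9 |
    py < -1e-9 | py > nrow(map$grid) - 1 + 1e-9
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) um lies outside the map extent %g x %g um",
                 x[i], y[i], ext[1], ext[2]), call. = FALSE)
  }
  px <- pmin(pmax(px, 0), ncol(map$grid) - 1)
  py <- pmin(pmax(py, 0), nrow(map$grid) - 1)
  j0 <- pmin(floor(px), ncol(map$grid) - 2); j0 <- pmax(j0, 0)
  i0 <- pmin(floor(py), nrow(map$grid) - 2); i0 <- pmax(i0, 0)
  if (ncol(map$grid) == 1L) j0 <- rep(0L, length(px))
  if (nrow(map$grid) == 1L) i0 <- rep(0L, length(py))
  tx <- px - j0
  ty <- py - i0
  g <- map$grid
  idx <- function(i, j) g[cbind(pmin(i, nrow(g) - 1) + 1,
                                pmin(j, ncol(g) - 1) + 1)]
  v00 <- idx(i0, j0)
  v01 <- idx(i0, j0 + 1)
  v10 <- idx(i0 + 1, j0)
  v11 <- idx(i0 + 1, j0 + 1)
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}
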