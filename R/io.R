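#' File formats
#'
#' All files use micrometres for coordinates, seconds for times, pascals
#' for moduli and degrees for angles; CSV is comma-separated UTF-8 with a
#' header and '.' decimal; matrices may be TSV.
#'
#' * Tracks: CSV `track_id,t_s,x_um,y_um`.
#' * Force curves: CSV `delta_m,force_n` (SI units) plus a JSON sidecar
#'   (`<file>.json`) holding probe constants.
#' * Stiffness maps: TSV matrix in Pa plus JSON sidecar with `pitch_um`,
#'   `origin_um`, `provenance`.
#' * Flux tables: CSV `animal_id,site,photon_flux`.
#' * Fibres: CSV `fiber_id,point_index,x_um,y_um[,width_um]`.
#'
#' @name durotaxr-formats
#' @keywords internal
NULL

sidecar_path <- function(path) paste0(path, ".json")

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read and write tidy track tables
#'
#' @param path CSV file with header `track_id,t_s,x_um,y_um`.
#' @return `read_tracks()`: a validated track table (columns `track_id`,
#'   `t`, `x`, `y`). `write_tracks()`: the path, invisibly.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("track_id", "t_s", "x_um", "y_um"), path)
  out <- data.frame(track_id = df$track_id, t = df$t_s,
                    x = df$x_um, y = df$y_um)
  tryCatch(as_track_table(out), error = function(e) {
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  })
}

#' @rdname read_tracks
#' @param tracks A tidy track table.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- as_track_table(tracks)
  utils::write.csv(
    data.frame(track_id = tracks$track_id, t_s = tracks$t,
               x_um = tracks$x, y_um = tracks$y),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write force curves
#'
#' A single curve per CSV file (`delta_m,force_n`), probe constants in a
#' JSON sidecar `<file>.json` with fields `tip_radius_m`, `poisson`,
#' `spring_constant_n_per_m` and optional `position_um`.
#'
#' @param path CSV path.
#' @return `read_force_curve()`: a [force_curve()].
#' @export
read_force_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("delta_m", "force_n"), path)
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  pos <- if (!is.null(meta$position_um)) unlist(meta$position_um) else NULL
  tryCatch(
    force_curve(df$delta_m, df$force_n,
                tip_radius = meta$tip_radius_m %||% 2.5e-6,
                poisson = meta$poisson %||% 0.4,
                spring_constant = meta$spring_constant_n_per_m %||% 0.06,
                position = pos),
    error = function(e) {
      stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_force_curve
#' @param curve A [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(data.frame(delta_m = curve$delta, force_n = curve$force),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(tip_radius_m = curve$tip_radius, poisson = curve$poisson,
               spring_constant_n_per_m = curve$spring_constant)
  if (!is.null(curve$position)) meta$position_um <- curve$position
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write stiffness maps
#'
#' The map matrix is a plain TSV of moduli in Pa (rows = y, columns = x,
#' `NA` for missing nodes); pitch, origin and provenance live in a JSON
#' sidecar `<file>.json`.
#'
#' @param path TSV path.
#' @return `read_map()`: a [stiffness_map()].
#' @export
read_map <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(grid) <- NULL
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop(sprintf("%s: sidecar %s with pitch metadata not found",
                 path, side), call. = FALSE)
  }
  meta <- jsonlite::read_json(side)
  if (is.null(meta$pitch_um)) {
    stop(sprintf("%s: sidecar lacks `pitch_um`", side), call. = FALSE)
  }
  stiffness_map(grid, pitch = meta$pitch_um,
                origin = unlist(meta$origin_um %||% c(0, 0)),
                provenance = meta$provenance %||% "")
}

#' @rdname read_map
#' @param map A [stiffness_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "stiffness_map"))
  utils::write.table(map$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pitch_um = map$pitch, origin_um = map$origin,
         provenance = map$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write photon-flux tables
#'
#' @param path CSV with header `animal_id,site,photon_flux`.
#' @return `read_flux()`: a validated flux data frame.
#' @export
read_flux <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("animal_id", "site", "photon_flux"), path)
  bad <- which(!is.finite(df$photon_flux) | df$photon_flux < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative or non-numeric photon_flux at row %d",
                 path, bad[1]), call. = FALSE)
  }
  df
}

#' @rdname read_flux
#' @param flux Flux data frame (`animal_id`, `site`, `photon_flux`).
#' @export
write_flux <- function(flux, path) {
  require_cols(flux, c("animal_id", "site", "photon_flux"), "flux table")
  utils::write.csv(flux[, c("animal_id", "site", "photon_flux")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fibre centerlines
#'
#' @param path CSV with header `fiber_id,point_index,x_um,y_um` and an
#'   optional `width_um` column.
#' @return `read_fibers()`: list of fibre data frames (`x`, `y`, and
#'   `width` when present), ordered by `point_index`.
#' @export
read_fibers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("fiber_id", "point_index", "x_um", "y_um"), path)
  out <- lapply(split(df, df$fiber_id), function(sub) {
    sub <- sub[order(sub$point_index), , drop = FALSE]
    f <- data.frame(x = sub$x_um, y = sub$y_um)
    if ("width_um" %in% names(sub)) f$width <- sub$width_um
    as_fiber_matrix(f)  # validates; errors name the file below
    f
  })
  out
}

#' @rdname read_fibers
#' @param fibers List of fibre data frames.
#' @export
write_fibers <- function(fibers, path) {
  rows <- lapply(seq_along(fibers), function(k) {
    f <- fibers[[k]]
    id <- names(fibers)[k] %||% sprintf("f%04d", k)
    if (is.null(names(fibers)) || id == "") id <- sprintf("f%04d", k)
    d <- data.frame(fiber_id = id, point_index = seq_len(nrow(f)) - 1L,
                    x_um = f$x, y_um = f$y)
    if (!is.null(f$width)) d$width_um <- f$width
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
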