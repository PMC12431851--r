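#' Default demo pipeline configuration
#'
#' Desk-scale configuration for [run_pipeline()]: an elastography flow
#' (simulate Hertzian curves on a fibrotic-field lattice, fit, assemble
#' the map, summarise slopes and foci) and a durotaxis flow (simulate
#' biased walkers on a shallow-gradient substrate, compute migration
#' metrics, rose histogram and the end-point durotactic index on a step
#' substrate).
#'
#' @param seed Root integer seed; per-stage seeds are derived from it.
#' @return Named list of configuration values.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    afm = list(extent = c(80, 80), pitch = 5, n_samples = 60,
               noise_frac = 0.02, field_kind = "fibrotic"),
    slopes = list(n_slopes = 50),
    tracks = list(n_tracks = 60, duration = 21600, dt = 300,
                  speed_mean = 0.5, bias_strength = 2),
    assay = list(n_cells = 400, timepoint_h = 24)
  )
}

known_config_keys <- c("seed", "afm", "slopes", "tracks", "assay")

#' Run the demonstration analysis pipeline
#'
#' Executes two seeded end-to-end flows on synthetic data and writes all
#' outputs plus a run manifest into `out_dir`:
#'
#' 1. elastography: simulated fibrotic stiffness field -> per-node
#'    Hertzian force curves -> [fit_hertz()] -> [build_stiffness_map()]
#'    -> [average_slope()] and [detect_peaks_valleys()];
#' 2. durotaxis: [sim_tracks()] on a shallow-gradient substrate ->
#'    [track_metrics()] / [rose_histogram()] -> end-point
#'    [durotactic_index()] of walker endpoints on a step substrate
#'    against their uniform starting positions.
#'
#' Reruns with the same config produce identical numerical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]);
#'   unknown keys are rejected before any computation.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`map`,
#'   `slope_summary`, `foci`, `track_metrics`, `rose`, `assay`) and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("durotaxr_run_")) {
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("config needs a `seed`", call. = FALSE)
  cfg <- utils::modifyList(default_pipeline_config(config$seed), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  stage <- "elastography"
  res <- tryCatch({
    # -- flow 1: curves -> fits -> map -> slopes/foci ----------------------
    truth_field <- sim_stiffness_field(
      cfg$afm$field_kind, extent = cfg$afm$extent, pitch = cfg$afm$pitch,
      seed = derive_seed(cfg$seed, 1))
    xs <- seq(0, cfg$afm$extent[1], by = cfg$afm$pitch)
    ys <- seq(0, cfg$afm$extent[2], by = cfg$afm$pitch)
    fits <- list()
    k <- 0L
    for (iy in seq_along(ys)) {
      for (ix in seq_along(xs)) {
        k <- k + 1L
        E_true <- truth_field$grid[iy, ix]
        cv <- sim_force_curves(1, E_true, n_samples = cfg$afm$n_samples,
                               noise_frac = cfg$afm$noise_frac,
                               seed = derive_seed(cfg$seed, 100 + k))[[1]]
        cv$position <- c(xs[ix], ys[iy])
        fits[[k]] <- fit_hertz(cv)
      }
    }
    map <- build_stiffness_map(fits, pitch = cfg$afm$pitch)
    write_map(map, file.path(out_dir, "stiffness_map.tsv"))
    slopes <- average_slope(map, n_slopes = cfg$slopes$n_slopes,
                            seed = derive_seed(cfg$seed, 2))
    foci <- detect_peaks_valleys(map, min_prominence = 1000)
    jsonlite::write_json(
      list(average_slope_pa_per_um = slopes$average_slope,
           n_slopes = slopes$n_slopes, seed = slopes$seed,
           slopes = slopes$slopes),
      file.path(out_dir, "slope_summary.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(foci, file.path(out_dir, "foci.csv"),
                     row.names = FALSE)

    # -- flow 2: tracks -> metrics -> assay --------------------------------
    stage <- "migration"
    grad_pat <- substrate_pattern("linear_gradient", 4000, 40000,
                                  transition_width = 1000,
                                  extent = c(1000, 1000))
    tracks <- sim_tracks(grad_pat, n_tracks = cfg$tracks$n_tracks,
                         duration = cfg$tracks$duration,
                         dt = cfg$tracks$dt,
                         speed_mean = cfg$tracks$speed_mean,
                         bias_strength = cfg$tracks$bias_strength,
                         seed = derive_seed(cfg$seed, 3))
    tracks <- filter_tracks(tracks, cfg$tracks$duration)
    metrics <- track_metrics(tracks, "+x")
    rose <- rose_histogram(tracks, "+x")
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    utils::write.csv(metrics, file.path(out_dir, "track_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(bin_edges_deg = rose$bin_edges, counts = rose$counts,
           n_excluded = rose$n_excluded),
      file.path(out_dir, "rose_histogram.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "assay"
    step_pat <- substrate_pattern("step_stripes", 4000, 40000,
                                  extent = c(1020, 1020))
    walkers <- sim_tracks(step_pat, n_tracks = cfg$assay$n_cells,
                          duration = cfg$assay$timepoint_h * 3600,
                          dt = 1200, speed_mean = cfg$tracks$speed_mean,
                          bias_strength = cfg$tracks$bias_strength,
                          seed = derive_seed(cfg$seed, 4))
    first <- walkers[!duplicated(walkers$track_id), c("x", "y")]
    last <- walkers[!duplicated(walkers$track_id, fromLast = TRUE),
                    c("x", "y")]
    assay <- durotactic_index(last, step_pat, baseline = first)
    jsonlite::write_json(
      list(n_stiff = assay$n_stiff, n_soft = assay$n_soft,
           n_excluded = assay$n_excluded, index_raw = assay$index_raw,
           index_normalized = assay$index_normalized,
           saturated = assay$saturated),
      file.path(out_dir, "durotaxis_result.json"), auto_unbox = TRUE,
      digits = NA)

    list(map = map, slope_summary = slopes, foci = foci,
         track_metrics = metrics, rose = rose, assay = assay)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    command = "run_pipeline",
    config = cfg,
    config_hash = fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
    package_version = as.character(utils::packageVersion("durotaxr")),
    seed = cfg$seed,
    outputs = list.files(out_dir),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
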