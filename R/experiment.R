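#' Fully resolved experiment configuration
#'
#' Builds the nested configuration driving [run_experiment()], resolving
#' every default so the serialized copy written beside the outputs describes
#' the run completely. Seeds are mandatory for stochastic runs.
#'
#' @param ... Named overrides, nested as in the returned list (e.g.
#'   `map = list(n_levels = 100)`, `feedback = list(gain = 0.3)`).
#' @param seed Master integer seed.
#' @return An `experiment_config` list with sections `instrument`
#'   (response model, drift, stage, detector noise), `map` (region, pitch,
#'   n_levels), `tracker` (block_size, digitization_rate, overhead),
#'   `feedback` (setpoint, gain, loop_rate), `hold` (duration),
#'   `steptest` (axis, step_nm, positions, samples, dwell, feedback_on),
#'   `fluor` (region, pixel, n_emitters, dwell, drift_px), and `seed`.
#' @export
experiment_config <- function(..., seed = 1) {
  defaults <- list(
    instrument = list(
      w = c(100, 100), envelope_sigma = 300, kappa = 0.1,
      noise_rms = 0.01,
      drift = list(linear_rate = c(3, -2), fluct_amplitude = c(5, 3),
                   fluct_corner = 0.5, fluct_cutoff = 20),
      stage = list(resonant_freq = 340, damping_ratio = 0.5,
                   servo_rate = 20000, sensor_noise_rms = 0.1)),
    map = list(region = c(-50, 50, -50, 50), pixel_pitch = 0.5,
               n_levels = 200, scan_noise_rms = 0),
    tracker = list(block_size = 100, digitization_rate = 1e6,
                   overhead = 0.86),
    feedback = list(setpoint = c(0, 0), gain = 0.2, loop_rate = 5900),
    hold = list(duration = 10),
    steptest = list(axis = "x", step_nm = 4, n_positions = 250,
                    samples_per_position = 200, dwell = 0.017,
                    feedback_on = TRUE),
    fluor = list(region = c(-1500, 1500, -1500, 1500), pixel = 60,
                 n_emitters = 8, dwell = 0.01, drift_px = c(4.9, 3.02)),
    seed = seed)
  overrides <- list(...)
  merge_into <- function(base, over, path = character(0)) {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("invalid config key: ", paste(c(path, nm), collapse = "$"))
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], over[[nm]], c(path, nm))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_into(defaults, overrides)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop("invalid config key: seed (must be a finite integer)")
  structure(cfg, class = c("experiment_config", "list"))
}

.cfg_model <- function(cfg) {
  qapd_response_model(w = cfg$instrument$w,
                      envelope_sigma = cfg$instrument$envelope_sigma,
                      kappa = cfg$instrument$kappa)
}

.cfg_map <- function(cfg, model) {
  pair <- scan_image_pair(model, region = cfg$map$region,
                          pixel_pitch = cfg$map$pixel_pitch,
                          noise_rms = cfg$map$scan_noise_rms,
                          seed = cfg$seed)
  build_map(pair, cfg$map$n_levels)
}

.cfg_drift <- function(cfg) {
  do.call(drift_model, cfg$instrument$drift)
}

.cfg_stage <- function(cfg) {
  do.call(stage_state, cfg$instrument$stage)
}

#' Run an end-to-end experiment
#'
#' Drives the package's four standard demonstrations from a single
#' configuration and writes a deterministic output bundle: the resolved
#' `config.json`, and per experiment a `summary.json` plus the map file,
#' trace CSVs, or TIFF images it produces. Partial outputs are removed on
#' failure. The input config is never mutated.
#'
#' @param config An [experiment_config()].
#' @param which One of `"mapbuild"` (scan + build + serialize the map),
#'   `"hold"` (closed-loop hold for `hold$duration` seconds), `"steptest"`
#'   (back-and-forth step benchmark), `"fluor"` (before/after emitter scans
#'   with injected drift and centroid drift measurement).
#' @param out_dir Output directory (created; must not exist or be empty).
#' @return The summary list, invisibly; all artifacts are in `out_dir`.
#' @export
run_experiment <- function(config, which = c("mapbuild", "hold", "steptest",
                                             "fluor"), out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  which <- match.arg(which)
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop("out_dir exists and is not empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  t_start <- proc.time()[["elapsed"]]
  write_config(unclass(config), file.path(out_dir, "config.json"))
  model <- .cfg_model(config)
  summary <- switch(which,
    mapbuild = {
      map <- .cfg_map(config, model)
      write_map(map, file.path(out_dir, "map.bin"))
      map$build_metadata
    },
    hold = {
      map <- .cfg_map(config, model)
      write_map(map, file.path(out_dir, "map.bin"))
      fb <- config$feedback
      rec <- run_closed_loop(
        model, map,
        feedback_config(setpoint = fb$setpoint, gain = fb$gain,
                        loop_rate = fb$loop_rate,
                        block_size = config$tracker$block_size),
        duration = config$hold$duration, drift = .cfg_drift(config),
        stage = .cfg_stage(config),
        noise_rms = config$instrument$noise_rms, seed = config$seed)
      dir.create(file.path(out_dir, "traces"))
      write_trace(rec$tracked, file.path(out_dir, "traces", "tracked.csv"),
                  map_file = file.path(out_dir, "map.bin"))
      write_trace(rec$sensed, file.path(out_dir, "traces", "sensed.csv"))
      write_trace(rec$commanded, file.path(out_dir, "traces", "commanded.csv"))
      r <- rms_about(rec$tracked, fb$setpoint)
      list(rms_x_nm = r[["x"]], rms_y_nm = r[["y"]],
           miss_rate = rec$misses / (nrow(rec$tracked) *
                                     config$tracker$block_size),
           clamped_ticks = rec$clamped_ticks,
           duration_s = config$hold$duration,
           loop_rate_hz = fb$loop_rate)
    },
    steptest = {
      map <- .cfg_map(config, model)
      st <- config$steptest
      res <- run_step_test(
        model, map, axis = st$axis, step_nm = st$step_nm,
        n_positions = st$n_positions,
        samples_per_position = st$samples_per_position,
        feedback_on = st$feedback_on, dwell = st$dwell,
        config = feedback_config(setpoint = config$feedback$setpoint,
                                 gain = config$feedback$gain,
                                 loop_rate = config$feedback$loop_rate,
                                 block_size = config$tracker$block_size),
        drift = .cfg_drift(config), stage = .cfg_stage(config),
        noise_rms = config$instrument$noise_rms, seed = config$seed)
      utils::write.csv(data.frame(step_nm = res$step_sizes),
                       file.path(out_dir, "steps.csv"), row.names = FALSE)
      list(axis = st$axis, commanded_nm = st$step_nm,
           mean_step_nm = res$mean, std_step_nm = res$std,
           accuracy_pm = 1000 * res$accuracy,
           precision_pm = 1000 * res$precision,
           n_steps = length(res$step_sizes), warnings = res$warnings)
    },
    fluor = {
      fl <- config$fluor
      ef <- random_emitter_field(
        fl$n_emitters,
        region = fl$region + c(1, -1, 1, -1) * 5 * fl$pixel,
        seed = config$seed)
      shift <- fl$drift_px * fl$pixel
      ef2 <- emitter_field(sweep(ef$positions, 2, -shift),
                           brightness = ef$brightness,
                           psf_sigma = ef$psf_sigma,
                           background = ef$background)
      dir.create(file.path(out_dir, "images"))
      img1 <- render_raster(ef, fl$region, pixel = fl$pixel,
                            dwell = fl$dwell, seed = config$seed + 1)
      img2 <- render_raster(ef2, fl$region, pixel = fl$pixel,
                            dwell = fl$dwell, seed = config$seed + 2)
      write_image(img1, file.path(out_dir, "images", "before.tif"))
      write_image(img2, file.path(out_dir, "images", "after.tif"))
      dm <- measure_drift(img1, img2)
      utils::write.csv(dm$per_emitter,
                       file.path(out_dir, "centroids.csv"),
                       row.names = FALSE)
      list(injected_drift_px = fl$drift_px,
           measured_drift_px = unname(dm$mean_displacement),
           n_matched = dm$n_matched, pixel_nm = fl$pixel)
    })
  summary$experiment <- which
  summary$seed <- config$seed
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # timing and versions go in the log, not the (reproducible) summary
  writeLines(c(
    sprintf("experiment: %s", which),
    sprintf("package: fidustab %s",
            tryCatch(as.character(utils::packageVersion("fidustab")),
                     error = function(e) "(source)")),
    sprintf("R: %s", R.version.string),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("elapsed_s: %.3f", proc.time()[["elapsed"]] - t_start)),
    file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(summary)
}
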