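# Run orchestration: build -> settle (actin frozen, arms binding) ->
# production stepping with periodic snapshots -> measurement.

#' Experiment presets
#'
#' Ready-made system specifications for the standard experiments, at full
#' scale (the published conditions) and at desk scale (shortened filaments
#' and domain so a run completes on a workstation; see the methods
#' vignette for the exact choices). Desk presets keep all per-motor and
#' per-cross-linker physics identical and scale only system extent.
#'
#' @param name one of `"two_filament_full"`, `"two_filament_desk"`,
#'   `"bundle_full"`, `"bundle_desk"`, `"network_full"`,
#'   `"network_desk"`; or `NULL` to list all names.
#' @return A `system_spec`, or a character vector of names.
#' @export
preset <- function(name = NULL) {
  all <- list(
    two_filament_full = system_spec("two_filament"),
    two_filament_desk = system_spec("two_filament", box_um = c(5, 5, 8),
                                    filament_um = 6, N_M = 2, N_ACP = 6),
    bundle_full = system_spec("bundle", N_F = 2, N_M = 4, N_ACP = 400),
    bundle_desk = system_spec("bundle", box_um = c(5, 5, 14),
                              filament_um = 6, N_F = 2, N_M = 4,
                              N_ACP = 120),
    network_full = system_spec("network"),
    network_desk = system_spec("network", box_um = c(6, 6, 0.1),
                               N_M = 4, N_ACP = 20,
                               target_length_um = 2, total_actin_um = 30)
  )
  if (is.null(name)) return(names(all))
  if (!name %in% names(all)) stop("unknown preset: ", name)
  all[[name]]
}

#' Build, settle and run a system to completion
#'
#' The full protocol: build the system from its spec, let cross-linkers
#' and motor arms attach while actin is held stationary (settling phase,
#' no walking or unbinding), then release everything and integrate the
#' production phase with periodic snapshot recording, and finally measure
#' cross-section forces.
#'
#' Randomness is consumed from R's RNG; call `set.seed()` first for a
#' reproducible run.
#'
#' @param spec a `system_spec` (or preset name).
#' @param params an `actomyo_params` object.
#' @param t_production production time (s).
#' @param settle_steps settling steps with frozen actin.
#' @param record_every snapshot interval (steps).
#' @param measure run the measurement stage (needs >= 50 snapshots).
#' @return list with `state`, `snapshots`, `measurement` (or `NULL`),
#'   `spec` and `params`.
#' @export
simulate_system <- function(spec, params = default_params(),
                            t_production = 9, settle_steps = 1e4,
                            record_every = 5000, measure = TRUE) {
  if (is.character(spec)) spec <- preset(spec)
  st <- build_system(spec, params)
  if (settle_steps > 0) {
    st <- advance(st, settle_steps, freeze_actin = TRUE,
                  walk = FALSE, unbind = FALSE)$state
  }
  nsteps <- ceiling(t_production / params$dt)
  run <- advance(st, nsteps, record_every = record_every)
  meas <- NULL
  if (measure) {
    mode <- if (spec$kind == "network") "network" else "bundle"
    meas <- measure_run(run$state, run$snapshots, mode = mode,
                        keep_profiles = TRUE)
  }
  list(state = run$state, snapshots = run$snapshots, measurement = meas,
       spec = spec, params = params)
}

#' Run an experiment from a config file and write its outputs
#'
#' Reads a config (YAML or JSON) holding a `params` section and a `system`
#' section, runs [simulate_system()] under the given seed, and writes the
#' summary CSV, the cross-section profile CSV, the trajectory and a JSON
#' manifest into `outdir`. The manifest records the config snapshot, seed,
#' package version, timing and all warnings, and is written last so its
#' presence marks a complete run.
#'
#' @param config path to a config file, or a list with `params`
#'   (see [read_params()]) and `system` (arguments of [system_spec()]),
#'   or a preset name.
#' @param seed integer RNG seed.
#' @param outdir output directory (created if missing).
#' @param t_production,record_every see [simulate_system()].
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config, seed, outdir,
                           t_production = 9, record_every = 5000) {
  cfg <- .load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  t0 <- Sys.time()
  res <- simulate_system(cfg$spec, cfg$params,
                         t_production = t_production,
                         record_every = record_every)
  m <- res$measurement
  summary_df <- data.frame(
    seed = seed,
    F_tot_pN = m$F_tot, F_M_max_pN = m$F_M_max, eta = m$eta,
    steady_start_s = m$window$t_start, steady_end_s = m$window$t_end,
    steady_qualified = m$window$qualified
  )
  utils::write.csv(summary_df, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  ser <- m$series
  names(ser) <- c("time_s", "force_pN")
  utils::write.csv(ser, file.path(outdir, "force_series.csv"),
                   row.names = FALSE)
  sec <- m$sections
  names(sec) <- c("plane_nm", "actin_pN", "acp_pN", "motor_arm_pN",
                  "motor_backbone_pN", "total_pN")
  utils::write.csv(sec, file.path(outdir, "sections.csv"), row.names = FALSE)
  prof <- m$profiles[c("time", "axis", "plane", "actin", "acp", "motor_arm",
                       "motor_backbone", "total")]
  names(prof) <- c("time_s", "axis", "plane_nm", "actin_pN", "acp_pN",
                   "motor_arm_pN", "motor_backbone_pN", "total_pN")
  utils::write.csv(prof, file.path(outdir, "sections_timeseries.csv"),
                   row.names = FALSE)
  write_trajectory(res$snapshots, file.path(outdir, "trajectory.json"),
                   state = res$state)
  manifest <- list(
    package = "actomyosim",
    version = as.character(utils::packageVersion("actomyosim")),
    seed = seed,
    config = list(params = unclass(cfg$params), system = unclass(cfg$spec)),
    t_start = format(t0), t_end = format(Sys.time()),
    simulated_time_s = res$state$time,
    outputs = c("summary.csv", "force_series.csv", "sections.csv",
                "sections_timeseries.csv", "trajectory.json"),
    warnings = res$state$warnings
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1 && !file.exists(config) &&
      config %in% preset()) {
    return(list(spec = preset(config), params = default_params()))
  }
  if (is.character(config)) {
    x <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  } else x <- config
  if (is.null(x$system)) stop("config must contain a 'system' section")
  spec <- do.call(system_spec, x$system)
  params <- if (is.null(x$params)) default_params() else {
    known <- names(default_params_skeleton())
    bad <- setdiff(names(x$params), known)
    if (length(bad))
      stop("unknown key(s) in params section: ", paste(bad, collapse = ", "))
    do.call(default_params, x$params)
  }
  list(spec = spec, params = params)
}
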