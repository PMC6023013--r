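# Orchestrated parametric studies: magnet position, ancillary flow, mixer
# voltage/frequency sweeps, and the integrated separator -> mixer run.

#' Spread (dispersion) metric: max - min
#'
#' The outlet-sizing metric used throughout the sweeps: the spread of
#' wall-hit or terminal particle positions.
#'
#' @param x numeric vector of positions.
#' @return max(x) - min(x); NA if fewer than 2 finite values.
#' @export
spread_metric <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  max(x) - min(x)
}

new_sweep_result <- function(parameter, table, config, seed) {
  structure(list(parameter = parameter, table = table, config = config,
                 seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result over", x$parameter, "(seed", x$seed, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Magnet-position sweep
#'
#' Solves the separator flow once, then for each magnet x-position rebuilds
#' the analytic field, traces the three-tracer ensemble, and records the
#' wall-hit x-positions and their dispersion distance (max - min). A row is
#' complete only if all three tracers reach the bottom wall before `t_max`;
#' the minimizing position among complete rows is flagged.
#'
#' @param positions_mm magnet center x-positions (mm), at least 3.
#' @param config a `ctc_config`.
#' @param geometry separator geometry (default gradual).
#' @param flow optional pre-solved `flow_field` (solved once here otherwise).
#' @param seed stored with the result (tracer seeding is deterministic).
#' @param dt,t_max tracing controls.
#' @return a `sweep_result`; table columns `position_mm`, `x1..x3` (wall-hit
#'   positions, mm), `dispersion_mm`, `complete`, `is_minimum`.
#' @export
magnet_position_sweep <- function(positions_mm, config = default_config(),
                                  geometry = NULL, flow = NULL, seed = 1L,
                                  dt = 2e-4, t_max = 6) {
  if (length(positions_mm) < 3) stop_ctc("need at least 3 magnet positions")
  geometry <- geometry %||% build_geometry("separator_gradual")
  flow <- flow %||% solve_steady_flow(geometry, NULL, config)
  params <- force_model_params(config)
  wall_y <- geometry$bbox["ymin"]
  rows <- lapply(positions_mm, function(X) {
    cfgX <- config; cfgX$magnet$center_x <- X * 1e-3
    fm <- field_map_analytic(magnet_spec(cfgX, channel_bottom_y = wall_y),
                             mu_r = config$medium$mu_r,
                             mu0 = config$constants$mu0)
    ens <- seed_particles(geometry, 3, "three_tracers", seed = seed,
                          flow = flow)
    tr <- trace(ens, flow, fm, params, dt = dt, t_max = t_max)
    hit <- tr$status == "hit_bottom_wall"
    data.frame(position_mm = X,
               x1 = 1e3 * tr$wall_hit_x[1], x2 = 1e3 * tr$wall_hit_x[2],
               x3 = 1e3 * tr$wall_hit_x[3],
               dispersion_mm = if (all(hit)) 1e3 * tr$dispersion_distance
                               else NA_real_,
               complete = all(hit))
  })
  tab <- do.call(rbind, rows)
  tab$is_minimum <- FALSE
  ok <- which(tab$complete)
  if (length(ok)) tab$is_minimum[ok[which.min(tab$dispersion_mm[ok])]] <- TRUE
  new_sweep_result("magnet position (mm)", tab, config, seed)
}

#' Ancillary-flow study
#'
#' For each ancillary-inlet mean velocity: solve the flow, trace the three
#' tracers with the magnet off, and record the transverse positions where
#' they cross the channel terminal section (0.5 mm upstream of the outlets,
#' avoiding the stagnation wall between them), their spread (max - min), and
#' the recirculation-zone area.
#'
#' @param velocities ancillary mean velocities (m/s), >= 0.
#' @param kind separator geometry kind.
#' @param config a `ctc_config`.
#' @param seed stored with the result.
#' @param dt,t_max tracing controls.
#' @return a `sweep_result`; table columns `velocity`, `y1..y3` (transverse
#'   positions at the terminal section, mm), `spread_mm`, `vortex_area_m2`,
#'   `complete`.
#' @export
ancillary_flow_study <- function(velocities, kind = "separator_gradual",
                                 config = default_config(), seed = 1L,
                                 dt = 2e-4, t_max = 6) {
  if (any(velocities < 0)) stop_ctc("ancillary velocities must be >= 0")
  geometry <- build_geometry(kind)
  params <- force_model_params(config, tagged = FALSE)
  station <- geometry$bbox["xmax"] - 0.5e-3
  rows <- lapply(velocities, function(va) {
    fl <- tryCatch(
      solve_steady_flow(geometry, NULL, config,
                        bc_overrides = list(ancillary_inlet =
                                              list(type = "velocity", mean = va))),
      error = function(e) NULL)
    if (is.null(fl))
      return(data.frame(velocity = va, y1 = NA, y2 = NA, y3 = NA,
                        spread_mm = NA, vortex_area_m2 = NA, complete = FALSE))
    ens <- seed_particles(geometry, 3, "three_tracers", seed = seed, flow = fl)
    tr <- trace(ens, fl, NULL, params, dt = dt, t_max = t_max,
                station_x = station)
    rc <- detect_recirculation(fl)
    data.frame(velocity = va,
               y1 = 1e3 * tr$station_y[1],
               y2 = 1e3 * tr$station_y[2],
               y3 = 1e3 * tr$station_y[3],
               spread_mm = 1e3 * spread_metric(tr$station_y),
               vortex_area_m2 = rc$vortex_area,
               complete = !anyNA(tr$station_y))
  })
  new_sweep_result("ancillary velocity (m/s)", do.call(rbind, rows), config,
                   seed)
}

#' Mixer voltage/frequency sweeps
#'
#' Runs the mixer pipeline over a voltage x frequency factorial (or
#' one-at-a-time around the config defaults) and reports the period-averaged
#' mixing index per cell, the argmax frequency at each voltage, and the MI
#' ordering across voltages at each frequency.
#'
#' @param voltages drive amplitudes (V).
#' @param frequencies drive frequencies (Hz).
#' @param config a `ctc_config`.
#' @param t_end transport horizon (s).
#' @param factorial full factorial (default) or one-at-a-time.
#' @param unsteady passed to [periodic_flow()].
#' @return a `sweep_result`; table columns `v0`, `frequency`, `mi`.
#' @export
mixer_sweeps <- function(voltages, frequencies,
                         config = default_config("mixer"), t_end = 2,
                         factorial = TRUE, unsteady = TRUE) {
  if (!length(voltages) || !length(frequencies))
    stop_ctc("voltage and frequency lists must be non-empty")
  cells <- if (factorial) expand.grid(v0 = voltages, frequency = frequencies)
           else rbind(data.frame(v0 = voltages,
                                 frequency = config$electrodes$frequency),
                      data.frame(v0 = config$electrodes$v0,
                                 frequency = frequencies))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    rec <- suppressWarnings(
      run_mixer(config, v0 = cells$v0[i], frequency = cells$frequency[i],
                t_end = t_end, unsteady = unsteady))
    data.frame(v0 = cells$v0[i], frequency = cells$frequency[i], mi = rec$mi)
  })
  tab <- do.call(rbind, rows)
  res <- new_sweep_result("mixer drive (V0, f)", tab, config, seed = 0L)
  res$argmax_frequency <- vapply(unique(tab$v0), function(v) {
    sub <- tab[tab$v0 == v, ]
    sub$frequency[which.max(sub$mi)]
  }, numeric(1))
  names(res$argmax_frequency) <- unique(tab$v0)
  res
}

#' Integrated separator -> mixer run
#'
#' Runs the full chip: separator flow + magnetic field + 100-particle tagged
#' ensemble (and an untagged control ensemble with K = 0), computes the
#' capture fraction (bottom-wall hits plus bottom-outlet exits) and the
#' purity (tagged / total collected at the bottom), measures the bottom
#' outlet's mean velocity, and runs the mixer with inlet A carrying the
#' CTC-enriched stream at that velocity.
#'
#' @param config a `ctc_config`.
#' @param n particles per ensemble.
#' @param seed ensemble seed.
#' @param t_end mixer horizon (s).
#' @param dt,t_max separator tracing controls.
#' @return list with `separator` (tallies, capture fraction, purity, outlet
#'   mean velocities), `mixer` (a `mixing_record`), and `config`.
#' @export
integrated_run <- function(config = default_config("integrated"), n = 100,
                           seed = 1L, t_end = 2, dt = 2e-4, t_max = 6) {
  geometry <- build_geometry("separator_gradual")
  flow <- solve_steady_flow(geometry, NULL, config)
  fm <- field_map_analytic(magnet_spec(config,
                                       channel_bottom_y = geometry$bbox["ymin"]),
                           mu_r = config$medium$mu_r,
                           mu0 = config$constants$mu0)
  tagged <- trace(seed_particles(geometry, n, "uniform_inlet", seed = seed,
                                 flow = flow),
                  flow, fm, force_model_params(config, tagged = TRUE),
                  dt = dt, t_max = t_max)
  untagged <- trace(seed_particles(geometry, n, "uniform_inlet", seed = seed,
                                   flow = flow),
                    flow, fm, force_model_params(config, tagged = FALSE),
                    dt = dt, t_max = t_max)
  collected <- function(tr) sum(tr$status %in% c("hit_bottom_wall",
                                                 "exited_bottom_outlet"))
  cap_t <- collected(tagged); cap_u <- collected(untagged)
  purity <- if (cap_t + cap_u > 0) cap_t / (cap_t + cap_u) else NA_real_
  # bottom-outlet mean velocity feeds mixer inlet A
  g <- flow$grid
  yc <- g$y0 + (seq_len(g$ny) - 0.5) * g$hy
  ob <- geometry_segments(geometry, "outlet_bottom")
  bsel <- yc >= min(ob$y1, ob$y2) & yc <= max(ob$y1, ob$y2)
  u_out <- flow$u[g$nx + 1, ]
  v_handoff <- mean(u_out[bsel])
  mix_cfg <- config
  mix_cfg$flow$mixer_inlet_velocity <- v_handoff
  mixer <- suppressWarnings(run_mixer(mix_cfg, t_end = t_end))
  list(separator = list(
         tagged_tally = tagged$outlet_tally,
         untagged_tally = untagged$outlet_tally,
         capture_fraction = cap_t / n,
         untagged_capture_fraction = cap_u / n,
         purity = purity,
         bottom_outlet_mean_velocity = v_handoff),
       mixer = mixer,
       config = config)
}
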