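# Lagrangian tracing of tagged / untagged cells: Schiller-Naumann drag,
# magnetophoretic force, wall-capture and outlet-exit event detection,
# dispersion statistics, and the order-of-magnitude force audit.

#' Bundle force-model parameters
#'
#' @param config a `ctc_config`.
#' @param correlation drag law: `"schiller_naumann"` (default), `"stokes"`, or
#'   `"half_response"` (compatibility variant whose low-Reynolds response time is
#'   half the Stokes value; see the methods vignette).
#' @param tagged logical; untagged cells have `mu_r_p = mu_r`, i.e. K = 0.
#' @param include_gravity_buoyancy include net gravity-buoyancy in traces
#'   (off by default; see [force_audit()]).
#' @return list of drag and magnetic parameters, class `force_model_params`.
#' @export
force_model_params <- function(config = default_config(),
                               correlation = c("schiller_naumann", "stokes",
                                               "half_response"),
                               tagged = TRUE,
                               include_gravity_buoyancy = FALSE) {
  correlation <- match.arg(correlation)
  dp <- config$particle$diameter
  mu_r_p <- if (tagged) config$particle$mu_r_p else config$medium$mu_r
  K <- contrast_factor(mu_r_p, config$medium$mu_r)
  if (K <= -0.5 || K >= 1) stop_ctc("unphysical permeability contrast")
  structure(list(
    dp = dp, rp = dp / 2,
    rho_p = config$particle$density,
    rho_f = config$fluid$density,
    mu = config$fluid$viscosity,
    mu0 = config$constants$mu0,
    mu_r = config$medium$mu_r,
    mu_r_p = mu_r_p,
    K = K,
    g = config$constants$g,
    mp = config$particle$density * pi / 6 * dp^3,
    correlation = correlation,
    include_gravity_buoyancy = include_gravity_buoyancy
  ), class = "force_model_params")
}

#' Drag response time and drag coefficient
#'
#' Relative Reynolds number Re_r = rho_f |u - v| dp / mu, Schiller-Naumann
#' drag coefficient CD = 24/Re_r (1 + 0.15 Re_r^0.687), and the particle
#' response time tau_p = 4 rho_p dp^2 / (3 mu CD Re_r), handled through the
#' product CD*Re_r so the Stokes limit (CD*Re_r -> 24,
#' tau_p -> rho_p dp^2 / 18 mu) is exact at zero slip.
#'
#' @param params a `force_model_params`.
#' @param slip_speed |u - v| (m/s), scalar or vector.
#' @return list with `tau_p` (s), `CD` (Inf at zero slip), `Re_r`,
#'   `phi` (drag correction CD*Re_r/24).
#' @export
drag_response_time <- function(params, slip_speed) {
  if (any(slip_speed < 0)) stop_ctc("slip speed must be non-negative")
  if (params$mu <= 0) stop_ctc("fluid viscosity must be positive")
  Re <- params$rho_f * slip_speed * params$dp / params$mu
  phi <- if (params$correlation == "stokes") rep(1, length(Re))
         else 1 + 0.15 * Re^0.687
  cdre <- 24 * phi
  tau_stokes <- params$rho_p * params$dp^2 / (18 * params$mu)
  tau <- tau_stokes / phi
  if (params$correlation == "half_response") tau <- tau / 2
  list(tau_p = tau, CD = ifelse(Re > 0, cdre / Re, Inf), Re_r = Re, phi = phi)
}

#' Magnetophoretic force on a tagged cell
#'
#' F = 2 pi rp^3 mu0 mu_r K grad(|H|^2): the magnetic buoyancy force on a
#' sphere of permeability contrast K in a field-intensity gradient.
#'
#' @param params a `force_model_params`.
#' @param grad_h2 n x 2 matrix of grad(|H|^2) samples (A^2/m^3).
#' @return n x 2 matrix of force components (N).
#' @export
magnetophoretic_force <- function(params, grad_h2) {
  grad_h2 <- matrix(grad_h2, ncol = 2)
  2 * pi * params$rp^3 * params$mu0 * params$mu_r * params$K * grad_h2
}

# net gravity-buoyancy force per particle (N), downward negative y
gravity_buoyancy_force <- function(params) {
  vol <- (4 / 3) * pi * params$rp^3
  c(0, -vol * (params$rho_p - params$rho_f) * params$g)
}

# total external (non-drag) force at positions; n x 2
external_force <- function(params, field, pos) {
  F <- if (!is.null(field) && params$K != 0) {
    magnetophoretic_force(params, grad_H2(field, pos))
  } else matrix(0, nrow(pos), 2)
  if (params$include_gravity_buoyancy) {
    F <- sweep(F, 2, gravity_buoyancy_force(params), "+")
  }
  F
}

# overdamped particle velocity v = u + F/(3 pi mu dp phi(Re)); the drag
# correction is resolved by fixed-point iteration on the slip speed
overdamped_velocity <- function(params, flow, field, pos) {
  u <- interp_velocity(flow, pos, check = FALSE)
  F <- external_force(params, field, pos)
  drift <- F / (3 * pi * params$mu * params$dp)
  if (params$correlation != "stokes") {
    for (it in 1:3) {
      phi <- drag_response_time(params, sqrt(rowSums(drift^2)))$phi
      drift <- F / (3 * pi * params$mu * params$dp * phi)
    }
  }
  if (params$correlation == "half_response") drift <- drift / 2
  u + drift
}

# lower boundary chain of the separator polygon (used to classify wall hits)
lower_chain <- function(geometry) {
  v <- geometry$vertices
  xmax <- max(v[, 1])
  # vertices are CCW starting at the inlet-bottom corner; the lower chain runs
  # from the first vertex to the first vertex at x = xmax (minimal y there)
  stopi <- which(v[, 1] == xmax)[which.min(v[v[, 1] == xmax, 2])]
  v[1:stopi, , drop = FALSE]
}

#' Trace a particle ensemble through flow and magnetic field
#'
#' Integrates particle motion in the one-way-coupled limit. `"overdamped"`
#' (default) uses the force-balance limit v = u + F_ext/(3 pi mu dp phi) --
#' appropriate because the particle response time (microseconds) is far below
#' the transit time -- with classical RK4 on dx/dt = v(x). `"inertial_rk"`
#' integrates the full momentum equation m dv/dt = F_D + F_ext (RK4), which
#' requires dt <= tau_p / 2.
#'
#' Per-particle integration stops on bottom-wall capture (segment-crossing
#' detection with bisection to the wall), outlet exit, or `t_max`.
#'
#' @param ensemble a `particle_ensemble`.
#' @param flow a `flow_field`.
#' @param field a `magnetic_field_map` or NULL (no magnetic force).
#' @param params a `force_model_params`.
#' @param integrator `"overdamped"` or `"inertial_rk"`.
#' @param dt time step (s).
#' @param t_max maximum trace time (s).
#' @param store_times times (s) at which particle positions are recorded.
#' @param station_x optional x of a vertical station line (m); the transverse
#'   position at the first crossing is recorded per particle (`station_y`).
#' @return object of class `trace_result`: `status`, `wall_hit_x`,
#'   `final_positions`, `dispersion_distance` (max - min wall-hit x, m),
#'   `outlet_tally`, `snapshots` (list of n x 2 matrices at `store_times`),
#'   and `station_y` when `station_x` is given.
#' @export
trace <- function(ensemble, flow, field, params,
                  integrator = c("overdamped", "inertial_rk"),
                  dt = 2e-4, t_max = 2, store_times = numeric(0),
                  station_x = NULL) {
  integrator <- match.arg(integrator)
  if (dt <= 0) stop_ctc("dt must be positive")
  if (integrator == "inertial_rk") {
    tau0 <- params$rho_p * params$dp^2 / (18 * params$mu)
    if (params$correlation == "half_response") tau0 <- tau0 / 2
    if (dt > tau0 / 2)
      stop_ctc(sprintf("inertial integration requires dt <= tau_p/2 = %.3g s",
                       tau0 / 2))
  }
  geom <- flow$geometry
  if (!all(point_in_polygon(ensemble$positions[, 1], ensemble$positions[, 2],
                            geom$vertices)))
    stop_ctc("particle initialized outside the domain")
  n <- ensemble$n
  pos <- ensemble$positions
  vel <- ensemble$velocities
  status <- rep("in_flight", n)
  wall_x <- rep(NA_real_, n)
  xmax <- geom$bbox["xmax"]
  tol <- 1e-9
  segs <- geom$segments
  ob <- segs[segs$label %in% c("outlet_bottom", "mixer_outlet"), ]
  ot <- segs[segs$label == "outlet_top", ]
  low <- lower_chain(geom)
  dist_lower <- function(px, py) {
    d <- rep(Inf, length(px))
    for (s in seq_len(nrow(low) - 1))
      d <- pmin(d, point_segment_distance(px, py, low[s, 1], low[s, 2],
                                          low[s + 1, 1], low[s + 1, 2]))
    d
  }

  store_times <- sort(unique(store_times))
  snapshots <- vector("list", length(store_times))
  names(snapshots) <- format(store_times)
  si <- 1L
  station_y <- rep(NA_real_, n)
  # wall capture requires an attractive external force; force-free tracers
  # that graze the staircase boundary are held inside instead
  can_capture <- (!is.null(field) && params$K != 0) ||
    params$include_gravity_buoyancy

  deriv <- function(p) overdamped_velocity(params, flow, field, p)

  nsteps <- ceiling(t_max / dt)
  t <- 0
  for (step in seq_len(nsteps)) {
    act <- status == "in_flight"
    if (!any(act)) break
    pa <- pos[act, , drop = FALSE]
    if (integrator == "overdamped") {
      k1 <- deriv(pa)
      k2 <- deriv(pa + dt / 2 * k1)
      k3 <- deriv(pa + dt / 2 * k2)
      k4 <- deriv(pa + dt * k3)
      newp <- pa + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      newv <- k1
    } else {
      va <- vel[act, , drop = FALSE]
      acc <- function(p, v) {
        u <- interp_velocity(flow, p, check = FALSE)
        slip <- sqrt(rowSums((u - v)^2))
        taup <- drag_response_time(params, slip)$tau_p
        Fx <- external_force(params, field, p)
        (u - v) / taup + Fx / params$mp
      }
      a1 <- acc(pa, va);                          p1 <- va
      a2 <- acc(pa + dt / 2 * p1, va + dt / 2 * a1); p2 <- va + dt / 2 * a1
      a3 <- acc(pa + dt / 2 * p2, va + dt / 2 * a2); p3 <- va + dt / 2 * a2
      a4 <- acc(pa + dt * p3, va + dt * a3);         p4 <- va + dt * a3
      newp <- pa + dt / 6 * (p1 + 2 * p2 + 2 * p3 + p4)
      newv <- va + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4)
    }
    inside <- point_in_polygon(newp[, 1], newp[, 2], geom$vertices)
    if (any(!inside)) {
      # bisect each exiting segment to the boundary crossing
      out_idx <- which(!inside)
      for (q in out_idx) {
        a <- pa[q, ]; b <- newp[q, ]
        for (itb in 1:25) {
          m <- (a + b) / 2
          if (point_in_polygon(m[1], m[2], geom$vertices)) a <- m else b <- m
        }
        cross <- (a + b) / 2
        gi <- which(act)[q]
        if (cross[1] >= xmax - max(flow$grid$hx, 1e-6)) {
          inb <- nrow(ob) > 0 && cross[2] >= min(ob$y1, ob$y2) - tol &&
                 cross[2] <= max(ob$y1, ob$y2) + tol
          int <- nrow(ot) > 0 && cross[2] >= min(ot$y1, ot$y2) - tol &&
                 cross[2] <= max(ot$y1, ot$y2) + tol
          if (!inb && !int && !can_capture) {
            newp[q, ] <- a     # grazing the end wall without a capture force
            next
          }
          status[gi] <- if (inb) "exited_bottom_outlet"
                        else if (int) "exited_top_outlet"
                        else "hit_bottom_wall"  # right wall between outlets
          if (!inb && !int) wall_x[gi] <- cross[1]
          pos[gi, ] <- cross
          newp[q, ] <- cross
        } else if (can_capture &&
                   dist_lower(cross[1], cross[2]) <
                   0.5 * min(flow$grid$hx, flow$grid$hy)) {
          status[gi] <- "hit_bottom_wall"
          wall_x[gi] <- cross[1]
          pos[gi, ] <- cross
          newp[q, ] <- cross
        } else {
          # grazing contact with the upper boundary: hold at the entry point
          newp[q, ] <- a
        }
      }
    }
    if (!is.null(station_x)) {
      gact <- which(act)
      crossed <- is.na(station_y[gact]) & pa[, 1] < station_x &
        newp[, 1] >= station_x
      if (any(crossed)) {
        w <- (station_x - pa[crossed, 1]) /
          (newp[crossed, 1] - pa[crossed, 1])
        station_y[gact[crossed]] <- pa[crossed, 2] +
          w * (newp[crossed, 2] - pa[crossed, 2])
      }
    }
    act2 <- status[which(act)] == "in_flight"
    sel <- which(act)[act2]
    pos[sel, ] <- newp[act2, , drop = FALSE]
    vel[sel, ] <- newv[act2, , drop = FALSE]
    t <- t + dt
    while (si <= length(store_times) && store_times[si] <= t + 1e-12) {
      snapshots[[si]] <- pos
      si <- si + 1L
    }
  }
  status[status == "in_flight"] <- "trapped_max_time"
  while (si <= length(store_times)) { snapshots[[si]] <- pos; si <- si + 1L }
  hits <- wall_x[!is.na(wall_x)]
  structure(list(
    status = status,
    wall_hit_x = wall_x,
    final_positions = pos,
    final_velocities = vel,
    dispersion_distance = if (length(hits) >= 2) max(hits) - min(hits) else
      if (length(hits) == 1) 0 else NA_real_,
    outlet_tally = c(top = sum(status == "exited_top_outlet"),
                     bottom = sum(status == "exited_bottom_outlet"),
                     captured = sum(status == "hit_bottom_wall"),
                     trapped = sum(status == "trapped_max_time")),
    store_times = store_times,
    snapshots = snapshots,
    station_x = station_x,
    station_y = station_y,
    rng_seed = ensemble$rng_seed,
    t_end = t, dt = dt, integrator = integrator
  ), class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat("trace_result:", length(x$status), "particles;",
      paste(names(x$outlet_tally), x$outlet_tally, sep = "=", collapse = ", "),
      "\n")
  if (!is.na(x$dispersion_distance))
    cat(sprintf("  wall-hit dispersion distance: %.4f mm\n",
                1e3 * x$dispersion_distance))
  invisible(x)
}

#' Ensemble statistics over time
#'
#' Mean transverse position and histogram of transverse positions at the
#' requested times (captured particles are held at their capture location).
#'
#' @param result a `trace_result` whose `store_times` cover `times`.
#' @param times times to report (s); must be among the stored snapshots.
#' @param breaks histogram bin count.
#' @return list with `summary` (data.frame time, mean_y, sd_y) and
#'   `histograms` (list of `hist` objects).
#' @export
ensemble_statistics <- function(result, times = result$store_times,
                                breaks = 10) {
  if (length(result$status) == 0) stop_ctc("empty ensemble")
  idx <- match(times, result$store_times)
  if (anyNA(idx)) stop_ctc("requested time not among stored snapshots")
  ally <- unlist(lapply(result$snapshots[idx], function(s) s[, 2]))
  brks <- seq(min(ally), max(ally) + 1e-12, length.out = breaks + 1)
  hists <- lapply(idx, function(i)
    graphics::hist(result$snapshots[[i]][, 2], breaks = brks, plot = FALSE))
  summ <- data.frame(
    time = times,
    mean_y = vapply(idx, function(i) mean(result$snapshots[[i]][, 2]), 0),
    sd_y = vapply(idx, function(i) stats::sd(result$snapshots[[i]][, 2]), 0))
  list(summary = summ, histograms = hists)
}

#' Order-of-magnitude force audit
#'
#' Evaluates the characteristic magnitude of every force the transport model
#' considers: gravity (4/3 pi Rc^3 rho_c g), buoyancy (same with rho_f),
#' characteristic Stokes drag 3 pi mu dp U_slip, and the magnetophoretic
#' force at a reference point near the magnet. Forces below 1% of the largest
#' are classified "negligible", others "retained". DLVO, Brownian and
#' interparticle forces are excluded by assumption (dilute, surface-treated
#' suspension) and reported as such.
#'
#' @param config a `ctc_config`.
#' @param field optional `magnetic_field_map`; built from the config when NULL.
#' @param reference_point point for the magnetophoretic evaluation (m);
#'   default: channel bottom wall above the magnet center.
#' @param slip_speed characteristic slip speed for the drag entry (m/s).
#' @return object of class `force_audit_report`.
#' @export
force_audit <- function(config = default_config(), field = NULL,
                        reference_point = NULL, slip_speed = NULL) {
  Rc <- particle_radius(config)
  vol <- (4 / 3) * pi * Rc^3
  g <- config$constants$g
  Fg <- vol * config$particle$density * g
  Fb <- vol * config$fluid$density * g
  U <- slip_speed %||% config$flow$main_inlet_velocity
  Fd <- 3 * pi * config$fluid$viscosity * config$particle$diameter * U
  if (is.null(field)) field <- field_map_analytic(magnet_spec(config),
                                                  mu_r = config$medium$mu_r,
                                                  mu0 = config$constants$mu0)
  if (is.null(reference_point)) {
    m <- field$magnet
    reference_point <- c(m$center[1], m$center[2] + m$height / 2 +
                           m$standoff + 1e-4)
  }
  params <- force_model_params(config)
  Fm <- sqrt(sum(magnetophoretic_force(params,
                                       grad_H2(field, rbind(reference_point)))^2))
  forces <- c(gravity = Fg, buoyancy = Fb, drag = Fd, magnetophoretic = Fm)
  cls <- ifelse(forces >= 0.01 * max(forces), "retained", "negligible")
  structure(list(
    forces = forces, classification = cls,
    reference_point = reference_point,
    excluded_by_assumption = c("DLVO", "Brownian", "interparticle"),
    note = paste("Gravity and buoyancy are about two orders of magnitude",
                 "below the magnetophoretic force at the reference point;",
                 "DLVO, Brownian and interparticle forces are excluded by",
                 "the dilute, surface-treated-suspension assumption.")
  ), class = "force_audit_report")
}

#' @export
print.force_audit_report <- function(x, ...) {
  cat("force audit (N):\n")
  for (nm in names(x$forces))
    cat(sprintf("  %-16s %.3e  (%s)\n", nm, x$forces[nm],
                x$classification[nm]))
  cat("  excluded by assumption:",
      paste(x$excluded_by_assumption, collapse = ", "), "\n")
  invisible(x)
}
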