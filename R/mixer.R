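# Y-mixer electrokinetics: quasi-static electric field of the zigzag
# electrode array, Helmholtz-Smoluchowski wall slip, time-periodic Stokes
# flow (harmonic unsteady response by default, quasi-steady superposition as
# an option), passive-scalar transport of the lysis-buffer/CTC interface, and
# the coefficient-of-variation mixing index.

#' Electrode array description
#'
#' Reads the `electrode_k` segments from the mixer geometry and attaches the
#' drive: adjacent electrodes along the channel (which alternate walls in the
#' zigzag layout) are driven in antiphase, electrode k carrying phase sign
#' (-1)^(k+1).
#'
#' @param geometry a mixer `device_geometry`.
#' @param config a `ctc_config` (drive amplitude, frequency, waveform).
#' @return object of class `electrode_array`.
#' @export
electrode_array <- function(geometry, config = default_config("mixer")) {
  segs <- geometry$segments
  es <- segs[grepl("^electrode_", segs$label), , drop = FALSE]
  if (nrow(es) == 0) stop_ctc("geometry has no electrode segments")
  k <- as.integer(sub("^electrode_", "", es$label))
  es <- es[order(k), ]; k <- sort(k)
  W <- geometry$dims$channel_width
  structure(list(
    segments = data.frame(k = k, x1 = es$x1, x2 = es$x2, y = es$y1,
                          wall = ifelse(es$y1 == 0, "bottom", "top"),
                          sign = (-1)^(k + 1)),
    v0 = config$electrodes$v0,
    frequency = config$electrodes$frequency,
    waveform = config$electrodes$waveform %||% "sinusoid"
  ), class = "electrode_array")
}

#' Solve the quasi-static electric field of the electrode array
#'
#' Solves div(sigma grad V) = 0 (uniform conductivity, no impressed currents
#' or sources) with V = +-1 on the electrode wall segments (unit spatial
#' mode; the drive amplitude and waveform scale it in time) and zero normal
#' current on all other boundaries.
#'
#' @param geometry mixer `device_geometry`.
#' @param grid a `grid2d` over the mixer (full rectangle).
#' @param array an `electrode_array`.
#' @return list with `V` (nx x ny cell potentials for unit drive), `Ex`, `Ey`
#'   (cell-centered), `Et_bottom`, `Et_top` (tangential E at the wall u-face
#'   stations, length nx+1), grid.
#' @export
solve_electric_field <- function(geometry, grid, array) {
  if (length(unique(array$segments$sign)) < 2)
    stop_ctc("all electrodes share one phase sign: potential defined only up to a constant")
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  x0 <- grid$x0; y0 <- grid$y0
  N <- nx * ny
  id <- function(ci, j) (j - 1L) * nx + ci
  # electrode lookup for a bottom/top wall face midpoint
  esb <- array$segments[array$segments$wall == "bottom", ]
  est <- array$segments[array$segments$wall == "top", ]
  elec_sign <- function(x, wall) {
    e <- if (wall == "bottom") esb else est
    hit <- which(x >= pmin(e$x1, e$x2) & x <= pmax(e$x1, e$x2))
    if (length(hit)) e$sign[hit[1]] else NA_real_
  }
  rows <- integer(0); cols <- integer(0); vals <- numeric(0); rhs <- numeric(N)
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  me <- id(ii, jj)
  diagv <- numeric(N)
  # interior x neighbours
  for (s in c(-1L, 1L)) {
    keep <- ii + s >= 1 & ii + s <= nx
    rows <- c(rows, me[keep]); cols <- c(cols, id(ii + s, jj)[keep])
    vals <- c(vals, rep(1 / hx^2, sum(keep)))
    diagv[keep] <- diagv[keep] - 1 / hx^2
    # channel ends: insulating (zero-gradient) -> no diagonal contribution
  }
  for (s in c(-1L, 1L)) {
    keep <- jj + s >= 1 & jj + s <= ny
    rows <- c(rows, me[keep]); cols <- c(cols, id(ii, jj + s)[keep])
    vals <- c(vals, rep(1 / hy^2, sum(keep)))
    diagv[keep] <- diagv[keep] - 1 / hy^2
    # wall faces: electrode segments are Dirichlet via linear ghost, plain
    # walls are insulating
    wallcells <- which(!keep)
    for (q in wallcells) {
      x <- x0 + (ii[q] - 0.5) * hx
      sg <- elec_sign(x, if (s == -1L) "bottom" else "top")
      if (!is.na(sg)) {
        # Dirichlet via linear ghost (V_ghost = 2 V_e - V_c): the face flux
        # is (2 V_e - 2 V_c) / h^2
        diagv[q] <- diagv[q] - 2 / hy^2
        rhs[me[q]] <- rhs[me[q]] - 2 * sg / hy^2
      }
    }
  }
  rows <- c(rows, me); cols <- c(cols, me)
  vals <- c(vals, diagv - 1e-12)  # regularize the pure-Neumann nullspace
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  V <- matrix(as.numeric(Matrix::solve(A, rhs)), nx, ny)
  Ex <- matrix(0, nx, ny); Ey <- matrix(0, nx, ny)
  Ex[2:(nx - 1), ] <- -(V[3:nx, ] - V[1:(nx - 2), ]) / (2 * hx)
  Ey[, 2:(ny - 1)] <- -(V[, 3:ny] - V[, 1:(ny - 2)]) / (2 * hy)
  # tangential E at the wall, at u-face stations: extrapolate the potential to
  # the wall from the two nearest cell rows, then difference along x
  wall_Et <- function(jrow1, jrow2, wall) {
    Vw <- 1.5 * V[, jrow1] - 0.5 * V[, jrow2]
    # on electrodes the wall potential is the electrode potential
    xs <- x0 + (seq_len(nx) - 0.5) * hx
    for (ci in seq_len(nx)) {
      sg <- elec_sign(xs[ci], wall)
      if (!is.na(sg)) Vw[ci] <- sg
    }
    Et <- numeric(nx + 1)
    Et[2:nx] <- -(Vw[2:nx] - Vw[1:(nx - 1)]) / hx
    Et
  }
  list(V = V, Ex = Ex, Ey = Ey,
       Et_bottom = wall_Et(1, 2, "bottom"),
       Et_top = wall_Et(ny, ny - 1, "top"),
       grid = grid)
}

#' Helmholtz-Smoluchowski slip velocity
#'
#' u_T = -(eps_w zeta / eta) E_t: the effective wall velocity replacing the
#' unresolved electric double layer.
#'
#' @param Et tangential electric field at the wall (V/m), scalar or vector.
#' @param config a `ctc_config` (zeta potential, permittivity, viscosity).
#' @return slip velocity (m/s), same shape as `Et`.
#' @export
slip_velocity <- function(Et, config = default_config("mixer")) {
  if (config$fluid$viscosity <= 0) stop_ctc("viscosity must be positive")
  epsw <- config$constants$eps0 * config$fluid$eps_r
  -(epsw * config$electrokinetics$zeta / config$fluid$viscosity) * Et
}

# build a slip_bc closure for the flow solver from wall-station slip arrays
slip_bc_from_arrays <- function(grid, s_bottom, s_top) {
  x0 <- grid$x0; hx <- grid$hx
  ybot <- grid$y0; ytop <- grid$y0 + grid$ny * grid$hy
  function(x, y, orient) {
    if (orient != "h") return(0)
    a <- round((x - x0) / hx) + 1
    a <- min(max(a, 1), grid$nx + 1)
    if (abs(y - ybot) < abs(y - ytop)) s_bottom[a] else s_top[a]
  }
}

#' Time-periodic mixer flow
#'
#' Exploits linearity of the Stokes regime: one pressure-driven base solve
#' plus one electroosmotic slip mode. With `unsteady = TRUE` (default) the
#' slip mode is the harmonic response of the unsteady Stokes equations at the
#' drive frequency (i omega rho u = mu lap u - grad p), which captures the
#' finite response time of the fluid: above the viscous corner frequency of
#' the channel the bulk no longer follows the drive and the actuation
#' amplitude falls off. With `unsteady = FALSE` the mode is the steady Stokes
#' solution scaled by the instantaneous waveform (quasi-steady
#' superposition).
#'
#' @param geometry mixer `device_geometry`.
#' @param grid a `grid2d`.
#' @param config a `ctc_config`.
#' @param array an `electrode_array`.
#' @param efield optional result of [solve_electric_field()].
#' @param unsteady include fluid inertia in the oscillatory mode.
#' @return object of class `periodic_flow`: base `flow_field`, mode fields
#'   `ur`, `vr` (in-phase with sin(omega t)) and `ui`, `vi` (quadrature),
#'   `omega`, and `velocity_at(t)` returning face arrays (u, v).
#' @export
periodic_flow <- function(geometry, grid, config = default_config("mixer"),
                          array = electrode_array(geometry, config),
                          efield = NULL, unsteady = TRUE) {
  Re <- config$fluid$density * config$flow$mixer_inlet_velocity *
    geometry$dims$channel_width / config$fluid$viscosity
  if (Re > 1)
    warning("base-flow Reynolds number >= 1: linear superposition is approximate")
  if (is.null(efield)) efield <- solve_electric_field(geometry, grid, array)
  base <- solve_steady_flow(geometry, grid, config, stokes = TRUE)
  s_bot <- slip_velocity(efield$Et_bottom, config) * array$v0
  s_top <- slip_velocity(efield$Et_top, config) * array$v0
  slip <- slip_bc_from_arrays(grid, s_bot, s_top)
  zerobc <- list(mixer_inlet_A = list(type = "velocity", mean = 0),
                 mixer_inlet_B = list(type = "velocity", mean = 0))
  omega <- 2 * pi * array$frequency
  if (!unsteady) {
    mode <- solve_steady_flow(geometry, grid, config, slip_bc = slip,
                              stokes = TRUE, bc_overrides = zerobc)
    ur <- mode$u; vr <- mode$v
    ui <- matrix(0, nrow(ur), ncol(ur)); vi <- matrix(0, nrow(vr), ncol(vr))
  } else {
    hm <- solve_harmonic_stokes(geometry, grid, config, slip, zerobc, omega)
    ur <- hm$ur; vr <- hm$vr; ui <- hm$ui; vi <- hm$vi
  }
  wf <- function(t) sin(omega * t)     # drive V(t) = V0 sin(omega t)
  wfq <- function(t) cos(omega * t)
  structure(list(
    base = base, ur = ur, vr = vr, ui = ui, vi = vi, omega = omega,
    array = array, efield = efield, grid = grid, geometry = geometry,
    unsteady = unsteady,
    velocity_at = function(t) {
      a <- wf(t); b <- wfq(t)
      list(u = base$u + a * ur + b * ui, v = base$v + a * vr + b * vi)
    }
  ), class = "periodic_flow")
}

# harmonic unsteady Stokes: i omega rho u = mu lap u - grad p with boundary
# slip applied to the in-phase (sin) component. Solved as a real 2x2 block
# system over (in-phase, quadrature) parts.
solve_harmonic_stokes <- function(geometry, grid, config, slip, bc_overrides,
                                  omega) {
  bc <- default_flow_bc(geometry, config)
  bc[names(bc_overrides)] <- bc_overrides
  fc <- classify_faces(grid, bc, profile = config$flow$profile %||% "parabolic")
  sys_r <- assemble_flow_system(grid, fc, config, slip = slip)
  nvel <- sys_r$nu + sys_r$nv
  N <- nrow(sys_r$A)
  rhs_i <- numeric(N)  # quadrature part has homogeneous BCs
  # with drive sin(omega t): u = ur sin + ui cos; substituting into
  # rho du/dt = mu lap u - grad p gives, for the sin/cos components,
  #   [L  -omega*rho*I] [ur]   [rhs_r]
  #   [omega*rho*I   L] [ui] = [0]
  # where L is the steady Stokes operator (momentum rows only get the mass
  # coupling; continuity rows do not)
  m <- omega * config$fluid$density
  Ivel <- Matrix::sparseMatrix(i = seq_len(nvel), j = seq_len(nvel),
                               x = rep(m, nvel), dims = c(N, N))
  A <- rbind(cbind(sys_r$A, -Ivel), cbind(Ivel, sys_r$A))
  rhs <- c(sys_r$rhs, rhs_i)
  sol <- as.numeric(Matrix::solve(A, rhs))
  fr <- unpack_flow(sol[1:N], grid, fc, sys_r)
  fc0 <- fc; fc0$uval[] <- 0; fc0$vval[] <- 0  # quadrature BC values are zero
  fi <- unpack_flow(sol[N + (1:N)], grid, fc0, sys_r)
  list(ur = fr$u, vr = fr$v, ui = fi$u, vi = fi$v,
       pr = fr$p, pi = fi$p)
}

#' @export
print.periodic_flow <- function(x, ...) {
  cat(sprintf("periodic_flow: f = %g Hz, V0 = %g V, %s mode; max slip-mode |u| = %.3g m/s\n",
              x$omega / (2 * pi), x$array$v0,
              if (x$unsteady) "harmonic (inertial)" else "quasi-steady",
              max(abs(x$ur), abs(x$vr), abs(x$ui), abs(x$vi))))
  invisible(x)
}

# ---- scalar transport -----------------------------------------------------

#' Advect and diffuse the species concentration
#'
#' Explicit conservative finite-volume transport of the dimensionless
#' concentration on the mixer grid: first-order upwind convection (satisfies
#' the discrete maximum principle under the CFL bound, which is checked and
#' auto-reduced) plus isotropic diffusion. Inlet A carries c = 1, inlet B
#' c = 0, walls are no-flux, the outlet is advective.
#'
#' @param pflow a `periodic_flow` (or a steady `flow_field` for u = const).
#' @param config a `ctc_config` (diffusivity).
#' @param t_end end time (s).
#' @param dt time step (s); auto-selected from the CFL bound when NULL, and
#'   reduced with a warning if the supplied value violates it.
#' @param c0 initial field (nx x ny); default: unmixed parallel streams
#'   (c = 1 in the upper half fed by inlet A).
#' @param record_times times at which the mixing index is evaluated; default
#'   16 per drive period over the horizon.
#' @param sample_x x of the transverse sampling line (m); default 0.5 mm
#'   upstream of the outlet.
#' @param n_pixels sample count on the line.
#' @return object of class `mixing_record`: data.frame `series` (t, CoV, MI),
#'   scalar `mi` (time-average of MI over the last drive period), final
#'   concentration matrix `c`, `sample_x`, `n_pixels`.
#' @export
advect_diffuse <- function(pflow, config = default_config("mixer"),
                           t_end = 2, dt = NULL, c0 = NULL,
                           record_times = NULL, sample_x = NULL,
                           n_pixels = 100) {
  D <- config$electrokinetics$diffusivity
  if (D < 0) stop_ctc("diffusivity must be non-negative")
  g <- pflow$grid
  nx <- g$nx; ny <- g$ny; hx <- g$hx; hy <- g$hy
  W <- ny * hy
  steady <- inherits(pflow, "flow_field")
  vel_at <- if (steady) function(t) list(u = pflow$u, v = pflow$v)
            else pflow$velocity_at
  # CFL bound from the maximum possible face speed over a period
  amp_u <- if (steady) abs(pflow$u) else
    abs(pflow$base$u) + sqrt(pflow$ur^2 + pflow$ui^2)
  amp_v <- if (steady) abs(pflow$v) else
    abs(pflow$base$v) + sqrt(pflow$vr^2 + pflow$vi^2)
  umax <- max(amp_u) / hx + max(amp_v) / hy
  dt_cfl <- 0.3 / max(umax, 1e-12)
  dt_diff <- 0.2 * min(hx, hy)^2 / max(D, 1e-300)
  period <- if (steady) Inf else 2 * pi / pflow$omega
  dt_auto <- min(dt_cfl, dt_diff, period / 32, t_end / 10)
  if (is.null(dt)) dt <- dt_auto
  else if (dt > min(dt_cfl, dt_diff)) {
    warning(sprintf("dt = %.3g violates the CFL bound; reduced to %.3g", dt,
                    dt_auto))
    dt <- dt_auto
  }
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  if (is.null(sample_x)) sample_x <- g$x0 + nx * hx - 0.5e-3
  if (is.null(record_times)) {
    drec <- if (is.finite(period)) period / 16 else t_end / 64
    record_times <- seq(0, t_end, by = drec)
  }
  # inlet concentrations by wall-face row: inlet A is the upper half
  yc <- g$y0 + (seq_len(ny) - 0.5) * hy
  c_in <- ifelse(yc > g$y0 + W / 2, 1, 0)
  cc <- c0 %||% matrix(rep(c_in, each = nx), nx, ny)
  sample_line <- function(cm) {
    ys <- seq(g$y0 + hy / 2, g$y0 + W - hy / 2, length.out = n_pixels)
    bilinear(cm, g$x0 + hx / 2, g$y0 + hy / 2, hx, hy,
             rep(sample_x, n_pixels), ys)
  }
  rec_t <- c(); rec_cov <- c(); rec_mi <- c()
  record <- function(t, cm) {
    ci <- sample_line(cm)
    mi <- mixing_index_values(ci)
    rec_t <<- c(rec_t, t); rec_cov <<- c(rec_cov, mi["CoV"])
    rec_mi <<- c(rec_mi, mi["MI"])
  }
  ri <- 1L
  while (ri <= length(record_times) && record_times[ri] <= 0) {
    record(0, cc); ri <- ri + 1L
  }
  t <- 0
  dif_x <- D / hx^2; dif_y <- D / hy^2
  for (step in seq_len(nsteps)) {
    vv <- vel_at(t + dt / 2)
    u <- vv$u; v <- vv$v
    # MUSCL/minmod limited upwind face values (TVD: preserves the discrete
    # maximum principle while staying second order away from extrema)
    cpx <- rbind(c_in, c_in, cc, cc[nx, ], cc[nx, ])  # two ghost rows each side
    cLL <- cpx[1:(nx + 1), ]; cL <- cpx[2:(nx + 2), ]
    cRx <- cpx[3:(nx + 3), ]; cRR <- cpx[4:(nx + 4), ]
    fpos <- cL + 0.5 * minmod(cRx - cL, cL - cLL)
    fneg <- cRx - 0.5 * minmod(cRx - cL, cRR - cRx)
    fx <- u * ifelse(u >= 0, fpos, fneg)
    cpy <- cbind(cc[, 1], cc[, 1], cc, cc[, ny], cc[, ny])
    cBB <- cpy[, 1:(ny + 1)]; cB <- cpy[, 2:(ny + 2)]
    cT <- cpy[, 3:(ny + 3)]; cTT <- cpy[, 4:(ny + 4)]
    gpos <- cB + 0.5 * minmod(cT - cB, cB - cBB)
    gneg <- cT - 0.5 * minmod(cT - cB, cTT - cT)
    fy <- v * ifelse(v >= 0, gpos, gneg)
    adv <- (fx[2:(nx + 1), ] - fx[1:nx, ]) / hx +
           (fy[, 2:(ny + 1)] - fy[, 1:ny]) / hy
    # diffusion (no-flux walls, Dirichlet inflow only through advection)
    lap <- matrix(0, nx, ny)
    lap[2:(nx - 1), ] <- lap[2:(nx - 1), ] +
      dif_x * (cc[3:nx, ] - 2 * cc[2:(nx - 1), ] + cc[1:(nx - 2), ])
    lap[1, ] <- lap[1, ] + dif_x * (cc[2, ] - cc[1, ])
    lap[nx, ] <- lap[nx, ] + dif_x * (cc[nx - 1, ] - cc[nx, ])
    lap[, 2:(ny - 1)] <- lap[, 2:(ny - 1)] +
      dif_y * (cc[, 3:ny] - 2 * cc[, 2:(ny - 1)] + cc[, 1:(ny - 2)])
    lap[, 1] <- lap[, 1] + dif_y * (cc[, 2] - cc[, 1])
    lap[, ny] <- lap[, ny] + dif_y * (cc[, ny - 1] - cc[, ny])
    cc <- cc - dt * adv + dt * lap
    t <- t + dt
    while (ri <= length(record_times) && record_times[ri] <= t + 1e-12) {
      record(t, cc); ri <- ri + 1L
    }
  }
  series <- data.frame(t = rec_t, CoV = rec_cov, MI = rec_mi)
  lastp <- if (is.finite(period)) series$t >= t_end - period - 1e-9
           else series$t == max(series$t)
  structure(list(series = series, mi = mean(series$MI[lastp]),
                 c = cc, sample_x = sample_x, n_pixels = n_pixels,
                 t_end = t_end, dt = dt),
            class = "mixing_record")
}

#' @export
print.mixing_record <- function(x, ...) {
  cat(sprintf("mixing_record: MI = %.4f (period-averaged at t = %g s), %d samples on line x = %.2f mm\n",
              x$mi, x$t_end, x$n_pixels, 1e3 * x$sample_x))
  invisible(x)
}

# componentwise minmod slope limiter
minmod <- function(a, b) {
  s <- (sign(a) + sign(b)) / 2
  s * pmin(abs(a), abs(b))
}

# CoV / MI of sampled pixel values (n-1 denominator)
mixing_index_values <- function(ci) {
  cavg <- mean(ci)
  if (cavg == 0) stop_ctc("mean concentration on the sample line is zero; CoV undefined")
  cov <- stats::sd(ci) / cavg
  c(CoV = cov, MI = 1 - cov)
}

#' Mixing index on a transverse sample line
#'
#' Samples the concentration at `n` uniformly spaced pixels across the
#' channel on the vertical line `x = sample_x` and returns the coefficient of
#' variation CoV = sd(ci)/mean(ci) (n-1 denominator) and the mixing index
#' M.I = 1 - CoV (1 = perfectly mixed).
#'
#' @param conc concentration matrix (nx x ny) or a `mixing_record`.
#' @param grid the `grid2d` the concentrations live on (not needed for a
#'   `mixing_record`).
#' @param sample_x x position of the line (m).
#' @param n pixel count (>= 2).
#' @return named vector `c(CoV, MI)`.
#' @export
mixing_index <- function(conc, grid = NULL, sample_x, n = 100) {
  if (n < 2) stop_ctc("need at least 2 pixels")
  if (inherits(conc, "mixing_record")) stop_ctc("pass the concentration matrix")
  g <- grid
  ys <- seq(g$y0 + g$hy / 2, g$y0 + g$ny * g$hy - g$hy / 2, length.out = n)
  if (sample_x < g$x0 || sample_x > g$x0 + g$nx * g$hx)
    stop_ctc("sample line outside the domain")
  ci <- bilinear(conc, g$x0 + g$hx / 2, g$y0 + g$hy / 2, g$hx, g$hy,
                 rep(sample_x, n), ys)
  mixing_index_values(ci)
}

#' Run the mixer pipeline at one operating point
#'
#' Electric-field solve, Helmholtz-Smoluchowski slip, periodic Stokes flow,
#' and scalar transport from the unmixed parallel-stream initial condition;
#' reports the mixing-index time series and its period-averaged scalar.
#'
#' @param config a `ctc_config`.
#' @param v0 drive amplitude (V); default from config.
#' @param frequency drive frequency (Hz); default from config.
#' @param t_end transport horizon (s).
#' @param nx,ny grid; default from `config$solver$mixer_nx/ny`.
#' @param unsteady passed to [periodic_flow()].
#' @return a `mixing_record` (see [advect_diffuse()]); its `pflow` attribute
#'   holds the periodic flow.
#' @export
run_mixer <- function(config = default_config("mixer"), v0 = NULL,
                      frequency = NULL, t_end = 2, nx = NULL, ny = NULL,
                      unsteady = TRUE) {
  cfg <- config
  if (!is.null(v0)) cfg$electrodes$v0 <- v0
  if (!is.null(frequency)) cfg$electrodes$frequency <- frequency
  geom <- build_geometry("mixer_Y")
  grid <- build_grid(geom, nx %||% cfg$solver$mixer_nx,
                     ny %||% cfg$solver$mixer_ny)
  arr <- electrode_array(geom, cfg)
  ef <- solve_electric_field(geom, grid, arr)
  pf <- if (cfg$electrodes$v0 == 0) {
    solve_steady_flow(geom, grid, cfg, stokes = TRUE)
  } else {
    periodic_flow(geom, grid, cfg, arr, efield = ef, unsteady = unsteady)
  }
  rec <- advect_diffuse(pf, cfg, t_end = t_end)
  attr(rec, "pflow") <- pf
  rec
}
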