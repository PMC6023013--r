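# Steady incompressible laminar flow on a MAC staggered grid.
#
# Discretization: finite volumes on the staggered grid, central differences
# for diffusion and (in Navier-Stokes mode) convection, quadratic ghost
# extrapolation for tangential wall values (reproduces quadratic profiles
# exactly), sparse direct LU on the coupled velocity-pressure saddle system,
# Picard iteration on the Oseen linearization for the convective term.
#
# Boundary conditions per labelled segment: velocity inlets (parabolic or
# plug profile across the segment), fixed-pressure openings (outlets or
# pressure-driven inlets), and walls with optional prescribed tangential slip
# (used by the electroosmotic mixer).

# ---- boundary-condition spec ---------------------------------------------

default_flow_bc <- function(geometry, config) {
  labs <- unique(geometry$segments$label)
  bc <- list()
  for (lb in labs) {
    bc[[lb]] <- switch(lb,
      main_inlet      = list(type = "velocity",
                             mean = config$flow$main_inlet_velocity),
      ancillary_inlet = list(type = "velocity",
                             mean = config$flow$ancillary_velocity),
      mixer_inlet_A   = ,
      mixer_inlet_B   = list(type = "velocity",
                             mean = config$flow$mixer_inlet_velocity),
      outlet_top      = ,
      outlet_bottom   = ,
      mixer_outlet    = list(type = "pressure", value = 0),
      list(type = "wall")  # walls and electrodes
    )
  }
  bc
}

# classify staggered faces: returns status/value/aux arrays for u and v.
# status codes: 0 solid, 1 unknown interior, 2 Dirichlet, 3 open (pressure)
classify_faces <- function(grid, bc, profile = "parabolic") {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  x0 <- grid$x0; y0 <- grid$y0
  mask <- grid$mask
  segs <- grid$geometry$segments
  nonwall <- segs[segs$label != "wall" &
                  !grepl("^electrode_", segs$label), , drop = FALSE]
  fluid <- function(ci, j) ci >= 1 && ci <= nx && j >= 1 && j <= ny && mask[ci, j]
  tol <- 0.45 * min(hx, hy)
  lookup_label <- function(x, y) {
    if (nrow(nonwall) == 0) return("wall")
    d <- mapply(function(x1, y1, x2, y2)
      point_segment_distance(x, y, x1, y1, x2, y2),
      nonwall$x1, nonwall$y1, nonwall$x2, nonwall$y2)
    k <- which.min(d)
    if (d[k] < tol) nonwall$label[k] else "wall"
  }
  inflow_profile <- function(bcent, s, w) {
    if (profile == "plug") bcent$mean
    else 6 * bcent$mean * s * (w - s) / w^2
  }

  ustat <- matrix(0L, nx + 1, ny); uval <- matrix(0, nx + 1, ny)
  upbc <- matrix(NA_real_, nx + 1, ny); uside <- matrix(0L, nx + 1, ny)
  for (a in seq_len(nx + 1)) for (j in seq_len(ny)) {
    L <- fluid(a - 1, j); R <- fluid(a, j)
    if (L && R) { ustat[a, j] <- 1L; next }
    if (!L && !R) next
    x <- x0 + (a - 1) * hx; y <- y0 + (j - 0.5) * hy
    lb <- lookup_label(x, y)
    b <- bc[[lb]] %||% list(type = "wall")
    if (b$type == "velocity") {
      seg <- segs[segs$label == lb, ][1, ]
      sy0 <- min(seg$y1, seg$y2); w <- abs(seg$y2 - seg$y1)
      val <- inflow_profile(b, y - sy0, w)
      ustat[a, j] <- 2L
      uval[a, j] <- if (R) val else -val   # inward normal
    } else if (b$type == "pressure") {
      ustat[a, j] <- 3L
      upbc[a, j] <- b$value
      uside[a, j] <- if (R) -1L else 1L    # side where the ghost cell lies
    } else {
      ustat[a, j] <- 2L; uval[a, j] <- 0   # wall: no penetration
    }
  }

  vstat <- matrix(0L, nx, ny + 1); vval <- matrix(0, nx, ny + 1)
  vpbc <- matrix(NA_real_, nx, ny + 1); vside <- matrix(0L, nx, ny + 1)
  for (ci in seq_len(nx)) for (b2 in seq_len(ny + 1)) {
    D <- fluid(ci, b2 - 1); U <- fluid(ci, b2)
    if (D && U) { vstat[ci, b2] <- 1L; next }
    if (!D && !U) next
    x <- x0 + (ci - 0.5) * hx; y <- y0 + (b2 - 1) * hy
    lb <- lookup_label(x, y)
    b <- bc[[lb]] %||% list(type = "wall")
    if (b$type == "velocity") {
      seg <- segs[segs$label == lb, ][1, ]
      sx0 <- min(seg$x1, seg$x2); w <- abs(seg$x2 - seg$x1)
      val <- inflow_profile(b, x - sx0, w)
      vstat[ci, b2] <- 2L
      vval[ci, b2] <- if (U) val else -val
    } else if (b$type == "pressure") {
      vstat[ci, b2] <- 3L
      vpbc[ci, b2] <- b$value
      vside[ci, b2] <- if (U) -1L else 1L
    } else {
      vstat[ci, b2] <- 2L; vval[ci, b2] <- 0
    }
  }
  list(ustat = ustat, uval = uval, upbc = upbc, uside = uside,
       vstat = vstat, vval = vval, vpbc = vpbc, vside = vside)
}

# ---- assembly -------------------------------------------------------------

# Assemble the coupled system. If uprev/vprev are NULL, Stokes; otherwise the
# Oseen linearization about (uprev, vprev). Returns list(A, rhs, index maps).
assemble_flow_system <- function(grid, fc, config, slip = NULL,
                                 uprev = NULL, vprev = NULL) {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  x0 <- grid$x0; y0 <- grid$y0
  mu <- config$fluid$viscosity; rho <- config$fluid$density
  ustat <- fc$ustat; uval <- fc$uval; upbc <- fc$upbc; uside <- fc$uside
  vstat <- fc$vstat; vval <- fc$vval; vpbc <- fc$vpbc; vside <- fc$vside
  advect <- !is.null(uprev)
  slip_at <- slip %||% function(x, y, orient) 0

  iu <- matrix(0L, nx + 1, ny); un <- which(ustat == 1L | ustat == 3L)
  iu[un] <- seq_along(un)
  iv <- matrix(0L, nx, ny + 1); vn <- which(vstat == 1L | vstat == 3L)
  iv[vn] <- length(un) + seq_along(vn)
  ip <- matrix(0L, nx, ny); pn <- which(grid$mask)
  ip[pn] <- length(un) + length(vn) + seq_along(pn)
  N <- length(un) + length(vn) + length(pn)

  cap <- 30L * N
  II <- integer(cap); JJ <- integer(cap); XX <- numeric(cap)
  k <- 0L
  rhs <- numeric(N)
  push <- function(r, c, v) {
    k <<- k + 1L
    if (k > length(II)) {  # grow (rare)
      II <<- c(II, integer(cap)); JJ <<- c(JJ, integer(cap))
      XX <<- c(XX, numeric(cap))
    }
    II[k] <<- r; JJ[k] <<- c; XX[k] <<- v
  }

  # generic tangential-neighbor handling for momentum rows.
  # own: (arr index of this face); nb1: neighbor face toward the wall; nb2:
  # second face away from the wall (for the quadratic ghost).
  # stat/val/idx are closures into the face arrays.

  ax <- mu / hx^2; ay <- mu / hy^2

  # --- u-momentum rows ---
  for (a in seq_len(nx + 1)) for (j in seq_len(ny)) {
    st <- ustat[a, j]
    if (st != 1L && st != 3L) next
    r <- iu[a, j]
    xf <- x0 + (a - 1) * hx; yf <- y0 + (j - 0.5) * hy
    diag <- 0
    Ux <- 0; Uy <- 0
    if (advect) {
      Ux <- uprev[a, j]
      vs <- c(if (a > 1) vprev[a - 1, j] else NA, if (a > 1) vprev[a - 1, j + 1] else NA,
              if (a <= nx) vprev[a, j] else NA, if (a <= nx) vprev[a, j + 1] else NA)
      Uy <- mean(vs, na.rm = TRUE); if (is.nan(Uy)) Uy <- 0
    }
    cx <- if (advect) rho * Ux / (2 * hx) else 0
    cy <- if (advect) rho * Uy / (2 * hy) else 0
    # x-direction neighbors (normal direction)
    for (s in c(-1L, 1L)) {
      an <- a + s
      coeff <- ax - s * cx   # diffusion + central advection on that neighbor
      if (an >= 1 && an <= nx + 1 && ustat[an, j] > 0L) {
        stn <- ustat[an, j]
        if (stn == 2L) rhs[r] <- rhs[r] - coeff * uval[an, j]
        else push(r, iu[an, j], coeff)
      } else {
        # beyond an open boundary: zero-gradient ghost (only happens for
        # open faces at the domain edge)
        diag <- diag + coeff
      }
      diag <- diag - ax
    }
    # y-direction neighbors (tangential direction: walls possible)
    for (s in c(-1L, 1L)) {
      jn <- j + s
      coeff <- ay - s * cy
      nb_ok <- jn >= 1 && jn <= ny && ustat[a, jn] > 0L
      if (nb_ok) {
        stn <- ustat[a, jn]
        if (stn == 2L) rhs[r] <- rhs[r] - coeff * uval[a, jn]
        else push(r, iu[a, jn], coeff)
        diag <- diag - ay
      } else {
        # wall or open boundary on the tangential side; inspect the normal
        # v-faces separating this row from the next to decide
        open_side <- FALSE
        bv <- j + (if (s == 1L) 1L else 0L)  # v-face level between rows j, jn
        for (ci in c(a - 1L, a)) {
          if (ci >= 1 && ci <= nx && vstat[ci, bv] == 3L) open_side <- TRUE
        }
        if (open_side) {  # zero-gradient tangential ghost
          diag <- diag + coeff
          diag <- diag - ay
        } else {
          yw <- y0 + (bv - 1) * hy
          uw <- slip_at(xf, yw, "h")
          j2 <- j - s
          quad <- j2 >= 1 && j2 <= ny && ustat[a, j2] > 0L
          if (quad) {
            # ghost = 8/3 uw - 2 u0 + 1/3 u2
            rhs[r] <- rhs[r] - coeff * (8 / 3) * uw
            diag <- diag - 2 * coeff
            st2 <- ustat[a, j2]
            if (st2 == 2L) rhs[r] <- rhs[r] - coeff * (1 / 3) * uval[a, j2]
            else push(r, iu[a, j2], coeff / 3)
          } else {
            rhs[r] <- rhs[r] - coeff * 2 * uw
            diag <- diag - coeff
          }
          diag <- diag - ay
        }
      }
    }
    push(r, r, diag)
    # pressure gradient: cells (a-1, j) left, (a, j) right
    cl_ok <- (a - 1 >= 1) && grid$mask[a - 1, j]
    cr_ok <- (a <= nx) && grid$mask[a, j]
    if (cl_ok && cr_ok) {
      push(r, ip[a, j], -1 / hx)      # p right
      push(r, ip[a - 1, j], 1 / hx)   # p left
    } else if (st == 3L) {
      pb <- upbc[a, j]
      if (uside[a, j] == 1L) {        # ghost on the right
        push(r, ip[a - 1, j], 2 / hx)
        rhs[r] <- rhs[r] + 2 * pb / hx
      } else {                        # ghost on the left
        push(r, ip[a, j], -2 / hx)
        rhs[r] <- rhs[r] - 2 * pb / hx
      }
    } else {
      stop_ctc("internal: unknown u-face without pressure neighbours")
    }
  }

  # --- v-momentum rows ---
  for (ci in seq_len(nx)) for (b2 in seq_len(ny + 1)) {
    st <- vstat[ci, b2]
    if (st != 1L && st != 3L) next
    r <- iv[ci, b2]
    xf <- x0 + (ci - 0.5) * hx; yf <- y0 + (b2 - 1) * hy
    diag <- 0
    Ux <- 0; Uy <- 0
    if (advect) {
      Uy <- vprev[ci, b2]
      us <- c(if (b2 > 1) uprev[ci, b2 - 1] else NA, if (b2 > 1) uprev[ci + 1, b2 - 1] else NA,
              if (b2 <= ny) uprev[ci, b2] else NA, if (b2 <= ny) uprev[ci + 1, b2] else NA)
      Ux <- mean(us, na.rm = TRUE); if (is.nan(Ux)) Ux <- 0
    }
    cx <- if (advect) rho * Ux / (2 * hx) else 0
    cy <- if (advect) rho * Uy / (2 * hy) else 0
    # y-direction (normal)
    for (s in c(-1L, 1L)) {
      bn <- b2 + s
      coeff <- ay - s * cy
      if (bn >= 1 && bn <= ny + 1 && vstat[ci, bn] > 0L) {
        stn <- vstat[ci, bn]
        if (stn == 2L) rhs[r] <- rhs[r] - coeff * vval[ci, bn]
        else push(r, iv[ci, bn], coeff)
      } else {
        diag <- diag + coeff
      }
      diag <- diag - ay
    }
    # x-direction (tangential)
    for (s in c(-1L, 1L)) {
      cn <- ci + s
      coeff <- ax - s * cx
      nb_ok <- cn >= 1 && cn <= nx && vstat[cn, b2] > 0L
      if (nb_ok) {
        stn <- vstat[cn, b2]
        if (stn == 2L) rhs[r] <- rhs[r] - coeff * vval[cn, b2]
        else push(r, iv[cn, b2], coeff)
        diag <- diag - ax
      } else {
        open_side <- FALSE
        au <- ci + (if (s == 1L) 1L else 0L)  # u-face column between cells
        for (jj2 in c(b2 - 1L, b2)) {
          if (jj2 >= 1 && jj2 <= ny && ustat[au, jj2] == 3L) open_side <- TRUE
        }
        if (open_side) {
          diag <- diag + coeff
          diag <- diag - ax
        } else {
          xw <- x0 + (au - 1) * hx
          vw <- slip_at(xw, yf, "v")
          c2 <- ci - s
          quad <- c2 >= 1 && c2 <= nx && vstat[c2, b2] > 0L
          if (quad) {
            rhs[r] <- rhs[r] - coeff * (8 / 3) * vw
            diag <- diag - 2 * coeff
            st2 <- vstat[c2, b2]
            if (st2 == 2L) rhs[r] <- rhs[r] - coeff * (1 / 3) * vval[c2, b2]
            else push(r, iv[c2, b2], coeff / 3)
          } else {
            rhs[r] <- rhs[r] - coeff * 2 * vw
            diag <- diag - coeff
          }
          diag <- diag - ax
        }
      }
    }
    push(r, r, diag)
    cl_ok <- (b2 - 1 >= 1) && grid$mask[ci, b2 - 1]
    cr_ok <- (b2 <= ny) && grid$mask[ci, b2]
    if (cl_ok && cr_ok) {
      push(r, ip[ci, b2], -1 / hy)
      push(r, ip[ci, b2 - 1], 1 / hy)
    } else if (st == 3L) {
      pb <- vpbc[ci, b2]
      if (vside[ci, b2] == 1L) {
        push(r, ip[ci, b2 - 1], 2 / hy)
        rhs[r] <- rhs[r] + 2 * pb / hy
      } else {
        push(r, ip[ci, b2], -2 / hy)
        rhs[r] <- rhs[r] - 2 * pb / hy
      }
    } else {
      stop_ctc("internal: unknown v-face without pressure neighbours")
    }
  }

  # --- continuity rows ---
  for (ci in seq_len(nx)) for (j in seq_len(ny)) {
    if (!grid$mask[ci, j]) next
    r <- ip[ci, j]
    f <- list(list(arr = "u", a = ci + 1L, b = j, sgn = 1 / hx),
              list(arr = "u", a = ci, b = j, sgn = -1 / hx),
              list(arr = "v", a = ci, b = j + 1L, sgn = 1 / hy),
              list(arr = "v", a = ci, b = j, sgn = -1 / hy))
    for (ff in f) {
      if (ff$arr == "u") {
        stn <- ustat[ff$a, ff$b]
        if (stn == 2L) rhs[r] <- rhs[r] - ff$sgn * uval[ff$a, ff$b]
        else push(r, iu[ff$a, ff$b], ff$sgn)
      } else {
        stn <- vstat[ff$a, ff$b]
        if (stn == 2L) rhs[r] <- rhs[r] - ff$sgn * vval[ff$a, ff$b]
        else push(r, iv[ff$a, ff$b], ff$sgn)
      }
    }
    push(r, r, -1e-12)  # tiny regularization; keeps LU robust when no
                        # pressure level is fixed by an open boundary
  }

  A <- Matrix::sparseMatrix(i = II[seq_len(k)], j = JJ[seq_len(k)],
                            x = XX[seq_len(k)], dims = c(N, N))
  list(A = A, rhs = rhs, iu = iu, iv = iv, ip = ip, nu = length(un),
       nv = length(vn))
}

# unpack solution vector into full face arrays (Dirichlet values filled in)
unpack_flow <- function(sol, grid, fc, sys) {
  u <- fc$uval; u[sys$iu > 0] <- sol[sys$iu[sys$iu > 0]]
  v <- fc$vval; v[sys$iv > 0] <- sol[sys$iv[sys$iv > 0]]
  p <- matrix(0, grid$nx, grid$ny); p[sys$ip > 0] <- sol[sys$ip[sys$ip > 0]]
  list(u = u, v = v, p = p)
}

# ---- main entry -----------------------------------------------------------

#' Solve steady incompressible flow over a device geometry
#'
#' Solves the continuity and steady momentum equations with velocity inlets,
#' fixed-pressure outlets and (slip-)walls, either as Stokes flow or with the
#' convective term included via Picard iteration.
#'
#' @param geometry a `device_geometry`.
#' @param grid optional `grid2d`; built from `config$solver$nx/ny` when NULL.
#' @param config a `ctc_config`.
#' @param slip_bc optional wall-slip function `f(x, y, orient)` returning the
#'   tangential wall velocity (m/s); `orient` is `"h"` for horizontal walls
#'   (tangential u) and `"v"` for vertical walls (tangential v).
#' @param stokes drop the convective term (linear Stokes solve).
#' @param bc_overrides named list overriding the per-label boundary
#'   conditions, e.g. `list(ancillary_inlet = list(type = "velocity",
#'   mean = 0.012))` or `list(main_inlet = list(type = "pressure", value = 5))`.
#' @return object of class `flow_field` with staggered face velocities `u`
#'   (`(nx+1) x ny`), `v` (`nx x (ny+1)`), cell pressures `p`, the grid, and
#'   `metadata` (Reynolds number, Picard residual history, max divergence,
#'   net boundary flux, cell count).
#' @export
solve_steady_flow <- function(geometry, grid = NULL, config = default_config(),
                              slip_bc = NULL, stokes = FALSE,
                              bc_overrides = NULL) {
  if (is.null(grid)) {
    if (geometry$kind == "mixer_Y")
      grid <- build_grid(geometry, config$solver$mixer_nx, config$solver$mixer_ny)
    else grid <- build_grid(geometry, config$solver$nx, config$solver$ny)
  }
  bc <- default_flow_bc(geometry, config)
  if (!is.null(bc_overrides)) bc[names(bc_overrides)] <- bc_overrides
  # laminar-assumption guard
  Uref <- max(vapply(bc, function(b) if (b$type == "velocity") abs(b$mean) else 0,
                     numeric(1)))
  Lref <- diff(range(geometry$vertices[, 2]))
  Re <- config$fluid$density * Uref * Lref / config$fluid$viscosity
  if (Re >= 100)
    stop_ctc(sprintf("Reynolds number %.1f violates the laminar guard (< 100)",
                     Re))
  has_pressure_bc <- any(vapply(bc, function(b) b$type == "pressure", logical(1)))
  fc <- classify_faces(grid, bc, profile = config$flow$profile %||% "parabolic")

  sys <- assemble_flow_system(grid, fc, config, slip = slip_bc)
  sol <- as.numeric(Matrix::solve(sys$A, sys$rhs))
  fields <- unpack_flow(sol, grid, fc, sys)
  resid <- numeric(0)
  if (!stokes && Uref > 0) {
    umax0 <- max(abs(fields$u), abs(fields$v), Uref)
    for (it in seq_len(config$solver$max_iter)) {
      sysN <- assemble_flow_system(grid, fc, config, slip = slip_bc,
                                   uprev = fields$u, vprev = fields$v)
      solN <- as.numeric(Matrix::solve(sysN$A, sysN$rhs))
      newf <- unpack_flow(solN, grid, fc, sysN)
      ch <- max(abs(newf$u - fields$u), abs(newf$v - fields$v)) / umax0
      fields <- newf
      resid <- c(resid, ch)
      if (ch < config$solver$tol) break
    }
    if (length(resid) && resid[length(resid)] >= config$solver$tol &&
        length(resid) >= config$solver$max_iter)
      warning(sprintf("Picard iteration stopped at relative change %.2e after %d iterations",
                      resid[length(resid)], length(resid)))
  }

  # diagnostics: discrete divergence and net boundary flux
  u <- fields$u; v <- fields$v
  div <- (u[2:(grid$nx + 1), , drop = FALSE] - u[1:grid$nx, , drop = FALSE]) / grid$hx +
         (v[, 2:(grid$ny + 1), drop = FALSE] - v[, 1:grid$ny, drop = FALSE]) / grid$hy
  div[!grid$mask] <- 0
  # net flux = sum of divergence over fluid cells * cell area
  netflux <- sum(div[grid$mask]) * grid$hx * grid$hy
  influx <- sum(abs(fc$uval[fc$ustat == 2L])) * grid$hy +
            sum(abs(fc$vval[fc$vstat == 2L])) * grid$hx
  structure(list(grid = grid, geometry = geometry, u = u, v = v, p = fields$p,
                 fc = fc,
                 metadata = list(Re = Re, picard_residuals = resid,
                                 max_divergence = max(abs(div)),
                                 net_flux = netflux, influx = max(influx, 1e-300),
                                 n_cells = sum(grid$mask),
                                 stokes = stokes, Uref = Uref)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("flow_field on %d fluid cells: Re=%.2f, max|u|=%.3g m/s, max div=%.2e, %s\n",
              m$n_cells, m$Re, max(abs(x$u), abs(x$v)), m$max_divergence,
              if (m$stokes) "Stokes" else
                sprintf("NS (%d Picard iters)", length(m$picard_residuals))))
  invisible(x)
}

# ---- interpolation --------------------------------------------------------

#' Interpolate velocity at arbitrary points
#'
#' Bilinear interpolation of the staggered velocity components on their own
#' grids. With `check = TRUE` (the contract default) querying a point outside
#' the flow domain is an error.
#'
#' @param flow a `flow_field`.
#' @param pts n x 2 matrix of points (m).
#' @param check error on out-of-domain points.
#' @return n x 2 matrix of (u, v) (m/s).
#' @export
interp_velocity <- function(flow, pts, check = TRUE) {
  pts <- matrix(pts, ncol = 2)
  g <- flow$grid
  if (check) {
    ok <- point_in_polygon(pts[, 1], pts[, 2], flow$geometry$vertices)
    if (!all(ok)) stop_ctc("velocity query outside the flow domain")
  }
  u <- bilinear(flow$u, g$x0, g$y0 + 0.5 * g$hy, g$hx, g$hy, pts[, 1], pts[, 2])
  v <- bilinear(flow$v, g$x0 + 0.5 * g$hx, g$y0, g$hx, g$hy, pts[, 1], pts[, 2])
  cbind(u = u, v = v)
}

#' Interpolate pressure at arbitrary points
#' @inheritParams interp_velocity
#' @return numeric vector of pressures (Pa).
#' @export
interp_pressure <- function(flow, pts, check = TRUE) {
  pts <- matrix(pts, ncol = 2)
  g <- flow$grid
  if (check) {
    ok <- point_in_polygon(pts[, 1], pts[, 2], flow$geometry$vertices)
    if (!all(ok)) stop_ctc("pressure query outside the flow domain")
  }
  bilinear(flow$p, g$x0 + 0.5 * g$hx, g$y0 + 0.5 * g$hy, g$hx, g$hy,
           pts[, 1], pts[, 2])
}

#' Pressure profile along a polyline
#'
#' Samples pressure by bilinear interpolation at uniformly spaced arc-length
#' stations along the polyline.
#'
#' @param flow a `flow_field`.
#' @param polyline m x 2 matrix of waypoints inside the domain.
#' @param n number of stations.
#' @return data.frame with columns `s` (arc length, m), `x`, `y`, `p` (Pa).
#' @export
pressure_profile <- function(flow, polyline, n = 200) {
  polyline <- matrix(polyline, ncol = 2)
  dseg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                        polyline[-nrow(polyline), , drop = FALSE])^2))
  cs <- c(0, cumsum(dseg))
  s <- seq(0, cs[length(cs)], length.out = n)
  xs <- stats::approx(cs, polyline[, 1], xout = s)$y
  ys <- stats::approx(cs, polyline[, 2], xout = s)$y
  p <- interp_pressure(flow, cbind(xs, ys))
  data.frame(s = s, x = xs, y = ys, p = p)
}

# ---- recirculation --------------------------------------------------------

#' Detect a recirculation (reversed axial flow) zone
#'
#' Flags a vortex when a connected patch of interior cells has axial velocity
#' reversed relative to the bulk (+x) direction, with patch area above a
#' configurable floor.
#'
#' @param flow a `flow_field`.
#' @param region optional bounding box `c(xmin, xmax, ymin, ymax)` (m);
#'   default is the whole domain.
#' @param threshold_frac reversal threshold as a fraction of the reference
#'   inlet speed.
#' @param min_cells minimum patch size in cells.
#' @return list with `has_vortex`, `vortex_area` (m^2, largest patch),
#'   `n_reversed_cells`, `patch_bbox`.
#' @export
detect_recirculation <- function(flow, region = NULL, threshold_frac = 1e-3,
                                 min_cells = 3) {
  g <- flow$grid
  ucc <- (flow$u[1:g$nx, , drop = FALSE] + flow$u[2:(g$nx + 1), , drop = FALSE]) / 2
  thr <- -threshold_frac * flow$metadata$Uref
  rev <- (ucc < thr) & g$mask
  if (!is.null(region)) {
    xc <- g$x0 + (seq_len(g$nx) - 0.5) * g$hx
    yc <- g$y0 + (seq_len(g$ny) - 0.5) * g$hy
    rev <- rev & outer(xc >= region[1] & xc <= region[2],
                       yc >= region[3] & yc <= region[4], "&")
  }
  if (!any(rev))
    return(list(has_vortex = FALSE, vortex_area = 0, n_reversed_cells = 0L,
                patch_bbox = NULL))
  # connected components by BFS (4-connectivity)
  lab <- matrix(0L, g$nx, g$ny); cur <- 0L
  idx <- which(rev, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, 1], idx[r, 2]] > 0L) next
    cur <- cur + 1L
    queue <- matrix(idx[r, ], ncol = 2)
    lab[idx[r, 1], idx[r, 2]] <- cur
    while (nrow(queue) > 0) {
      cpt <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cpt[1] + d[1]; nj <- cpt[2] + d[2]
        if (ni >= 1 && ni <= g$nx && nj >= 1 && nj <= g$ny &&
            rev[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  has <- sizes[big] >= min_cells
  cells <- which(lab == big, arr.ind = TRUE)
  bbox <- c(xmin = g$x0 + (min(cells[, 1]) - 1) * g$hx,
            xmax = g$x0 + max(cells[, 1]) * g$hx,
            ymin = g$y0 + (min(cells[, 2]) - 1) * g$hy,
            ymax = g$y0 + max(cells[, 2]) * g$hy)
  list(has_vortex = has, vortex_area = sizes[big] * g$hx * g$hy,
       n_reversed_cells = sum(sizes), patch_bbox = bbox)
}

# ---- grid convergence -----------------------------------------------------

#' Grid-convergence study
#'
#' Re-solves the problem at increasing cell counts and reports the monitored
#' value — the domain-maximum velocity magnitude (`"max_velocity"`, the
#' separator monitor) or the period-averaged mixing index (`"mixing_index"`,
#' for the mixer) — and its relative change between successive refinements.
#'
#' @param geometry a `device_geometry`.
#' @param config a `ctc_config`.
#' @param element_counts increasing vector (length >= 3) of total cell counts.
#' @param monitor `"max_velocity"` or `"mixing_index"`.
#' @param stokes passed to [solve_steady_flow()] (max-velocity monitor only).
#' @param t_end mixer horizon (mixing-index monitor only).
#' @return data.frame with `elements` (actual fluid-cell count), `nx`, `ny`,
#'   `monitored`, `rel_change`.
#' @export
grid_convergence_study <- function(geometry, config = default_config(),
                                   element_counts,
                                   monitor = c("max_velocity", "mixing_index"),
                                   stokes = FALSE, t_end = 1) {
  monitor <- match.arg(monitor)
  if (length(element_counts) < 3) stop_ctc("need at least 3 element counts")
  if (is.unsorted(element_counts))
    stop_ctc("element counts must be non-decreasing")
  bb <- geometry$bbox
  aspect <- (bb["xmax"] - bb["xmin"]) / (bb["ymax"] - bb["ymin"])
  rows <- lapply(element_counts, function(ne) {
    ny <- max(8L, as.integer(round(sqrt(ne / aspect))))
    nx <- max(8L, as.integer(round(ne / ny)))
    if (monitor == "max_velocity") {
      grid <- build_grid(geometry, nx, ny)
      fl <- solve_steady_flow(geometry, grid, config, stokes = stokes)
      val <- max(sqrt(pmax(
        ((fl$u[1:nx, ] + fl$u[2:(nx + 1), ]) / 2)^2 +
        ((fl$v[, 1:ny] + fl$v[, 2:(ny + 1)]) / 2)^2, 0))[grid$mask])
      data.frame(elements = fl$metadata$n_cells, nx = nx, ny = ny,
                 monitored = val)
    } else {
      rec <- suppressWarnings(run_mixer(config, t_end = t_end,
                                        nx = nx, ny = ny))
      data.frame(elements = nx * ny, nx = nx, ny = ny, monitored = rec$mi)
    }
  })
  out <- do.call(rbind, rows)
  out$rel_change <- c(NA, abs(diff(out$monitored)) /
                        abs(out$monitored[-nrow(out)]))
  out
}

#' Export a flow field as CSV (cell-centered)
#' @param flow a `flow_field`.
#' @param path output file.
#' @export
write_flow_csv <- function(flow, path) {
  g <- flow$grid
  xc <- g$x0 + (seq_len(g$nx) - 0.5) * g$hx
  yc <- g$y0 + (seq_len(g$ny) - 0.5) * g$hy
  ucc <- (flow$u[1:g$nx, ] + flow$u[2:(g$nx + 1), ]) / 2
  vcc <- (flow$v[, 1:g$ny] + flow$v[, 2:(g$ny + 1)]) / 2
  df <- data.frame(x = rep(xc, g$ny), y = rep(yc, each = g$nx),
                   u = as.vector(ucc), v = as.vector(vcc),
                   p = as.vector(flow$p), fluid = as.vector(g$mask))
  utils::write.csv(df[df$fluid, names(df) != "fluid"], path, row.names = FALSE)
  invisible(path)
}
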