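# Magnetostatics of a uniformly magnetized rectangular permanent magnet in 2D.
#
# The analytic field is the equivalent surface-charge solution: a uniform
# magnetization M jumping to zero across a face is equivalent to a magnetic
# surface charge sigma = M . n on that face; each face is a charged line
# segment whose field has a closed form. A numeric scalar-potential solver
# (div(-grad Vm + M) = 0 with far-field decay) serves as an independent
# cross-check.

#' Construct a magnet specification
#'
#' By default the magnet block sits below the separator channel: its top face
#' is `standoff` below the wide-section bottom wall, magnetized along +y.
#'
#' @param config a `ctc_config` supplying defaults.
#' @param center optional explicit center (m); otherwise derived from
#'   `config$magnet$center_x`, the channel bottom wall at y = -1.5 mm, the
#'   standoff and the magnet height.
#' @param channel_bottom_y y of the channel wall the magnet sits under (m).
#' @return object of class `magnet_spec`.
#' @export
magnet_spec <- function(config = default_config(), center = NULL,
                        channel_bottom_y = -1.5e-3) {
  m <- config$magnet
  if (is.null(center)) {
    center <- c(m$center_x, channel_bottom_y - m$standoff - m$height / 2)
  }
  dirn <- m$direction / sqrt(sum(m$direction^2))
  structure(list(center = center, width = m$width, height = m$height,
                 M = m$magnetization, direction = dirn,
                 standoff = m$standoff),
            class = "magnet_spec")
}

# field of a horizontal charged segment y = ys, x in [x1, x2], unit charge
# density; returns cbind(Hx, Hy). The normal component uses the principal
# atan branch so it jumps by the charge density across the sheet.
segment_field_h <- function(px, py, x1, x2, ys) {
  dy <- py - ys
  r1 <- (px - x1)^2 + dy^2
  r2 <- (px - x2)^2 + dy^2
  Hx <- log(r1 / r2) / (4 * pi)
  Hy <- (atan((px - x1) / dy) - atan((px - x2) / dy)) / (2 * pi)
  cbind(Hx, Hy)
}

# vertical segment x = xs, y in [y1, y2], unit charge density
segment_field_v <- function(px, py, xs, y1, y2) {
  dx <- px - xs
  r1 <- dx^2 + (py - y1)^2
  r2 <- dx^2 + (py - y2)^2
  Hy <- log(r1 / r2) / (4 * pi)
  Hx <- (atan((py - y1) / dx) - atan((py - y2) / dx)) / (2 * pi)
  cbind(Hx, Hy)
}

#' Analytic magnetic field of the rectangular magnet
#'
#' Closed-form H (and B) at arbitrary points from the equivalent
#' surface-charge sheets on the magnet faces. Inside the magnet
#' B = mu0 (H + M); outside B = mu0 mu_r H.
#'
#' @param magnet a `magnet_spec`.
#' @param points n x 2 matrix (m).
#' @param mu_r relative permeability of the surrounding medium.
#' @param mu0 vacuum permeability (H/m).
#' @return data.frame with `x`, `y`, `Hx`, `Hy` (A/m), `Bx`, `By` (T),
#'   `Hmag`, `Bmag`, `inside` (logical).
#' @export
analytic_field <- function(magnet, points, mu_r = 1, mu0 = 4e-7 * pi) {
  points <- matrix(points, ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  cx <- magnet$center[1]; cy <- magnet$center[2]
  x1 <- cx - magnet$width / 2; x2 <- cx + magnet$width / 2
  y1 <- cy - magnet$height / 2; y2 <- cy + magnet$height / 2
  # corner-singularity guard
  eps <- 1e-12 * max(magnet$width, magnet$height, 1)
  corners <- rbind(c(x1, y1), c(x1, y2), c(x2, y1), c(x2, y2))
  for (r in seq_len(4)) {
    bad <- abs(px - corners[r, 1]) < eps & abs(py - corners[r, 2]) < eps
    if (any(bad))
      stop_ctc(sprintf("evaluation point on magnet corner (%.4g, %.4g)",
                       corners[r, 1], corners[r, 2]))
  }
  My <- magnet$M * magnet$direction[2]
  Mx <- magnet$M * magnet$direction[1]
  H <- matrix(0, length(px), 2)
  if (My != 0) {  # charges +My on top face, -My on bottom face
    H <- H + My * (segment_field_h(px, py, x1, x2, y2) -
                   segment_field_h(px, py, x1, x2, y1))
  }
  if (Mx != 0) {  # charges +Mx on right face, -Mx on left face
    H <- H + Mx * (segment_field_v(px, py, x2, y1, y2) -
                   segment_field_v(px, py, x1, y1, y2))
  }
  inside <- px > x1 & px < x2 & py > y1 & py < y2
  Bx <- mu0 * (mu_r * H[, 1] * (!inside) + (H[, 1] + Mx) * inside)
  By <- mu0 * (mu_r * H[, 2] * (!inside) + (H[, 2] + My) * inside)
  data.frame(x = px, y = py, Hx = H[, 1], Hy = H[, 2], Bx = Bx, By = By,
             Hmag = sqrt(H[, 1]^2 + H[, 2]^2), Bmag = sqrt(Bx^2 + By^2),
             inside = inside)
}

#' Field map: evaluator object for H, B, |H| and grad |H|^2
#'
#' Wraps either the analytic solution (`source = "analytic"`) or a numeric
#' scalar-potential solve (`source = "numeric"`, see [numeric_field()]) behind
#' a common evaluator contract.
#'
#' @param magnet a `magnet_spec`.
#' @param mu_r medium relative permeability.
#' @param mu0 vacuum permeability.
#' @return object of class `magnetic_field_map` with functions `H(pts)`,
#'   `Hmag2(pts)` and fields `source`, `magnet`.
#' @export
field_map_analytic <- function(magnet, mu_r = 1, mu0 = 4e-7 * pi) {
  # lean evaluator (no guards, no data.frame): called in the tracing hot loop
  cx <- magnet$center[1]; cy <- magnet$center[2]
  x1 <- cx - magnet$width / 2; x2 <- cx + magnet$width / 2
  y1 <- cy - magnet$height / 2; y2 <- cy + magnet$height / 2
  Mx <- magnet$M * magnet$direction[1]
  My <- magnet$M * magnet$direction[2]
  Hfun <- function(pts) {
    pts <- matrix(pts, ncol = 2)
    px <- pts[, 1]; py <- pts[, 2]
    Hx <- numeric(length(px)); Hy <- numeric(length(px))
    if (My != 0) {
      h1 <- segment_field_h(px, py, x1, x2, y2)
      h2 <- segment_field_h(px, py, x1, x2, y1)
      Hx <- Hx + My * (h1[, 1] - h2[, 1]); Hy <- Hy + My * (h1[, 2] - h2[, 2])
    }
    if (Mx != 0) {
      v1 <- segment_field_v(px, py, x2, y1, y2)
      v2 <- segment_field_v(px, py, x1, y1, y2)
      Hx <- Hx + Mx * (v1[, 1] - v2[, 1]); Hy <- Hy + Mx * (v1[, 2] - v2[, 2])
    }
    cbind(Hx = Hx, Hy = Hy)
  }
  structure(list(
    H = Hfun,
    Hmag2 = function(pts) { h <- Hfun(pts); h[, 1]^2 + h[, 2]^2 },
    source = "analytic", magnet = magnet, mu_r = mu_r, mu0 = mu0,
    grad_h = 1e-7),
    class = "magnetic_field_map")
}

#' Numeric scalar-potential field solve (independent oracle)
#'
#' Solves div(-grad Vm + M) = 0 on a padded rectangular grid with Vm = 0 on
#' the far boundary, H = -grad Vm. Used as the independent cross-check of the
#' analytic solution.
#'
#' @param magnet a `magnet_spec`.
#' @param n grid cells per direction.
#' @param padding domain half-width as a multiple of the larger magnet
#'   dimension (must be >= 5).
#' @param mu_r,mu0 medium constants.
#' @return a `magnetic_field_map` with `source = "numeric"`.
#' @export
numeric_field <- function(magnet, n = 256, padding = 6, mu_r = 1,
                          mu0 = 4e-7 * pi) {
  if (padding < 5) stop_ctc("padding must be at least 5 magnet sizes")
  Lm <- max(magnet$width, magnet$height)
  half <- padding * Lm
  x0 <- magnet$center[1] - half; y0 <- magnet$center[2] - half
  h <- 2 * half / n
  # potential at nodes (n+1)^2, Dirichlet Vm = 0 on the outer boundary
  nn <- n - 1  # interior nodes per direction
  idx <- function(i, j) (j - 1) * nn + i
  N <- nn * nn
  # RHS: div M with M staggered at edge midpoints; for y-magnetization My is
  # nonzero at vertical-edge midpoints inside the magnet
  Mx <- magnet$M * magnet$direction[1]; My <- magnet$M * magnet$direction[2]
  cx <- magnet$center[1]; cy <- magnet$center[2]
  xi <- x0 + seq_len(nn) * h
  yi <- y0 + seq_len(nn) * h
  X <- rep(xi, nn); Y <- rep(yi, each = nn)
  # RHS of lap(Vm) = div M: the magnetization divergence is a surface charge
  # -M.n on each magnet face; deposit it onto the nodes with linear
  # (cloud-in-cell) weights so the result is second order in the face
  # position relative to the grid
  rhs <- numeric(N)
  xl <- cx - magnet$width / 2; xr <- cx + magnet$width / 2
  yb <- cy - magnet$height / 2; yt <- cy + magnet$height / 2
  if (My != 0) {
    ov_x <- pmax(0, pmin(X + h / 2, xr) - pmax(X - h / 2, xl))
    for (fc in list(list(yf = yt, s = -1), list(yf = yb, s = 1))) {
      wy <- pmax(0, 1 - abs(Y - fc$yf) / h)
      rhs <- rhs + fc$s * My * ov_x * wy / h^2
    }
  }
  if (Mx != 0) {
    ov_y <- pmax(0, pmin(Y + h / 2, yt) - pmax(Y - h / 2, yb))
    for (fc in list(list(xf = xr, s = -1), list(xf = xl, s = 1))) {
      wx <- pmax(0, 1 - abs(X - fc$xf) / h)
      rhs <- rhs + fc$s * Mx * ov_y * wx / h^2
    }
  }
  # far-field Dirichlet boundary: the leading line-dipole asymptotic of the
  # potential, Vm = m . r / (2 pi r^2) with dipole moment per unit depth
  # m = M * (magnet area); the interior solve remains a full FD solution
  dip <- magnet$M * magnet$width * magnet$height / (2 * pi)
  Vbc <- function(x, y) {
    rx <- x - cx; ry <- y - cy; r2 <- rx^2 + ry^2
    dip * (magnet$direction[1] * rx + magnet$direction[2] * ry) / r2
  }
  # 5-point Laplacian
  iL <- rep(seq_len(nn), nn); jL <- rep(seq_len(nn), each = nn)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  me <- idx(iL, jL)
  addn <- function(di, dj) {
    keep <- iL + di >= 1 & iL + di <= nn & jL + dj >= 1 & jL + dj <= nn
    rows <<- c(rows, me[keep]); cols <<- c(cols, idx(iL + di, jL + dj)[keep])
    vals <<- c(vals, rep(1 / h^2, sum(keep)))
    # Dirichlet neighbours move to the RHS
    out <- !keep
    if (any(out))
      rhs[me[out]] <<- rhs[me[out]] -
        Vbc(X[out] + di * h, Y[out] + dj * h) / h^2
  }
  addn(1, 0); addn(-1, 0); addn(0, 1); addn(0, -1)
  rows <- c(rows, me); cols <- c(cols, me); vals <- c(vals, rep(-4 / h^2, N))
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  Vm <- as.numeric(Matrix::solve(A, rhs))
  Vmat <- matrix(Vm, nn, nn)
  # pad with the Dirichlet boundary; node (1,1) of Vfull sits at (x0, y0)
  xsall <- x0 + (0:(nn + 1)) * h; ysall <- y0 + (0:(nn + 1)) * h
  Vfull <- outer(xsall, ysall, Vbc)
  Vfull[2:(nn + 1), 2:(nn + 1)] <- Vmat
  xs0 <- x0; ys0 <- y0
  # differentiate at the nodes first (second-order central differences), then
  # interpolate the node field values
  nf <- nn + 2
  Hxn <- matrix(0, nf, nf); Hyn <- matrix(0, nf, nf)
  Hxn[2:(nf - 1), ] <- -(Vfull[3:nf, ] - Vfull[1:(nf - 2), ]) / (2 * h)
  Hyn[, 2:(nf - 1)] <- -(Vfull[, 3:nf] - Vfull[, 1:(nf - 2)]) / (2 * h)
  Hfun <- function(pts) {
    pts <- matrix(pts, ncol = 2)
    cbind(Hx = bilinear(Hxn, xs0, ys0, h, h, pts[, 1], pts[, 2]),
          Hy = bilinear(Hyn, xs0, ys0, h, h, pts[, 1], pts[, 2]))
  }
  structure(list(
    H = Hfun,
    Hmag2 = function(pts) { hh <- Hfun(pts); hh[, 1]^2 + hh[, 2]^2 },
    source = "numeric", magnet = magnet, mu_r = mu_r, mu0 = mu0,
    grad_h = h, Vm = Vfull, h = h, x0 = xs0, y0 = ys0),
    class = "magnetic_field_map")
}

#' Evaluate B at points through a field map
#' @param map a `magnetic_field_map`.
#' @param points n x 2 matrix (m).
#' @return n x 2 matrix of (Bx, By) in tesla.
#' @export
field_B <- function(map, points) {
  points <- matrix(points, ncol = 2)
  H <- map$H(points)
  m <- map$magnet
  inside <- abs(points[, 1] - m$center[1]) < m$width / 2 &
            abs(points[, 2] - m$center[2]) < m$height / 2
  Mx <- m$M * m$direction[1]; My <- m$M * m$direction[2]
  cbind(Bx = map$mu0 * ifelse(inside, H[, 1] + Mx, map$mu_r * H[, 1]),
        By = map$mu0 * ifelse(inside, H[, 2] + My, map$mu_r * H[, 2]))
}

#' Gradient of |H|^2 at points
#'
#' Central differences of |H|^2 through the field-map evaluator; this is the
#' field factor of the magnetophoretic buoyancy force.
#'
#' @param map a `magnetic_field_map`.
#' @param points n x 2 matrix (m).
#' @param h stencil spacing (m); defaults to the map's own (1e-7 m analytic,
#'   one grid cell numeric).
#' @return n x 2 matrix of d|H|^2/dx, d|H|^2/dy (A^2/m^3).
#' @export
grad_H2 <- function(map, points, h = NULL) {
  points <- matrix(points, ncol = 2)
  h <- h %||% map$grad_h
  gx <- (map$Hmag2(cbind(points[, 1] + h, points[, 2])) -
         map$Hmag2(cbind(points[, 1] - h, points[, 2]))) / (2 * h)
  gy <- (map$Hmag2(cbind(points[, 1], points[, 2] + h)) -
         map$Hmag2(cbind(points[, 1], points[, 2] - h))) / (2 * h)
  cbind(gx = gx, gy = gy)
}

#' @export
print.magnetic_field_map <- function(x, ...) {
  m <- x$magnet
  cat(sprintf("magnetic_field_map (%s): %g x %g mm magnet, M = %g kA/m at (%g, %g) mm\n",
              x$source, 1e3 * m$width, 1e3 * m$height, 1e-3 * m$M,
              1e3 * m$center[1], 1e3 * m$center[2]))
  invisible(x)
}

#' Export field samples to CSV
#' @param map a `magnetic_field_map`.
#' @param points n x 2 matrix (m).
#' @param path output file.
#' @export
write_field_csv <- function(map, points, path) {
  points <- matrix(points, ncol = 2)
  H <- map$H(points); B <- field_B(map, points); G <- grad_H2(map, points)
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2],
                              Hx = H[, 1], Hy = H[, 2],
                              Bmag = sqrt(B[, 1]^2 + B[, 2]^2),
                              dH2dx = G[, 1], dH2dy = G[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
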