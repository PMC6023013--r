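# Small internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctc <- function(...) stop(..., call. = FALSE)

#' Signed area of a simple polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy two-column matrix of vertices (m), not repeated at the end.
#' @return signed area in m^2.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Point-in-polygon test (ray casting), vectorized over points
#'
#' Points on the boundary are classified inside within a small tolerance.
#'
#' @param px,py point coordinates (m).
#' @param xy polygon vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, xy) {
  nv <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a segment, vectorized over points
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# bilinear interpolation on a regular grid given node coordinates implied by
# origin/spacing; `f` is an nx-by-ny matrix with f[i, j] at
# (x0 + (i-1)*hx, y0 + (j-1)*hy). Queries are clamped to the grid hull.
bilinear <- function(f, x0, y0, hx, hy, px, py) {
  nx <- nrow(f); ny <- ncol(f)
  s <- (px - x0) / hx
  t <- (py - y0) / hy
  s <- pmin(pmax(s, 0), nx - 1 - 1e-12)
  t <- pmin(pmax(t, 0), ny - 1 - 1e-12)
  i <- floor(s); j <- floor(t)
  fs <- s - i; ft <- t - j
  i1 <- i + 1L; j1 <- j + 1L
  f00 <- f[cbind(i1, j1)]
  f10 <- f[cbind(i1 + 1L, j1)]
  f01 <- f[cbind(i1, j1 + 1L)]
  f11 <- f[cbind(i1 + 1L, j1 + 1L)]
  f00 * (1 - fs) * (1 - ft) + f10 * fs * (1 - ft) +
    f01 * (1 - fs) * ft + f11 * fs * ft
}
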