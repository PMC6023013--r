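# Structured grid over a device geometry: rectangular bounding box, cell mask
# from point-in-polygon rasterization, staggered (MAC) face bookkeeping.

#' Build a structured grid over a device geometry
#'
#' Cells are marked fluid when their center lies inside the geometry polygon;
#' oblique boundaries (the gradual taper) become staircase walls. Boundary
#' faces inherit their labels from the nearest labelled geometry segment.
#'
#' @param geometry a `device_geometry`.
#' @param nx,ny cell counts along x and y.
#' @return object of class `grid2d`: `nx`, `ny`, `hx`, `hy`, `x0`, `y0`
#'   (lower-left corner of the bounding box), logical `mask` (nx x ny), and
#'   the geometry.
#' @export
build_grid <- function(geometry, nx, ny) {
  bb <- geometry$bbox
  hx <- (bb["xmax"] - bb["xmin"]) / nx
  hy <- (bb["ymax"] - bb["ymin"]) / ny
  xc <- bb["xmin"] + (seq_len(nx) - 0.5) * hx
  yc <- bb["ymin"] + (seq_len(ny) - 0.5) * hy
  pts <- expand.grid(x = xc, y = yc)
  mask <- matrix(point_in_polygon(pts$x, pts$y, geometry$vertices), nx, ny)
  if (!any(mask)) stop_ctc("grid does not intersect the geometry")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 hx = unname(hx), hy = unname(hy),
                 x0 = unname(bb["xmin"]), y0 = unname(bb["ymin"]),
                 mask = mask, geometry = geometry),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %d x %d cells (h = %.3g x %.3g um), %d fluid cells\n",
              x$nx, x$ny, 1e6 * x$hx, 1e6 * x$hy, sum(x$mask)))
  invisible(x)
}
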