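# Device geometries for the two functional subunits of the biochip:
# a diverging-channel magnetophoretic separator and a Y-type electroosmotic
# mixer. Coordinates: x along the main channel (x = 0 at the main-inlet
# mouth), y transverse (y = 0 at the bottom wall of the inlet channel),
# SI units (m) throughout.

default_dims <- function(kind) {
  switch(kind,
    separator_prompt = ,
    separator_gradual = list(
      inlet_width         = 500e-6,  # main inlet
      inlet_length        = 3e-3,    # straight run before the diverging region
      taper_length        = 2e-3,    # diverging passage 500 um -> 2 mm
      wide_width          = 2e-3,
      wide_length         = 7e-3,
      outlet_top_width    = 500e-6,  # non-tagged cell exit
      outlet_bottom_width = 700e-6,  # tagged cell exit (sized by magnet study)
      ancillary_width     = 500e-6,
      ancillary_center_x  = 2e-3     # 1 mm upstream of the taper start
    ),
    mixer_Y = list(
      channel_length   = 9e-3,
      channel_width    = 1e-3,
      inlet_width      = 500e-6,     # each arm of the Y occupies half the width
      n_electrodes     = 10L,
      electrode_length = 0.6e-3,
      electrode_gap    = 0.6e-3,
      electrode_start_x = 1e-3       # first electrode, downstream of the junction
    ),
    stop_ctc("unknown geometry kind: ", kind)
  )
}

#' Build a labelled device geometry
#'
#' Constructs the polygon outline and labelled boundary segments of one of the
#' biochip subunits. The separator is a 500 um-wide inlet channel that widens
#' to 2 mm -- either through a right-angle step (`separator_prompt`) or a
#' linear taper over a 2 mm passage (`separator_gradual`) -- followed by a
#' 7 mm straight section ending in two outlets; an ancillary inlet joins the
#' bottom wall perpendicularly upstream of the expansion. The mixer is a
#' 9 mm x 1 mm straight channel fed by two half-width inlets, with ten wall
#' electrodes in a zigzag (staggered, alternating-wall) arrangement.
#'
#' The widening is on the bottom side of the channel: the bottom wall drops
#' from y = 0 to y = -1.5 mm while the top wall stays at y = 0.5 mm, so the
#' magnet (placed below the chip) pulls tagged cells into the widened region.
#'
#' @param kind one of `"separator_prompt"`, `"separator_gradual"`, `"mixer_Y"`.
#' @param overrides optional named list of dimension overrides (m); names must
#'   match the defaults returned by the geometry kind, values must be positive.
#' @return an object of class `device_geometry`: list with `kind`, `vertices`
#'   (two-column matrix, counter-clockwise, m), `segments` (data.frame
#'   `x1,y1,x2,y2,label` covering the whole boundary), `dims`, `bbox`.
#' @export
build_geometry <- function(kind = c("separator_gradual", "separator_prompt",
                                    "mixer_Y"),
                           overrides = list()) {
  kind <- match.arg(kind)
  dims <- default_dims(kind)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(dims))
    if (length(bad)) stop_ctc("unknown dimension override(s): ",
                              paste(bad, collapse = ", "))
    num <- vapply(overrides, is.numeric, logical(1))
    if (!all(num) || any(unlist(overrides) <= 0))
      stop_ctc("dimension overrides must be positive numbers")
    dims[names(overrides)] <- overrides
  }
  geom <- if (kind == "mixer_Y") build_mixer_geometry(dims)
          else build_separator_geometry(kind, dims)
  geom$kind <- kind
  geom$dims <- dims
  geom$bbox <- c(xmin = min(geom$vertices[, 1]), xmax = max(geom$vertices[, 1]),
                 ymin = min(geom$vertices[, 2]), ymax = max(geom$vertices[, 2]))
  class(geom) <- "device_geometry"
  validate_geometry(geom)
  geom
}

build_separator_geometry <- function(kind, d) {
  x_taper0 <- d$inlet_length
  x_taper1 <- d$inlet_length + d$taper_length
  x_end    <- x_taper1 + d$wide_length
  y_top    <- d$inlet_width
  y_bot    <- d$inlet_width - d$wide_width   # bottom wall of the wide section
  verts <- if (kind == "separator_gradual") {
    rbind(c(0, 0), c(x_taper0, 0), c(x_taper1, y_bot), c(x_end, y_bot),
          c(x_end, y_top), c(0, y_top))
  } else {
    rbind(c(0, 0), c(x_taper0, 0), c(x_taper0, y_bot), c(x_end, y_bot),
          c(x_end, y_top), c(0, y_top))
  }
  a0 <- d$ancillary_center_x - d$ancillary_width / 2
  a1 <- d$ancillary_center_x + d$ancillary_width / 2
  if (a0 <= 0 || a1 >= x_taper0)
    stop_ctc("ancillary inlet must lie on the inlet-channel bottom wall")
  seg <- function(x1, y1, x2, y2, label)
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, label = label)
  segments <- rbind(
    seg(0, 0, a0, 0, "wall"),
    seg(a0, 0, a1, 0, "ancillary_inlet"),
    seg(a1, 0, x_taper0, 0, "wall"),
    if (kind == "separator_gradual") seg(x_taper0, 0, x_taper1, y_bot, "wall")
    else rbind(seg(x_taper0, 0, x_taper0, y_bot, "wall")),
    seg(if (kind == "separator_gradual") x_taper1 else x_taper0, y_bot,
        x_end, y_bot, "wall"),
    seg(x_end, y_bot, x_end, y_bot + d$outlet_bottom_width, "outlet_bottom"),
    seg(x_end, y_bot + d$outlet_bottom_width, x_end,
        y_top - d$outlet_top_width, "wall"),
    seg(x_end, y_top - d$outlet_top_width, x_end, y_top, "outlet_top"),
    seg(x_end, y_top, 0, y_top, "wall"),
    seg(0, y_top, 0, 0, "main_inlet")
  )
  list(vertices = verts, segments = segments)
}

build_mixer_geometry <- function(d) {
  L <- d$channel_length; W <- d$channel_width
  verts <- rbind(c(0, 0), c(L, 0), c(L, W), c(0, W))
  seg <- function(x1, y1, x2, y2, label)
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, label = label)
  # electrodes alternate walls along the channel (zigzag): odd indices on the
  # bottom wall, even on the top. Same-wall pitch is length + gap; the
  # opposite wall is staggered by half a pitch, so with gap = length the
  # electrodes abut axially while alternating walls.
  ne <- as.integer(d$n_electrodes)
  pitch <- d$electrode_length + d$electrode_gap
  k <- seq_len(ne)
  starts <- d$electrode_start_x + ((k - 1) %/% 2) * pitch +
    ((k - 1) %% 2) * pitch / 2
  if (max(starts) + d$electrode_length > L)
    stop_ctc("electrode array does not fit in the mixer channel")
  segs_elec <- do.call(rbind, lapply(seq_len(ne), function(k) {
    y <- if (k %% 2 == 1) 0 else W
    seg(starts[k], y, starts[k] + d$electrode_length, y,
        paste0("electrode_", k))
  }))
  # wall filler on each wall between/around electrodes
  wall_fill <- function(y, elec_on_wall) {
    xs <- sort(c(0, as.vector(rbind(elec_on_wall$x1, elec_on_wall$x2)), L))
    out <- list()
    for (i in seq(1, length(xs) - 1, by = 2)) {
      if (xs[i + 1] > xs[i])
        out[[length(out) + 1]] <- seg(xs[i], y, xs[i + 1], y, "wall")
    }
    do.call(rbind, out)
  }
  eb <- segs_elec[segs_elec$y1 == 0, ]
  et <- segs_elec[segs_elec$y1 == W, ]
  segments <- rbind(
    wall_fill(0, eb), eb,
    seg(L, 0, L, W, "mixer_outlet"),
    wall_fill(W, et), et,
    seg(0, W, 0, W - d$inlet_width, "mixer_inlet_A"),  # top arm: CTC stream
    seg(0, W - d$inlet_width, 0, 0, "mixer_inlet_B")   # bottom arm: lysis buffer
  )
  list(vertices = verts, segments = segments)
}

validate_geometry <- function(geom) {
  if (polygon_area(geom$vertices) <= 0)
    stop_ctc("geometry polygon must be counter-clockwise with positive area")
  # boundary segments must cover the polygon perimeter exactly once
  per <- {
    v <- geom$vertices
    vn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    sum(sqrt(rowSums((vn - v)^2)))
  }
  s <- geom$segments
  slen <- sum(sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2))
  if (abs(slen - per) > 1e-9 * per)
    stop_ctc("boundary segments do not tile the polygon perimeter")
  invisible(geom)
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("device_geometry:", x$kind, "\n")
  cat(sprintf("  bbox: x [%g, %g] mm, y [%g, %g] mm\n",
              1e3 * x$bbox["xmin"], 1e3 * x$bbox["xmax"],
              1e3 * x$bbox["ymin"], 1e3 * x$bbox["ymax"]))
  cat(sprintf("  area: %.4g mm^2, %d boundary segments\n",
              1e6 * polygon_area(x$vertices), nrow(x$segments)))
  invisible(x)
}

#' Export geometry vertices to CSV
#'
#' @param geom a `device_geometry`.
#' @param path output file.
#' @export
write_geometry_csv <- function(geom, path) {
  utils::write.csv(data.frame(x = geom$vertices[, 1], y = geom$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

# labelled segments of a given label (used for BC lookup)
geometry_segments <- function(geom, label) {
  geom$segments[geom$segments$label == label, , drop = FALSE]
}
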