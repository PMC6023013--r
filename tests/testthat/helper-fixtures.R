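# Shared fixtures. Flow solves are the expensive step, so they are cached
# lazily in this environment and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# coarse but contract-respecting separator grid (>= 8 cells across the
# 2 mm passage)
test_config <- function(profile = "integrated") {
  cfg <- default_config(profile)
  cfg$solver$nx <- 120L
  cfg$solver$ny <- 20L
  cfg
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

sep_geometry <- function() cached("sep_geom", build_geometry("separator_gradual"))

# gradual separator, default BCs, coarse grid, full Navier-Stokes
sep_flow <- function() cached("sep_flow", {
  solve_steady_flow(sep_geometry(), NULL, test_config())
})

# same flow field is reused for tracer tests with the magnet off
sep_field <- function() cached("sep_field", {
  field_map_analytic(magnet_spec(test_config(),
                                 channel_bottom_y = sep_geometry()$bbox["ymin"]))
})

# straight rectangular channel (mixer outline without electrodes in the way)
# used for closed-form flow checks
straight_geometry <- function(L = 3e-3, W = 5e-4) {
  build_geometry("mixer_Y",
                 overrides = list(channel_length = L, channel_width = W,
                                  inlet_width = W / 2,
                                  electrode_start_x = L / 30,
                                  electrode_length = L / 30,
                                  electrode_gap = L / 30))
}

# plane-Poiseuille solve: pressure-driven, Stokes, ny transverse cells
poiseuille_flow <- function(ny = 64, dp = 10, L = 3e-3, W = 5e-4, nx = 60) {
  geom <- straight_geometry(L, W)
  grid <- build_grid(geom, nx, ny)
  solve_steady_flow(geom, grid, default_config("mixer"), stokes = TRUE,
                    bc_overrides = list(
                      mixer_inlet_A = list(type = "pressure", value = dp),
                      mixer_inlet_B = list(type = "pressure", value = dp)))
}

# synthetic uniform flow field on a rectangle (test double for closed-form
# drift checks): u = (U, 0) everywhere
uniform_flow_field <- function(U = 0.01, L = 10e-3, W = 2e-3,
                               nx = 50, ny = 20) {
  geom <- straight_geometry(L, W)
  grid <- build_grid(geom, nx, ny)
  structure(list(
    grid = grid, geometry = geom,
    u = matrix(U, nx + 1, ny),
    v = matrix(0, nx, ny + 1),
    p = matrix(0, nx, ny),
    metadata = list(Re = 0, Uref = U, stokes = TRUE, n_cells = nx * ny,
                    max_divergence = 0, net_flux = 0, influx = U * W)),
    class = "flow_field")
}

# test-double field map whose |H|^2 is linear in y: grad|H|^2 = (0, slope)
linear_h2_map <- function(slope = 1e13) {
  structure(list(
    H = function(pts) cbind(Hx = rep(0, nrow(matrix(pts, ncol = 2))), Hy = 0),
    Hmag2 = function(pts) {
      pts <- matrix(pts, ncol = 2)
      slope * pts[, 2]
    },
    source = "analytic", mu_r = 1, mu0 = 4e-7 * pi, grad_h = 1e-7,
    magnet = structure(list(center = c(0, -1), width = 1e-3, height = 1e-3,
                            M = 0, direction = c(0, 1)),
                       class = "magnet_spec")),
    class = "magnetic_field_map")
}

# uniform-field test double: grad|H|^2 = 0
uniform_h2_map <- function(value = 1e10) {
  m <- linear_h2_map(0)
  m$Hmag2 <- function(pts) rep(value, nrow(matrix(pts, ncol = 2)))
  m
}
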