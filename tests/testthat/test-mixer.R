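# Mixer electrokinetics: electric field, slip, periodic flow superposition,
# scalar transport, mixing index.

# rectangle with one full-wall electrode per wall (parallel-plate closed form)
parallel_plate_geometry <- function(L = 2e-3, W = 1e-3) {
  seg <- function(x1, y1, x2, y2, label)
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, label = label)
  structure(list(
    kind = "mixer_Y",
    vertices = rbind(c(0, 0), c(L, 0), c(L, W), c(0, W)),
    segments = rbind(seg(0, 0, L, 0, "electrode_1"),
                     seg(L, 0, L, W, "mixer_outlet"),
                     seg(L, W, 0, W, "electrode_2"),
                     seg(0, W, 0, W / 2, "mixer_inlet_A"),
                     seg(0, W / 2, 0, 0, "mixer_inlet_B")),
    dims = list(channel_length = L, channel_width = W, inlet_width = W / 2),
    bbox = c(xmin = 0, xmax = L, ymin = 0, ymax = W)),
    class = "device_geometry")
}

test_that("parallel-plate electrodes give the uniform closed-form field", {
  geom <- parallel_plate_geometry()
  grid <- build_grid(geom, 40, 20)
  cfg <- default_config("mixer")
  arr <- electrode_array(geom, cfg)
  expect_equal(arr$segments$sign, c(1, -1))
  ef <- solve_electric_field(geom, grid, arr)
  # |E| = deltaV / W = 2 / 1 mm = 2000 V/m for the unit +-1 drive
  expect_equal(mean(-ef$Ey[, 10]), -2000, tolerance = 0.01)
  inner <- ef$Ey[5:36, 5:16]
  expect_lt(max(abs(inner - mean(inner))) / abs(mean(inner)), 1e-6)
  # flipping all signs negates the potential exactly
  arr2 <- arr; arr2$segments$sign <- -arr$segments$sign
  ef2 <- solve_electric_field(geom, grid, arr2)
  expect_equal(ef2$V, -ef$V, tolerance = 1e-9)
  # same-sign electrodes are rejected (potential defined up to a constant)
  arr3 <- arr; arr3$segments$sign <- c(1, 1)
  expect_error(solve_electric_field(geom, grid, arr3), "phase sign")
})

test_that("zigzag array drives tangential wall field of alternating sign across each gap", {
  geom <- build_geometry("mixer_Y")
  grid <- build_grid(geom, 128, 24)
  cfg <- default_config("mixer")
  ef <- solve_electric_field(geom, grid, electrode_array(geom, cfg))
  # in every bottom-wall gap (beneath an opposite-sign top electrode) the
  # tangential field points into the gap on one side and out on the other:
  # positive in the first half, negative in the second, in all four gaps
  xs_face <- grid$x0 + (0:grid$nx) * grid$hx
  gapstart <- 1.6e-3 + (0:3) * 1.2e-3
  for (gs in gapstart) {
    q1 <- which.min(abs(xs_face - (gs + 0.15e-3)))
    q3 <- which.min(abs(xs_face - (gs + 0.45e-3)))
    expect_gt(ef$Et_bottom[q1], 0)
    expect_lt(ef$Et_bottom[q3], 0)
  }
})

test_that("Helmholtz-Smoluchowski slip evaluates the stated closed form", {
  cfg <- default_config("mixer")
  # eps_r 80, zeta -0.1 V, eta 1e-3, E_t 1e4 V/m -> 7.08e-4 m/s
  expect_equal(signif(slip_velocity(1e4, cfg), 3), 7.08e-4)
  cfg0 <- cfg; cfg0$electrokinetics$zeta <- 0
  expect_equal(slip_velocity(1e4, cfg0), 0)
  expect_equal(slip_velocity(-1e4, cfg), -slip_velocity(1e4, cfg))
})

test_that("quasi-steady superposition matches direct re-solves at arbitrary times", {
  geom <- build_geometry("mixer_Y")
  grid <- build_grid(geom, 64, 16)
  cfg <- default_config("mixer")
  arr <- electrode_array(geom, cfg)
  ef <- solve_electric_field(geom, grid, arr)
  pf <- suppressWarnings(
    periodic_flow(geom, grid, cfg, arr, efield = ef, unsteady = FALSE))
  s_bot <- slip_velocity(ef$Et_bottom, cfg) * arr$v0
  s_top <- slip_velocity(ef$Et_top, cfg) * arr$v0
  for (t in c(0.03, 0.111, 0.27)) {
    a <- sin(pf$omega * t)
    direct <- solve_steady_flow(geom, grid, cfg, stokes = TRUE,
                                slip_bc = ctcchip:::slip_bc_from_arrays(
                                  grid, a * s_bot, a * s_top))
    sup <- pf$velocity_at(t)
    scale <- max(abs(direct$u)) + 1e-15
    expect_lt(max(abs(sup$u - direct$u)) / scale, 1e-8)
    expect_lt(max(abs(sup$v - direct$v)) / scale, 1e-8)
  }
  # waveform zero crossing: quasi-steady flow equals the base flow exactly
  z <- pf$velocity_at(1 / arr$frequency)
  expect_equal(z$u, pf$base$u, tolerance = 1e-12)
})

test_that("harmonic mode attenuates with frequency (finite response time)", {
  geom <- build_geometry("mixer_Y")
  grid <- build_grid(geom, 64, 16)
  cfg <- default_config("mixer")
  arr <- electrode_array(geom, cfg)
  ef <- solve_electric_field(geom, grid, arr)
  amp <- vapply(c(2, 32), function(f) {
    cfgf <- cfg; cfgf$electrodes$frequency <- f
    pf <- suppressWarnings(periodic_flow(geom, grid, cfgf,
                                         electrode_array(geom, cfgf),
                                         efield = ef, unsteady = TRUE))
    # interior actuation amplitude (exclude the slip boundary itself)
    max(sqrt(pf$ur[, 8]^2 + pf$ui[, 8]^2))
  }, numeric(1))
  expect_gt(amp[1], 2 * amp[2])
})

test_that("scalar transport conserves mass and relaxes a closed step to uniform", {
  geom <- parallel_plate_geometry(L = 1e-3, W = 1e-3)
  grid <- build_grid(geom, 20, 20)
  cfg <- default_config("mixer")
  cfg$electrokinetics$diffusivity <- 1e-8
  # quiescent closed box: zero-velocity steady flow double
  fl0 <- structure(list(
    grid = grid, geometry = geom,
    u = matrix(0, 21, 20), v = matrix(0, 20, 21), p = matrix(0, 20, 20),
    metadata = list(Uref = 0)), class = "flow_field")
  rec <- advect_diffuse(fl0, cfg, t_end = 5, sample_x = 0.5e-3)
  expect_true(all(rec$c >= -1e-9 & rec$c <= 1 + 1e-9))
  expect_equal(mean(rec$c), 0.5, tolerance = 1e-10)  # mass conserved
  # L2 distance to the uniform state decays monotonically
  cfg2 <- cfg
  steps <- vapply(c(0.5, 2, 5), function(tend) {
    r <- advect_diffuse(fl0, cfg2, t_end = tend, sample_x = 0.5e-3)
    sqrt(mean((r$c - 0.5)^2))
  }, numeric(1))
  expect_true(all(diff(steps) < 0))
  # pure-diffusion eigenmode decay rate as an independent oracle: the step
  # profile relaxes at the slowest-mode rate pi^2 D / W^2
  lam <- pi^2 * 1e-8 / (1e-3)^2
  r1 <- advect_diffuse(fl0, cfg, t_end = 20, sample_x = 0.5e-3)
  r2 <- advect_diffuse(fl0, cfg, t_end = 30, sample_x = 0.5e-3)
  a1 <- sqrt(mean((r1$c - 0.5)^2)); a2 <- sqrt(mean((r2$c - 0.5)^2))
  expect_equal(log(a1 / a2) / 10, lam, tolerance = 0.05)
  cfg_neg <- cfg; cfg_neg$electrokinetics$diffusivity <- -1
  expect_error(advect_diffuse(fl0, cfg_neg), "non-negative")
})

test_that("mixing index matches direct arithmetic and its invariances", {
  # uniform line: perfectly mixed
  g <- build_grid(parallel_plate_geometry(), 10, 10)
  cm <- matrix(0.5, 10, 10)
  mi <- mixing_index(cm, g, sample_x = 1e-3, n = 100)
  expect_equal(unname(mi["CoV"]), 0)
  expect_equal(unname(mi["MI"]), 1)
  # half/half unmixed with n = 100 and the n-1 denominator
  ci <- c(rep(1, 50), rep(0, 50))
  v <- ctcchip:::mixing_index_values(ci)
  expect_equal(unname(v["CoV"]), sqrt(25 / 99) / 0.5, tolerance = 1e-12)
  expect_equal(signif(unname(v["MI"]), 3), -0.00504)
  # permutation invariance
  set.seed(9)
  expect_equal(ctcchip:::mixing_index_values(sample(ci)), v)
  expect_error(ctcchip:::mixing_index_values(rep(0, 10)), "zero")
  expect_error(mixing_index(cm, g, sample_x = 1e-3, n = 1), "2 pixels")
  expect_error(mixing_index(cm, g, sample_x = 9e-3, n = 10), "outside")
})

test_that("zero drive leaves the mixer diffusion-limited; actuation mixes", {
  cfg <- default_config("mixer")
  rec0 <- suppressWarnings(run_mixer(cfg, v0 = 0, t_end = 1, nx = 64, ny = 16))
  rec100 <- suppressWarnings(run_mixer(cfg, v0 = 100, frequency = 4,
                                       t_end = 1, nx = 64, ny = 16))
  expect_lt(rec0$mi, rec100$mi)
  # maximum principle on the actuated run
  expect_true(all(rec100$c >= -1e-6 & rec100$c <= 1 + 1e-6))
  # V0 = 0: flow constant in time (steady base flow only)
  pf0 <- attr(rec0, "pflow")
  expect_s3_class(pf0, "flow_field")
})
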