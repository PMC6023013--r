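# Flow solver: closed-form checks, conservation, linearity, symmetry,
# recirculation detection, grid convergence.

test_that("pressure-driven channel reproduces plane Poiseuille at 64 cells", {
  W <- 5e-4; L <- 3e-3; dp <- 10; mu <- 1e-3
  fl <- poiseuille_flow(ny = 64, dp = dp, L = L, W = W)
  g <- fl$grid
  yj <- (seq_len(64) - 0.5) * g$hy
  G <- dp / L
  uex <- G / (2 * mu) * yj * (W - yj)
  umid <- fl$u[g$nx %/% 2, ]
  expect_lt(max(abs(umid - uex)) / max(uex), 0.01)
  # peak-to-mean ratio of the profile is 1.5
  expect_equal(max(umid) / mean(umid), 1.5, tolerance = 1e-3)
  # discrete divergence and global mass conservation
  expect_lt(fl$metadata$max_divergence,
            1e-8 * max(uex) / W)
  expect_lt(abs(fl$metadata$net_flux), 1e-10 * max(uex) * W)
})

test_that("axial pressure decay matches the analytic Poiseuille gradient", {
  W <- 5e-4; L <- 3e-3; dp <- 10; mu <- 1e-3
  fl <- poiseuille_flow(ny = 32, dp = dp, L = L, W = W)
  prof <- pressure_profile(fl, rbind(c(0.5e-3, W / 2), c(2.5e-3, W / 2)),
                           n = 50)
  slope <- coef(lm(p ~ s, prof))[["s"]]
  U <- mean(fl$u[fl$grid$nx %/% 2, ])   # depth-mean velocity
  expect_equal(slope, -12 * mu * U / W^2, tolerance = 0.01)
  # a constant field gives a flat profile
  fl0 <- fl; fl0$p[] <- 3.14
  prof0 <- pressure_profile(fl0, rbind(c(0.5e-3, W / 2), c(2.5e-3, W / 2)))
  expect_true(all(abs(prof0$p - 3.14) < 1e-12))
  expect_error(pressure_profile(fl, rbind(c(-1e-3, 0), c(1e-3, 0))), "outside")
})

test_that("null forcing gives an identically zero field", {
  geom <- straight_geometry()
  grid <- build_grid(geom, 30, 16)
  cfg <- default_config("mixer")
  fl <- solve_steady_flow(geom, grid, cfg, stokes = TRUE,
                          bc_overrides = list(
                            mixer_inlet_A = list(type = "velocity", mean = 0),
                            mixer_inlet_B = list(type = "velocity", mean = 0)))
  expect_lt(max(abs(fl$u), abs(fl$v), abs(fl$p)), 1e-12)
})

test_that("Stokes mode is linear: doubling boundary velocities doubles u and p", {
  geom <- straight_geometry()
  grid <- build_grid(geom, 30, 16)
  cfg <- default_config("mixer")
  cfg$flow$mixer_inlet_velocity <- 2e-3
  f1 <- solve_steady_flow(geom, grid, cfg, stokes = TRUE)
  cfg$flow$mixer_inlet_velocity <- 4e-3
  f2 <- solve_steady_flow(geom, grid, cfg, stokes = TRUE)
  expect_equal(f2$u, 2 * f1$u, tolerance = 1e-10)
  expect_equal(f2$p, 2 * f1$p, tolerance = 1e-8)
})

test_that("straight-channel flow is symmetric under y-reflection", {
  geom <- straight_geometry()
  grid <- build_grid(geom, 30, 16)
  fl <- solve_steady_flow(geom, grid, default_config("mixer"), stokes = TRUE)
  u <- fl$u
  expect_lt(max(abs(u - u[, ncol(u):1])), 1e-12 * max(abs(u)))
})

test_that("interpolation contract rejects out-of-domain queries", {
  fl <- sep_flow()
  expect_error(interp_velocity(fl, rbind(c(1e-3, 2e-3))), "outside")
  v <- interp_velocity(fl, rbind(c(1e-3, 2.5e-4)))
  expect_equal(ncol(v), 2)
  expect_gt(v[1, 1], 0)  # downstream flow at the inlet channel centerline
})

test_that("recirculation appears in the prompt geometry at high ancillary flow only", {
  cfg <- test_config()
  gp <- build_geometry("separator_prompt")
  fl_hi <- solve_steady_flow(gp, NULL, cfg,
                             bc_overrides = list(ancillary_inlet =
                                                   list(type = "velocity",
                                                        mean = 12e-3)))
  rc_hi <- detect_recirculation(fl_hi)
  expect_true(rc_hi$has_vortex)
  expect_gt(rc_hi$vortex_area, 0)
  # vortex sits near the bottom expansion corner
  expect_lt(rc_hi$patch_bbox["ymin"], -0.5e-3)
  expect_gt(rc_hi$patch_bbox["xmin"], 2e-3)
  # the gradual geometry at 4 mm/s has attached streamlines
  rc_lo <- detect_recirculation(sep_flow())
  expect_false(rc_lo$has_vortex)
  # and plane Poiseuille flow is unidirectional
  expect_false(detect_recirculation(poiseuille_flow(ny = 16))$has_vortex)
})

test_that("vortex area grows with ancillary velocity in the prompt geometry", {
  cfg <- test_config()
  gp <- build_geometry("separator_prompt")
  areas <- vapply(c(4e-3, 12e-3), function(va) {
    fl <- solve_steady_flow(gp, NULL, cfg,
                            bc_overrides = list(ancillary_inlet =
                                                  list(type = "velocity",
                                                       mean = va)))
    detect_recirculation(fl)$vortex_area
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("grid refinement drives the monitored maximum velocity to convergence", {
  cfg <- default_config()
  tab <- grid_convergence_study(sep_geometry(), cfg,
                                element_counts = c(1200, 2400, 4800))
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$rel_change[1]))
  # successive changes shrink and end below 5% on these coarse grids
  expect_lt(tab$rel_change[3], tab$rel_change[2] + 1e-9)
  expect_lt(tab$rel_change[3], 0.05)
  # identical counts give identical monitored values
  tab2 <- grid_convergence_study(sep_geometry(), cfg,
                                 element_counts = c(1200, 1200, 1200))
  expect_equal(tab2$rel_change[2], 0)
  expect_error(grid_convergence_study(sep_geometry(), cfg, c(100, 200)),
               "at least 3")
  expect_error(grid_convergence_study(sep_geometry(), cfg, c(300, 200, 100)),
               "non-decreasing")
  # mixer monitor: the mixing index, repeated counts give zero change
  tabm <- grid_convergence_study(build_geometry("mixer_Y"),
                                 default_config("mixer"),
                                 element_counts = c(768, 768, 768),
                                 monitor = "mixing_index", t_end = 0.25)
  expect_equal(tabm$rel_change[2], 0)
})

test_that("pressure drop across the expansion reflects the longer narrow path of the taper", {
  # at these viscous conditions (Re = 20) friction dominates the expansion
  # loss: the gradual taper keeps the channel narrow over an extra 2 mm of
  # path, so it loses more pressure across the expansion window than the
  # prompt step (the inertial Borda-Carnot excess of the step, ~rho du^2/2,
  # is two orders smaller here)
  cfg <- test_config()
  drop_across_expansion <- function(kind) {
    geom <- build_geometry(kind)
    fl <- solve_steady_flow(geom, NULL, cfg)
    prof <- pressure_profile(fl, rbind(c(2.8e-3, 2.5e-4), c(5.2e-3, 2.5e-4)),
                             n = 60)
    prof$p[1] - prof$p[nrow(prof)]
  }
  dp_prompt <- drop_across_expansion("separator_prompt")
  dp_gradual <- drop_across_expansion("separator_gradual")
  expect_gt(dp_gradual, dp_prompt)
  expect_gt(dp_prompt, 0)
})

test_that("flow and field CSV exports write the sampled columns", {
  fl <- poiseuille_flow(ny = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(fl, path)
  df <- read.csv(path)
  expect_named(df, c("x", "y", "u", "v", "p"))
  expect_equal(nrow(df), fl$metadata$n_cells)
  mg <- magnet_spec(default_config())
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(field_map_analytic(mg), rbind(mg$center + c(0, 3e-3)), path2)
  df2 <- read.csv(path2)
  expect_true(all(c("Hx", "Hy", "Bmag", "dH2dx", "dH2dy") %in% names(df2)))
})

test_that("laminar guard rejects high-Reynolds configurations", {
  cfg <- default_config()
  cfg$flow$main_inlet_velocity <- 0.2   # Re = 400 on the 2 mm channel
  expect_error(solve_steady_flow(sep_geometry(), NULL, cfg), "laminar")
})
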