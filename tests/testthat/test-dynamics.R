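# Particle dynamics: drag law, magnetophoretic force, integrators, events,
# ensemble statistics, force audit.

test_that("drag response time has the Stokes limit and the stated CD values", {
  cfg <- default_config("separator")
  pars <- force_model_params(cfg)
  d0 <- drag_response_time(pars, 0)
  expect_equal(d0$tau_p, 1050 * (10e-6)^2 / (18e-3), tolerance = 1e-12)
  expect_equal(signif(d0$tau_p, 3), 5.83e-6)
  # CD at Re_r = 1 is 24 * 1.15
  slip_re1 <- cfg$fluid$viscosity / (cfg$fluid$density * cfg$particle$diameter)
  expect_equal(drag_response_time(pars, slip_re1)$CD, 27.6, tolerance = 1e-9)
  # Schiller-Naumann collapses onto Stokes at vanishing Reynolds
  slip_re4 <- 1e-4 * slip_re1
  tau_sn <- drag_response_time(pars, slip_re4)$tau_p
  tau_st <- drag_response_time(force_model_params(cfg, correlation = "stokes"),
                               slip_re4)$tau_p
  expect_equal(tau_sn / tau_st, 1, tolerance = 1e-3)
  # the printed-variant response time is half the standard one
  tau_p7 <- drag_response_time(force_model_params(cfg, correlation = "half_response"),
                               0)$tau_p
  expect_equal(tau_p7, d0$tau_p / 2)
  expect_error(drag_response_time(pars, -1), "non-negative")
})

test_that("magnetophoretic force follows the contrast and cubic-radius scaling", {
  cfg <- default_config("separator")
  pars <- force_model_params(cfg)
  g <- cbind(1e13, -2e13)
  F1 <- magnetophoretic_force(pars, g)
  expect_equal(F1, 2 * pi * pars$rp^3 * pars$mu0 * pars$mu_r * pars$K * g,
               ignore_attr = TRUE)
  # K = 0 (untagged) and uniform field both give zero force
  expect_true(all(magnetophoretic_force(force_model_params(cfg, tagged = FALSE),
                                        g) == 0))
  expect_true(all(magnetophoretic_force(pars, cbind(0, 0)) == 0))
  # doubling the radius scales the force by 8
  cfg2 <- cfg; cfg2$particle$diameter <- 2 * cfg$particle$diameter
  F2 <- magnetophoretic_force(force_model_params(cfg2), g)
  expect_equal(unname(F2 / F1), matrix(8, 1, 2), tolerance = 1e-12)
})

test_that("overdamped drift in uniform flow matches the ballistic closed form", {
  cfg <- default_config("separator")
  pars <- force_model_params(cfg)
  U <- 0.01
  fl <- uniform_flow_field(U = U)
  fmap <- linear_h2_map(slope = -1e13)   # grad|H|^2 = (0, -1e13): downward pull
  Fy <- magnetophoretic_force(pars, cbind(0, -1e13))[2]
  drift <- Fy / (3 * pi * pars$mu * pars$dp)
  phi <- drag_response_time(pars, abs(drift))$phi
  drift <- Fy / (3 * pi * pars$mu * pars$dp * phi)
  ens <- structure(list(n = 1L, positions = cbind(x = 1e-3, y = 1.5e-3),
                        velocities = matrix(0, 1, 2),
                        status = "in_flight", rng_seed = 1L,
                        release_time = 0),
                   class = "particle_ensemble")
  tr <- trace(ens, fl, fmap, pars, dt = 1e-3, t_max = 0.35)
  dx <- tr$final_positions[1, 1] - 1e-3
  dy <- tr$final_positions[1, 2] - 1.5e-3
  expect_equal(unname(dy / dx), drift / U, tolerance = 1e-3)
  # inertial integration converges to the same drift line
  ens2 <- ens
  tri <- trace(ens2, fl, fmap, pars, integrator = "inertial_rk",
               dt = 2.5e-6, t_max = 0.02)
  dyi <- tri$final_positions[1, 2] - 1.5e-3
  dxi <- tri$final_positions[1, 1] - 1e-3
  expect_equal(unname(dyi / dxi), drift / U, tolerance = 0.01)
  expect_error(trace(ens2, fl, fmap, pars, integrator = "inertial_rk",
                     dt = 1e-3), "tau_p")
})

test_that("with forces off, overdamped tracing reproduces streamline advection", {
  fl <- sep_flow()
  cfg <- test_config()
  pars <- force_model_params(cfg, tagged = FALSE)
  ens <- seed_particles(fl$geometry, 3, "three_tracers", flow = fl)
  station <- fl$geometry$bbox["xmax"] - 0.5e-3
  tr <- trace(ens, fl, NULL, pars, dt = 2e-4, t_max = 6, station_x = station)
  # oracle: dense RK4 integration of the interpolated velocity field
  oracle_y <- vapply(seq_len(3), function(i) {
    p <- ens$positions[i, ]
    dt <- 5e-5
    for (s in seq_len(200000)) {
      k1 <- interp_velocity(fl, rbind(p), check = FALSE)[1, ]
      k2 <- interp_velocity(fl, rbind(p + dt / 2 * k1), check = FALSE)[1, ]
      k3 <- interp_velocity(fl, rbind(p + dt / 2 * k2), check = FALSE)[1, ]
      k4 <- interp_velocity(fl, rbind(p + dt * k3), check = FALSE)[1, ]
      pn <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (pn[1] >= station) {
        w <- (station - p[1]) / (pn[1] - p[1])
        return(p[2] + w * (pn[2] - p[2]))
      }
      p <- pn
    }
    NA_real_
  }, numeric(1))
  cell <- max(fl$grid$hx, fl$grid$hy)
  expect_true(all(abs(tr$station_y - oracle_y) < cell))
  # no magnetic response: nothing is captured on the bottom wall
  expect_true(all(tr$status != "hit_bottom_wall"))
})

test_that("tagged ensembles capture on the bottom wall; capture grows with contrast", {
  fl <- sep_flow()
  cfg <- test_config()
  fm <- sep_field()
  caps <- vapply(c(1.05, 1.15), function(mrp) {
    cfgk <- cfg; cfgk$particle$mu_r_p <- mrp
    ens <- seed_particles(fl$geometry, 30, "uniform_inlet", seed = 3,
                          flow = fl)
    tr <- trace(ens, fl, fm, force_model_params(cfgk), dt = 4e-4, t_max = 4)
    sum(tr$status == "hit_bottom_wall")
  }, numeric(1))
  expect_gt(caps[1], 0)
  expect_gte(caps[2], caps[1])
  # mean transverse position is non-increasing while the magnet pulls down
  ens <- seed_particles(fl$geometry, 30, "uniform_inlet", seed = 3, flow = fl)
  tr <- trace(ens, fl, sep_field(), force_model_params(cfg), dt = 4e-4,
              t_max = 4, store_times = c(0.5, 1, 1.5, 2))
  st <- ensemble_statistics(tr, c(0.5, 1, 1.5, 2), breaks = 8)
  expect_true(all(diff(st$summary$mean_y) <= 1e-12))
  # histogram counts always sum to the ensemble size
  expect_true(all(vapply(st$histograms,
                         function(h) sum(h$counts), numeric(1)) == 30))
  expect_error(ensemble_statistics(tr, times = 99), "stored")
})

test_that("trace validates inputs and preserves determinism", {
  fl <- sep_flow()
  pars <- force_model_params(test_config())
  ens <- seed_particles(fl$geometry, 3, "three_tracers", flow = fl)
  expect_error(trace(ens, fl, NULL, pars, dt = -1), "positive")
  bad <- ens; bad$positions[1, ] <- c(5e-3, 4e-4) * c(1, 10)
  expect_error(trace(bad, fl, NULL, pars), "outside")
  t1 <- trace(ens, fl, sep_field(), pars, dt = 5e-4, t_max = 1)
  t2 <- trace(ens, fl, sep_field(), pars, dt = 5e-4, t_max = 1)
  expect_identical(t1$final_positions, t2$final_positions)
})

test_that("force audit reproduces the printed reference magnitudes", {
  cfg <- default_config("separator")
  fa <- force_audit(cfg)
  # (4/3) pi R^3 rho g at R = 5 um: 5.13 pN for rho = 1000 (buoyancy, the
  # fluid density) and 5.39 pN for rho = 1050 (gravity, the cell density)
  expect_equal(signif(fa$forces[["buoyancy"]] * 1e12, 3), 5.13)
  expect_equal(signif(fa$forces[["gravity"]] * 1e12, 3), 5.39)
  # equal densities make the two body forces identical
  cfg_eq <- cfg; cfg_eq$particle$density <- cfg_eq$fluid$density
  fa_eq <- force_audit(cfg_eq)
  expect_equal(fa_eq$forces[["gravity"]], fa_eq$forces[["buoyancy"]])
  # body forces are orders below the magnetic force near the magnet
  expect_gt(fa$forces[["magnetophoretic"]] / fa$forces[["gravity"]], 100)
  expect_equal(unname(fa$classification[c("gravity", "buoyancy")]),
               c("negligible", "negligible"))
  expect_setequal(fa$excluded_by_assumption,
                  c("DLVO", "Brownian", "interparticle"))
})
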