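test_that("layer geometry derives depths, velocities and residence times", {
  col <- filter_column(list(column_layer("mix", 11, 1.5, 0.4)),
                       diameter = 0.34, flow_rate = 1)
  geom <- layer_geometry(col)
  A <- pi * 0.34^2 / 4
  expect_equal(geom$depth, 11 / (1500 * A), tolerance = 1e-12)  # ~0.0807 m
  expect_equal(geom$depth, 0.0807, tolerance = 1e-2)
  expect_equal(geom$velocity, (1 / 60000) / (A * 0.4), tolerance = 1e-12)
  expect_equal(geom$velocity, 4.59e-4, tolerance = 1e-2)
  expect_equal(geom$residence, geom$depth / geom$velocity)
  # high porosity: residence approaches plug-flow pore volume / Q
  col2 <- filter_column(list(column_layer("open", 11, 1.5, 0.99)),
                        diameter = 0.34, flow_rate = 1)
  g2 <- layer_geometry(col2)
  expect_equal(g2$residence, attr(g2, "total_pore_volume") / 1 * 60,
               tolerance = 1e-9)
})

test_that("retardation follows the linear-equilibrium closure", {
  lay <- column_layer("mix", 11, 1.6, 0.4, f_sand = 10 / 11,
                      f_biochar = 1 / 11)
  expect_equal(retardation(lay, solute_transport_params()), 1)
  # pilot-magnitude coefficients: K_d ~ 2.38 L/kg, R ~ 10.5
  p <- solute_transport_params(K_s = 1.4, K_bc = 12.2)
  expect_equal(retardation(lay, p),
               1 + 1.6 / 0.4 * (10 / 11 * 1.4 + 1 / 11 * 12.2),
               tolerance = 1e-12)
  expect_equal(retardation(lay, p), 10.53, tolerance = 1e-3)
  p2 <- solute_transport_params(K_s = 1.4, K_bc = 24.4)
  expect_gt(retardation(lay, p2), retardation(lay, p))
})

test_that("a conservative tracer breaks through near one pore volume", {
  col <- hom_column()
  sim <- simulate_breakthrough(col, solute_transport_params(),
                               target_volume = 4, n_cells = 400)
  pv <- attr(layer_geometry(col), "total_pore_volume")
  v50 <- stats::approx(sim$c_over_cin, sim$cum_volume, 0.5,
                       ties = "ordered")$y
  expect_equal(v50, pv, tolerance = 0.05)
  expect_true(all(sim$c_over_cin <= 1 + 1e-6))
})

test_that("the equilibrium solver matches the closed-form solution", {
  col <- hom_column()
  for (R in c(1, 2, 10)) {
    par <- solute_transport_params(K_s = hom_ks_for_R(R))
    sim <- simulate_breakthrough(col, par, target_volume = 0.24 * 500 * R / 60,
                                 n_cells = 400, courant = 0.95)
    eff <- attr(sim, "effluent")
    ana <- analytic_breakthrough(hom_L, hom_v, hom_D, R, eff$time)
    expect_lt(max(abs(eff$conc - ana)), 0.01, label = paste("R =", R))
  }
})

test_that("the closed form behaves at its limits", {
  # complete breakthrough at long time
  expect_equal(analytic_breakthrough(hom_L, hom_v, hom_D, 2, 1e8), 1)
  expect_equal(analytic_breakthrough(hom_L, hom_v, hom_D, 2, c(-5, 0)),
               c(0, 0))
  # half breakthrough at t = R L / v when dispersion is weak
  t_half <- 2 * hom_L / hom_v
  expect_equal(analytic_breakthrough(hom_L, hom_v, 1e-7, 2, t_half), 0.5,
               tolerance = 0.02)
  # derived case: L=0.2, v=1e-3, D=1e-5, R=2 -> half breakthrough ~400 s
  f <- function(t) analytic_breakthrough(0.2, 1e-3, 1e-5, 2, t) - 0.5
  t50 <- stats::uniroot(f, c(100, 1000))$root
  expect_equal(t50, 400, tolerance = 0.06)
  # first- and third-type forms converge (like 1/sqrt(Pe)) at large
  # column Peclet number
  tt <- seq(50, 800, by = 10)
  gap <- vapply(c(2e-6, 2e-7, 2e-8), function(D) {
    max(abs(analytic_breakthrough(0.2, 1e-3, D, 1, tt, inlet = "concentration") -
              analytic_breakthrough(0.2, 1e-3, D, 1, tt, inlet = "flux")))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("every simulation closes its mass balance within 0.5%", {
  col <- hom_column()
  runs <- list(
    simulate_breakthrough(col, solute_transport_params(),
                          target_volume = 3, n_cells = 200),
    simulate_breakthrough(col, solute_transport_params(K_s = hom_ks_for_R(2)),
                          target_volume = 5, n_cells = 200),
    simulate_breakthrough(col, solute_transport_params(K_s = 0.25, k = 1e-3,
                                                       mode = "kinetic"),
                          target_volume = 5, n_cells = 200),
    simulate_breakthrough(default_filter_column(),
                          solute_transport_params(K_s = 1.4, K_bc = 12.2),
                          target_volume = 24)
  )
  for (sim in runs) {
    mb <- attr(sim, "mass_balance")
    expect_lt(abs(mb$relative_error), 0.005)
    expect_equal(mb$influent + mb$initial_storage,
                 mb$effluent + mb$aqueous + mb$sorbed,
                 tolerance = 1e-8)
  }
})

test_that("kinetic mode recovers its two limits", {
  col <- hom_column()
  eq <- simulate_breakthrough(col, solute_transport_params(K_s = 0.25),
                              target_volume = 4, n_cells = 400)
  # large k: local equilibrium; k = 1e3 * v / L
  kbig <- 1e3 * hom_v / hom_L
  kin <- simulate_breakthrough(col,
    solute_transport_params(K_s = 0.25, k = kbig, mode = "kinetic"),
    target_volume = 4, n_cells = 400)
  dev <- abs(curve_at(kin, eq$cum_volume) - eq$c_over_cin)
  expect_lt(max(dev), 0.01)
  # k = 0: conservative tracer
  tracer <- simulate_breakthrough(col, solute_transport_params(),
                                  target_volume = 4, n_cells = 400)
  k0 <- simulate_breakthrough(col,
    solute_transport_params(K_s = 0.25, k = 0, mode = "kinetic"),
    target_volume = 4, n_cells = 400)
  expect_equal(k0$c_over_cin, tracer$c_over_cin, tolerance = 1e-12)
})

test_that("mid-breakthrough arrival scales linearly with retardation", {
  col <- hom_column()
  t50 <- vapply(c(1, 2, 4), function(R) {
    sim <- simulate_breakthrough(col,
      solute_transport_params(K_s = hom_ks_for_R(R)),
      target_volume = 1.5 * R, n_cells = 300)
    eff <- attr(sim, "effluent")
    stats::approx(eff$conc, eff$time, 0.5, ties = "ordered")$y
  }, numeric(1))
  expect_equal(t50[2] / t50[1], 2, tolerance = 0.05)
  expect_equal(t50[3] / t50[1], 4, tolerance = 0.05)
})

test_that("moderate kinetics front and tail relative to equilibrium", {
  col <- hom_column()
  eq <- simulate_breakthrough(col, solute_transport_params(K_s = 0.25),
                              target_volume = 4, n_cells = 300)
  kin <- simulate_breakthrough(col,
    solute_transport_params(K_s = 0.25, k = 1e-3, mode = "kinetic"),
    target_volume = 4, n_cells = 300)
  diff_curve <- kin$c_over_cin - curve_at(eq, kin$cum_volume)
  early <- kin$cum_volume < 1
  late <- kin$cum_volume > 1.5
  expect_gt(max(diff_curve[early]), 0.05)   # fronting: earlier arrival
  expect_lt(min(diff_curve[late]), -0.01)   # tailing: slower approach to 1
})

test_that("halving the grid spacing changes the effluent curve marginally", {
  col <- hom_column()
  par <- solute_transport_params(K_s = hom_ks_for_R(2))
  coarse <- simulate_breakthrough(col, par, target_volume = 4,
                                  n_cells = 400, courant = 0.8)
  fine <- simulate_breakthrough(col, par, target_volume = 4,
                                n_cells = 800, courant = 0.4)
  dev <- abs(curve_at(fine, coarse$cum_volume) - coarse$c_over_cin)
  expect_lt(max(dev), 0.002)
})

test_that("conditioning pre-equilibrates the bed and starts breakthrough high", {
  # weakly sorbing bed conditioned with influent: immediate breakthrough
  col <- hom_column(conditioning_time = 15)
  sim <- simulate_breakthrough(col, solute_transport_params(),
                               target_volume = 2, n_cells = 200)
  expect_gt(sim$c_over_cin[1], 0.9)
  # strong sorption holds the conditioned pore water down at the start
  simR <- simulate_breakthrough(col,
    solute_transport_params(K_s = hom_ks_for_R(10)),
    target_volume = 2, n_cells = 200)
  expect_lt(simR$c_over_cin[1], 0.15)
})

test_that("invalid solver settings and inputs are rejected", {
  col <- hom_column()
  expect_error(simulate_breakthrough(col, solute_transport_params(),
                                     courant = 1.5), "courant")
  expect_error(solute_transport_params(K_s = -1), "non-negative")
  expect_error(column_layer("x", 1, 1.5, 1.2), "porosity")
  expect_error(column_layer("x", 1, 1.5, 0.4, f_sand = 0.7, f_biochar = 0.5),
               "sum")
  expect_error(simulate_breakthrough(col, solute_transport_params(),
                                     c_in = function(t) 1), "c_in_ref")
})

test_that("self-fit on a simulated curve returns the generating parameter", {
  truth <- solute_transport_params(K_s = 1.4, K_bc = 12.2)
  obs <- generate_breakthrough(column_truth(truth, noise_cv = 0, seed = 1))
  fit <- fit_column_params(obs, default_filter_column(), free = "K_bc",
                           params = solute_transport_params(K_s = 1.4))
  expect_equal(unname(fit$estimates["K_bc"]), 12.2, tolerance = 0.02)
  expect_lt(fit$objective, 1e-4)
})

test_that("non-identifiable or empty fits are refused", {
  truth <- solute_transport_params(K_s = 1.4)
  sand_col <- default_filter_column(amended = FALSE)
  obs <- generate_breakthrough(column_truth(truth, column = sand_col,
                                            noise_cv = 0, seed = 1))
  expect_error(fit_column_params(obs, sand_col, free = "K_bc"),
               "identifiable")
  zero <- breakthrough_curve(1:10, rep(0, 10))
  expect_error(fit_column_params(zero, default_filter_column(),
                                 free = "K_bc"), "lower bound")
  expect_error(fit_column_params(obs, sand_col, free = c("K_s", "k"),
                                 mode = "equilibrium"), "kinetic|equilibrium")
  few <- breakthrough_curve(1:3, c(0.1, 0.2, 0.3))
  expect_error(fit_column_params(few, sand_col, free = "K_s"), "5")
})

test_that("a kinetic truth is matched better by the kinetic closure", {
  kin_truth <- solute_transport_params(K_s = 1.4, K_bc = 12.2, k = 1e-4,
                                       mode = "kinetic")
  obs <- generate_breakthrough(column_truth(kin_truth, noise_cv = 0,
                                            seed = 2))
  both <- fit_column_params(obs, default_filter_column(), free = "K_bc",
                            params = solute_transport_params(K_s = 1.4),
                            mode = "both", n_starts = 2, seed = 1)
  expect_lt(both$objective_by_mode[["kinetic"]],
            both$objective_by_mode[["equilibrium"]])
})
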