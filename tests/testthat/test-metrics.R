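# Scalar output metrics against closed forms and synthetic profiles.

test_that("boundary pressures and mid-wall velocity: trivial and toy cases", {
  ps0 <- fixture_ps("vasa.N_v" = 0, "lymph.N_l" = 0)
  sol0 <- solve_radial_flow(ps0)
  expect_equal(midwall_velocity(sol0), 0, tolerance = 1e-25)
  bp0 <- boundary_pressures(sol0)
  expect_equal(unname(bp0), rep(pa_to_mmhg(ps0$p_lu), 2), tolerance = 1e-9)
  # constant-sink toy against the piecewise quadrature oracle
  ps <- fixture_ps("vasa.N_v" = 0)
  sol <- solve_radial_flow(ps, solver_options(n_grid = 600, max_refine = 2))
  rr <- wall_radii(ps)
  ora <- constant_sink_oracle(c(rr[["r_ia"]], rr[["r_ap"]]), ps)
  bp <- boundary_pressures(sol)
  expect_equal(unname(bp), pa_to_mmhg(ora$p), tolerance = 1e-6)
  # decreasing adventitial permeability raises the EEL pressure
  lo_ka <- solve_radial_flow(set_params(ps, "tissue.k_a" = ps$tissue$k_a / 10))
  expect_gt(boundary_pressures(lo_ka)[["p_ia"]], bp[["p_ia"]])
})

test_that("dilution distance interpolates the tracer threshold", {
  r_ia <- 1.9e-3
  r <- seq(r_ia, 3.1e-3, length.out = 5000)
  gamma <- 3000
  u <- rep(2e-8, length(r))
  flow <- synthetic_flow(r, q = u * r, J_v = gamma * u)
  flow$f <- luminal_fraction(flow)
  d <- dilution_distance(flow, threshold = 0.1)
  expect_equal(d, r_ia + log(10) / gamma, tolerance = 1e-7)
  # a degenerate threshold of 1 trips immediately at the source node
  expect_equal(dilution_distance(flow, threshold = 1), r[1], tolerance = 1e-6)
  # no vasa -> never diluted
  flow0 <- synthetic_flow(r, q = u * r, J_v = rep(0, length(r)))
  flow0$f <- luminal_fraction(flow0)
  expect_identical(dilution_distance(flow0), Inf)
})

test_that("EEL concentration interpolates lumen-source profiles only", {
  ps <- fixture_ps("vasa.N_v" = 0, "lymph.N_l" = 0)
  flow <- solve_radial_flow(ps)
  sol <- solve_solute(ps, flow, solute_params(D = 1e-11, kappa_v = 0, source = "lumen"))
  expect_equal(eel_concentration(sol), 1, tolerance = 1e-10)
  sole <- solve_solute(ps, flow, solute_params(D = 1e-11, kappa_v = 0, source = "eel"))
  expect_error(eel_concentration(sole), "lumen-source")
})

test_that("maximum adventitial gradient uses the collocation derivative", {
  radii <- c(r_lu = 1.5e-3, r_ia = 1.9e-3, r_ap = 2.3e-3, r_ext = 3.1e-3)
  r <- seq(1.9e-3, 3.9e-3, length.out = 800)
  L <- 4e-4
  c_prof <- exp(-(r - 1.9e-3) / L)
  dcdr <- -c_prof / L
  sol <- synthetic_solute(r, c_prof, dcdr, radii, t_p = 8e-4)
  mg <- max_adventitial_gradient(sol)
  # monotone decay: maximum gradient at the EEL, magnitude 1/L (per mm)
  expect_equal(mg$value, 1 / L / 1e3, tolerance = 1e-9)
  expect_equal(mg$r_at, 1.9e-3)
  # uniform profile has zero gradient
  sol1 <- synthetic_solute(r, rep(1, length(r)), rep(0, length(r)), radii, 8e-4)
  expect_equal(max_adventitial_gradient(sol1)$value, 0)
  expect_error(max_adventitial_gradient(synthetic_solute(r, c_prof, dcdr, radii, 8e-4,
                                                         source = "lumen")),
               "EEL-source")
})

test_that("DC transport distance finds the last threshold crossing", {
  radii <- c(r_lu = 1.5e-3, r_ia = 1.9e-3, r_ap = 2.3e-3, r_ext = 3.1e-3)
  r <- seq(1.9e-3, 3.9e-3, length.out = 4000)
  # |dc/dr| = 0.8 exp(-(r - r_ap)/0.5 mm) per mm beyond the border
  g_mm <- 0.8 * exp(-pmax(r - 2.3e-3, 0) / 5e-4)
  sol <- synthetic_solute(r, rep(NA_real_, length(r)), -g_mm * 1e3, radii, t_p = 8e-4)
  dc <- dc_transport_distance(sol, threshold = 0.4)
  expect_equal(dc$distance, 5e-4 * log(2), tolerance = 1e-6)
  expect_equal(dc$t_star, dc$distance / 8e-4)
  # already below threshold at the border -> zero
  sol0 <- synthetic_solute(r, rep(NA_real_, length(r)), -0.2e3 * exp(-(r - 1.9e-3) / 5e-4),
                           radii, t_p = 8e-4)
  expect_equal(dc_transport_distance(sol0, threshold = 0.4)$distance, 0)
})

test_that("profile classification separates convex, accumulative and plain decay", {
  radii <- c(r_lu = 1.5e-3, r_ia = 1.9e-3, r_ap = 2.3e-3, r_ext = 3.1e-3)
  r <- seq(1.9e-3, 3.9e-3, length.out = 1000)
  # plain exponential decay: gradient maximal at the EEL -> neither
  L <- 3e-4
  c1 <- exp(-(r - 1.9e-3) / L)
  s1 <- synthetic_solute(r, c1, -c1 / L, radii, 8e-4)
  expect_identical(classify_profile(s1), "neither")
  # interior bump above the source value -> accumulative
  c2 <- 1 + 0.05 * exp(-((r - 2.1e-3) / 1e-4)^2)
  d2 <- -0.05 * 2 * (r - 2.1e-3) / 1e-8 * exp(-((r - 2.1e-3) / 1e-4)^2)
  expect_identical(classify_profile(synthetic_solute(r, c2, d2, radii, 8e-4)), "accumulative")
  # sigmoidal decrease with the inflection inside the adventitia -> convex
  c3 <- 1 / (1 + exp((r - 2.1e-3) / 5e-5))
  d3 <- -exp((r - 2.1e-3) / 5e-5) / (5e-5 * (1 + exp((r - 2.1e-3) / 5e-5))^2)
  c3 <- c3 / c3[1]; d3 <- d3 / c3[1]
  expect_identical(classify_profile(synthetic_solute(r, c3, d3, radii, 8e-4)), "convex")
})

test_that("whole-tissue balance audit evaluates both sides of the conservation law", {
  # trivial case: both sides vanish
  ps0 <- fixture_ps("vasa.N_v" = 0, "lymph.N_l" = 0)
  expect_equal(global_balance_audit(solve_radial_flow(ps0)), 0)
  # constant-sink toy: lymph outflow equals lumen inflow analytically
  ps <- fixture_ps("vasa.N_v" = 0)
  expect_lt(global_balance_audit(solve_radial_flow(ps)), 1e-6)
  # sampled full-model solutions
  sets <- sample_parameter_sets(default_distributions()$registry, 10, seed = 8)
  for (ps in sets) {
    expect_lt(global_balance_audit(solve_radial_flow(ps, fast_opts)), 1e-6)
  }
})

test_that("metrics records carry the reporting units and sentinels", {
  ps <- default_parameter_set()
  flow <- solve_radial_flow(ps, fast_opts)
  sl <- solve_solute(ps, flow, solute_params(D = 1e-11, R_d = 0.5, source = "lumen"), fast_opts)
  se <- solve_solute(ps, flow, solute_params(D = 1e-11, R_d = 0.5, source = "eel"), fast_opts)
  rec <- metrics_record(flow, sl, se)
  expect_equal(rec$u_mid_um_s, 1e6 * midwall_velocity(flow))
  expect_equal(rec$p_ap_mmHg, unname(boundary_pressures(flow)[["p_ap"]]))
  expect_true(rec$vasa_fraction >= 0 && rec$vasa_fraction <= 1)
  expect_equal(rec$c_ia, eel_concentration(sl))
  expect_true(rec$profile_class %in% c("convex", "accumulative", "neither"))
  # never-diluted sentinel
  ps0 <- fixture_ps("vasa.N_v" = 0)
  rec0 <- metrics_record(solve_radial_flow(ps0, fast_opts))
  expect_true(rec0$dilution_never)
  expect_false(is.finite(rec0$dilution_r_mm))
})
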