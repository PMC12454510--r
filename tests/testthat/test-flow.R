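# Radial Darcy flow: flux laws, solver against closed forms, conservation,
# monotone parameter dependences and the luminal-fraction tracer.

test_that("Starling flux clamps, scales linearly and matches direct arithmetic", {
  v <- list(l_pv = 1e-10, N_v = 1e8, d_v = 1e-5, p_v = 10 * MMHG,
            pi_v = 25 * MMHG, pi_t = 25 * MMHG, sigma = 1, kappa_v = 0)
  # dP = p_v - p here (osmotic terms cancel); at p = 0, dP = 10 mmHg
  A_v <- vasa_area_density(v)
  expect_equal(A_v, 3141.593, tolerance = 1e-6)
  expect_equal(starling_flux(0, v), 1e-10 * A_v * 10 * MMHG)   # ~4.19e-4 1/s
  expect_equal(starling_flux(0, v), 4.1888e-4, tolerance = 1e-4)
  # clamped to zero for large tissue pressure
  expect_equal(starling_flux(100 * MMHG, v), 0)
  # linear in the driving pressure
  expect_equal(starling_flux(-10 * MMHG, v), 2 * starling_flux(0, v))
  # smoothing converges to the hard clamp as eps -> 0
  expect_equal(starling_flux(5 * MMHG, v, eps = 1e-6),
               starling_flux(5 * MMHG, v), tolerance = 1e-6)
})

test_that("lymph flux is a pressure-independent sink", {
  l <- list(N_l = 3e6, q_tilde_l = 1e-11, l_bar_l = 1)
  expect_equal(lymph_flux(l), -3e-5)
  l$N_l <- 0
  expect_equal(lymph_flux(l), 0)
  l2 <- list(N_l = 2e6, q_tilde_l = 1.5e-11, l_bar_l = 1)
  expect_equal(lymph_flux(l2), -l2$N_l * l2$q_tilde_l)
})

test_that("source-free problem returns the trivial no-flow solution", {
  ps <- fixture_ps("vasa.N_v" = 0, "lymph.N_l" = 0)
  sol <- solve_radial_flow(ps)
  expect_lt(max(abs(sol$u)), 1e-20)
  expect_equal(sol$p, rep(ps$p_lu, length(sol$p)), tolerance = 1e-12)
  expect_equal(unname(flow_rates(sol)), c(0, 0, 0))
  expect_true(all(sol$f == 1))
})

test_that("constant-sink flow matches the symbolic-integration oracle", {
  ps <- fixture_ps("vasa.N_v" = 0)   # lymph only
  sol <- solve_radial_flow(ps, solver_options(n_grid = 600, max_refine = 2))
  ora <- constant_sink_oracle(sol$r, ps)
  expect_lt(max(abs(sol$q - ora$q)) / max(abs(ora$q)), 1e-6)
  p_scale <- diff(range(ora$p))
  expect_lt(max(abs(sol$p - ora$p)) / p_scale, 1e-6)
  fr <- flow_rates(sol)
  expect_equal(unname(fr[["Q_lu"]]), ora$Q_lu, tolerance = 1e-9)
  expect_equal(unname(fr[["Q_l"]]), ora$Q_l, tolerance = 1e-9)
  expect_equal(unname(fr[["Q_v"]]), 0)
  # mid-layer velocity against the closed form
  rm <- ps$geometry$r_lu + ps$geometry$t_i / 2
  expect_equal(midwall_velocity(sol), constant_sink_oracle(rm, ps)$u, tolerance = 1e-6)
})

test_that("single-region constant-coefficient solve matches the modified-Bessel closed form", {
  ps <- default_parameter_set()
  r0 <- 1.5e-3; r1 <- 3e-3
  core <- periwall:::.solve_flow_core(
    breaks = c(r0, r1), k_layer = 1e-16, src_layer = TRUE,
    s_l = 3e-5, vasa = ps$vasa, mu = 1e-3, p_inner = mmhg_to_pa(5),
    opts = solver_options(n_grid = 800, max_refine = 2, starling_eps = 0)
  )
  ora <- bessel_flow_oracle(core$r, r0, r1, 1e-16, 1e-3, 3e-5, ps$vasa, mmhg_to_pa(5))
  # p_inner = 5 mmHg < P_inf keeps the Starling term unclamped everywhere
  expect_true(all(core$p < periwall:::.starling_p_inf(ps$vasa)))
  expect_lt(max(abs(core$p - ora$p)) / max(abs(ora$p)), 1e-6)
  expect_lt(max(abs(core$q - ora$q)) / max(abs(ora$q)), 1e-6)
})

test_that("global mass conservation holds on sampled parameter sets", {
  sets <- sample_parameter_sets(default_distributions()$registry, 20, seed = 3)
  for (ps in sets) {
    sol <- solve_radial_flow(ps, fast_opts)
    fr <- flow_rates(sol)
    expect_lt(abs(sum(fr)) / max(abs(fr)), 1e-6)
    expect_lt(sol$residual, 1e-3)
    # outer no-flow boundary
    expect_lt(abs(sol$u[length(sol$u)]), 1e-12 * max(abs(sol$u)))
    expect_equal(sol$p[1], ps$p_lu)
  }
})

test_that("pressure responds monotonically to drainage and vasa conductivity", {
  ps <- default_parameter_set()
  base <- solve_radial_flow(ps, fast_opts)
  # more drainage -> lower pressure everywhere
  hi_drain <- solve_radial_flow(set_params(ps, "lymph.q_tilde_l" = 2 * ps$lymph$q_tilde_l),
                                fast_opts)
  expect_true(all(stats::approx(hi_drain$r, hi_drain$p, base$r)$y <= base$p + 1e-9))
  # more vasa conductivity -> outer pressure pulled toward the Starling
  # equilibrium pressure
  p_inf <- periwall:::.starling_p_inf(ps$vasa)
  hi_vasa <- solve_radial_flow(set_params(ps, "vasa.l_pv" = 5 * ps$vasa$l_pv), fast_opts)
  p_ap0 <- boundary_pressures(base)[["p_ap"]]
  p_ap1 <- boundary_pressures(hi_vasa)[["p_ap"]]
  expect_lt(abs(p_ap1 - pa_to_mmhg(p_inf)), abs(p_ap0 - pa_to_mmhg(p_inf)))
})

test_that("grid refinement is converged at the default tolerance", {
  ps <- default_parameter_set()
  coarse <- solve_radial_flow(ps, solver_options(n_grid = 200, max_refine = 0))
  fine <- solve_radial_flow(ps, solver_options(n_grid = 1600, max_refine = 0))
  p_ap_c <- boundary_pressures(coarse)[["p_ap"]]
  p_ap_f <- boundary_pressures(fine)[["p_ap"]]
  # well under 0.1% of the transmural pressure scale
  expect_lt(abs(p_ap_c - p_ap_f) / pa_to_mmhg(ps$p_lu), 1e-3)
})

test_that("pressure drop localises in the inner layers when k_i << k_a", {
  ps <- fixture_ps("tissue.k_i" = 1e-19)
  sol <- solve_radial_flow(ps)
  rr <- wall_radii(ps)
  p_ia <- stats::approx(sol$r, sol$p, rr[["r_ia"]])$y
  frac_inner <- (ps$p_lu - p_ia) / (ps$p_lu - sol$p[length(sol$p)])
  expect_gt(frac_inner, 0.95)
})

test_that("luminal fraction follows the tracer ODE closed form", {
  # constant J_v/u = gamma over the source region -> f = exp(-gamma (r - r_ia))
  r_ia <- 1.9e-3
  r <- seq(r_ia, 3.1e-3, length.out = 400)
  gamma <- 1200  # 1/m
  u <- rep(2e-8, length(r))
  sol <- synthetic_flow(r, q = u * r, J_v = gamma * u)
  f <- luminal_fraction(sol)
  expect_equal(as.numeric(f), exp(-gamma * (r - r_ia)), tolerance = 1e-5)
  # no vasa inflow -> no dilution
  sol0 <- synthetic_flow(r, q = u * r, J_v = rep(0, length(r)))
  expect_true(all(luminal_fraction(sol0) == 1))
})

test_that("tracer bookkeeping: vasa share of lymph equals 1 - flux-weighted mean f", {
  for (ps in list(default_parameter_set(),
                  fixture_ps("vasa.l_pv" = 5e-12, "lymph.q_tilde_l" = 2.5e-11))) {
    sol <- solve_radial_flow(ps, solver_options(n_grid = 800, max_refine = 1))
    w <- abs(sol$J_l) * sol$r
    f_bar <- sum(diff(sol$r) * (w[-1] * sol$f[-1] + w[-length(w)] * sol$f[-length(w)]) / 2) /
      sum(diff(sol$r) * (w[-1] + w[-length(w)]) / 2)
    lhs <- sol$Q_v / (sol$Q_v + sol$Q_lu)
    expect_equal(lhs, 1 - f_bar, tolerance = 0.01)
    expect_true(all(diff(sol$f) <= 1e-12))
    expect_equal(sol$f[1], 1)
  }
})

test_that("Starling smoothing epsilon does not alter the solution materially", {
  ps <- default_parameter_set()
  a <- solve_radial_flow(ps, solver_options(starling_eps = 1e-3 * MMHG))
  b <- solve_radial_flow(ps, solver_options(starling_eps = 1e-7 * MMHG))
  expect_lt(max(abs(a$p - b$p)) / MMHG, 1e-3)   # under 0.001 mmHg
})
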