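# Solute transport: trivial limits, special-function oracle, dimensional vs
# non-dimensional equivalence, comparison principle and conservation.

test_that("without flow and sinks the concentration is uniform", {
  ps <- fixture_ps("vasa.N_v" = 0, "lymph.N_l" = 0)
  flow <- solve_radial_flow(ps)
  sol <- solve_solute(ps, flow, solute_params(D = 1e-11, kappa_v = 0, source = "lumen"))
  expect_equal(sol$c, rep(1, length(sol$c)), tolerance = 1e-9)
  expect_lt(max(abs(sol$dcdr)) * 1e-3, 1e-6)   # per mm, far below any threshold
  sole <- solve_solute(ps, flow, solute_params(D = 1e-11, kappa_v = 0, source = "eel"))
  expect_equal(sole$c, rep(1, length(sole$c)), tolerance = 1e-9)
})

test_that("pure diffusion with a uniform sink matches the modified-Bessel closed form", {
  r0 <- 1.9e-3; r1 <- 3.1e-3
  D <- 1e-11; lam_s <- 4e-5
  r <- seq(r0, r1, length.out = 3000)
  num <- periwall:::.solve_linear_advdiff(
    r, D, u = rep(0, length(r)), uprime = rep(0, length(r)),
    sink = rep(lam_s, length(r))
  )
  ora <- bessel_solute_oracle(r, r0, r1, D, lam_s)
  expect_lt(max(abs(num$c - ora)) / max(ora), 1e-6)
})

test_that("dimensional and non-dimensional solvers agree after rescaling", {
  set.seed(5)
  sets <- sample_parameter_sets(default_distributions()$registry, 5, seed = 5)
  for (ps in sets) {
    flow <- solve_radial_flow(ps, fast_opts)
    for (src in c("lumen", "eel")) {
      sp <- solute_params(D = 1e-11, R_d = exp(stats::runif(1, log(0.01), log(10))),
                         source = src)
      sol <- solve_solute(ps, flow, sp, solver_options(n_grid = 300, max_refine = 0))
      nd <- nondim_counterpart(ps, flow, sp, sol)
      expect_lt(max(abs(nd$c - sol$c)) / max(sol$c), 1e-8)
    }
  }
})

test_that("the trivial non-dimensional problem returns uniform concentration", {
  nums <- structure(list(Pe = 0, Da_v = 0, Da_l = 0, R_d = 0),
                    class = "dimensionless_numbers")
  r <- seq(1, 3, length.out = 200)
  sol <- solve_solute_nondim(nums, r, u_star = rep(0, 200), uprime_star = rep(0, 200))
  expect_equal(sol$c, rep(1, 200), tolerance = 1e-12)
})

test_that("stronger lymphatic uptake depresses the profile pointwise", {
  set.seed(21)
  r <- seq(1, 3, length.out = 300)
  for (i in 1:20) {
    nums <- structure(list(Pe = stats::runif(1, 0, 8), Da_v = stats::runif(1, 0, 5),
                           Da_l = stats::runif(1, 0, 10), R_d = stats::runif(1, 0, 3)),
                      class = "dimensionless_numbers")
    u <- stats::runif(1, 0, 1) * (r[1] / r)   # decaying, positive
    up <- -u / r
    c1 <- solve_solute_nondim(nums, r, u, up)$c
    nums2 <- nums; nums2$Da_l <- nums$Da_l + stats::runif(1, 0.5, 3)
    c2 <- solve_solute_nondim(nums2, r, u, up)$c
    expect_true(all(c2 <= c1 + 1e-9))
  }
})

test_that("dimensionless numbers scale as 1/D and match direct arithmetic", {
  ps <- fixture_ps(
    "tissue.k_i" = 1e-18, "tissue.mu" = 1e-3, "boundary.p_lu" = 100 * MMHG,
    "geometry.t_i" = 4e-4, "geometry.t_a" = 4e-4, "geometry.t_p" = 4e-4
  )
  sp <- solute_params(D = 1e-10, R_d = 1, source = "lumen")
  nums <- dimensionless_numbers(ps, sp)
  # Pe = (k_i/mu)(p_lu/t_i)(t_a+t_p)/D by direct arithmetic
  pe_hand <- (1e-18 / 1e-3) * (100 * MMHG / 4e-4) * 8e-4 / 1e-10
  expect_equal(nums$Pe, pe_hand, tolerance = 1e-12)
  expect_equal(pe_hand, 0.2667, tolerance = 1e-3)
  # dividing D by 100 multiplies all four numbers by 100
  nums2 <- dimensionless_numbers(ps, solute_params(D = 1e-12, kappa_v = 3e-9, source = "lumen"))
  nums1 <- dimensionless_numbers(ps, solute_params(D = 1e-10, kappa_v = 3e-9, source = "lumen"))
  for (nm in c("Pe", "Da_v", "Da_l", "R_d")) {
    expect_equal(nums2[[nm]], 100 * nums1[[nm]], tolerance = 1e-12)
  }
  # baseline configuration at D = 100 um^2/s has Pe of order 1
  pe_base <- dimensionless_numbers(default_parameter_set(),
                                   solute_params(D = 1e-10, R_d = 1, source = "lumen"))$Pe
  expect_gt(pe_base, 0.1)
  expect_lt(pe_base, 10)
})

test_that("solute mass balances: source influx equals uptake plus advective export", {
  ps <- default_parameter_set()
  flow <- solve_radial_flow(ps, solver_options(n_grid = 800, max_refine = 1))
  sol <- solve_solute(ps, flow, solute_params(D = 1e-11, R_d = 0.5, source = "eel"),
                      solver_options(n_grid = 4000, max_refine = 0))
  r <- sol$r
  trap <- function(y) sum(diff(r) * (y[-1] + y[-length(y)]) / 2)
  # integral form of the transport equation between the source and the
  # outer zero-flux boundary (advection enters as d(uc)/dr):
  #   r0 (u0 c0 - D c'(r0)) + int u c dr - int r sink c dr = 0
  influx <- r[1] * (sol$u[1] * sol$c[1] - sol$D * sol$dcdr[1])
  uptake <- trap(r * sol$sink * sol$c) - trap(sol$u * sol$c)
  expect_equal(influx, uptake, tolerance = 1e-5)
})

test_that("interior accumulation emerges as Pe crosses the unit-to-ten range", {
  ps0 <- default_parameter_set()
  L <- ps0$geometry$t_a + ps0$geometry$t_p
  D <- 1e-11   # 10 um^2/s
  max_c <- vapply(c(1, 10), function(Pe) {
    k_i <- Pe * D / L * ps0$tissue$mu * ps0$geometry$t_i / ps0$p_lu
    ps <- set_params(ps0, "tissue.k_i" = k_i)
    flow <- solve_radial_flow(ps, fast_opts)
    max(solve_solute(ps, flow, solute_params(D = D, R_d = 0.3, source = "lumen"),
                     fast_opts)$c)
  }, numeric(1))
  expect_lte(max_c[1], 1 + 1e-3)   # diffusion-balanced: no interior maximum
  expect_gt(max_c[2], 1 + 1e-2)    # convection-dominated: accumulation near the EEL
})

test_that("extension-region sink options change only the outer tail", {
  ps <- default_parameter_set()
  flow <- solve_radial_flow(ps, fast_opts)
  sp <- solute_params(D = 1e-11, R_d = 0.5, source = "eel")
  a <- solve_solute(ps, flow, sp, fast_opts, extension_sinks = "frozen")
  b <- solve_solute(ps, flow, sp, fast_opts, extension_sinks = "off")
  r_ext <- wall_radii(ps)[["r_ext"]]
  in_wall_a <- a$r <= r_ext
  # without extension sinks the tail concentration cannot be lower
  bb <- stats::approx(b$r, b$c, a$r)$y
  expect_true(all(bb >= a$c - 1e-9))
  # the deviation inside the wall stays modest compared to the tail change
  expect_gt(max(abs(bb - a$c)[!in_wall_a]), max(abs(bb - a$c)[a$r < r_ext - 5e-4]))
})
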