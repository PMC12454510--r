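# Closed-form oracles and fixture builders shared across the test files.
# All fixtures are built in code; no stored data.

MMHG <- 133.322

# Baseline healthy set with selected overrides ("path" = value, SI units).
fixture_ps <- function(...) {
  ps <- default_parameter_set()
  if (...length() > 0) ps <- set_params(ps, ...)
  ps
}

# Closed-form solution of the source-free constant-lymph-sink flow problem
# (vasa off, sink s_l on [r_ia, r_ext], stepwise permeability, p(r_lu) = p0,
# no flow at r_ext), obtained by symbolic integration:
#   q = r u; q' = -s_l r on the sink region, q' = 0 inside
#   => q(r) = s_l (r_ext^2 - r^2)/2 on [r_ia, r_ext],
#      q = s_l (r_ext^2 - r_ia^2)/2 on [r_lu, r_ia]
#   p from dp/dr = -mu q / (k r), integrated analytically per layer.
constant_sink_oracle <- function(r, ps) {
  rr <- wall_radii(ps)
  r_lu <- rr[["r_lu"]]; r_ia <- rr[["r_ia"]]; r_ap <- rr[["r_ap"]]; r_ext <- rr[["r_ext"]]
  s_l <- lymph_sink_rate(ps$lymph)
  mu <- ps$tissue$mu
  q_in <- s_l * (r_ext^2 - r_ia^2) / 2
  q <- ifelse(r < r_ia, q_in, s_l * (r_ext^2 - r^2) / 2)
  # antiderivative of q(r)/r on the sink region
  Fsink <- function(r) s_l / 2 * (r_ext^2 * log(r) - r^2 / 2)
  p <- numeric(length(r))
  k <- function(rx) ifelse(rx < r_ia, ps$tissue$k_i, ifelse(rx < r_ap, ps$tissue$k_a, ps$tissue$k_p))
  # pressure drops accumulated from the lumen
  drop_inner <- function(rx) mu * q_in * log(rx / r_lu) / ps$tissue$k_i
  drop_sink <- function(k_alpha, a, b) mu * (Fsink(b) - Fsink(a)) / k_alpha
  for (i in seq_along(r)) {
    rx <- r[i]
    if (rx <= r_ia) {
      p[i] <- ps$p_lu - drop_inner(rx)
    } else if (rx <= r_ap) {
      p[i] <- ps$p_lu - drop_inner(r_ia) - drop_sink(ps$tissue$k_a, r_ia, rx)
    } else {
      p[i] <- ps$p_lu - drop_inner(r_ia) - drop_sink(ps$tissue$k_a, r_ia, r_ap) -
        drop_sink(ps$tissue$k_p, r_ap, rx)
    }
  }
  list(p = p, q = q, u = q / r,
       Q_lu = 2 * pi * q_in, Q_l = -s_l * pi * (r_ext^2 - r_ia^2), Q_v = 0)
}

# Modified-Bessel closed form for the full single-region model with constant
# coefficients and an unclamped Starling source:
#   (k/mu)(1/r)(r p')' = beta (p - P_inf) + s_l, p(r0) = p0, p'(r1) = 0
#   => phi = p - (P_inf - s_l/beta) = A I0(lam r) + B K0(lam r),
#      lam = sqrt(mu beta / k).
bessel_flow_oracle <- function(r, r0, r1, k, mu, s_l, vasa, p0) {
  beta <- vasa$l_pv * vasa_area_density(vasa)
  P_inf <- vasa$p_v - vasa$sigma * (vasa$pi_t - vasa$pi_v)
  lam <- sqrt(mu * beta / k)
  shift <- P_inf - s_l / beta
  # p'(r1) = 0: A I1(lam r1) - B K1(lam r1) = 0 => A = B K1/I1
  ratio <- besselK(lam * r1, 1) / besselI(lam * r1, 1)
  # p(r0) = p0: A I0(lam r0) + B K0(lam r0) = p0 - shift, with A = ratio * B
  B <- (p0 - shift) / (ratio * besselI(lam * r0, 0) + besselK(lam * r0, 0))
  A <- ratio * B
  p <- shift + A * besselI(lam * r, 0) + B * besselK(lam * r, 0)
  dp <- lam * (A * besselI(lam * r, 1) - B * besselK(lam * r, 1))
  list(p = p, u = -(k / mu) * dp, q = -(k / mu) * dp * r)
}

# Modified-Bessel closed form for pure-diffusion transport with a uniform
# first-order sink on an annulus: D (c'' + c'/r) = lam_s c, c(r0) = 1,
# c'(r1) = 0; c = A I0(m r) + B K0(m r), m = sqrt(lam_s / D).
bessel_solute_oracle <- function(r, r0, r1, D, lam_s) {
  m <- sqrt(lam_s / D)
  ratio <- besselK(m * r1, 1) / besselI(m * r1, 1)
  B <- 1 / (ratio * besselI(m * r0, 0) + besselK(m * r0, 0))
  A <- ratio * B
  A * besselI(m * r, 0) + B * besselK(m * r, 0)
}

# Non-dimensional counterpart of a dimensional solute solve, built from the
# same flow solution with the scales of the transport model; used to check
# the dimensional/non-dimensional equivalence.
nondim_counterpart <- function(ps, flow, sp, sol) {
  rr <- wall_radii(ps)
  L <- ps$geometry$t_a + ps$geometry$t_p
  U <- (ps$tissue$k_i / ps$tissue$mu) * (ps$p_lu / ps$geometry$t_i)
  r <- sol$r
  in_wall <- r <= rr[["r_ext"]] * (1 + 1e-12)
  in_sink <- r >= rr[["r_ia"]] * (1 - 1e-12)
  eps <- flow$opts$starling_eps
  p <- stats::approx(flow$r, flow$p, pmin(r, rr[["r_ext"]]), rule = 2)$y
  dP0 <- ps$vasa$p_v - ps$vasa$sigma * (ps$vasa$pi_t - ps$vasa$pi_v)
  ramp <- function(x) (x + sqrt(x * x + eps * eps)) / 2
  dPr <- ramp(dP0 - p) / dP0
  dPr[!in_wall] <- ramp(dP0 - flow$p[length(flow$p)]) / dP0
  mask_sink <- as.numeric(in_sink)
  nums <- dimensionless_numbers(ps, sp)
  solve_solute_nondim(nums, r / L, sol$u / U, sol$uprime * L / U,
                      dP_ratio = dPr * mask_sink,
                      mask_rd = mask_sink, mask_l = mask_sink)
}

# Minimal hand-built flow/solute solution objects for metric unit tests.
synthetic_flow <- function(r, q, J_v, J_l = rep(0, length(r)), ps = NULL) {
  structure(list(r = r, q = q, u = q / r, J_v = J_v, J_l = J_l,
                 params = ps, opts = list(starling_eps = 0)),
            class = "flow_solution")
}

synthetic_solute <- function(r, c, dcdr, radii, t_p, source = "eel") {
  structure(list(r = r, c = c, dcdr = dcdr, radii = radii, t_p = t_p,
                 source = source), class = "solute_solution")
}

# Fast solver options for ensemble-heavy tests.
fast_opts <- solver_options(n_grid = 160L, max_refine = 1L)
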