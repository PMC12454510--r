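# Radial Darcy flow across the layered wall.
#
# Mass conservation in the cylindrical annulus, (1/r) d(r u)/dr = J_v + J_l,
# with Darcy's law u = -(k/mu) dp/dr, stepwise permeability per layer,
# a distributed Starling source J_v from vasa vasorum and a constant
# lymphatic sink J_l in the adventitia and PVAT. Boundary conditions:
# p = p_lu at the lumen-side boundary and no flow (dp/dr = 0) at the outer
# PVAT. Solved as a first-order system in (p, q = r u): q is the conserved
# flux per radian, so continuity of p and q across layer interfaces is
# automatic when interface radii are grid nodes. Discretisation is a
# midpoint (box) collocation scheme, second order, with damped Newton on the
# smoothed Starling clamp.

#' Solver options for the flow and solute boundary-value problems
#'
#' @param n_grid target number of grid nodes before refinement (distributed
#'   across layers proportionally to thickness, interfaces always nodes).
#' @param rel_tol relative tolerance for grid refinement: the grid is doubled
#'   until the pressure profile changes by less than `rel_tol` (relative to
#'   the pressure range), at most `max_refine` times.
#' @param starling_eps half-width (Pa) over which the Starling clamp
#'   `max(dP, 0)` is smoothed to keep the Newton Jacobian continuous;
#'   default 1e-3 mmHg, far below any physiologic pressure scale.
#' @param max_iter maximum Newton iterations per grid.
#' @param max_refine maximum number of grid doublings.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(n_grid = 400L, rel_tol = 1e-6,
                           starling_eps = 1e-3 * .MMHG,
                           max_iter = 40L, max_refine = 3L) {
  stopifnot(n_grid >= 24, rel_tol > 0, starling_eps >= 0, max_iter >= 1)
  structure(list(n_grid = as.integer(n_grid), rel_tol = rel_tol,
                 starling_eps = starling_eps, max_iter = as.integer(max_iter),
                 max_refine = as.integer(max_refine)),
            class = "solver_options")
}

# Smoothed positive part: (x + sqrt(x^2 + eps^2))/2; exact max(x, 0) at eps = 0.
.ramp <- function(x, eps = 0) {
  if (eps <= 0) pmax(x, 0) else (x + sqrt(x * x + eps * eps)) / 2
}
.ramp_d <- function(x, eps = 0) {
  if (eps <= 0) as.numeric(x > 0) else (1 + x / sqrt(x * x + eps * eps)) / 2
}

#' Starling filtration flux density from vasa vasorum
#'
#' Volumetric source strength (1/s) of plasma filtration across the vasa
#' vasorum endothelium under the revised Starling principle: proportional to
#' the positive part of the driving pressure
#' `dP = p_v - p - sigma * (pi_t - pi_v)`, clamped to zero when `dP <= 0`
#' (optionally smoothed over `eps` Pa for use inside Newton iterations).
#'
#' @param p local interstitial hydrostatic pressure (Pa); vectorised.
#' @param vasa the `vasa` component of a `wall_params`.
#' @param eps clamp smoothing half-width in Pa (0 = hard clamp).
#' @return source density `l_pv * A_bar_v * max(dP, 0)` in 1/s.
#' @export
starling_flux <- function(p, vasa, eps = 0) {
  dP <- vasa$p_v - p - vasa$sigma * (vasa$pi_t - vasa$pi_v)
  vasa$l_pv * vasa_area_density(vasa) * .ramp(dP, eps)
}

# Starling equilibrium pressure: dP(p) = 0 at p = p_v - sigma (pi_t - pi_v).
.starling_p_inf <- function(vasa) vasa$p_v - vasa$sigma * (vasa$pi_t - vasa$pi_v)

#' Lymphatic drainage flux density
#'
#' Constant volumetric sink strength `-N_l * q_tilde_l * l_bar_l` (1/s),
#' independent of local pressure.
#'
#' @param lymph the `lymph` component of a `wall_params`.
#' @return sink density (<= 0) in 1/s.
#' @export
lymph_flux <- function(lymph) -lymph_sink_rate(lymph)

# Grid over layered annulus: nodes forced at the break radii, points per
# layer proportional to thickness (minimum 8). Returns node radii and the
# layer index of every interval.
.layer_grid <- function(breaks, n) {
  widths <- diff(breaks)
  counts <- pmax(8L, round(n * widths / sum(widths)))
  r <- unlist(lapply(seq_along(widths), function(i) {
    seq(breaks[i], breaks[i + 1], length.out = counts[i] + 1L)[-(counts[i] + 1L)]
  }))
  r <- c(r, breaks[length(breaks)])
  reg <- rep(seq_along(widths), counts)
  list(r = r, reg = reg)
}

# Core nonlinear BVP solve on a fixed grid. src is a logical per layer
# (Starling + lymph active); returns p, q at nodes.
.flow_solve_grid <- function(r, reg, k_layer, src_layer, s_l, vasa, mu,
                             p_inner, eps, max_iter, p0 = NULL, q0 = NULL) {
  N <- length(r)
  h <- diff(r)
  rm <- (r[-1] + r[-N]) / 2
  k_iv <- k_layer[reg]
  src_iv <- src_layer[reg]
  sink_iv <- ifelse(src_iv, s_l, 0)
  beta <- vasa$l_pv * vasa_area_density(vasa)
  p_inf <- .starling_p_inf(vasa)

  # Scale the unknowns (p in units of P0, q in units of Q0) so the Newton
  # system is well conditioned: raw pressures ~1e4 Pa against fluxes
  # ~1e-10 m^2/s would make the Jacobian numerically singular.
  P0 <- max(abs(p_inner), abs(p_inf), .MMHG)
  S0 <- max(s_l, beta * P0)
  R_ext <- r[N]
  Q0 <- if (S0 > 0) S0 * R_ext^2 else P0 * max(k_layer) / (mu * R_ext)
  a_iv <- h * mu / (2 * k_iv * rm) * (Q0 / P0)  # dF1/dq, scaled

  # fixed sparsity pattern (rows: 1 = inner BC, 2..N = F1, N+1..2N-1 = F2,
  # 2N = outer BC; cols: p_j = j, q_j = N + j)
  i1 <- seq_len(N - 1)
  rows <- c(1,
            1 + i1, 1 + i1, 1 + i1, 1 + i1,
            N + i1, N + i1, N + i1, N + i1,
            2 * N)
  cols <- c(1,
            i1, i1 + 1, N + i1, N + i1 + 1,
            N + i1, N + i1 + 1, i1, i1 + 1,
            2 * N)
  # scaled unknowns: ph = p / P0, qh = q / Q0
  ph <- if (is.null(p0)) rep(p_inner / P0, N) else p0 / P0
  qh <- if (is.null(q0)) rep(0, N) else q0 / Q0

  resid_fun <- function(ph, qh) {
    pm <- P0 * (ph[-1] + ph[-N]) / 2
    qm <- (qh[-1] + qh[-N]) / 2
    jv <- ifelse(src_iv, beta * .ramp(p_inf - pm, eps), 0)
    F1 <- (ph[-1] - ph[-N]) + 2 * a_iv * qm
    F2 <- (qh[-1] - qh[-N]) - h * rm * (jv - sink_iv) / Q0
    c(ph[1] - p_inner / P0, F1, F2, qh[N])
  }

  Fv <- resid_fun(ph, qh)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    pm <- P0 * (ph[-1] + ph[-N]) / 2
    jv_d <- ifelse(src_iv, -beta * .ramp_d(p_inf - pm, eps), 0)  # d jv / d p
    b_iv <- -h * rm * jv_d / 2 * (P0 / Q0)                       # dF2/dph
    vals <- c(1,
              rep(-1, N - 1), rep(1, N - 1), a_iv, a_iv,
              rep(-1, N - 1), rep(1, N - 1), b_iv, b_iv,
              1)
    A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(2 * N, 2 * N))
    dx <- as.numeric(Matrix::solve(A, -Fv))
    dp <- dx[seq_len(N)]
    dq <- dx[N + seq_len(N)]
    # damped step: backtrack while the residual norm grows
    t_step <- 1
    n0 <- max(abs(Fv))
    for (k in 0:12) {
      p_try <- ph + t_step * dp
      q_try <- qh + t_step * dq
      F_try <- resid_fun(p_try, q_try)
      if (max(abs(F_try)) <= n0 * (1 - 1e-4 * t_step) || max(abs(F_try)) < 1e-13) break
      t_step <- t_step / 2
    }
    ph <- p_try; qh <- q_try; Fv <- F_try
    qref <- max(abs(qh), 1e-12)
    step <- max(abs(t_step * dp), abs(t_step * dq) / qref)
    if (step < 1e-11) { converged <- TRUE; break }
  }
  if (!converged) {
    # accept if the residual itself is tiny relative to the problem scales
    qref <- max(abs(qh), 1e-12)
    rel <- max(abs(Fv) / c(1, rep(1, N - 1), rep(qref, N - 1), qref))
    if (rel > 1e-9) {
      stop(sprintf("flow solver failed to converge (relative residual %.3g after %d iterations)",
                   rel, max_iter))
    }
  }
  list(p = P0 * ph, q = Q0 * qh, niter = iter)
}

#' Solve the radial Darcy flow boundary-value problem
#'
#' Solves steady radial interstitial flow across the inner layers,
#' adventitia and PVAT of a wall parameter set: Darcy flow with stepwise
#' permeability, the Starling vasa vasorum source and the constant lymphatic
#' sink active in the adventitia and PVAT only, luminal pressure imposed at
#' `r_lu` and no flow at `r_ext`. The grid is refined (doubled) until the
#' pressure profile is converged to `opts$rel_tol`.
#'
#' @param ps a `wall_params` object.
#' @param opts a `solver_options` object.
#' @return object of class `flow_solution` with node vectors `r`, `p` (Pa),
#'   `u` (m/s), `q = r u` (m^2/s), `J_v` (1/s, >= 0), `J_l` (1/s, <= 0),
#'   luminal-origin fluid fraction `f`, integrated rates `Q_lu`, `Q_v`,
#'   `Q_l` (m^2/s per unit axial length, summing to zero), and the
#'   mass-balance audit `residual`.
#' @seealso [luminal_fraction()], [flow_rates()]
#' @export
solve_radial_flow <- function(ps, opts = solver_options()) {
  validate_wall_params(ps)
  breaks <- unname(wall_radii(ps))
  k_layer <- c(ps$tissue$k_i, ps$tissue$k_a, ps$tissue$k_p)
  src_layer <- c(FALSE, TRUE, TRUE)
  s_l <- lymph_sink_rate(ps$lymph)
  sol <- .solve_flow_core(breaks, k_layer, src_layer, s_l, ps$vasa,
                          ps$tissue$mu, ps$p_lu, opts)
  sol$params <- ps
  sol
}

# Layer-generic core (also used directly by oracle tests on reduced
# geometries). breaks has length(n_layer) + 1.
.solve_flow_core <- function(breaks, k_layer, src_layer, s_l, vasa, mu,
                             p_inner, opts = solver_options()) {
  g <- .layer_grid(breaks, opts$n_grid)
  fit <- .flow_solve_grid(g$r, g$reg, k_layer, src_layer, s_l, vasa, mu,
                          p_inner, opts$starling_eps, opts$max_iter)
  for (lev in seq_len(opts$max_refine)) {
    g2 <- .layer_grid(breaks, 2L * (length(g$r) - 1L))
    p0 <- stats::approx(g$r, fit$p, g2$r, rule = 2)$y
    q0 <- stats::approx(g$r, fit$q, g2$r, rule = 2)$y
    fit2 <- .flow_solve_grid(g2$r, g2$reg, k_layer, src_layer, s_l, vasa, mu,
                             p_inner, opts$starling_eps, opts$max_iter,
                             p0 = p0, q0 = q0)
    scale <- max(diff(range(fit$p)), .MMHG)
    delta <- max(abs(stats::approx(g2$r, fit2$p, g$r)$y - fit$p)) / scale
    g <- g2; fit <- fit2
    if (delta < opts$rel_tol) break
  }
  r <- g$r; reg <- g$reg; N <- length(r)
  p <- fit$p; q <- fit$q
  h <- diff(r); rm <- (r[-1] + r[-N]) / 2
  src_iv <- src_layer[reg]

  # node-wise source/sink densities (interface node belongs to the sink side)
  node_src <- if (any(src_layer)) {
    r >= breaks[min(which(src_layer))] * (1 - 1e-12)
  } else {
    rep(FALSE, N)
  }
  J_v <- ifelse(node_src, starling_flux(p, vasa, opts$starling_eps), 0)
  J_l <- ifelse(node_src, -s_l, 0)

  # integrated rates with the scheme's own midpoint quadrature, so that
  # Q_lu + Q_v + Q_l = 0 holds to machine precision for a converged solve
  pm <- (p[-1] + p[-N]) / 2
  jv_m <- ifelse(src_iv, starling_flux(pm, vasa, opts$starling_eps), 0)
  Q_lu <- 2 * pi * q[1]
  Q_v <- 2 * pi * sum(h * rm * jv_m)
  Q_l <- -2 * pi * sum(h * rm * ifelse(src_iv, s_l, 0))

  # independent audit of the conservation equation by central differences
  interior <- 2:(N - 1)
  no_jump <- interior[reg[interior - 1] == reg[interior]]
  dqdr <- (q[no_jump + 1] - q[no_jump - 1]) / (r[no_jump + 1] - r[no_jump - 1])
  res_loc <- dqdr / r[no_jump] - (J_v[no_jump] + J_l[no_jump])
  res_scale <- max(abs(J_v), abs(J_l), abs(Q_lu) / (pi * (r[N]^2 - r[1]^2)), 1e-30)
  residual <- max(abs(res_loc)) / res_scale

  u <- q / r
  sol <- structure(list(
    r = r, p = p, q = q, u = u, J_v = J_v, J_l = J_l,
    region = reg, breaks = breaks, src_layer = src_layer,
    Q_lu = Q_lu, Q_v = Q_v, Q_l = Q_l,
    residual = residual, niter = fit$niter,
    reverse_flow = any(u[2:(N - 1)] < -1e-12 * max(abs(u))),
    opts = list(starling_eps = opts$starling_eps)
  ), class = "flow_solution")
  fr <- luminal_fraction(sol)
  sol$f <- fr
  sol$f_truncated <- isTRUE(attr(fr, "truncated"))
  sol
}

#' Luminal-origin fluid fraction along the wall
#'
#' Steady well-mixed tracer of fluid that entered through the arterial
#' endothelium: vasa vasorum add pure non-luminal plasma and lymphatics
#' remove mixed fluid, so the luminal fraction obeys `df/dr = -(J_v/u) f`
#' with `f = 1` at the lumen. `f` is 1 throughout the inner layers (no vasa
#' there) and non-increasing outward. Where the radial velocity crosses zero
#' the tracer is undefined beyond that radius: the profile is frozen there
#' and flagged via `attr(, "truncated")`.
#'
#' @param sol a `flow_solution`.
#' @return numeric vector `f` on `sol$r`, in \[0, 1\].
#' @export
luminal_fraction <- function(sol) {
  r <- sol$r; q <- sol$q; J_v <- sol$J_v
  N <- length(r)
  f <- rep(1, N)
  if (all(J_v == 0)) return(f)
  idx <- which(J_v > 0 | r >= min(r[J_v > 0]))
  i0 <- min(idx)
  qref <- max(abs(q))
  truncated <- FALSE
  # integrate d(log f)/dr = -J_v r / q by trapezoid from the first source node
  lnf <- 0
  for (i in seq(i0 + 1L, N)) {
    ql <- q[i - 1L]; qr <- q[i]
    last <- i == N
    if (qr <= qref * 1e-10 && !last) {
      truncated <- TRUE
      f[i:N] <- f[i - 1L]
      break
    }
    gl <- if (ql > qref * 1e-10) J_v[i - 1L] * r[i - 1L] / ql else NA_real_
    gr <- if (qr > qref * 1e-10) J_v[i] * r[i] / qr else NA_real_
    if (last && !is.finite(gr)) {
      # outer boundary: q -> 0; f -> 0 when vasa inflow persists there
      f[i] <- if (J_v[i] > 0) 0 else f[i - 1L]
      break
    }
    if (!is.finite(gl)) gl <- gr
    lnf <- lnf - (r[i] - r[i - 1L]) * (gl + gr) / 2
    f[i] <- exp(lnf)
  }
  attr(f, "truncated") <- truncated
  f
}

#' Integrated flow rates of a solution
#'
#' Flow per unit axial length (m^2/s): `Q_lu` across the arterial
#' endothelium (`2 pi r_lu u(r_lu)`), `Q_v` from vasa vasorum
#' (`integral of J_v 2 pi r dr`) and `Q_l` into lymphatics (negative). A
#' converged solution satisfies `Q_lu + Q_v + Q_l = 0`.
#'
#' @param sol a `flow_solution`.
#' @return named numeric vector `c(Q_lu, Q_v, Q_l)`.
#' @export
flow_rates <- function(sol) c(Q_lu = sol$Q_lu, Q_v = sol$Q_v, Q_l = sol$Q_l)

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "flow_solution: %d nodes on [%.3f, %.3f] mm (%d Newton iterations)\n",
    length(x$r), 1e3 * x$r[1], 1e3 * x$r[length(x$r)], x$niter
  ))
  cat(sprintf("  p: %.2f -> %.2f mmHg | u(inner) %.4f um/s\n",
              pa_to_mmhg(x$p[1]), pa_to_mmhg(x$p[length(x$p)]), 1e6 * x$u[1]))
  cat(sprintf("  Q_lu %.3g, Q_v %.3g, Q_l %.3g m^2/s (closure %.1e)\n",
              x$Q_lu, x$Q_v, x$Q_l,
              abs(x$Q_lu + x$Q_v + x$Q_l) / max(abs(x$Q_lu), abs(x$Q_l), 1e-300)))
  cat(sprintf("  mass-balance audit residual %.2e%s%s\n", x$residual,
              if (x$reverse_flow) " | reverse flow present" else "",
              if (x$f_truncated) " | tracer truncated" else ""))
  invisible(x)
}

#' Export a flow solution to CSV (+ optional JSON sidecar of scalars)
#'
#' Columns `r_mm`, `p_mmHg`, `u_um_per_s`, `J_v`, `J_l`, `f`.
#'
#' @param sol a `flow_solution`.
#' @param csv_path output CSV path.
#' @param json_path optional path for the scalar outputs
#'   (`Q_lu`, `Q_v`, `Q_l`, `residual`).
#' @return `csv_path`, invisibly.
#' @export
write_flow_solution <- function(sol, csv_path, json_path = NULL) {
  df <- data.frame(
    r_mm = 1e3 * sol$r, p_mmHg = pa_to_mmhg(sol$p),
    u_um_per_s = 1e6 * sol$u, J_v = sol$J_v, J_l = sol$J_l, f = sol$f
  )
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(Q_lu = sol$Q_lu, Q_v = sol$Q_v, Q_l = sol$Q_l, residual = sol$residual),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
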