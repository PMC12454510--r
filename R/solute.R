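# Steady solute transport across the wall periphery.
#
# Advection-diffusion of a non-binding solute on the solved interstitial
# flow, with first-order microvascular sinks: convective + diffusive uptake
# into vasa vasorum, -(J_v + kappa_v A_bar_v) c, and removal by lymphatic
# drainage, J_l c. A concentration of c0 is imposed at the source (arterial
# lumen or the EEL) and zero diffusive flux one PVAT thickness beyond the
# outer PVAT, where solutes still diffuse and are taken up although the
# fluid model ends. The equation is linear in c and solved in one pass on
# the collocation grid; solutions are stored normalised by c0.

#' Solute transport parameters
#'
#' @param D solute diffusivity in tissue (m^2/s); chemokine-like solutes are
#'   near 100 um^2/s (=1e-10 m^2/s), LDL near 10 um^2/s, hindered LDL near
#'   1 um^2/s.
#' @param kappa_v diffusive permeability of the vasa endothelium (m/s);
#'   supply either this or `R_d`.
#' @param R_d ratio of diffusive flux into vasa vasorum to diffusive flux in
#'   tissue, `kappa_v A_bar_v (t_a+t_p)^2 / D`; converted to `kappa_v` for
#'   the parameter set at hand.
#' @param source `"lumen"` (Dirichlet at `r_lu`) or `"eel"` (Dirichlet at
#'   `r_ia`).
#' @param c0 source concentration (arbitrary units; solutions are stored
#'   normalised by it).
#' @return list of class `solute_params`.
#' @export
solute_params <- function(D, kappa_v = NULL, R_d = NULL,
                          source = c("lumen", "eel"), c0 = 1) {
  source <- match.arg(source)
  if (D <= 0) stop("diffusivity D must be strictly positive")
  if (is.null(kappa_v) == is.null(R_d)) {
    stop("supply exactly one of kappa_v and R_d")
  }
  if (!is.null(kappa_v) && kappa_v < 0) stop("kappa_v must be non-negative")
  if (!is.null(R_d) && R_d < 0) stop("R_d must be non-negative")
  structure(list(D = D, kappa_v = kappa_v, R_d = R_d, source = source, c0 = c0),
            class = "solute_params")
}

.kappa_from_sp <- function(ps, sp) {
  if (!is.null(sp$kappa_v)) return(sp$kappa_v)
  A_v <- vasa_area_density(ps$vasa)
  L <- ps$geometry$t_a + ps$geometry$t_p
  if (A_v == 0) {
    if (sp$R_d > 0) stop("R_d > 0 requires a non-zero vasa area density")
    return(0)
  }
  sp$R_d * sp$D / (A_v * L^2)
}

#' Non-dimensional transport numbers of a configuration
#'
#' The four groups governing peripheral solute transport, built on the
#' length scale `t_a + t_p` and the velocity scale `(k_i/mu)(p_lu/t_i)`:
#' Peclet number `Pe` (advection vs diffusion), vasa Damkohler `Da_v`
#' (Starling uptake at zero tissue pressure vs diffusion), lymphatic
#' Damkohler `Da_l` (drainage vs diffusion) and the diffusive flux ratio
#' `R_d` (transendothelial vs tissue diffusion).
#'
#' @param ps a `wall_params` object.
#' @param sp a `solute_params` object.
#' @return named list of class `dimensionless_numbers` with `Pe`, `Da_v`,
#'   `Da_l`, `R_d`.
#' @export
dimensionless_numbers <- function(ps, sp) {
  L <- ps$geometry$t_a + ps$geometry$t_p
  u_scale <- (ps$tissue$k_i / ps$tissue$mu) * (ps$p_lu / ps$geometry$t_i)
  dP0 <- max(.starling_p_inf(ps$vasa), 0)  # driving pressure at p = 0, clamped
  kappa <- .kappa_from_sp(ps, sp)
  A_v <- vasa_area_density(ps$vasa)
  structure(list(
    Pe = u_scale * L / sp$D,
    Da_v = ps$vasa$l_pv * A_v * dP0 * L^2 / sp$D,
    Da_l = lymph_sink_rate(ps$lymph) * L^2 / sp$D,
    R_d = if (!is.null(sp$R_d)) sp$R_d else kappa * A_v * L^2 / sp$D
  ), class = "dimensionless_numbers")
}

#' @export
print.dimensionless_numbers <- function(x, ...) {
  cat(sprintf("Pe = %.3g | Da_v = %.3g | Da_l = %.3g | R_d = %.3g\n",
              x$Pe, x$Da_v, x$Da_l, x$R_d))
  invisible(x)
}

# Generic linear advection-diffusion-uptake solve on a radial grid:
#   Dc (c'' + c'/r) - u c' - (uprime + sink) c = 0,
#   c(r[1]) = c_in,  dc/dr (r[N]) = 0.
# Non-uniform 3-point central differences; 2nd-order one-sided outer
# Neumann. Returns c and its collocation derivative.
.solve_linear_advdiff <- function(r, Dc, u, uprime, sink, c_in = 1) {
  N <- length(r)
  h1 <- r[2:(N - 1)] - r[1:(N - 2)]
  h2 <- r[3:N] - r[2:(N - 1)]
  # first and second derivative weights at interior nodes
  w1_l <- -h2 / (h1 * (h1 + h2)); w1_c <- (h2 - h1) / (h1 * h2); w1_r <- h1 / (h2 * (h1 + h2))
  w2_l <- 2 / (h1 * (h1 + h2));  w2_c <- -2 / (h1 * h2);        w2_r <- 2 / (h2 * (h1 + h2))
  i_int <- 2:(N - 1)
  adv <- Dc / r[i_int] - u[i_int]
  lo <- Dc * w2_l + adv * w1_l
  di <- Dc * w2_c + adv * w1_c - (uprime[i_int] + sink[i_int])
  up <- Dc * w2_r + adv * w1_r
  # outer Neumann: one-sided 2nd-order derivative = 0
  hN1 <- r[N] - r[N - 1]; hN2 <- r[N - 1] - r[N - 2]
  aN <- (2 * hN1 + hN2) / (hN1 * (hN1 + hN2))
  bN <- -(hN1 + hN2) / (hN1 * hN2)
  cN <- hN1 / (hN2 * (hN1 + hN2))
  rows <- c(1, i_int, i_int, i_int, N, N, N)
  cols <- c(1, i_int - 1L, i_int, i_int + 1L, N, N - 1L, N - 2L)
  vals <- c(1, lo, di, up, aN, bN, cN)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  rhs <- c(c_in, rep(0, N - 2), 0)
  cc <- as.numeric(Matrix::solve(A, rhs))
  # collocation derivative (same stencils; one-sided at both ends)
  dcdr <- numeric(N)
  dcdr[i_int] <- w1_l * cc[i_int - 1L] + w1_c * cc[i_int] + w1_r * cc[i_int + 1L]
  h12 <- r[2] - r[1]; h22 <- r[3] - r[2]
  dcdr[1] <- -(2 * h12 + h22) / (h12 * (h12 + h22)) * cc[1] +
    (h12 + h22) / (h12 * h22) * cc[2] - h12 / (h22 * (h12 + h22)) * cc[3]
  dcdr[N] <- aN * cc[N] + bN * cc[N - 1L] + cN * cc[N - 2L]
  list(c = cc, dcdr = dcdr)
}

#' Solve steady solute transport on a flow solution
#'
#' Solves the linear advection-diffusion equation with microvascular uptake
#' on the radial domain from the source (lumen or EEL) to one PVAT
#' thickness beyond the outer PVAT. Sinks act in the adventitia, PVAT and
#' the extension region only; in the extension the fluid model ends
#' (`u = 0`) and the sink coefficients are frozen at their outer-PVAT
#' values (with the Starling factor evaluated at `p(r_ext)`), optionally
#' without the lymphatic term.
#'
#' @param ps a `wall_params` object.
#' @param flow the matching `flow_solution`.
#' @param sp a `solute_params` object.
#' @param opts `solver_options`; the grid is doubled until the
#'   concentration profile changes by less than `rel_tol`.
#' @param extension_sinks `"frozen"` (default) or `"off"`: microvascular
#'   sinks in the extension region.
#' @param lymph_in_extension keep the lymphatic uptake term in the
#'   extension (default TRUE; the uptake terms of the transport equation
#'   act independently).
#' @return object of class `solute_solution`: grid `r`, normalised
#'   concentration `c` (`c = 1` at the source), collocation gradient `dcdr`
#'   (1/m), the `dimensionless_numbers`, source label and domain radii.
#' @export
solve_solute <- function(ps, flow, sp, opts = solver_options(),
                         extension_sinks = c("frozen", "off"),
                         lymph_in_extension = TRUE) {
  extension_sinks <- match.arg(extension_sinks)
  rr <- wall_radii(ps)
  r0 <- if (sp$source == "lumen") rr[["r_lu"]] else rr[["r_ia"]]
  r_end <- rr[["r_ext"]] + ps$geometry$t_p
  breaks <- unique(c(r0, rr[["r_ia"]], rr[["r_ap"]], rr[["r_ext"]], r_end))
  breaks <- breaks[breaks >= r0]
  kappa <- .kappa_from_sp(ps, sp)
  A_v <- vasa_area_density(ps$vasa)
  s_l <- lymph_sink_rate(ps$lymph)
  eps <- flow$opts$starling_eps
  p_ext <- flow$p[length(flow$p)]
  jv_ext <- starling_flux(p_ext, ps$vasa, eps)

  build <- function(n) {
    g <- .layer_grid(breaks, n)
    r <- g$r
    p <- stats::approx(flow$r, flow$p, pmin(r, rr[["r_ext"]]), rule = 2)$y
    q <- stats::approx(flow$r, flow$q, pmin(r, rr[["r_ext"]]), rule = 2)$y
    in_wall <- r <= rr[["r_ext"]] * (1 + 1e-12)
    in_sink <- r >= rr[["r_ia"]] * (1 - 1e-12) & in_wall
    in_ext <- !in_wall
    u <- ifelse(in_wall, q / r, 0)
    jv <- ifelse(in_sink, starling_flux(p, ps$vasa, eps), 0)
    jl <- ifelse(in_sink, s_l, 0)
    uprime <- ifelse(in_wall, (jv - jl) - u / r, 0)
    sink <- jv + kappa * A_v * as.numeric(in_sink) + jl
    if (extension_sinks == "frozen") {
      sink[in_ext] <- jv_ext + kappa * A_v +
        if (lymph_in_extension) s_l else 0
    }
    list(r = r, u = u, uprime = uprime, sink = sink)
  }

  n <- opts$n_grid
  gr <- build(n)
  sol <- .solve_linear_advdiff(gr$r, sp$D, gr$u, gr$uprime, gr$sink)
  for (lev in seq_len(opts$max_refine)) {
    gr2 <- build(2L * (length(gr$r) - 1L))
    sol2 <- .solve_linear_advdiff(gr2$r, sp$D, gr2$u, gr2$uprime, gr2$sink)
    delta <- max(abs(stats::approx(gr2$r, sol2$c, gr$r)$y - sol$c)) /
      max(abs(sol$c), 1e-12)
    gr <- gr2; sol <- sol2
    if (delta < opts$rel_tol) break
  }
  if (min(sol$c) < -1e-6 * max(abs(sol$c))) {
    stop(sprintf("discretisation error: negative concentration (min %.3g)", min(sol$c)))
  }
  structure(list(
    r = gr$r, c = sol$c, dcdr = sol$dcdr,
    u = gr$u, uprime = gr$uprime, sink = gr$sink,
    source = sp$source, D = sp$D, kappa_v = kappa,
    numbers = dimensionless_numbers(ps, sp),
    radii = rr, t_p = ps$geometry$t_p, r_end = r_end,
    extension_sinks = extension_sinks, lymph_in_extension = lymph_in_extension
  ), class = "solute_solution")
}

#' Solve the non-dimensional solute transport equation
#'
#' Starred form of the transport equation on a non-dimensional grid
#' (lengths scaled by `t_a + t_p`, velocity by `(k_i/mu)(p_lu/t_i)`):
#' `(1/r)(r c')' - Pe (u c)' - Da_v [dP(p)/dP(0)] c - R_d c - Da_l c = 0`,
#' with `c = 1` at the inner boundary and zero gradient at the outer one.
#' Profiles (`u_star`, its derivative, the Starling pressure ratio and the
#' sink masks) are supplied on the grid, so the caller controls where each
#' uptake term acts.
#'
#' @param numbers a `dimensionless_numbers` object.
#' @param r_star non-dimensional radial grid (increasing).
#' @param u_star non-dimensional velocity profile on `r_star`.
#' @param uprime_star derivative of `u_star` (same grid).
#' @param dP_ratio Starling driving-pressure ratio `dP(p)/dP(0)` profile
#'   (clamped like the flux itself).
#' @param mask_v,mask_rd,mask_l multiplier profiles (0/1) for the vasa
#'   convective, vasa diffusive and lymphatic uptake terms; default active
#'   everywhere.
#' @return a `solute_solution` in starred variables (`dcdr` per unit
#'   non-dimensional length).
#' @export
solve_solute_nondim <- function(numbers, r_star, u_star, uprime_star,
                                dP_ratio = rep(1, length(r_star)),
                                mask_v = rep(1, length(r_star)),
                                mask_rd = rep(1, length(r_star)),
                                mask_l = rep(1, length(r_star))) {
  stopifnot(length(u_star) == length(r_star), all(diff(r_star) > 0))
  sink <- numbers$Da_v * dP_ratio * mask_v + numbers$R_d * mask_rd +
    numbers$Da_l * mask_l
  sol <- .solve_linear_advdiff(r_star, 1, numbers$Pe * u_star,
                               numbers$Pe * uprime_star, sink)
  structure(list(
    r = r_star, c = sol$c, dcdr = sol$dcdr, source = "nondimensional",
    numbers = numbers
  ), class = "solute_solution")
}

#' @export
print.solute_solution <- function(x, ...) {
  cat(sprintf("solute_solution (%s source): %d nodes on [%.3g, %.3g]\n",
              x$source, length(x$r), x$r[1], x$r[length(x$r)]))
  cat(sprintf("  c range [%.3g, %.3g]; ", min(x$c), max(x$c)))
  print(x$numbers)
  invisible(x)
}

#' Export a solute profile to CSV
#'
#' Columns `r_mm`, `c_norm`, `dcdr_per_mm`; the attached non-dimensional
#' numbers are written as a header comment line.
#'
#' @param sol a (dimensional) `solute_solution`.
#' @param csv_path output path.
#' @return `csv_path`, invisibly.
#' @export
write_solute_solution <- function(sol, csv_path) {
  con <- file(csv_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Pe=%.6g Da_v=%.6g Da_l=%.6g R_d=%.6g source=%s",
                     sol$numbers$Pe, sol$numbers$Da_v, sol$numbers$Da_l,
                     sol$numbers$R_d, sol$source), con)
  utils::write.csv(
    data.frame(r_mm = 1e3 * sol$r, c_norm = sol$c, dcdr_per_mm = sol$dcdr / 1e3),
    con, row.names = FALSE
  )
  invisible(csv_path)
}
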