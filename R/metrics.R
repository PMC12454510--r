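# Key model outputs: scalar metrics extracted from flow and solute
# solutions, reported in the units used for wall physiology (mmHg, um/s,
# mm, 1/mm).

.interp <- function(x, y, x0) stats::approx(x, y, x0, rule = 2)$y

#' Interstitial velocity halfway across the inner layers
#'
#' @param flow a `flow_solution` from [solve_radial_flow()].
#' @return velocity at `r_lu + t_i/2` (m/s).
#' @export
midwall_velocity <- function(flow) {
  g <- flow$params$geometry
  r_mid <- g$r_lu + g$t_i / 2
  # interpolate the conserved flux q = r u (exactly piecewise linear on the
  # solver grid) rather than u itself, which varies as 1/r between nodes
  .interp(flow$r, flow$q, r_mid) / r_mid
}

#' Pressures at the wall layer boundaries
#'
#' @param flow a `flow_solution`.
#' @return named vector `c(p_ia, p_ap)`: interstitial pressure at the
#'   medial-adventitial boundary and the outer adventitia, in mmHg.
#' @export
boundary_pressures <- function(flow) {
  rr <- wall_radii(flow$params)
  c(p_ia = pa_to_mmhg(.interp(flow$r, flow$p, rr[["r_ia"]])),
    p_ap = pa_to_mmhg(.interp(flow$r, flow$p, rr[["r_ap"]])))
}

#' Dilution distance of luminal fluid
#'
#' First radius at which fluid of arterial-lumen origin falls below
#' `threshold` (default 10%) of the local interstitial fluid, by linear
#' interpolation of the tracer fraction between grid nodes. Reported from
#' the lumen centre; `Inf` when the fluid is never diluted below the
#' threshold inside the wall.
#'
#' @param flow a `flow_solution` (with its luminal fraction `f`).
#' @param threshold dilution threshold on the luminal fraction.
#' @return radius (m), or `Inf`.
#' @export
dilution_distance <- function(flow, threshold = 0.1) {
  f <- flow$f
  below <- which(f < threshold)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(flow$r[1])
  # linear interpolation between the straddling nodes
  r1 <- flow$r[i - 1]; r2 <- flow$r[i]
  f1 <- f[i - 1]; f2 <- f[i]
  r1 + (threshold - f1) * (r2 - r1) / (f2 - f1)
}

#' Solute concentration at the EEL
#'
#' For a lumen-source solution, the normalised concentration interpolated at
#' the medial-adventitial boundary.
#'
#' @param sol a `solute_solution` with `source == "lumen"`.
#' @return `c_ia` (dimensionless).
#' @export
eel_concentration <- function(sol) {
  if (!identical(sol$source, "lumen")) {
    stop("eel_concentration requires a lumen-source solute solution")
  }
  .interp(sol$r, sol$c, sol$radii[["r_ia"]])
}

#' Maximum concentration gradient in the adventitia
#'
#' For an EEL-source solution, the maximum of `|dc/dr|` over the adventitia
#' (between the EEL and the adventitia-PVAT border), from the solver's
#' collocation derivative, together with its radius.
#'
#' @param sol a `solute_solution` with `source == "eel"`.
#' @return list with `value` (1/mm, on the normalised concentration) and
#'   `r_at` (m).
#' @export
max_adventitial_gradient <- function(sol) {
  if (!identical(sol$source, "eel")) {
    stop("max_adventitial_gradient requires an EEL-source solute solution")
  }
  idx <- which(sol$r >= sol$radii[["r_ia"]] * (1 - 1e-12) &
                 sol$r <= sol$radii[["r_ap"]] * (1 + 1e-12))
  g <- abs(sol$dcdr[idx])
  i <- idx[which.max(g)]
  list(value = abs(sol$dcdr[i]) / 1e3, r_at = sol$r[i])
}

#' Dendritic-cell chemokine transport distance
#'
#' Distance from the adventitia-PVAT border at which the normalised
#' concentration gradient of an EEL-source solute first drops below the
#' dendritic-cell chemotaxis threshold (0.4 per mm for CCL19) and stays
#' below it outward. Zero when the gradient is already below threshold at
#' the border; also returned normalised by the PVAT thickness (`t_star`).
#'
#' @param sol a `solute_solution` with `source == "eel"`.
#' @param threshold gradient threshold (1/mm on normalised concentration).
#' @return list with `distance` (m) and `t_star` (distance / `t_p`).
#' @export
dc_transport_distance <- function(sol, threshold = 0.4) {
  if (!identical(sol$source, "eel")) {
    stop("dc_transport_distance requires an EEL-source solute solution")
  }
  r_ap <- sol$radii[["r_ap"]]
  idx <- which(sol$r >= r_ap * (1 - 1e-12))
  r <- sol$r[idx]
  g <- abs(sol$dcdr[idx]) / 1e3  # per mm
  above <- which(g >= threshold)
  if (!length(above) || above[1] > 1) {
    # below threshold already at the border
    dist <- 0
  } else {
    i_last <- max(above)  # last node at/above threshold; stays below beyond
    if (i_last == length(r)) {
      dist <- r[i_last] - r_ap
    } else {
      # interpolate the crossing between i_last and i_last + 1
      g1 <- g[i_last]; g2 <- g[i_last + 1]
      r_cross <- r[i_last] + (threshold - g1) * (r[i_last + 1] - r[i_last]) / (g2 - g1)
      dist <- r_cross - r_ap
    }
  }
  list(distance = dist, t_star = dist / sol$t_p)
}

#' Classify the shape of an EEL-source concentration profile
#'
#' `"accumulative"` when the concentration exceeds the source value by more
#' than `acc_tol` anywhere beyond the EEL (interior maximum above the
#' source); otherwise `"convex"` when the profile is non-increasing and the
#' largest adventitial gradient sits strictly inside the adventitia (more
#' than `interior_cells` grid cells from the EEL) - low gradient at the EEL,
#' higher further out; otherwise `"neither"` (e.g. a plain exponential-like
#' decay with its largest gradient at the EEL).
#'
#' @param sol a `solute_solution` with `source == "eel"`.
#' @param acc_tol accumulation tolerance on the normalised concentration.
#' @param interior_cells how many grid cells from the EEL the gradient
#'   maximum must lie to count as interior.
#' @return `"convex"`, `"accumulative"` or `"neither"`.
#' @export
classify_profile <- function(sol, acc_tol = 1e-3, interior_cells = 2L) {
  if (!identical(sol$source, "eel")) {
    stop("classify_profile requires an EEL-source solute solution")
  }
  r_ia <- sol$radii[["r_ia"]]; r_ap <- sol$radii[["r_ap"]]
  beyond <- sol$r > r_ia * (1 + 1e-12)
  if (max(sol$c[beyond]) > 1 + acc_tol) return("accumulative")
  adv <- which(sol$r >= r_ia * (1 - 1e-12) & sol$r <= r_ap * (1 + 1e-12))
  i_max <- which.max(abs(sol$dcdr[adv]))
  non_increasing <- all(diff(sol$c) <= acc_tol)
  if (i_max > interior_cells && non_increasing) "convex" else "neither"
}

#' Whole-tissue mass-conservation audit
#'
#' Evaluates both sides of the global fluid balance of the wall periphery:
#' lymphatic outflow `N_l q_l V` against the lumen-wall inflow `v_i A_i`
#' (mid-layer velocity times the circumference there) plus the vasa inflow
#' `l_pv A_bar_v mean(dP) V`, with the driving pressure averaged over the
#' tissue cross-section. Converged solutions balance to solver precision.
#'
#' @param flow a `flow_solution`.
#' @return relative mismatch between the two sides (dimensionless).
#' @export
global_balance_audit <- function(flow) {
  ps <- flow$params
  rr <- wall_radii(ps)
  V <- pi * (rr[["r_ext"]]^2 - rr[["r_ia"]]^2)
  lhs <- lymph_sink_rate(ps$lymph) * V
  v_i <- midwall_velocity(flow)
  A_i <- 2 * pi * (ps$geometry$r_lu + ps$geometry$t_i / 2)
  # cross-section-weighted mean Starling driving pressure over the sink
  # region, with the same midpoint quadrature as the solver
  N <- length(flow$r)
  h <- diff(flow$r); rm <- (flow$r[-1] + flow$r[-N]) / 2
  pm <- (flow$p[-1] + flow$p[-N]) / 2
  in_sink <- rm >= rr[["r_ia"]]
  eps <- flow$opts$starling_eps
  dPm <- .ramp(.starling_p_inf(ps$vasa) - pm, eps)
  dP_bar <- sum((h * rm * dPm)[in_sink]) / sum((h * rm)[in_sink])
  rhs <- v_i * A_i + ps$vasa$l_pv * vasa_area_density(ps$vasa) * dP_bar * V
  abs(lhs - rhs) / max(abs(lhs), abs(rhs), 1e-300)
}

#' Collect the key metrics of one simulated sample
#'
#' Builds one row of ensemble output from a flow solution and (optionally)
#' lumen- and EEL-source solute solutions, in reporting units: pressures in
#' mmHg, velocity in um/s, distances in mm, gradients in 1/mm.
#'
#' @param flow a `flow_solution`.
#' @param solute_lumen optional lumen-source `solute_solution`.
#' @param solute_eel optional EEL-source `solute_solution`.
#' @return one-row `data.frame`.
#' @export
metrics_record <- function(flow, solute_lumen = NULL, solute_eel = NULL) {
  ps <- flow$params
  bp <- boundary_pressures(flow)
  d <- dilution_distance(flow)
  rr <- wall_radii(ps)
  out <- data.frame(
    sample_id = ps$sample_id,
    condition = ps$condition,
    t_a_mm = 1e3 * ps$geometry$t_a,
    t_p_mm = 1e3 * ps$geometry$t_p,
    lambda = mass_balance_deviation(ps),
    sink_rate = lymph_sink_rate(ps$lymph),
    u_mid_um_s = 1e6 * midwall_velocity(flow),
    p_ia_mmHg = unname(bp[["p_ia"]]),
    p_ap_mmHg = unname(bp[["p_ap"]]),
    vasa_fraction = flow$Q_v / (flow$Q_v + flow$Q_lu),
    dilution_r_mm = 1e3 * d,
    dilution_adv_frac = (d - rr[["r_ia"]]) / ps$geometry$t_a,
    dilution_never = !is.finite(d),
    reverse_flow = flow$reverse_flow,
    balance_residual = abs(flow$Q_lu + flow$Q_v + flow$Q_l) /
      max(abs(flow$Q_lu), abs(flow$Q_l), 1e-300)
  )
  if (!is.null(solute_lumen)) {
    out$c_ia <- eel_concentration(solute_lumen)
    out$Pe <- solute_lumen$numbers$Pe
  }
  if (!is.null(solute_eel)) {
    mg <- max_adventitial_gradient(solute_eel)
    dc <- dc_transport_distance(solute_eel)
    out$max_grad_per_mm <- mg$value
    out$max_grad_r_mm <- 1e3 * mg$r_at
    out$dc_distance_mm <- 1e3 * dc$distance
    out$t_star_dc <- dc$t_star
    out$profile_class <- classify_profile(solute_eel)
    out$Da_l <- solute_eel$numbers$Da_l
    out$Da_v <- solute_eel$numbers$Da_v
    out$R_d <- solute_eel$numbers$R_d
  }
  out
}
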