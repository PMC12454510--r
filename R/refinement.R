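# Mass-balance deviation (Lambda) and the physiologic-plausibility
# parameter-refinement workflow.
#
# Lambda is a scalar surrogate for whole-tissue fluid balance: the ratio of
# the lymphatic outflow rate to the sum of a two-layer Darcy estimate of the
# lumen-wall inflow and the Starling vasa inflow, both evaluated at a
# constant test tissue pressure. Lambda near its physiologic interval marks
# parameter sets whose solved outer adventitial pressure is plausible;
# inverting Lambda for the per-vessel lymph drainage rate lets ensembles
# impose that plausibility before solving.

#' Context for the Lambda refinement workflow
#'
#' @param p_test test tissue pressure (Pa) at which the mass-balance
#'   deviation is evaluated; default -2.5 mmHg, the midpoint of the
#'   physiologic interval.
#' @param physiologic_interval plausible range for the outer adventitial
#'   pressure (Pa); default \[-10, 5\] mmHg.
#' @param lambda_interval refined Lambda interval, once known.
#' @return list of class `lambda_context`.
#' @export
lambda_context <- function(p_test = mmhg_to_pa(-2.5),
                           physiologic_interval = mmhg_to_pa(c(-10, 5)),
                           lambda_interval = NULL) {
  stopifnot(length(physiologic_interval) == 2,
            physiologic_interval[1] < physiologic_interval[2])
  if (!is.null(lambda_interval)) {
    stopifnot(length(lambda_interval) == 2, lambda_interval[1] <= lambda_interval[2])
  }
  structure(list(p_test = p_test, physiologic_interval = physiologic_interval,
                 lambda_interval = lambda_interval),
            class = "lambda_context")
}

# The three flow-rate terms of the Lambda ratio (all in 1/s, per unit
# tissue volume of the scalar exchange model):
#  - darcy: two-layer (inner + adventitia) cylindrical Darcy inflow estimate
#    spread over the PVAT volume,
#  - vasa: Starling inflow at the test pressure (clamped),
#  - lymph: lymphatic outflow N_l q_tilde_l l_bar_l.
.lambda_terms <- function(ps, p_test) {
  r <- wall_radii(ps)
  k_i <- ps$tissue$k_i; k_a <- ps$tissue$k_a; mu <- ps$tissue$mu
  t_p <- ps$geometry$t_p
  k_eff <- log(r[["r_ap"]] / r[["r_lu"]]) * k_i * k_a /
    (log(r[["r_ap"]] / r[["r_ia"]]) * k_i + log(r[["r_ia"]] / r[["r_lu"]]) * k_a)
  darcy <- k_eff * 2 * (ps$p_lu - p_test) / (mu * (t_p^2 + 2 * r[["r_ap"]] * t_p))
  vasa <- starling_flux(p_test, ps$vasa)  # hard clamp, no smoothing
  lymph <- lymph_sink_rate(ps$lymph)
  c(darcy = unname(darcy), vasa = unname(vasa), lymph = lymph)
}

#' Mass-balance deviation of a parameter set
#'
#' The ratio of outgoing to incoming whole-tissue mass flow rates when all
#' microvascular exchange is assumed to occur in the PVAT at the constant
#' test pressure `p_test`:
#' `Lambda = N_l q_l / (darcy_term + l_pv A_bar_v dP(p_test))`, where the
#' Darcy term combines the inner-layer and adventitial permeabilities in
#' series and spreads the inflow over the PVAT volume, and the Starling term
#' uses the clamped driving pressure. `Lambda = 1` means the parameter set
#' is in whole-tissue balance at `p_test`.
#'
#' @param ps a `wall_params` object.
#' @param p_test test tissue pressure (Pa).
#' @return Lambda (dimensionless, >= 0).
#' @seealso [lymph_rate_from_lambda()] for the inversion.
#' @export
mass_balance_deviation <- function(ps, p_test = mmhg_to_pa(-2.5)) {
  tm <- .lambda_terms(ps, p_test)
  denom <- tm[["darcy"]] + tm[["vasa"]]
  if (denom <= 0) {
    stop(sprintf(
      "non-positive Lambda denominator (darcy term %.3g, vasa term %.3g); requires p_lu > p_test or active Starling filtration",
      tm[["darcy"]], tm[["vasa"]]
    ))
  }
  unname(tm[["lymph"]] / denom)
}

#' Lymphatic drainage rate from a prescribed mass-balance deviation
#'
#' Algebraic inversion of the Lambda definition for the per-vessel drainage
#' rate `q_tilde_l`, keeping the sample's lymphatic density `N_l`:
#' `q_tilde_l = Lambda * (darcy_term + vasa_term) / (N_l * l_bar_l)`.
#' Round-trips with [mass_balance_deviation()] to machine precision.
#'
#' @param lambda target mass-balance deviation (>= 0).
#' @param ps a `wall_params` object (its `q_tilde_l` is ignored).
#' @param p_test test tissue pressure (Pa).
#' @return drainage rate `q_tilde_l` (m^2/s).
#' @export
lymph_rate_from_lambda <- function(lambda, ps, p_test = mmhg_to_pa(-2.5)) {
  if (lambda < 0) stop("lambda must be non-negative")
  tm <- .lambda_terms(ps, p_test)
  denom <- tm[["darcy"]] + tm[["vasa"]]
  if (denom <= 0) {
    stop(sprintf(
      "non-positive Lambda denominator (darcy term %.3g, vasa term %.3g)",
      tm[["darcy"]], tm[["vasa"]]
    ))
  }
  lambda * denom / (ps$lymph$N_l * ps$lymph$l_bar_l)
}

#' Refine the physiologic Lambda interval from stage-1 samples
#'
#' Fits `p_ap = a + b * Lambda` by ordinary least squares over the initial
#' ensemble and returns the preimage of the physiologic pressure interval
#' under the fitted line, intersected with the observed Lambda range. The
#' outer adventitial pressure decreases with Lambda, so `b < 0` is required
#' (a non-negative slope raises a degenerate-relationship error).
#'
#' @param lambda numeric vector of mass-balance deviations.
#' @param p_ap matching outer adventitial pressures (Pa).
#' @param physiologic_interval plausible `p_ap` range (Pa).
#' @param method `"regression"` (preimage of the interval under the OLS
#'   line) or `"empirical"` (range of Lambda among samples with physiologic
#'   `p_ap`).
#' @return list with `interval` (Lambda bounds), `slope` (Pa per unit
#'   Lambda), `intercept` (Pa), `r_squared` and `n`.
#' @export
refine_lambda_interval <- function(lambda, p_ap,
                                   physiologic_interval = mmhg_to_pa(c(-10, 5)),
                                   method = c("regression", "empirical")) {
  method <- match.arg(method)
  ok <- is.finite(lambda) & is.finite(p_ap)
  lambda <- lambda[ok]; p_ap <- p_ap[ok]
  if (length(lambda) < 100) stop("need at least 100 samples to refine the Lambda interval")
  fit <- stats::lm(p_ap ~ lambda)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (b >= 0) {
    stop(sprintf("degenerate Lambda relationship: fitted slope %.3g Pa is not negative", b))
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  interval <- if (method == "regression") {
    sort((physiologic_interval - a) / b)
  } else {
    inside <- p_ap >= physiologic_interval[1] & p_ap <= physiologic_interval[2]
    if (!any(inside)) stop("no sample has a physiologic outer adventitial pressure")
    range(lambda[inside])
  }
  interval <- c(max(interval[1], min(lambda)), min(interval[2], max(lambda)))
  if (interval[1] >= interval[2]) stop("refined Lambda interval is empty")
  list(interval = interval, slope = b, intercept = a, r_squared = r2,
       n = length(lambda), method = method)
}

#' Sensitivity of Lambda to its three mass flow rates
#'
#' Central finite-difference derivatives of the mass-balance deviation with
#' respect to the lumen-wall Darcy inflow term, the vasa Starling inflow
#' term and the lymphatic outflow term, each perturbed by `rel_step` about
#' the baseline parameter set. Lambda increases with the lymph term and
#' decreases with both inflow terms; comparable magnitudes indicate that
#' none of the three flow rates is negligible.
#'
#' @param ps a `wall_params` object.
#' @param p_test test tissue pressure (Pa).
#' @param rel_step relative perturbation, in (0, 0.1].
#' @return named vector of derivatives (`darcy`, `vasa`, `lymph`), each
#'   d Lambda / d term in s (inverse of the term's 1/s unit), with the
#'   evaluated term values in `attr(, "terms")`.
#' @export
sensitivity_lambda <- function(ps, p_test = mmhg_to_pa(-2.5), rel_step = 0.01) {
  if (rel_step <= 0 || rel_step > 0.1) stop("rel_step must be in (0, 0.1]")
  tm <- .lambda_terms(ps, p_test)
  lam <- function(t) t[["lymph"]] / (t[["darcy"]] + t[["vasa"]])
  out <- vapply(names(tm), function(nm) {
    if (tm[[nm]] == 0) return(NA_real_)
    hi <- tm; hi[[nm]] <- tm[[nm]] * (1 + rel_step)
    lo <- tm; lo[[nm]] <- tm[[nm]] * (1 - rel_step)
    l_hi <- lam(hi); l_lo <- lam(lo)
    if (!is.finite(l_hi) || !is.finite(l_lo)) stop("non-finite Lambda at perturbed point")
    (l_hi - l_lo) / (2 * rel_step * tm[[nm]])
  }, numeric(1))
  attr(out, "terms") <- tm
  out
}

#' Sensitivity of the lumen-wall flow rate to wall properties
#'
#' Central finite-difference derivatives of the solved transmural flow rate
#' `Q_lu` with respect to `sqrt(k_i)`, `sqrt(k_a)` and the PVAT thickness
#' `t_p`; each evaluation re-solves the flow boundary-value problem. In the
#' physiologic regime (`k_a >> k_i`) the inner-layer permeability dominates.
#'
#' @param ps a `wall_params` object.
#' @param rel_step relative perturbation, in (0, 0.1].
#' @param opts `solver_options` passed to the flow solves.
#' @return named vector of derivatives (`sqrt_k_i`, `sqrt_k_a`, `t_p`).
#' @export
sensitivity_lumen_flow <- function(ps, rel_step = 0.02, opts = solver_options()) {
  if (rel_step <= 0 || rel_step > 0.1) stop("rel_step must be in (0, 0.1]")
  qlu <- function(ps) solve_radial_flow(ps, opts)$Q_lu
  centre <- list(
    sqrt_k_i = sqrt(ps$tissue$k_i),
    sqrt_k_a = sqrt(ps$tissue$k_a),
    t_p = ps$geometry$t_p
  )
  perturb <- function(nm, x) {
    switch(nm,
      sqrt_k_i = set_params(ps, "tissue.k_i" = x^2),
      sqrt_k_a = set_params(ps, "tissue.k_a" = x^2),
      t_p = set_params(ps, "geometry.t_p" = x)
    )
  }
  vapply(names(centre), function(nm) {
    x0 <- centre[[nm]]
    (qlu(perturb(nm, x0 * (1 + rel_step))) - qlu(perturb(nm, x0 * (1 - rel_step)))) /
      (2 * rel_step * x0)
  }, numeric(1))
}
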