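# Two-stage Monte-Carlo workflow:
#   stage 1 - draw parameter sets from the healthy distributions, solve the
#     flow model, compute the mass-balance deviation Lambda at the test
#     pressure and regress the outer adventitial pressure on Lambda to find
#     the physiologic Lambda interval;
#   stage 2 - resample the accepted stage-1 sets, draw Lambda uniformly in
#     the refined interval, set the lymph drainage rate by inversion (so
#     physiologic plausibility is imposed before solving), optionally apply
#     the atherosclerotic factors, then solve flow (+ tracer) and the
#     configured solute cases and collect the metric distributions.

#' Configuration of a Monte-Carlo ensemble run
#'
#' @param n_samples number of Monte-Carlo samples.
#' @param seed integer RNG seed for the run.
#' @param D_values solute diffusivities (m^2/s) to run per sample; default
#'   100, 10 and 1 um^2/s.
#' @param R_d_range log-uniform sampling range of the diffusive flux ratio,
#'   drawn once per sample and applied at every diffusivity.
#' @param sources solute source locations to run.
#' @param p_test test pressure for the mass-balance deviation (Pa).
#' @param physiologic_interval plausible outer adventitial pressures (Pa).
#' @param solute run the solute cases in stage 2 (`FALSE` for flow-only).
#' @param opts `solver_options` used for all solves (ensemble default is a
#'   lighter grid than the single-solve default; pressures converge well
#'   before the metric tolerances matter).
#' @param max_failure_frac abort when more than this fraction of solves
#'   fails (a failing parameterisation, not bad luck).
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_samples = 1000L, seed = 1L,
                            D_values = c(100, 10, 1) * 1e-12,
                            R_d_range = c(0.01, 10),
                            sources = c("lumen", "eel"),
                            p_test = mmhg_to_pa(-2.5),
                            physiologic_interval = mmhg_to_pa(c(-10, 5)),
                            solute = TRUE,
                            opts = solver_options(n_grid = 240L, max_refine = 1L),
                            max_failure_frac = 0.05) {
  stopifnot(n_samples >= 1, all(D_values > 0),
            length(R_d_range) == 2, R_d_range[1] > 0, R_d_range[1] < R_d_range[2])
  structure(list(
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    D_values = D_values, R_d_range = R_d_range,
    sources = match.arg(sources, several.ok = TRUE),
    p_test = p_test, physiologic_interval = physiologic_interval,
    solute = solute, opts = opts, max_failure_frac = max_failure_frac
  ), class = "ensemble_config")
}

#' Run the initial (stage-1) healthy ensemble
#'
#' Draws `cfg$n_samples` healthy parameter sets, solves the flow model for
#' each, computes the mass-balance deviation at `cfg$p_test` and refines the
#' physiologic Lambda interval by regression of the outer adventitial
#' pressure on Lambda. Failed solves are recorded and counted, never
#' silently dropped; more than `cfg$max_failure_frac` failures aborts.
#'
#' @param cfg an `ensemble_config`.
#' @param distributions result of [load_distributions()] (default: the
#'   shipped configuration).
#' @return object of class `initial_ensemble`: the per-sample `table`
#'   (`lambda`, `p_ap_mmHg`, `failed`), the regression `fit`, the refined
#'   `context` (a `lambda_context`), the drawn `samples` and the indices of
#'   the `accepted` pool (Lambda inside the refined interval).
#' @export
run_initial_ensemble <- function(cfg = ensemble_config(),
                                 distributions = default_distributions()) {
  samples <- sample_parameter_sets(distributions$registry, cfg$n_samples, cfg$seed)
  n <- length(samples)
  lambda <- p_ap <- rep(NA_real_, n)
  failed <- character(n)
  for (i in seq_len(n)) {
    lambda[i] <- mass_balance_deviation(samples[[i]], cfg$p_test)
    res <- tryCatch(
      boundary_pressures(solve_radial_flow(samples[[i]], cfg$opts))[["p_ap"]],
      error = function(e) e
    )
    if (inherits(res, "error")) failed[i] <- conditionMessage(res) else p_ap[i] <- res
  }
  n_fail <- sum(failed != "")
  if (n_fail > cfg$max_failure_frac * n) {
    stop(sprintf("stage-1 ensemble: %d/%d solver failures; parameterisation suspect", n_fail, n))
  }
  fit <- refine_lambda_interval(lambda, mmhg_to_pa(p_ap),
                                cfg$physiologic_interval)
  ctx <- lambda_context(cfg$p_test, cfg$physiologic_interval, fit$interval)
  accepted <- which(lambda >= fit$interval[1] & lambda <= fit$interval[2] & failed == "")
  if (!length(accepted)) stop("no stage-1 sample falls inside the refined Lambda interval")
  structure(list(
    table = data.frame(sample_id = seq_len(n), lambda = lambda,
                       p_ap_mmHg = p_ap, failed = failed != ""),
    fit = fit, context = ctx, samples = samples, accepted = accepted,
    n_failed = n_fail,
    provenance = list(seed = cfg$seed, n = n,
                      package_version = as.character(utils::packageVersion("periwall")))
  ), class = "initial_ensemble")
}

#' @export
print.initial_ensemble <- function(x, ...) {
  cat(sprintf(
    "initial_ensemble: %d samples (%d failed)\n  p_ap = %.2f %+.2f Lambda mmHg (r^2 = %.3f)\n  refined Lambda interval [%.3f, %.3f]; %d accepted\n",
    nrow(x$table), x$n_failed, pa_to_mmhg(x$fit$intercept), pa_to_mmhg(x$fit$slope),
    x$fit$r_squared, x$fit$interval[1], x$fit$interval[2], length(x$accepted)
  ))
  invisible(x)
}

# One stage-2 sample: resample, impose Lambda, optionally athero, solve.
.refined_sample <- function(init, cfg, condition, factors, idx, lambda, R_d) {
  ps <- init$samples[[idx]]
  q_l <- lymph_rate_from_lambda(lambda, ps, init$context$p_test)
  ps <- set_params(ps, "lymph.q_tilde_l" = q_l)
  if (condition == "atherosclerotic") {
    ps <- apply_athero_factors(ps, factors)
  }
  flow <- solve_radial_flow(ps, cfg$opts)
  if (!cfg$solute) return(metrics_record(flow))
  base <- metrics_record(flow)
  for (D in cfg$D_values) {
    tag <- sprintf("_D%g", D * 1e12)
    sl <- if ("lumen" %in% cfg$sources) {
      solve_solute(ps, flow, solute_params(D = D, R_d = R_d, source = "lumen"), cfg$opts)
    }
    se <- if ("eel" %in% cfg$sources) {
      solve_solute(ps, flow, solute_params(D = D, R_d = R_d, source = "eel"), cfg$opts)
    }
    rec <- metrics_record(flow, solute_lumen = sl, solute_eel = se)
    extra <- setdiff(names(rec), names(base))
    names(extra) <- NULL
    for (nm in extra) base[[paste0(nm, tag)]] <- rec[[nm]]
  }
  base
}

#' Run a refined (stage-2) ensemble
#'
#' For each sample: draw a parameter set uniformly from the accepted
#' stage-1 pool, draw Lambda uniformly on the refined interval, set the
#' lymph drainage rate by inversion of the mass-balance deviation (using
#' the sample's own lymphatic density), apply the atherosclerotic factors
#' when requested, solve the flow model with the luminal-fraction tracer
#' and, if configured, the solute cases (both sources at each diffusivity,
#' with one diffusive-flux-ratio draw per sample), and collect the metrics.
#'
#' @param init an `initial_ensemble`.
#' @param cfg an `ensemble_config` (its `n_samples` and `seed` drive this
#'   stage).
#' @param condition `"healthy"` or `"atherosclerotic"`.
#' @param factors atherosclerotic factors (ignored for healthy runs).
#' @return object of class `ensemble_result` with the per-sample metrics
#'   `table`, the failure count and provenance.
#' @export
run_refined_ensemble <- function(init, cfg, condition = c("healthy", "atherosclerotic"),
                                 factors = default_athero_factors()) {
  condition <- match.arg(condition)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  lo <- init$context$lambda_interval[1]
  hi <- init$context$lambda_interval[2]
  rows <- vector("list", n)
  failed <- character(n)
  for (i in seq_len(n)) {
    idx <- init$accepted[sample.int(length(init$accepted), 1L)]
    lambda <- stats::runif(1, lo, hi)
    R_d <- exp(stats::runif(1, log(cfg$R_d_range[1]), log(cfg$R_d_range[2])))
    res <- tryCatch(
      .refined_sample(init, cfg, condition, factors, idx, lambda, R_d),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[i] <- conditionMessage(res)
    } else {
      res$sample_id <- i
      res$base_id <- idx
      rows[[i]] <- res
    }
  }
  n_fail <- sum(failed != "")
  if (n_fail > cfg$max_failure_frac * n) {
    stop(sprintf("stage-2 ensemble: %d/%d solver failures; parameterisation suspect", n_fail, n))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(
    table = tab, condition = condition, n_failed = n_fail,
    failures = failed[failed != ""],
    provenance = list(seed = cfg$seed, n = n, condition = condition,
                      lambda_interval = c(lo, hi),
                      package_version = as.character(utils::packageVersion("periwall")))
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result (%s): %d samples (%d failed)\n",
              x$condition, nrow(x$table) + x$n_failed, x$n_failed))
  cat(sprintf("  p_ap %.1f +/- %.1f mmHg | u_mid %.3f um/s | vasa fraction %.2f (median)\n",
              mean(x$table$p_ap_mmHg), stats::sd(x$table$p_ap_mmHg),
              mean(x$table$u_mid_um_s), stats::median(x$table$vasa_fraction)))
  invisible(x)
}

#' Summarise an ensemble result
#'
#' Means, standard deviations and quartiles of every numeric metric, the
#' headline exceedance fractions (physiologic and positive outer
#' adventitial pressure, measured-velocity window, vasa-dominated lymph,
#' dilution beyond the adventitia) and, when solute cases were run, the
#' proportions of convex and accumulative EEL-source profiles per
#' diffusivity.
#'
#' @param res an `ensemble_result`.
#' @param physiologic_mmHg physiologic `p_ap` window (mmHg).
#' @param u_window_um_s measured mid-wall velocity window (um/s).
#' @return list with `metrics` (data.frame), `fractions` (named numeric)
#'   and `profile_classes` (data.frame or NULL).
#' @export
summarize_ensemble <- function(res, physiologic_mmHg = c(-10, 5),
                               u_window_um_s = c(0.025, 0.055)) {
  tab <- res$table
  if (is.null(tab) || !nrow(tab)) stop("empty ensemble table")
  num <- tab[vapply(tab, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("sample_id", "base_id"))]
  metrics <- data.frame(
    metric = names(num),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    q25 = vapply(num, function(v) unname(stats::quantile(v, 0.25, na.rm = TRUE)), numeric(1)),
    median = vapply(num, function(v) stats::median(v, na.rm = TRUE), numeric(1)),
    q75 = vapply(num, function(v) unname(stats::quantile(v, 0.75, na.rm = TRUE)), numeric(1)),
    row.names = NULL
  )
  p <- tab$p_ap_mmHg
  fractions <- c(
    p_ap_physiologic = mean(p >= physiologic_mmHg[1] & p <= physiologic_mmHg[2]),
    p_ap_positive = mean(p > 0),
    p_ap_above_10 = mean(p > 10),
    u_mid_in_window = mean(tab$u_mid_um_s >= u_window_um_s[1] &
                             tab$u_mid_um_s <= u_window_um_s[2]),
    vasa_majority = mean(tab$vasa_fraction > 0.5),
    vasa_over_75 = mean(tab$vasa_fraction > 0.75),
    diluted_before_adventitia_end = mean(is.finite(tab$dilution_adv_frac) &
                                           tab$dilution_adv_frac < 1)
  )
  class_cols <- grep("^profile_class_D", names(tab), value = TRUE)
  profile_classes <- if (length(class_cols)) {
    do.call(rbind, lapply(class_cols, function(cc) {
      D <- sub("^profile_class_D", "", cc)
      data.frame(
        D_um2_s = as.numeric(D),
        convex = mean(tab[[cc]] == "convex", na.rm = TRUE),
        accumulative = mean(tab[[cc]] == "accumulative", na.rm = TRUE),
        neither = mean(tab[[cc]] == "neither", na.rm = TRUE)
      )
    }))
  }
  list(metrics = metrics, fractions = fractions, profile_classes = profile_classes)
}
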