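# Parameter space of the wall model: one `wall_params` object is a complete
# physical configuration (geometry, Darcy permeabilities, vasa vasorum and
# lymphatic properties, boundary pressure). Distribution registries describe
# how each parameter is drawn in Monte-Carlo ensembles.

# Schema of samplable parameters: config-file unit and positivity class.
# positivity: "strict" (> 0), "nonneg" (>= 0), "unit" ([0, 1]), "free".
.param_schema <- function() {
  data.frame(
    path = c(
      "geometry.r_lu", "geometry.t_i", "geometry.t_a", "geometry.t_p",
      "tissue.k_i", "tissue.k_a", "tissue.k_p", "tissue.mu",
      "vasa.l_pv", "vasa.N_v", "vasa.d_v", "vasa.p_v", "vasa.pi_v",
      "vasa.pi_t", "vasa.sigma", "vasa.kappa_v",
      "lymph.N_l", "lymph.q_tilde_l", "lymph.l_bar_l",
      "boundary.p_lu"
    ),
    unit = c(
      "um", "um", "um", "um",
      "si", "si", "si", "si",
      "si", "si", "um", "mmHg", "mmHg",
      "mmHg", "si", "si",
      "si", "si", "si",
      "mmHg"
    ),
    positivity = c(
      "strict", "strict", "strict", "strict",
      "strict", "strict", "strict", "strict",
      "nonneg", "nonneg", "nonneg", "free", "free",
      "free", "unit", "nonneg",
      "nonneg", "nonneg", "strict",
      "free"
    ),
    stringsAsFactors = FALSE
  )
}

.config_to_si <- function(x, unit) {
  switch(unit, um = x * 1e-6, mmHg = mmhg_to_pa(x), si = x)
}

#' Construct a wall parameter set
#'
#' Assembles and validates one complete physical configuration of the
#' peri-arterial wall. All values are in SI units (m, s, Pa). The radial
#' domain consists of three porous layers: the inner layers (intima + media)
#' of thickness `t_i`, the adventitia (`t_a`) and the perivascular adipose
#' tissue, PVAT (`t_p`), starting at the lumen radius `r_lu`.
#'
#' @param geometry list with `r_lu`, `t_i`, `t_a`, `t_p` (m).
#' @param tissue list with Darcy permeabilities `k_i`, `k_a`, `k_p` (m^2) and
#'   interstitial fluid viscosity `mu` (Pa s).
#' @param vasa list with vasa vasorum properties: endothelial hydraulic
#'   conductivity `l_pv` (m/Pa/s), vessel count per cross-sectional area `N_v`
#'   (1/m^2), capillary diameter `d_v` (m), luminal hydrostatic pressure `p_v`
#'   (Pa), plasma osmotic pressure `pi_v` (Pa), tissue osmotic pressure `pi_t`
#'   (Pa), reflection coefficient `sigma` (-) and endothelial solute
#'   permeability `kappa_v` (m/s).
#' @param lymph list with lymphatic vessel count per area `N_l` (1/m^2),
#'   drainage flux per unit vessel length `q_tilde_l` (m^2/s) and vessel
#'   length per unit radial thickness `l_bar_l` (-, conventionally 1).
#' @param p_lu luminal pressure (Pa), imposed at `r_lu`.
#' @param condition `"healthy"` or `"atherosclerotic"`.
#' @param sample_id,seed integers recording Monte-Carlo provenance.
#' @return an object of class `wall_params`.
#' @seealso [default_parameter_set()], [sample_parameter_sets()]
#' @export
wall_params <- function(geometry, tissue, vasa, lymph, p_lu,
                        condition = "healthy", sample_id = 1L, seed = NA_integer_) {
  ps <- structure(
    list(
      geometry = geometry, tissue = tissue, vasa = vasa, lymph = lymph,
      p_lu = p_lu, condition = match.arg(condition, c("healthy", "atherosclerotic")),
      sample_id = as.integer(sample_id), seed = seed
    ),
    class = "wall_params"
  )
  validate_wall_params(ps)
  ps
}

#' Validate a wall parameter set
#'
#' Checks positivity of geometry and permeabilities, ordering of the derived
#' radii, `sigma` in \[0, 1\] and non-negativity of microvessel properties.
#' Called by every constructor; exported for use on hand-built sets.
#'
#' @param ps a `wall_params` object.
#' @return `ps`, invisibly; errors describe the violated invariant.
#' @export
validate_wall_params <- function(ps) {
  g <- ps$geometry
  if (any(!is.finite(unlist(g))) || any(unlist(g) <= 0)) {
    stop("geometry fields r_lu, t_i, t_a, t_p must be finite and strictly positive")
  }
  tt <- ps$tissue
  if (any(unlist(tt[c("k_i", "k_a", "k_p", "mu")]) <= 0)) {
    stop("tissue permeabilities and viscosity must be strictly positive")
  }
  v <- ps$vasa
  if (v$sigma < 0 || v$sigma > 1) stop("vasa reflection coefficient sigma must lie in [0, 1]")
  if (any(unlist(v[c("l_pv", "N_v", "d_v", "kappa_v")]) < 0)) {
    stop("vasa l_pv, N_v, d_v, kappa_v must be non-negative")
  }
  l <- ps$lymph
  if (any(unlist(l[c("N_l", "q_tilde_l")]) < 0)) stop("lymph N_l, q_tilde_l must be non-negative")
  if (l$l_bar_l <= 0) stop("lymph l_bar_l must be strictly positive")
  r <- wall_radii(ps)
  if (!all(diff(r) > 0)) stop("derived radii must satisfy r_lu < r_ia < r_ap < r_ext")
  invisible(ps)
}

#' Derived interface radii of a parameter set
#'
#' @param ps a `wall_params` object.
#' @return named numeric vector `r_lu`, `r_ia` (inner layers/adventitia),
#'   `r_ap` (adventitia/PVAT), `r_ext` (outer PVAT), in m.
#' @export
wall_radii <- function(ps) {
  g <- ps$geometry
  c(
    r_lu = g$r_lu,
    r_ia = g$r_lu + g$t_i,
    r_ap = g$r_lu + g$t_i + g$t_a,
    r_ext = g$r_lu + g$t_i + g$t_a + g$t_p
  )
}

#' Surface-area density of vasa vasorum
#'
#' Approximates the endothelial surface area of vasa vasorum per unit tissue
#' volume by the total vessel circumference per unit cross-sectional area,
#' `N_v * pi * d_v` (units 1/m).
#'
#' @param vasa the `vasa` component of a `wall_params` object (or any list
#'   with `N_v` and `d_v`).
#' @return area density (1/m).
#' @export
vasa_area_density <- function(vasa) vasa$N_v * pi * vasa$d_v

#' Volumetric lymphatic drainage rate
#'
#' The distributed lymphatic sink strength `N_l * q_tilde_l * l_bar_l`
#' (units 1/s); the local sink flux is minus this value.
#'
#' @param lymph the `lymph` component of a `wall_params` object.
#' @return drainage rate (1/s).
#' @export
lymph_sink_rate <- function(lymph) lymph$N_l * lymph$q_tilde_l * lymph$l_bar_l

#' @export
print.wall_params <- function(x, ...) {
  r <- wall_radii(x)
  cat(sprintf(
    "wall_params (%s, sample %d)\n  radii [mm]: lumen %.3f | EEL %.3f | adv-PVAT %.3f | outer %.3f\n",
    x$condition, x$sample_id, 1e3 * r[1], 1e3 * r[2], 1e3 * r[3], 1e3 * r[4]
  ))
  cat(sprintf(
    "  k_i %.3g  k_a %.3g  k_p %.3g m^2 | mu %.3g Pa s\n",
    x$tissue$k_i, x$tissue$k_a, x$tissue$k_p, x$tissue$mu
  ))
  cat(sprintf(
    "  vasa: l_pv %.3g m/Pa/s, N_v %.3g /m^2, A_bar_v %.1f /m\n",
    x$vasa$l_pv, x$vasa$N_v, vasa_area_density(x$vasa)
  ))
  cat(sprintf(
    "  lymph: N_l %.3g /m^2, q_tilde_l %.3g m^2/s (sink %.3g /s)\n",
    x$lymph$N_l, x$lymph$q_tilde_l, lymph_sink_rate(x$lymph)
  ))
  cat(sprintf("  p_lu %.1f mmHg\n", pa_to_mmhg(x$p_lu)))
  invisible(x)
}

#' Baseline wall parameter set
#'
#' The means of the shipped default distributions (see
#' [default_distributions()]): a healthy coronary-scale configuration with a
#' 1.5 mm lumen radius, 0.4 mm inner layers and adventitia, 0.8 mm PVAT, and
#' microvessel properties placed so that the whole-tissue mass balance is
#' close to equilibrium (mass-balance deviation near 1) at a test tissue
#' pressure of -2.5 mmHg.
#'
#' @return a `wall_params` object.
#' @export
default_parameter_set <- function() {
  wall_params(
    geometry = list(r_lu = 1.5e-3, t_i = 4e-4, t_a = 4e-4, t_p = 8e-4),
    tissue = list(k_i = 1e-18, k_a = 1e-16, k_p = 1e-16, mu = 1e-3),
    vasa = list(
      l_pv = 2.8e-12, N_v = 1e8, d_v = 1e-5,
      p_v = mmhg_to_pa(18), pi_v = mmhg_to_pa(20), pi_t = mmhg_to_pa(25.2),
      sigma = 0.9, kappa_v = 3e-9
    ),
    lymph = list(N_l = 2e6, q_tilde_l = 1.8e-11, l_bar_l = 1),
    p_lu = mmhg_to_pa(100)
  )
}

#' Define a sampling distribution for one parameter
#'
#' @param kind one of `"fixed"`, `"gaussian"`, `"uniform"`, `"loguniform"`.
#' @param value fixed value (kind `"fixed"`).
#' @param mean,sd Gaussian moments (kind `"gaussian"`).
#' @param low,high bounds (kinds `"uniform"`, `"loguniform"`; `low > 0`
#'   required for log-uniform).
#' @return a `dist_spec` object.
#' @export
dist_spec <- function(kind, value = NULL, mean = NULL, sd = NULL,
                      low = NULL, high = NULL) {
  kind <- match.arg(kind, c("fixed", "gaussian", "uniform", "loguniform"))
  spec <- switch(kind,
    fixed = {
      if (is.null(value) || !is.finite(value)) stop("fixed distribution needs a finite 'value'")
      list(kind = kind, value = value)
    },
    gaussian = {
      if (is.null(mean) || is.null(sd)) stop("gaussian distribution needs 'mean' and 'sd'")
      if (sd < 0) stop("gaussian 'sd' must be non-negative")
      list(kind = kind, mean = mean, sd = sd)
    },
    {
      if (is.null(low) || is.null(high)) stop(kind, " distribution needs 'low' and 'high'")
      if (low >= high) stop(kind, " distribution needs low < high")
      if (kind == "loguniform" && low <= 0) stop("loguniform distribution needs low > 0")
      list(kind = kind, low = low, high = high)
    }
  )
  structure(spec, class = "dist_spec")
}

# Draw n values from a dist_spec (no positivity handling here).
.draw_spec <- function(spec, n = 1L) {
  switch(spec$kind,
    fixed = rep(spec$value, n),
    gaussian = stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$low, spec$high),
    loguniform = exp(stats::runif(n, log(spec$low), log(spec$high)))
  )
}

# Rejection sampling respecting a positivity class; max 1000 attempts.
.draw_valid <- function(spec, positivity, path, max_attempts = 1000L) {
  ok <- switch(positivity,
    strict = function(x) is.finite(x) && x > 0,
    nonneg = function(x) is.finite(x) && x >= 0,
    unit = function(x) is.finite(x) && x >= 0 && x <= 1,
    free = function(x) is.finite(x)
  )
  for (i in seq_len(max_attempts)) {
    x <- .draw_spec(spec, 1L)
    if (ok(x)) return(x)
    if (spec$kind != "gaussian") break
  }
  stop(sprintf(
    "could not draw a value satisfying the '%s' constraint for parameter '%s' after %d attempts",
    positivity, path, max_attempts
  ))
}

.parse_spec_entry <- function(x, path, unit) {
  if (is.numeric(x) && length(x) == 1L) {
    return(dist_spec("fixed", value = .config_to_si(x, unit)))
  }
  if (!is.list(x) || is.null(x$kind)) {
    stop(sprintf("malformed distribution entry for '%s': need a scalar or a {kind, ...} list", path))
  }
  conv <- function(v) if (is.null(v)) NULL else .config_to_si(v, unit)
  dist_spec(x$kind,
    value = conv(x$value), mean = conv(x$mean),
    sd = if (is.null(x$sd)) NULL else if (identical(unit, "um")) x$sd * 1e-6 else if (identical(unit, "mmHg")) mmhg_to_pa(x$sd) else x$sd,
    low = conv(x$low), high = conv(x$high)
  )
}

#' Load a parameter distribution registry and atherosclerotic factors
#'
#' Reads a structured configuration (JSON or YAML file, or an equivalent
#' nested list) with sections `geometry`, `tissue`, `vasa`, `lymph`,
#' `boundary` and optionally `athero_factors`. Each leaf is either a scalar
#' (fixed value) or a list `{kind: gaussian|uniform|loguniform|fixed, ...}`.
#' Lengths are given in micrometres and pressures in mmHg in configuration
#' files; everything is converted to SI on load.
#'
#' Parameters absent from the configuration fall back to the shipped default
#' distributions with a single warning listing them. `tissue.k_p` is special:
#' when no distribution is supplied it mirrors the sampled `tissue.k_a`
#' (the PVAT resistance is secondary to the inner-layer and adventitial
#' resistances that control transmural flow).
#'
#' @param config_source `NULL` for the shipped defaults, a file path
#'   (`.json`, `.yaml`/`.yml`) or a nested list.
#' @return a list with `registry` (named list of `dist_spec`, keyed by
#'   parameter path such as `"tissue.k_i"`) and `athero` (named list of
#'   multiplicative factors, scalar or `dist_spec`).
#' @export
load_distributions <- function(config_source = NULL) {
  default_path <- system.file("extdata", "default_config.yaml", package = "periwall")
  is_default <- is.null(config_source)
  if (is_default) config_source <- default_path
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) stop("configuration file not found: ", config_source)
    if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config_source)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be NULL, a file path or a list")
  }

  schema <- .param_schema()
  known_sections <- c("geometry", "tissue", "vasa", "lymph", "boundary")
  extra <- setdiff(names(cfg), c(known_sections, "athero_factors"))
  if (length(extra)) stop("unknown configuration section(s): ", paste(extra, collapse = ", "))

  registry <- list()
  missing_paths <- character()
  for (i in seq_len(nrow(schema))) {
    path <- schema$path[i]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    entry <- cfg[[parts[1]]][[parts[2]]]
    if (is.null(entry)) {
      missing_paths <- c(missing_paths, path)
      next
    }
    registry[[path]] <- .parse_spec_entry(entry, path, schema$unit[i])
  }
  # reject unknown parameter names inside known sections
  for (sec in intersect(names(cfg), known_sections)) {
    bad <- setdiff(paste(sec, names(cfg[[sec]]), sep = "."), schema$path)
    if (length(bad)) stop("unknown parameter name(s) in configuration: ", paste(bad, collapse = ", "))
  }

  if ("tissue.k_p" %in% missing_paths) {
    # k_p intentionally mirrors the sampled k_a when unspecified; no warning
    registry[["tissue.k_p"]] <- structure(list(kind = "mirror", target = "tissue.k_a"),
                                          class = "dist_spec")
    missing_paths <- setdiff(missing_paths, "tissue.k_p")
  }
  if (length(missing_paths)) {
    if (is_default) {
      stop("shipped default configuration is incomplete; missing: ",
           paste(missing_paths, collapse = ", "))
    }
    defaults <- load_distributions(NULL)$registry
    warning("configuration is missing ", paste(missing_paths, collapse = ", "),
            "; using in-package defaults for these parameters", call. = FALSE)
    for (path in missing_paths) registry[[path]] <- defaults[[path]]
  }

  athero <- default_athero_factors()
  if (!is.null(cfg$athero_factors)) {
    af <- cfg$athero_factors
    flat <- list()
    for (sec in names(af)) {
      for (nm in names(af[[sec]])) {
        path <- paste(sec, nm, sep = ".")
        if (!path %in% schema$path) stop("unknown parameter in athero_factors: ", path)
        x <- af[[sec]][[nm]]
        flat[[path]] <- if (is.numeric(x) && length(x) == 1L) x else .parse_spec_entry(x, path, "si")
      }
    }
    athero <- flat
  }
  list(registry = registry, athero = athero)
}

#' Default atherosclerotic modification factors
#'
#' Multiplicative factors applied to a healthy draw: thicker inner layers and
#' adventitia, more permeable inner layers, denser and more conductive vasa
#' vasorum, denser but slower-draining lymphatics. The factor magnitudes are
#' chosen so that the total lymphatic sink rate roughly doubles (about
#' 3e-5 1/s to 7e-5 1/s on average) while the vasa filtration conductance per
#' unit pressure (`l_pv * N_v`) grows several-fold more, which drives the
#' adventitial pressure elevation in the diseased configuration.
#'
#' @return named list of scalar factors keyed by parameter path.
#' @export
default_athero_factors <- function() {
  list(
    "geometry.t_i" = 2.5,
    "geometry.t_a" = 1.5,
    "tissue.k_i" = 2.0,
    "vasa.N_v" = 2.5,
    "vasa.l_pv" = 2.7,
    "lymph.N_l" = 3.5,
    "lymph.q_tilde_l" = 0.65
  )
}

#' Shipped default distribution registry
#'
#' Equivalent to `load_distributions(NULL)`: reads the packaged
#' `default_config.yaml`, whose entries carry per-value provenance comments.
#'
#' @return as [load_distributions()].
#' @export
default_distributions <- function() load_distributions(NULL)

.set_path <- function(ps, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[1], "boundary")) {
    ps$p_lu <- value
  } else {
    ps[[parts[1]]][[parts[2]]] <- value
  }
  ps
}

.get_path <- function(ps, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[1], "boundary")) ps$p_lu else ps[[parts[1]]][[parts[2]]]
}

#' Modify parameters of a wall parameter set by path
#'
#' Convenience for constructing variants in analyses and tests, e.g.
#' `set_params(ps, "tissue.k_i" = 1e-18, "lymph.N_l" = 0)`. Values in SI.
#'
#' @param ps a `wall_params` object.
#' @param ... named SI values, names being parameter paths
#'   (`"section.name"`, with `"boundary.p_lu"` for the luminal pressure).
#' @return the modified, re-validated `wall_params`.
#' @export
set_params <- function(ps, ...) {
  upd <- list(...)
  schema <- .param_schema()
  for (path in names(upd)) {
    if (!path %in% schema$path) stop("unknown parameter path: ", path)
    ps <- .set_path(ps, path, upd[[path]])
  }
  validate_wall_params(ps)
  ps
}

#' Sample wall parameter sets from a distribution registry
#'
#' Draws `n` complete parameter sets. Gaussian draws violating the target
#' parameter's positivity class are rejected and redrawn (at most 1000
#' attempts, then an error naming the parameter). Sampling is reproducible:
#' the same `registry`, `n` and `seed` give identical sets.
#'
#' @param registry named list of `dist_spec` as produced by
#'   [load_distributions()] (its `$registry` element).
#' @param n number of sets (>= 1).
#' @param seed integer RNG seed.
#' @return list of `wall_params`, with `sample_id` 1..n.
#' @export
sample_parameter_sets <- function(registry, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  schema <- .param_schema()
  miss <- setdiff(schema$path, names(registry))
  if (length(miss)) stop("registry is incomplete; missing: ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  template <- default_parameter_set()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- template
    for (j in seq_len(nrow(schema))) {
      path <- schema$path[j]
      spec <- registry[[path]]
      if (identical(spec$kind, "mirror")) next
      ps <- .set_path(ps, path, .draw_valid(spec, schema$positivity[j], path))
    }
    if (identical(registry[["tissue.k_p"]]$kind, "mirror")) {
      ps$tissue$k_p <- .get_path(ps, registry[["tissue.k_p"]]$target)
    }
    ps$sample_id <- i
    ps$seed <- as.integer(seed)
    validate_wall_params(ps)
    out[[i]] <- ps
  }
  out
}

#' Apply atherosclerotic modification factors to a healthy parameter set
#'
#' Multiplies the named parameters of a healthy draw by their factors and
#' flags the result as atherosclerotic. Factors may be scalars or
#' `dist_spec` objects (drawn once per call). A warning is emitted when a
#' factor direction contradicts the expected disease remodelling
#' (`t_i`, `t_a`, `k_i`, `N_v`, `l_pv`, `N_l` increase; `q_tilde_l`
#' decreases).
#'
#' @param ps a healthy `wall_params`.
#' @param factors named list of factors keyed by parameter path
#'   (default [default_athero_factors()]).
#' @return a new atherosclerotic `wall_params`.
#' @export
apply_athero_factors <- function(ps, factors = default_athero_factors()) {
  if (!identical(ps$condition, "healthy")) stop("input parameter set must be healthy")
  expect_up <- c("geometry.t_i", "geometry.t_a", "tissue.k_i",
                 "vasa.N_v", "vasa.l_pv", "lymph.N_l")
  expect_down <- "lymph.q_tilde_l"
  schema <- .param_schema()
  out <- ps
  for (path in names(factors)) {
    if (!path %in% schema$path) stop("unknown parameter path in factors: ", path)
    f <- factors[[path]]
    if (inherits(f, "dist_spec")) f <- .draw_spec(f, 1L)
    if (!is.finite(f) || f < 0) stop("factor for ", path, " must be a finite non-negative number")
    if (path %in% expect_up && f < 1) {
      warning("atherosclerotic factor for ", path, " is < 1; expected an increase", call. = FALSE)
    }
    if (path %in% expect_down && f > 1) {
      warning("atherosclerotic factor for ", path, " is > 1; expected a decrease", call. = FALSE)
    }
    out <- .set_path(out, path, .get_path(out, path) * f)
  }
  out$condition <- "atherosclerotic"
  validate_wall_params(out)
  out
}

#' Flatten parameter sets to a data frame
#'
#' One row per set, columns named by parameter path (SI units), plus
#' `sample_id` and `condition`; suitable for CSV export.
#'
#' @param ps_list list of `wall_params`.
#' @return data.frame.
#' @export
params_table <- function(ps_list) {
  if (inherits(ps_list, "wall_params")) ps_list <- list(ps_list)
  schema <- .param_schema()
  rows <- lapply(ps_list, function(ps) {
    vals <- vapply(schema$path, function(p) .get_path(ps, p), numeric(1))
    out <- as.data.frame(as.list(vals), check.names = FALSE)
    out$sample_id <- ps$sample_id
    out$condition <- ps$condition
    out
  })
  do.call(rbind, rows)
}
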