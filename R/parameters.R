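#' Define a single model input parameter
#'
#' A parameter spec bundles a point estimate with its uncertainty interval,
#' the distribution family used to sample it in probabilistic sensitivity
#' analysis, and its role in the model (which fixes its admissible range and
#' the one-way sensitivity fallback range).
#'
#' @param name Identifier, e.g. `"p_mi_statin"`.
#' @param base Point estimate (base-case value). For role
#'   `"log_hazard_ratio"` the value is on the log scale.
#' @param low,high Interval bounds (typically a 95\% confidence interval).
#'   `NA` if no interval is reported; one-way sensitivity then falls back to
#'   a proportional range (see [owsa_range()]).
#' @param dist Distribution family for probabilistic sampling: `"beta"`,
#'   `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param role One of `"probability"`, `"relative_risk"`,
#'   `"log_hazard_ratio"`, `"cost_THB_per_year"`, `"utility"`,
#'   `"utility_decrement"`.
#' @return An object of class `"parameter_spec"`.
#' @examples
#' parameter_spec("u_acs", 0.82, 0.738, 0.902, "beta", "utility")
#' @export
parameter_spec <- function(name, base, low = NA_real_, high = NA_real_,
                           dist = c("beta", "gamma", "lognormal", "fixed"),
                           role = c("probability", "relative_risk",
                                    "log_hazard_ratio", "cost_THB_per_year",
                                    "utility", "utility_decrement")) {
  dist <- match.arg(dist)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  base <- as.numeric(base)
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (!is.finite(base)) {
    stop("parameter '", name, "': base value must be a finite number",
         call. = FALSE)
  }
  if (role %in% c("probability", "utility") &&
      (base < 0 || base > 1)) {
    stop("parameter '", name, "': ", role, " out of [0,1]", call. = FALSE)
  }
  if (!is.na(low) && !is.na(high)) {
    if (!(low <= base && base <= high)) {
      stop("parameter '", name, "': interval must satisfy low <= base <= high",
           call. = FALSE)
    }
  } else if (xor(is.na(low), is.na(high))) {
    stop("parameter '", name, "': provide both interval bounds or neither",
         call. = FALSE)
  }
  if (role == "cost_THB_per_year" && base < 0) {
    stop("parameter '", name, "': cost must be non-negative", call. = FALSE)
  }
  if (role == "relative_risk" && base <= 0) {
    stop("parameter '", name, "': relative risk must be positive",
         call. = FALSE)
  }
  if (role == "utility_decrement" && base < 0) {
    stop("parameter '", name, "': utility decrement must be non-negative",
         call. = FALSE)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, role = role),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  int <- if (is.na(x$low)) "no interval" else
    sprintf("%g-%g", x$low, x$high)
  cat(sprintf("<parameter_spec> %s = %g (%s; %s, %s)\n",
              x$name, x$base, int, x$dist, x$role))
  invisible(x)
}

# Canonical parameter order. Sampling draws one value per parameter in this
# order, so probabilistic results are stable under refactoring.
.param_order <- c(
  "p_mi_statin", "p_stroke_statin", "p_death_mi", "p_death_stroke",
  "p_mi_ez", "p_stroke_ez",
  "log_hr_excess", "rr_death_mi", "rr_death_stroke", "rr_death_any",
  "cost_statin_annual", "cost_ez_annual",
  "cost_acs_y1", "cost_acs_y2plus",
  "cost_mi_y1", "cost_mi_y2plus",
  "cost_stroke_y1", "cost_stroke_y2plus",
  "cost_dnm_y1", "cost_dnm_y2plus",
  "u_acs", "dec_mi", "dec_stroke")

#' Base-case model parameters
#'
#' The default clinical, economic and utility inputs of the model: annual
#' event probabilities per arm (from the IMPROVE-IT trial), post-event
#' annual case-fatality probabilities (Thai registry data), the hazard
#' ratio for post-ACS excess background mortality (HR 2.0, stored as the
#' log hazard ratio 0.693), relative risks of death under ezetimibe add-on
#' therapy, annual drug and treatment costs in 2024 Thai baht, direct
#' non-medical costs, the post-ACS baseline utility and the annual utility
#' decrements after myocardial infarction and stroke. Each entry carries
#' its reported interval and probabilistic distribution family.
#'
#' @return An object of class `"cua_parameters"`: a named list of
#'   [parameter_spec()] objects in canonical order.
#' @examples
#' p <- default_parameters()
#' p$cost_ez_annual
#' @export
default_parameters <- function() {
  specs <- list(
    parameter_spec("p_mi_statin",     0.016900, 0.0152, 0.0186, "beta", "probability"),
    parameter_spec("p_stroke_statin", 0.005415, 0.0049, 0.0060, "beta", "probability"),
    parameter_spec("p_death_mi",      0.090263, 0.0812, 0.0993, "beta", "probability"),
    parameter_spec("p_death_stroke",  0.071593, 0.0644, 0.0788, "beta", "probability"),
    parameter_spec("p_mi_ez",         0.014779, 0.0133, 0.0163, "beta", "probability"),
    parameter_spec("p_stroke_ez",     0.004653, 0.0042, 0.0051, "beta", "probability"),
    parameter_spec("log_hr_excess",   0.693, 0.62, 0.76, "lognormal", "log_hazard_ratio"),
    parameter_spec("rr_death_mi",     0.840, 0.55, 1.07, "lognormal", "relative_risk"),
    parameter_spec("rr_death_stroke", 0.900, 0.84, 0.96, "lognormal", "relative_risk"),
    parameter_spec("rr_death_any",    0.990, 0.91, 1.07, "lognormal", "relative_risk"),
    parameter_spec("cost_statin_annual", 292,  234,  350, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_ez_annual",  1730, 1384, 2075, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_acs_y1",     65507, 45174, 67762, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_acs_y2plus", 39617, 27320, 40980, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_mi_y1",      148366, 102314, 153472, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_mi_y2plus",  15924, 10982, 16472, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_stroke_y1",  73440, 50645, 75967, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_stroke_y2plus", 11634, 8023, 12035, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_dnm_y1",     3730, 2572, 3858, "gamma", "cost_THB_per_year"),
    parameter_spec("cost_dnm_y2plus", 5394, 3720, 5580, "gamma", "cost_THB_per_year"),
    parameter_spec("u_acs",           0.82, 0.738, 0.902, "beta", "utility"),
    parameter_spec("dec_mi",          0.41635, 0.3747, 0.4580, "gamma", "utility_decrement"),
    parameter_spec("dec_stroke",      0.2259, 0.2033, 0.2485, "gamma", "utility_decrement"))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  as_cua_parameters(specs[.param_order])
}

as_cua_parameters <- function(specs) {
  stopifnot(is.list(specs))
  ok <- vapply(specs, inherits, logical(1), "parameter_spec")
  if (!all(ok)) stop("all entries must be parameter_spec objects", call. = FALSE)
  obj <- structure(specs, class = "cua_parameters")
  validate_parameters(obj)
  obj
}

#' Validate a parameter set against model-level invariants
#'
#' Checks, beyond the per-parameter range checks done at construction, the
#' cross-parameter constraints the model relies on: event probabilities lie
#' strictly inside (0,1); post-event utilities (baseline utility minus
#' decrement) are non-negative; and the ezetimibe-arm event probabilities do
#' not exceed their statin-arm counterparts at base case.
#'
#' @param params A `"cua_parameters"` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_parameters <- function(params) {
  need <- setdiff(.param_order, names(params))
  if (length(need)) {
    stop("missing parameter(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  b <- function(nm) params[[nm]]$base
  probs <- c("p_mi_statin", "p_stroke_statin", "p_death_mi", "p_death_stroke",
             "p_mi_ez", "p_stroke_ez")
  for (nm in probs) {
    if (b(nm) <= 0 || b(nm) >= 1) {
      stop("parameter '", nm, "': annual event probability must lie in (0,1)",
           call. = FALSE)
    }
  }
  if (b("u_acs") - b("dec_mi") < 0) {
    stop("post-MI utility u_acs - dec_mi is negative", call. = FALSE)
  }
  if (b("u_acs") - b("dec_stroke") < 0) {
    stop("post-stroke utility u_acs - dec_stroke is negative", call. = FALSE)
  }
  if (b("p_mi_ez") > b("p_mi_statin") || b("p_stroke_ez") > b("p_stroke_statin")) {
    stop("ezetimibe-arm event probabilities must not exceed statin-arm values",
         call. = FALSE)
  }
  invisible(params)
}

#' @export
print.cua_parameters <- function(x, ...) {
  cat("<cua_parameters> ", length(x), " model inputs\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate a parameter set
#'
#' Canonical flat form of a parameter set, used for audit serialisation:
#' one row per parameter with name, base value, interval bounds,
#' distribution family and role, in canonical order.
#'
#' @param x A `"cua_parameters"` object.
#' @param ... Unused.
#' @return A `data.frame` with columns `name`, `base`, `low`, `high`,
#'   `distribution`, `role`.
#' @export
as.data.frame.cua_parameters <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1), "name"),
    base = vapply(x, `[[`, numeric(1), "base"),
    low = vapply(x, `[[`, numeric(1), "low"),
    high = vapply(x, `[[`, numeric(1), "high"),
    distribution = vapply(x, `[[`, character(1), "dist"),
    role = vapply(x, `[[`, character(1), "role"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Replace the base value of one parameter
#'
#' Convenience for sensitivity analyses: returns a copy of the parameter
#' set with one base value replaced. Interval bounds and distribution are
#' left untouched; per-parameter range checks are re-applied.
#'
#' @param params A `"cua_parameters"` object.
#' @param name Parameter name.
#' @param value New base value.
#' @param validate Re-run cross-parameter validation (default `TRUE`).
#'   One-way sensitivity analysis disables it so that single-parameter
#'   excursions (e.g. a relative risk above 1) can be explored.
#' @return The modified `"cua_parameters"` object.
#' @export
set_parameter <- function(params, name, value, validate = TRUE) {
  if (!name %in% names(params)) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  old <- params[[name]]
  # re-run the constructor checks, widening the interval if the new value
  # falls outside it (the interval describes uncertainty around the original
  # base, not a hard constraint on what-if values)
  lo <- if (is.na(old$low)) NA_real_ else min(old$low, value)
  hi <- if (is.na(old$high)) NA_real_ else max(old$high, value)
  params[[name]] <- parameter_spec(old$name, value, lo, hi, old$dist, old$role)
  if (validate) validate_parameters(params)
  params
}

#' Standard error implied by a 95\% interval
#'
#' Treats a reported interval as a normal-approximation 95\% confidence
#' interval, `mean +/- 1.96 SE`, so `SE = (high - low) / (2 * 1.96)`.
#'
#' @param low,high Interval bounds, `high > low`.
#' @return The implied standard error.
#' @examples
#' se_from_interval(0.738, 0.902) # 0.0418...
#' @export
se_from_interval <- function(low, high) {
  if (any(high <= low)) stop("interval requires high > low", call. = FALSE)
  (high - low) / (2 * 1.96)
}

#' Fit a beta distribution to a point estimate and interval
#'
#' Method-of-moments fit: with mean `m = base` and the standard error
#' implied by the interval, `nu = m(1-m)/SE^2 - 1`, `alpha = m * nu`,
#' `beta = (1-m) * nu`. The fitted mean equals the base value exactly.
#'
#' @param spec A [parameter_spec()] with role probability or utility and a
#'   finite interval.
#' @return A `"distribution_fit"` list with `family = "beta"` and shape
#'   parameters `alpha`, `beta`.
#' @export
fit_beta <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  if (!spec$role %in% c("probability", "utility")) {
    stop("beta fit requires a probability or utility parameter", call. = FALSE)
  }
  m <- spec$base
  if (m <= 0 || m >= 1) stop("beta fit requires base in (0,1)", call. = FALSE)
  se <- se_from_interval(spec$low, spec$high)
  if (se^2 >= m * (1 - m)) {
    stop("parameter '", spec$name,
         "': interval too wide for a beta fit (SE^2 >= m(1-m))", call. = FALSE)
  }
  nu <- m * (1 - m) / se^2 - 1
  structure(list(family = "beta", alpha = m * nu, beta = (1 - m) * nu),
            class = "distribution_fit")
}

#' Fit a gamma distribution to a point estimate and interval
#'
#' Method-of-moments fit: `shape = (base/SE)^2`, `scale = SE^2/base`. The
#' fitted mean equals the base value exactly.
#'
#' @param spec A [parameter_spec()] with role cost or utility decrement and
#'   a finite interval; `base > 0`.
#' @return A `"distribution_fit"` list with `family = "gamma"`, `shape`,
#'   `scale`.
#' @export
fit_gamma <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  if (!spec$role %in% c("cost_THB_per_year", "utility_decrement")) {
    stop("gamma fit requires a cost or utility-decrement parameter",
         call. = FALSE)
  }
  if (spec$base <= 0) stop("gamma fit requires base > 0", call. = FALSE)
  se <- se_from_interval(spec$low, spec$high)
  structure(list(family = "gamma", shape = (spec$base / se)^2,
                 scale = se^2 / spec$base),
            class = "distribution_fit")
}

#' Fit a log-normal distribution to a point estimate and interval
#'
#' For relative risks the interval is taken as a 95\% CI on the ratio
#' scale: `meanlog = log(base)`, `sdlog = (log(high) - log(low)) / 3.92`,
#' so the fitted median equals the base value. For the log hazard ratio
#' the stored value and interval are already on the log scale, so
#' `meanlog = base` and `sdlog = (high - low) / 3.92`; the sampled hazard
#' ratio is log-normal with median `exp(base)`.
#'
#' @param spec A [parameter_spec()] with role relative risk or log hazard
#'   ratio and a finite, positive interval.
#' @return A `"distribution_fit"` list with `family = "lognormal"`,
#'   `meanlog`, `sdlog`, and `log_scale_value` (`TRUE` when the parameter
#'   itself is stored on the log scale).
#' @export
fit_lognormal <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  if (spec$role == "log_hazard_ratio") {
    return(structure(list(family = "lognormal", meanlog = spec$base,
                          sdlog = (spec$high - spec$low) / 3.92,
                          log_scale_value = TRUE),
                     class = "distribution_fit"))
  }
  if (spec$role != "relative_risk") {
    stop("log-normal fit requires a relative-risk or log-hazard-ratio ",
         "parameter", call. = FALSE)
  }
  if (spec$base <= 0 || spec$low <= 0 || spec$high <= 0) {
    stop("log-normal fit requires positive base and bounds", call. = FALSE)
  }
  structure(list(family = "lognormal", meanlog = log(spec$base),
                 sdlog = (log(spec$high) - log(spec$low)) / 3.92,
                 log_scale_value = FALSE),
            class = "distribution_fit")
}

#' Fit the probabilistic distribution declared by a parameter spec
#'
#' Dispatches to [fit_beta()], [fit_gamma()] or [fit_lognormal()] according
#' to the parameter's `dist` field; `"fixed"` parameters get a degenerate
#' fit.
#'
#' @param spec A [parameter_spec()].
#' @return A `"distribution_fit"` object.
#' @export
fit_distribution <- function(spec) {
  switch(spec$dist,
         beta = fit_beta(spec),
         gamma = fit_gamma(spec),
         lognormal = fit_lognormal(spec),
         fixed = structure(list(family = "fixed", value = spec$base),
                           class = "distribution_fit"))
}

#' One-way sensitivity range for a parameter
#'
#' Returns the reported interval when one is present. When no interval is
#' available, probabilities and utilities are varied by +/-10\% and costs
#' by +/-20\% of the base value; `"fixed"` parameters get the degenerate
#' range `(base, base)`.
#'
#' @param spec A [parameter_spec()].
#' @return Numeric vector `c(low, high)`.
#' @export
owsa_range <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  if (spec$dist == "fixed") return(c(spec$base, spec$base))
  if (!is.na(spec$low) && !is.na(spec$high)) return(c(spec$low, spec$high))
  frac <- if (spec$role == "cost_THB_per_year") 0.2 else 0.1
  spec$base * c(1 - frac, 1 + frac)
}
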