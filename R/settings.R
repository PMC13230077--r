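#' Analysis settings
#'
#' Collects the cohort and evaluation settings of the analysis: starting
#' age, annual cycle length, age horizon, discount rates, willingness-to-pay
#' threshold, perspective, number of probabilistic iterations, half-cycle
#' correction, discount timing, the THB/USD exchange rate used for
#' reporting, and the bookkeeping switches for post-event mortality,
#' first-year cost attribution and maintenance-cost accrual.
#'
#' @param start_age Cohort age at model entry, years. Default 62, the mean
#'   age of ACS patients in the Thai registry.
#' @param cycle_length Cycle length in years (the model is annual; 1).
#' @param max_age Age at which the trace is truncated. Default 100; under
#'   the default mortality assumptions less than 1\% of the cohort survives
#'   past it.
#' @param discount_rate_costs,discount_rate_outcomes Annual discount rates
#'   as fractions; 0.03 for both per Thai HTA guidance.
#' @param wtp Willingness-to-pay ceiling ratio, THB per QALY (160,000).
#' @param perspective `"societal"` (includes direct non-medical costs) or
#'   `"provider"` (direct medical costs only).
#' @param psa_iterations Monte-Carlo iterations for probabilistic
#'   sensitivity analysis (1,000).
#' @param rng_seed Integer seed for probabilistic sampling.
#' @param half_cycle Apply the half-cycle correction (trapezoidal
#'   state-time) when `TRUE`; end-of-cycle occupancy otherwise.
#' @param timing_offset Discount timing within a cycle: cycle `t` is
#'   discounted by `1/(1+r)^(t - timing_offset)`. `0.5` (mid-cycle,
#'   default) or `0` (end of cycle).
#' @param exchange_rate_thb_per_usd THB per USD for derived USD columns
#'   (2024 average, 35.2952). Reporting only; never enters the model.
#' @param post_event_mortality How the annual post-event case-fatality
#'   probability combines with age-specific background mortality in the MI
#'   and stroke states: `"event_only"` (default; the registry-derived
#'   annual case-fatality probability is the sole mortality in the state,
#'   the convention the base-case results follow), `"max"` (the larger of
#'   case fatality and HR-adjusted background mortality, so post-event
#'   mortality never falls below general-population mortality), or
#'   `"competing"` (independent-risk combination `1-(1-a)(1-b)`).
#' @param first_year_cost_basis Attribution of first-year MI/stroke costs:
#'   `"cycle1"` (default; charged on state occupancy in the first model
#'   cycle only, the convention the base-case cost ledger follows) or
#'   `"inflow"` (charged per incident event in its inflow cycle, a one-cycle
#'   tunnel).
#' @param acs_cost_states Which states accrue ongoing post-ACS maintenance
#'   cost: `"no_event_only"` (default; post-event states accrue their own
#'   maintenance costs instead) or `"all_living"`.
#' @return An object of class `"cua_settings"`.
#' @examples
#' s <- default_settings(wtp = 200000)
#' s$wtp
#' @export
default_settings <- function(start_age = 62L,
                             cycle_length = 1,
                             max_age = 100L,
                             discount_rate_costs = 0.03,
                             discount_rate_outcomes = 0.03,
                             wtp = 160000,
                             perspective = c("societal", "provider"),
                             psa_iterations = 1000L,
                             rng_seed = 1L,
                             half_cycle = TRUE,
                             timing_offset = 0.5,
                             exchange_rate_thb_per_usd = 35.2952,
                             post_event_mortality = c("event_only", "max",
                                                      "competing"),
                             first_year_cost_basis = c("cycle1", "inflow"),
                             acs_cost_states = c("no_event_only",
                                                 "all_living")) {
  perspective <- match.arg(perspective)
  post_event_mortality <- match.arg(post_event_mortality)
  first_year_cost_basis <- match.arg(first_year_cost_basis)
  acs_cost_states <- match.arg(acs_cost_states)
  s <- list(start_age = as.integer(start_age),
            cycle_length = as.numeric(cycle_length),
            max_age = as.integer(max_age),
            discount_rate_costs = discount_rate_costs,
            discount_rate_outcomes = discount_rate_outcomes,
            wtp = wtp,
            perspective = perspective,
            psa_iterations = as.integer(psa_iterations),
            rng_seed = as.integer(rng_seed),
            half_cycle = isTRUE(half_cycle),
            timing_offset = timing_offset,
            exchange_rate_thb_per_usd = exchange_rate_thb_per_usd,
            post_event_mortality = post_event_mortality,
            first_year_cost_basis = first_year_cost_basis,
            acs_cost_states = acs_cost_states)
  class(s) <- "cua_settings"
  validate_settings(s)
  s
}

#' Validate analysis settings
#'
#' @param s A `"cua_settings"` object.
#' @return `s`, invisibly; stops with an informative error otherwise.
#' @export
validate_settings <- function(s) {
  if (s$discount_rate_costs < 0 || s$discount_rate_outcomes < 0) {
    stop("discount rates must be non-negative", call. = FALSE)
  }
  if (s$psa_iterations < 1L) stop("psa_iterations must be >= 1", call. = FALSE)
  if (s$start_age >= s$max_age) stop("start_age must be below max_age",
                                     call. = FALSE)
  if (s$cycle_length <= 0) stop("cycle_length must be positive", call. = FALSE)
  if (s$wtp < 0) stop("wtp must be non-negative", call. = FALSE)
  if (s$exchange_rate_thb_per_usd <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  if (!s$timing_offset %in% c(0, 0.5)) {
    stop("timing_offset must be 0 (end of cycle) or 0.5 (mid-cycle)",
         call. = FALSE)
  }
  invisible(s)
}

#' @export
print.cua_settings <- function(x, ...) {
  cat("<cua_settings>\n")
  cat(sprintf("  cohort: age %d to %d, %g-year cycles\n",
              x$start_age, x$max_age, x$cycle_length))
  cat(sprintf("  discounting: costs %.1f%%, outcomes %.1f%% (offset %.1f)\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_outcomes,
              x$timing_offset))
  cat(sprintf("  WTP: %s THB/QALY; perspective: %s\n",
              format(x$wtp, big.mark = ","), x$perspective))
  cat(sprintf("  half-cycle correction: %s; PSA: %d iterations (seed %d)\n",
              x$half_cycle, x$psa_iterations, x$rng_seed))
  cat(sprintf("  switches: post_event_mortality=%s, first_year_cost_basis=%s, acs_cost_states=%s\n",
              x$post_event_mortality, x$first_year_cost_basis,
              x$acs_cost_states))
  invisible(x)
}

#' Convert THB to USD for reporting
#'
#' @param thb Amount in Thai baht.
#' @param settings A `"cua_settings"` object supplying the exchange rate.
#' @return Amount in USD.
#' @examples
#' to_usd(160000, default_settings()) # ~4533
#' @export
to_usd <- function(thb, settings = default_settings()) {
  thb / settings$exchange_rate_thb_per_usd
}
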