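#' Per-cycle discount factors
#'
#' Cycle `t` (1-based) is discounted by `1/(1+rate)^(t - timing_offset)`;
#' the default mid-cycle offset 0.5 pairs with the half-cycle-corrected
#' state-time, `timing_offset = 0` gives conventional end-of-cycle
#' discounting.
#'
#' @param cycles Integer vector of cycle indices, `>= 1`.
#' @param rate Annual discount rate as a fraction, `>= 0`.
#' @param timing_offset 0 (end of cycle) or 0.5 (mid-cycle).
#' @return Discount factor(s).
#' @examples
#' discount_factor(3, 0.03, timing_offset = 0) # 1/1.03^3
#' @export
discount_factor <- function(cycles, rate, timing_offset = 0.5) {
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  if (any(cycles < 1)) stop("cycles are 1-based", call. = FALSE)
  1 / (1 + rate)^(cycles - timing_offset)
}

ledger_categories <- c("drug_statin", "drug_ez", "acs_y1", "acs_y2plus",
                       "mi_y1", "mi_y2plus", "stroke_y1", "stroke_y2plus",
                       "dnm_y1", "dnm_y2plus")

#' Accumulate the discounted cost ledger for one arm
#'
#' Turns a cohort trace into discounted costs by category (2024 THB):
#' \itemize{
#'   \item Drug costs: annual price times discounted living state-time;
#'     statin in both arms, ezetimibe only in the add-on arm. This makes
#'     the statin ledger entry exactly `annual price x discounted
#'     life-years`.
#'   \item Post-ACS treatment costs: the first-year cost applies to
#'     no-event state-time in cycle 1, the maintenance cost to no-event
#'     state-time from cycle 2 on (or to all living state-time if
#'     `acs_cost_states = "all_living"`).
#'   \item MI and stroke costs: under the default `"cycle1"` attribution,
#'     the first-year cost applies to the state's occupancy time in cycle
#'     1 and the maintenance cost to its occupancy time thereafter. Under
#'     `"inflow"`, the first-year cost is charged once per incident event
#'     in its inflow cycle (a one-cycle tunnel) and maintenance applies to
#'     continuing occupants only.
#'   \item Direct non-medical costs: first-year value on living state-time
#'     in cycle 1, the subsequent-year value on living state-time
#'     thereafter. Counted only under the societal perspective.
#' }
#'
#' @param trace A `"cohort_trace"`.
#' @param params A `"cua_parameters"` object.
#' @param settings A `"cua_settings"` object.
#' @return An object of class `"cost_ledger"`: named numeric vector of
#'   category totals with attributes `direct_medical` and
#'   `societal_total`.
#' @export
accumulate_costs <- function(trace, params, settings) {
  st <- state_time(trace, settings$half_cycle)
  n <- nrow(st)
  disc <- discount_factor(seq_len(n), settings$discount_rate_costs,
                          settings$timing_offset)
  b <- function(nm) params[[nm]]$base
  living <- st[, "no_event"] + st[, "mi"] + st[, "stroke"]
  first <- c(1, rep(0, n - 1L))
  later <- 1 - first

  led <- stats::setNames(numeric(length(ledger_categories)),
                         ledger_categories)
  led["drug_statin"] <- b("cost_statin_annual") * sum(disc * living)
  led["drug_ez"] <- if (trace$arm == "ezetimibe_plus_statin") {
    b("cost_ez_annual") * sum(disc * living)
  } else 0

  acs_basis <- if (settings$acs_cost_states == "all_living") living else
    st[, "no_event"]
  led["acs_y1"] <- b("cost_acs_y1") * sum(disc * acs_basis * first)
  led["acs_y2plus"] <- b("cost_acs_y2plus") * sum(disc * acs_basis * later)

  if (settings$first_year_cost_basis == "cycle1") {
    led["mi_y1"] <- b("cost_mi_y1") * sum(disc * st[, "mi"] * first)
    led["mi_y2plus"] <- b("cost_mi_y2plus") * sum(disc * st[, "mi"] * later)
    led["stroke_y1"] <- b("cost_stroke_y1") *
      sum(disc * st[, "stroke"] * first)
    led["stroke_y2plus"] <- b("cost_stroke_y2plus") *
      sum(disc * st[, "stroke"] * later)
  } else {
    # one-cycle tunnel: first-year cost per incident event; maintenance on
    # the state-time of occupants past their inflow cycle
    occ <- trace$occupancy
    cont_mi <- (occ[seq_len(n), "mi"] +
                  pmax(occ[seq_len(n) + 1L, "mi"] - trace$new_mi, 0)) / 2
    cont_stroke <- (occ[seq_len(n), "stroke"] +
                      pmax(occ[seq_len(n) + 1L, "stroke"] - trace$new_stroke,
                           0)) / 2
    if (!settings$half_cycle) {
      cont_mi <- pmax(occ[seq_len(n) + 1L, "mi"] - trace$new_mi, 0)
      cont_stroke <- pmax(occ[seq_len(n) + 1L, "stroke"] - trace$new_stroke, 0)
    }
    led["mi_y1"] <- b("cost_mi_y1") * sum(disc * trace$new_mi)
    led["mi_y2plus"] <- b("cost_mi_y2plus") * sum(disc * cont_mi)
    led["stroke_y1"] <- b("cost_stroke_y1") * sum(disc * trace$new_stroke)
    led["stroke_y2plus"] <- b("cost_stroke_y2plus") * sum(disc * cont_stroke)
  }

  led["dnm_y1"] <- b("cost_dnm_y1") * sum(disc * living * first)
  led["dnm_y2plus"] <- b("cost_dnm_y2plus") * sum(disc * living * later)

  dnm <- unname(led["dnm_y1"] + led["dnm_y2plus"])
  structure(led,
            direct_medical = sum(led) - dnm,
            societal_total = sum(led),
            class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("<cost_ledger> discounted THB by category\n")
  print(round(unclass(x)[seq_along(x)]))
  cat(sprintf("direct medical: %.0f; societal total: %.0f\n",
              attr(x, "direct_medical"), attr(x, "societal_total")))
  invisible(x)
}

#' Total cost of a ledger under a perspective
#'
#' @param ledger A `"cost_ledger"`.
#' @param perspective `"societal"` (includes direct non-medical costs) or
#'   `"provider"`.
#' @return Total discounted cost, THB.
#' @export
ledger_total <- function(ledger, perspective = c("societal", "provider")) {
  perspective <- match.arg(perspective)
  if (perspective == "societal") attr(ledger, "societal_total") else
    attr(ledger, "direct_medical")
}

#' Accumulate discounted life-years and QALYs for one arm
#'
#' State utilities are `u_acs` in the no-further-event state,
#' `u_acs - dec_mi` after MI, `u_acs - dec_stroke` after stroke, and 0 in
#' death. QALYs are the discounted sum of half-cycle state-time weighted
#' by state utility; life-years use weight 1 for every living state.
#'
#' @inheritParams accumulate_costs
#' @return List with `life_years` and `qalys` (both discounted at
#'   `settings$discount_rate_outcomes`).
#' @export
accumulate_qalys <- function(trace, params, settings) {
  st <- state_time(trace, settings$half_cycle)
  disc <- discount_factor(seq_len(nrow(st)), settings$discount_rate_outcomes,
                          settings$timing_offset)
  u <- c(no_event = params$u_acs$base,
         mi = params$u_acs$base - params$dec_mi$base,
         stroke = params$u_acs$base - params$dec_stroke$base)
  if (any(u < 0)) {
    stop("validation error: a post-event state utility is negative",
         call. = FALSE)
  }
  living <- st[, "no_event"] + st[, "mi"] + st[, "stroke"]
  list(life_years = sum(disc * living),
       qalys = sum(disc * (st[, "no_event"] * u["no_event"] +
                             st[, "mi"] * u["mi"] +
                             st[, "stroke"] * u["stroke"])))
}

#' Evaluate one strategy arm end-to-end
#'
#' Runs the cohort trace and accumulates the discounted cost ledger,
#' life-years and QALYs for one arm.
#'
#' @inheritParams transition_matrix
#' @return An object of class `"arm_outcome"`: list with `arm`, `trace`,
#'   `ledger`, `life_years`, `qalys`.
#' @export
arm_outcome <- function(params, settings, lt, arm) {
  trace <- run_cohort(params, settings, lt, arm)
  led <- accumulate_costs(trace, params, settings)
  eff <- accumulate_qalys(trace, params, settings)
  structure(list(arm = trace$arm, trace = trace, ledger = led,
                 life_years = eff$life_years, qalys = eff$qalys),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s: cost (societal) %.0f THB, LYs %.4f, QALYs %.4f\n",
              x$arm, attr(x$ledger, "societal_total"), x$life_years, x$qalys))
  invisible(x)
}

#' Incremental cost-effectiveness of one arm over another
#'
#' Computes incremental discounted cost (under the requested perspective),
#' life-years and QALYs of `alt` over `ref`, the ICER per QALY and per
#' life-year, a dominance flag where a ratio would be undefined or
#' misleading, and whether the intervention is cost-effective at the
#' willingness-to-pay threshold (dominant, or ICER at or below the
#' threshold).
#'
#' @param ref,alt `"arm_outcome"` objects computed under identical
#'   settings (`ref` is the comparator).
#' @param settings A `"cua_settings"` object.
#' @param perspective Cost perspective; defaults to `settings$perspective`.
#' @return An object of class `"icer_result"`.
#' @export
compute_icer <- function(ref, alt, settings,
                         perspective = settings$perspective) {
  perspective <- match.arg(perspective, c("societal", "provider"))
  dc <- ledger_total(alt$ledger, perspective) -
    ledger_total(ref$ledger, perspective)
  dly <- alt$life_years - ref$life_years
  dq <- alt$qalys - ref$qalys
  flag <- if (dq > 0 && dc < 0) "dominant"
  else if (dq < 0 && dc > 0) "dominated"
  else if (dq == 0) "zero-effect"
  else NA_character_
  icer_q <- if (is.na(flag)) dc / dq else NA_real_
  icer_ly <- if (dly != 0) dc / dly else NA_real_
  ce <- identical(flag, "dominant") ||
    (is.na(flag) && dq > 0 && icer_q <= settings$wtp)
  structure(list(perspective = perspective,
                 delta_cost = dc, delta_ly = dly, delta_qaly = dq,
                 icer_per_qaly = icer_q, icer_per_ly = icer_ly,
                 dominance = flag,
                 wtp = settings$wtp,
                 cost_effective_at_wtp = ce,
                 exchange_rate = settings$exchange_rate_thb_per_usd),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> %s perspective\n", x$perspective))
  cat(sprintf("  incremental cost: %.0f THB (%.1f USD); QALYs: %+.4f; LYs: %+.4f\n",
              x$delta_cost, x$delta_cost / x$exchange_rate, x$delta_qaly,
              x$delta_ly))
  if (!is.na(x$dominance)) {
    cat("  result:", x$dominance, "\n")
  } else {
    cat(sprintf("  ICER: %.0f THB/QALY (%.1f USD/QALY); %.0f THB/LY\n",
                x$icer_per_qaly, x$icer_per_qaly / x$exchange_rate,
                x$icer_per_ly))
  }
  cat(sprintf("  cost-effective at %s THB/QALY: %s\n",
              format(x$wtp, big.mark = ","), x$cost_effective_at_wtp))
  invisible(x)
}
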