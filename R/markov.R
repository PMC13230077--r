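#' Model health states and strategy arms
#'
#' The model has four mutually exclusive health states. Patients enter in
#' `no_event` (alive after the index ACS with no further event), may
#' transition to non-fatal `mi` or non-fatal `stroke`, remain there until
#' death, or die (`death`, absorbing). No MI-stroke crossover, recurrent
#' events or concurrent events are modelled.
#'
#' @format `cua_states` is a character vector of the four state names;
#'   `cua_arms` names the two strategies.
#' @name model_structure
NULL

#' @rdname model_structure
#' @export
cua_states <- c("no_event", "mi", "stroke", "death")

#' @rdname model_structure
#' @export
cua_arms <- c("statin_alone", "ezetimibe_plus_statin")

# Arm-specific inputs: event probabilities and death relative risks.
# The ezetimibe relative risks apply to, respectively, the MI-state death
# probability, the stroke-state death probability, and the no-event-state
# background death probability; the statin arm is the reference (RR 1).
arm_inputs <- function(params, arm) {
  arm <- match.arg(arm, cua_arms)
  b <- function(nm) params[[nm]]$base
  if (arm == "statin_alone") {
    list(p_mi = b("p_mi_statin"), p_stroke = b("p_stroke_statin"),
         rr_mi = 1, rr_stroke = 1, rr_any = 1)
  } else {
    list(p_mi = b("p_mi_ez"), p_stroke = b("p_stroke_ez"),
         rr_mi = b("rr_death_mi"), rr_stroke = b("rr_death_stroke"),
         rr_any = b("rr_death_any"))
  }
}

# Combine the event-specific annual death probability with background
# mortality in a post-event state, per the configured convention.
combine_mortality <- function(p_event, p_bg, mode) {
  switch(mode,
         event_only = p_event,
         max = pmax(p_event, p_bg),
         competing = 1 - (1 - p_event) * (1 - p_bg),
         stop("unknown post_event_mortality mode: ", mode, call. = FALSE))
}

#' Build the one-cycle transition matrix for one arm at one age
#'
#' Rows and columns are ordered `no_event`, `mi`, `stroke`, `death`. The
#' `no_event` row carries the arm's annual MI and stroke probabilities and
#' the age-specific background death probability (rate scaled by the
#' post-ACS excess hazard ratio `exp(log_hr_excess)`, converted with
#' `p = 1 - exp(-r)`, and multiplied by the all-cause relative risk in the
#' ezetimibe arm). Post-event rows combine the annual case-fatality
#' probability (scaled by the arm's relative risk) with HR-adjusted
#' background mortality according to `settings$post_event_mortality`.
#' The death row is absorbing; MI-stroke crossovers are structurally zero.
#'
#' @param params A `"cua_parameters"` object.
#' @param settings A `"cua_settings"` object.
#' @param lt A `"life_table"`.
#' @param arm `"statin_alone"` or `"ezetimibe_plus_statin"`.
#' @param age Age at the start of the cycle.
#' @return A 4x4 row-stochastic matrix with dimnames `cua_states`.
#' @export
transition_matrix <- function(params, settings, lt, arm, age) {
  arm <- match.arg(arm, cua_arms)
  inp <- arm_inputs(params, arm)
  hr <- exp(params$log_hr_excess$base)
  p_bg <- rate_to_prob(adjust_rate_by_hr(mortality_rate_at(lt, age), hr), 1)
  p_ne_death <- apply_rr(p_bg, inp$rr_any)
  leave <- inp$p_mi + inp$p_stroke + p_ne_death
  if (leave > 1) {
    stop("infeasible parameters: no_event row probabilities sum to ",
         format(leave), " (> 1) at age ", age, call. = FALSE)
  }
  p_mi_death <- combine_mortality(apply_rr(params$p_death_mi$base, inp$rr_mi),
                                  p_bg, settings$post_event_mortality)
  p_stroke_death <- combine_mortality(
    apply_rr(params$p_death_stroke$base, inp$rr_stroke),
    p_bg, settings$post_event_mortality)
  if (p_mi_death > 1 || p_stroke_death > 1) {
    stop("infeasible parameters: post-event death probability exceeds 1 ",
         "at age ", age, call. = FALSE)
  }
  m <- matrix(0, 4, 4, dimnames = list(cua_states, cua_states))
  m["no_event", ] <- c(1 - leave, inp$p_mi, inp$p_stroke, p_ne_death)
  m["mi", ] <- c(0, 1 - p_mi_death, 0, p_mi_death)
  m["stroke", ] <- c(0, 0, 1 - p_stroke_death, p_stroke_death)
  m["death", ] <- c(0, 0, 0, 1)
  m
}

#' Run the cohort trace for one strategy arm
#'
#' Starts the full cohort in `no_event` at `settings$start_age` and
#' propagates it through annual cycles to `settings$max_age`, rebuilding
#' the transition matrix each cycle from the age-specific background
#' mortality. New-event inflows into the MI and stroke states are recorded
#' per cycle (they carry the first-year event costs under the inflow
#' attribution convention). Deterministic.
#'
#' @inheritParams transition_matrix
#' @return An object of class `"cohort_trace"`: list with `occupancy`
#'   (`(n_cycles + 1) x 4` matrix, row 0 = `(1, 0, 0, 0)`), `ages` (age at
#'   the start of each cycle), `new_mi`, `new_stroke` (per-cycle inflows)
#'   and `arm`.
#' @examples
#' tr <- run_cohort(default_parameters(), default_settings(),
#'                  synthetic_life_table(), "statin_alone")
#' utils::head(as.data.frame(tr))
#' @export
run_cohort <- function(params, settings, lt, arm) {
  arm <- match.arg(arm, cua_arms)
  n <- settings$max_age - settings$start_age
  ages <- settings$start_age + seq_len(n) - 1L
  occ <- matrix(0, n + 1L, 4L, dimnames = list(0:n, cua_states))
  occ[1L, "no_event"] <- 1
  new_mi <- new_stroke <- numeric(n)
  for (t in seq_len(n)) {
    m <- transition_matrix(params, settings, lt, arm, ages[t])
    prev <- occ[t, ]
    occ[t + 1L, ] <- prev %*% m
    new_mi[t] <- prev["no_event"] * m["no_event", "mi"]
    new_stroke[t] <- prev["no_event"] * m["no_event", "stroke"]
  }
  structure(list(occupancy = occ, ages = ages, new_mi = new_mi,
                 new_stroke = new_stroke, arm = arm),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- length(x$ages)
  cat(sprintf("<cohort_trace> %s: %d annual cycles (ages %d-%d), dead at end: %.4f\n",
              x$arm, n, x$ages[1L], x$ages[n] + 1L,
              x$occupancy[n + 1L, "death"]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  n <- length(x$ages)
  data.frame(cycle = 0:n,
             age = c(x$ages, x$ages[n] + 1L),
             no_event = x$occupancy[, "no_event"],
             mi = x$occupancy[, "mi"],
             stroke = x$occupancy[, "stroke"],
             death = x$occupancy[, "death"],
             new_mi = c(NA, x$new_mi),
             new_stroke = c(NA, x$new_stroke),
             row.names = NULL)
}

#' Per-cycle state-time with optional half-cycle correction
#'
#' Time (in years) attributed to each living state during each cycle.
#' With the half-cycle correction (the default) cycle `t` is credited the
#' trapezoid `(occupancy[t-1, s] + occupancy[t, s]) / 2`, reflecting that
#' transitions occur on average mid-cycle; without it, end-of-cycle
#' occupancy is used. The death state accrues no time.
#'
#' @param trace A `"cohort_trace"`.
#' @param half_cycle Logical; apply the trapezoidal correction.
#' @return An `n_cycles x 4` matrix of state-years (death column zero).
#' @export
state_time <- function(trace, half_cycle = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy
  n <- nrow(occ) - 1L
  st <- if (isTRUE(half_cycle)) {
    (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(n) + 1L, , drop = FALSE]
  }
  st[, "death"] <- 0
  rownames(st) <- seq_len(n)
  st
}
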