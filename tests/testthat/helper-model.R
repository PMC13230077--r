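# Shared fixtures, built in code.

# Flat life table: constant annual mortality rate over a wide age span.
flat_life_table <- function(rate, age_min = 62L, age_max = 162L) {
  life_table(seq.int(age_min, age_max), rep(rate, age_max - age_min + 1L))
}

# Parameter set with events and adjustments switched off (background
# mortality only): useful for closed-form survival oracles. Bypasses the
# base-case cross-parameter validation on purpose.
null_event_parameters <- function(params = default_parameters()) {
  for (nm in c("p_mi_statin", "p_stroke_statin", "p_mi_ez", "p_stroke_ez")) {
    params[[nm]]$base <- 0
  }
  params$log_hr_excess$base <- 0       # HR = 1
  for (nm in c("rr_death_mi", "rr_death_stroke", "rr_death_any")) {
    params[[nm]]$base <- 1
  }
  params
}

# Minimal stand-in arm outcome for ICER arithmetic tests.
fake_outcome <- function(cost_societal, cost_provider, ly, qaly,
                         arm = "statin_alone") {
  led <- structure(stats::setNames(numeric(length(ezcua:::ledger_categories)),
                                   ezcua:::ledger_categories),
                   direct_medical = cost_provider,
                   societal_total = cost_societal,
                   class = "cost_ledger")
  structure(list(arm = arm, trace = NULL, ledger = led,
                 life_years = ly, qalys = qaly),
            class = "arm_outcome")
}

# Hand-built probabilistic draw set for quadrant/CEAC arithmetic tests.
fake_psa <- function(delta_cost, delta_qaly, wtp = 160000) {
  out <- data.frame(iteration = seq_along(delta_cost),
                    delta_cost_thb = delta_cost,
                    delta_cost_societal_thb = delta_cost,
                    delta_cost_provider_thb = delta_cost,
                    delta_qaly = delta_qaly,
                    delta_ly = delta_qaly)
  attr(out, "seed") <- 0L
  attr(out, "perspective") <- "societal"
  attr(out, "wtp") <- wtp
  attr(out, "n_resampled") <- 0L
  class(out) <- c("cua_psa", "data.frame")
  out
}

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "ezcua")
}

# Optional data-present tier: a user-supplied national life table of
# age-specific mortality rates enables the printed-value reproduction
# checks. Absent by default (the file is not shipped).
national_life_table_path <- function() {
  testthat::test_path("thai_asmr.csv")
}
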