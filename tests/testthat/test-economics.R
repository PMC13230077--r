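test_that("discount factors follow the timing convention", {
  expect_identical(discount_factor(1, 0, timing_offset = 0), 1)
  expect_equal(discount_factor(3, 0.03, timing_offset = 0), 0.915142,
               tolerance = 1e-6)
  expect_equal(discount_factor(1, 0.03, timing_offset = 0.5),
               1 / 1.03^0.5, tolerance = 1e-12)
  f <- discount_factor(1:50, 0.03)
  expect_true(all(diff(f) < 0))
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("drug cost equals annual price times discounted life-years", {
  params <- default_parameters()
  settings <- default_settings()
  lt <- synthetic_life_table()
  for (arm in cua_arms) {
    out <- arm_outcome(params, settings, lt, arm)
    expect_equal(unclass(out$ledger)[["drug_statin"]],
                 292 * out$life_years, tolerance = 1e-9, info = arm)
  }
  ez <- arm_outcome(params, settings, lt, "ezetimibe_plus_statin")
  expect_equal(unclass(ez$ledger)[["drug_ez"]], 1730 * ez$life_years,
               tolerance = 1e-9)
  st <- arm_outcome(params, settings, lt, "statin_alone")
  expect_identical(unclass(st$ledger)[["drug_ez"]], 0)
})

test_that("zero unit costs give an identically zero ledger", {
  params <- default_parameters()
  for (nm in grep("^cost_", names(params), value = TRUE)) {
    params[[nm]]$base <- 0
  }
  out <- arm_outcome(params, default_settings(), synthetic_life_table(),
                     "ezetimibe_plus_statin")
  expect_true(all(unclass(out$ledger) == 0))
  expect_identical(attr(out$ledger, "societal_total"), 0)
})

test_that("ledger categories are additive and perspective-consistent", {
  fit <- cua_model()
  for (arm in names(fit$arms)) {
    led <- fit$arms[[arm]]$ledger
    v <- unclass(led)
    expect_equal(attr(led, "societal_total"), sum(v), tolerance = 1e-6)
    expect_equal(attr(led, "direct_medical"),
                 sum(v) - v[["dnm_y1"]] - v[["dnm_y2plus"]],
                 tolerance = 1e-6)
    expect_true(all(v >= 0))
  }
  # societal increment exceeds provider increment by the non-medical delta
  soc <- fit$icer$societal
  prov <- fit$icer$provider
  expect_gte(soc$delta_cost, prov$delta_cost)
  expect_equal(soc$delta_qaly, prov$delta_qaly, tolerance = 1e-12)
  expect_equal(soc$delta_ly, prov$delta_ly, tolerance = 1e-12)
})

test_that("first-year cost attribution conventions differ as designed", {
  params <- default_parameters()
  lt <- synthetic_life_table()
  s_cyc <- default_settings(first_year_cost_basis = "cycle1")
  s_inf <- default_settings(first_year_cost_basis = "inflow")
  tr <- run_cohort(params, s_cyc, lt, "statin_alone")
  led_cyc <- accumulate_costs(tr, params, s_cyc)
  led_inf <- accumulate_costs(tr, params, s_inf)
  # cycle-1 attribution charges first-year MI cost only on cycle-1 occupancy
  disc1 <- discount_factor(1, 0.03, s_cyc$timing_offset)
  st1 <- state_time(tr, TRUE)[1, "mi"]
  expect_equal(unclass(led_cyc)[["mi_y1"]], 148366 * st1 * disc1,
               tolerance = 1e-9)
  # inflow attribution charges it once per incident event, so much more
  expect_gt(unclass(led_inf)[["mi_y1"]], 5 * unclass(led_cyc)[["mi_y1"]])
  # ACS costs do not depend on the switch (entry event is at cycle 1)
  expect_equal(unclass(led_inf)[["acs_y1"]], unclass(led_cyc)[["acs_y1"]],
               tolerance = 1e-12)
})

test_that("discounting strictly lowers totals against the undiscounted run", {
  params <- default_parameters()
  lt <- synthetic_life_table()
  d3 <- arm_outcome(params, default_settings(), lt, "statin_alone")
  d0 <- arm_outcome(params, default_settings(discount_rate_costs = 0,
                                             discount_rate_outcomes = 0),
                    lt, "statin_alone")
  expect_lt(attr(d3$ledger, "societal_total"),
            attr(d0$ledger, "societal_total"))
  expect_lt(d3$life_years, d0$life_years)
  expect_lt(d3$qalys, d0$qalys)
  # discounted life-years never exceed the undiscounted life expectancy
  expect_lte(d3$life_years, d0$life_years)
})

test_that("QALYs apply state utilities to half-cycle state-time", {
  # cohort pinned in the no-event state for one undiscounted cycle
  params <- null_event_parameters()
  lt <- flat_life_table(0)
  s <- default_settings(max_age = 63, discount_rate_outcomes = 0,
                        discount_rate_costs = 0)
  out <- arm_outcome(params, s, lt, "statin_alone")
  expect_equal(out$qalys, 0.82, tolerance = 1e-12)
  expect_equal(out$life_years, 1, tolerance = 1e-12)
  # negative post-event utility is a validation error
  bad <- default_parameters()
  bad$u_acs$base <- 0.3
  tr <- run_cohort(bad, default_settings(), synthetic_life_table(),
                   "statin_alone")
  expect_error(accumulate_qalys(tr, bad, default_settings()), "negative")
})

test_that("constant-mortality QALYs match the closed-form geometric series", {
  q <- 0.25
  params <- null_event_parameters()
  lt <- flat_life_table(prob_to_rate(q))
  s <- default_settings()
  out <- arm_outcome(params, s, lt, "statin_alone")
  t <- seq_len(s$max_age - s$start_age)
  surv <- (1 - q)^t
  trap <- (c(1, surv[-length(surv)]) + surv) / 2
  disc <- 1 / 1.03^(t - 0.5)
  expect_equal(out$life_years, sum(disc * trap), tolerance = 1e-12)
  expect_equal(out$qalys, 0.82 * sum(disc * trap), tolerance = 1e-12)
  # and QALYs never exceed the utility ceiling times life-years
  expect_lte(out$qalys, 0.82 * out$life_years + 1e-12)
})

test_that("ICER arithmetic handles ratios, dominance and thresholds", {
  s <- default_settings()
  ref <- fake_outcome(489774, 430287, 11.3216, 8.5772)
  alt <- fake_outcome(489774 + 31470, 430287 + 30178, 11.5612, 8.5772 + 0.2026,
                      arm = "ezetimibe_plus_statin")
  soc <- compute_icer(ref, alt, s, "societal")
  expect_equal(soc$icer_per_qaly, 31470 / 0.2026, tolerance = 1e-9)
  expect_equal(soc$icer_per_qaly, 155331, tolerance = 1e-4)
  expect_true(soc$cost_effective_at_wtp)
  prov <- compute_icer(ref, alt, s, "provider")
  expect_equal(prov$icer_per_qaly, 30178 / 0.2026, tolerance = 1e-9)
  expect_equal(prov$icer_per_qaly, 148953, tolerance = 1e-4)
  expect_equal(prov$icer_per_ly, 30178 / 0.2396, tolerance = 1e-9)

  dominant <- compute_icer(ref, fake_outcome(489773, 430286, 11.4, 8.6777),
                           s, "societal")
  expect_identical(dominant$dominance, "dominant")
  expect_true(dominant$cost_effective_at_wtp)
  dominated <- compute_icer(ref, fake_outcome(489775, 430288, 11.3, 8.5),
                            s, "societal")
  expect_identical(dominated$dominance, "dominated")
  expect_false(dominated$cost_effective_at_wtp)
  zero <- compute_icer(ref, fake_outcome(489775, 430288, 11.3216, 8.5772),
                       s, "societal")
  expect_identical(zero$dominance, "zero-effect")
  expect_false(zero$cost_effective_at_wtp)
})

test_that("identical arms give null increments and the zero-effect flag", {
  params <- default_parameters()
  # make the add-on arm clinically identical to the comparator
  params$p_mi_ez$base <- params$p_mi_statin$base
  params$p_stroke_ez$base <- params$p_stroke_statin$base
  for (nm in c("rr_death_mi", "rr_death_stroke", "rr_death_any")) {
    params[[nm]]$base <- 1
  }
  params$cost_ez_annual$base <- 0
  fit <- cua_model(params)
  ic <- fit$icer$societal
  expect_equal(ic$delta_cost, 0, tolerance = 1e-9)
  expect_equal(ic$delta_qaly, 0, tolerance = 1e-12)
  expect_identical(ic$dominance, "zero-effect")
})

test_that("the ICER rises strictly with the ezetimibe price", {
  params <- default_parameters()
  lt <- synthetic_life_table()
  s <- default_settings()
  icers <- vapply(c(1000, 1730, 2500), function(price) {
    fit <- cua_model(set_parameter(params, "cost_ez_annual", price), s, lt)
    fit$icer$societal$icer_per_qaly
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("currency conversion uses the fixed reporting rate", {
  s <- default_settings()
  expect_equal(to_usd(160000, s), 4533, tolerance = 1e-4)
  expect_identical(to_usd(0, s), 0)
  expect_equal(to_usd(35.2952, s), 1.0, tolerance = 1e-12)
})
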