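test_that("packaged defaults carry the base-case inputs and pass validation", {
  p <- default_parameters()
  expect_s3_class(p, "cua_parameters")
  expect_identical(p$p_mi_statin$base, 0.016900)
  expect_identical(p$cost_ez_annual$base, 1730)
  expect_identical(p$log_hr_excess$base, 0.693)
  expect_identical(p$u_acs$base, 0.82)
  expect_silent(validate_parameters(p))
  # add-on therapy never increases event risk at base case
  expect_lte(p$p_mi_ez$base, p$p_mi_statin$base)
  expect_lte(p$p_stroke_ez$base, p$p_stroke_statin$base)
})

test_that("parameter construction rejects invalid inputs", {
  expect_error(parameter_spec("u_bad", 1.2, role = "utility"), "\\[0,1\\]")
  expect_error(parameter_spec("p", 0.5, 0.6, 0.7, "beta", "probability"),
               "low <= base <= high")
  expect_error(parameter_spec("c", -5, role = "cost_THB_per_year"),
               "non-negative")
  p <- default_parameters()
  p$dec_mi$base <- 0.9  # exceeds u_acs
  expect_error(validate_parameters(p), "negative")
})

test_that("config loading fills defaults, applies overrides, validates", {
  cfg <- load_config(default_config_path())
  expect_identical(cfg$parameters$p_mi_statin$base, 0.016900)
  expect_identical(cfg$parameters$cost_ez_annual$base, 1730)
  expect_equal(cfg$settings$wtp, 160000)
  expect_identical(cfg$settings$start_age, 62L)
  # annual drug costs derive from the daily prices recorded in metadata
  expect_equal(cfg$metadata$statin_daily_cost_thb * 365, 292)
  expect_equal(round(cfg$metadata$ezetimibe_daily_cost_thb * 365), 1730)

  ov <- tempfile(fileext = ".yaml")
  writeLines(c("settings:", "  wtp: 200000"), ov)
  cfg2 <- load_config(ov)
  expect_equal(cfg2$settings$wtp, 200000)
  expect_identical(cfg2$settings$start_age, 62L)
  expect_identical(cfg2$parameters$p_mi_statin$base, 0.016900)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  u_acs: {base: 1.2}"), bad)
  expect_error(load_config(bad), "\\[0,1\\]")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  u_acs: {low: 0.7}"), bad2)
  expect_error(load_config(bad2), "base")
  bad3 <- tempfile(fileext = ".yaml")
  writeLines(c("settings:", "  wttp: 1"), bad3)
  expect_error(load_config(bad3), "wttp")
})

test_that("canonical serialisation round-trips byte-identically", {
  cfg <- load_config(default_config_path())
  f1 <- tempfile(); f2 <- tempfile()
  write_parameters_csv(cfg$parameters, f1)
  reparsed <- utils::read.csv(f1)
  expect_identical(reparsed$name, names(cfg$parameters))
  expect_equal(reparsed$base,
               unname(vapply(cfg$parameters, `[[`, numeric(1), "base")))
  # re-serialising the reloaded set reproduces the bytes exactly
  write_parameters_csv(load_config(default_config_path())$parameters, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("interval-implied standard errors match hand-computed values", {
  expect_equal(se_from_interval(0.738, 0.902), 0.164 / 3.92,
               tolerance = 1e-12)
  expect_equal(se_from_interval(1384, 2075), 691 / 3.92, tolerance = 1e-12)
  x <- 2.7
  expect_equal(se_from_interval(x, x + 3.92), 1.0, tolerance = 1e-12)
  expect_error(se_from_interval(1, 1), "high > low")
})

test_that("beta fit matches moments worked by hand and preserves the mean", {
  p <- default_parameters()
  f <- fit_beta(p$u_acs)
  # nu = m(1-m)/SE^2 - 1 with SE = 0.164/3.92, worked independently
  se <- 0.164 / 3.92
  nu <- 0.82 * 0.18 / se^2 - 1
  expect_equal(f$alpha, 0.82 * nu, tolerance = 1e-12)
  expect_equal(f$beta, 0.18 * nu, tolerance = 1e-12)
  expect_equal(f$alpha, 68.33, tolerance = 1e-4)
  expect_equal(f$beta, 15.00, tolerance = 1e-3)
  expect_equal(f$alpha / (f$alpha + f$beta), 0.82, tolerance = 1e-9)
  # symmetric interval around 0.5 gives alpha = beta
  sym <- parameter_spec("sym", 0.5, 0.4, 0.6, "beta", "probability")
  fs <- fit_beta(sym)
  expect_equal(fs$alpha, fs$beta, tolerance = 1e-12)
  # infeasible moments are refused
  wide <- parameter_spec("wide", 0.5, -1, 2, "beta", "probability")
  expect_error(fit_beta(wide), "too wide")
})

test_that("gamma fit matches moments worked by hand and preserves the mean", {
  p <- default_parameters()
  f <- fit_gamma(p$cost_ez_annual)
  se <- 691 / 3.92
  expect_equal(f$shape, (1730 / se)^2, tolerance = 1e-12)
  expect_equal(f$scale, se^2 / 1730, tolerance = 1e-12)
  expect_equal(f$shape, 96.32, tolerance = 1e-4)
  expect_equal(f$scale, 17.96, tolerance = 1e-4)
  expect_equal(f$shape * f$scale, 1730, tolerance = 1e-9)
  fd <- fit_gamma(p$dec_mi)
  expect_equal(fd$shape * fd$scale, 0.41635, tolerance = 1e-9)
})

test_that("log-normal fit is median-preserving with log-range SD", {
  p <- default_parameters()
  f <- fit_lognormal(p$rr_death_mi)
  expect_equal(f$meanlog, log(0.84), tolerance = 1e-12)
  expect_equal(f$sdlog, (log(1.07) - log(0.55)) / 3.92, tolerance = 1e-12)
  expect_equal(f$sdlog, 0.16977, tolerance = 1e-4)
  expect_equal(exp(f$meanlog), 0.84, tolerance = 1e-12)  # median = base
  fa <- fit_lognormal(p$rr_death_any)
  expect_equal(fa$sdlog, 0.04131, tolerance = 1e-3)
  # base 1 with a (1/k, k) interval centres the log scale at 0
  sym <- parameter_spec("rr1", 1, 1 / 1.3, 1.3, "lognormal", "relative_risk")
  expect_equal(fit_lognormal(sym)$meanlog, 0, tolerance = 1e-12)
  # the excess-mortality parameter is fitted on its native log scale
  fh <- fit_lognormal(p$log_hr_excess)
  expect_true(fh$log_scale_value)
  expect_equal(fh$meanlog, 0.693, tolerance = 1e-12)
  expect_equal(fh$sdlog, (0.76 - 0.62) / 3.92, tolerance = 1e-12)
})

test_that("every fitted distribution is centred on its base value", {
  p <- default_parameters()
  for (nm in names(p)) {
    f <- fit_distribution(p[[nm]])
    centre <- switch(f$family,
                     beta = f$alpha / (f$alpha + f$beta),
                     gamma = f$shape * f$scale,
                     lognormal = if (isTRUE(f$log_scale_value)) f$meanlog
                     else exp(f$meanlog),
                     fixed = f$value)
    expect_equal(centre, p[[nm]]$base, tolerance = 1e-9,
                 info = paste("parameter", nm))
  }
})

test_that("beta/gamma fits round-trip the interval via the normal approximation", {
  p <- default_parameters()
  for (nm in names(p)) {
    spec <- p[[nm]]
    if (!spec$dist %in% c("beta", "gamma")) next
    f <- fit_distribution(spec)
    se_fit <- switch(f$family,
                     beta = sqrt(f$alpha * f$beta /
                                   ((f$alpha + f$beta)^2 *
                                      (f$alpha + f$beta + 1))),
                     gamma = sqrt(f$shape) * f$scale)
    # the fitted SD always recovers the interval's width; for symmetric
    # intervals (most of the table) it recovers the bounds themselves
    expect_equal(2 * 1.96 * se_fit, spec$high - spec$low, tolerance = 1e-6,
                 info = nm)
    mid <- (spec$low + spec$high) / 2
    if (abs(mid - spec$base) < 1e-9 * max(1, spec$base)) {
      expect_equal(spec$base - 1.96 * se_fit, spec$low, tolerance = 1e-6,
                   info = nm)
      expect_equal(spec$base + 1.96 * se_fit, spec$high, tolerance = 1e-6,
                   info = nm)
    }
  }
})

test_that("Monte-Carlo sample means agree with the fitted means", {
  set.seed(101)
  f <- fit_beta(default_parameters()$u_acs)
  x <- rbeta(1e5, f$alpha, f$beta)
  mc_se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.82), 3 * mc_se)
})

test_that("one-way ranges use reported intervals with proportional fallback", {
  p <- default_parameters()
  expect_identical(owsa_range(p$p_mi_statin), c(0.0152, 0.0186))
  expect_identical(owsa_range(p$cost_ez_annual), c(1384, 2075))
  # fallback when no interval is reported: +/-10% probabilities, +/-20% costs
  prob_ni <- parameter_spec("p", 0.0169, dist = "beta", role = "probability")
  expect_equal(owsa_range(prob_ni), c(0.01521, 0.01859), tolerance = 1e-12)
  cost_ni <- parameter_spec("c", 1730, dist = "gamma",
                            role = "cost_THB_per_year")
  expect_equal(owsa_range(cost_ni), c(1384, 2076), tolerance = 1e-12)
  fx <- parameter_spec("f", 5, dist = "fixed", role = "cost_THB_per_year")
  expect_identical(owsa_range(fx), c(5, 5))
  # order-preservation across the whole default set
  for (nm in names(p)) {
    rng <- owsa_range(p[[nm]])
    expect_true(rng[1] <= p[[nm]]$base && p[[nm]]$base <= rng[2], info = nm)
  }
})
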