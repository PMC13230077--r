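# Fit every parameter's sampling distribution once; reused across draws.
fit_all_distributions <- function(params) {
  lapply(params, fit_distribution)
}

#' Draw one parameter set from the fitted uncertainty distributions
#'
#' Samples every parameter independently from its declared distribution
#' (beta for probabilities and utilities, gamma for costs and utility
#' decrements, log-normal for relative risks and the excess-mortality
#' hazard ratio), in canonical parameter order, using the current RNG
#' state. `"fixed"` parameters keep their base value. Beta and gamma
#' fits are mean-preserving; log-normal fits are median-preserving.
#'
#' @param params A `"cua_parameters"` object.
#' @param fits Optional precomputed list of distribution fits (from
#'   repeated calls, e.g. inside the probabilistic loop).
#' @return A `"cua_parameters"` object with sampled base values.
#' @export
sample_parameter_set <- function(params, fits = fit_all_distributions(params)) {
  out <- params
  for (nm in names(params)) {
    f <- fits[[nm]]
    val <- switch(f$family,
                  fixed = f$value,
                  beta = stats::rbeta(1, f$alpha, f$beta),
                  gamma = stats::rgamma(1, shape = f$shape, scale = f$scale),
                  lognormal = if (isTRUE(f$log_scale_value)) {
                    stats::rnorm(1, f$meanlog, f$sdlog)
                  } else {
                    stats::rlnorm(1, f$meanlog, f$sdlog)
                  })
    # sampled values bypass interval bookkeeping; range invariants that the
    # families already guarantee are not re-checked
    out[[nm]]$base <- val
  }
  out
}

# Incremental outcomes of ezetimibe add-on over statin alone for one
# parameter set; skips cross-parameter validation so that sampled or
# what-if sets (e.g. RR > 1) can be evaluated.
incremental_outcomes <- function(params, settings, lt) {
  ref <- arm_outcome(params, settings, lt, "statin_alone")
  alt <- arm_outcome(params, settings, lt, "ezetimibe_plus_statin")
  list(delta_cost_societal = ledger_total(alt$ledger, "societal") -
         ledger_total(ref$ledger, "societal"),
       delta_cost_provider = ledger_total(alt$ledger, "provider") -
         ledger_total(ref$ledger, "provider"),
       delta_ly = alt$life_years - ref$life_years,
       delta_qaly = alt$qalys - ref$qalys)
}

owsa_icer <- function(inc, perspective) {
  dc <- if (perspective == "societal") inc$delta_cost_societal else
    inc$delta_cost_provider
  dc / inc$delta_qaly
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic model with each parameter set to the
#' low and high end of its one-way range (see [owsa_range()]) while all
#' other inputs stay at base case, and records the ICER at each bound and
#' its percentage change from the base-case ICER. Entries whose bound
#' makes the model infeasible are flagged in the `note` column rather
#' than dropped. Rows are sorted by tornado spread
#' (`|icer_high - icer_low|`), widest first.
#'
#' @inheritParams cua_model
#' @param life_table A `"life_table"`.
#' @param perspective Cost perspective for the ICER; defaults to
#'   `settings$perspective`.
#' @return An object of class `"cua_owsa"`: a `data.frame` with columns
#'   `parameter`, `low_input`, `high_input`, `icer_low`, `icer_high`,
#'   `pct_low`, `pct_high`, `spread`, `note`, and attributes `base_icer`
#'   and `perspective`.
#' @examples
#' \donttest{
#' tor <- run_owsa(default_parameters(), default_settings(),
#'                 synthetic_life_table())
#' utils::head(as.data.frame(tor), 3)
#' }
#' @export
run_owsa <- function(params = default_parameters(),
                     settings = default_settings(),
                     life_table = synthetic_life_table(
                       age_min = settings$start_age,
                       age_max = settings$max_age),
                     perspective = settings$perspective) {
  perspective <- match.arg(perspective, c("societal", "provider"))
  base_icer <- owsa_icer(incremental_outcomes(params, settings, life_table),
                         perspective)
  rows <- lapply(names(params), function(nm) {
    rng <- owsa_range(params[[nm]])
    icers <- numeric(2)
    note <- ""
    for (i in 1:2) {
      p2 <- set_parameter(params, nm, rng[i], validate = FALSE)
      icers[i] <- tryCatch(
        owsa_icer(incremental_outcomes(p2, settings, life_table),
                  perspective),
        error = function(e) {
          note <<- conditionMessage(e)
          NA_real_
        })
    }
    data.frame(parameter = nm, low_input = rng[1], high_input = rng[2],
               icer_low = icers[1], icer_high = icers[2],
               pct_low = (icers[1] - base_icer) / base_icer * 100,
               pct_high = (icers[2] - base_icer) / base_icer * 100,
               spread = abs(icers[2] - icers[1]),
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "perspective") <- perspective
  class(out) <- c("cua_owsa", "data.frame")
  out
}

#' @export
print.cua_owsa <- function(x, n = 10L, ...) {
  cat(sprintf("<cua_owsa> %s perspective; base ICER %.0f THB/QALY\n",
              attr(x, "perspective"), attr(x, "base_icer")))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("parameter", "low_input", "high_input",
                           "icer_low", "icer_high", "pct_low", "pct_high")]
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 6) else col)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER at each parameter's low and high
#' bound, widest spread at the top, with the base-case ICER as a vertical
#' reference line.
#'
#' @param x A `"cua_owsa"`.
#' @param n Number of parameters shown (default 10).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cua_owsa <- function(x, n = 10L, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$spread) & df$spread > 0, , drop = FALSE]
  df <- df[seq_len(min(n, nrow(df))), , drop = FALSE]
  df <- df[rev(seq_len(nrow(df))), ]
  base <- attr(x, "base_icer")
  xlim <- range(c(df$icer_low, df$icer_high, base), na.rm = TRUE)
  old <- graphics::par(mar = c(5, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(df) + 0.5),
                 yaxt = "n", xlab = "ICER (THB/QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  graphics::abline(v = base, lty = 2)
  for (i in seq_len(nrow(df))) {
    graphics::segments(df$icer_low[i], i, df$icer_high[i], i, lwd = 8,
                       col = "steelblue", lend = 1)
  }
  graphics::axis(2, at = seq_len(nrow(df)), labels = df$parameter, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws
#' a full parameter set from the fitted distributions (one draw per
#' parameter, shared by both arms within the iteration) and re-evaluates
#' the model, recording incremental cost under both perspectives and
#' incremental QALYs/life-years. Draws that make the model infeasible
#' (e.g. a sampled utility decrement exceeding the sampled baseline
#' utility) are re-sampled and counted. Fully reproducible for a given
#' seed.
#'
#' @inheritParams run_owsa
#' @param iterations Number of Monte-Carlo iterations; defaults to
#'   `settings$psa_iterations` (1,000).
#' @param seed RNG seed; defaults to `settings$rng_seed`.
#' @return An object of class `"cua_psa"`: a `data.frame` with columns
#'   `iteration`, `delta_cost_thb` (under `perspective`),
#'   `delta_cost_societal_thb`, `delta_cost_provider_thb`, `delta_qaly`,
#'   `delta_ly`; attributes `seed`, `perspective`, `wtp`, `n_resampled`.
#' @examples
#' \donttest{
#' psa <- run_psa(iterations = 50, seed = 1)
#' quadrant_shares(psa)
#' }
#' @export
run_psa <- function(params = default_parameters(),
                    settings = default_settings(),
                    life_table = synthetic_life_table(
                      age_min = settings$start_age,
                      age_max = settings$max_age),
                    iterations = settings$psa_iterations,
                    seed = settings$rng_seed,
                    perspective = settings$perspective) {
  perspective <- match.arg(perspective, c("societal", "provider"))
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  fits <- fit_all_distributions(params)
  set.seed(seed)
  dc_soc <- dc_prov <- dq <- dly <- numeric(iterations)
  n_resampled <- 0L
  for (i in seq_len(iterations)) {
    repeat {
      drawn <- sample_parameter_set(params, fits)
      inc <- tryCatch(incremental_outcomes(drawn, settings, life_table),
                      error = function(e) NULL)
      if (!is.null(inc)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100L * iterations) {
        stop("probabilistic analysis: too many infeasible draws",
             call. = FALSE)
      }
    }
    dc_soc[i] <- inc$delta_cost_societal
    dc_prov[i] <- inc$delta_cost_provider
    dq[i] <- inc$delta_qaly
    dly[i] <- inc$delta_ly
  }
  out <- data.frame(
    iteration = seq_len(iterations),
    delta_cost_thb = if (perspective == "societal") dc_soc else dc_prov,
    delta_cost_societal_thb = dc_soc,
    delta_cost_provider_thb = dc_prov,
    delta_qaly = dq, delta_ly = dly)
  attr(out, "seed") <- seed
  attr(out, "perspective") <- perspective
  attr(out, "wtp") <- settings$wtp
  attr(out, "n_resampled") <- n_resampled
  class(out) <- c("cua_psa", "data.frame")
  out
}

#' @export
print.cua_psa <- function(x, ...) {
  q <- quadrant_shares(x)
  wtp <- attr(x, "wtp")
  cat(sprintf("<cua_psa> %d iterations (seed %d), %s perspective\n",
              nrow(x), attr(x, "seed"), attr(x, "perspective")))
  cat(sprintf("  mean dCost %.0f THB, mean dQALY %.4f\n",
              mean(x$delta_cost_thb), mean(x$delta_qaly)))
  cat(sprintf("  quadrants: NE %.1f%%, NW %.1f%%, SE %.1f%%, SW %.1f%%\n",
              100 * q["NE"], 100 * q["NW"], 100 * q["SE"], 100 * q["SW"]))
  cat(sprintf("  P(cost-effective at %s THB/QALY): %.1f%%\n",
              format(wtp, big.mark = ","),
              100 * prob_cost_effective(x, wtp)))
  if (attr(x, "n_resampled") > 0L) {
    cat("  infeasible draws re-sampled:", attr(x, "n_resampled"), "\n")
  }
  if (nrow(x) < 1000L) {
    cat("  note: fewer than 1,000 iterations; Monte-Carlo error may be",
        "substantial\n")
  }
  invisible(x)
}

#' Cost-effectiveness plane quadrant shares
#'
#' Shares of probabilistic draws in each quadrant of the
#' cost-effectiveness plane (incremental QALYs on the x axis, incremental
#' cost on the y axis): NE more effective/more costly, NW less
#' effective/more costly, SE more effective/less costly, SW both lower.
#' Boundary draws follow a half-open convention: an exact zero counts as
#' positive. Shares sum to 1.
#'
#' @param draws A `"cua_psa"` object.
#' @return Named numeric vector with entries `NE`, `NW`, `SE`, `SW`.
#' @export
quadrant_shares <- function(draws) {
  stopifnot(inherits(draws, "cua_psa"), nrow(draws) > 0L)
  qpos <- draws$delta_qaly >= 0
  cpos <- draws$delta_cost_thb >= 0
  c(NE = mean(qpos & cpos), NW = mean(!qpos & cpos),
    SE = mean(qpos & !cpos), SW = mean(!qpos & !cpos))
}

#' Probability of cost-effectiveness at one threshold
#'
#' Share of draws with strictly positive net monetary benefit
#' `wtp * dQALY - dCost` at the given willingness-to-pay.
#'
#' @param draws A `"cua_psa"` object.
#' @param wtp Willingness-to-pay threshold, THB/QALY.
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(draws, wtp = attr(draws, "wtp")) {
  stopifnot(inherits(draws, "cua_psa"))
  mean(wtp * draws$delta_qaly - draws$delta_cost_thb > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the probability that
#' ezetimibe add-on therapy is cost-effective — the share of
#' probabilistic draws with positive net monetary benefit. The default
#' grid runs from 0 to 400,000 THB/QALY in steps of 10,000 and therefore
#' includes the Thai threshold of 160,000 exactly.
#'
#' @param draws A `"cua_psa"` object.
#' @param wtp_grid Ascending willingness-to-pay grid, THB/QALY.
#' @return An object of class `"cua_ceac"`: `data.frame` with columns
#'   `wtp_thb` and `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(draws, "cua_psa"))
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be strictly ascending", call. = FALSE)
  }
  out <- data.frame(
    wtp_thb = wtp_grid,
    prob_ce = vapply(wtp_grid, function(w) prob_cost_effective(draws, w),
                     numeric(1)))
  class(out) <- c("cua_ceac", "data.frame")
  out
}

#' @export
print.cua_ceac <- function(x, ...) {
  cat("<cua_ceac>", nrow(x), "willingness-to-pay points\n")
  print(as.data.frame(x)[x$wtp_thb %in%
                           c(0, 80000, 160000, 240000, 400000), ],
        row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness plane scatter
#'
#' @param x A `"cua_psa"` object.
#' @param wtp Threshold line slope (THB/QALY); default from the draws.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cua_psa <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$delta_qaly, x$delta_cost_thb, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (THB)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `"cua_ceac"` object.
#' @param wtp Vertical reference line (THB/QALY), default 160,000.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cua_ceac <- function(x, wtp = 160000, ...) {
  graphics::plot(x$wtp_thb, x$prob_ce, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Willingness to pay (THB/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(v = wtp, lty = 2)
  invisible(x)
}
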