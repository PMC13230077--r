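#' Fit the cost-utility model
#'
#' Evaluates the four-state Markov cohort model for both strategies —
#' moderate-intensity statin alone (comparator) and ezetimibe added to
#' moderate-intensity statin — and computes incremental cost-effectiveness
#' from both the societal and healthcare-provider perspectives.
#'
#' @param params Model inputs, a `"cua_parameters"` object
#'   (default [default_parameters()]).
#' @param settings Analysis settings, a `"cua_settings"` object
#'   (default [default_settings()]).
#' @param life_table Background mortality, a `"life_table"` object
#'   (default [synthetic_life_table()]; supply a national life table via
#'   [read_life_table()] when one is available).
#' @return An object of class `"cua_model"` with components `arms` (named
#'   list of `"arm_outcome"` objects), `icer` (named list of
#'   `"icer_result"` objects for `societal` and `provider`), and the
#'   inputs used.
#' @examples
#' fit <- cua_model()
#' fit
#' summary(fit)
#' @export
cua_model <- function(params = default_parameters(),
                      settings = default_settings(),
                      life_table = synthetic_life_table(
                        age_min = settings$start_age,
                        age_max = settings$max_age)) {
  validate_parameters(params)
  validate_settings(settings)
  stopifnot(inherits(life_table, "life_table"))
  arms <- lapply(stats::setNames(cua_arms, cua_arms), function(a) {
    arm_outcome(params, settings, life_table, a)
  })
  ref <- arms$statin_alone
  alt <- arms$ezetimibe_plus_statin
  icer <- list(societal = compute_icer(ref, alt, settings, "societal"),
               provider = compute_icer(ref, alt, settings, "provider"))
  structure(list(arms = arms, icer = icer, params = params,
                 settings = settings, life_table = life_table),
            class = "cua_model")
}

#' @export
print.cua_model <- function(x, ...) {
  cat("Cost-utility model: ezetimibe + moderate-intensity statin vs",
      "moderate-intensity statin alone\n")
  cat(sprintf("Cohort entering at age %d; %d annual cycles; discounting %g%%\n",
              x$settings$start_age,
              x$settings$max_age - x$settings$start_age,
              100 * x$settings$discount_rate_outcomes))
  ref <- x$arms$statin_alone
  alt <- x$arms$ezetimibe_plus_statin
  cat(sprintf("Comparator:   LYs %.4f, QALYs %.4f\n", ref$life_years,
              ref$qalys))
  cat(sprintf("Intervention: LYs %.4f, QALYs %.4f\n", alt$life_years,
              alt$qalys))
  for (p in names(x$icer)) {
    ic <- x$icer[[p]]
    val <- if (is.na(ic$dominance)) {
      sprintf("ICER %.0f THB/QALY (%.1f USD/QALY)", ic$icer_per_qaly,
              ic$icer_per_qaly / ic$exchange_rate)
    } else ic$dominance
    cat(sprintf("%-9s perspective: dCost %.0f THB, dQALY %.4f, %s%s\n",
                p, ic$delta_cost, ic$delta_qaly, val,
                if (ic$cost_effective_at_wtp) " [cost-effective]" else ""))
  }
  invisible(x)
}

#' Summarise a fitted cost-utility model
#'
#' Builds the base-case results table: discounted costs by category and
#' perspective totals for each arm with incremental columns, plus
#' discounted life-years and QALYs, in THB and (derived) USD.
#'
#' @param object A `"cua_model"`.
#' @param ... Unused.
#' @return An object of class `"summary.cua_model"`: a `data.frame` with
#'   one row per ledger category/outcome and columns for each arm and the
#'   increment.
#' @export
summary.cua_model <- function(object, ...) {
  ref <- object$arms$statin_alone
  alt <- object$arms$ezetimibe_plus_statin
  rows <- c(ledger_categories,
            "total_direct_medical", "total_societal",
            "life_years", "qalys")
  val <- function(o) c(unclass(o$ledger)[ledger_categories],
                       attr(o$ledger, "direct_medical"),
                       attr(o$ledger, "societal_total"),
                       o$life_years, o$qalys)
  df <- data.frame(item = rows,
                   statin_alone = val(ref),
                   ezetimibe_plus_statin = val(alt),
                   row.names = NULL)
  df$incremental <- df$ezetimibe_plus_statin - df$statin_alone
  attr(df, "icer") <- object$icer
  attr(df, "exchange_rate") <- object$settings$exchange_rate_thb_per_usd
  class(df) <- c("summary.cua_model", "data.frame")
  df
}

#' @export
print.summary.cua_model <- function(x, ...) {
  df <- as.data.frame(x)
  money <- !df$item %in% c("life_years", "qalys")
  for (col in c("statin_alone", "ezetimibe_plus_statin", "incremental")) {
    df[[col]] <- ifelse(money, sprintf("%.0f", df[[col]]),
                        sprintf("%.4f", df[[col]]))
  }
  print(df, row.names = FALSE, right = TRUE)
  for (p in names(attr(x, "icer"))) {
    ic <- attr(x, "icer")[[p]]
    if (is.na(ic$dominance)) {
      cat(sprintf("ICER (%s): %.0f THB/QALY, %.0f THB/LY\n", p,
                  ic$icer_per_qaly, ic$icer_per_ly))
    } else {
      cat(sprintf("ICER (%s): %s\n", p, ic$dominance))
    }
  }
  invisible(x)
}

#' Check one transition matrix against the structural invariants
#'
#' Used by [validate_model()] on every generated matrix, and available
#' directly so that an externally supplied (or deliberately corrupted)
#' matrix can be audited: rows must sum to 1 within `tol`, entries must
#' lie in `[0, 1]`, and the death row must be absorbing.
#'
#' @param m A 4x4 transition matrix over the model states.
#' @param label Context string included in failure messages.
#' @param tol Row-sum tolerance.
#' @return Character vector of failure descriptions (empty when valid).
#' @export
check_transition_matrix <- function(m, label = "", tol = 1e-12) {
  failures <- character(0)
  ctx <- if (nzchar(label)) paste0(" (", label, ")") else ""
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    failures <- c(failures, sprintf("row sum != 1 for state %s%s",
                                    paste(rownames(m)[bad], collapse = "/"),
                                    ctx))
  }
  if (any(m < 0) || any(m > 1)) {
    failures <- c(failures, paste0("entry outside [0,1]", ctx))
  }
  if (!identical(unname(m[4L, ]), c(0, 0, 0, 1))) {
    failures <- c(failures, paste0("death state not absorbing", ctx))
  }
  failures
}

#' Internal-validity report for the model
#'
#' Re-derives every per-cycle transition matrix for both arms and checks
#' the model's structural invariants: each row sums to 1 (within 1e-12),
#' all entries lie in `[0, 1]`, and the death row is absorbing. Also
#' reports the external-validity reference quantities: the comparator
#' arm's discounted life-years and undiscounted life expectancy at the
#' starting age, and the annual post-MI case-fatality probability.
#'
#' @inheritParams cua_model
#' @param tol Row-sum tolerance (default 1e-12).
#' @return An object of class `"cua_validation"`: list with `pass`
#'   (logical), `failures` (character), and `reference` (named list of
#'   external-validity quantities).
#' @export
validate_model <- function(params = default_parameters(),
                           settings = default_settings(),
                           life_table = synthetic_life_table(
                             age_min = settings$start_age,
                             age_max = settings$max_age),
                           tol = 1e-12) {
  failures <- character(0)
  ages <- seq.int(settings$start_age, settings$max_age - 1L)
  for (arm in cua_arms) {
    for (age in ages) {
      m <- transition_matrix(params, settings, life_table, arm, age)
      failures <- c(failures,
                    check_transition_matrix(m, sprintf("%s, age %d", arm, age),
                                            tol))
    }
  }
  ref <- arm_outcome(params, settings, life_table, "statin_alone")
  reference <- list(
    comparator_discounted_life_years = ref$life_years,
    comparator_life_expectancy_undiscounted = life_expectancy(
      life_table, settings$start_age, settings$max_age),
    annual_fatal_mi_probability = params$p_death_mi$base)
  structure(list(pass = length(failures) == 0L, failures = failures,
                 reference = reference, n_ages = length(ages)),
            class = "cua_validation")
}

#' @export
print.cua_validation <- function(x, ...) {
  cat("<cua_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  row-stochasticity checked at %d ages x 2 arms\n", x$n_ages))
  if (!x$pass) {
    cat("  failures:\n")
    for (f in x$failures) cat("   -", f, "\n")
  }
  r <- x$reference
  cat(sprintf("  comparator discounted LYs: %.4f\n",
              r$comparator_discounted_life_years))
  cat(sprintf("  comparator undiscounted life expectancy at start age: %.2f\n",
              r$comparator_life_expectancy_undiscounted))
  cat(sprintf("  annual fatal-MI probability: %.4f\n",
              r$annual_fatal_mi_probability))
  invisible(x)
}

#' Export model results and a run manifest to a directory
#'
#' Writes the base-case ledger table (`base_case_ledger.csv`), the ICER
#' table for both perspectives in THB and USD (`icer.csv`), the per-arm
#' cohort traces (`trace_<arm>.csv`), the canonical parameter audit CSV
#' (`parameters.csv`), and a JSON manifest recording input file hashes,
#' the settings snapshot (including every bookkeeping switch in effect),
#' the package version and a timestamp.
#'
#' @param fit A `"cua_model"`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
export_results <- function(fit, dir) {
  stopifnot(inherits(fit, "cua_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  s <- summary(fit)
  utils::write.csv(as.data.frame(s), path("base_case_ledger.csv"),
                   row.names = FALSE)

  fx <- fit$settings$exchange_rate_thb_per_usd
  ic <- do.call(rbind, lapply(fit$icer, function(i) {
    data.frame(perspective = i$perspective,
               delta_cost_thb = i$delta_cost,
               delta_cost_usd = i$delta_cost / fx,
               delta_ly = i$delta_ly, delta_qaly = i$delta_qaly,
               icer_thb_per_ly = i$icer_per_ly,
               icer_thb_per_qaly = i$icer_per_qaly,
               icer_usd_per_qaly = i$icer_per_qaly / fx,
               dominance = ifelse(is.na(i$dominance), "", i$dominance),
               cost_effective_at_wtp = i$cost_effective_at_wtp)
  }))
  utils::write.csv(ic, path("icer.csv"), row.names = FALSE)

  for (a in names(fit$arms)) {
    utils::write.csv(as.data.frame(fit$arms[[a]]$trace),
                     path(sprintf("trace_%s.csv", a)), row.names = FALSE)
  }
  write_parameters_csv(fit$params, path("parameters.csv"))
  write_life_table(fit$life_table, path("life_table.csv"))

  manifest <- list(
    package = "ezcua",
    version = as.character(utils::packageVersion("ezcua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters_md5 = unname(tools::md5sum(path("parameters.csv"))),
    life_table_md5 = unname(tools::md5sum(path("life_table.csv"))),
    settings = unclass(fit$settings))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
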