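# Orchestration: from raw outcome measures to report tables.

#' Recovery-time summaries
#'
#' Mean, standard error and median of the time since recovery started, per
#' group (the numbers shown alongside each pooled debt estimate).
#'
#' @param records Data frame with a `t_years` column.
#' @param grouping Optional name of a grouping column; `NULL` summarises all
#'   records as one group labelled `"all"`.
#' @return A tibble: `label`, `mean_t`, `se_t` (NA for single records),
#'   `median_t`, `k`, `n_studies`.
#' @export
recovery_time_summary <- function(records, grouping = NULL) {
  if (nrow(records) == 0) abort("recovery_time_summary() requires records")
  df <- tibble::as_tibble(records)
  df$label <- if (is.null(grouping)) "all" else as.character(df[[grouping]])
  df <- df[!is.na(df$label), , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(df, .data$label),
    mean_t = mean(.data$t_years),
    se_t = ifelse(dplyr::n() > 1, sd(.data$t_years) / sqrt(dplyr::n()), NA_real_),
    median_t = median(.data$t_years),
    k = dplyr::n(),
    n_studies = if ("study_id" %in% names(df))
      dplyr::n_distinct(.data$study_id) else NA_integer_,
    .groups = "drop")
}

#' Run the full recovery-debt analysis
#'
#' The end-to-end pipeline: (1) select the zero-handling strategy on the
#' database (skipped when no record contains a zero); (2) compute per-record
#' debt ratios; (3) impute missing sampling variances within each metric; (4)
#' per metric, fit the three-level null model, and for each moderator the
#' omnibus Q_M test plus no-intercept category estimates; (5) compute
#' I-squared on the variance-reporting subset of each metric; (6) summarise
#' recovery times per metric and category. Deterministic given `db` and the
#' arguments.
#'
#' Stage failures (e.g. a moderator with a single category in a small subset)
#' are collected into the report's `errors` table and raised as warnings;
#' they never silently truncate the report.
#'
#' @param db Data frame of outcome measures (canonical schema).
#' @param method `"exponential"` or `"linear"` trajectory interpolation.
#' @param moderators Character vector of moderator columns to test.
#' @return A list of class `"recovery_report"` with elements `strategy`,
#'   `debts`, `effects`, `pooled`, `categories`, `qm`, `i2`, `times`,
#'   `scenario_counts`, `errors`, `method`.
#' @export
run_full_analysis <- function(db, method = c("exponential", "linear"),
                              moderators = c("ecosystem", "disturbance")) {
  method <- match.arg(method)
  if (nrow(db) == 0) abort("run_full_analysis() requires a non-empty database")
  errors <- tibble::tibble(stage = character(), subset = character(),
                           message = character())
  note_err <- function(stage, subset, msg) {
    errors <<- dplyr::bind_rows(errors,
      tibble::tibble(stage = stage, subset = subset, message = msg))
    warn(paste0("[", stage, " / ", subset, "] ", msg))
  }

  # (1) zero strategy
  any_zero <- any(db$x_start == 0 | db$x_end == 0 | db$x_ref == 0, na.rm = TRUE)
  strategy <- NULL
  zs <- 7
  if (any_zero) {
    strategy <- tryCatch(select_zero_strategy(db, method = method),
                         error = function(e) {
                           note_err("select_zero_strategy", "all", conditionMessage(e))
                           NULL
                         })
    if (!is.null(strategy)) zs <- attr(strategy, "selected")
  }

  # (2) debts
  debts <- compute_debt(db, method = method, zero_strategy = zs)
  scenario_counts <- dplyr::count(dplyr::filter(debts, .data$usable),
                                  .data$scenario, name = "k")

  # (3) effects table with imputed variances, per metric
  effects <- dplyr::filter(debts, .data$usable, !is.na(.data$ratio_pct))
  effects <- tryCatch(impute_variances(effects), error = function(e) {
    note_err("impute_variances", "all", conditionMessage(e))
    dplyr::mutate(effects, imputed = is.na(.data$variance))
  })

  pooled <- categories <- qm <- i2 <- times <- NULL
  for (m in intersect(debt_levels$metric, unique(effects$metric))) {
    sub <- dplyr::filter(effects, .data$metric == m, !is.na(.data$variance))
    if (nrow(sub) == 0) next
    null_fit <- tryCatch(fit_debt_model(sub), error = function(e) {
      note_err("null_fit", m, conditionMessage(e)); NULL
    })
    if (!is.null(null_fit)) {
      pooled <- dplyr::bind_rows(pooled,
        dplyr::bind_cols(tibble::tibble(metric = m), glance(null_fit)))
    }
    obs <- dplyr::filter(sub, !.data$imputed)
    if (nrow(obs) >= 2) {
      i2 <- dplyr::bind_rows(i2, tibble::tibble(
        metric = m, i_squared = i_squared(obs$ratio_pct, obs$variance),
        k_observed = nrow(obs)))
    }
    times <- dplyr::bind_rows(times, dplyr::bind_cols(
      tibble::tibble(metric = m, moderator = "none"),
      recovery_time_summary(sub)))
    for (mod in moderators) {
      if (!mod %in% names(sub)) next
      qfit <- tryCatch(fit_debt_model(sub, moderator = mod, intercept = TRUE),
                       error = function(e) {
                         note_err("moderator_fit", paste(m, mod), conditionMessage(e))
                         NULL
                       })
      if (is.null(qfit)) next
      qm <- dplyr::bind_rows(qm, dplyr::bind_cols(
        tibble::tibble(metric = m, moderator = mod), omnibus_test(qfit)))
      cfit <- tryCatch(fit_debt_model(sub, moderator = mod, intercept = FALSE),
                       error = function(e) {
                         note_err("category_fit", paste(m, mod), conditionMessage(e))
                         NULL
                       })
      if (is.null(cfit)) next
      ce <- category_estimates(cfit)
      tt <- recovery_time_summary(sub, grouping = mod)
      ce <- dplyr::left_join(ce, tt[, c("label", "mean_t", "se_t", "median_t")],
                             by = "label")
      categories <- dplyr::bind_rows(categories, dplyr::bind_cols(
        tibble::tibble(metric = m, moderator = mod), ce))
    }
  }

  structure(list(strategy = strategy, debts = debts, effects = effects,
                 pooled = pooled, categories = categories, qm = qm, i2 = i2,
                 times = times, scenario_counts = scenario_counts,
                 errors = errors, method = method),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery-debt analysis (", x$method, " interpolation)\n", sep = "")
  cat(sprintf("  %d usable records in %d scenarios; %d stage error(s)\n",
              sum(x$debts$usable), nrow(x$scenario_counts), nrow(x$errors)))
  if (!is.null(x$pooled)) {
    cat("  Pooled per-annum debt ratios (%):\n")
    for (i in seq_len(nrow(x$pooled))) {
      cat(sprintf("    %-10s %4.0f [%.0f, %.0f]  k=%d, studies=%d\n",
                  x$pooled$metric[i], x$pooled$mean[i], x$pooled$ci_low[i],
                  x$pooled$ci_high[i], x$pooled$k[i], x$pooled$n_studies[i]))
    }
  }
  invisible(x)
}

#' Write all report tables of an analysis
#'
#' One machine-readable CSV per table (full precision) plus a plain-text
#' summary with integer-rounded confidence intervals. Re-running the same
#' analysis on the same inputs writes byte-identical files.
#'
#' @param report A `"recovery_report"` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "recovery_report")) abort("write_report() expects a recovery_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(debts = report$debts, pooled = report$pooled,
                 categories = report$categories, qm = report$qm,
                 i2 = report$i2, times = report$times,
                 scenario_counts = report$scenario_counts,
                 strategy = report$strategy, errors = report$errors)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.null(tb) && nrow(tb) > 0) {
      write_results(tibble::as_tibble(tb), file.path(dir, paste0(nm, ".csv")))
    }
  }
  lines <- c(paste0("Recovery-debt analysis, ", report$method, " interpolation"),
             paste0("usable records: ", sum(report$debts$usable)))
  if (!is.null(report$pooled)) {
    lines <- c(lines, "pooled per-annum debt ratios (% of reference):",
               sprintf("  %-10s %d [%d, %d]  (k=%d, studies=%d)",
                       report$pooled$metric, round(report$pooled$mean),
                       round(report$pooled$ci_low), round(report$pooled$ci_high),
                       report$pooled$k, report$pooled$n_studies))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
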