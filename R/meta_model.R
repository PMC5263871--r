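# Three-level random-effects pooling of debt ratios.
#
# Effects (debt ratios) are clustered within studies, so the model carries two
# heterogeneity components: between-study (u_j) and between-effect-within-
# study (w_ij), plus known sampling variance v_ij at level 1:
#   y_ij = x_ij' beta + u_j + w_ij + e_ij,
#   u_j ~ N(0, tau2_study), w_ij ~ N(0, tau2_effect), e_ij ~ N(0, v_ij).
# Variance components are estimated by REML (metafor::rma.mv), beta by GLS at
# the estimates; CIs are Wald.

#' Impute missing sampling variances within metric groups
#'
#' Primary studies in ecological meta-analyses rarely report the data needed
#' to compute a sampling variance (79% missing in the source database). The
#' standard workaround is adopted: within each recovery metric, missing
#' variances are replaced by the arithmetic mean of the observed ones, and the
#' row is flagged `imputed`. Observed variances are never touched.
#'
#' @param df Data frame with columns `metric` and `variance` (NA = missing).
#' @return The input tibble with `variance` completed and a logical `imputed`
#'   column.
#' @export
impute_variances <- function(df) {
  if (!all(c("metric", "variance") %in% names(df))) {
    abort("impute_variances() needs columns metric and variance")
  }
  out <- dplyr::mutate(dplyr::group_by(tibble::as_tibble(df), .data$metric),
    imputed = is.na(.data$variance),
    variance = ifelse(is.na(.data$variance),
                      mean(.data$variance, na.rm = TRUE), .data$variance))
  out <- dplyr::ungroup(out)
  bad <- unique(out$metric[is.nan(out$variance) | is.na(out$variance)])
  if (length(bad)) {
    abort(paste0("no observed variances to average in metric group(s): ",
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Higgins' I-squared heterogeneity index
#'
#' Computed on the variance-reporting subset only: with weights `w_i = 1/v_i`
#' and weighted mean `yb`, `Q = sum(w_i (y_i - yb)^2)` and
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100`. Values above 90% indicate that
#' between-study heterogeneity, not sampling error, dominates.
#'
#' @param effect Numeric vector of effects (debt ratios, %).
#' @param variance Positive observed sampling variances, same length.
#' @return I-squared as a percentage in \[0, 100\].
#' @export
#' @examples
#' i_squared(c(0, 2), c(1, 1))  # Q = 2, I2 = 50
i_squared <- function(effect, variance) {
  keep <- !is.na(effect) & !is.na(variance)
  effect <- effect[keep]; variance <- variance[keep]
  if (length(effect) < 2) abort("i_squared() needs k >= 2 effects with observed variance")
  if (any(variance <= 0)) abort("i_squared() requires positive variances")
  w <- 1 / variance
  yb <- sum(w * effect) / sum(w)
  q <- sum(w * (effect - yb)^2)
  if (q == 0) return(0)
  max(0, (q - (length(effect) - 1)) / q) * 100
}

#' Fit a three-level random-effects model to debt ratios
#'
#' Pools debt ratios with effects nested in studies, optionally with a
#' categorical moderator. With `intercept = FALSE` the coefficients are the
#' per-category means (the form used for category estimates); with a moderator
#' and `intercept = TRUE` the omnibus moderator test Q_M (Wald chi-square on
#' the non-intercept coefficients) asks whether categories differ.
#'
#' @param df Data frame with columns `ratio_pct` (or `effect`), `variance`,
#'   `study_id`, and any moderator columns.
#' @param moderator Optional name of a category column (e.g. `"ecosystem"`).
#' @param intercept Include an intercept? Ignored without a moderator.
#' @param fix_tau2_study Optional value at which to fix the between-study
#'   component (e.g. 0 to collapse to a conventional two-level random-effects
#'   model); `NULL` (default) estimates it.
#' @return An object of class `"debt_fit"` wrapping the `metafor::rma.mv`
#'   fit; see [tidy.debt_fit()], [glance.debt_fit()], [category_estimates()],
#'   [omnibus_test()].
#' @export
fit_debt_model <- function(df, moderator = NULL, intercept = TRUE,
                           fix_tau2_study = NULL) {
  df <- tibble::as_tibble(df)
  ycol <- if ("ratio_pct" %in% names(df)) "ratio_pct" else "effect"
  need <- c(ycol, "variance", "study_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("fit_debt_model() needs columns: ",
                                 paste(miss, collapse = ", ")))
  keep <- !is.na(df[[ycol]]) & !is.na(df$variance)
  df <- df[keep, , drop = FALSE]
  if (any(df$variance <= 0)) abort("all variances must be > 0 (impute first)")
  if (nrow(df) < 1) abort("no usable effects to fit")

  if (nrow(df) == 1 && is.null(moderator)) {
    # a single effect carries no information about heterogeneity: both
    # variance components pin at 0 and the estimate is the effect itself
    y <- df[[ycol]]; se <- sqrt(df$variance)
    f <- list(beta = matrix(y, dimnames = list("intrcpt", NULL)),
              se = se, ci.lb = y - qnorm(0.975) * se,
              ci.ub = y + qnorm(0.975) * se,
              pval = 2 * stats::pnorm(-abs(y / se)), k = 1L)
    return(structure(list(rma = f, data = df, moderator = NULL,
                          intercept = TRUE, k = 1L, n_studies = 1L,
                          tau2_study = 0, tau2_effect = 0,
                          loglik_reml = NA_real_),
                     class = "debt_fit"))
  }

  if (!is.null(moderator)) {
    if (!moderator %in% names(df)) abort(paste0("moderator column not found: ", moderator))
    lv <- table(df[[moderator]])
    if (length(lv) < 2) abort("moderator needs >= 2 categories")
    if (any(lv < 2)) abort(paste0("moderator category too small: ",
                                  paste(names(lv)[lv < 2], collapse = ", ")))
    df[[moderator]] <- factor(df[[moderator]])
    mods <- if (intercept) stats::reformulate(moderator) else
      stats::as.formula(paste0("~ 0 + ", moderator))
  } else {
    mods <- NULL
  }

  dat <- data.frame(y = df[[ycol]], v = df$variance,
                    study = factor(df$study_id),
                    es = factor(seq_len(nrow(df))))
  if (!is.null(moderator)) dat[[moderator]] <- df[[moderator]]
  sparse <- nrow(dat) > 1000  # dense algebra is faster below this size
  sig2 <- if (is.null(fix_tau2_study)) c(NA, NA) else c(fix_tau2_study, NA)
  fit <- if (is.null(mods)) {
    metafor::rma.mv(yi = y, V = v, random = list(~ 1 | study, ~ 1 | es),
                    data = dat, method = "REML", sparse = sparse,
                    sigma2 = sig2)
  } else {
    metafor::rma.mv(yi = y, V = v, mods = mods,
                    random = list(~ 1 | study, ~ 1 | es),
                    data = dat, method = "REML", sparse = sparse,
                    sigma2 = sig2)
  }

  structure(list(
    rma = fit,
    data = df,
    moderator = moderator,
    intercept = intercept || is.null(moderator),
    k = fit$k,
    n_studies = length(unique(df$study_id)),
    tau2_study = unname(fit$sigma2[1]),
    tau2_effect = unname(fit$sigma2[2]),
    loglik_reml = as.numeric(stats::logLik(fit))
  ), class = "debt_fit")
}

#' @export
print.debt_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Three-level debt model: k = %d effects in %d studies\n",
              g$k, g$n_studies))
  cat(sprintf("  tau2 (study) = %.3f, tau2 (effect) = %.3f\n",
              g$tau2_study, g$tau2_effect))
  if (is.null(x$moderator)) {
    cat(sprintf("  pooled debt = %.1f%% [%.1f, %.1f]\n",
                g$mean, g$ci_low, g$ci_high))
  } else {
    cat(sprintf("  moderator: %s (Q_M = %.2f, df = %d, p = %.3g)\n",
                x$moderator, g$q_m, g$q_m_df, g$q_m_p))
  }
  invisible(x)
}

#' Tidy a three-level debt model
#'
#' @param x A `"debt_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient: `term`,
#'   `estimate`, `std.error`, `ci.low`, `ci.high`, `p.value`.
#' @method tidy debt_fit
#' @export
tidy.debt_fit <- function(x, ...) {
  f <- x$rma
  term <- rownames(f$beta)
  if (!is.null(x$moderator)) term <- sub(x$moderator, "", term, fixed = TRUE)
  term[term %in% c("intrcpt", "")] <- if (is.null(x$moderator)) "overall" else "intercept"
  tibble::tibble(term = term,
                 estimate = as.numeric(f$beta),
                 std.error = as.numeric(f$se),
                 ci.low = as.numeric(f$ci.lb),
                 ci.high = as.numeric(f$ci.ub),
                 p.value = as.numeric(f$pval))
}

#' One-row summary of a three-level debt model
#'
#' @param x A `"debt_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: pooled `mean`/`se`/`ci_low`/`ci_high` (only for
#'   intercept-only fits), `tau2_study`, `tau2_effect`, `k`, `n_studies`,
#'   `loglik_reml`, and `q_m`/`q_m_df`/`q_m_p` for moderator fits.
#' @method glance debt_fit
#' @export
glance.debt_fit <- function(x, ...) {
  f <- x$rma
  base <- tibble::tibble(
    k = x$k, n_studies = x$n_studies,
    tau2_study = x$tau2_study, tau2_effect = x$tau2_effect,
    loglik_reml = x$loglik_reml)
  if (is.null(x$moderator)) {
    dplyr::bind_cols(tibble::tibble(
      mean = as.numeric(f$beta)[1], se = as.numeric(f$se)[1],
      ci_low = as.numeric(f$ci.lb)[1], ci_high = as.numeric(f$ci.ub)[1]), base)
  } else {
    dplyr::bind_cols(base, tibble::tibble(
      q_m = as.numeric(f$QM), q_m_df = as.integer(f$QMdf[1]),
      q_m_p = as.numeric(f$QMp)))
  }
}

#' Omnibus test of a categorical moderator
#'
#' Wald-type chi-square on the moderator coefficients (excluding the intercept
#' when present): does the moderator explain variation in pooled debts?
#'
#' @param fit A `"debt_fit"` with a moderator.
#' @return A one-row tibble: `q_m`, `df`, `p_value`.
#' @export
omnibus_test <- function(fit) {
  if (!inherits(fit, "debt_fit")) abort("omnibus_test() expects a debt_fit")
  if (is.null(fit$moderator)) abort("omnibus_test() requires a fit with a moderator")
  f <- fit$rma
  tibble::tibble(q_m = as.numeric(f$QM), df = as.integer(f$QMdf[1]),
                 p_value = as.numeric(f$QMp))
}

#' Per-category debt estimates from a no-intercept moderator fit
#'
#' With `intercept = FALSE`, each coefficient of the moderator fit is the
#' pooled mean of one category; this extracts them with Wald CIs and the
#' effect/study counts per category (the table behind a per-category forest
#' panel).
#'
#' @param fit A `"debt_fit"` fitted with a moderator and `intercept = FALSE`.
#' @return A tibble: `label`, `mean`, `se`, `ci_low`, `ci_high`, `k`,
#'   `n_studies`.
#' @export
category_estimates <- function(fit) {
  if (!inherits(fit, "debt_fit")) abort("category_estimates() expects a debt_fit")
  if (is.null(fit$moderator) || fit$intercept) {
    abort("category_estimates() requires a moderator fit with intercept = FALSE")
  }
  td <- tidy(fit)
  counts <- dplyr::summarise(
    dplyr::group_by(fit$data, label = .data[[fit$moderator]]),
    k = dplyr::n(), n_studies = dplyr::n_distinct(.data$study_id),
    .groups = "drop")
  counts$label <- as.character(counts$label)
  dplyr::left_join(
    tibble::tibble(label = td$term, mean = td$estimate, se = td$std.error,
                   ci_low = td$ci.low, ci_high = td$ci.high),
    counts, by = "label")
}

#' Compare two submetrics within a metric
#'
#' Fits a no-moderator three-level model to each submetric separately and
#' compares the raw debt-ratio distributions with a two-sided Mann-Whitney
#' rank-sum test. Used to check that, e.g., species richness and diversity
#' indexes (or carbon pools and fluxes) behave similarly enough to keep the
#' metric undivided.
#'
#' @param df Data frame of effects with `submetric` plus the columns
#'   [fit_debt_model()] needs.
#' @param submetrics Character vector of the two submetric labels to compare.
#' @return A list with `fits` (tibble of per-submetric pooled estimates),
#'   `mw_p` (Mann-Whitney p-value), `statistic`.
#' @export
compare_subcategories <- function(df, submetrics) {
  if (length(submetrics) != 2) abort("submetrics must name exactly two levels")
  sides <- lapply(submetrics, function(s) df[df$submetric %in% s, , drop = FALSE])
  nn <- vapply(sides, nrow, integer(1))
  if (any(nn < 2)) {
    abort(paste0("submetric with < 2 effects: ",
                 paste(submetrics[nn < 2], collapse = ", ")))
  }
  fits <- purrr::map2_dfr(sides, submetrics, function(d, s) {
    g <- glance(fit_debt_model(d))
    dplyr::bind_cols(tibble::tibble(submetric = s), g)
  })
  ycol <- if ("ratio_pct" %in% names(df)) "ratio_pct" else "effect"
  mw <- suppressWarnings(wilcox.test(sides[[1]][[ycol]], sides[[2]][[ycol]],
                                     exact = FALSE))
  list(fits = fits, mw_p = unname(mw$p.value), statistic = unname(mw$statistic))
}
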