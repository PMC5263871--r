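test_that("variance imputation is the within-metric arithmetic mean", {
  df <- tibble::tibble(metric = c("carbon", "carbon", "carbon", "nitrogen"),
                       variance = c(2, 4, NA, 1),
                       ratio_pct = c(30, 40, 50, 20),
                       study_id = c("a", "a", "b", "c"))
  out <- impute_variances(df)
  expect_equal(out$variance, c(2, 4, 3, 1))
  expect_equal(out$imputed, c(FALSE, FALSE, TRUE, FALSE))

  # fully observed group is untouched
  full <- impute_variances(df[c(1, 2, 4), ])
  expect_equal(full$variance, df$variance[c(1, 2, 4)])

  # a group with nothing to average is an error naming the group
  df$variance[4] <- NA
  expect_error(impute_variances(df), "nitrogen")
})

test_that("heavy masking still yields positive variances after imputation", {
  db <- generate_recovery_db(synthetic_config(n_studies = 80, seed = 31))
  d <- compute_debt(db, zero_strategy = 7)
  eff <- impute_variances(d[d$usable, ])
  expect_true(all(eff$variance > 0))
  expect_gt(mean(eff$imputed), 0.7)  # ~79% masked by construction
})

test_that("I-squared follows the Q formula and its invariances", {
  expect_equal(i_squared(c(5, 5, 5), c(1, 2, 3)), 0)
  expect_equal(i_squared(c(0, 2), c(1, 1)), 50)  # Q = 2, k - 1 = 1
  # scale invariance: common rescaling of variances and squared deviations
  set.seed(9)
  y <- rnorm(20, 40, 8); v <- runif(20, 0.5, 3)
  expect_equal(i_squared(y, v), i_squared(40 + (y - 40) * 3, v * 9),
               tolerance = 1e-12)
  expect_error(i_squared(1, 1), "k >= 2")
})

test_that("dominant heterogeneity pushes I-squared above 90%", {
  set.seed(10)
  i2 <- replicate(100, {
    tab <- simulate_effect_table(30, 2, mu = 45, tau2_study = 25,
                                 tau2_effect = 4, v = 1)
    i_squared(tab$effect, tab$variance)
  })
  expect_gt(mean(i2), 90)  # tau2 / (tau2 + v) heuristic: 29/30
})

test_that("degenerate fits behave: single effect and zero heterogeneity", {
  f1 <- fit_debt_model(tibble::tibble(ratio_pct = 42, variance = 4,
                                      study_id = "s1"))
  g1 <- glance(f1)
  expect_equal(g1$mean, 42)
  expect_equal(g1$se, 2)
  expect_equal(g1$tau2_study + g1$tau2_effect, 0)

  # identical effects, equal variances: both components 0, mu = common value
  df <- tibble::tibble(ratio_pct = rep(37, 8), variance = 1,
                       study_id = rep(c("a", "b", "c", "d"), each = 2))
  g <- glance(fit_debt_model(df))
  expect_equal(g$mean, 37, tolerance = 1e-8)
  expect_lt(g$tau2_study + g$tau2_effect, 1e-6)
})

test_that("three-level REML matches the independent grid-search oracle", {
  set.seed(11)
  tab <- simulate_effect_table(5, 2, mu = 40, tau2_study = 25,
                               tau2_effect = 4, v = 1)
  fit <- fit_debt_model(tab)
  oracle <- reml_oracle_3level(tab$effect, tab$variance, tab$study_id)
  expect_equal(glance(fit)$mean, oracle$mu, tolerance = 1e-6)
  expect_equal(fit$tau2_study, oracle$tau2_study, tolerance = 1e-4)
  expect_equal(fit$tau2_effect, oracle$tau2_effect, tolerance = 1e-4)
  # no spurious optimum: metafor's solution is at least as good as the grid's
  ll_fit <- reml_ll_3level(fit$tau2_study, fit$tau2_effect,
                           tab$effect, tab$variance, tab$study_id)
  expect_gte(ll_fit, oracle$ll - 1e-6)
})

test_that("with the study component pinned at 0 the fit is a two-level model", {
  set.seed(12)
  for (i in 1:10) {
    k <- sample(8:15, 1)
    tab <- tibble::tibble(effect = rnorm(k, 35, 6),
                          variance = runif(k, 0.5, 2),
                          study_id = paste0("s", seq_len(k)))
    fit <- fit_debt_model(tab, fix_tau2_study = 0)
    oracle <- reml_oracle_2level(tab$effect, tab$variance)
    expect_equal(glance(fit)$mean, oracle$mu, tolerance = 1e-6)
    expect_equal(fit$tau2_effect, oracle$tau2, tolerance = 1e-4)
  }
})

test_that("weighted-mean limit: equal variances and no heterogeneity", {
  df <- tibble::tibble(ratio_pct = rep(c(40, 40), 4), variance = 2,
                       study_id = paste0("s", 1:8))
  expect_equal(glance(fit_debt_model(df))$mean, 40, tolerance = 1e-8)
})

test_that("the omnibus moderator test has the right shape and power", {
  set.seed(13)
  tab <- simulate_effect_table(20, 2, mu = c(all = 0, low = 30, high = 60),
                               tau2_study = 4, tau2_effect = 1, v = 1,
                               categories = c("low", "high"))
  fit <- fit_debt_model(tab, moderator = "group")
  ot <- omnibus_test(fit)
  expect_equal(ot$df, 1)  # categories - 1 with intercept
  expect_lt(ot$p_value, 0.001)
  expect_error(omnibus_test(fit_debt_model(tab)), "moderator")
})

test_that("category estimates carry label, CI and per-category counts", {
  set.seed(14)
  tab <- simulate_effect_table(30, 3, mu = c(all = 0, low = 30, high = 60),
                               tau2_study = 4, tau2_effect = 1, v = 1,
                               categories = c("low", "high"))
  fit <- fit_debt_model(tab, moderator = "group", intercept = FALSE)
  ce <- category_estimates(fit)
  expect_setequal(ce$label, c("low", "high"))
  expect_true(all(ce$ci_low <= ce$mean & ce$mean <= ce$ci_high))
  expect_equal(sum(ce$k), nrow(tab))
  expect_equal(ce$mean[ce$label == "low"], 30, tolerance = 3)
  expect_equal(ce$mean[ce$label == "high"], 60, tolerance = 3)
  # intercept fits are not category estimates
  expect_error(category_estimates(fit_debt_model(tab, moderator = "group")),
               "intercept")
})

test_that("moderator fits refuse degenerate designs", {
  tab <- tibble::tibble(effect = rnorm(6, 40, 2), variance = 1,
                        study_id = paste0("s", 1:6),
                        group = c("x", "x", "x", "x", "x", "y"))
  expect_error(fit_debt_model(tab, moderator = "group"), "too small")
  tab$group <- "x"
  expect_error(fit_debt_model(tab, moderator = "group"), ">= 2 categories")
  expect_error(fit_debt_model(tab, moderator = "missing_col"), "not found")
})

test_that("subcategory comparison reports fits and a rank-sum p-value", {
  set.seed(15)
  db <- generate_recovery_db(synthetic_config(n_studies = 120, seed = 15))
  d <- compute_debt(db, zero_strategy = 7)
  eff <- impute_variances(d[d$usable, ])
  div <- eff[eff$metric == "diversity", ]
  cmp <- compare_subcategories(div, c("richness", "diversity_index"))
  expect_equal(nrow(cmp$fits), 2)
  expect_true(cmp$mw_p >= 0 && cmp$mw_p <= 1)
  # identical generating distributions: no detectable difference expected here
  expect_gt(cmp$mw_p, 0.01)
  expect_error(compare_subcategories(div, c("richness", "pool")), "< 2 effects")
})

test_that("shifted subcategory distributions are detected", {
  set.seed(16)
  tab <- simulate_effect_table(40, 2, mu = 40, tau2_study = 2,
                               tau2_effect = 1, v = 0.5)
  tab$submetric <- rep(c("pool", "flux"), length.out = nrow(tab))
  tab$effect[tab$submetric == "flux"] <- tab$effect[tab$submetric == "flux"] + 20
  cmp <- compare_subcategories(tab, c("pool", "flux"))
  expect_lt(cmp$mw_p, 0.05)
})
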