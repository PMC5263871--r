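rec <- function(xs, xe, xr, t = 10) {
  tibble::tibble(x_start = xs, x_end = xe, x_ref = xr, t_years = t)
}

test_that("scenario classification follows the five-case geometry", {
  expect_equal(classify_scenario(2, 8, 10), "a")
  expect_equal(classify_scenario(25, 12.5, 10), "b")
  expect_equal(classify_scenario(8, 2, 10), "c")
  expect_equal(classify_scenario(15, 5, 10), "d")
  expect_equal(classify_scenario(3, 7, 0), "e")
  # upward crossing is handled with the above-reference machinery
  expect_equal(classify_scenario(4, 12, 10), "b")
  # boundary: end exactly at the reference is still recovery from below
  expect_equal(classify_scenario(2, 10, 10), "a")
  expect_error(classify_scenario(NaN, 1, 2), "finite")
})

test_that("the inverse transform reflects about the reference and is bounded", {
  expect_equal(inverse_transform(25, 10), 4)
  expect_equal(inverse_transform(10, 10), 10)
  expect_equal(inverse_transform(12.5, 10), 8)
  # involution and ordering
  v <- runif(50, 0.1, 50)
  expect_equal(inverse_transform(inverse_transform(v, 10), 10), v)
  expect_true(all(inverse_transform(v[v > 10], 10) < 10))
  expect_error(inverse_transform(0, 10), "zero handling")
})

test_that("zero constants: fixed values and magnitude-specific decades", {
  for (s in 1:5) {
    expect_equal(zero_constant(123, 0, 7, s), c(0.01, 0.05, 0.1, 0.5, 1)[s])
  }
  # worked decade example: m = 0.81
  expect_equal(vapply(6:9, function(s) zero_constant(0.81, 0, 1, s),
                      numeric(1)), c(0.1, 0.5, 1, 5))
  # m = 7 sits in decade [1, 10): median is 5
  expect_equal(zero_constant(7, 0, 10, 7), 5)
  # both endpoints zero: fall back to the reference magnitude
  expect_equal(zero_constant(0, 0, 42, 7), 50)
  # all three zero is unusable
  expect_true(is.na(zero_constant(0, 0, 0, 3)))
  expect_error(zero_constant(1, 2, 3, 10), "1..9")
})

test_that("exponential debt matches quadrature on the worked example chain", {
  d <- compute_debt(rec(2, 8, 10, 10))
  expect_equal(d$scenario, "a")
  expect_equal(d$r, log(4) / 10, tolerance = 1e-12)
  expect_equal(d$auc, simpson_auc(2, 8, 10), tolerance = 1e-8)
  expect_equal(d$rd_per_annum, 10 - 6 / log(4), tolerance = 1e-12)
  expect_equal(d$ratio_pct, oracle_ratio(2, 8, 10, 10), tolerance = 1e-7)
  expect_equal(d$ratio_pct, 56.719, tolerance = 1e-4)

  # flat trajectory: the r -> 0 limit
  flat <- compute_debt(rec(4, 4, 10, 5))
  expect_equal(flat$rd_per_annum, 6)
  expect_equal(flat$ratio_pct, 60)

  # both endpoints above the reference: transformed to (4, 8) first
  b <- compute_debt(rec(25, 12.5, 10, 10))
  expect_true(b$transformed)
  expect_equal(b$rd_per_annum, 10 - 4 / log(2), tolerance = 1e-12)
  expect_equal(b$ratio_pct, oracle_ratio(4, 8, 10, 10), tolerance = 1e-7)
  expect_equal(b$ratio_pct, 42.294, tolerance = 1e-3)
})

test_that("linear debt is the trapezoid, after the same preprocessing", {
  expect_equal(compute_debt(rec(2, 8, 10, 10), method = "linear")$ratio_pct, 50)
  expect_equal(compute_debt(rec(8, 2, 10, 4), method = "linear")$ratio_pct, 50)
  # zero start with explicit constant: both endpoints shifted inside the mean
  z <- compute_debt(rec(0, 6, 10, 3), method = "linear", zero_const = 5)
  expect_equal(z$ratio_pct, oracle_ratio(5, 11, 10, 3, method = "linear"),
               tolerance = 1e-10)
})

test_that("closed-form AUC equals Simpson quadrature on random triples", {
  set.seed(101)
  n <- 300
  xs <- rlnorm(n, 1, 1)
  xe <- rlnorm(n, 1, 1)     # both signs of r occur
  tt <- rlnorm(n, 1.5, 0.5)
  d <- compute_debt(tibble::tibble(x_start = xs, x_end = xe,
                                   x_ref = pmax(xs, xe) * 1.5, t_years = tt))
  oracle <- mapply(simpson_auc, xs, xe, tt)
  expect_lt(max(abs(d$auc - oracle) / oracle), 1e-8)
})

test_that("debt ratio respects the 100% recovery threshold on both branches", {
  expect_equal(debt_ratio(5.6719, 10), 56.719)
  expect_equal(debt_ratio(10, 10), 100)
  expect_equal(debt_ratio(20, 10), 50)    # reflected branch
  expect_equal(debt_ratio(-3, 10), 0)     # clamped
  expect_error(debt_ratio(5, 0), "x_ref")
})

test_that("ratios are scale invariant and vanish at the fixed point", {
  set.seed(7)
  base <- tibble::tibble(x_start = runif(100, 0.1, 30),
                         x_end = runif(100, 0.1, 30),
                         x_ref = runif(100, 0.1, 30), t_years = rlnorm(100, 2, 0.5))
  r1 <- compute_debt(base)$ratio_pct
  for (k in c(0.01, 3, 1e4)) {
    scaled <- dplyr::mutate(base, x_start = x_start * k, x_end = x_end * k,
                            x_ref = x_ref * k)
    expect_equal(compute_debt(scaled)$ratio_pct, r1, tolerance = 1e-9)
  }
  fixed <- compute_debt(rec(3, 3, 3, 5))
  expect_equal(fixed$ratio_pct, 0)
})

test_that("exponential >= linear for below-reference monotone recovery", {
  set.seed(8)
  xr <- runif(200, 5, 50)
  xs <- xr * runif(200, 0.05, 0.9)
  xe <- xs + (xr - xs) * runif(200, 0.05, 0.95)
  df <- tibble::tibble(x_start = xs, x_end = xe, x_ref = xr,
                       t_years = rlnorm(200, 2, 0.5))
  e <- compute_debt(df)$ratio_pct
  l <- compute_debt(df, method = "linear")$ratio_pct
  expect_true(all(e >= l - 1e-10))
  expect_lt(max(abs(e - l)), max(e))  # differences small relative to the effect
})

test_that("opposite-sign endpoints fall back to the linear formula, flagged", {
  d <- compute_debt(rec(-2, 5, 10, 4))
  expect_equal(d$method, "linear")
  expect_match(d$flags, "linear_fallback")
  expect_equal(d$rd_per_annum, 10 - (5 - 2) / 2)
  # all-zero record is unusable
  z <- compute_debt(rec(0, 0, 0, 4))
  expect_false(z$usable)
  expect_match(z$flags, "all_zero")
})

test_that("zero-reference records are shifted by the constant and bounded", {
  d <- compute_debt(rec(3, 7, 0, 10), zero_strategy = 7)
  expect_equal(d$scenario, "e")
  expect_equal(d$zero_constant, 5)  # max(3,7) = 7, decade [1,10)
  expect_true(d$ratio_pct >= 0 && d$ratio_pct <= 100)
  # the shifted triple is (8, 12, 5): both above ref, reflected inside
  expect_true(d$transformed)
})

test_that("strategy selection demands zeros and a comparison pool", {
  clean <- generate_recovery_db(synthetic_config(
    n_studies = 10, zero_endpoint_fraction = 0,
    scenario_mixture = c(a = 1, b = 0, c = 0, d = 0, e = 0), seed = 2))
  expect_error(select_zero_strategy(clean), "zero-affected")
  few <- rec(c(0, 2), c(5, 8), c(10, 10))
  few$study_id <- c("a", "b")
  expect_error(select_zero_strategy(few), "20")
})
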