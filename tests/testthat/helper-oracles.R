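# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of the closed form, direct
# REML linear algebra instead of metafor.

# Simpson quadrature of the area under x_s * exp(r t) on [0, T].
simpson_auc <- function(x_s, x_e, t_total, panels = 1e4) {
  if (x_s == x_e) return(x_s * t_total)
  r <- log(x_e / x_s) / t_total
  f <- function(t) x_s * exp(r * t)
  h <- t_total / panels
  t <- seq(0, t_total, length.out = panels + 1)
  y <- f(t)
  h / 3 * (y[1] + y[panels + 1] +
             4 * sum(y[seq(2, panels, by = 2)]) +
             2 * sum(y[seq(3, panels - 1, by = 2)]))
}

# Per-annum debt ratio by quadrature (or trapezoid), applied to values that
# have already been through the same preprocessing as the implementation.
oracle_ratio <- function(x_s, x_e, x_ref, t_total, method = "exponential") {
  auc <- if (method == "exponential") simpson_auc(x_s, x_e, t_total) else
    (x_s + x_e) * t_total / 2
  rdt <- (x_ref * t_total - auc) / t_total
  a <- abs(x_ref)
  if (rdt < 0) 0 else if (rdt <= a) 100 * rdt / a else 100 * a / rdt
}

# REML log-likelihood of the three-level model at (tau2_study, tau2_effect),
# by direct dense linear algebra.
reml_ll_3level <- function(tau2_s, tau2_e, y, v, study, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  Z <- stats::model.matrix(~ 0 + factor(study))
  Sigma <- diag(v + tau2_e, n) + tau2_s * tcrossprod(Z)
  Wi <- solve(Sigma)
  XtWX <- crossprod(X, Wi %*% X)
  beta <- solve(XtWX, crossprod(X, Wi %*% y))
  r <- y - X %*% beta
  p <- ncol(X)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       determinant(XtWX, logarithm = TRUE)$modulus +
                       crossprod(r, Wi %*% r)))
}

# Oracle REML solution: coarse grid over the two variance components, then a
# bounded quasi-Newton polish of the same objective.
reml_oracle_3level <- function(y, v, study, grid_max = NULL) {
  if (is.null(grid_max)) grid_max <- max(4 * var(y), 1)
  gr <- seq(0, grid_max, length.out = 25)
  best <- c(0, 0); best_ll <- -Inf
  for (a in gr) for (b in gr) {
    ll <- reml_ll_3level(a, b, y, v, study)
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  op <- optim(best, function(p) -reml_ll_3level(p[1], p[2], y, v, study),
              method = "L-BFGS-B", lower = c(0, 0),
              upper = c(4 * grid_max, 4 * grid_max),
              control = list(factr = 10))
  tau <- op$par
  n <- length(y)
  Z <- stats::model.matrix(~ 0 + factor(study))
  Sigma <- diag(v + tau[2], n) + tau[1] * tcrossprod(Z)
  Wi <- solve(Sigma)
  X <- matrix(1, n, 1)
  XtWX <- crossprod(X, Wi %*% X)
  mu <- as.numeric(solve(XtWX, crossprod(X, Wi %*% y)))
  list(mu = mu, se = sqrt(1 / as.numeric(XtWX)),
       tau2_study = tau[1], tau2_effect = tau[2], ll = -op$value)
}

# Two-level REML oracle (no study clustering): dense 1-D grid over tau2 plus
# golden-section refinement of the profile REML objective.
reml_oracle_2level <- function(y, v) {
  ll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    -0.5 * ((length(y) - 1) * log(2 * pi) + sum(log(v + tau2)) +
              log(sum(w)) + sum(w * (y - mu)^2))
  }
  gr <- seq(0, max(4 * var(y), 1), length.out = 400)
  lls <- vapply(gr, ll, numeric(1))
  i <- which.max(lls)
  lo <- gr[max(1, i - 1)]; hi <- gr[min(length(gr), i + 1)]
  op <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-12)
  tau2 <- if (op$objective >= lls[i]) op$maximum else gr[i]
  w <- 1 / (v + tau2)
  list(mu = sum(w * y) / sum(w), tau2 = tau2,
       se = sqrt(1 / sum(w)), ll = ll(tau2))
}

# Direct simulation of an effect table from the three-level model, for
# meta_model-level checks that do not need the full record geometry.
simulate_effect_table <- function(n_studies, effects_per_study, mu,
                                  tau2_study, tau2_effect, v = 1,
                                  categories = NULL) {
  idx <- rep(seq_len(n_studies), each = effects_per_study)
  n <- length(idx)
  u <- rnorm(n_studies, 0, sqrt(tau2_study))
  cat_col <- if (is.null(categories)) rep("all", n) else
    sample(categories, n, replace = TRUE)
  mu_i <- if (length(mu) > 1) mu[cat_col] else rep(mu, n)
  y <- mu_i + u[idx] + rnorm(n, 0, sqrt(tau2_effect)) + rnorm(n, 0, sqrt(v))
  tibble::tibble(effect = y, variance = v,
                 study_id = paste0("s", idx), group = cat_col)
}
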