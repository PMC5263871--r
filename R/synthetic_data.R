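# Synthetic outcome-measure databases with known ground truth.
#
# The generator works backwards from the estimand: it draws a true debt ratio
# for every record from the three-level model (category mean + study effect +
# within-study effect + sampling error), then constructs an (x_start, x_end,
# x_ref, t_years) triple whose forward debt computation returns exactly that
# ratio. Scenario b/d records are built by reflecting endpoints above the
# reference (the forward inverse transform undoes the reflection); zero-value
# records are built so that the median-same-decade constant (strategy 7)
# reproduces the drawn truth exactly.

#' Configuration for the synthetic-database generator
#'
#' Defaults emulate the statistical structure of the source database at desk
#' scale: effects clustered in studies with between-study and within-study
#' heterogeneity, ~79% of sampling variances missing, a scenario mixture
#' proportional to the observed counts (a:b:c:d:e = 1993:424:446:953:236),
#' zero endpoints in 628/3816 of records, and log-normal recovery times with
#' median 9 years.
#'
#' @param n_studies Number of studies.
#' @param effects_per_study Integer vector of possible effect counts per study
#'   (sampled uniformly).
#' @param true_means Named vector of true mean debt ratios (%) per metric.
#' @param tau2_study,tau2_effect Between-study and within-study (effect-level)
#'   variance components.
#' @param sampling_variance_median,sampling_variance_sdlog Log-normal law for
#'   the per-record sampling variance; a median of 0 disables sampling error.
#' @param missing_variance_fraction Fraction of records whose variance is
#'   masked (reported as missing).
#' @param scenario_mixture Named probabilities over scenarios a--e (normalized
#'   internally).
#' @param zero_endpoint_fraction Overall fraction of records with a zero
#'   start or end value (realized within scenarios a and c).
#' @param t_years_meanlog,t_years_sdlog Log-normal law for recovery time.
#' @param x_ref_scale Typical magnitude of reference values.
#' @param metric_probs Named sampling probabilities for the four metrics.
#' @param seed Integer seed; the same config is bitwise reproducible.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_studies = 150,
                             effects_per_study = 2:6,
                             true_means = c(abundance = 48.5, diversity = 30,
                                            carbon = 37, nitrogen = 36),
                             tau2_study = 25,
                             tau2_effect = 4,
                             sampling_variance_median = 2,
                             sampling_variance_sdlog = 0.8,
                             missing_variance_fraction = 0.79,
                             scenario_mixture = c(a = 1993, b = 424, c = 446,
                                                  d = 953, e = 236),
                             zero_endpoint_fraction = 628 / 3816,
                             t_years_meanlog = log(9),
                             t_years_sdlog = 0.86,
                             x_ref_scale = 100,
                             metric_probs = c(abundance = 0.52, diversity = 0.29,
                                              carbon = 0.12, nitrogen = 0.07),
                             seed = 1L) {
  stopifnot(n_studies >= 1, all(effects_per_study >= 1),
            tau2_study >= 0, tau2_effect >= 0,
            missing_variance_fraction >= 0, missing_variance_fraction <= 1,
            zero_endpoint_fraction >= 0, zero_endpoint_fraction <= 1,
            all(scenario_mixture >= 0), sum(scenario_mixture) > 0,
            setequal(names(scenario_mixture), c("a", "b", "c", "d", "e")),
            setequal(names(true_means), names(metric_probs)))
  cfg <- list(n_studies = n_studies, effects_per_study = effects_per_study,
              true_means = true_means, tau2_study = tau2_study,
              tau2_effect = tau2_effect,
              sampling_variance_median = sampling_variance_median,
              sampling_variance_sdlog = sampling_variance_sdlog,
              missing_variance_fraction = missing_variance_fraction,
              scenario_mixture = scenario_mixture / sum(scenario_mixture),
              zero_endpoint_fraction = zero_endpoint_fraction,
              t_years_meanlog = t_years_meanlog, t_years_sdlog = t_years_sdlog,
              x_ref_scale = x_ref_scale,
              metric_probs = metric_probs / sum(metric_probs),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# Evaluate code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Solve for the end value that yields a target debt ratio
#'
#' Constructive inverse of the exponential debt formula: given `x_start`,
#' `x_ref` and a target ratio, finds `x_end` such that
#' `x_ref - logmean(x_start, x_end) = ratio * x_ref / 100`, where the
#' logarithmic mean is the time average of the exponential trajectory. The
#' map is monotone (the log-mean increases in `x_end`), so bisection on a
#' bracketed interval converges; tolerance 1e-10 relative.
#'
#' @param ratio_pct Target debt ratio in (0, 100).
#' @param x_start Positive start value below `x_ref`.
#' @param x_ref Positive reference value.
#' @param t_years Recovery time (the ratio does not depend on it; kept for
#'   interface symmetry).
#' @return The end value `x_end > 0`.
#' @export
#' @examples
#' invert_debt(56.719, 2, 10)  # ~ 8
invert_debt <- function(ratio_pct, x_start, x_ref, t_years = 1) {
  if (length(ratio_pct) > 1 || length(x_start) > 1 || length(x_ref) > 1) {
    return(mapply(invert_debt, ratio_pct, x_start, x_ref, t_years))
  }
  if (!is.finite(ratio_pct) || ratio_pct <= 0 || ratio_pct >= 100) {
    abort("ratio_pct must be in (0, 100)")
  }
  if (x_start <= 0 || x_ref <= 0 || x_start >= x_ref) {
    abort("invert_debt() requires 0 < x_start < x_ref")
  }
  target <- x_ref * (1 - ratio_pct / 100)
  if (abs(target - x_start) < 1e-14 * x_ref) return(x_start)
  g <- function(xe) log_mean(x_start, xe) - target
  if (target > x_start) {
    lo <- x_start * (1 + 1e-12)
    hi <- max(2 * target, x_start * 2)
    while (g(hi) < 0) hi <- hi * 2
  } else {
    hi <- x_start * (1 - 1e-12)
    lo <- x_start * 1e-8
    while (g(lo) > 0) lo <- lo / 10
  }
  uniroot(g, c(lo, hi), tol = 1e-10 * x_ref)$root
}

# Solve log_mean(a, x) = target for x on a bracket below a (declining case).
solve_logmean_below <- function(a, target) {
  stopifnot(target < a, target > 0)
  g <- function(x) log_mean(x, a) - target
  lo <- a * 1e-10
  while (g(lo) > 0) lo <- lo / 10
  uniroot(g, c(lo, a * (1 - 1e-12)), tol = 1e-12 * a)$root
}

# Build a below-reference pair (xs, xe) with log-mean x_ref*(1 - rho/100).
# increasing = scenario-a geometry (xs < xe <= x_ref), else scenario c.
build_pair <- function(rho, x_ref, increasing) {
  target <- x_ref * (1 - rho / 100)
  if (increasing) {
    # need log_mean(xs, x_ref) >= target so xe <= x_ref: xs >= xs_min
    h <- function(u) log_mean(u, x_ref) - target
    lo <- x_ref * 1e-12
    while (h(lo) > 0) lo <- lo / 10
    xs_min <- uniroot(h, c(lo, target), tol = 1e-12 * x_ref,
                      extendInt = "upX")$root
    xs <- xs_min + runif(1, 0.05, 0.95) * (target - xs_min)
    xe <- invert_debt(rho, xs, x_ref)
  } else {
    xs <- target + runif(1, 0.05, 0.95) * (x_ref - target)
    xe <- solve_logmean_below(xs, target)
  }
  c(xs = xs, xe = xe)
}

# Zero-reference (scenario e) record reproducing rho exactly under the
# strategy-7 constant c = 5 * 10^k: work on the scale z = Z / c of the
# post-adjustment reflected values; the magnitude-consistency constraint
# (max(x_start, x_end) must lie in c's own decade) restricts min(z) to
# (1/3, 5/6], which is feasible for rho roughly in (9, 66).
build_e_record <- function(rho, k) {
  q <- 1 - rho / 100
  cst <- 5 * 10^k
  f <- function(z) (1 - z) / (-log(z)) # log_mean(z, 1)
  z_lb <- uniroot(function(z) f(z) - q, c(1e-6, 1 - 1e-9),
                  tol = 1e-12)$root          # smallest zs with L(zs, 1) >= q
  lo <- max(1 / 3 + 1e-9, z_lb + 1e-12)
  hi <- min(q * (1 - 1e-9), 5 / 6)
  if (lo >= hi) return(NULL)
  zs <- lo + runif(1, 0.05, 0.95) * (hi - lo)
  g <- function(ze) log_mean(zs, ze) - q
  ze <- uniroot(g, c(q, 1 - 1e-12), tol = 1e-14, extendInt = "upX")$root
  # Undo reflection about the (future) reference c, then undo the shift by c.
  c(xs = cst * (1 / zs - 1), xe = cst * (1 / ze - 1), cst = cst)
}

# Zero-endpoint record (x_start = 0 if increasing, else x_end = 0) exact
# under strategy 7: pick the non-zero endpoint s in the lower third of decade
# k so its strategy-7 constant is c = 5*10^k, then solve the reference from
# the target ratio.
build_zero_record <- function(rho, k, increasing) {
  cst <- 5 * 10^k
  s <- 10^k * runif(1, 1, 3)
  lm <- log_mean(cst, s + cst)
  x_ref <- lm / (1 - rho / 100)
  if (increasing) c(xs = 0, xe = s, xr = x_ref) else c(xs = s, xe = 0, xr = x_ref)
}

#' Generate a synthetic outcome-measure database
#'
#' Draws studies and effects from the three-level model, then constructs for
#' each record a (start, end, reference, time) quadruple whose forward debt
#' computation (with the exponential method and, for zero-affected records,
#' the strategy-7 constant) returns the drawn debt ratio. True ratios are
#' clamped to (1, 99) to keep the inversion well-posed; zero-reference
#' records are additionally confined to ratios in (10, 65), where a
#' magnitude-consistent constant exists (clamp counts are reported in the
#' truth attribute).
#'
#' @param config A [synthetic_config()].
#' @return A tibble of outcome measures in the canonical schema, with
#'   attribute `"truth"`: a list holding the config, the per-study random
#'   effects, per-record true ratios and variances, and clamp counts.
#' @export
generate_recovery_db <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    metrics <- names(config$true_means)
    n_eff <- config$effects_per_study[sample.int(length(config$effects_per_study),
                                                 config$n_studies, replace = TRUE)]
    study_id <- paste0("S", sprintf("%03d", seq_len(config$n_studies)))
    u <- rnorm(config$n_studies, 0, sqrt(config$tau2_study))
    idx <- rep(seq_len(config$n_studies), n_eff)
    n <- length(idx)

    metric <- sample(metrics, n, replace = TRUE, prob = config$metric_probs)
    mu <- unname(config$true_means[metric])
    w <- rnorm(n, 0, sqrt(config$tau2_effect))
    v <- if (config$sampling_variance_median > 0) {
      rlnorm(n, log(config$sampling_variance_median), config$sampling_variance_sdlog)
    } else rep(0, n)
    eps <- rnorm(n, 0, sqrt(v))
    rho_raw <- mu + u[idx] + w + eps
    rho <- pmin(pmax(rho_raw, 1), 99)
    n_clamped <- sum(rho != rho_raw)

    scen <- sample(names(config$scenario_mixture), n, replace = TRUE,
                   prob = config$scenario_mixture)
    p_ac <- sum(config$scenario_mixture[c("a", "c")])
    p_zero_cond <- if (p_ac > 0) min(1, config$zero_endpoint_fraction / p_ac) else 0
    zero_flag <- scen %in% c("a", "c") & runif(n) < p_zero_cond

    t_years <- rlnorm(n, config$t_years_meanlog, config$t_years_sdlog)
    x_ref <- config$x_ref_scale * rlnorm(n, 0, 0.6)

    xs <- xe <- xr <- numeric(n)
    n_e_clamped <- 0L
    for (i in seq_len(n)) {
      if (scen[i] == "e") {
        rho_e <- min(max(rho[i], 10), 65)
        if (rho_e != rho[i]) {
          n_e_clamped <- n_e_clamped + 1L
          rho[i] <- rho_e
        }
        k <- sample(-1:2, 1)
        rec <- build_e_record(rho_e, k)
        xs[i] <- rec[["xs"]]; xe[i] <- rec[["xe"]]; xr[i] <- 0
      } else if (zero_flag[i]) {
        k <- sample(-1:2, 1)
        rec <- build_zero_record(rho[i], k, increasing = scen[i] == "a")
        xs[i] <- rec[["xs"]]; xe[i] <- rec[["xe"]]; xr[i] <- rec[["xr"]]
      } else if (scen[i] %in% c("a", "c")) {
        p <- build_pair(rho[i], x_ref[i], increasing = scen[i] == "a")
        xs[i] <- p[["xs"]]; xe[i] <- p[["xe"]]; xr[i] <- x_ref[i]
      } else if (scen[i] == "b") {
        p <- build_pair(rho[i], x_ref[i], increasing = runif(1) < 0.5)
        xs[i] <- x_ref[i]^2 / p[["xs"]]; xe[i] <- x_ref[i]^2 / p[["xe"]]
        xr[i] <- x_ref[i]
      } else { # d: reflect only the start of a declining below-ref pair
        p <- build_pair(rho[i], x_ref[i], increasing = FALSE)
        xs[i] <- x_ref[i]^2 / p[["xs"]]; xe[i] <- p[["xe"]]
        xr[i] <- x_ref[i]
      }
    }

    masked <- runif(n) < config$missing_variance_fraction
    variance <- ifelse(masked | v == 0, NA_real_, v)

    submetric <- rep("none", n)
    div <- metric == "diversity"
    submetric[div] <- sample(c("richness", "diversity_index"), sum(div),
                             replace = TRUE, prob = c(0.7, 0.3))
    cn <- metric %in% c("carbon", "nitrogen")
    submetric[cn] <- sample(c("pool", "flux"), sum(cn),
                            replace = TRUE, prob = c(0.88, 0.12))

    db <- tibble::tibble(
      study_id = study_id[idx],
      outcome_id = paste0(study_id[idx], "_", stats::ave(idx, idx, FUN = seq_along)),
      metric = metric, submetric = submetric,
      ecosystem = sample(debt_levels$ecosystem, n, replace = TRUE,
                         prob = c(0.30, 0.17, 0.18, 0.12, 0.08, 0.15)),
      disturbance = sample(debt_levels$disturbance, n, replace = TRUE,
                           prob = c(0.24, 0.16, 0.11, 0.10, 0.12, 0.09,
                                    0.05, 0.04, 0.04, 0.05)),
      x_start = xs, x_end = xe, x_ref = xr, t_years = t_years,
      variance = variance)

    attr(db, "truth") <- list(
      config = config,
      studies = tibble::tibble(study_id = study_id, u = u),
      true_ratio = rho, mu_metric = mu, w = w, eps = eps,
      sampling_variance = v, scenario = scen, zero_endpoint = zero_flag,
      n_clamped = n_clamped, n_e_clamped = n_e_clamped)
    db
  })
}

#' Ground truth of a synthetic database
#'
#' @param db A tibble from [generate_recovery_db()].
#' @return The truth list attached by the generator.
#' @export
synthetic_truth <- function(db) attr(db, "truth")

#' Write a synthetic database and its truth sidecar
#'
#' Writes the records in the canonical CSV schema plus a YAML sidecar with
#' the generating configuration, the per-study random effects and per-record
#' true ratios, so downstream runs can be scored against ground truth.
#'
#' @param db A tibble from [generate_recovery_db()].
#' @param path Output CSV path.
#' @param truth_path Output YAML path; default replaces the extension.
#' @return `path`, invisibly.
#' @export
write_synthetic_db <- function(db, path,
                               truth_path = sub("\\.csv$", "_truth.yaml", path)) {
  write_results(db, path)
  tr <- synthetic_truth(db)
  if (!is.null(tr)) {
    cfg <- tr$config
    yaml::write_yaml(list(
      config = lapply(unclass(cfg), function(x)
        if (is.numeric(x) || is.character(x)) as.vector(x) else x),
      studies = list(study_id = tr$studies$study_id, u = tr$studies$u),
      true_ratio = tr$true_ratio,
      scenario = tr$scenario,
      zero_endpoint = tr$zero_endpoint,
      n_clamped = tr$n_clamped,
      n_e_clamped = tr$n_e_clamped), truth_path)
  }
  invisible(path)
}
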