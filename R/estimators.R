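# Core causal estimators: Wald ratios, IVW, weighted median, MR-Egger.

#' Construct an MR causal estimate
#'
#' @param method method tag (e.g. "ivw", "weighted_median").
#' @param beta causal log odds ratio per exposure-scale unit.
#' @param se its standard error.
#' @param n_snps number of instruments used.
#' @param scale exposure-scale unit factor, carried for reporting.
#' @return list of class `mr_estimate` with Wald-type 95% confidence limits
#'   and the exponentiated odds-ratio scale.
#' @export
mr_estimate <- function(method, beta, se, n_snps, scale = 1) {
  z <- stats::qnorm(0.975)
  est <- list(
    method = method,
    beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pval = z_pvalue(beta / se),
    or = exp(beta), or_low = exp(beta - z * se), or_high = exp(beta + z * se),
    n_snps = n_snps, scale = scale
  )
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$method, x$n_snps, x$or, x$or_low, x$or_high, x$pval))
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' Computes the per-instrument causal ratio theta_j = beta_Yj / beta_Xj with
#' either first-order standard errors se_j = se_Yj / |beta_Xj| (the common
#' default, exact when the exposure betas are treated as known) or
#' second-order delta-method standard errors
#' sqrt(se_Yj^2/beta_Xj^2 + beta_Yj^2 se_Xj^2 / beta_Xj^4), which also
#' propagate the exposure-beta uncertainty.
#'
#' @param set a `harmonized_set`.
#' @param se_order `"first"` (default) or `"second"`.
#' @return list of class `ratio_estimates` with components `rsid`, `theta`,
#'   `se`, `weight` (= 1/se^2).
#' @export
wald_ratios <- function(set, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  weak <- which(set$beta_exp == 0)
  if (length(weak))
    stop_mr(sprintf("exposure beta is exactly 0 for %s; Wald ratio undefined",
                    paste(set$rsid[weak], collapse = ", ")),
            "mr_weak_instrument")
  theta <- set$beta_out / set$beta_exp
  se <- if (se_order == "first") {
    set$se_out / abs(set$beta_exp)
  } else {
    sqrt(set$se_out^2 / set$beta_exp^2 +
           set$beta_out^2 * set$se_exp^2 / set$beta_exp^4)
  }
  structure(list(rsid = set$rsid, theta = theta, se = se, weight = 1 / se^2),
            class = "ratio_estimates")
}

# Closed-form IVW on ratio vectors; shared by the public estimator and the
# internal resampling loops.
ivw_fit <- function(theta, se, model, J = length(theta)) {
  w <- 1 / se^2
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  if (model == "auto") model <- if (J < 4L) "fixed" else "random"
  se_out <- if (model == "random") {
    se_fixed * max(1, sqrt(q / (J - 1)))
  } else se_fixed
  list(beta = beta, se = se_out, q = q, model = model)
}

#' Inverse-variance weighted estimator with heterogeneity diagnostics
#'
#' Meta-analyzes the per-SNP Wald ratios with inverse-variance weights:
#' beta = sum(w_j theta_j) / sum(w_j) with w_j = 1/se_j^2. The fixed-effect
#' standard error is (sum w_j)^(-1/2); under the multiplicative
#' random-effects model it is inflated by max(1, sqrt(Q/(J-1))) where Q is
#' Cochran's heterogeneity statistic. `model = "auto"` (default) uses fixed
#' effects for J < 4 and multiplicative random effects otherwise.
#'
#' @param set a `harmonized_set` with at least 2 instruments.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param se_order ratio standard-error order, see [wald_ratios()].
#' @return list with `estimate` (an [mr_estimate]) and `heterogeneity`
#'   (Cochran's Q, its df and p-value, and the instrument-strength I2_GX).
#' @export
mr_ivw <- function(set, model = c("auto", "fixed", "random"),
                   se_order = "first") {
  model <- match.arg(model)
  J <- nrow(set)
  if (J < 2L)
    stop_mr("IVW requires at least 2 instruments", "mr_insufficient_instruments")
  r <- wald_ratios(set, se_order)
  fit <- ivw_fit(r$theta, r$se, model, J)
  est <- mr_estimate(paste0("ivw_", fit$model), fit$beta, fit$se, J,
                     scale = attr(set, "exposure_scale") %||% 1)
  het <- list(
    cochran_q = fit$q, q_df = J - 1L,
    q_pval = stats::pchisq(fit$q, df = J - 1L, lower.tail = FALSE),
    i2_gx = i2_gx(set),
    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
    egger_intercept_pval = NA_real_
  )
  list(estimate = est, heterogeneity = het)
}

# Weighted-median point estimate on sorted ratios: interpolate theta against
# the cumulative weight midpoints p_j = cumsum(w') - w'/2 at p = 0.5.
weighted_median_point <- function(theta, weight) {
  o <- order(theta)
  th <- theta[o]
  wn <- weight[o] / sum(weight)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(th[1])
  J <- length(th)
  if (0.5 >= p[J]) return(th[J])
  stats::approx(p, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent when at least half of the analytic weight comes from valid
#' instruments. The point estimate inverts the weighted empirical CDF of the
#' Wald ratios at 0.5; the standard error is the standard deviation of the
#' estimate over `n_boot` parametric bootstrap resamples in which the
#' exposure and outcome betas are redrawn from normals with their reported
#' standard errors.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param n_boot number of bootstrap resamples (>= 100; default 1000).
#' @param seed RNG seed for the bootstrap (default 1), so the stochastic
#'   standard error is reproducible.
#' @param se_order ratio standard-error order, see [wald_ratios()].
#' @return an [mr_estimate].
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = 1L,
                               se_order = "first") {
  J <- nrow(set)
  if (J < 3L)
    stop_mr("weighted median requires at least 3 instruments",
            "mr_insufficient_instruments")
  if (n_boot < 100L)
    stop_mr("n_boot must be at least 100", "mr_domain_error")
  r <- wald_ratios(set, se_order)
  point <- weighted_median_point(r$theta, r$weight)

  boots <- withr::with_seed(seed, {
    bx <- matrix(stats::rnorm(n_boot * J, set$beta_exp, set$se_exp),
                 nrow = n_boot, byrow = TRUE)
    by <- matrix(stats::rnorm(n_boot * J, set$beta_out, set$se_out),
                 nrow = n_boot, byrow = TRUE)
    th <- by / bx
    w <- (bx / matrix(set$se_out, n_boot, J, byrow = TRUE))^2
    vapply(seq_len(n_boot),
           function(b) weighted_median_point(th[b, ], w[b, ]),
           numeric(1))
  })
  mr_estimate("weighted_median", point, stats::sd(boots), J,
              scale = attr(set, "exposure_scale") %||% 1)
}

# Orient instrument pairs so every exposure beta is positive (negating both
# betas of a pair leaves the Wald ratio unchanged but is required before
# fitting an intercept).
orient_positive <- function(set) {
  flip <- set$beta_exp < 0
  set$beta_exp[flip] <- -set$beta_exp[flip]
  set$beta_out[flip] <- -set$beta_out[flip]
  set
}

# Closed-form WLS of y on (1, x) with weights w; SEs scaled multiplicatively
# by max(1, sqrt(RSS_w/(n-2))).
egger_wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (abs(det) < .Machine$double.eps * sw * swxx)
    stop_mr("degenerate design in Egger regression (no spread in exposure betas)",
            "mr_numerical_error")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  n <- length(x)
  scale2 <- max(1, sum(w * resid^2) / (n - 2))
  var_slope <- sw / det * scale2
  var_intercept <- swxx / det * scale2
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_intercept),
       rss = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas
#' (weights 1/se_Yj^2) with a free intercept, after orienting all pairs so
#' the exposure betas are positive. The slope is the pleiotropy-adjusted
#' causal estimate (consistent under the InSIDE assumption); the intercept
#' estimates the average directional pleiotropic effect and its p-value is
#' the directional-pleiotropy test. Standard errors carry a multiplicative
#' residual scale of max(1, sqrt(RSS/(J-2))).
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @return list with `estimate` (slope, an [mr_estimate]) and
#'   `heterogeneity` (intercept, its SE and p-value, plus I2_GX).
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 3L)
    stop_mr("MR-Egger requires at least 3 instruments",
            "mr_insufficient_instruments")
  s <- orient_positive(set)
  fit <- egger_wls(s$beta_exp, s$beta_out, 1 / s$se_out^2)
  est <- mr_estimate("egger", fit$slope, fit$se_slope, J,
                     scale = attr(set, "exposure_scale") %||% 1)
  het <- list(
    cochran_q = fit$rss, q_df = J - 2L,
    q_pval = stats::pchisq(fit$rss, df = J - 2L, lower.tail = FALSE),
    i2_gx = i2_gx(set),
    egger_intercept = fit$intercept,
    egger_intercept_se = fit$se_intercept,
    egger_intercept_pval = z_pvalue(fit$intercept / fit$se_intercept)
  )
  list(estimate = est, heterogeneity = het)
}

#' Instrument-strength statistic I2_GX
#'
#' Quantifies violation of the no-measurement-error (NOME) assumption in
#' MR-Egger: an I2-type statistic on the exposure betas,
#' I2_GX = max(0, (Q_GX - (J-1)) / Q_GX) where Q_GX is the inverse-variance
#' weighted dispersion of the (positively oriented) exposure betas around
#' their weighted mean. Values below 0.9 indicate substantial regression
#' dilution of the Egger slope; 1 - I2_GX is the expected relative dilution.
#'
#' @param set a `harmonized_set` with at least 2 instruments.
#' @return a scalar in `[0, 1]`.
#' @export
i2_gx <- function(set) {
  if (any(set$se_exp <= 0))
    stop_mr("exposure standard errors must be > 0", "mr_domain_error")
  if (nrow(set) < 2L)
    stop_mr("I2_GX requires at least 2 instruments",
            "mr_insufficient_instruments")
  b <- abs(set$beta_exp)
  w <- 1 / set$se_exp^2
  mu <- sum(w * b) / sum(w)
  q_gx <- sum(w * (b - mu)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (nrow(set) - 1)) / q_gx)
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation-extrapolation correction of the Egger slope for regression
#' dilution caused by measurement error in the exposure betas. For each
#' lambda > 0 in `lambda_grid`, `n_sim` replicate datasets are generated by
#' adding noise of variance lambda * se_Xj^2 to each exposure beta; the mean
#' Egger slope is computed per lambda, a quadratic in lambda is fitted
#' through the means (lambda = 0 being the naive slope) and extrapolated to
#' lambda = -1, the error-free limit. The standard error extrapolates the
#' SIMEX jackknife variance component (mean within-replicate model variance
#' minus between-replicate variance) to lambda = -1, falling back to the
#' naive Egger variance if the extrapolated variance is not positive.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param lambda_grid nonnegative noise multiples; default
#'   `c(0, 0.5, 1, 1.5, 2)`.
#' @param n_sim replicates per lambda (>= 100; default 1000).
#' @param seed RNG seed (default 1).
#' @return an [mr_estimate] (method `"simex_egger"`) with attribute
#'   `"simex"` holding the per-lambda mean slopes.
#' @export
mr_simex_egger <- function(set, lambda_grid = c(0, 0.5, 1, 1.5, 2),
                           n_sim = 1000L, seed = 1L) {
  J <- nrow(set)
  if (J < 3L)
    stop_mr("SIMEX-Egger requires at least 3 instruments",
            "mr_insufficient_instruments")
  if (n_sim < 100L)
    stop_mr("n_sim must be at least 100", "mr_domain_error")
  lambda_grid <- sort(unique(c(0, lambda_grid)))
  s <- orient_positive(set)
  w <- 1 / s$se_out^2
  naive <- egger_wls(s$beta_exp, s$beta_out, w)

  mean_slope <- numeric(length(lambda_grid))
  tau <- numeric(length(lambda_grid))  # jackknife variance component
  mean_slope[1] <- naive$slope
  tau[1] <- naive$se_slope^2

  withr::with_seed(seed, {
    for (k in seq_along(lambda_grid)[-1]) {
      lam <- lambda_grid[k]
      noise <- matrix(stats::rnorm(n_sim * J, 0, sqrt(lam) * s$se_exp),
                      nrow = n_sim, byrow = TRUE)
      bx <- matrix(s$beta_exp, n_sim, J, byrow = TRUE) + noise
      slopes <- numeric(n_sim)
      vars <- numeric(n_sim)
      for (b in seq_len(n_sim)) {
        f <- egger_wls(bx[b, ], s$beta_out, w)
        slopes[b] <- f$slope
        vars[b] <- f$se_slope^2
      }
      mean_slope[k] <- mean(slopes)
      tau[k] <- mean(vars) - stats::var(slopes)
    }
  })

  # quadratic extrapolation to lambda = -1
  quad_extrap <- function(y) {
    fit <- stats::lm(y ~ lambda_grid + I(lambda_grid^2))
    unname(stats::predict(fit, data.frame(lambda_grid = -1)))
  }
  beta_simex <- quad_extrap(mean_slope)
  var_simex <- quad_extrap(tau)
  if (!is.finite(var_simex) || var_simex <= 0) var_simex <- naive$se_slope^2
  est <- mr_estimate("simex_egger", beta_simex, sqrt(var_simex), J,
                     scale = attr(set, "exposure_scale") %||% 1)
  attr(est, "simex") <- data.frame(lambda = lambda_grid,
                                   mean_slope = mean_slope,
                                   tau = tau)
  est
}
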