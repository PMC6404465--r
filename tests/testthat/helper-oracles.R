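# Independent oracles used to cross-check the estimators. Each is written
# against the definition, not the implementation path it checks.

# IVW as weighted least squares through the origin of beta_out on beta_exp
# with weights 1/se_out^2 (equivalent to inverse-variance weighting of the
# Wald ratios with first-order SEs).
oracle_ivw_wls <- function(bx, by, sy) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  beta <- unname(stats::coef(fit))
  # undo lm's residual-variance scaling to recover the fixed-effect SE
  sigma <- summary(fit)$sigma
  se_fixed <- unname(sqrt(diag(stats::vcov(fit)))) / sigma
  q <- sum((1 / sy^2) * stats::residuals(fit)^2)
  list(beta = beta, se_fixed = se_fixed, q = q)
}

# Weighted median as numerical root of the interpolated weighted empirical
# CDF at one half (root finding, independent of the interpolation call used
# by the estimator).
oracle_weighted_median <- function(theta, weight) {
  o <- order(theta)
  th <- theta[o]
  wn <- weight[o] / sum(weight)
  p <- cumsum(wn) - wn / 2
  cdf <- stats::approxfun(th, p, rule = 2, ties = "ordered")
  stats::uniroot(function(t) cdf(t) - 0.5,
                 interval = range(th), tol = 1e-12)$root
}

# HetPen criterion by independent subset enumeration (combn by size, not bit
# masks) evaluated on a caller-supplied grid.
oracle_hetpen_mode <- function(theta, se, prior_valid, grid) {
  J <- length(theta)
  w <- 1 / se^2
  theta_s <- c(); se_s <- c(); logw <- c()
  for (size in 2:J) {
    subsets <- utils::combn(J, size, simplify = FALSE)
    for (idx in subsets) {
      ws <- w[idx]
      th <- sum(ws * theta[idx]) / sum(ws)
      q <- sum(ws * (theta[idx] - th)^2)
      theta_s <- c(theta_s, th)
      se_s <- c(se_s, 1 / sqrt(sum(ws)))
      logw <- c(logw, size * log(prior_valid) +
                  (J - size) * log(1 - prior_valid) - q / 2)
    }
  }
  wts <- exp(logw - max(logw)); wts <- wts / sum(wts)
  crit <- vapply(grid, function(t)
    sum(wts * stats::dnorm(t, theta_s, se_s)), numeric(1))
  grid[which.max(crit)]
}

# Brute-force palindromic orientation: try both orientations of the outcome
# record and keep the one whose eaf is concordant with the exposure eaf.
oracle_palindrome_orientation <- function(eaf_exp, eaf_out) {
  candidates <- data.frame(flip = c(FALSE, TRUE),
                           eaf = c(eaf_out, 1 - eaf_out))
  concordant <- (candidates$eaf - 0.5) * (eaf_exp - 0.5) > 0
  candidates$flip[concordant][1]
}

# Monte-Carlo power oracle: individual-level simulation of the outcome
# sample with a standardized genotype score and a logistic outcome model;
# the causal z-statistic is the genotype log-odds slope over its SE divided
# through the (known) instrument effect, as in a Wald ratio.
oracle_power_mc <- function(n_total, case_frac, r2, or_alt, alpha,
                            n_rep = 1500, seed = 1) {
  withr::with_seed(seed, {
    intercept <- stats::qlogis(case_frac)
    slope_g <- log(or_alt) * sqrt(r2)  # per genotype-score SD
    zcrit <- stats::qnorm(1 - alpha / 2)
    hits <- vapply(seq_len(n_rep), function(i) {
      g <- stats::rnorm(n_total)
      y <- stats::rbinom(n_total, 1, stats::plogis(intercept + slope_g * g))
      fit <- stats::glm(y ~ g, family = stats::binomial())
      z <- summary(fit)$coefficients["g", "z value"]
      abs(z) >= zcrit
    }, logical(1))
    mean(hits)
  })
}

# A clean 10-instrument world, optionally with strongly pleiotropic SNPs
# (offsets in outcome-SE units), used by the MR-PRESSO checks.
presso_world <- function(seed, offset_snps = integer(0), offset_size = 10) {
  withr::with_seed(seed, {
    J <- 10
    b <- stats::runif(J, 0.05, 0.15)
    sx <- rep(0.003, J)
    sy <- rep(0.01, J)
    mu_y <- 0.3 * b
    mu_y[offset_snps] <- mu_y[offset_snps] + offset_size * sy[offset_snps]
    harmonized_set(sprintf("rs%d", 1:J),
                   stats::rnorm(J, b, sx), sx,
                   stats::rnorm(J, mu_y, sy), sy)
  })
}

# Small simulated instrument sets for property-style loops.
random_instrument_set <- function(J, theta = 0.3, seed = 1,
                                  pleiotropy = rep(0, J)) {
  withr::with_seed(seed, {
    bx <- stats::runif(J, 0.05, 0.2)
    sx <- stats::runif(J, 0.005, 0.02)
    sy <- stats::runif(J, 0.02, 0.08)
    by <- stats::rnorm(J, theta * bx + pleiotropy, sy)
    harmonized_set(sprintf("rs%d", seq_len(J)), bx, sx, by, sy)
  })
}
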