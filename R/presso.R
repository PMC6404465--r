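# MR-PRESSO: residual-sum-of-squares global heterogeneity test, per-SNP
# outlier test, and post-removal distortion test.

# Leave-one-out through-origin WLS slopes (equivalently IVW on the remaining
# Wald ratios with first-order weights), in closed form for speed.
loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO outlier detection
#'
#' Detects horizontal-pleiotropy outliers among the instruments. For each
#' SNP j the leave-one-out IVW slope theta_(-j) is computed and the SNP's
#' residual r_j = beta_Yj - theta_(-j) * beta_Xj measured; the observed
#' residual sum of squares RSS_obs = sum(w_j r_j^2) (weighted by 1/se_Yj^2
#' by default) is compared to its distribution over `n_sim` simulated
#' datasets drawn under the no-pleiotropy model (beta_Xj* ~ N(beta_Xj,
#' se_Xj), beta_Yj* ~ N(theta_(-j) beta_Xj, se_Yj), residuals recomputed
#' leave-one-out on each simulated dataset). The global p-value uses the
#' add-one estimator (1 + #{RSS* >= RSS_obs}) / (n_sim + 1), so it is never
#' exactly zero. Each SNP's squared residual is compared to its own
#' simulated distribution, Bonferroni-adjusted by J; SNPs below
#' `outlier_threshold` (default 0.10) are flagged. The distortion test
#' compares the change in the IVW estimate after removing the flagged
#' outliers with changes from removing 1000 random subsets of the same size.
#'
#' @param set a `harmonized_set` with at least 4 instruments.
#' @param n_sim number of simulated datasets (>= 100; default 1000).
#' @param seed RNG seed (default 1).
#' @param outlier_threshold adjusted per-SNP p cut for flagging (default
#'   0.10).
#' @param weighted if `TRUE` (default) residuals enter RSS weighted by
#'   1/se_Yj^2; `FALSE` gives the unweighted variant.
#' @return list of class `presso_result`: `rss_obs`, `global_pval`,
#'   `per_snp` (data frame of rsid, residual, raw and adjusted p),
#'   `outliers`, `distortion_pval`, `estimate_raw`,
#'   `estimate_outlier_corrected` (NULL when nothing is flagged).
#' @export
mr_presso <- function(set, n_sim = 1000L, seed = 1L, outlier_threshold = 0.10,
                      weighted = TRUE) {
  J <- nrow(set)
  if (J < 4L)
    stop_mr("MR-PRESSO requires at least 4 instruments (leave-one-out IVW needs >= 3 remaining)",
            "mr_insufficient_instruments")
  if (n_sim < 100L)
    stop_mr("n_sim must be at least 100", "mr_domain_error")
  x <- set$beta_exp; y <- set$beta_out
  sx <- set$se_exp; sy <- set$se_out
  w <- 1 / sy^2
  rw <- if (weighted) w else rep(1, J)

  th_loo <- loo_slopes(x, y, w)
  resid_obs <- y - th_loo * x
  rss_obs <- sum(rw * resid_obs^2)

  sim <- withr::with_seed(seed, {
    xs <- matrix(stats::rnorm(n_sim * J, x, sx), nrow = n_sim, byrow = TRUE)
    mu_y <- th_loo * x
    ys <- matrix(stats::rnorm(n_sim * J, mu_y, sy), nrow = n_sim, byrow = TRUE)
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    wxy <- wm * xs * ys
    wxx <- wm * xs^2
    th_star <- (rowSums(wxy) - wxy) / (rowSums(wxx) - wxx)
    rs <- ys - th_star * xs
    rss_star <- as.vector(rs^2 %*% rw)
    list(rss = rss_star, resid2 = rs^2)
  })
  if (stats::sd(sim$rss) == 0)
    stop_mr("simulated RSS distribution has zero variance", "mr_numerical_error")

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(sim$resid2 >= matrix(resid_obs^2, n_sim, J,
                                             byrow = TRUE))) / (n_sim + 1)
  p_adj <- pmin(1, J * p_raw)
  outliers <- set$rsid[p_adj < outlier_threshold]

  est_raw <- mr_ivw(set)$estimate
  est_corr <- NULL
  distortion_pval <- NA_real_
  if (length(outliers) > 0 && J - length(outliers) >= 2L) {
    reduced <- set[!(set$rsid %in% outliers), , drop = FALSE]
    est_corr <- mr_ivw(new_harmonized_set(
      reduced, exposure_scale = attr(set, "exposure_scale") %||% 1))$estimate
    d_obs <- est_corr$beta - est_raw$beta
    k <- length(outliers)
    if (J - k >= 2L) {
      r <- wald_ratios(set)
      d_null <- withr::with_seed(seed + 1L, {
        vapply(seq_len(1000L), function(i) {
          drop_idx <- sample.int(J, k)
          fit <- ivw_fit(r$theta[-drop_idx], r$se[-drop_idx], "auto")
          fit$beta - est_raw$beta
        }, numeric(1))
      })
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / 1001
    }
  }

  structure(list(
    rss_obs = rss_obs,
    global_pval = global_pval,
    per_snp = data.frame(rsid = set$rsid, residual = resid_obs,
                         pval = p_raw, pval_adj = p_adj,
                         stringsAsFactors = FALSE),
    outliers = outliers,
    distortion_pval = distortion_pval,
    estimate_raw = est_raw,
    estimate_outlier_corrected = est_corr,
    n_sim = n_sim, seed = seed
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat("Outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else cat("No outliers flagged.\n")
  invisible(x)
}
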