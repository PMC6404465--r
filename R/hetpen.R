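# Heterogeneity-penalized model averaging over instrument subsets.

#' Heterogeneity-penalized model averaging (HetPen)
#'
#' Consistent causal estimation when only a plurality of instruments is
#' valid. Every subset S of instruments with |S| >= 2 contributes its
#' fixed-effect IVW estimate theta_S with standard error
#' se_S = (sum of within-subset weights)^(-1/2); the subset receives weight
#' proportional to prior_valid^|S| * (1 - prior_valid)^(J - |S|) *
#' exp(-Q_S / 2), where Q_S is Cochran's heterogeneity within S — so
#' internally discordant subsets are penalized away. The model-averaged
#' criterion L(theta) = sum_S weight_S * dnorm(theta; theta_S, se_S) is
#' evaluated on a grid; the mode is its argmax and the confidence set
#' collects grid points with 2 * (log L(mode) - log L(theta)) <= 3.84 (the
#' 95% chi-squared(1) cut), merged into intervals. Because valid and invalid
#' instrument clusters can each support a local mode, the confidence set may
#' be a union of disjoint intervals; it is reported as such, flagged
#' `multimodal`, and never bridged.
#'
#' @param set a `harmonized_set` with 2 to 25 instruments (subset
#'   enumeration is exhaustive, 2^J models).
#' @param prior_valid prior probability that any one instrument is valid
#'   (default 0.5, which makes the prior term constant).
#' @param grid_lo,grid_hi grid limits; default
#'   `min(theta_S) - 6 max(se_S)` to `max(theta_S) + 6 max(se_S)`.
#' @param grid_n number of grid points (default 2001).
#' @param se_order ratio standard-error order, see [wald_ratios()].
#' @return list of class `hetpen_estimate`: `mode`, `ci_set` (data frame of
#'   `lo`/`hi` interval endpoints), `multimodal`, `grid`, `criterion`,
#'   `subset_weights` summary.
#' @export
mr_hetpen <- function(set, prior_valid = 0.5, grid_lo = NULL, grid_hi = NULL,
                      grid_n = 2001L, se_order = "first") {
  J <- nrow(set)
  if (J < 2L)
    stop_mr("HetPen requires at least 2 instruments",
            "mr_insufficient_instruments")
  if (J > 25L)
    stop_mr("HetPen enumerates 2^J subsets; J > 25 is intractable - subsample the instruments",
            "mr_complexity_error")
  assert_scalar_prob(prior_valid, "prior_valid")
  r <- wald_ratios(set, se_order)

  models <- enumerate_subset_models(r$theta, r$weight, prior_valid)
  theta_s <- models$theta_s
  se_s <- models$se_s
  wts <- models$weight_s

  if (is.null(grid_lo)) grid_lo <- min(theta_s) - 6 * max(se_s)
  if (is.null(grid_hi)) grid_hi <- max(theta_s) + 6 * max(se_s)
  if (grid_hi <= grid_lo)
    stop_mr("empty criterion grid: grid_hi <= grid_lo", "mr_config_error")
  grid <- seq(grid_lo, grid_hi, length.out = grid_n)

  # L(theta) = sum_S W_S dnorm(theta; theta_S, se_S): outer over grid x models
  dens <- stats::dnorm(outer(grid, theta_s, "-"),
                       sd = matrix(se_s, length(grid), length(se_s),
                                   byrow = TRUE))
  crit <- as.vector(dens %*% wts)
  imode <- which.max(crit)
  mode <- grid[imode]
  inside <- 2 * (log(crit[imode]) - log(crit)) <= stats::qchisq(0.95, 1)
  ci_set <- runs_to_intervals(grid, inside)

  structure(list(
    mode = mode,
    ci_set = ci_set,
    multimodal = nrow(ci_set) > 1L,
    grid = grid, criterion = crit,
    n_models = length(wts),
    max_weight_subset = models$subsets[[top_subset(wts, models$size)]],
    weights_sum = sum(wts)
  ), class = "hetpen_estimate")
}

# All subsets of size >= 2 with their IVW stats and normalized penalty
# weights. Bit enumeration keeps it dependency-free; used both by the
# estimator and (re-derived independently) by the test oracle.
enumerate_subset_models <- function(theta, weight, prior_valid) {
  J <- length(theta)
  n_sub <- 2L^J - 1L
  subsets <- vector("list", n_sub)
  theta_s <- se_s <- logw <- size <- numeric(n_sub)
  k <- 0L
  for (m in seq_len(n_sub)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(J) - 1L)) != 0L)
    if (length(idx) < 2L) next
    k <- k + 1L
    w <- weight[idx]
    th <- sum(w * theta[idx]) / sum(w)
    q <- sum(w * (theta[idx] - th)^2)
    subsets[[k]] <- idx
    theta_s[k] <- th
    se_s[k] <- 1 / sqrt(sum(w))
    size[k] <- length(idx)
    logw[k] <- length(idx) * log(prior_valid) +
      (J - length(idx)) * log(1 - prior_valid) - q / 2
  }
  subsets <- subsets[seq_len(k)]
  theta_s <- theta_s[seq_len(k)]; se_s <- se_s[seq_len(k)]
  logw <- logw[seq_len(k)]
  wts <- exp(logw - max(logw))
  wts <- wts / sum(wts)
  list(subsets = subsets, theta_s = theta_s, se_s = se_s, weight_s = wts,
       size = size[seq_len(k)])
}

# Maximal-weight model; weight ties (exact with prior 0.5 and zero
# heterogeneity) resolve toward the largest subset.
top_subset <- function(wts, size) {
  tied <- which(wts >= max(wts) * (1 - 1e-9))
  tied[which.max(size[tied])]
}

# Contiguous TRUE runs of `inside` over `grid` as [lo, hi] intervals.
runs_to_intervals <- function(grid, inside) {
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]])
}

#' @export
print.hetpen_estimate <- function(x, ...) {
  ints <- paste(sprintf("[%.3f, %.3f]", x$ci_set$lo, x$ci_set$hi),
                collapse = " U ")
  cat(sprintf("HetPen mode %.3f, 95%% confidence set %s%s\n",
              x$mode, ints, if (x$multimodal) " (multimodal)" else ""))
  invisible(x)
}
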