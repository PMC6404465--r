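# Leave-one-out and named-SNP exclusion reanalysis, multiplicity thresholds,
# and binary-outcome power.

ivw_estimate_only <- function(set, ...) mr_ivw(set, ...)$estimate

#' Leave-one-out reanalysis
#'
#' Re-runs an estimator J times, each time omitting one instrument; the
#' workhorse behind outlier-exclusion reporting.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param estimator a function `(harmonized_set, ...) -> mr_estimate`;
#'   defaults to the IVW estimate.
#' @param ... passed on to `estimator`.
#' @return data frame with one row per omitted SNP: `omitted`, `n_snps`,
#'   `beta`, `se`, `or`, `or_low`, `or_high`, `pval`.
#' @export
mr_leave_one_out <- function(set, estimator = ivw_estimate_only, ...) {
  J <- nrow(set)
  if (J < 3L)
    stop_mr("leave-one-out requires at least 3 instruments",
            "mr_insufficient_instruments")
  scale <- attr(set, "exposure_scale") %||% 1
  rows <- lapply(seq_len(J), function(j) {
    est <- estimator(new_harmonized_set(set[-j, , drop = FALSE],
                                        exposure_scale = scale), ...)
    data.frame(omitted = set$rsid[j], n_snps = est$n_snps, beta = est$beta,
               se = est$se, or = est$or, or_low = est$or_low,
               or_high = est$or_high, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Named-SNP exclusion specification
#'
#' A labelled list of instruments to drop in a sensitivity analysis, with
#' the reason (e.g. pleiotropic association with a confounder or
#' intermediate of the exposure-outcome relationship).
#'
#' @param label short label for the analysis row.
#' @param rsids character vector of rsids to exclude.
#' @param reason free-text rationale.
#' @return list of class `exclusion_spec`.
#' @export
exclusion_spec <- function(label, rsids, reason = "") {
  structure(list(label = label, rsids = as.character(rsids),
                 reason = reason), class = "exclusion_spec")
}

#' Packaged exclusion specifications for the mineral panels
#'
#' The named-SNP sensitivity analyses for the serum mineral instruments:
#' for magnesium, dropping the two SNPs with pleiotropic associations with
#' atrial fibrillation (MUC1 and SHROOM3 loci) and the TRPM6-locus outlier;
#' for calcium, dropping the GCKR SNP, which is pleiotropically associated
#' with blood lipids and type 2 diabetes.
#'
#' @return named list of [exclusion_spec] objects.
#' @export
mineral_exclusions <- function() {
  al <- snp_allowlist()
  rs <- function(genes) al$rsid[al$gene %in% genes]
  list(
    atrial_fibrillation = exclusion_spec(
      "atrial-fibrillation SNPs", rs(c("MUC1", "SHROOM3")),
      "associated with atrial fibrillation, a cause of cardioembolic stroke"),
    trpm6_outlier = exclusion_spec(
      "TRPM6 outlier", rs("TRPM6"),
      "flagged as an outlier by MR-PRESSO for cardioembolic stroke"),
    gckr = exclusion_spec(
      "GCKR", rs("GCKR"),
      "pleiotropic associations with blood lipids and type 2 diabetes")
  )
}

#' Exclude named instruments and re-estimate
#'
#' @param set a `harmonized_set`.
#' @param spec an [exclusion_spec] (or character vector of rsids, which is
#'   wrapped into one).
#' @param estimator a function `(harmonized_set, ...) -> mr_estimate`;
#'   defaults to the IVW estimate.
#' @param ... passed on to `estimator`.
#' @return an [mr_estimate] with attribute `"label"` set from the spec.
#' @export
mr_exclude <- function(set, spec, estimator = ivw_estimate_only, ...) {
  if (is.character(spec)) spec <- exclusion_spec("exclusion", spec)
  unknown <- setdiff(spec$rsids, set$rsid)
  if (length(spec$rsids) > 0 && length(unknown) > 0)
    stop_mr(sprintf("exclusion '%s' names rsid(s) not in the instrument set: %s",
                    spec$label, paste(unknown, collapse = ", ")),
            "mr_config_error")
  keep <- !(set$rsid %in% spec$rsids)
  if (sum(keep) < 2L)
    stop_mr(sprintf("fewer than 2 instruments remain after exclusion '%s'",
                    spec$label), "mr_insufficient_instruments")
  est <- estimator(new_harmonized_set(set[keep, , drop = FALSE],
                                      exposure_scale =
                                        attr(set, "exposure_scale") %||% 1),
                   ...)
  attr(est, "label") <- spec$label
  est
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test threshold `alpha / n_tests`, with attribute
#'   `"display"` giving it rounded to 2 significant figures as reported in
#'   text.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1)
    stop_mr("n_tests must be >= 1", "mr_domain_error")
  assert_scalar_prob(alpha, "alpha")
  thr <- alpha / n_tests
  attr(thr, "display") <- signif(thr, 2)
  thr
}

#' Statistical power for two-sample MR with a binary outcome
#'
#' Analytic power following the noncentrality approximation of Brion-style
#' MR power calculators: with N total outcome-sample individuals, case
#' fraction K, instrument variance explained R2_GX and detectable odds
#' ratio OR, the IVW z-statistic is approximately normal with noncentrality
#' NCP = N * R2_GX * K * (1 - K) * log(OR)^2, giving two-sided power
#' pnorm(-z_(1-alpha/2) + sqrt(NCP)) + pnorm(-z_(1-alpha/2) - sqrt(NCP)).
#'
#' @param n_total total outcome sample size (cases + noncases).
#' @param case_fraction proportion of cases, in (0, 1).
#' @param r2_gx exposure variance explained by the instruments, in (0, 1).
#' @param or_alt odds ratio per exposure SD to detect.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in (0, 1), with attribute `"percent"` giving the value
#'   rounded to the nearest integer percent.
#' @export
mr_power <- function(n_total, case_fraction, r2_gx, or_alt, alpha = 0.05) {
  if (!is.numeric(n_total) || n_total <= 0)
    stop_mr("n_total must be positive", "mr_domain_error")
  assert_scalar_prob(case_fraction, "case_fraction")
  assert_scalar_prob(r2_gx, "r2_gx")
  assert_scalar_prob(alpha, "alpha")
  if (!is.numeric(or_alt) || or_alt <= 0)
    stop_mr("or_alt must be positive", "mr_domain_error")
  ncp <- n_total * r2_gx * case_fraction * (1 - case_fraction) *
    log(or_alt)^2
  z <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(-z + sqrt(ncp)) + stats::pnorm(-z - sqrt(ncp))
  attr(pow, "percent") <- round(100 * pow)
  pow
}
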