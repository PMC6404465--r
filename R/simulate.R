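# Synthetic two-sample summary-statistics generator.

#' Configuration for a simulated two-sample summary-statistics study
#'
#' Defaults mirror the serum-magnesium setting: 6 independent instruments
#' explaining 1.6% of the variance of a standardized exposure, an exposure
#' GWAS of 23,829 individuals, and a binary outcome sample of 34,217 cases
#' and 404,630 noncases.
#'
#' @param n_snps number of instruments J (>= 2).
#' @param theta true causal log odds ratio per exposure SD.
#' @param r2_total total exposure variance explained by the instruments,
#'   in (0, 1); split across SNPs by a seeded Dirichlet draw so instrument
#'   strength is heterogeneous, as in real panels.
#' @param n_exposure exposure GWAS sample size.
#' @param n_cases,n_controls outcome sample sizes.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects
#'   N(0, tau^2)) or `"directional"` (N(mu, tau^2)); direct effects are
#'   drawn independently of instrument strength, so InSIDE holds.
#' @param pleiotropy_sd tau, SD of the per-SNP direct effects.
#' @param pleiotropy_mean mu, mean direct effect under `"directional"`.
#' @param n_outliers number of SNPs given an additional pleiotropic offset.
#' @param outlier_offset offset size in units of the outcome SE.
#' @param seed RNG seed; the same config and seed give a bit-identical
#'   study.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 6L, theta = 0, r2_total = 0.016,
                       n_exposure = 23829L, n_cases = 34217L,
                       n_controls = 404630L,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       n_outliers = 0L, outlier_offset = 0, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_snps < 2L) stop_mr("n_snps must be >= 2", "mr_domain_error")
  assert_scalar_prob(r2_total, "r2_total")
  if (pleiotropy_sd < 0 || outlier_offset < 0)
    stop_mr("pleiotropy_sd and outlier_offset must be >= 0", "mr_domain_error")
  if (n_outliers < 0L || n_outliers > n_snps)
    stop_mr("n_outliers must be in [0, n_snps]", "mr_domain_error")
  structure(list(
    n_snps = as.integer(n_snps), theta = theta, r2_total = r2_total,
    n_exposure = as.numeric(n_exposure), n_cases = as.numeric(n_cases),
    n_controls = as.numeric(n_controls),
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean, n_outliers = as.integer(n_outliers),
    outlier_offset = outlier_offset, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-sample summary-statistics study
#'
#' Generates exposure and outcome per-SNP summary statistics with the
#' structure the estimators assume, directly on the summary level (no
#' individual genotypes). Genotypes are taken as standardized, so SNP j's
#' true per-allele effect is b_j = sqrt(r2_j) where the r2_j are a Dirichlet
#' split of `r2_total`; the exposure beta is observed with standard error
#' se_Xj = 1/sqrt(n_exposure) and the outcome log odds with
#' se_Yj = sqrt((n_cases + n_controls) / (n_cases * n_controls)). The true
#' outcome association is theta * b_j plus the SNP's direct (pleiotropic)
#' effect; planted outliers additionally receive `outlier_offset * se_Yj`.
#' Alleles are assigned at random from non-palindromic pairs with effect
#' allele frequency Uniform(0.05, 0.95), shared between the two samples.
#'
#' @param config a [sim_config].
#' @return list of class `simulated_study` with `exposure` and `outcome`
#'   ([summary_stats] frames) and `truth` (theta, per-SNP true effects and
#'   direct effects, outlier indices).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps
  withr::with_seed(config$seed, {
    r2_split <- stats::rgamma(J, 1)
    r2_j <- config$r2_total * r2_split / sum(r2_split)
    b <- sqrt(r2_j)

    se_x <- rep(1 / sqrt(config$n_exposure), J)
    se_y <- rep(sqrt((config$n_cases + config$n_controls) /
                       (config$n_cases * config$n_controls)), J)

    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, config$pleiotropy_sd),
      directional = stats::rnorm(J, config$pleiotropy_mean,
                                 config$pleiotropy_sd))
    outlier_idx <- if (config$n_outliers > 0)
      sort(sample.int(J, config$n_outliers)) else integer(0)
    offset <- rep(0, J)
    offset[outlier_idx] <- config$outlier_offset * se_y[outlier_idx]

    beta_x <- stats::rnorm(J, b, se_x)
    beta_y <- stats::rnorm(J, config$theta * b + alpha + offset, se_y)

    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), J, replace = TRUE)
    eaf <- stats::runif(J, 0.05, 0.95)
    rsid <- sprintf("rs%d", seq_len(J))

    exposure <- summary_stats(
      rsid, pairs[pick, 1], pairs[pick, 2],
      beta = beta_x, se = se_x, eaf = eaf,
      pval = z_pvalue(beta_x / se_x), n = config$n_exposure)
    outcome <- summary_stats(
      rsid, pairs[pick, 1], pairs[pick, 2],
      beta = beta_y, se = se_y, eaf = eaf,
      pval = z_pvalue(beta_y / se_y),
      n = config$n_cases + config$n_controls)

    structure(list(
      exposure = exposure, outcome = outcome,
      truth = list(theta = config$theta, b = b, r2_j = r2_j, alpha = alpha,
                   outlier_idx = outlier_idx, config = config)
    ), class = "simulated_study")
  })
}

#' Harmonized set directly from a simulated study
#'
#' Simulated exposure/outcome records share alleles and orientation, so this
#' is a convenience that skips re-harmonization (the full [harmonize()] path
#' is exercised separately in the test suite and gives the same set).
#'
#' @param study a `simulated_study`.
#' @return a `harmonized_set`.
#' @export
as_harmonized <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  harmonized_set(
    rsid = study$exposure$rsid,
    beta_exp = study$exposure$beta, se_exp = study$exposure$se,
    beta_out = study$outcome$beta, se_out = study$outcome$se,
    eaf = study$exposure$eaf
  )
}

#' Write a simulated study to disk
#'
#' Writes the exposure and outcome tables as TSV plus the generative truth
#' as JSON, the on-disk layout the `simulate` CLI subcommand produces.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "sim").
#' @return character vector of the three paths written, invisibly.
#' @export
write_study <- function(study, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_exposure.tsv", "_outcome.tsv",
                                           "_truth.json")))
  utils::write.table(study$exposure, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$outcome, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
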