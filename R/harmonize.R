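# Allele harmonization of exposure and outcome summary statistics.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  chars <- strsplit(a, "", fixed = TRUE)
  vapply(chars, function(ch) {
    comp <- ALLELE_COMPLEMENT[ch]
    if (anyNA(comp)) NA_character_ else paste(rev(comp), collapse = "")
  }, character(1))
}

is_palindromic <- function(ea, oa) {
  comp <- complement_allele(ea)
  !is.na(comp) & comp == oa
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two [summary_stats] sets on a common effect-allele orientation so
#' that each SNP's exposure and outcome betas refer to the same allele.
#' Outcome records whose alleles are swapped relative to the exposure have
#' their beta negated and eaf complemented; alleles that match only after
#' strand complement (A-T, C-G) are treated as a strand flip and then
#' aligned. Palindromic SNPs (A/T or C/G), whose strand cannot be resolved
#' from the alleles, are handled according to `palindrome_policy`.
#'
#' @param exposure,outcome [summary_stats] for the same SNPs in two
#'   non-overlapping samples.
#' @param palindrome_policy one of `"freq-infer"` (default: orient by
#'   effect-allele frequency, dropping SNPs whose eaf falls in the ambiguous
#'   window or is missing), `"drop"` (remove all palindromic SNPs), `"keep"`
#'   (take alleles at face value).
#' @param ambiguity_window eaf interval (open) within which frequency-based
#'   orientation is considered unreliable; default `c(0.42, 0.58)`.
#' @return A `harmonized_set`: a data frame with one row per retained SNP
#'   (columns `rsid`, `effect_allele`, `other_allele`, `eaf_exp`, `beta_exp`,
#'   `se_exp`, `pval_exp`, `n_exp`, `eaf_out`, `beta_out`, `se_out`,
#'   `pval_out`, `n_out`), carrying attributes `exposure_scale`
#'   (multiplicative unit factor, initially 1) and `provenance` (a data frame
#'   logging the action taken for every shared rsid: kept / flipped /
#'   strand-aligned / dropped-palindromic / dropped-ambiguous /
#'   dropped-mismatch).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("freq-infer", "drop", "keep"),
                      ambiguity_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$rsid) || anyDuplicated(outcome$rsid))
    stop_mr("duplicate rsids within a summary_stats input; deduplicate first",
            "mr_invariant_error")
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) < 2L)
    stop_mr(sprintf("only %d shared rsid(s); need at least 2 instruments",
                    length(shared)), "mr_insufficient_instruments")

  ex <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  action <- character(length(shared))
  keep <- logical(length(shared))
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      if (palindrome_policy == "drop") {
        action[i] <- "dropped-palindromic"; next
      }
      # face-value alignment first (for a palindromic SNP strand flip and
      # allele swap are indistinguishable, so only same/swapped can occur)
      if (ea_y == ea_x && oa_y == oa_x) {
        swapped <- FALSE
      } else if (ea_y == oa_x && oa_y == ea_x) {
        swapped <- TRUE
      } else {
        action[i] <- "dropped-mismatch"; next
      }
      if (swapped) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
      if (palindrome_policy == "keep") {
        action[i] <- if (swapped) "flipped" else "kept"
        keep[i] <- TRUE; next
      }
      # freq-infer
      f_x <- ex$eaf[i]; f_y <- eaf_out[i]
      if (is.na(f_x) || is.na(f_y)) {
        action[i] <- "dropped-palindromic"; next
      }
      ambiguous <- function(f) f > ambiguity_window[1] & f < ambiguity_window[2]
      if (ambiguous(f_x) || ambiguous(f_y)) {
        action[i] <- "dropped-ambiguous"; next
      }
      if ((f_x - 0.5) * (f_y - 0.5) < 0) {
        # frequencies disagree: outcome record refers to the opposite strand
        beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped-freq"
      } else {
        action[i] <- if (swapped) "flipped" else "kept"
      }
      keep[i] <- TRUE; next
    }

    comp_ea <- complement_allele(ea_y); comp_oa <- complement_allele(oa_y)
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"; keep[i] <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"; keep[i] <- TRUE
    } else if (!is.na(comp_ea) && comp_ea == ea_x && comp_oa == oa_x) {
      action[i] <- "strand-aligned"; keep[i] <- TRUE
    } else if (!is.na(comp_ea) && comp_ea == oa_x && comp_oa == ea_x) {
      beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "strand-flipped"; keep[i] <- TRUE
    } else {
      action[i] <- "dropped-mismatch"
    }
  }

  provenance <- data.frame(rsid = shared, action = action,
                           stringsAsFactors = FALSE)
  idx <- which(keep)
  if (length(idx) < 2L)
    stop_mr(sprintf("only %d instrument(s) survived harmonization; need >= 2",
                    length(idx)), "mr_insufficient_instruments")
  out <- data.frame(
    rsid = shared[idx],
    effect_allele = ex$effect_allele[idx],
    other_allele = ex$other_allele[idx],
    eaf_exp = ex$eaf[idx],
    beta_exp = ex$beta[idx],
    se_exp = ex$se[idx],
    pval_exp = ex$pval[idx],
    n_exp = ex$n[idx],
    eaf_out = eaf_out[idx],
    beta_out = beta_out[idx],
    se_out = ou$se[idx],
    pval_out = ou$pval[idx],
    n_out = ou$n[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  new_harmonized_set(out, exposure_scale = 1, provenance = provenance)
}

new_harmonized_set <- function(df, exposure_scale = 1, provenance = NULL) {
  attr(df, "exposure_scale") <- exposure_scale
  attr(df, "provenance") <- provenance
  class(df) <- c("harmonized_set", "data.frame")
  df
}

#' Construct a harmonized instrument set directly from aligned vectors
#'
#' Convenience constructor for instrument sets that are already on a common
#' effect-allele orientation (e.g. simulated data, or consortium tables that
#' were aligned upstream).
#'
#' @param rsid SNP identifiers (unique).
#' @param beta_exp,se_exp exposure association betas and standard errors.
#' @param beta_out,se_out outcome association betas and standard errors
#'   (log odds for a binary outcome).
#' @param eaf effect-allele frequency (optional).
#' @param exposure_scale multiplicative exposure unit factor.
#' @return a `harmonized_set` data frame.
#' @export
harmonized_set <- function(rsid, beta_exp, se_exp, beta_out, se_out,
                           eaf = NA_real_, exposure_scale = 1) {
  J <- length(rsid)
  if (anyDuplicated(rsid))
    stop_mr("duplicate rsids in harmonized_set", "mr_invariant_error")
  if (any(se_exp <= 0) || any(se_out <= 0))
    stop_mr("standard errors must be > 0", "mr_invariant_error")
  df <- data.frame(
    rsid = as.character(rsid),
    effect_allele = rep("A", J), other_allele = rep("G", J),
    eaf_exp = as.numeric(eaf), beta_exp = as.numeric(beta_exp),
    se_exp = as.numeric(se_exp), pval_exp = NA_real_, n_exp = NA_real_,
    eaf_out = as.numeric(eaf), beta_out = as.numeric(beta_out),
    se_out = as.numeric(se_out), pval_out = NA_real_, n_out = NA_real_,
    stringsAsFactors = FALSE
  )
  new_harmonized_set(df, exposure_scale = exposure_scale,
                     provenance = data.frame(rsid = df$rsid,
                                             action = "kept",
                                             stringsAsFactors = FALSE))
}

#' Rescale the exposure unit of a harmonized set
#'
#' Causal estimates downstream are expressed per one unit of the exposure as
#' encoded in the exposure betas. `rescale_exposure` changes that unit: after
#' `rescale_exposure(set, unit)` the downstream causal log odds ratio is per
#' `unit` of the original exposure scale (e.g. `unit = 0.1` turns a
#' per-mmol/L estimate into a per-0.1-mmol/L estimate). Implemented by
#' dividing the exposure betas and SEs by `unit`, which multiplies every Wald
#' ratio by `unit`; the cumulative factor is recorded in the
#' `exposure_scale` attribute.
#'
#' @param set a `harmonized_set`.
#' @param unit positive unit factor.
#' @return the rescaled `harmonized_set`.
#' @export
rescale_exposure <- function(set, unit) {
  if (!is.numeric(unit) || length(unit) != 1L || !is.finite(unit) || unit <= 0)
    stop_mr("`unit` must be a single positive number", "mr_domain_error")
  set$beta_exp <- set$beta_exp / unit
  set$se_exp <- set$se_exp / unit
  attr(set, "exposure_scale") <- attr(set, "exposure_scale") * unit
  set
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d SNPs (exposure scale factor %g)\n",
              nrow(x), attr(x, "exposure_scale")))
  print(as.data.frame(x), ...)
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    tab <- table(prov$action)
    cat("Harmonization actions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a harmonized set to TSV with its provenance column
#'
#' @param set a `harmonized_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(set, path) {
  prov <- attr(set, "provenance")
  df <- as.data.frame(set)
  df$provenance <- prov$action[match(df$rsid, prov$rsid)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
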