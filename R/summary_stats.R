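#' Per-SNP summary associations
#'
#' A `summary_stats` object is a data frame with one row per SNP holding the
#' association of that SNP with a single trait: alleles, effect-allele
#' frequency, per-allele effect (beta, in trait units for a quantitative
#' exposure or log odds for a binary outcome), its standard error, p-value and
#' sample size. It is the atomic input of every two-sample analysis in this
#' package.
#'
#' @param rsid character vector of SNP identifiers.
#' @param effect_allele,other_allele allele strings (single base or indel);
#'   upper-cased on construction.
#' @param beta numeric per-allele effects.
#' @param se positive standard errors.
#' @param eaf effect-allele frequencies in `[0, 1]`, `NA` permitted.
#' @param pval p-values in `(0, 1]`, `NA` permitted.
#' @param n sample sizes, `NA` permitted.
#' @return A data frame of class `summary_stats`.
#' @export
summary_stats <- function(rsid, effect_allele, other_allele, beta, se,
                          eaf = NA_real_, pval = NA_real_, n = NA_real_) {
  df <- data.frame(
    rsid = as.character(rsid),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  validate_summary_stats(df)
  class(df) <- c("summary_stats", "data.frame")
  df
}

validate_summary_stats <- function(df, source = "summary_stats") {
  bad_se <- which(!is.finite(df$se) | df$se <= 0)
  if (length(bad_se))
    stop_mr(sprintf("%s: se must be finite and > 0 (rows %s)",
                    source, paste(bad_se, collapse = ", ")),
            "mr_invariant_error")
  bad_al <- which(df$effect_allele == df$other_allele)
  if (length(bad_al))
    stop_mr(sprintf("%s: effect and other allele identical (rows %s)",
                    source, paste(bad_al, collapse = ", ")),
            "mr_invariant_error")
  bad_eaf <- which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  if (length(bad_eaf))
    stop_mr(sprintf("%s: eaf outside [0,1] (rows %s)",
                    source, paste(bad_eaf, collapse = ", ")),
            "mr_invariant_error")
  invisible(df)
}

#' Read summary statistics from a delimited text file
#'
#' Reads a TSV/CSV of GWAS summary statistics into a [summary_stats] frame.
#' Column names are resolved through `column_map`, so any header dialect can
#' be accommodated without editing the file.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` means
#'   comma, anything else tab) unless `sep` is given.
#' @param column_map named character vector mapping the canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, and optionally
#'   `eaf`, `pval`, `n`) to the header names in the file. Defaults to the
#'   canonical names themselves.
#' @param sep field separator; overrides the extension heuristic.
#' @param strict if `TRUE` (default) malformed rows (non-numeric beta/se,
#'   nonpositive se, duplicate rsid) are errors naming the offending line;
#'   otherwise such rows are dropped with a warning.
#' @return A [summary_stats] data frame.
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = NULL,
                               strict = TRUE) {
  if (!file.exists(path))
    stop_mr(sprintf("file not found: %s", path), "mr_config_error")
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  canonical <- c("rsid", "effect_allele", "other_allele", "beta", "se",
                 "eaf", "pval", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  required <- canonical[1:5]
  missing_cols <- required[!(map[required] %in% names(raw))]
  if (length(missing_cols))
    stop_mr(sprintf("required column(s) not found in %s: %s (mapped to %s)",
                    path, paste(missing_cols, collapse = ", "),
                    paste(map[missing_cols], collapse = ", ")),
            "mr_config_error")

  get_col <- function(canon, default = NA_character_) {
    if (map[[canon]] %in% names(raw)) raw[[map[[canon]]]] else
      rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    rsid = get_col("rsid"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    pval = num(get_col("pval")),
    n = num(get_col("n")),
    stringsAsFactors = FALSE
  )

  # data rows are offset by the header line when reporting positions
  line_no <- seq_len(nrow(df)) + 1L
  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
    df$effect_allele == df$other_allele
  if (any(bad)) {
    msg <- sprintf("malformed row(s) in %s at line(s) %s (non-numeric beta/se, se <= 0, or identical alleles)",
                   path, paste(line_no[bad], collapse = ", "))
    if (strict) stop_mr(msg, "mr_parse_error")
    warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df$rsid)
  if (any(dup)) {
    msg <- sprintf("duplicate rsid(s) in %s: %s",
                   path, paste(unique(df$rsid[dup]), collapse = ", "))
    if (strict) stop_mr(msg, "mr_parse_error")
    warning(paste(msg, "- keeping first occurrence"), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  validate_summary_stats(df, source = path)
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Instrument allow-list for the serum mineral panels
#'
#' The 13 genome-wide-significant, independent SNPs used as instruments for
#' serum magnesium (6 SNPs, together explaining about 1.6% of variance) and
#' serum calcium (7 SNPs, about 0.9% of variance) in the published mineral
#' GWAS, with their nearest-gene labels. Used to tag and subset panels read
#' from generic summary-statistic files.
#'
#' @param trait optionally restrict to `"magnesium"` or `"calcium"`.
#' @return data frame with columns `rsid`, `gene`, `trait`.
#' @export
snp_allowlist <- function(trait = NULL) {
  al <- data.frame(
    rsid = c("rs4072037", "rs7965584", "rs3925584", "rs448378",
             "rs13146355", "rs11144134",
             "rs1801725", "rs1550532", "rs7481584", "rs1570669",
             "rs7336933", "rs780094", "rs10491003"),
    gene = c("MUC1", "ATP2B1", "DCDC5", "MDS1", "SHROOM3", "TRPM6",
             "CASR", "DGKD", "CARS", "CYP24A1", "DGKH", "GCKR", "GATA3"),
    trait = rep(c("magnesium", "calcium"), c(6L, 7L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(trait)) {
    trait <- match.arg(trait, c("magnesium", "calcium"))
    al <- al[al$trait == trait, , drop = FALSE]
    rownames(al) <- NULL
  }
  al
}
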