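# Internal helpers shared across estimators.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mr <- function(msg, class) {
  stop(structure(
    class = c(class, "mr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_prob <- function(x, name, open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > 0 else x >= 0) && (if (open_hi) x < 1 else x <= 1)
  if (!ok) stop_mr(sprintf("`%s` must be a probability in %s0,1%s, got %s",
                           name, if (open_lo) "(" else "[",
                           if (open_hi) ")" else "]",
                           paste(format(x), collapse = ",")),
                   "mr_domain_error")
  invisible(x)
}

# Two-sided p from a z statistic, normal approximation.
z_pvalue <- function(z) 2 * stats::pnorm(-abs(z))
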