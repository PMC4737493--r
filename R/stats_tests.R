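## Significance tests used throughout the pipeline. Thin wrappers over
## stats::t.test with the degenerate zero-variance convention: when both
## samples are constant, p = 1 if the means are equal, otherwise an error.

zero_var <- function(x) stats::var(x) < .Machine$double.eps

t_wrap <- function(expr, a, b = NULL, mu = NULL) {
  degenerate <- function() {
    const_a <- zero_var(a)
    const_b <- if (is.null(b)) TRUE else zero_var(b)
    if (const_a && const_b) {
      ref <- if (is.null(b)) mu else mean(b)
      if (isTRUE(all.equal(mean(a), ref)))
        return(list(t = 0, p = 1, df = NA_real_))
    }
    stop("degenerate t-test: zero variance with unequal means", call. = FALSE)
  }
  res <- tryCatch(expr(), error = function(e) NULL)
  if (is.null(res)) return(degenerate())
  out <- list(t = unname(res$statistic), p = unname(res$p.value),
              df = unname(res$parameter))
  if (!is.finite(out$p)) return(degenerate())
  out
}

#' Two-sided Student's t-test (equal variances)
#' @param sample_a,sample_b Numeric vectors (>= 2 values each).
#' @return List `t`, `p`, `df`.
#' @export
t_test_two_sided <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  t_wrap(function() stats::t.test(sample_a, sample_b, var.equal = TRUE),
         sample_a, sample_b)
}

#' Welch two-sample t-test
#' @inheritParams t_test_two_sided
#' @return List `t`, `p`, `df` (Welch-Satterthwaite degrees of freedom).
#' @export
welch_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  t_wrap(function() stats::t.test(sample_a, sample_b, var.equal = FALSE),
         sample_a, sample_b)
}

#' One-sample t-test against a reference value
#' @param sample Numeric vector (>= 2 values).
#' @param mu0 Reference mean (default 0).
#' @return List `t`, `p`, `df`.
#' @export
one_sample_t <- function(sample, mu0 = 0) {
  stopifnot(length(sample) >= 2)
  t_wrap(function() stats::t.test(sample, mu = mu0), sample, mu = mu0)
}
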