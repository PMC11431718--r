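# Gene-level classification performance: sensitivity, specificity,
# accuracy at a fixed significance threshold.

#' Classification performance of gene-level calls
#'
#' A gene is called positive when its p-value is strictly below
#' `threshold`. Sensitivity is the fraction of truly associated genes
#' called; specificity the fraction of non-associated genes not called;
#' accuracy the fraction of all genes classified correctly — equivalently
#' the prevalence-weighted combination of sensitivity and specificity.
#'
#' @param pvals_pos P-values of the truly associated genes.
#' @param pvals_neg P-values of the non-associated genes.
#' @param threshold Significance threshold in `(0, 1)` (default 2.5e-6,
#'   the conventional gene-level cut-off).
#' @return An object of class `"perf_metrics"`: counts `n_pos_called`,
#'   `n_pos_total`, `n_neg_called`, `n_neg_total` and metrics
#'   `sensitivity`, `specificity`, `accuracy` (each `NA` when its
#'   denominator is empty). Values are unrounded; see [format.perf_metrics]
#'   for two-decimal presentation.
#' @export
#' @examples
#' # 12 of 15 causal genes called, 5 of 54 non-causal genes called:
#' performance_from_counts(12, 15, 5, 54)
performance <- function(pvals_pos, pvals_neg, threshold = 2.5e-6) {
  stopifnot(threshold > 0, threshold < 1)
  if (length(pvals_pos) == 0L && length(pvals_neg) == 0L) {
    stop("both gene sets are empty")
  }
  performance_from_counts(sum(pvals_pos < threshold), length(pvals_pos),
                          sum(pvals_neg < threshold), length(pvals_neg))
}

#' @rdname performance
#' @param n_pos_called,n_pos_total Associated genes called / total.
#' @param n_neg_called,n_neg_total Non-associated genes called / total.
#' @export
performance_from_counts <- function(n_pos_called, n_pos_total,
                                    n_neg_called, n_neg_total) {
  stopifnot(n_pos_called <= n_pos_total, n_neg_called <= n_neg_total,
            n_pos_called >= 0, n_neg_called >= 0)
  sens <- if (n_pos_total > 0) n_pos_called / n_pos_total else NA_real_
  spec <- if (n_neg_total > 0) (n_neg_total - n_neg_called) / n_neg_total
          else NA_real_
  total <- n_pos_total + n_neg_total
  acc <- if (total > 0) {
    (n_pos_called + n_neg_total - n_neg_called) / total
  } else NA_real_
  structure(list(n_pos_called = n_pos_called, n_pos_total = n_pos_total,
                 n_neg_called = n_neg_called, n_neg_total = n_neg_total,
                 sensitivity = sens, specificity = spec, accuracy = acc),
            class = "perf_metrics")
}

# Half-up rounding for presentation (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
format.perf_metrics <- function(x, digits = 2, ...) {
  fmt <- function(v) {
    if (is.na(v)) "NA" else sprintf("%.*f", digits, round_half_up(v, digits))
  }
  sprintf("sensitivity %s (%d/%d), specificity %s (%d/%d), accuracy %s",
          fmt(x$sensitivity), x$n_pos_called, x$n_pos_total,
          fmt(x$specificity), x$n_neg_total - x$n_neg_called, x$n_neg_total,
          fmt(x$accuracy))
}

#' @export
print.perf_metrics <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
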