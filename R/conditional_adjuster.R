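# Conditional adjustment of the intragenic covariance: the regional
# polygenic background inflates Cov(z_g) from U_g to tau*U_gr*t(U_gr) + U_g.

#' Adjust the intragenic covariance for the regional polygenic background
#'
#' Computes `sigma = tau * U_gr %*% t(U_gr) + U_g`, the covariance of the
#' intragenic z statistics conditionally independent of the regional
#' background, used in place of `U_g` in secondary gene-based analysis.
#' The conditional mean stays zero: the observed z_g vector is passed to
#' the tests unchanged; only the null covariance is corrected.
#'
#' `sigma` is deliberately not re-standardized to a correlation matrix:
#' the tests consume the covariance (diagonal >= 1), and rescaling would
#' cancel the correction for single-SNP genes and break the kernel-test
#' p-value monotonicity guarantee.
#'
#' @param part A [partition_region] result, or a plain list with `U_g`,
#'   `U_gr` (and optionally `degenerate`).
#' @param tau Nonnegative scalar, typically `estimate_tau(...)$tau_hat`.
#' @return An object of class `"adjusted_gene_cov"`: list with the
#'   symmetric matrix `sigma`, `tau_used`, and `m_g`. For a degenerate
#'   partition (empty region) `sigma = U_g` and `tau_used = 0`.
#' @export
#' @examples
#' part <- list(U_g = diag(1), U_gr = matrix(c(0.6, 0.2), 1, 2))
#' adjust_gene_cov(part, tau = 2)$sigma  # 1 + 2 * (0.36 + 0.04) = 1.8
adjust_gene_cov <- function(part, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("'tau' must be a single nonnegative number")
  }
  U_g <- part$U_g
  stopifnot(is.matrix(U_g), nrow(U_g) == ncol(U_g))
  degenerate <- isTRUE(part$degenerate) || is.null(part$U_gr) ||
    ncol(part$U_gr) == 0L
  if (degenerate) {
    return(structure(list(sigma = U_g, tau_used = 0, m_g = nrow(U_g)),
                     class = "adjusted_gene_cov"))
  }
  U_gr <- part$U_gr
  if (nrow(U_gr) != nrow(U_g)) {
    stop("U_gr must be m_g x m_r (rows = intragenic SNPs)")
  }
  sigma <- tau * tcrossprod(U_gr) + U_g
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- dimnames(U_g)
  structure(list(sigma = sigma, tau_used = tau, m_g = nrow(U_g)),
            class = "adjusted_gene_cov")
}

#' @export
print.adjusted_gene_cov <- function(x, ...) {
  cat(sprintf("Adjusted intragenic covariance: %d x %d, tau = %.4g, max diag = %.4g\n",
              x$m_g, x$m_g, x$tau_used, max(diag(x$sigma))))
  invisible(x)
}
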