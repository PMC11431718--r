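# Gene-based association tests on a z vector and a covariance matrix.
#
# Every test consumes the marginal intragenic z statistics z_g together
# with a null covariance Sigma — the raw LD matrix U_g for the initial
# analysis, or the background-adjusted tau*U_gr*t(U_gr) + U_g for the
# conditional analysis. Weights default to 1: the z statistics are already
# standardized; MAF-based weighting is exposed but not the default.

gba_result <- function(test, statistic, p, log10p, meta = list()) {
  structure(list(test = test, statistic = statistic,
                 p = p, log10p = log10p, meta = meta),
            class = "gba_result")
}

#' @export
print.gba_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (log10p = %.3f)\n",
              x$test, x$statistic, x$p, x$log10p))
  invisible(x)
}

check_gba_input <- function(z, Sigma, w) {
  stopifnot(is.numeric(z), is.matrix(Sigma),
            nrow(Sigma) == ncol(Sigma), length(z) == nrow(Sigma))
  if (is.null(w)) w <- rep(1, length(z))
  if (length(w) != length(z) || any(w <= 0)) {
    stop("weights must be positive, one per SNP")
  }
  w
}

# Eigenvalues of the null mixture for a kernel K: eig(K^{1/2} Sigma K^{1/2}),
# equivalently the (real) spectrum of K %*% Sigma. Small negative values
# from floating error are clipped with a warning threshold of -1e-8.
mixture_lambdas <- function(Sigma, Ksqrt) {
  A <- Ksqrt %*% Sigma %*% t(Ksqrt)
  lam <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8) {
    warning(sprintf("covariance not PSD (min mixture eigenvalue %.3g); clipping",
                    min(lam)))
  }
  pmax(lam, 0)
}

#' Burden test from summary statistics
#'
#' Collapses the weighted z statistics into one signed score:
#' `T = (w'z)^2 / (w' Sigma w)`, distributed chi-square(1) under the null.
#'
#' @param z Numeric vector of intragenic z statistics.
#' @param Sigma Null covariance matrix of `z` (LD matrix or adjusted
#'   covariance).
#' @param w Positive per-SNP weights (default all 1).
#' @return A `"gba_result"` with the statistic, `p` and underflow-safe
#'   `log10p`.
#' @export
burden_test <- function(z, Sigma, w = NULL) {
  w <- check_gba_input(z, Sigma, w)
  denom <- drop(crossprod(w, Sigma %*% w))
  if (denom <= 0) stop("w' Sigma w must be positive")
  T_stat <- drop(crossprod(w, z))^2 / denom
  logp <- stats::pchisq(T_stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  gba_result("burden", T_stat, p = max(exp(logp), 1e-300),
             log10p = logp / log(10), meta = list(df = 1))
}

#' SKAT-type variance-component test from summary statistics
#'
#' Score statistic `Q = sum_i w_i^2 z_i^2`; under the null `Q` follows the
#' chi-square mixture with weights equal to the eigenvalues of
#' `W Sigma W`, `W = diag(w)`, evaluated by [quadform_pvalue].
#'
#' @inheritParams burden_test
#' @return A `"gba_result"`; `meta` records the number of mixture
#'   eigenvalues and the p-value method used.
#' @export
skat_test <- function(z, Sigma, w = NULL) {
  w <- check_gba_input(z, Sigma, w)
  Q <- sum((w * z)^2)
  lam <- mixture_lambdas(Sigma, diag(w, nrow = length(w)))
  pv <- quadform_pvalue(Q, lam)
  gba_result("skat", Q, p = pv$p, log10p = pv$log10p,
             meta = list(n_lambda = sum(lam > 0), method = pv$method))
}

#' SKAT-O: optimal combination of the burden and SKAT kernels
#'
#' For each `rho` in `rho_grid` the kernel `K_rho = (1 - rho) W^2 +
#' rho w w'` yields `Q_rho = z' K_rho z` with a chi-square-mixture null
#' from the eigenvalues of `K_rho^{1/2} Sigma K_rho^{1/2}`; the per-rho
#' p-values are combined into one by the Cauchy combination
#' ([acat_combine]) with equal weights. `rho = 0` is SKAT, `rho = 1` is
#' the burden test.
#'
#' @inheritParams burden_test
#' @param rho_grid Grid of kernel mixing proportions in `[0, 1]`; the
#'   default follows the usual SKAT-O grid.
#' @return A `"gba_result"`; `meta` records the grid, per-rho p-values and
#'   the rho attaining the smallest one.
#' @export
skato_test <- function(z, Sigma, w = NULL,
                       rho_grid = c(0, (1:5 / 10)^2, 0.5, 1)) {
  w <- check_gba_input(z, Sigma, w)
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 1))
  m <- length(z)
  W2 <- diag(w^2, nrow = m)
  p_rho <- vapply(rho_grid, function(rho) {
    K <- (1 - rho) * W2 + rho * tcrossprod(w)
    Q <- drop(crossprod(z, K %*% z))
    ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
    pos <- ek$values > 1e-12 * max(ek$values)
    Ksqrt <- ek$vectors[, pos, drop = FALSE] %*%
      (sqrt(ek$values[pos]) * t(ek$vectors[, pos, drop = FALSE]))
    lam <- mixture_lambdas(Sigma, Ksqrt)
    quadform_pvalue(Q, lam)$p
  }, numeric(1))
  if (length(rho_grid) == 1L) {
    p_comb <- p_rho
  } else {
    p_comb <- acat_combine(p_rho)
  }
  Q_burden <- drop(crossprod(w, z))^2
  gba_result("skat-o", Q_burden,
             p = p_comb, log10p = log10(max(p_comb, 1e-300)),
             meta = list(rho_grid = rho_grid, p_per_rho = p_rho,
                         rho_min = rho_grid[which.min(p_rho)]))
}

#' Principal-component chi-square test from summary statistics
#'
#' Eigendecomposes `Sigma`, retains the smallest leading set of components
#' reaching `var_fraction` of the trace, and tests
#' `T = sum_k (v_k' z)^2 / lambda_k ~ chi-square(k)` under the null.
#' Unlike the kernel tests, the retained subspace changes with the
#' covariance, so conditional adjustment carries no p-value monotonicity
#' guarantee for this test.
#'
#' @inheritParams burden_test
#' @param var_fraction Fraction of total variance to retain, in `(0, 1]`
#'   (default 0.85).
#' @return A `"gba_result"`; `meta` records the retained component count.
#' @export
pca_test <- function(z, Sigma, var_fraction = 0.85) {
  stopifnot(var_fraction > 0, var_fraction <= 1)
  check_gba_input(z, Sigma, NULL)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  lam <- e$values
  if (max(lam) <= 1e-10) stop("covariance has no eigenvalue above 1e-10")
  k <- which(cumsum(lam) >= var_fraction * sum(pmax(lam, 0)))[1L]
  k <- min(k, sum(lam > 1e-10))
  k <- max(k, 1L)
  proj <- drop(crossprod(e$vectors[, seq_len(k), drop = FALSE], z))
  T_stat <- sum(proj^2 / lam[seq_len(k)])
  logp <- stats::pchisq(T_stat, df = k, lower.tail = FALSE, log.p = TRUE)
  gba_result("pca", T_stat, p = max(exp(logp), 1e-300),
             log10p = logp / log(10), meta = list(df = k))
}

#' Cauchy combination (ACAT) of p-values
#'
#' Transforms each p-value to a standard Cauchy quantile, averages with
#' the given weights, and maps back:
#' `T = sum_j w_j tan((0.5 - p_j) pi) / sum_j w_j`,
#' `p = 0.5 - atan(T) / pi`. Valid under arbitrary dependence of the
#' component tests. Inputs are clipped to `[1e-300, 1 - 1e-16]`.
#'
#' @param pvals Numeric vector of p-values in `(0, 1)`.
#' @param weights Nonnegative weights (default equal).
#' @return The combined p-value (scalar).
#' @export
#' @examples
#' acat_combine(c(0.01, 0.5))  # ~0.0198
acat_combine <- function(pvals, weights = NULL) {
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (is.null(weights)) weights <- rep(1, length(pvals))
  stopifnot(length(weights) == length(pvals), all(weights >= 0),
            sum(weights) > 0)
  p <- pmin(pmax(pvals, 1e-300), 1 - 1e-16)
  # tan((0.5 - p) * pi) overflows harmlessly to the Cauchy tail for tiny p;
  # use the 1/(p*pi) tail expansion there for accuracy.
  t_j <- ifelse(p < 1e-15, 1 / (p * pi), tan((0.5 - p) * pi))
  T_acat <- sum(weights * t_j) / sum(weights)
  if (T_acat > 1e15) return(1 / (T_acat * pi))
  0.5 - atan(T_acat) / pi
}

#' Run a set of gene-based tests on one gene
#'
#' Convenience wrapper running any subset of the tests on the same z
#' vector and covariance, optionally adding the ACAT-O Cauchy combination
#' of their p-values.
#'
#' @inheritParams burden_test
#' @param tests Character subset of `c("burden", "skat", "skat-o", "pca")`.
#' @param acat Add an `"acat-o"` row combining the computed p-values.
#' @param var_fraction,rho_grid Passed to [pca_test] and [skato_test].
#' @return A data.frame with columns `test`, `statistic`, `p`, `log10p`.
#' @export
gba_all <- function(z, Sigma, tests = c("burden", "skat", "skat-o", "pca"),
                    w = NULL, acat = FALSE, var_fraction = 0.85,
                    rho_grid = c(0, (1:5 / 10)^2, 0.5, 1)) {
  tests <- match.arg(tests, several.ok = TRUE)
  res <- lapply(tests, function(tst) {
    switch(tst,
           "burden" = burden_test(z, Sigma, w),
           "skat" = skat_test(z, Sigma, w),
           "skat-o" = skato_test(z, Sigma, w, rho_grid = rho_grid),
           "pca" = pca_test(z, Sigma, var_fraction = var_fraction))
  })
  out <- data.frame(test = vapply(res, `[[`, "", "test"),
                    statistic = vapply(res, `[[`, 0, "statistic"),
                    p = vapply(res, `[[`, 0, "p"),
                    log10p = vapply(res, `[[`, 0, "log10p"),
                    stringsAsFactors = FALSE)
  if (acat) {
    p_comb <- acat_combine(out$p)
    out <- rbind(out, data.frame(test = "acat-o", statistic = NA_real_,
                                 p = p_comb,
                                 log10p = log10(max(p_comb, 1e-300))))
  }
  out
}
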