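# P-values for quadratic forms in standard normal variables:
# P(sum_i lambda_i * chisq_1 > q).
#
# Three engines, tried in order of exactness for the regime at hand:
#  - Ruben's series (a mixture of central chi-square survival functions
#    with nonnegative weights and a computable truncation bound) — exact,
#    used for small mixture sizes where it converges quickly;
#  - Imhof's inversion integral — exact, fast when the mixture has many
#    components, but its oscillating integrand has an absolute error
#    floor that makes small p-values unreliable;
#  - Liu-Tang-Zhang moment matching — approximate, underflow-safe on the
#    log scale, used deep in the tail and as the fallback of last resort.

# Ruben (1962) / Farebrother (1984): with 0 < beta <= min(lambda),
# P(Q <= q) = sum_k a_k * P(chisq_{r+2k} <= q/beta), a_k >= 0, sum a_k = 1.
# The survival form sum_k a_k * S_{r+2k}(q/beta) has truncation error
# bounded by the missing mixture mass 1 - sum_{k<=K} a_k.
ruben_pvalue <- function(q, lambdas, n_max = 16384L, rel_err = 1e-7) {
  r <- length(lambdas)
  beta <- min(lambdas)
  la0 <- 0.5 * sum(log(beta / lambdas))
  if (la0 < -600) return(NULL)          # series weights would overflow
  u <- 1 - beta / lambdas               # in [0, 1)
  u_max <- max(u)
  if (u_max <= 0) {                     # all weights equal: plain chi-square
    p <- stats::pchisq(q / beta, df = r, lower.tail = FALSE)
    return(list(p = p, err = 0))
  }
  # the mass deficit decays like u_max^N: size the series upfront and
  # bail out when it cannot converge within the term cap
  n <- ceiling(log(rel_err * 1e-12) / log(u_max))
  n <- max(n, 64)
  if (n > n_max) return(NULL)
  b <- colSums(exp(log(u) %o% seq_len(n)))
  cc <- .Call(ruben_coef_c, b, as.integer(n))
  a <- exp(la0) * cc
  surv <- stats::pchisq(q / beta, df = r + 2 * (0:n), lower.tail = FALSE)
  p_part <- cumsum(a * surv)
  deficit <- 1 - cumsum(a)
  # the discarded terms contribute at most the missing mixture mass
  ok <- which(deficit <= rel_err * pmax(p_part, 1e-320))
  if (length(ok) == 0L || !is.finite(p_part[n + 1L])) return(NULL)
  k <- ok[1L]
  list(p = min(max(p_part[k], 0), 1), err = deficit[k])
}

# Imhof (1961) inversion:
# P(Q > q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du
imhof_pvalue <- function(q, lambdas) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambdas^2, u^2))))
    sin(theta) / (u * rho)
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     subdivisions = 5000L, rel.tol = 1e-7, abs.tol = 1e-11),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  p <- 0.5 + res$value / pi
  if (!is.finite(p)) return(NULL)
  list(p = p, abs.error = res$abs.error / pi)
}

# Liu, Tang & Zhang (2009) moment matching: approximate the mixture by a
# (noncentral) chi-square matched on skewness/kurtosis. Returns the p-value
# and a log10 p-value that stays finite far below double underflow.
liu_pvalue <- function(q, lambdas) {
  c1 <- sum(lambdas)
  c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3)
  c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- a^2  # = 1/s1^2
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  x <- t_star * sqrt(2 * df + 4 * delta) + df + delta
  x <- max(x, 0)
  logp <- stats::pchisq(x, df = df, ncp = delta, lower.tail = FALSE,
                        log.p = TRUE)
  if (!is.finite(logp)) {
    # the noncentral tail loses accuracy far out; fall back to the
    # central match on mean/variance/skewness (delta = 0)
    df0 <- 1 / s1^2
    x0 <- t_star * sqrt(2 * df0) + df0
    logp <- stats::pchisq(max(x0, 0), df = df0, lower.tail = FALSE,
                          log.p = TRUE)
  }
  list(p = exp(logp), log10p = logp / log(10))
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_i lambda_i * X_i > q)` with independent `X_i ~
#' chisq(1)`, the null distribution of the variance-component score
#' statistics used by the kernel gene-based tests. Exact methods (Ruben's
#' mixture series for small mixtures, Imhof's inversion integral
#' otherwise) are evaluated first; the Liu-Tang-Zhang moment-matching
#' approximation takes over when the exact methods fail to converge or
#' cannot resolve the p-value against their own numerical error, and
#' always supplies the underflow-safe `log10p`. Fully deterministic.
#'
#' @param q Nonnegative observed statistic.
#' @param lambdas Nonnegative mixture weights; zeros are dropped.
#' @return List with `p` (in `(0, 1]`), `log10p`, and `method`
#'   (`"ruben"`, `"imhof"` or `"liu"`).
#' @export
#' @examples
#' quadform_pvalue(3.841459, 1)$p        # ~0.05 (chi-square(1))
#' quadform_pvalue(3, c(1, 1, 1))$p      # ~0.3916 (chi-square(3))
quadform_pvalue <- function(q, lambdas) {
  stopifnot(q >= 0, all(lambdas >= -1e-12))
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) stop("all mixture weights are zero")
  if (q == 0) return(list(p = 1, log10p = 0, method = "exact-zero"))
  if (length(lambdas) == 1L) {
    logp <- stats::pchisq(q / lambdas, df = 1, lower.tail = FALSE, log.p = TRUE)
    return(list(p = max(exp(logp), 1e-300), log10p = logp / log(10),
                method = "chisq1"))
  }
  liu <- liu_pvalue(q, lambdas)
  # deep tail: neither exact engine resolves p this small at tolerable
  # cost; the log-scale moment match is the only underflow-safe route
  if (liu$p < 1e-12) {
    return(list(p = max(liu$p, 1e-300), log10p = liu$log10p, method = "liu"))
  }
  if (length(lambdas) <= 20L) {
    rb <- ruben_pvalue(q, lambdas)
    if (!is.null(rb) && rb$p > 0) {
      return(list(p = rb$p, log10p = log10(rb$p), method = "ruben"))
    }
  }
  # when the series engine cannot handle the spectrum, the inversion
  # integral is only worth its cost where it can actually be accepted
  # (p clearly above its error floor); otherwise report the moment match
  if (liu$p < 1e-5) {
    return(list(p = max(liu$p, 1e-300), log10p = liu$log10p, method = "liu"))
  }
  im <- imhof_pvalue(q, lambdas)
  # the oscillatory integral has an absolute error floor, so small p-values
  # must clear their own numerical-error estimate by a wide margin
  if (!is.null(im) && im$p <= 1 &&
      im$p > max(1e-10, 100 * im$abs.error)) {
    p <- min(im$p, 1)
    return(list(p = p, log10p = log10(p), method = "imhof"))
  }
  list(p = max(liu$p, 1e-300), log10p = liu$log10p, method = "liu")
}
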