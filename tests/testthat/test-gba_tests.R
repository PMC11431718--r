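test_that("quadform_pvalue matches chi-square closed forms", {
  expect_equal(quadform_pvalue(3.841459, 1)$p, 0.05, tolerance = 1e-4)
  expect_equal(quadform_pvalue(3, c(1, 1, 1))$p,
               pchisq(3, 3, lower.tail = FALSE), tolerance = 1e-8)
  # scaled chi-square: P(2 chi2_1 > q) = P(chi2_1 > q/2)
  expect_equal(quadform_pvalue(5, 2)$p, pchisq(2.5, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(quadform_pvalue(0, c(1, 2))$p, 1)
  expect_error(quadform_pvalue(1, c(0, 0)), "zero")
})

test_that("quadform_pvalue matches a Monte-Carlo oracle for mixed weights", {
  set.seed(31)
  lam <- c(2, 0.5)
  q <- 4
  draws <- colSums(lam * matrix(rchisq(2 * 1e6, df = 1), 2))
  mc <- mean(draws > q)
  mc_se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(quadform_pvalue(q, lam)$p - mc), 3 * mc_se)
})

test_that("quadform tail p-values are finite, monotone, and underflow-safe", {
  lam <- c(1.5, 1, 0.5, 0.25)
  qs <- c(10, 50, 200, 1000, 5000)
  res <- lapply(qs, quadform_pvalue, lambdas = lam)
  l10 <- vapply(res, `[[`, 0, "log10p")
  expect_true(all(is.finite(l10)))
  expect_true(all(diff(l10) < 0))
  expect_true(all(vapply(res, `[[`, 0, "p") > 0))
  # deep tail must not fail and must report via log10p
  deep <- quadform_pvalue(5000, lam)
  expect_lt(deep$log10p, -300)
  expect_equal(deep$method, "liu")
  # moderate p-values come from an exact engine, not the moment match
  mid <- quadform_pvalue(20, lam)
  expect_true(mid$method %in% c("ruben", "imhof"))
})

test_that("burden test follows the chi-square(1) form", {
  # Sigma = I3, w = 1, z = (1,1,1): T = 9/3 = 3
  r <- burden_test(c(1, 1, 1), diag(3))
  expect_equal(r$statistic, 3)
  expect_equal(r$p, pchisq(3, 1, lower.tail = FALSE), tolerance = 1e-10)
  # null point
  expect_equal(burden_test(rep(0, 4), diag(4))$p, 1)
  # inflating the denominator can only raise the p-value
  set.seed(32)
  for (i in 1:10) {
    Sigma <- random_corr(5)
    z <- rnorm(5)
    cvec <- rnorm(5)
    p1 <- burden_test(z, Sigma)$p
    p2 <- burden_test(z, Sigma + tcrossprod(cvec))$p
    expect_gte(p2, p1)
  }
})

test_that("skat test: mixture null, one-SNP equivalence with burden", {
  r <- skat_test(c(1, 1, 1), diag(3))
  expect_equal(r$statistic, 3)
  expect_equal(r$p, pchisq(3, 3, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(skat_test(rep(0, 3), diag(3))$p, 1)
  # m_g = 1: SKAT equals burden exactly
  set.seed(33)
  for (i in 1:5) {
    z1 <- rnorm(1, sd = 2)
    S1 <- matrix(runif(1, 0.5, 2))
    expect_equal(skat_test(z1, S1)$p, burden_test(z1, S1)$p)
  }
})

test_that("skat-o degenerates to burden at rho=1 and skat at rho=0", {
  set.seed(34)
  for (i in 1:10) {
    m <- sample(2:8, 1)
    Sigma <- random_corr(m)
    z <- rnorm(m, sd = 1.5)
    expect_equal(skato_test(z, Sigma, rho_grid = 1)$p,
                 burden_test(z, Sigma)$p, tolerance = 1e-10)
    expect_equal(skato_test(z, Sigma, rho_grid = 0)$p,
                 skat_test(z, Sigma)$p, tolerance = 1e-10)
    # Cauchy combination bound: skato p is at least the smallest per-rho p
    full <- skato_test(z, Sigma)
    expect_lte(full$p, 1)
    expect_gte(full$p, min(full$meta$p_per_rho) - 1e-12)
  }
})

test_that("pca test follows identity and rank-1 spectra", {
  set.seed(35)
  z <- rnorm(6)
  r <- pca_test(z, diag(6), var_fraction = 1)
  expect_equal(r$statistic, sum(z^2))
  expect_equal(r$meta$df, 6)
  # all-ones 3x3: rank 1, v = 1/sqrt(3), lambda = 3, so
  # T = (v'z)^2 / lambda = (sum z)^2 / 9, which is chi-square(1) under the
  # null (z = s * 1 with s ~ N(0,1) gives T = s^2)
  z3 <- rnorm(3)
  r1 <- pca_test(z3, matrix(1, 3, 3), var_fraction = 0.5)
  expect_equal(r1$meta$df, 1)
  expect_equal(r1$statistic, sum(z3)^2 / 9)
  expect_equal(pca_test(rep(0, 3), diag(3))$p, 1)
  expect_error(pca_test(z3, matrix(0, 3, 3)), "eigenvalue")
})

test_that("acat combination follows the Cauchy formula", {
  expect_equal(acat_combine(0.5), 0.5)
  # identical components are returned unchanged
  for (p in c(0.3, 1e-5, 1e-20)) {
    expect_equal(acat_combine(rep(p, 4)), p, tolerance = 1e-6)
  }
  expect_equal(acat_combine(c(0.01, 0.5)),
               0.5 - atan(tan(0.49 * pi) / 2) / pi, tolerance = 1e-12)
  expect_lt(abs(acat_combine(c(0.01, 0.5)) - 0.0198), 5e-4)
  # extreme underflow does not break the combination
  expect_gt(acat_combine(c(1e-300, 0.5)), 0)
  expect_lt(acat_combine(c(1e-300, 0.5)), 1e-290)
  expect_error(acat_combine(numeric(0)), "no p-values")
})

test_that("p-values are deterministic for fixed input", {
  set.seed(36)
  Sigma <- random_corr(5)
  z <- rnorm(5)
  expect_identical(skat_test(z, Sigma)$p, skat_test(z, Sigma)$p)
  expect_identical(skato_test(z, Sigma)$p, skato_test(z, Sigma)$p)
  expect_identical(quadform_pvalue(7, c(1, 2, 0.3))$p,
                   quadform_pvalue(7, c(1, 2, 0.3))$p)
})

test_that("gba_all collects tests and optionally adds ACAT-O", {
  set.seed(37)
  Sigma <- random_corr(4)
  z <- rnorm(4)
  res <- gba_all(z, Sigma, acat = TRUE)
  expect_equal(res$test, c("burden", "skat", "skat-o", "pca", "acat-o"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$p[res$test == "acat-o"],
               acat_combine(res$p[res$test != "acat-o"]))
})
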