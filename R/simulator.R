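# Direct simulation of GWAS summary statistics over a gene and its
# surrounding region, without phenotype simulation.
#
# Causal SNPs are placed by per-SNP Bernoulli draws (K expected causal
# SNPs in total, a fraction rho of them in the gene); causal joint z
# effects are N(0, tau) with tau tied to genome-wide heritability; the
# marginal z statistics are z ~ N(U z_joint, U) for the common LD matrix
# U of the gene + region. A synthetic block-autoregressive LD generator
# stands in for reference-panel matrices so the whole pipeline is testable
# without genotype data.

#' Define a simulation scenario
#'
#' @param m_g,m_r Intragenic and extragenic SNP counts.
#' @param K Expected total number of causal SNPs (default 10).
#' @param rho Fraction of causal SNPs in the gene, in `[0, 1]`: 1 places
#'   all causal SNPs inside the gene, 0 places them all in the region.
#' @param h_gw2 Genome-wide SNP heritability in `[0, 1]`.
#' @param n_over_M Ratio of GWAS sample size to the genome-wide SNP count
#'   (default 0.05).
#' @param n GWAS sample size; defaults to `n_over_M * 20 * (m_g + m_r)`,
#'   i.e. the gene + region is taken to cover 1/20 of the genome panel, so
#'   that `n` and `M = n / n_over_M` are mutually consistent.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(m_g, m_r, K = 10, rho = 1, h_gw2 = 0.5,
                         n_over_M = 0.05, n = NULL) {
  stopifnot(m_g >= 1, m_r >= 0, K >= 1, rho >= 0, rho <= 1,
            h_gw2 >= 0, h_gw2 <= 1, n_over_M > 0)
  if (rho * K > m_g) stop("rho * K exceeds the number of gene SNPs")
  if ((1 - rho) * K > m_r) stop("(1 - rho) * K exceeds the number of region SNPs")
  if (is.null(n)) n <- round(n_over_M * 20 * (m_g + m_r))
  structure(list(m_g = m_g, m_r = m_r, K = K, rho = rho, h_gw2 = h_gw2,
                 n_over_M = n_over_M, n = n),
            class = "sim_scenario")
}

#' Synthetic block-autoregressive LD matrix
#'
#' Block-diagonal correlation matrix with AR(1) decay `ar_rho^|i-j|`
#' within each block — a stylized stand-in for haplotype-block LD. PSD by
#' construction.
#'
#' @param m Total SNP count.
#' @param block_sizes Integer block sizes summing to `m`; a scalar is
#'   recycled (last block truncated).
#' @param ar_rho Within-block decay in `[0, 1)`; 0 gives the identity.
#' @return An `m` x `m` correlation matrix with auto-generated SNP ids.
#' @export
#' @examples
#' synth_ld(3, 3, ar_rho = 0.5)  # off-diagonals 0.5 and 0.25
synth_ld <- function(m, block_sizes, ar_rho) {
  stopifnot(m >= 1, ar_rho >= 0, ar_rho < 1)
  if (length(block_sizes) == 1L) {
    block_sizes <- rep(block_sizes, ceiling(m / block_sizes))
    extra <- sum(block_sizes) - m
    if (extra > 0) block_sizes[length(block_sizes)] <-
        block_sizes[length(block_sizes)] - extra
    block_sizes <- block_sizes[block_sizes > 0]
  }
  if (sum(block_sizes) != m) stop("block sizes must sum to m")
  U <- matrix(0, m, m)
  off <- 0L
  for (b in block_sizes) {
    idx <- off + seq_len(b)
    U[idx, idx] <- ar_rho^abs(outer(seq_len(b), seq_len(b), `-`))
    off <- off + b
  }
  ids <- paste0("snp", seq_len(m))
  dimnames(U) <- list(ids, ids)
  U
}

#' Draw per-SNP causal status
#'
#' Independent Bernoulli draws: probability `rho * K / m_g` for each gene
#' SNP and `(1 - rho) * K / m_r` for each region SNP, so the expected
#' causal count is `K` with expected fraction `rho` inside the gene. The
#' realized count varies (no fixed-K sampling).
#'
#' @param scn A [sim_scenario].
#' @return Integer 0/1 vector of length `m_g + m_r` (gene SNPs first).
#' @export
draw_causal_status <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  p_g <- scn$rho * scn$K / scn$m_g
  p_r <- if (scn$m_r > 0) (1 - scn$rho) * scn$K / scn$m_r else 0
  if (p_g > 1 || p_r > 1) stop("causal probability exceeds 1")
  c(stats::rbinom(scn$m_g, 1L, p_g), stats::rbinom(scn$m_r, 1L, p_r))
}

#' Per-causal-SNP effect variance implied by genome-wide heritability
#'
#' Under equal per-SNP heritability, the local heritability attributable
#' to the `m_g + m_r` SNPs is `((m_g + m_r) / M) * h_gw2`; split over `K`
#' causal SNPs with per-SNP joint-z variance `n * h_snp2`, this gives
#' `tau = (n / M) * (m_g + m_r) * h_gw2 / K`.
#'
#' @param scn A [sim_scenario].
#' @return The scalar simulation variance `tau`.
#' @export
#' @examples
#' scn <- sim_scenario(m_g = 200, m_r = 4800, K = 10, h_gw2 = 0.5)
#' tau_sim(scn)  # 0.05 * 5000 * 0.5 / 10 = 12.5
tau_sim <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  scn$n_over_M * (scn$m_g + scn$m_r) * scn$h_gw2 / scn$K
}

# Symmetric PSD square root via eigendecomposition (rank-deficient safe).
psd_sqrt <- function(U) {
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Simulate one replicate of marginal z statistics
#'
#' Draws causal status, joint z effects `z_joint_i ~ N(0, tau)` for causal
#' SNPs (0 otherwise), and marginal z statistics
#' `z = U z_joint + L eps` with `L L' = U`, i.e. `z ~ N(U z_joint, U)`.
#' Deterministic given the RNG state; pass `causal` to fix the causal
#' vector across replicates.
#'
#' @param scn A [sim_scenario].
#' @param U Common LD matrix of dimension `m_g + m_r` (gene SNPs first).
#' @param Usqrt Optional precomputed PSD square root of `U` (saves the
#'   eigendecomposition when simulating many replicates).
#' @param causal Optional fixed 0/1 causal vector.
#' @return List with `causal`, `z_joint`, `z_marginal`, `tau_sim`.
#' @export
simulate_replicate <- function(scn, U, Usqrt = NULL, causal = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  m <- scn$m_g + scn$m_r
  if (nrow(U) != m) stop("LD matrix dimension does not match scenario")
  if (is.null(causal)) causal <- draw_causal_status(scn)
  tau <- tau_sim(scn)
  z_joint <- numeric(m)
  nc <- sum(causal)
  if (nc > 0 && tau > 0) {
    z_joint[causal == 1L] <- stats::rnorm(nc, 0, sqrt(tau))
  }
  if (is.null(Usqrt)) Usqrt <- psd_sqrt(U)
  z_marginal <- drop(U %*% z_joint) + drop(Usqrt %*% stats::rnorm(m))
  list(causal = causal, z_joint = z_joint, z_marginal = z_marginal,
       tau_sim = tau)
}

#' Run a simulation scenario through initial and conditional analysis
#'
#' For each replicate: simulate marginal z statistics over the gene +
#' region, run the requested initial gene-based tests on the gene slice
#' (z_g with U_g), select replicates whose initial p-value falls in
#' `(p_floor, threshold)`, and for those estimate tau from the region,
#' adjust the intragenic covariance, and rerun the tests conditionally.
#'
#' @param scn A [sim_scenario].
#' @param U Common LD matrix (`m_g + m_r`; gene SNPs are the first `m_g`).
#' @param reps Number of replicates.
#' @param tests Subset of `c("burden", "skat", "skat-o", "pca")`.
#' @param threshold Selection threshold on the initial p-value (default
#'   2.5e-6, the usual gene-level significance cut-off).
#' @param p_floor Lower selection bound (default 1e-30, mirroring
#'   comparator tools that cannot process more extreme initial signals;
#'   set to 0 to disable).
#' @param var_fraction Retained-variance fraction for the PCA test.
#' @param frac,eps Truncation rule for the regional eigendecomposition.
#' @return A data.frame, one row per replicate x test: replicate index,
#'   test, initial `p_init`/`log10p_init`, `selected` flag, and for
#'   selected replicates `tau_hat`, `h_r2`, conditional `p_cond`,
#'   `log10p_cond`.
#' @export
run_scenario <- function(scn, U, reps, tests = c("burden", "skat", "pca"),
                         threshold = 2.5e-6, p_floor = 1e-30,
                         var_fraction = 0.85, frac = 0.999, eps = 1e-8) {
  stopifnot(inherits(scn, "sim_scenario"), reps >= 1)
  m_g <- scn$m_g
  m <- m_g + scn$m_r
  gi <- seq_len(m_g)
  ri <- m_g + seq_len(scn$m_r)
  U_g <- U[gi, gi, drop = FALSE]
  U_r <- U[ri, ri, drop = FALSE]
  U_gr <- U[gi, ri, drop = FALSE]
  Usqrt <- psd_sqrt(U)
  eig_r <- if (scn$m_r > 0) {
    truncated_eigen(repair_psd(U_r), frac = frac, eps = eps)
  } else NULL
  part <- list(U_g = U_g, U_gr = U_gr, degenerate = scn$m_r == 0L)
  run_tests <- function(z, Sigma) {
    gba_all(z, Sigma, tests = tests, var_fraction = var_fraction)
  }
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_r <- simulate_replicate(scn, U, Usqrt = Usqrt)
    z_g <- rep_r$z_marginal[gi]
    z_r <- rep_r$z_marginal[ri]
    init <- run_tests(z_g, U_g)
    sel <- init$p < threshold & init$p > p_floor
    row <- data.frame(rep = r, test = init$test,
                      p_init = init$p, log10p_init = init$log10p,
                      selected = sel,
                      tau_hat = NA_real_, h_r2 = NA_real_,
                      p_cond = NA_real_, log10p_cond = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(sel) && scn$m_r > 0) {
      est <- estimate_tau(z_r, n = scn$n, eig = eig_r)
      sigma <- adjust_gene_cov(part, est$tau_hat)$sigma
      cond <- run_tests(z_g, sigma)
      row$tau_hat[sel] <- est$tau_hat
      row$h_r2[sel] <- est$h_r2
      row$p_cond[sel] <- cond$p[sel]
      row$log10p_cond[sel] <- cond$log10p[sel]
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}
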