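# taucor

Conditional gene-based association analysis from GWAS summary statistics,
correcting for the regional polygenic background.

## What problem this solves

Gene-based association (GBA) tests aggregate per-SNP GWAS z statistics
over the SNPs of a gene. Linkage disequilibrium (LD) with causal variants
*outside* the gene induces spurious gene-level signal, so a conditional
analysis step is needed before a hit can be attributed to the gene
itself. Instead of recomputing per-SNP statistics conditional on a few
selected top external SNPs, this package models the whole surrounding
region as a polygenic background with random SNP effects of common
variance τ, estimates τ by maximum likelihood from the extragenic z
statistics, and corrects the intragenic LD matrix:

- regional model: `z_r ~ N(0, τ·U_r² + U_r)`, with
  `τ = n·h_r²/m_r ∈ [0, n/m_r]` proportional to the local SNP
  heritability of the region (`n` = GWAS sample size, `m_r` = regional
  SNP count);
- corrected intragenic covariance: `Σ = τ·U_gr·U_grᵀ + U_g`, used in
  place of `U_g` by any GBA test, with the observed intragenic z vector
  unchanged.

Because `Σ − U_g` is positive semidefinite, kernel score tests (Burden,
SKAT, SKAT-O) can only lose significance after the correction — the
adjustment removes induced signal and never manufactures it. The PCA
test does not carry this guarantee.

Intended users: statistical geneticists running gene-based scans from
summary statistics and reference LD panels.

## What is in the package

- `read_sumstats()`, `read_ld_matrix()`, `read_gene_intervals()` — TSV
  summary statistics (SNP, POS, Z or BETA+SE, N), square-text / PLINK
  `--r square` LD matrices, BED-like gene intervals.
- `partition_region()`, `repair_psd()`, `truncated_eigen()` — gene/region
  partition and the low-rank spectral machinery.
- `estimate_tau()`, `neg2_loglik()` — bounded 1-D maximum likelihood for τ.
- `adjust_gene_cov()` — the corrected covariance.
- `burden_test()`, `skat_test()`, `skato_test()`, `pca_test()`,
  `acat_combine()`, `gba_all()` — gene-based tests on a z vector and a
  covariance matrix, with an exact chi-square-mixture p-value engine
  (`quadform_pvalue()`) that stays finite far below p = 1e-300.
- `run_pipeline()` — the two-step scan over a gene list;
  `inst/cli/taucor.R` is a thin command-line front end
  (`estimate-tau`, `adjust`, `test`, `simulate`, `evaluate`, `pipeline`).
- `sim_scenario()`, `synth_ld()`, `simulate_replicate()`,
  `run_scenario()` — direct simulation of marginal z statistics
  `z ~ N(U·z_joint, U)` over a gene + region, without phenotype data.
- `performance()` — sensitivity / specificity / accuracy of gene-level
  calls at a significance threshold (default 2.5e-6).

See `vignettes/taucor-methods.Rmd` for the model, assumptions, defaults
and limitations.

## Worked example

Simulate a locus (50 intragenic + 450 extragenic SNPs, block-AR LD with
the gene embedded in a larger haplotype block) where all causal SNPs lie
*outside* the gene — the nearest just 5 SNPs beyond its boundary — and
run the two-step analysis:

```r
library(taucor)
set.seed(7)

m_g <- 50; m_r <- 450
U   <- synth_ld(m_g + m_r, 100, ar_rho = 0.95)   # gene = first half of block 1
scn <- sim_scenario(m_g = m_g, m_r = m_r, K = 5, rho = 0,  # signal only outside
                    h_gw2 = 0.7)
causal <- rep(0L, 500); causal[c(55, 70, 160, 300, 420)] <- 1L
rep1 <- simulate_replicate(scn, U, causal = causal)

gi  <- 1:m_g
z_g <- rep1$z_marginal[gi];  z_r <- rep1$z_marginal[-gi]
U_g <- U[gi, gi];  U_r <- U[-gi, -gi];  U_gr <- U[gi, -gi, drop = FALSE]

init <- gba_all(z_g, U_g, tests = c("burden", "skat", "pca"))
est  <- estimate_tau(z_r, U_r = U_r, n = scn$n)
sig  <- adjust_gene_cov(list(U_g = U_g, U_gr = U_gr), est$tau_hat)$sigma
cond <- gba_all(z_g, sig, tests = c("burden", "skat", "pca"))

print(est)
print(cbind(init[1:2], p_init = init$p, p_cond = cond$p))
```

Output:

```
tau estimate: tau_hat = 0.0462851 (bounds [0, 1.111]), h_r2 = 0.04166, m_r = 450, rank 433
    test statistic       p_init      p_cond
1 burden  11.17515 0.0008290023 0.001555894
2   skat 310.49836 0.0008684236 0.001669678
3    pca  21.14867 0.0002958830 0.001048103
```

The gene carries no causal variant, yet all three tests show nominal
initial signal (p ≈ 3e-4 to 9e-4) induced by LD with the causal SNP
sitting just outside the boundary (its joint z in this replicate is
4.3). The regional fit attributes local heritability h_r² ≈ 0.04 to the
450 surrounding SNPs (τ̂ ≈ 0.046 within its admissible bound
n/m_r ≈ 1.11); the corrected covariance `τ̂·U_gr·U_grᵀ + U_g` widens the
null, and every conditional p-value retreats roughly two- to four-fold
toward insignificance. For the Burden/SKAT family that retreat is
one-directional by construction: the conditional p-value can never be
smaller than the initial one.

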