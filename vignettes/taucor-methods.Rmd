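---
title: "Conditional gene-based analysis with a regional polygenic background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional gene-based analysis with a regional polygenic background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taucor)
```

## The problem

Gene-based association (GBA) tests aggregate per-SNP GWAS summary
statistics over all SNPs of a gene. Because SNP genotypes are correlated
through linkage disequilibrium (LD), a causal variant *outside* a gene
induces association signal in the gene's own z statistics; a gene-level
test then flags the gene even though it carries no causal variant.
Conditional analysis aims to remove this induced signal. Per-SNP
approaches (COJO-style) recompute each intragenic z statistic conditional
on a small set of selected top extragenic SNPs; this package instead
treats the *entire* surrounding region as a polygenic background and
corrects the *covariance* of the intragenic z statistics, leaving the z
statistics themselves untouched. Any GBA test that consumes a z vector
and an LD matrix can then be rerun unchanged on the corrected covariance.

## Model

Let setG be the $m_g$ SNPs inside a gene and setR the $m_r$ SNPs in a
flanking window, with marginal z statistics $z_g$, $z_r$, LD blocks
$U_g$ ($m_g \times m_g$), $U_r$ ($m_r \times m_r$) and the cross block
$U_{gr}$ ($m_g \times m_r$). A linear model for standardized data with
*random* extragenic effects $\bar\beta_r \sim N(0, \tau I_{m_r})$ yields,
under the gene-level null,

$$z_r = U_r \bar\beta_r + \xi_{m_r}, \qquad \xi_{m_r} \sim N(0, U_r),$$

so the marginal distribution of the regional z statistics is

$$z_r \sim N(0,\; \tau U_r^2 + U_r).$$

The scalar $\tau$ is the common variance of the random joint extragenic
effects and is proportional to the local SNP heritability of the region:
$\tau = n h_r^2 / m_r$ for GWAS sample size $n$, which bounds the
admissible range to $0 \le \tau \le n/m_r$.

**Step 1 — estimate $\tau$.** Up to a constant, minus twice the
log-likelihood is

$$-2\log L(\tau) = \log\left|\tau U_r^2 + U_r\right|
  + z_r^\top \left(\tau U_r^2 + U_r\right)^{-1} z_r .$$

Reference LD matrices are strongly collinear, so the inverse is taken as
a pseudo-inverse on a truncated eigen-subspace: with eigenpairs
$(\lambda_i, v_i)$ of $U_r$ and $w_i = v_i^\top z_r$,

$$-2\log L(\tau) = \sum_{i \le r^\*}
  \left[\log(\tau\lambda_i^2 + \lambda_i)
  + \frac{w_i^2}{\tau\lambda_i^2 + \lambda_i}\right],$$

where $r^\*$ is the retained rank. One $O(m_r^3)$ decomposition is done
per region; each likelihood evaluation afterwards is $O(r^\*)$, so the
one-dimensional bounded minimization over $[0, n/m_r]$
(`stats::optimize`, tolerance $10^{-6}$ on $\tau$) is essentially free.
For $U_r = I$ the maximizer has the closed form
$\hat\tau = \mathrm{clip}(\overline{z^2} - 1,\, 0,\, n/m_r)$, which the
test suite uses as an independent oracle.

**Step 2 — correct the intragenic covariance.** The top row of the joint
model gives, under the gene-level null $\bar\beta_g = 0$,

$$\mathrm{Cov}(z_g) = \tau\, U_{gr} U_{gr}^\top + U_g,$$

and this matrix simply replaces $U_g$ in the secondary GBA analysis. Two
points are deliberate:

* the conditional mean of $z_g$ is zero — the observed $z_g$ is **not**
  shifted; only the null covariance changes;
* the corrected matrix is **not** re-standardized to a correlation
  matrix. The inflation of the diagonal above 1 *is* the correction; for
  a single-SNP gene rescaling would cancel it entirely, and
  re-standardization would break the monotonicity guarantee below.

**Monotonicity.** $\tau U_{gr}U_{gr}^\top \succeq 0$, so the corrected
covariance dominates $U_g$ in the Loewner order. For kernel score tests
(Burden, SKAT, SKAT-O) the statistic is a fixed quadratic functional of
$z_g$ while the null distribution widens, so the conditional p-value is
always $\ge$ the initial one: the correction can only *remove*
significance, never create it. The PCA test does not share the property:
its retained subspace and component variances change with the
covariance, so conditional significance can occasionally increase. The
test suite demonstrates both facts empirically (1000 random instances
for the kernel tests; a seeded counterexample search for PCA).

## The gene-based tests

All tests consume $(z, \Sigma)$ with default unit weights ($z$ statistics
are already standardized; MAF-based weights are exposed as an option):

* **Burden**: $T = (w^\top z)^2 / (w^\top \Sigma w) \sim \chi^2_1$.
* **SKAT**: $Q = \sum_i w_i^2 z_i^2$; null is the chi-square mixture
  with weights the eigenvalues of $W\Sigma W$.
* **SKAT-O**: kernels $K_\rho = (1-\rho)W^2 + \rho\, w w^\top$ over a
  $\rho$ grid ($\{0, 0.1^2, \dots, 0.5^2, 0.5, 1\}$); the per-$\rho$
  p-values are combined with the Cauchy combination. This replaces the
  original one-dimensional-integration combination: it is simpler,
  well-calibrated under dependence, and degenerates exactly to SKAT at
  $\rho = 0$ and Burden at $\rho = 1$.
* **PCA**: retain the smallest leading set of eigencomponents of
  $\Sigma$ reaching `var_fraction` (default 0.85) of the trace; $T =
  \sum_k (v_k^\top z)^2/\lambda_k \sim \chi^2_k$.
* **ACAT-O**: Cauchy combination
  $T = \tfrac1{\sum w_j}\sum_j w_j \tan((0.5 - p_j)\pi)$,
  $p = 0.5 - \arctan(T)/\pi$, valid under arbitrary dependence.

**Chi-square mixture p-values.** `quadform_pvalue()` evaluates
$P(\sum_i \lambda_i \chi^2_{1,i} > q)$ by the exact Imhof inversion
integral (`stats::integrate`, relative tolerance $10^{-7}$). Deep in the
tail the oscillating integrand cannot beat its absolute error floor
(about $10^{-10}$), so when the preliminary Liu–Tang–Zhang
moment-matching estimate is below $10^{-9}$, or the integral fails to
converge or falls below 100 times its own error estimate, the
moment-matching value is used instead and the choice is recorded in the
result. The Liu branch computes the survival function on the log scale,
so p-values far below the double-precision underflow limit are reported
via `log10p` with `p` clamped at $10^{-300}$ — the pipeline never fails
on extreme initial signals, where per-SNP conditional tools are known to.
A single mixture weight short-circuits to the exact scaled
$\chi^2_1$ survival function, which also makes the SKAT-O degeneracies
exact.

## Simulator

The summary-statistics simulator draws, for a gene + region of
$m = m_g + m_r$ SNPs with common LD matrix $U$:

1. causal status $c_i \sim \mathrm{Bernoulli}(\rho K / m_g)$ in the gene
   and $\mathrm{Bernoulli}((1-\rho)K/m_r)$ in the region — the expected
   causal count is $K$ (default 10) with expected fraction $\rho$ inside
   the gene; the realized count varies by design;
2. joint z effects $z_{j,i} \sim N(0, \tau_{\mathrm{sim}})$ for causal
   SNPs, 0 otherwise, with
   $\tau_{\mathrm{sim}} = (n/M)\,(m_g + m_r)\, h_{GW}^2 / K$ — equal
   per-SNP heritability, so that the $K$ causal SNPs jointly carry the
   local heritability $\left((m_g+m_r)/M\right) h_{GW}^2$ of the locus
   ($M$ = genome-wide SNP count, $n/M$ default 0.05);
3. marginal z statistics $z \sim N(U z_j,\, U)$ via the PSD eigen square
   root of $U$.

The implied covariance identity
$\mathrm{Cov}(z) = U\,\tau_{\mathrm{sim}} D_c\,U + U$ (with
$D_c = \mathrm{diag}(c)$) is verified empirically in the test suite at
5000 replicates. A block-autoregressive generator
(`synth_ld()`: within-block correlation $\rho_{AR}^{|i-j|}$) stands in
for reference-panel LD so that everything runs without genotype data.
What the synthetic LD does **not** emulate: long-range irregular LD,
allele-frequency-dependent correlation, sample mismatch between the
GWAS and the reference panel, and indefiniteness of estimated LD
matrices (the latter is exercised separately through `repair_psd`).
Passing simulation tests therefore validates the machinery and the
distributional claims, not robustness to real-panel artefacts.

Note on the two taus: the simulator's $\tau_{\mathrm{sim}}$ is a
*per-causal-SNP* variance under a sparse causal model, while the
estimator's $\tau$ spreads the regional contribution over *all* $m_r$
SNPs. The estimator is applied to the simulated data as-is — the method
is meant to tolerate exactly this mis-specification — and no
reconciliation between the two scales is attempted.

## Defaults and numerical choices

| parameter | default | meaning |
|---|---|---|
| `window` | 1,000,000 bp | flanking window from the gene boundaries (1 Mb; larger windows are appropriate for dense real panels) |
| `frac` | 0.999 | retained eigenvalue mass of $U_r$ |
| `eps` | $10^{-8}$ | relative eigenvalue floor ($\times \lambda_{max}$) |
| `tol` | $10^{-6}$ | optimizer tolerance on $\tau$ |
| `var_fraction` | 0.85 | PCA retained-variance fraction |
| `threshold` | $2.5\times10^{-6}$ | gene-level significance / selection cut-off |
| `p_floor` | 0 | optional lower selection bound ($10^{-30}$ for comparator parity) |
| `rho_grid` | $\{0, .01, .04, .09, .16, .25, .5, 1\}$ | SKAT-O kernels |

The truncation defaults keep essentially all information while removing
the numerically null space of collinear LD; both knobs are exposed
because no canonical rule exists. Indefinite LD input is repaired by
eigenvalue clipping *without* rescaling the diagonal back to one —
rescaling can reintroduce indefiniteness — and the diagonal perturbation
is reported. Gene intervals are 1-based half-open $[start, end)$; SNPs
are matched to LD matrices by exact identifier and order, with no allele
harmonization (z signs are taken as given). Flat likelihoods
($z_r \approx 0$) return the boundary $\hat\tau = 0$ with
`at_lower_bound` set; boundary proximity is flagged within $10\times$
the optimizer tolerance. Degenerate partitions (no extragenic SNPs)
skip the adjustment and return $U_g$ unchanged.

## Problem sizes used in the shipped analyses

The package's own verification runs are sized for a laptop-class
single-core budget: identity-LD oracle agreement over 1000 random
instances; dense-likelihood agreement up to $m_r = 50$; parameter
recovery at $m_r = 500$ with 200 replicates per $\tau \in
\{0, 0.5, 1, 2\}$; kernel monotonicity over 1000 random instances with
$m_g \le 10$; type-I calibration at $10^5$ null replicates; and a
simulation grid with $m_g = 100$ intragenic plus $m_r = 2000$
extragenic SNPs under long-range AR LD, $h_{GW}^2 \in \{0.3, 0.5,
0.7\}$ and $\rho \in \{0, 1\}$, with 150–300 replicates per cell.
These are scaled-down analogues of panel-scale runs (hundreds of genes,
thousands of replicates, 4000–9000 regional SNPs), which the same code
handles by supplying real LD matrices.

## Known limitations

* LD matrices are consumed, not computed: no genotype handling, no
  allele flipping, no reference-panel management.
* The method corrects gene-level inference, not per-SNP statistics; it
  does not produce conditional per-SNP z values.
* A single variance component is fitted per region; no covariates, no
  multi-region joint fit.
* With very small regions ($m_r$ of a few dozen) the $\tau$ estimate is
  noisy and frequently sits at a boundary; the boundary flags should be
  inspected before interpreting $h_r^2$.
* The Cauchy-combination SKAT-O is a deliberate simplification of the
  original omnibus; its per-$\rho$ degeneracies are exact but
  intermediate-$\rho$ behaviour differs slightly.
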