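# Shared fixtures: random correlation-like matrices and MVN draws.

# Random m x m correlation matrix: random PSD with unit diagonal.
random_corr <- function(m, df = m + 2) {
  A <- matrix(rnorm(m * df), m, df)
  S <- tcrossprod(A) / df
  D <- diag(1 / sqrt(diag(S)), m)
  U <- D %*% S %*% D
  (U + t(U)) / 2
}

# Draw k MVN(0, Sigma) vectors as columns, via the PSD eigen square root.
rmvn_cols <- function(k, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  L %*% matrix(rnorm(nrow(Sigma) * k), nrow(Sigma), k)
}

# A joint (gene + region) correlation matrix plus its blocks.
random_gene_region <- function(m_g, m_r) {
  U <- random_corr(m_g + m_r)
  gi <- seq_len(m_g)
  ri <- m_g + seq_len(m_r)
  list(U = U, U_g = U[gi, gi, drop = FALSE],
       U_r = U[ri, ri, drop = FALSE],
       U_gr = U[gi, ri, drop = FALSE])
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
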