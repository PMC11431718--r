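test_that("read_ld_matrix handles identity, headers, and symmetrization", {
  f <- write_lines_tmp(c("1 0", "0 1"))
  U <- read_ld_matrix(f)
  expect_equal(unname(U), diag(2))
  expect_equal(rownames(U), c("snp1", "snp2"))

  # header row of SNP ids
  fh <- write_lines_tmp(c("rs1\trs2", "1\t0.3", "0.3\t1"))
  Uh <- read_ld_matrix(fh)
  expect_equal(rownames(Uh), c("rs1", "rs2"))
  expect_equal(Uh["rs1", "rs2"], 0.3)

  # small asymmetry repaired by averaging
  fa <- write_lines_tmp(c("1 0.5", "0.5000001 1"))
  Ua <- read_ld_matrix(fa)
  expect_equal(Ua[1, 2], 0.50000005)
  expect_equal(Ua[1, 2], Ua[2, 1])
})

test_that("read_ld_matrix rejects malformed input", {
  expect_error(read_ld_matrix(write_lines_tmp(c("1 0 0", "0 1 0"))),
               "non-square")
  expect_error(read_ld_matrix(write_lines_tmp(c("1 1.2 0", "1.2 1 0", "0 0 1"))),
               "\\[-1, 1\\]")
  expect_error(read_ld_matrix(write_lines_tmp(c("1 0.5", "0.6 1"))),
               "asymmetry")
  expect_error(read_ld_matrix(write_lines_tmp(c("1 0", "0 0.9"))),
               "diagonal")
  expect_error(read_ld_matrix(write_lines_tmp(c("1 NaN", "NaN 1"))))
})

test_that("read_sumstats derives z from beta/se and enforces contracts", {
  f <- write_lines_tmp(c("SNP\tPOS\tBETA\tSE", "rs1\t100\t0.2\t0.1",
                         "rs2\t200\t-0.3\t0.15"), ext = ".tsv")
  ss <- read_sumstats(f)
  expect_equal(ss$z, c(2, -2))
  expect_equal(ss$pos, c(100L, 200L))

  fz <- write_lines_tmp(c("SNP\tZ", "rs1\t1.5", "rs2\t-0.7"), ext = ".tsv")
  expect_equal(read_sumstats(fz)$z, c(1.5, -0.7))

  fdup <- write_lines_tmp(c("SNP\tZ", "rs1\t1", "rs1\t2"), ext = ".tsv")
  expect_error(read_sumstats(fdup), "duplicated")
  fnone <- write_lines_tmp(c("SNP\tBETA", "rs1\t1"), ext = ".tsv")
  expect_error(read_sumstats(fnone), "Z|BETA")
  expect_error(sumstats("rs1", beta = 1, se = -0.1), "se")
  expect_error(sumstats("rs1", z = 5, beta = 1, se = 1), "inconsistent")
  # N column -> median n
  fn <- write_lines_tmp(c("SNP\tZ\tN", "rs1\t1\t900", "rs2\t0\t1100",
                          "rs3\t2\t1000"), ext = ".tsv")
  expect_equal(read_sumstats(fn)$n, 1000)
})

test_that("partition_region slices gene and window correctly", {
  ids <- paste0("rs", 1:5)
  ss <- sumstats(ids, pos = c(10, 20, 30, 40, 50), z = rnorm(5), n = 100)
  U <- diag(5); dimnames(U) <- list(ids, ids)
  part <- partition_region(ss, U, gene_start = 25, gene_end = 45, window = 100)
  expect_equal(part$m_g, 2)
  expect_equal(part$m_r, 3)
  expect_equal(part$gene$pos, c(30L, 40L))
  expect_equal(dim(part$U_gr), c(2L, 3L))
  expect_false(part$degenerate)

  # all SNPs inside the gene -> degenerate region
  part2 <- partition_region(ss, U, gene_start = 5, gene_end = 55, window = 100)
  expect_true(part2$degenerate)
  expect_equal(part2$m_r, 0)

  # permuted labels violate the order contract
  Up <- U[5:1, 5:1]
  expect_error(partition_region(ss, Up, 25, 45, 100), "reordered|differ")
  # no intragenic SNPs
  expect_error(partition_region(ss, U, 60, 70, 100), "intragenic")
})

test_that("partition conservation: restacking blocks recovers the matrix", {
  set.seed(42)
  ids <- paste0("rs", 1:12)
  pos <- seq(100, 1200, by = 100)
  U <- random_corr(12); dimnames(U) <- list(ids, ids)
  ss <- sumstats(ids, pos = pos, z = rnorm(12), n = 50)
  part <- partition_region(ss, U, gene_start = 350, gene_end = 750,
                           window = 10000)
  restacked <- rbind(cbind(part$U_g, part$U_gr),
                     cbind(t(part$U_gr), part$U_r))
  ord <- c(part$gene$snp_ids, part$region$snp_ids)
  expect_equal(unname(restacked), unname(U[ord, ord]))
})

test_that("repair_psd clips negative eigenvalues and is idempotent", {
  expect_equal(repair_psd(diag(3)), diag(3))

  # 2x2 with eigenvalues 2.1 and -0.1 -> rank-1 PSD after clipping
  U <- matrix(c(1, -1.1, -1.1, 1), 2)
  expect_equal(sort(eigen(U)$values), c(-0.1, 2.1))
  R <- repair_psd(U, floor = 0)
  ev <- eigen(R, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(ev[1], 2.1)
  expect_equal(sum(ev > 1e-10), 1)
  # hand eigendecomposition: v = (1,-1)/sqrt(2), R = 2.1 * v v'
  expect_equal(R, 2.1 * outer(c(1, -1), c(1, -1)) / 2)

  # idempotence and PSD no-op
  set.seed(7)
  for (i in 1:5) {
    A <- random_corr(6) - 0.3 * diag(6)  # possibly indefinite
    R1 <- repair_psd(A)
    expect_equal(repair_psd(R1), R1, tolerance = 1e-10)
  }
  P <- random_corr(5)
  expect_equal(repair_psd(P), P, tolerance = 1e-10)
})

test_that("truncated_eigen applies the fraction and floor rules", {
  e1 <- truncated_eigen(diag(4))
  expect_equal(e1$rank, 4)
  expect_equal(e1$values, rep(1, 4))
  expect_equal(crossprod(e1$vectors), diag(4), tolerance = 1e-8)

  # all-ones 3x3: spectrum (3, 0, 0) -> rank 1
  e2 <- truncated_eigen(matrix(1, 3, 3))
  expect_equal(e2$rank, 1)
  expect_equal(e2$values, 3)

  # eigenvalue floor: (2, 1, 1e-12) with eps = 1e-8 -> rank 2
  D <- diag(c(2, 1, 1e-12))
  e3 <- truncated_eigen(D, frac = 1, eps = 1e-8)
  expect_equal(e3$rank, 2)

  expect_error(truncated_eigen(matrix(0, 2, 2)), "positive")
})

test_that("truncated reconstruction error equals discarded eigenvalue mass", {
  set.seed(11)
  for (i in 1:5) {
    U <- random_corr(8)
    e <- truncated_eigen(U, frac = 0.9)
    recon <- e$vectors %*% (e$values * t(e$vectors))
    all_ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
    discarded <- all_ev[-seq_len(e$rank)]
    expect_equal(sum((U - recon)^2), sum(discarded^2), tolerance = 1e-8)
  }
})

test_that("gene interval reader parses BED-like files", {
  f <- write_lines_tmp(c("22\t100\t500\tGENE1", "22\t900\t1200\tGENE2"))
  g <- read_gene_intervals(f)
  expect_equal(g$name, c("GENE1", "GENE2"))
  expect_equal(g$start, c(100L, 900L))
  expect_error(read_gene_intervals(write_lines_tmp("22\t500\t100\tG")),
               "start < end")
})
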