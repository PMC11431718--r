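# LD-matrix and summary-statistics handling: reading, validation, the
# gene/region partition, PSD repair and truncated eigendecomposition.

#' Construct a summary-statistics object
#'
#' Container for per-SNP GWAS summary statistics over a gene and its
#' surrounding region: SNP identifiers, base-pair positions, marginal z
#' statistics (optionally derived from effect sizes and standard errors),
#' and the GWAS sample size.
#'
#' @param snp_ids Character vector of unique SNP identifiers.
#' @param pos Integer vector of 1-based base-pair positions (or `NULL`).
#' @param z Numeric vector of marginal z statistics. If `NULL`, computed
#'   as `beta / se`.
#' @param beta,se Optional numeric vectors of effect sizes and standard
#'   errors (`se > 0`). When both `z` and `beta`/`se` are given they must
#'   agree: `|z - beta/se| <= 1e-6`.
#' @param n Positive integer GWAS sample size, or `NA` if unknown.
#'
#' @return An object of class `"sumstats"`: a list with elements
#'   `snp_ids`, `pos`, `z`, `beta`, `se`, `n`.
#' @export
#' @examples
#' ss <- sumstats(c("rs1", "rs2"), pos = c(100L, 200L),
#'                beta = c(0.2, -0.1), se = c(0.1, 0.1), n = 10000)
#' ss$z  # 2, -1
sumstats <- function(snp_ids, pos = NULL, z = NULL, beta = NULL, se = NULL,
                     n = NA_integer_) {
  snp_ids <- as.character(snp_ids)
  m <- length(snp_ids)
  if (m == 0L) stop("at least one SNP is required")
  if (anyDuplicated(snp_ids)) {
    stop("duplicated SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  if (!is.null(beta) != !is.null(se)) {
    stop("'beta' and 'se' must be supplied together")
  }
  if (!is.null(se) && any(se <= 0)) stop("all 'se' values must be > 0")
  if (is.null(z)) {
    if (is.null(beta)) stop("either 'z' or both 'beta' and 'se' are required")
    z <- beta / se
  } else if (!is.null(beta)) {
    if (max(abs(z - beta / se)) > 1e-6) {
      stop("'z' inconsistent with 'beta'/'se' (|z - beta/se| > 1e-6)")
    }
  }
  z <- as.numeric(z)
  if (!is.null(pos)) pos <- as.integer(pos)
  for (v in list(pos, z, beta, se)) {
    if (!is.null(v) && length(v) != m) stop("all vectors must have equal length")
  }
  if (!is.na(n) && n < 1) stop("'n' must be >= 1")
  structure(list(snp_ids = snp_ids, pos = pos, z = z,
                 beta = beta, se = se, n = as.numeric(n)),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics: %d SNPs, n = %s\n", length(x$snp_ids),
              ifelse(is.na(x$n), "unknown", format(x$n))))
  invisible(x)
}

#' Read GWAS summary statistics from a TSV file
#'
#' The file must have a header with column `SNP` and either `Z` or both
#' `BETA` and `SE` (case-insensitive). Optional columns `POS` and `N` are
#' used for positions and the sample size (median of per-SNP `N`).
#'
#' @param path Path to a tab- or whitespace-delimited text file.
#' @param n Sample size override; required when the file has no `N` column
#'   and downstream steps need `n`.
#' @return A [sumstats] object with rows in file order.
#' @export
read_sumstats <- function(path, n = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df) <- toupper(names(df))
  if (!"SNP" %in% names(df)) stop("missing mandatory column 'SNP'")
  has_z <- "Z" %in% names(df)
  has_bs <- all(c("BETA", "SE") %in% names(df))
  if (!has_z && !has_bs) {
    stop("need column 'Z' or both 'BETA' and 'SE'")
  }
  if (is.na(n) && "N" %in% names(df)) n <- stats::median(df$N)
  sumstats(snp_ids = df$SNP,
           pos = if ("POS" %in% names(df)) df$POS else NULL,
           z = if (has_z) df$Z else NULL,
           beta = if (has_bs) df$BETA else NULL,
           se = if (has_bs) df$SE else NULL,
           n = n)
}

#' Read gene intervals from a BED-like file
#'
#' Columns: chrom, start, end, and optionally a gene name (tab- or
#' whitespace-delimited, no header). Intervals are interpreted as 1-based
#' half-open `[start, end)`.
#'
#' @param path Path to the interval file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need at least 3 columns: chrom, start, end")
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4L]])
                           else paste0("gene", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("intervals must satisfy start < end")
  out
}

# Validate an LD matrix: square, symmetric, unit diagonal, entries in [-1,1].
# 'full' = FALSE relaxes the unit-diagonal check (off-diagonal blocks).
validate_ld <- function(U, full = TRUE, tol_sym = 1e-8) {
  if (!is.matrix(U) || nrow(U) != ncol(U)) stop("LD matrix must be square")
  if (anyNA(U)) stop("LD matrix contains NA/NaN entries")
  asym <- max(abs(U - t(U)))
  if (asym > tol_sym) stop(sprintf("LD matrix asymmetric (max |U - t(U)| = %.3g)", asym))
  if (full && max(abs(diag(U) - 1)) > 1e-6) {
    stop("LD matrix diagonal deviates from 1 by more than 1e-6")
  }
  if (max(abs(U)) > 1 + 1e-8) stop("LD matrix entries outside [-1, 1]")
  invisible(U)
}

#' Read an LD (SNP-SNP correlation) matrix
#'
#' Supports plain square text matrices (whitespace/tab-delimited, with an
#' optional single header row of SNP ids) and PLINK `--r square` `.ld`
#' output, which is the same square layout without labels.
#'
#' Small asymmetries (at most `1e-6`) are repaired by averaging
#' `(U + t(U)) / 2`; larger ones are an error.
#'
#' @param path Path to the matrix file.
#' @param dialect `"square-text"` or `"plink-ld"` (both are square text;
#'   `"plink-ld"` never has a header).
#' @param snp_ids Optional SNP identifiers overriding header/auto-generated
#'   labels.
#' @return A validated symmetric numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path, dialect = c("square-text", "plink-ld"),
                           snp_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty LD matrix file")
  first <- strsplit(trimws(lines[1L]), "[ \t,]+")[[1L]]
  header <- NULL
  if (dialect == "square-text" &&
      anyNA(suppressWarnings(as.numeric(first)))) {
    header <- first
    lines <- lines[-1L]
  }
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[ \t,]+")[[1L]])
  })
  m <- length(rows)
  if (any(lengths(rows) != m)) {
    stop(sprintf("non-square input: %d rows but row lengths %s",
                 m, paste(unique(lengths(rows)), collapse = "/")))
  }
  U <- do.call(rbind, rows)
  if (anyNA(U)) stop("LD matrix contains non-numeric or NaN entries")
  asym <- max(abs(U - t(U)))
  if (asym > 1e-6) {
    stop(sprintf("LD matrix asymmetry %.3g exceeds 1e-6", asym))
  }
  U <- (U + t(U)) / 2
  if (max(abs(diag(U) - 1)) > 1e-4) {
    stop("LD matrix diagonal deviates from 1 by more than 1e-4")
  }
  diag(U) <- 1
  ids <- snp_ids
  if (is.null(ids)) ids <- header
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  if (length(ids) != m) stop("snp_ids length does not match matrix dimension")
  dimnames(U) <- list(ids, ids)
  validate_ld(U)
  U
}

#' Partition SNPs into the intragenic set and the surrounding region
#'
#' Splits summary statistics and the LD matrix into the intragenic SNP set
#' (setG, positions within the half-open gene interval `[start, end)`) and
#' the extragenic set (setR, positions within `window` bp of the gene
#' boundaries but outside the gene). The LD matrix is sliced into the
#' corresponding blocks `U_g` (gene), `U_r` (region) and `U_gr`
#' (gene-by-region cross-correlations).
#'
#' @param stats A [sumstats] object with positions.
#' @param ld LD matrix whose dimnames match `stats$snp_ids` in identical
#'   order.
#' @param gene_start,gene_end 1-based half-open gene interval bounds.
#' @param window Flanking window in base pairs measured from the gene
#'   boundaries (default 1 Mb).
#' @return An object of class `"region_partition"`: list with `gene` and
#'   `region` ([sumstats] slices), blocks `U_g`, `U_r`, `U_gr`, counts
#'   `m_g`, `m_r`, and a `degenerate` flag (`TRUE` when the region is
#'   empty, in which case the adjustment is a no-op).
#' @export
partition_region <- function(stats, ld, gene_start, gene_end,
                             window = 1e6) {
  stopifnot(inherits(stats, "sumstats"))
  if (is.null(stats$pos)) stop("summary statistics carry no positions")
  if (window <= 0) stop("'window' must be > 0")
  if (gene_end <= gene_start) stop("gene interval must satisfy start < end")
  validate_ld(ld)
  if (!identical(rownames(ld), stats$snp_ids)) {
    stop("SNP ids of LD matrix and summary statistics differ or are reordered")
  }
  pos <- stats$pos
  in_gene <- pos >= gene_start & pos < gene_end
  in_region <- pos >= gene_start - window & pos < gene_end + window & !in_gene
  if (!any(in_gene)) stop("no intragenic SNPs in [", gene_start, ", ", gene_end, ")")
  slice <- function(keep) {
    sumstats(stats$snp_ids[keep],
             pos = stats$pos[keep], z = stats$z[keep],
             beta = stats$beta[keep], se = stats$se[keep], n = stats$n)
  }
  gi <- which(in_gene)
  ri <- which(in_region)
  structure(list(
    gene = slice(in_gene),
    region = if (length(ri)) slice(in_region) else NULL,
    U_g = ld[gi, gi, drop = FALSE],
    U_r = ld[ri, ri, drop = FALSE],
    U_gr = ld[gi, ri, drop = FALSE],
    m_g = length(gi), m_r = length(ri),
    degenerate = length(ri) == 0L
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("Region partition: m_g = %d intragenic, m_r = %d extragenic SNPs%s\n",
              x$m_g, x$m_r, if (x$degenerate) " (degenerate: empty region)" else ""))
  invisible(x)
}

#' Repair an indefinite correlation matrix by eigenvalue clipping
#'
#' Reference LD matrices are frequently indefinite after regularization or
#' mismatched panels. Eigenvalues below `floor` are clipped to `floor` and
#' the matrix reassembled. The diagonal is deliberately NOT rescaled back
#' to 1: rescaling can reintroduce indefiniteness. The maximum diagonal
#' perturbation is reported via `message()` when non-negligible.
#'
#' @param U Symmetric numeric matrix.
#' @param floor Eigenvalue floor, `>= 0` (default 0).
#' @return The positive semidefinite repaired matrix (same dimnames).
#' @export
repair_psd <- function(U, floor = 0) {
  stopifnot(is.matrix(U), nrow(U) == ncol(U), floor >= 0)
  if (max(abs(U - t(U))) > 1e-8) stop("input must be symmetric")
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  if (all(e$values >= floor)) return(U)
  lam <- pmax(e$values, floor)
  if (all(e$values < floor) && floor == 0) {
    warning("all eigenvalues clipped: returning zero matrix")
  }
  V <- e$vectors
  R <- V %*% (lam * t(V))
  R <- (R + t(R)) / 2
  dperturb <- max(abs(diag(R) - diag(U)))
  if (dperturb > 1e-6) {
    message(sprintf("repair_psd: max diagonal perturbation %.3g", dperturb))
  }
  dimnames(R) <- dimnames(U)
  R
}

#' Truncated eigendecomposition of a PSD matrix
#'
#' Spectral decomposition retaining the smallest leading set of eigenpairs
#' whose eigenvalue sum reaches `frac` of the trace, additionally dropping
#' eigenvalues at or below `eps * lambda_max` (numerical null space). This
#' is the low-rank machinery behind the pseudo-inverse used by the tau
#' likelihood: inversion and log-determinants are restricted to the
#' retained eigen-subspace.
#'
#' @param U PSD symmetric matrix (run [repair_psd] first if in doubt).
#' @param frac Cumulative eigenvalue fraction to retain (default 0.999).
#' @param eps Relative eigenvalue floor (default 1e-8), applied as
#'   `eps * max(eigenvalue)`.
#' @return An object of class `"eigen_decomp"`: list with nonincreasing
#'   `values` and orthonormal `vectors` (retained columns only), the
#'   retained `rank`, and `total_trace` of the source matrix.
#' @export
truncated_eigen <- function(U, frac = 0.999, eps = 1e-8) {
  stopifnot(is.matrix(U), nrow(U) == ncol(U))
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  lam <- e$values
  tr <- sum(lam)
  if (max(lam) <= 0) stop("matrix has no positive eigenvalues")
  k_frac <- which(cumsum(lam) >= frac * tr)[1L]
  if (is.na(k_frac)) k_frac <- length(lam)
  k_eps <- sum(lam > eps * max(lam))
  rank <- max(1L, min(k_frac, k_eps))
  structure(list(values = lam[seq_len(rank)],
                 vectors = e$vectors[, seq_len(rank), drop = FALSE],
                 rank = rank,
                 total_trace = tr),
            class = "eigen_decomp")
}

#' @export
print.eigen_decomp <- function(x, ...) {
  cat(sprintf("Truncated eigendecomposition: rank %d, retained trace %.4g of %.4g\n",
              x$rank, sum(x$values), x$total_trace))
  invisible(x)
}
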