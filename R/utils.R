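## Internal numeric helpers shared across the pipeline stages.

#' @importFrom Matrix rowMeans rowSums colSums t
NULL

## Per-gene means and variances of a genes x cells sparse (or dense) matrix,
## computed without densifying: E[x^2] - E[x]^2 with the n/(n-1) correction.
.row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  v[v < 0] <- 0
  list(mean = as.numeric(mu), var = as.numeric(v))
}

.as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else m
}

## Vectorised two-sided Wilcoxon rank-sum test of each row of `x`
## (genes x cells, dense) between cells in `grp` (logical) and the rest.
## Normal approximation with tie correction and continuity correction,
## matching wilcox.test(exact = FALSE, correct = TRUE). Constant rows get
## p = 1. Returns a data.frame with the U statistic and two-sided p.
.rank_sum <- function(x, grp) {
  stopifnot(is.logical(grp), length(grp) == ncol(x))
  n1 <- sum(grp)
  n2 <- sum(!grp)
  N <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    r <- rank(v)
    U <- sum(r[grp]) - n1 * (n1 + 1) / 2
    ## variance under H0 with ties, via the rank second moment
    s2 <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    if (s2 <= 0) return(c(U, 1))
    z <- U - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(s2)
    c(U, 2 * stats::pnorm(-abs(z)))
  }, numeric(2)))
  data.frame(statistic = res[, 1], p_value = pmin(1, res[, 2]))
}

## Vectorised Spearman correlation of each row of `x` with `y`, with the
## t-approximation p-value. Constant rows (or constant y) give rho = 0, p = 1
## by convention.
.spearman_rows <- function(x, y) {
  n <- length(y)
  stopifnot(ncol(x) == n)
  ry <- rank(y)
  ry <- (ry - mean(ry))
  sy <- sqrt(sum(ry^2))
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    rv <- rank(v)
    rv <- rv - mean(rv)
    sv <- sqrt(sum(rv^2))
    if (sv == 0 || sy == 0) return(c(0, 1))
    rho <- sum(rv * ry) / (sv * sy)
    if (abs(rho) >= 1) return(c(rho, 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho, 2 * stats::pt(-abs(tt), df = n - 2))
  }, numeric(2)))
  data.frame(rho = res[, 1], p_value = res[, 2])
}

## log2 fold change on expm1-scale means with a pseudocount guarding
## against division by zero; an all-zero gene maps to exactly 0.
.log2_fc <- function(mean_in, mean_out, pseudo = 1e-9) {
  log2((mean_in + pseudo) / (mean_out + pseudo))
}

.check_genes_present <- function(genes, matrix_genes, what = "gene") {
  missing <- setdiff(genes, matrix_genes)
  if (length(missing)) {
    stop(sprintf("%s(s) not present in the matrix: %s", what,
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
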