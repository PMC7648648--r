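## Reader/writer for 10x Genomics Matrix Market triplet directories
## (matrix.mtx, features.tsv, barcodes.tsv; genes x cells orientation),
## plus the ground-truth TSV sidecar used by the simulator.

#' Write a count matrix as a 10x Matrix Market directory
#'
#' Writes `matrix.mtx` (genes x cells, 1-based coordinate integer format),
#' `features.tsv` (id, name, type) and `barcodes.tsv`; optionally gzipped.
#' If `truth` is given it is written as `truth.tsv` alongside.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param gzip write `.gz` files (Cell Ranger v3 dialect).
#' @param truth optional truth data.frame (see [simulate_counts()]).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir, gzip = FALSE, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  path <- function(f) file.path(dir, paste0(f, ext))
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "TsparseMatrix")
  con <- if (gzip) gzfile(path("matrix.mtx"), "w") else file(path("matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  ord <- order(m@j, m@i)
  writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                     as.integer(m@x[ord])), con)
  close(con)
  feats <- data.frame(id = rownames(m), name = rownames(m),
                      type = "Gene Expression")
  wtsv <- function(df, f, header = FALSE) {
    con <- if (gzip) gzfile(path(f), "w") else file(path(f), "w")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = header)
    close(con)
  }
  wtsv(feats, "features.tsv")
  wtsv(data.frame(colnames(m)), "barcodes.tsv")
  if (!is.null(truth)) wtsv(truth, "truth.tsv", header = TRUE)
  invisible(dir)
}

#' Read a 10x Matrix Market directory
#'
#' Accepts both the `features.tsv` (v3) and `genes.tsv` (v2) dialects, with
#' two or three columns, gzipped or plain. Returns a sparse genes x cells
#' matrix; if a `truth.tsv` sidecar is present it is attached.
#'
#' @param dir directory containing matrix/features/barcodes files.
#' @return A dgCMatrix; a `truth` data.frame is attached as an attribute
#'   when present.
#' @export
read_10x <- function(dir) {
  find <- function(names) {
    for (f in names) {
      for (ext in c("", ".gz")) {
        p <- file.path(dir, paste0(f, ext))
        if (file.exists(p)) return(p)
      }
    }
    NULL
  }
  mp <- find("matrix.mtx")
  fp <- find(c("features.tsv", "genes.tsv"))
  bp <- find("barcodes.tsv")
  if (is.null(mp) || is.null(fp) || is.null(bp)) {
    stop("not a 10x directory (need matrix.mtx, features.tsv/genes.tsv, barcodes.tsv): ", dir)
  }
  m <- methods::as(Matrix::readMM(mp), "CsparseMatrix")
  feats <- utils::read.table(fp, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  bars <- utils::read.table(bp, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m) || nrow(bars) != ncol(m)) {
    stop("feature/barcode counts do not match the matrix dimensions")
  }
  rownames(m) <- feats[[1]]
  colnames(m) <- bars[[1]]
  tp <- find("truth.tsv")
  if (!is.null(tp)) {
    attr(m, "truth") <- utils::read.table(tp, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE)
  }
  m
}
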