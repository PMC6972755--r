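#' Gene-by-cell count matrix container
#'
#' A light container for droplet single-cell digital gene expression (DGE)
#' data: a non-negative integer matrix of molecule counts with genes as rows
#' and cell barcodes as columns, plus a per-gene flag marking mitochondrial
#' genes (used by [qc_filter()]).
#'
#' @param counts numeric matrix of non-negative integer counts, genes x cells.
#'   Row and column names are used as gene/barcode identifiers when `genes`
#'   or `barcodes` are not given.
#' @param genes character vector of unique gene identifiers (one per row).
#' @param barcodes character vector of unique cell barcodes (one per column).
#' @param mito_prefix character vector of gene-name prefixes identifying
#'   mitochondrial genes (case-insensitive). Default `"MT-"` matches the
#'   human gene nomenclature (e.g. `MT-CO1`).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), `genes`, `barcodes` and `mito` (logical
#'   per-gene flag).
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(c("ACTB", "MT-CO1", "SCARA5"),
#'                             paste0("BC", 1:4)))
#' cm <- count_matrix(m)
#' cm$mito
count_matrix <- function(counts, genes = rownames(counts),
                         barcodes = colnames(counts),
                         mito_prefix = "MT-") {
  counts <- as.matrix(counts)
  if (is.null(genes) || is.null(barcodes)) {
    stop("`counts` needs gene row names and barcode column names ",
         "(or pass `genes`/`barcodes`)", call. = FALSE)
  }
  genes <- as.character(genes)
  barcodes <- as.character(barcodes)
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("gene identifiers must be unique",
                                 call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcode identifiers must be unique",
                                    call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, barcodes)
  mito <- rep(FALSE, length(genes))
  for (p in mito_prefix) {
    mito <- mito | startsWith(toupper(genes), toupper(p))
  }
  structure(list(counts = counts, genes = genes, barcodes = barcodes,
                 mito = mito),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%d mitochondrial genes)\n",
              length(x$genes), length(x$barcodes), sum(x$mito)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write Drop-seq-style dense DGE tables
#'
#' The dense digital-gene-expression text format has a `GENE` column followed
#' by one integer column per cell barcode, tab separated.
#'
#' @param path file path.
#' @param mito_prefix passed to [count_matrix()].
#' @return `read_dge()` returns a [count_matrix()]; `write_dge()` returns
#'   `path` invisibly.
#' @export
read_dge <- function(path, mito_prefix = "MT-") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "GENE") {
    stop("not a DGE table: first column must be named 'GENE'", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$GENE
  count_matrix(m, mito_prefix = mito_prefix)
}

#' @param cm a [count_matrix()].
#' @rdname read_dge
#' @export
write_dge <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(GENE = cm$genes, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write MatrixMarket triplet count matrices with sidecar files
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `genes.tsv` and
#' `barcodes.tsv` into `dir`; `read_counts_mtx()` reads them back.
#'
#' @param cm a [count_matrix()].
#' @param dir directory to hold the three files (created if missing).
#' @param mito_prefix passed to [count_matrix()] on read.
#' @return `read_counts_mtx()` returns a [count_matrix()];
#'   `write_counts_mtx()` returns `dir` invisibly.
#' @export
write_counts_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- Matrix::Matrix(cm$counts, sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(cm$genes, file.path(dir, "genes.tsv"))
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir, mito_prefix = "MT-") {
  sm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  m <- as.matrix(sm)
  dimnames(m) <- list(genes, barcodes)
  count_matrix(m, mito_prefix = mito_prefix)
}
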