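#' Construct a UMI count matrix
#'
#' Container for a sparse genes x cells matrix of unique molecular
#' identifier (UMI) counts, together with its gene and cell identifier
#' axes. All downstream stages of the pipeline consume this object.
#'
#' @param values A genes x cells matrix of non-negative integer counts
#'   (dense or any [Matrix::Matrix] sparse class; stored as `dgCMatrix`).
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param gene_symbols Character vector of gene symbols parallel to
#'   `gene_ids` (defaults to `gene_ids`). Mitochondrial genes are expected
#'   to carry the conventional `"MT-"` symbol prefix.
#' @param cell_barcodes Character vector of unique cell barcodes, one per
#'   column.
#'
#' @return A `count_matrix` object: a list with elements `values`
#'   (`dgCMatrix`, rownames = gene ids, colnames = barcodes), `gene_ids`,
#'   `gene_symbols` and `cell_barcodes`.
#' @export
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3), paste0("G", 1:3),
#'                   cell_barcodes = c("AAA", "CCC"))
#' dim(m)
count_matrix <- function(values, gene_ids, gene_symbols = gene_ids,
                         cell_barcodes) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (length(values@x) && (any(values@x < 0) ||
                           any(values@x != round(values@x)))) {
    stop("not a count matrix: entries must be non-negative integers",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  gene_symbols <- as.character(gene_symbols)
  cell_barcodes <- as.character(cell_barcodes)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")", call. = FALSE)
  if (length(gene_symbols) != length(gene_ids))
    stop("gene_symbols must be parallel to gene_ids", call. = FALSE)
  if (length(cell_barcodes) != ncol(values))
    stop("cell_barcodes length (", length(cell_barcodes),
         ") != number of columns (", ncol(values), ")", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(cell_barcodes))
    stop("cell_barcodes must be unique", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_barcodes)
  structure(
    list(values = values, gene_ids = gene_ids, gene_symbols = gene_symbols,
         cell_barcodes = cell_barcodes),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, ", length(x$values@x), " non-zero entries, total UMIs ",
      format(sum(x$values@x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Prefix cell barcodes with a sample identifier
#'
#' Barcodes are only unique within one 10x run; cohort assembly namespaces
#' them as `"<sample_id>:<barcode>"` so they are globally unique.
#'
#' @param matrix A [count_matrix].
#' @param sample_id Single string.
#' @return The matrix with namespaced barcodes.
#' @export
prefix_barcodes <- function(matrix, sample_id) {
  stopifnot(inherits(matrix, "count_matrix"), length(sample_id) == 1)
  bc <- paste0(sample_id, ":", matrix$cell_barcodes)
  count_matrix(matrix$values, matrix$gene_ids, matrix$gene_symbols, bc)
}

find_10x_file <- function(directory, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(directory, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}

#' Read a 10x-convention sparse count matrix
#'
#' Reads the Matrix Market triplet file plus features/barcodes TSVs that
#' the 10x Genomics toolchain emits (`matrix.mtx`, `features.tsv` or the
#' older `genes.tsv`, `barcodes.tsv`; `.gz` accepted transparently).
#' Orientation on disk is detected from the TSV line counts, so a
#' transposed (cells x genes) matrix is normalized to genes x cells.
#'
#' @param directory Path containing the three files.
#' @return A [count_matrix].
#' @export
read_10x_mtx <- function(directory) {
  if (!dir.exists(directory))
    stop("format error: directory not found: ", directory, call. = FALSE)
  mtx <- find_10x_file(directory, "matrix.mtx")
  feat <- find_10x_file(directory, c("features.tsv", "genes.tsv"))
  bc <- find_10x_file(directory, "barcodes.tsv")
  for (need in list(c(mtx, "matrix.mtx"), c(feat, "features.tsv"),
                    c(bc, "barcodes.tsv"))) {
    if (is.na(need[1]))
      stop("format error: missing file ", need[2], " in ", directory,
           call. = FALSE)
  }
  m <- Matrix::readMM(mtx)
  features <- utils::read.delim(feat, header = FALSE,
                                colClasses = "character")
  barcodes <- readLines(bc)
  nf <- nrow(features)
  nb <- length(barcodes)
  if (nrow(m) == nf && ncol(m) == nb) {
    # genes x cells, the 10x convention
  } else if (nrow(m) == nb && ncol(m) == nf) {
    m <- Matrix::t(m)
  } else {
    stop("corrupt matrix: header declares ", nrow(m), " x ", ncol(m),
         " but features.tsv has ", nf, " lines and barcodes.tsv has ",
         nb, call. = FALSE)
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  count_matrix(m, features[[1]], symbols, barcodes)
}

#' Write a count matrix in the 10x convention
#'
#' Emits `matrix.mtx` (Matrix Market coordinate integer, 1-based indices,
#' genes as rows), `features.tsv` (id, symbol, "Gene Expression") and
#' `barcodes.tsv`, all plain text, such that [read_10x_mtx()] inverts the
#' write exactly.
#'
#' @param matrix A [count_matrix].
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_10x_mtx <- function(matrix, directory) {
  if (!inherits(matrix, "count_matrix"))
    stop("not a count matrix", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  v <- matrix$values
  trip <- Matrix::summary(v)  # i, j, x with i = gene row, j = cell column
  con <- file(file.path(directory, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(v), ncol(v), nrow(trip))), con)
  if (nrow(trip))
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  utils::write.table(
    data.frame(matrix$gene_ids, matrix$gene_symbols, "Gene Expression"),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(matrix$cell_barcodes, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}
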