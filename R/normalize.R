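#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a log transform: for a cell
#' with total UMI count `T`, each count `x` maps to
#' `ln(1 + x * scale_factor / T)`. Cells with zero total map to all-zero
#' columns. The transform is monotone within each cell, so within-cell
#' rank order is preserved.
#'
#' @param matrix A [count_matrix] (or a sparse genes x cells `dgCMatrix`).
#' @param scale_factor Counts-per-cell target (default 10,000).
#' @return A sparse `dgCMatrix` of normalized expression, rownames = gene
#'   symbols (made unique if needed), colnames = barcodes.
#' @export
log_normalize <- function(matrix, scale_factor = 1e4) {
  if (inherits(matrix, "count_matrix")) {
    v <- matrix$values
    rn <- make.unique(matrix$gene_symbols)
  } else {
    v <- methods::as(matrix, "CsparseMatrix")
    rn <- rownames(v)
  }
  totals <- Matrix::colSums(v)
  out <- v
  if (length(out@x)) {
    # column index of each non-zero entry in a CsparseMatrix
    col_of <- rep.int(seq_len(ncol(out)), diff(out@p))
    denom <- totals[col_of]
    denom[denom == 0] <- 1
    out@x <- log1p(out@x * scale_factor / denom)
  }
  rownames(out) <- rn
  out
}

#' Select highly variable genes by variance-stabilized ranking
#'
#' Ranks genes by variance in excess of their mean-variance trend, the
#' "vst" approach: a loess trend of log10 variance on log10 mean is fit
#' over raw counts, each gene's counts are standardized by its fitted
#' standard deviation with values clipped at `sqrt(n_cells)`, and genes
#' are ranked by the variance of the clipped standardized counts.
#'
#' @param counts A [count_matrix] or sparse genes x cells matrix of raw
#'   counts (rownames used as gene names when a plain matrix).
#' @param n_hvg Number of genes to return (default 1000).
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of gene names (symbols), ranked by decreasing
#'   standardized variance; ties broken lexicographically. If fewer than
#'   `n_hvg` genes have positive variance, all such genes are returned
#'   with a warning.
#' @export
select_hvg <- function(counts, n_hvg = 1000, loess_span = 0.3) {
  if (inherits(counts, "count_matrix")) {
    v <- counts$values
    rn <- make.unique(counts$gene_symbols)
  } else {
    v <- methods::as(counts, "CsparseMatrix")
    rn <- rownames(v)
  }
  n_cells <- ncol(v)
  mu <- Matrix::rowSums(v) / n_cells
  ex2 <- Matrix::rowSums(v^2) / n_cells
  varg <- (ex2 - mu^2) * n_cells / (n_cells - 1)
  usable <- mu > 0 & varg > 0
  score <- numeric(nrow(v))
  if (sum(usable) >= 2) {
    lx <- log10(mu[usable])
    ly <- log10(varg[usable])
    # loess trend; falls back to a linear trend (or a flat one when the
    # means are degenerate) for very small or collapsed inputs
    fitted_ly <- NULL
    if (stats::sd(lx) > 1e-8 && sum(usable) >= 10) {
      fit <- tryCatch(suppressWarnings(
        stats::loess(ly ~ lx, span = loess_span, degree = 2)),
        error = function(e) NULL)
      if (!is.null(fit)) fitted_ly <- stats::fitted(fit)
      if (!is.null(fitted_ly) && !all(is.finite(fitted_ly)))
        fitted_ly <- NULL
    }
    if (is.null(fitted_ly)) {
      fitted_ly <- if (stats::sd(lx) > 1e-8) {
        stats::fitted(stats::lm(ly ~ lx))
      } else {
        rep(mean(ly), length(ly))
      }
    }
    sd_fit <- sqrt(10^fitted_ly)
    clip <- sqrt(n_cells)
    # Standardized-variance with clipping, computed sparsely: zeros of a
    # gene standardize to a shared value z0.
    vt <- Matrix::t(v[usable, , drop = FALSE])  # cells x genes, CSC by gene
    n_nz <- diff(vt@p)
    gene_of <- rep.int(seq_len(ncol(vt)), n_nz)
    z <- pmin((vt@x - mu[usable][gene_of]) / sd_fit[gene_of], clip)
    z0 <- pmax(pmin(-mu[usable] / sd_fit, clip), -clip)
    sum_z <- vapply(split(z, factor(gene_of, seq_len(ncol(vt)))), sum,
                    numeric(1)) + z0 * (n_cells - n_nz)
    sum_z2 <- vapply(split(z^2, factor(gene_of, seq_len(ncol(vt)))), sum,
                     numeric(1)) + z0^2 * (n_cells - n_nz)
    score[usable] <- (sum_z2 - sum_z^2 / n_cells) / (n_cells - 1)
    score[!is.finite(score)] <- 0
  }
  ord <- order(-score, rn)
  ranked <- rn[ord][score[ord] > 0]
  if (length(ranked) < n_hvg) {
    warning("only ", length(ranked), " genes with positive standardized ",
            "variance; returning all of them", call. = FALSE)
    return(ranked)
  }
  ranked[seq_len(n_hvg)]
}

#' Principal-component embedding of cells
#'
#' Scales each gene across cells to zero mean and unit variance with
#' values clipped at +/-10, then computes the leading principal
#' components of the cells x genes matrix. The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive, making
#' embeddings reproducible.
#'
#' @param normalized Normalized expression matrix (genes x cells),
#'   typically restricted to highly variable genes.
#' @param n_pcs Number of components to compute (default 50; reduced
#'   with a warning when exceeding the data rank bound).
#' @param clip Absolute cap on scaled expression values.
#' @return A numeric cells x `n_pcs` matrix of cell embeddings with
#'   attributes `sdev` (component standard deviations) and `rotation`
#'   (gene loadings).
#' @export
embed_pca <- function(normalized, n_pcs = 50, clip = 10) {
  x <- t(as.matrix(normalized))  # cells x genes
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- Inf  # constant genes carry no signal
  x <- sweep(sweep(x, 2, mu), 2, sd, "/")
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  max_rank <- min(dim(x))
  if (n_pcs > max_rank) {
    warning("n_pcs reduced from ", n_pcs, " to ", max_rank, call. = FALSE)
    n_pcs <- max_rank
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  emb <- pc$x
  rownames(emb) <- colnames(normalized)
  attr(emb, "sdev") <- pc$sdev[seq_len(n_pcs)]
  attr(emb, "rotation") <- pc$rotation
  emb
}
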