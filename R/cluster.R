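#' Clustering parameters
#'
#' Defaults mirror the standard single-cell toolchain settings used for
#' the cortical analysis this package implements: 1000 variable genes,
#' 50 computed / 20 used principal components, k = 20 nearest neighbors,
#' modularity resolution 1.
#'
#' @param n_hvg Highly variable genes to select.
#' @param n_pcs_computed,n_pcs_used Principal components computed and
#'   used for the neighbor graph (`used <= computed`).
#' @param knn_k Neighbors per cell (including self) for the SNN graph.
#' @param resolution Modularity resolution.
#' @param snn_prune Shared-neighbor Jaccard weights below this are
#'   dropped (default 1/15).
#' @param seed Integer seed for community detection.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(n_hvg = 1000, n_pcs_computed = 50,
                           n_pcs_used = 20, knn_k = 20, resolution = 1,
                           snn_prune = 1 / 15, seed = 0L) {
  stopifnot(n_pcs_used <= n_pcs_computed, resolution > 0, knn_k >= 2)
  structure(list(n_hvg = n_hvg, n_pcs_computed = n_pcs_computed,
                 n_pcs_used = n_pcs_used, knn_k = knn_k,
                 resolution = resolution, snn_prune = snn_prune,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

# Shared-nearest-neighbor graph: kNN by Euclidean distance (self
# included, as is conventional), edges weighted by the Jaccard overlap of
# neighbor sets, pruned below `prune`.
build_snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  n <- nrow(embedding)
  k <- min(k, n)
  nn <- RANN::nn2(embedding, k = k)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a Euclidean kNN graph on the given embedding, re-weights edges
#' by shared-neighbor Jaccard overlap, and partitions it by modularity
#' (Louvain) community detection at the given resolution. Labels are
#' renumbered `0..K-1` by decreasing cluster size and the procedure is
#' deterministic for a fixed seed.
#'
#' @param embedding Cells x dims numeric matrix (use the first
#'   `n_pcs_used` columns of [embed_pca()]).
#' @param knn_k,resolution,snn_prune,seed See [cluster_params()].
#' @return Integer vector of cluster labels (0-based), named by the
#'   embedding rownames.
#' @export
cluster_cells <- function(embedding, knn_k = 20, resolution = 1,
                          snn_prune = 1 / 15, seed = 0L) {
  n <- nrow(embedding)
  if (n < knn_k + 1) {
    warning("too few cells (", n, ") for k = ", knn_k,
            "; returning a single cluster", call. = FALSE)
    return(stats::setNames(integer(n), rownames(embedding)))
  }
  if (all(embedding == rep(embedding[1, ], each = n)))
    return(stats::setNames(integer(n), rownames(embedding)))
  g <- build_snn_graph(embedding, k = knn_k, prune = snn_prune)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  # decreasing size; ties by first appearance, for determinism
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  stats::setNames(unname(relabel[as.character(memb)]),
                  rownames(embedding))
}

#' One-vs-rest cluster markers by Wilcoxon rank-sum
#'
#' For each cluster, genes are pre-filtered at
#' `|log2FC| >= logfc_threshold` (cluster vs all other cells, on
#' de-logged normalized means) and the surviving genes tested with the
#' rank-sum test; p-values are adjusted within each cluster's tested set.
#'
#' @param normalized Normalized expression (genes x cells).
#' @param labels Cluster labels parallel to columns.
#' @param logfc_threshold Pre-filter on absolute log2 fold change
#'   (default 0.25).
#' @param max_adjusted_p Significance cutoff on adjusted p (default 0.1).
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @return A tibble: `gene`, `cluster`, `log2fc`, `raw_p`, `adjusted_p`,
#'   `pct_in`, `pct_out`, `significant`.
#' @export
find_markers <- function(normalized, labels, logfc_threshold = 0.25,
                         max_adjusted_p = 0.1,
                         adjust_method = c("bonferroni", "bh")) {
  adjust_method <- match.arg(adjust_method)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2)
    stop("find_markers needs >= 2 clusters", call. = FALSE)
  dense <- as.matrix(normalized)
  out <- purrr::map(lev, function(cl) {
    idx_in <- which(labels == cl)
    if (length(idx_in) < 2) {
      warning("cluster ", cl, " is a singleton; skipped", call. = FALSE)
      return(NULL)
    }
    idx_out <- which(labels != cl)
    tab <- de_two_groups(dense, idx_in, idx_out,
                         prefilter_log2fc = logfc_threshold,
                         adjust_method = adjust_method)
    if (!nrow(tab)) return(NULL)
    tab$cluster <- cl
    tab$pct_in <- unname(rowMeans(dense[tab$gene, idx_in,
                                        drop = FALSE] > 0))
    tab$pct_out <- unname(rowMeans(dense[tab$gene, idx_out,
                                         drop = FALSE] > 0))
    tab$significant <- tab$adjusted_p < max_adjusted_p
    tab
  })
  dplyr::bind_rows(out)[, c("gene", "cluster", "log2fc", "raw_p",
                            "adjusted_p", "pct_in", "pct_out",
                            "significant")]
}

#' Reference marker genes for cortical cell types
#'
#' The canonical single-marker reference used to annotate clusters:
#' astrocytes AQP4, endothelial cells CLDN5, excitatory neurons CAMK2A,
#' inhibitory neurons GAD1, microglia C3, oligodendrocytes MBP.
#'
#' @return Named list mapping type name to marker symbol vector.
#' @export
cell_type_reference <- function() {
  list(astrocyte = "AQP4", endothelial = "CLDN5",
       excitatory_neuron = "CAMK2A", inhibitory_neuron = "GAD1",
       microglia = "C3", oligodendrocyte = "MBP")
}

#' Assign cell types to clusters from reference markers
#'
#' Each cluster is scored per type as the mean, over the type's marker
#' genes, of the gene's cluster-mean expression z-scored across clusters;
#' the highest-scoring type is assigned. A cluster whose best score does
#' not exceed the runner-up by more than `margin` is labeled
#' `"unassigned"`.
#'
#' @param normalized Normalized expression (genes x cells, rownames =
#'   symbols).
#' @param labels Cluster labels parallel to columns.
#' @param reference Named list of marker symbol vectors
#'   ([cell_type_reference()] by default).
#' @param margin Required score gap over the runner-up (default 0: only
#'   exact ties are unassigned).
#' @return A tibble: `cluster`, `cell_type`, `score`, `runner_up_score`.
#' @export
assign_cell_types <- function(normalized, labels,
                              reference = cell_type_reference(),
                              margin = 0) {
  stopifnot(length(reference) >= 1)
  markers <- unique(unlist(reference))
  missing <- setdiff(markers, rownames(normalized))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  sub <- as.matrix(normalized[markers, , drop = FALSE])
  cl_mean <- vapply(lev, function(cl)
    rowMeans(sub[, labels == cl, drop = FALSE]), numeric(length(markers)))
  cl_mean <- matrix(cl_mean, nrow = length(markers),
                    dimnames = list(markers, lev))
  z <- t(apply(cl_mean, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  scores <- vapply(reference, function(genes)
    colMeans(z[genes, , drop = FALSE]), numeric(length(lev)))
  scores <- matrix(scores, nrow = length(lev),
                   dimnames = list(lev, names(reference)))
  purrr::map_dfr(lev, function(cl) {
    s <- sort(scores[cl, ], decreasing = TRUE)
    assigned <- if (length(s) > 1 && s[1] - s[2] <= margin) {
      "unassigned"
    } else {
      names(s)[1]
    }
    tibble::tibble(cluster = cl, cell_type = assigned,
                   score = unname(s[1]),
                   runner_up_score = if (length(s) > 1) unname(s[2])
                   else NA_real_)
  })
}
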