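#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end analysis, so a run
#' is fully described by a config plus a seed.
#'
#' @param qc A [qc_thresholds()].
#' @param cluster A [cluster_params()].
#' @param de A [de_thresholds()].
#' @param subpop A [subpop_params()].
#' @param concordance_alpha External replication level.
#' @param scale_factor Log-normalization scale factor.
#' @param seed Global seed, propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            cluster = cluster_params(),
                            de = de_thresholds(),
                            subpop = subpop_params(),
                            concordance_alpha = 0.05,
                            scale_factor = 1e4, seed = 0L) {
  cluster$seed <- as.integer(seed)
  subpop$seed <- as.integer(seed)
  structure(list(qc = qc, cluster = cluster, de = de, subpop = subpop,
                 concordance_alpha = concordance_alpha,
                 scale_factor = scale_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full case/control pipeline
#'
#' Stages, in order: per-sample quality control; pooling; normalization,
#' highly-variable-gene selection, PCA, SNN modularity clustering and
#' marker-based cell-type annotation; per-type case/control differential
#' expression; subpopulation analysis (re-clustering, enrichment
#' scoring, classification, proportion shifts); optionally cross-study
#' concordance against an external DE table. Identical inputs, config
#' and seed give identical outputs.
#'
#' @param matrices Named list of per-sample [count_matrix] objects, or a
#'   `cohort` from [generate_cohort()] (in which case `samples` is taken
#'   from it).
#' @param samples Sample metadata tibble (`sample_id`, `condition`, ...).
#' @param config A [pipeline_config()].
#' @param external_de Optional external DE tibble for concordance.
#' @param out_dir Optional directory; when given, per-stage artifacts
#'   (`qc_summary.csv`, `cell_table.csv`, `de_table.csv`,
#'   `subpop_report.csv`, `manifest.json`) are written there.
#' @return An `ns_pipeline` list: `qc_summary`, `cell_table` (per kept
#'   cell: ids, QC metrics, cluster, cell type, subpopulation), `de`
#'   ([run_celltype_de()]), `annotation`, `subpop`
#'   ([analyze_subpopulations()]), `concordance` (or `NULL`), `config`,
#'   `manifest`.
#' @export
run_all <- function(matrices, samples = NULL,
                    config = pipeline_config(), external_de = NULL,
                    out_dir = NULL) {
  if (inherits(matrices, "cohort")) {
    if (is.null(samples)) samples <- matrices$samples
    matrices <- matrices$matrices
  }
  stopifnot(!is.null(samples))
  validate_sample_metadata(samples)

  # --- qc ---------------------------------------------------------------
  masks <- list()
  qc_all <- list()
  for (sid in samples$sample_id) {
    qc <- compute_cell_qc(matrices[[sid]])
    masks[[sid]] <- apply_qc_filters(qc, config$qc)
    qc$sample_id <- sid
    qc_all[[sid]] <- qc[masks[[sid]], ]
  }
  qc_summary <- sample_qc_summary(matrices, samples, masks)
  kept <- purrr::imap(matrices, function(m, sid) {
    keep <- masks[[sid]]
    count_matrix(m$values[, keep, drop = FALSE], m$gene_ids,
                 m$gene_symbols, m$cell_barcodes[keep])
  })
  pooled <- bind_cohort(kept)
  message("qc: kept ", ncol(pooled$values), " of ",
          sum(qc_summary$n_cells), " nuclei across ",
          nrow(samples), " samples")

  # --- cluster + annotate ----------------------------------------------
  normalized <- log_normalize(pooled, config$scale_factor)
  colnames(normalized) <- pooled$cell_barcodes
  cp <- config$cluster
  hvg <- select_hvg(pooled, n_hvg = cp$n_hvg)
  emb <- embed_pca(normalized[hvg, , drop = FALSE],
                   n_pcs = cp$n_pcs_computed)
  labels <- cluster_cells(emb[, seq_len(min(cp$n_pcs_used, ncol(emb))),
                              drop = FALSE],
                          knn_k = cp$knn_k, resolution = cp$resolution,
                          snn_prune = cp$snn_prune, seed = cp$seed)
  annotation <- assign_cell_types(normalized, labels)
  message("cluster: ", length(unique(labels)), " clusters -> ",
          length(unique(annotation$cell_type)), " cell types")

  cell_table <- dplyr::bind_rows(qc_all)
  cell_table$cell_id <- paste0(cell_table$sample_id, ":",
                               cell_table$barcode)
  cell_table <- cell_table[match(pooled$cell_barcodes,
                                 cell_table$cell_id), ]
  cell_table$cluster <- unname(labels)
  cell_table <- dplyr::left_join(
    cell_table,
    dplyr::mutate(annotation[, c("cluster", "cell_type")],
                  cluster = as.integer(.data$cluster)),
    by = "cluster")
  cell_table <- dplyr::left_join(
    cell_table, samples[, c("sample_id", "condition")], by = "sample_id")
  cell_table <- cell_table[, c("cell_id", "barcode", "sample_id",
                               "condition", "n_genes_detected", "n_umi",
                               "mito_fraction", "cluster", "cell_type")]

  # --- de ---------------------------------------------------------------
  de <- run_celltype_de(normalized, cell_table, config$de)
  message("de: ", sum(de$significant), " significant DEGs across ",
          length(unique(de$cell_type)), " cell types")

  # --- subpop -----------------------------------------------------------
  subpop <- analyze_subpopulations(normalized, pooled, cell_table, de,
                                   samples, config$subpop)
  cell_table <- dplyr::left_join(
    cell_table, subpop$cell_labels[, c("cell_id", "subpop")],
    by = "cell_id")

  # --- concord ----------------------------------------------------------
  conc <- if (!is.null(external_de)) {
    concordance(de, external_de, config$concordance_alpha)
  }

  manifest <- list(
    package = "nucleoshift",
    version = as.character(utils::packageVersion("nucleoshift")),
    seed = config$seed, config_hash = rlang::hash(unclass(config)),
    n_samples = nrow(samples),
    n_cells_input = sum(qc_summary$n_cells),
    n_cells_kept = sum(qc_summary$n_kept),
    n_genes = nrow(pooled$values),
    n_clusters = length(unique(labels)),
    n_degs = sum(de$significant),
    n_subpops = nrow(subpop$report))

  result <- structure(
    list(qc_summary = qc_summary, cell_table = cell_table, de = de,
         annotation = annotation, subpop = subpop, concordance = conc,
         config = config, manifest = manifest),
    class = "ns_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(qc_summary, file.path(out_dir, "qc_summary.csv"))
    write_table(cell_table, file.path(out_dir, "cell_table.csv"))
    write_table(tidy(de), file.path(out_dir, "de_table.csv"))
    write_table(subpop$report, file.path(out_dir, "subpop_report.csv"))
    if (!is.null(conc))
      jsonlite::write_json(glance(conc),
                           file.path(out_dir, "concordance.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.ns_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<ns_pipeline> ", m$n_cells_kept, "/", m$n_cells_input,
      " nuclei kept, ", m$n_clusters, " clusters, ", m$n_degs,
      " DEGs, ", m$n_subpops, " subpopulations (seed ", m$seed, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.ns_pipeline <- function(x, ...) x$cell_table

#' @export
glance.ns_pipeline <- function(x, ...) {
  tibble::as_tibble(x$manifest[c("n_samples", "n_cells_input",
                                 "n_cells_kept", "n_clusters", "n_degs",
                                 "n_subpops", "seed", "config_hash")])
}

#' Plot per-cell quality-control metric distributions
#'
#' @param cell_table Tibble with `sample_id`, `n_genes_detected`,
#'   `n_umi`, `mito_fraction` (e.g. `tidy()` of a pipeline run, or
#'   [compute_cell_qc()] output with a `sample_id` column).
#' @return A ggplot of the three QC metric distributions per sample.
#' @export
plot_qc <- function(cell_table) {
  df <- tidyr::pivot_longer(
    cell_table[, c("sample_id", "n_genes_detected", "n_umi",
                   "mito_fraction")],
    cols = -"sample_id", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$value)) +
    ggplot2::geom_violin(scale = "width", fill = "steelblue",
                         alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
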