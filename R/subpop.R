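#' Subpopulation analysis parameters
#'
#' Per-type re-clustering resolutions (astrocytes 0.2, endothelial cells
#' 0.2, microglia 0.3, oligodendrocytes 0.2 — lower than the global
#' resolution because within-type structure is subtler) and the
#' enrichment-score threshold above which a subpopulation is designated
#' disease-associated. Excitatory and inhibitory neurons are excluded
#' from subcluster analysis by default.
#'
#' @param resolution_by_type Named numeric vector of modularity
#'   resolutions per cell type; types absent from it fall back to
#'   `default_resolution`.
#' @param default_resolution Fallback resolution.
#' @param enrichment_threshold Score above which (strictly) a
#'   subpopulation is classified as disease-associated (default 0.5).
#' @param n_hvg,n_pcs_used,knn_k,snn_prune Re-clustering controls, as
#'   [cluster_params()].
#' @param min_cells Floor below which a type is not re-clustered (one
#'   subpopulation, with a warning).
#' @param exclude_types Types skipped by [analyze_subpopulations()].
#' @param seed Integer seed.
#' @return A `subpop_params` list.
#' @export
subpop_params <- function(resolution_by_type = c(astrocyte = 0.2,
                                                 endothelial = 0.2,
                                                 microglia = 0.3,
                                                 oligodendrocyte = 0.2),
                          default_resolution = 0.2,
                          enrichment_threshold = 0.5, n_hvg = 1000,
                          n_pcs_used = 20, knn_k = 20, snn_prune = 1 / 15,
                          min_cells = 50,
                          exclude_types = c("excitatory_neuron",
                                            "inhibitory_neuron"),
                          seed = 0L) {
  stopifnot(all(resolution_by_type > 0), enrichment_threshold > 0)
  structure(list(resolution_by_type = resolution_by_type,
                 default_resolution = default_resolution,
                 enrichment_threshold = enrichment_threshold,
                 n_hvg = n_hvg, n_pcs_used = n_pcs_used, knn_k = knn_k,
                 snn_prune = snn_prune, min_cells = min_cells,
                 exclude_types = exclude_types, seed = as.integer(seed)),
            class = "subpop_params")
}

#' Re-cluster the cells of one type into subpopulations
#'
#' Repeats the clustering recipe (HVG selection on raw counts, scaling,
#' PCA, SNN graph, modularity communities) within one cell type at that
#' type's resolution. Labels are `"s1" .. "sK"` by decreasing size.
#'
#' @param normalized Normalized expression restricted to the type's
#'   cells (genes x cells).
#' @param counts Raw counts for the same cells (for HVG selection); a
#'   [count_matrix] or sparse matrix.
#' @param resolution Modularity resolution (default 0.2).
#' @param params A [subpop_params()] supplying the remaining controls.
#' @return Character vector of subpopulation labels, named by cell id.
#' @export
subcluster <- function(normalized, counts, resolution = 0.2,
                       params = subpop_params()) {
  n <- ncol(normalized)
  ids <- colnames(normalized)
  if (n < params$min_cells) {
    warning("only ", n, " cells (< ", params$min_cells,
            "); returning a single subpopulation", call. = FALSE)
    return(stats::setNames(rep("s1", n), ids))
  }
  hvg <- suppressWarnings(select_hvg(counts, n_hvg = params$n_hvg))
  emb <- embed_pca(normalized[hvg, , drop = FALSE],
                   n_pcs = min(50, length(hvg), n))
  use <- min(params$n_pcs_used, ncol(emb))
  lab <- cluster_cells(emb[, seq_len(use), drop = FALSE],
                       knn_k = params$knn_k, resolution = resolution,
                       snn_prune = params$snn_prune, seed = params$seed)
  stats::setNames(paste0("s", lab + 1L), ids)
}

#' Disease-DEG enrichment scores per subpopulation
#'
#' The classification statistic for disease-associated subpopulations:
#' every DEG's normalized expression is z-scored across *all* cells of
#' the type, and a subpopulation's score for a direction is the mean of
#' those z-values over its cells and over the direction's genes. Because
#' z-scores are centered over all cells of the type, the cell-count
#' weighted mean of any score over subpopulations is exactly 0, and
#' scores are comparable across subpopulations of different sizes. Genes
#' with zero variance contribute z = 0; genes absent from the matrix are
#' ignored.
#'
#' @param normalized Normalized expression of the type's cells.
#' @param labels Subpopulation labels parallel to columns.
#' @param up_genes,down_genes Character vectors of condition
#'   up-/down-regulated DEGs for this type (either may be empty; that
#'   direction's score is then `NA`).
#' @return A tibble: `subpop`, `n_cells`, `up_score`, `down_score`.
#' @export
enrichment_scores <- function(normalized, labels, up_genes,
                              down_genes = character()) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  score_set <- function(genes) {
    genes <- intersect(genes, rownames(normalized))
    if (!length(genes)) return(rep(NA_real_, length(lev)))
    sub <- as.matrix(normalized[genes, , drop = FALSE])
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    z <- (sub - mu) / ifelse(sd == 0, Inf, sd)  # zero-variance -> z = 0
    vapply(lev, function(l) mean(z[, labels == l, drop = FALSE]),
           numeric(1), USE.NAMES = FALSE)
  }
  tibble::tibble(subpop = lev,
                 n_cells = as.integer(table(factor(labels, lev))),
                 up_score = score_set(up_genes),
                 down_score = score_set(down_genes))
}

#' Classify subpopulations by enrichment score
#'
#' A subpopulation is `up_regulated` when its up-DEG score exceeds the
#' threshold, `down_regulated` when its down-DEG score does; when both
#' exceed it, the larger score wins and an exact tie is `ambiguous`;
#' otherwise `unaffected`.
#'
#' @param scores Tibble from [enrichment_scores()].
#' @param threshold Strict score threshold (default 0.5).
#' @return `scores` with a `classification` column.
#' @export
classify_subpops <- function(scores, threshold = 0.5) {
  up <- !is.na(scores$up_score) & scores$up_score > threshold
  down <- !is.na(scores$down_score) & scores$down_score > threshold
  cls <- rep("unaffected", nrow(scores))
  cls[up & !down] <- "up_regulated"
  cls[down & !up] <- "down_regulated"
  both <- up & down
  cls[both] <- dplyr::case_when(
    scores$up_score[both] > scores$down_score[both] ~ "up_regulated",
    scores$up_score[both] < scores$down_score[both] ~ "down_regulated",
    TRUE ~ "ambiguous")
  scores$classification <- cls
  scores
}

#' Transcriptomic signature of disease-associated subpopulations
#'
#' Differential expression of pooled up-regulated subpopulation cells
#' versus pooled down-regulated subpopulation cells, with the same
#' rank-sum test, fold-change definition and thresholds as the
#' case/control comparisons.
#'
#' @param normalized Normalized expression of the type's cells.
#' @param labels Subpopulation labels parallel to columns.
#' @param classifications Tibble from [classify_subpops()].
#' @param thresholds A [de_thresholds()].
#' @return A tibble: `gene`, `log2fc` (up- vs down-subpopulations),
#'   `raw_p`, `adjusted_p`, `direction`, `significant`.
#' @export
subpop_signatures <- function(normalized, labels, classifications,
                              thresholds = de_thresholds()) {
  labels <- as.character(labels)
  up_pops <- classifications$subpop[classifications$classification ==
                                      "up_regulated"]
  down_pops <- classifications$subpop[classifications$classification ==
                                        "down_regulated"]
  if (!length(up_pops) || !length(down_pops))
    stop("signature comparison undefined: need at least one up_regulated ",
         "and one down_regulated subpopulation", call. = FALSE)
  dense <- as.matrix(normalized)
  tab <- de_two_groups(dense, which(labels %in% up_pops),
                       which(labels %in% down_pops),
                       prefilter_log2fc = thresholds$prefilter_log2fc,
                       adjust_method = thresholds$adjust_method)
  tab$direction <- dplyr::case_when(tab$log2fc > 0 ~ "up",
                                    tab$log2fc < 0 ~ "down",
                                    TRUE ~ NA_character_)
  tab$significant <- tab$adjusted_p < thresholds$max_adjusted_p &
    abs(tab$log2fc) >= thresholds$min_abs_log2fc
  tab
}

#' Within-type subpopulation proportion shifts
#'
#' With the subject (sample) as the statistical unit: each sample's
#' within-type subpopulation proportions are computed, then summarised
#' per condition as mean +/- SEM. The shift is reported both in
#' percentage points (`delta_pp`, difference of condition means x 100)
#' and as relative change (`delta_relative`, difference over the control
#' mean) because "X% larger" can mean either.
#'
#' @param cell_table Tibble of the type's cells: `sample_id`, `subpop`.
#' @param samples Sample metadata (`sample_id`, `condition`).
#' @return A tibble, one row per subpopulation: cell counts and mean,
#'   SEM proportions per condition, `delta_pp`, `delta_relative`.
#'   Samples contributing no cells of the type are excluded with a
#'   warning.
#' @export
proportion_shift <- function(cell_table, samples) {
  absent <- setdiff(samples$sample_id, unique(cell_table$sample_id))
  if (length(absent))
    warning("sample(s) with zero cells of this type excluded: ",
            paste(absent, collapse = ", "), call. = FALSE)
  props <- dplyr::count(tibble::as_tibble(cell_table), .data$sample_id,
                        .data$subpop, name = "n_cells")
  props <- tidyr::complete(props, .data$sample_id, .data$subpop,
                           fill = list(n_cells = 0L))
  props <- dplyr::mutate(dplyr::group_by(props, .data$sample_id),
                         proportion = .data$n_cells / sum(.data$n_cells))
  props <- dplyr::inner_join(dplyr::ungroup(props),
                             samples[, c("sample_id", "condition")],
                             by = "sample_id")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- dplyr::summarise(
    dplyr::group_by(props, .data$subpop),
    n_cells_case = sum(.data$n_cells[.data$condition == "AD"]),
    n_cells_control = sum(.data$n_cells[.data$condition == "NC"]),
    mean_case = mean(.data$proportion[.data$condition == "AD"]),
    sem_case = sem(.data$proportion[.data$condition == "AD"]),
    mean_control = mean(.data$proportion[.data$condition == "NC"]),
    sem_control = sem(.data$proportion[.data$condition == "NC"]),
    .groups = "drop")
  dplyr::mutate(out,
                delta_pp = 100 * (.data$mean_case - .data$mean_control),
                delta_relative = (.data$mean_case - .data$mean_control) /
                  .data$mean_control)
}

#' Full subpopulation analysis across cell types
#'
#' For every analysed cell type: re-cluster its cells into
#' subpopulations, score each subpopulation for enrichment of the type's
#' condition up- and down-DEGs, classify disease-associated
#' subpopulations, and quantify per-sample proportion shifts. The
#' per-type DEG sets come from a [run_celltype_de()] result's
#' significant records.
#'
#' @param normalized Pooled normalized expression (genes x cells).
#' @param counts Pooled raw counts ([count_matrix] or sparse matrix)
#'   with the same columns.
#' @param cell_table Tibble: `cell_id`, `sample_id`, `condition`,
#'   `cell_type` (one row per matrix column).
#' @param de A [run_celltype_de()] result.
#' @param samples Sample metadata.
#' @param params A [subpop_params()].
#' @return A `subpop_analysis` object: `report` tibble (one row per
#'   subpopulation: scores, classification, proportion shift columns),
#'   `cell_labels` tibble (`cell_id`, `cell_type`, `subpop`),
#'   `signatures` (named list of [subpop_signatures()] tibbles for types
#'   having both an up- and a down-regulated subpopulation), `params`.
#' @export
analyze_subpopulations <- function(normalized, counts, cell_table, de,
                                   samples, params = subpop_params()) {
  cm <- if (inherits(counts, "count_matrix")) counts$values else counts
  rownames(cm) <- rownames(normalized)  # align on symbol axis
  types <- setdiff(sort(unique(cell_table$cell_type)),
                   params$exclude_types)
  sig <- de[de$significant, , drop = FALSE]
  reports <- list()
  labels_out <- list()
  signatures <- list()
  for (ct in types) {
    idx <- which(cell_table$cell_type == ct)
    if (!length(idx)) next
    norm_t <- normalized[, idx, drop = FALSE]
    res <- params$resolution_by_type[ct]
    if (is.na(res)) res <- params$default_resolution
    labs <- subcluster(norm_t, cm[, idx, drop = FALSE], resolution = res,
                       params = params)
    up <- sig$gene[sig$cell_type == ct & sig$direction == "up"]
    down <- sig$gene[sig$cell_type == ct & sig$direction == "down"]
    scores <- enrichment_scores(norm_t, labs, up, down)
    scores <- classify_subpops(scores, params$enrichment_threshold)
    shift <- proportion_shift(
      tibble::tibble(sample_id = cell_table$sample_id[idx], subpop = labs),
      samples)
    rep_t <- dplyr::left_join(scores, shift, by = "subpop")
    rep_t$cell_type <- ct
    reports[[ct]] <- rep_t
    labels_out[[ct]] <- tibble::tibble(
      cell_id = cell_table$cell_id[idx], cell_type = ct, subpop = labs)
    has_up <- any(scores$classification == "up_regulated")
    has_down <- any(scores$classification == "down_regulated")
    if (has_up && has_down)
      signatures[[ct]] <- subpop_signatures(norm_t, labs, scores)
  }
  report <- dplyr::bind_rows(reports)
  report <- report[, c("cell_type",
                       setdiff(names(report), "cell_type"))]
  structure(list(report = report,
                 cell_labels = dplyr::bind_rows(labels_out),
                 signatures = signatures, params = params),
            class = "subpop_analysis")
}

#' @export
print.subpop_analysis <- function(x, ...) {
  cat("<subpop_analysis> ", length(unique(x$report$cell_type)),
      " cell types, ", nrow(x$report), " subpopulations (",
      sum(x$report$classification != "unaffected"),
      " disease-associated)\n", sep = "")
  invisible(x)
}

#' @export
tidy.subpop_analysis <- function(x, ...) x$report

#' @export
glance.subpop_analysis <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$report, .data$cell_type),
    n_subpops = dplyr::n(),
    n_up_regulated = sum(.data$classification == "up_regulated"),
    n_down_regulated = sum(.data$classification == "down_regulated"),
    max_abs_delta_pp = max(abs(.data$delta_pp)),
    .groups = "drop")
}

#' Plot subpopulation proportions and classifications
#'
#' @param object A [analyze_subpopulations()] result.
#' @param ... Unused.
#' @return A ggplot: per-subpopulation mean within-type proportion by
#'   condition with SEM error bars, colored by classification, faceted
#'   by cell type.
#' @export
autoplot.subpop_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$report,
    cols = c("mean_case", "mean_control"),
    names_to = "condition", values_to = "mean_proportion")
  df$sem <- ifelse(df$condition == "mean_case", df$sem_case,
                   df$sem_control)
  df$condition <- ifelse(df$condition == "mean_case", "AD", "NC")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subpop,
                                   y = .data$mean_proportion,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_proportion - .data$sem,
                   ymax = .data$mean_proportion + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~cell_type, scales = "free_x") +
    ggplot2::labs(x = "subpopulation", y = "within-type proportion") +
    ggplot2::theme_minimal()
}
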