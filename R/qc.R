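#' Quality-control thresholds
#'
#' Nucleus-level filters excluding likely dead cells and debris. A
#' nucleus is removed when it has `<= min_genes` detected genes,
#' `>= max_umi` total UMIs, or a mitochondrial fraction `>= `
#' `max_mito_fraction` — the boundary value itself is always removed, so
#' the kept set satisfies the strict inequalities.
#'
#' @param min_genes Detected-gene floor (default 200; a cell with exactly
#'   200 genes is removed).
#' @param max_umi UMI ceiling (default 20,000; exactly 20,000 is removed).
#' @param max_mito_fraction Mitochondrial-fraction ceiling (default 0.20;
#'   exactly 0.20 is removed).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, max_umi = 20000,
                          max_mito_fraction = 0.20) {
  stopifnot(min_genes >= 0, max_umi > 0,
            max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes = min_genes, max_umi = max_umi,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' @param matrix A [count_matrix].
#' @param mito_genes Either `NULL` (default: genes whose symbol starts
#'   with `"MT-"`), a character vector of mitochondrial gene symbols, or
#'   a predicate function over symbols.
#' @return A tibble with one row per cell, in matrix column order:
#'   `barcode`, `n_genes_detected`, `n_umi`, `mito_fraction`
#'   (0 when `n_umi` is 0).
#' @export
compute_cell_qc <- function(matrix, mito_genes = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  v <- matrix$values
  is_mito <- if (is.null(mito_genes)) {
    startsWith(matrix$gene_symbols, "MT-")
  } else if (is.function(mito_genes)) {
    vapply(matrix$gene_symbols, mito_genes, logical(1), USE.NAMES = FALSE)
  } else {
    matrix$gene_symbols %in% mito_genes
  }
  n_umi <- Matrix::colSums(v)
  mito_umi <- if (any(is_mito)) {
    Matrix::colSums(v[is_mito, , drop = FALSE])
  } else {
    numeric(ncol(v))
  }
  tibble::tibble(
    barcode = matrix$cell_barcodes,
    n_genes_detected = as.integer(Matrix::colSums(v > 0)),
    n_umi = as.integer(n_umi),
    mito_fraction = ifelse(n_umi > 0, mito_umi / n_umi, 0))
}

#' Apply quality-control filters
#'
#' @param qc Tibble from [compute_cell_qc()].
#' @param thresholds A [qc_thresholds()].
#' @return Logical keep mask, `TRUE` for cells passing all three filters
#'   strictly.
#' @export
apply_qc_filters <- function(qc, thresholds = qc_thresholds()) {
  qc$n_genes_detected > thresholds$min_genes &
    qc$n_umi < thresholds$max_umi &
    qc$mito_fraction < thresholds$max_mito_fraction
}

#' Per-sample quality summary over kept cells
#'
#' @param matrices Named list of [count_matrix], one per sample.
#' @param samples Sample metadata tibble (`sample_id`, ...).
#' @param masks Named list of logical keep masks parallel to `matrices`.
#' @param mito_genes Passed to [compute_cell_qc()].
#' @return A tibble: `sample_id`, `n_cells`, `n_kept`,
#'   `mean_genes_per_nucleus`, `mean_umi_per_nucleus` (means over kept
#'   cells; `NA` with a warning when no cell survives).
#' @export
sample_qc_summary <- function(matrices, samples, masks, mito_genes = NULL) {
  stopifnot(identical(names(matrices), names(masks)))
  rows <- purrr::map(samples$sample_id, function(sid) {
    m <- matrices[[sid]]
    keep <- masks[[sid]]
    qc <- compute_cell_qc(m, mito_genes)
    if (!any(keep)) {
      warning("sample ", sid, ": no cells pass QC", call. = FALSE)
      return(tibble::tibble(sample_id = sid, n_cells = ncol(m$values),
                            n_kept = 0L,
                            mean_genes_per_nucleus = NA_real_,
                            mean_umi_per_nucleus = NA_real_))
    }
    tibble::tibble(
      sample_id = sid, n_cells = ncol(m$values), n_kept = sum(keep),
      mean_genes_per_nucleus = mean(qc$n_genes_detected[keep]),
      mean_umi_per_nucleus = mean(qc$n_umi[keep]))
  })
  dplyr::bind_rows(rows)
}

#' Postmortem-delay independence check
#'
#' Tests whether per-sample data quality (mean detected genes and mean
#' UMIs per nucleus) correlates with postmortem delay: Pearson r with a
#' two-sided t-test on n - 2 degrees of freedom. A non-significant result
#' supports treating sample quality as independent of postmortem
#' interval.
#'
#' @param summary Tibble from [sample_qc_summary()].
#' @param samples Sample metadata with `postmortem_delay_hours`.
#' @return A tibble with one row per metric: `metric`, `pearson_r`,
#'   `p_value`, `n`, `degenerate` (`TRUE` when a variable is constant, in
#'   which case r is reported as 0 and p as `NA`).
#' @export
pmd_independence <- function(summary, samples) {
  df <- dplyr::inner_join(summary, samples, by = "sample_id")
  df <- df[stats::complete.cases(
    df[, c("postmortem_delay_hours", "mean_genes_per_nucleus",
           "mean_umi_per_nucleus")]), ]
  if (nrow(df) < 3)
    stop("insufficient samples: need >= 3 with postmortem delay and QC ",
         "means, have ", nrow(df), call. = FALSE)
  one <- function(metric, y) {
    x <- df$postmortem_delay_hours
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(metric = metric, pearson_r = 0,
                            p_value = NA_real_, n = nrow(df),
                            degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(metric = metric, pearson_r = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(df), degenerate = FALSE)
  }
  dplyr::bind_rows(
    one("mean_genes_per_nucleus", df$mean_genes_per_nucleus),
    one("mean_umi_per_nucleus", df$mean_umi_per_nucleus))
}
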