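normalize_symbol <- function(x) toupper(trimws(x))

#' Match internal DE records to an external DE table
#'
#' Inner join on normalized gene symbol (uppercased, whitespace
#' stripped). Duplicate external rows for one gene are collapsed to the
#' median effect and smallest adjusted p, and flagged.
#'
#' @param internal A [run_celltype_de()] table (or tibble with `gene`,
#'   `log2fc`, optionally `cell_type`).
#' @param external Tibble with `gene`, `effect` (signed log-fold-change
#'   or t-statistic) and `adjusted_p`, as read by
#'   [read_table()]`(schema = "external_de")`.
#' @return A tibble of joined records with columns from `internal` plus
#'   `external_effect`, `external_adjusted_p`, `external_collapsed`.
#' @export
match_genes <- function(internal, external) {
  stopifnot(nrow(internal) > 0, nrow(external) > 0)
  ext <- tibble::as_tibble(external)
  ext$.gene_key <- normalize_symbol(ext$gene)
  dup <- anyDuplicated(ext$.gene_key) > 0
  ext <- dplyr::summarise(
    dplyr::group_by(ext, .data$.gene_key),
    external_effect = stats::median(.data$effect),
    external_adjusted_p = min(.data$adjusted_p),
    external_collapsed = dplyr::n() > 1, .groups = "drop")
  int <- if (inherits(internal, "celltype_de")) tidy(internal) else
    tibble::as_tibble(internal)
  int$.gene_key <- normalize_symbol(int$gene)
  joined <- dplyr::inner_join(int, ext, by = ".gene_key")
  joined$.gene_key <- NULL
  if (!nrow(joined)) stop("no common genes", call. = FALSE)
  if (dup)
    warning("duplicate external gene symbols collapsed to median effect",
            call. = FALSE)
  joined
}

#' Replicable DEGs in an external study
#'
#' Among matched genes, those whose external adjusted p is strictly
#' below `alpha`.
#'
#' @param joined Output of [match_genes()].
#' @param alpha External significance level (default 0.05, strict).
#' @return A list: `n` (count) and `records` (the qualifying rows).
#' @export
replicable_degs <- function(joined, alpha = 0.05) {
  stopifnot(nrow(joined) > 0)
  records <- joined[joined$external_adjusted_p < alpha, , drop = FALSE]
  list(n = nrow(records), records = records)
}

#' Direction concordance between two DE analyses
#'
#' Percentage of replicable genes whose internal log2 fold change and
#' external effect share a sign. Rows where either effect is exactly
#' zero are excluded (their count is reported). When internal records
#' carry cell types, a per-type breakdown is included.
#'
#' @param records Tibble from [replicable_degs()]`$records` (needs
#'   `log2fc` and `external_effect`).
#' @return A list: `percent_concordant` (0-100; `NA` with a warning when
#'   nothing remains after exclusions), `n_compared`, `n_concordant`,
#'   `n_zero_excluded`, `by_cell_type` tibble (when available).
#' @export
direction_concordance <- function(records) {
  zero <- records$log2fc == 0 | records$external_effect == 0
  kept <- records[!zero, , drop = FALSE]
  if (!nrow(kept)) {
    warning("no genes with nonzero effects in both studies",
            call. = FALSE)
    return(list(percent_concordant = NA_real_, n_compared = 0L,
                n_concordant = 0L, n_zero_excluded = sum(zero),
                by_cell_type = NULL))
  }
  agree <- sign(kept$log2fc) == sign(kept$external_effect)
  by_type <- NULL
  if ("cell_type" %in% names(kept)) {
    by_type <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(cell_type = kept$cell_type, agree),
                      .data$cell_type),
      n_compared = dplyr::n(),
      percent_concordant = 100 * mean(.data$agree), .groups = "drop")
  }
  list(percent_concordant = 100 * mean(agree),
       n_compared = nrow(kept), n_concordant = sum(agree),
       n_zero_excluded = sum(zero), by_cell_type = by_type)
}

#' Cross-study concordance summary
#'
#' Convenience wrapper: match genes, count replicable DEGs at `alpha`,
#' and compute direction concordance overall and per cell type.
#'
#' @inheritParams match_genes
#' @inheritParams replicable_degs
#' @return A `concordance` list: `n_matched`, `n_replicable`,
#'   `alpha`, plus the fields of [direction_concordance()].
#' @export
concordance <- function(internal, external, alpha = 0.05) {
  joined <- match_genes(internal, external)
  rep <- replicable_degs(joined, alpha)
  conc <- if (rep$n) direction_concordance(rep$records) else
    list(percent_concordant = NA_real_, n_compared = 0L,
         n_concordant = 0L, n_zero_excluded = 0L, by_cell_type = NULL)
  structure(c(list(n_matched = nrow(joined), n_replicable = rep$n,
                   alpha = alpha), conc),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance> ", x$n_matched, " matched genes, ", x$n_replicable,
      " replicable at external adjusted p < ", x$alpha, "; ",
      if (is.na(x$percent_concordant)) "concordance undefined" else
        sprintf("%.1f%% direction-concordant (%d/%d)",
                x$percent_concordant, x$n_concordant, x$n_compared),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(n_matched = x$n_matched, n_replicable = x$n_replicable,
                 alpha = x$alpha,
                 percent_concordant = x$percent_concordant,
                 n_compared = x$n_compared,
                 n_zero_excluded = x$n_zero_excluded)
}
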