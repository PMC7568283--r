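#' Differential-expression thresholds
#'
#' A gene is called differentially expressed when its adjusted p-value is
#' below `max_adjusted_p` and its absolute log2 fold change is at least
#' `min_abs_log2fc` (defaults 0.1 and 0.1, the significance rule used
#' throughout the per-type case/control comparisons).
#'
#' @param max_adjusted_p Adjusted-p ceiling (strict).
#' @param min_abs_log2fc Absolute log2FC floor (inclusive).
#' @param prefilter_log2fc Genes with `|log2FC|` below this are not
#'   tested at all (0 for condition DE; 0.25 for cluster markers).
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(max_adjusted_p = 0.1, min_abs_log2fc = 0.1,
                          prefilter_log2fc = 0,
                          adjust_method = c("bonferroni", "bh")) {
  stopifnot(max_adjusted_p > 0, min_abs_log2fc > 0)
  structure(list(max_adjusted_p = max_adjusted_p,
                 min_abs_log2fc = min_abs_log2fc,
                 prefilter_log2fc = prefilter_log2fc,
                 adjust_method = match.arg(adjust_method)),
            class = "de_thresholds")
}

# Tie-corrected normal approximation for the two-sided rank-sum test,
# given the ranks of the pooled sample. Returns U (Mann-Whitney statistic
# of x) and p; sigma == 0 flags a degenerate (all-identical) input.
rank_sum_normal <- function(rank_sum_x, n_x, n_y, tie_term) {
  n <- n_x + n_y
  u <- rank_sum_x - n_x * (n_x + 1) / 2
  mu <- n_x * n_y / 2
  sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, degenerate = TRUE))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))), degenerate = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test of `x` vs `y`. In `"exact"` mode
#' the p-value comes from the exact null distribution of the rank-sum
#' statistic (tie-free data only; falls back to the normal approximation
#' with a warning when ties are present). `"normal"` mode uses the
#' tie-corrected normal approximation with continuity correction.
#' `"auto"` picks exact when `length(x) + length(y) <= 16` and the pooled
#' data are tie-free.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list: `statistic` (U, the Mann-Whitney statistic of `x`),
#'   `p_value`, `method` used, and `degenerate` (`TRUE` when all pooled
#'   values are identical, in which case `p_value` is 1).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n_x <- length(x)
  n_y <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (mode == "auto") mode <- if (n_x + n_y <= 16 && !ties) "exact"
  else "normal"
  if (mode == "exact" && ties) {
    warning("exact mode requires tie-free data; using normal ",
            "approximation", call. = FALSE)
    mode <- "normal"
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(n_x)])
  u <- w - n_x * (n_x + 1) / 2
  if (mode == "exact") {
    p <- if (u > n_x * n_y / 2) {
      stats::pwilcox(u - 1, n_x, n_y, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n_x, n_y)
    }
    return(list(statistic = u, p_value = min(1, 2 * p), method = "exact",
                degenerate = FALSE))
  }
  tt <- table(r)
  res <- rank_sum_normal(w, n_x, n_y, sum(tt^3 - tt))
  list(statistic = res$u, p_value = res$p, method = "normal",
       degenerate = res$degenerate)
}

#' log2 fold change between two groups of normalized expression
#'
#' Computed on de-logged normalized means:
#' `log2((mean(exp(case) - 1) + eps) / (mean(exp(control) - 1) + eps))`,
#' positive when the case mean is higher.
#'
#' @param norm_case,norm_control Non-empty vectors of log-normalized
#'   expression.
#' @param eps Pseudocount guarding empty expression (default 1e-9).
#' @return A number; 0 when both groups are all-zero.
#' @export
log2_fold_change <- function(norm_case, norm_control, eps = 1e-9) {
  if (!length(norm_case) || !length(norm_control))
    stop("log2_fold_change: empty group", call. = FALSE)
  log2((mean(expm1(norm_case)) + eps) / (mean(expm1(norm_control)) + eps))
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector in `[0, 1]`.
#' @param method `"bonferroni"` (scale by m, cap at 1; the default) or
#'   `"bh"` (Benjamini-Hochberg step-up).
#' @return Adjusted p-values in the input order; elementwise `>= p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

# Vectorised two-group DE over the rows of a dense normalized matrix:
# log2FC prefilter, tie-corrected rank-sum per gene, adjustment within
# the tested set. Genes with no expression in either group are dropped.
de_two_groups <- function(dense, idx_case, idx_control,
                          prefilter_log2fc = 0,
                          adjust_method = "bonferroni", eps = 1e-9) {
  mean_case <- rowMeans(expm1(dense[, idx_case, drop = FALSE]))
  mean_control <- rowMeans(expm1(dense[, idx_control, drop = FALSE]))
  expressed <- mean_case > 0 | mean_control > 0
  lfc <- log2((mean_case + eps) / (mean_control + eps))
  testable <- expressed & abs(lfc) >= prefilter_log2fc
  genes <- rownames(dense)[testable]
  if (!length(genes)) {
    return(tibble::tibble(gene = character(), log2fc = numeric(),
                          raw_p = numeric(), adjusted_p = numeric()))
  }
  n_x <- length(idx_case)
  n_y <- length(idx_control)
  cols <- c(idx_case, idx_control)
  raw_p <- vapply(genes, function(g) {
    r <- rank(dense[g, cols])
    tt <- table(r)
    rank_sum_normal(sum(r[seq_len(n_x)]), n_x, n_y, sum(tt^3 - tt))$p
  }, numeric(1))
  tibble::tibble(gene = genes, log2fc = lfc[testable],
                 raw_p = unname(raw_p),
                 adjusted_p = adjust_pvalues(raw_p, adjust_method))
}

#' Per-cell-type case/control differential expression
#'
#' Within each annotated cell type, compares case (AD) and control (NC)
#' cells gene by gene with the tie-corrected Wilcoxon rank-sum test on
#' normalized expression, computes the case-vs-control log2 fold change
#' on de-logged means, adjusts p-values within the type's tested gene
#' set, and flags significance per [de_thresholds()]. Genes with no
#' expression in a type are untestable and absent from that type's rows.
#'
#' @param normalized Normalized expression (genes x cells, colnames =
#'   cell ids).
#' @param cell_table Tibble with one row per cell: `cell_id` (matching
#'   the matrix columns), `cell_type`, `condition` (`"AD"`/`"NC"`).
#' @param thresholds A [de_thresholds()].
#' @return A `celltype_de` tibble: `gene`, `cell_type`, `log2fc`,
#'   `raw_p`, `adjusted_p`, `direction`, `significant`. Types present in
#'   only one condition are skipped with a warning.
#' @export
run_celltype_de <- function(normalized, cell_table,
                            thresholds = de_thresholds()) {
  stopifnot(all(c("cell_id", "cell_type", "condition") %in%
                  names(cell_table)))
  cell_table <- cell_table[match(colnames(normalized),
                                 cell_table$cell_id), ]
  if (any(is.na(cell_table$cell_id)))
    stop("cell_table does not cover every matrix column", call. = FALSE)
  out <- purrr::map(sort(unique(cell_table$cell_type)), function(ct) {
    rows <- which(cell_table$cell_type == ct)
    cond <- cell_table$condition[rows]
    if (length(unique(cond)) < 2) {
      warning("cell type ", ct, " present in only one condition; skipped",
              call. = FALSE)
      return(NULL)
    }
    dense <- as.matrix(normalized[, rows, drop = FALSE])
    tab <- de_two_groups(dense, which(cond == "AD"), which(cond == "NC"),
                         prefilter_log2fc = thresholds$prefilter_log2fc,
                         adjust_method = thresholds$adjust_method)
    tab$cell_type <- ct
    tab
  })
  tab <- dplyr::bind_rows(out)
  if (!nrow(tab)) {
    tab <- tibble::tibble(gene = character(), log2fc = numeric(),
                          raw_p = numeric(), adjusted_p = numeric(),
                          cell_type = character())
  }
  tab$direction <- dplyr::case_when(tab$log2fc > 0 ~ "up",
                                    tab$log2fc < 0 ~ "down",
                                    TRUE ~ NA_character_)
  tab$significant <- tab$adjusted_p < thresholds$max_adjusted_p &
    abs(tab$log2fc) >= thresholds$min_abs_log2fc
  tab <- tab[, c("gene", "cell_type", "log2fc", "raw_p", "adjusted_p",
                 "direction", "significant")]
  attr(tab, "thresholds") <- thresholds
  class(tab) <- c("celltype_de", class(tab))
  tab
}

#' Cross-type overlap of differentially expressed genes
#'
#' Set algebra over each type's significant gene set: per-type up/down
#' counts, the genes significant in every type, and the genes exclusive
#' to a single type.
#'
#' @param de A [run_celltype_de()] table (or any tibble with `gene`,
#'   `cell_type`, `direction`, `significant`).
#' @return A `deg_overlap` list: `per_type` tibble (`cell_type`, `n_up`,
#'   `n_down`, `n_total`), `shared_all` (character vector of genes
#'   significant in all types), `exclusive` tibble (`gene`, `cell_type`).
#' @export
deg_overlap <- function(de) {
  sig <- de[de$significant, , drop = FALSE]
  types <- sort(unique(de$cell_type))
  if (length(types) < 2)
    stop("deg_overlap needs >= 2 cell types", call. = FALSE)
  per_type <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sig), .data$cell_type),
    n_up = sum(.data$direction == "up"),
    n_down = sum(.data$direction == "down"),
    n_total = dplyr::n(), .groups = "drop")
  per_type <- dplyr::left_join(tibble::tibble(cell_type = types), per_type,
                               by = "cell_type")
  per_type[is.na(per_type)] <- 0L
  sets <- split(sig$gene, factor(sig$cell_type, levels = types))
  shared <- Reduce(intersect, sets)
  counts <- table(unlist(lapply(sets, unique)))
  exclusive_genes <- names(counts)[counts == 1]
  exclusive <- dplyr::bind_rows(purrr::imap(sets, function(g, ct) {
    tibble::tibble(gene = intersect(unique(g), exclusive_genes),
                   cell_type = ct)
  }))
  structure(list(per_type = per_type, shared_all = sort(shared),
                 exclusive = dplyr::arrange(exclusive, .data$gene)),
            class = "deg_overlap")
}

#' @export
tidy.celltype_de <- function(x, ...) {
  out <- x
  attr(out, "thresholds") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @export
glance.celltype_de <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$cell_type),
    n_tested = dplyr::n(),
    n_significant = sum(.data$significant),
    n_up = sum(.data$significant & .data$direction == "up"),
    n_down = sum(.data$significant & .data$direction == "down"),
    .groups = "drop")
}

#' Volcano plot of per-type differential expression
#'
#' @param object A [run_celltype_de()] result.
#' @param ... Unused.
#' @return A ggplot: log2FC vs -log10 adjusted p, faceted by cell type,
#'   significant genes highlighted.
#' @export
autoplot.celltype_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$adjusted_p,
                                                   1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}
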