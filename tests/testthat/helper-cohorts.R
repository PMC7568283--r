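# Shared helpers: an independent adjusted-Rand-index oracle and small
# cohort builders used across test files.

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  sum_ij <- sum(choose(tab, 2))
  expected <- sum_i * sum_j / choose(n, 2)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# A small three-subpopulation compartment config for one cell type, with
# a strong condition-independent program in each subpopulation.
separable_subpop_config <- function(seed, case_shares = c(0.5, 0.3, 0.2),
                                    baseline_shares = c(0.5, 0.3, 0.2),
                                    cells_per_sample = 400,
                                    n_case = 2, n_control = 2) {
  cohort_config(
    n_samples_case = n_case, n_samples_control = n_control,
    cells_per_sample = cells_per_sample, n_genes = 2000,
    subpops = tibble::tibble(
      cell_type = "oligodendrocyte", name = c("o1", "o2", "o3"),
      baseline_share_within_type = baseline_shares,
      case_share_within_type = case_shares,
      marker_genes = 25L, marker_log2fc = 3, marker_base_mean = 1),
    seed = seed)
}

# Normalized matrix + truth for the non-debris cells of one type.
type_compartment <- function(cohort, type) {
  pooled <- bind_cohort(cohort$matrices)
  norm <- log_normalize(pooled)
  counts <- pooled$values
  rownames(counts) <- rownames(norm)
  truth <- cohort$truth$cells
  idx <- which(truth$cell_type == type & !truth$is_debris)
  list(norm = norm[, idx, drop = FALSE],
       counts = counts[, idx, drop = FALSE],
       truth = truth[idx, ])
}
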