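test_that("config validation rejects infeasible designs", {
  expect_error(cohort_config(cell_types = tibble::tibble(
    name = c("a", "b"), baseline_proportion = c(0.6, 0.6),
    marker_genes = 0L, marker_log2fc = 0)), "sum to 1")
  expect_error(cohort_config(
    subpops = tibble::tibble(cell_type = "astrocyte", name = c("x", "y"),
                             baseline_share_within_type = c(0.5, 0.5),
                             case_share_within_type = c(0.8, 0.1))),
    "sum to 1")
  expect_error(cohort_config(
    n_genes = 100,
    planted_degs = tibble::tibble(cell_type = "astrocyte", subpop = "all",
                                  gene_count = 500L, log2fc = 1)),
    "infeasible")
  expect_error(cohort_config(
    planted_degs = tibble::tibble(cell_type = "nonexistent",
                                  subpop = "all", gene_count = 5L,
                                  log2fc = 1)), "unknown cell types")
})

test_that("generation is bit-reproducible and truth is complete", {
  cfg <- cohort_config(n_samples_case = 2, n_samples_control = 2,
                       cells_per_sample = 150, n_genes = 400, seed = 41)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  for (sid in names(c1$matrices))
    expect_identical(as.matrix(c1$matrices[[sid]]$values),
                     as.matrix(c2$matrices[[sid]]$values))
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$truth$cells, c2$truth$cells)
  # every cell and gene appears exactly once in truth
  expect_equal(nrow(c1$truth$cells), 4 * 150)
  expect_false(anyDuplicated(c1$truth$cells$cell_id) > 0)
  expect_equal(nrow(c1$truth$genes), 400)
  expect_false(anyDuplicated(c1$truth$genes$gene_id) > 0)
  # metadata honours the Braak selection rule
  expect_silent(validate_sample_metadata(c1$samples))
})

test_that("debris counts are forced by construction", {
  cfg <- cohort_config(n_samples_case = 1, n_samples_control = 1,
                       cells_per_sample = 1000, n_genes = 2000,
                       debris_fraction = 0.1, seed = 42)
  coh <- generate_cohort(cfg)
  per_sample <- table(coh$truth$cells$sample_id,
                      coh$truth$cells$is_debris)[, "TRUE"]
  expect_true(all(per_sample == 100))  # round(0.1 x 1000)
  # low-UMI debris fall far below the detected-gene floor
  tr <- coh$truth$cells
  qc <- dplyr::bind_rows(purrr::imap(coh$matrices, function(m, sid) {
    q <- compute_cell_qc(m)
    q$cell_id <- paste0(sid, ":", q$barcode)
    q
  }))
  qc <- qc[match(tr$cell_id, qc$cell_id), ]
  expect_true(all(qc$n_genes_detected[tr$debris_kind == "low_umi"] < 200))
  expect_true(all(qc$mito_fraction[tr$debris_kind == "high_mito"] > 0.2))
  # mito genes carry the MT- prefix
  g <- coh$truth$genes
  expect_true(all(startsWith(g$symbol[g$role == "mito"], "MT-")))
})

test_that("a planted log2FC of 1 doubles the mean count empirically", {
  cfg <- cohort_config(
    n_samples_case = 1, n_samples_control = 1, cells_per_sample = 5500,
    n_genes = 400,
    cell_types = tibble::tibble(name = "astrocyte",
                                baseline_proportion = 1,
                                marker_genes = 0L, marker_log2fc = 0),
    planted_degs = tibble::tibble(cell_type = "astrocyte", subpop = "all",
                                  gene_count = 20L, log2fc = 1),
    debris_fraction = 0, seed = 43)
  coh <- generate_cohort(cfg)
  g <- coh$truth$genes
  planted <- which(!is.na(g$deg_cell_type))
  case_m <- coh$matrices[[which(coh$samples$condition == "AD")]]
  ctrl_m <- coh$matrices[[which(coh$samples$condition == "NC")]]
  ratio <- mean(as.matrix(case_m$values[planted, ])) /
    mean(as.matrix(ctrl_m$values[planted, ]))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("the null cohort carries no condition effects", {
  cfg <- separable_subpop_config(seed = 44, case_shares = c(0.2, 0.3, 0.5),
                                 baseline_shares = c(0.5, 0.3, 0.2),
                                 cells_per_sample = 100)
  cfg$planted_degs <- tibble::tibble(cell_type = "oligodendrocyte",
                                     subpop = "all", gene_count = 10L,
                                     log2fc = 2)
  nc <- null_cohort(cfg)
  expect_equal(sum(!is.na(nc$truth$genes$deg_cell_type)), 0)
  expect_identical(nc$config$subpops$case_share_within_type,
                   nc$config$subpops$baseline_share_within_type)
  expect_true(all(nc$truth$subpop_shifts$delta_pp == 0))
})

test_that("library sizes track the configured lognormal scale", {
  cfg <- cohort_config(n_samples_case = 1, n_samples_control = 1,
                       cells_per_sample = 2000, n_genes = 500,
                       libsize_lognormal_sigma = 0.5,
                       debris_fraction = 0, seed = 45)
  coh <- generate_cohort(cfg)
  totals <- Matrix::colSums(coh$matrices[[1]]$values)
  # sd(log totals) should approximate sigma (NB noise adds a little)
  expect_gt(stats::sd(log(totals)), 0.4)
  expect_lt(stats::sd(log(totals)), 0.65)
})
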