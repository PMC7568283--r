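test_that("exact p-values equal the textbook small cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # 2 x 1/20
  expect_identical(res$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 5, 9), c(9, 5, 1), mode = "normal")
  expect_equal(same$p_value, 1)
})

test_that("degenerate all-identical input is flagged with p = 1", {
  res <- wilcoxon_rank_sum(rep(2, 5), rep(2, 7))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("exact mode falls back with a warning under ties", {
  expect_warning(res <- wilcoxon_rank_sum(c(1, 2, 2), c(3, 4, 5),
                                          mode = "exact"),
                 "tie-free")
  expect_identical(res$method, "normal")
})

test_that("normal mode reproduces the reference implementation", {
  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:5, 40, replace = TRUE)   # heavy ties
    y <- sample(0:6, 55, replace = TRUE)
    ours <- wilcoxon_rank_sum(x, y, mode = "normal")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("fold changes follow the de-logged-mean definition", {
  # case mean (de-logged) exactly twice control
  ctrl <- log1p(c(1, 3))
  case <- log1p(c(2, 6))
  expect_equal(log2_fold_change(case, ctrl), 1, tolerance = 1e-6)
  expect_equal(log2_fold_change(ctrl, ctrl), 0)
  expect_equal(log2_fold_change(c(0, 0), c(0, 0)), 0)  # eps/eps
  expect_error(log2_fold_change(numeric(), ctrl), "empty")
})

test_that("p-value adjustment matches hand-computed cases", {
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1.0))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  set.seed(12)
  p <- runif(200)
  for (m in c("bonferroni", "bh"))
    expect_true(all(adjust_pvalues(p, m) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-type DE recovers a planted effect with correct direction", {
  set.seed(13)
  n <- 200
  counts <- matrix(rpois(50 * n, 1), 50, n)
  cond <- rep(c("AD", "NC"), each = n / 2)
  counts[1, cond == "AD"] <- rpois(n / 2, 4)    # planted up in case
  counts[50, ] <- 0                              # untestable gene
  rownames(counts) <- sprintf("g%02d", 1:50)
  colnames(counts) <- sprintf("c%03d", 1:n)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  ct <- tibble::tibble(cell_id = colnames(counts), cell_type = "astrocyte",
                       condition = cond)
  de <- run_celltype_de(norm, ct)
  hit <- de[de$gene == "g01", ]
  expect_true(hit$significant)
  expect_identical(hit$direction, "up")
  expect_false("g50" %in% de$gene)
  # direction anti-symmetry: swapping conditions negates log2fc exactly
  ct_swap <- ct
  ct_swap$condition <- ifelse(cond == "AD", "NC", "AD")
  de_swap <- run_celltype_de(norm, ct_swap)
  m <- match(de$gene, de_swap$gene)
  expect_equal(de_swap$log2fc[m], -de$log2fc, tolerance = 1e-9)
  expect_equal(de_swap$raw_p[m], de$raw_p, tolerance = 1e-12)
})

test_that("DE output is invariant to cell and gene order", {
  set.seed(14)
  counts <- matrix(rpois(40 * 120, 2), 40, 120)
  rownames(counts) <- sprintf("g%02d", 1:40)
  colnames(counts) <- sprintf("c%03d", 1:120)
  cond <- rep(c("AD", "NC"), 60)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  ct <- tibble::tibble(cell_id = colnames(counts), cell_type = "t",
                       condition = cond)
  de1 <- run_celltype_de(norm, ct)
  perm <- sample(120)
  de2 <- run_celltype_de(norm[sample(40), perm], ct[perm, ])
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-12)
  expect_equal(de1$raw_p, de2$raw_p, tolerance = 1e-12)
  expect_identical(de1$significant, de2$significant)
})

test_that("types lacking a condition are skipped with a warning", {
  counts <- matrix(rpois(20 * 30, 2), 20, 30)
  rownames(counts) <- paste0("g", 1:20)
  colnames(counts) <- paste0("c", 1:30)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  ct <- tibble::tibble(cell_id = colnames(counts),
                       cell_type = rep(c("a", "b"), c(20, 10)),
                       condition = c(rep(c("AD", "NC"), 10),
                                     rep("AD", 10)))
  expect_warning(de <- run_celltype_de(norm, ct), "only one condition")
  expect_identical(unique(de$cell_type), "a")
})

test_that("DEG overlap performs the toy set algebra", {
  de <- tibble::tibble(
    gene = c("A", "B", "B", "C", "B"),
    cell_type = c("t1", "t1", "t2", "t2", "t3"),
    log2fc = 1, raw_p = 0.001, adjusted_p = 0.001,
    direction = "up", significant = TRUE)
  ov <- deg_overlap(de)
  expect_identical(ov$shared_all, "B")
  expect_identical(ov$exclusive$gene, c("A", "C"))
  expect_identical(ov$exclusive$cell_type, c("t1", "t2"))
  expect_equal(ov$per_type$n_total, c(2L, 2L, 1L))
  # identical sets: full intersection, no exclusives
  de2 <- de[de$gene == "B", ]
  ov2 <- deg_overlap(de2)
  expect_identical(ov2$shared_all, "B")
  expect_equal(nrow(ov2$exclusive), 0)
})

test_that("tidy and glance summarise DE results", {
  de <- tibble::tibble(gene = c("A", "B"), cell_type = "t1",
                       log2fc = c(1, -2), raw_p = c(0.001, 0.2),
                       adjusted_p = c(0.002, 0.4),
                       direction = c("up", "down"),
                       significant = c(TRUE, FALSE))
  class(de) <- c("celltype_de", class(de))
  g <- glance(de)
  expect_equal(g$n_significant, 1L)
  expect_equal(g$n_up, 1L)
  expect_s3_class(tidy(de), "tbl_df")
  expect_false(inherits(tidy(de), "celltype_de"))
})
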