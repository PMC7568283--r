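test_that("enrichment scores obey the centering identity and symmetry", {
  set.seed(21)
  counts <- matrix(rpois(30 * 100, 2), 30, 100)
  rownames(counts) <- sprintf("g%02d", 1:30)
  colnames(counts) <- sprintf("c%03d", 1:100)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  # single subpopulation: score is exactly the grand z mean, i.e. 0
  sc_one <- enrichment_scores(norm, rep("s1", 100), paste0("g0", 1:5))
  expect_equal(sc_one$up_score, 0, tolerance = 1e-12)
  # balanced two-group split: scores are equal and opposite
  labels <- rep(c("A", "B"), 50)
  sc <- enrichment_scores(norm, labels, sprintf("g%02d", 1:10),
                          sprintf("g%02d", 11:20))
  expect_equal(sc$up_score[1], -sc$up_score[2], tolerance = 1e-10)
  # cell-count-weighted mean over subpops is 0 for any split
  labels3 <- rep(c("A", "B", "C"), c(50, 30, 20))
  sc3 <- enrichment_scores(norm, labels3, sprintf("g%02d", 1:10))
  expect_equal(sum(sc3$up_score * sc3$n_cells) / sum(sc3$n_cells), 0,
               tolerance = 1e-9)
})

test_that("a subpopulation expressing a program scores near +1 vs -1", {
  # one gene, two equal subpops, two-point expression: z approaches +/-1
  n <- 400
  counts <- matrix(0L, 3, n)
  counts[1, 1:(n / 2)] <- 5L            # program gene, on in A
  counts[2, (n / 2 + 1):n] <- 5L        # balances library sizes
  counts[3, ] <- 3L                     # constant given equal totals
  rownames(counts) <- c("sig", "bal", "other")
  colnames(counts) <- paste0("c", 1:n)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  labels <- rep(c("A", "B"), c(n / 2, n / 2))
  sc <- enrichment_scores(norm, labels, "sig")
  expect_equal(sc$up_score[sc$subpop == "A"], 1, tolerance = 0.01)
  expect_equal(sc$up_score[sc$subpop == "B"], -1, tolerance = 0.01)
  # zero-variance genes contribute z = 0; empty sets give NA
  sc2 <- enrichment_scores(norm, labels, "other")
  expect_equal(sc2$up_score, c(0, 0))
  expect_true(all(is.na(sc2$down_score)))
})

test_that("classification follows the threshold and tie rules", {
  sc <- tibble::tibble(
    subpop = paste0("s", 1:4), n_cells = 10L,
    up_score = c(0.6, 0.4, 0.7, 0.2),
    down_score = c(0.1, 0.4, 0.7, 0.8))
  cls <- classify_subpops(sc, threshold = 0.5)
  expect_identical(cls$classification,
                   c("up_regulated", "unaffected", "ambiguous",
                     "down_regulated"))
  # monotone in threshold: raising it never adds an associated subpop
  for (th in c(0.1, 0.3, 0.65, 0.75)) {
    lo <- classify_subpops(sc, th)$classification != "unaffected"
    hi <- classify_subpops(sc, th + 0.05)$classification != "unaffected"
    expect_true(all(lo | !hi))
  }
})

test_that("planted subpopulations are re-discovered with their shifts", {
  cfg <- separable_subpop_config(seed = 31,
                                 baseline_shares = c(0.5, 0.3, 0.2),
                                 case_shares = c(0.3, 0.5, 0.2),
                                 n_case = 4, n_control = 4)
  coh <- generate_cohort(cfg)
  comp <- type_compartment(coh, "oligodendrocyte")
  labs <- subcluster(comp$norm, comp$counts, resolution = 0.2)
  expect_gte(adjusted_rand_index(labs, comp$truth$subpop), 0.9)
  # deterministic re-run
  labs2 <- subcluster(comp$norm, comp$counts, resolution = 0.2)
  expect_identical(labs, labs2)
  ps <- proportion_shift(
    tibble::tibble(sample_id = comp$truth$sample_id, subpop = labs),
    coh$samples)
  # identify the recovered subpop matching truth o1 by majority vote
  map <- vapply(split(comp$truth$subpop, labs),
                function(x) names(sort(-table(x)))[1], character(1))
  s_o1 <- names(map)[map == "o1"]
  expect_length(s_o1, 1)
  expect_lt(abs(ps$delta_pp[ps$subpop == s_o1] - (-20)), 7)
})

test_that("sub-compartment floor yields a single subpopulation", {
  counts <- matrix(rpois(20 * 30, 2), 20, 30)
  rownames(counts) <- paste0("g", 1:20)
  colnames(counts) <- paste0("c", 1:30)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  expect_warning(labs <- subcluster(norm, counts, resolution = 0.2),
                 "single subpopulation")
  expect_identical(unique(unname(labs)), "s1")
})

test_that("proportion shifts match hand arithmetic, SEM included", {
  cells <- tibble::tibble(
    sample_id = c(rep("A1", 40), rep("A2", 60), rep("N1", 10),
                  rep("N2", 30), rep("A1", 60), rep("A2", 40),
                  rep("N1", 90), rep("N2", 70)),
    subpop = rep(c("s1", "s2"), c(140, 260)))
  samples <- tibble::tibble(sample_id = c("A1", "A2", "N1", "N2"),
                            condition = c("AD", "AD", "NC", "NC"))
  ps <- proportion_shift(cells, samples)
  s1 <- ps[ps$subpop == "s1", ]
  expect_equal(s1$mean_case, 0.5)     # (0.4 + 0.6) / 2
  expect_equal(s1$mean_control, 0.2)  # (0.1 + 0.3) / 2
  expect_equal(s1$delta_pp, 30)
  expect_equal(s1$delta_relative, 1.5)
  expect_equal(s1$sem_case, 0.1)      # sd(0.4, 0.6) / sqrt(2)
  # proportions sum to 1 per sample -> deltas of s2 mirror s1
  s2 <- ps[ps$subpop == "s2", ]
  expect_equal(s2$delta_pp, -30)
  # a sample without cells of the type is excluded with a warning
  samples3 <- dplyr::bind_rows(samples,
                               tibble::tibble(sample_id = "N3",
                                              condition = "NC"))
  expect_warning(proportion_shift(cells, samples3), "N3")
})

test_that("signatures compare up- vs down-subpopulations antisymmetrically", {
  set.seed(22)
  n <- 120
  counts <- matrix(rpois(30 * n, 2), 30, n)
  counts[5, 1:(n / 2)] <- rpois(n / 2, 8)  # planted in the up side
  rownames(counts) <- sprintf("g%02d", 1:30)
  colnames(counts) <- paste0("c", 1:n)
  norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
  labels <- rep(c("s1", "s2"), each = n / 2)
  cls <- tibble::tibble(subpop = c("s1", "s2"),
                        classification = c("up_regulated",
                                           "down_regulated"))
  sig <- subpop_signatures(norm, labels, cls)
  hit <- sig[sig$gene == "g05", ]
  expect_true(hit$significant)
  expect_identical(hit$direction, "up")
  # swapping classifications negates every log2fc
  cls_swap <- tibble::tibble(subpop = c("s1", "s2"),
                             classification = c("down_regulated",
                                                "up_regulated"))
  sig_swap <- subpop_signatures(norm, labels, cls_swap)
  m <- match(sig$gene, sig_swap$gene)
  expect_equal(sig_swap$log2fc[m], -sig$log2fc, tolerance = 1e-9)
  # one side empty is an explicit error
  cls_up <- tibble::tibble(subpop = c("s1", "s2"),
                           classification = c("up_regulated",
                                              "unaffected"))
  expect_error(subpop_signatures(norm, labels, cls_up),
               "signature comparison undefined")
})
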