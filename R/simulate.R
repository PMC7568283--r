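#' Default cell-type composition for simulated cohorts
#'
#' Six cortical cell types at the proportions reported for human
#' prefrontal cortex snRNA-seq (astrocytes 11.9%, endothelial cells 2.3%,
#' excitatory neurons 45.2%, inhibitory neurons 14.1%, microglia 4.7%,
#' oligodendrocytes 21.8%), each with a block of marker genes
#' over-expressed relative to all other types.
#'
#' @param marker_genes Number of marker genes per type.
#' @param marker_log2fc log2 fold elevation of a type's markers in that
#'   type relative to the baseline mean.
#' @return A tibble with columns `name`, `baseline_proportion`,
#'   `marker_genes`, `marker_log2fc`.
#' @export
default_cell_types <- function(marker_genes = 25, marker_log2fc = 3) {
  tibble::tibble(
    name = c("astrocyte", "endothelial", "excitatory_neuron",
             "inhibitory_neuron", "microglia", "oligodendrocyte"),
    baseline_proportion = c(0.119, 0.023, 0.452, 0.141, 0.047, 0.218),
    marker_genes = as.integer(marker_genes),
    marker_log2fc = marker_log2fc
  )
}

# Canonical marker symbols per type; the first is the reference marker the
# annotation step keys on, the rest are reported co-markers.
type_marker_symbols <- list(
  astrocyte = c("AQP4", "ADGRV1", "GPC5", "RYR3"),
  endothelial = c("CLDN5", "ABCB1", "EBF1"),
  excitatory_neuron = c("CAMK2A", "CBLN2", "LDB2"),
  inhibitory_neuron = c("GAD1", "LHFPL3", "PCDH15"),
  microglia = c("C3", "LRMDA", "DOCK8"),
  oligodendrocyte = c("MBP", "PLP1", "ST18")
)

mito_symbols <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                  "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                  "MT-ND5", "MT-ND6", "MT-CYB")

#' Configure a synthetic case/control cohort
#'
#' Defines the generative model for [generate_cohort()]: a multi-sample
#' case (AD) / control (NC) cohort of UMI counts with a cell-type
#' hierarchy, optional within-type subpopulations, planted differentially
#' expressed genes of given effect size, planted subpopulation proportion
#' shifts, lognormal library-size variation, mitochondrial count
#' allocation, and QC-violating debris nuclei.
#'
#' Counts are negative binomial: for cell c and gene g the mean is
#' `libsize_factor_c * baseline_mean_g * 2^(effects applying to (c, g))`
#' with a single shared dispersion (`size = 1/nb_dispersion`). Baseline
#' means are lognormal with median `exp(baseline_meanlog)` counts/cell,
#' mimicking sparse snRNA-seq.
#'
#' @param n_samples_case,n_samples_control Number of case/control subjects.
#' @param cells_per_sample Nuclei per subject.
#' @param n_genes Total genes (including mitochondrial and marker genes).
#' @param cell_types Tibble as [default_cell_types()]: `name`,
#'   `baseline_proportion` (summing to 1), `marker_genes`, `marker_log2fc`.
#' @param subpops Optional tibble of within-type subpopulations:
#'   `cell_type`, `name`, `baseline_share_within_type`,
#'   `case_share_within_type` (each summing to 1 within a type), and
#'   optionally `marker_genes`/`marker_log2fc` giving each subpopulation a
#'   condition-independent expression program so it is discoverable by
#'   re-clustering, and `marker_base_mean` pinning those program genes'
#'   baseline means (counts/cell) to the expressed stratum, as the
#'   signature genes of real subpopulations are.
#' @param planted_degs Optional tibble of condition effects: `cell_type`,
#'   `subpop` (a subpopulation name or `"all"`), `gene_count`, `log2fc`
#'   (signed; applied to case cells only).
#' @param nb_dispersion Negative binomial dispersion (> 0); `size` is its
#'   reciprocal.
#' @param libsize_lognormal_sigma sdlog of the per-cell library-size
#'   factor (mean fixed at 1).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline per-gene mean counts/cell.
#' @param mito_gene_count Number of `"MT-"` genes.
#' @param mito_fraction_mean Expected mitochondrial share of a healthy
#'   nucleus's counts.
#' @param debris_fraction Fraction of each sample's nuclei that are
#'   debris and should fail quality control.
#' @param debris_high_mito_share Share of debris nuclei that fail via a
#'   high mitochondrial fraction; the remainder fail via a library
#'   collapsed far below the 200-detected-gene floor.
#' @param debris_mito_fraction Expected mitochondrial share of a
#'   high-mito debris nucleus (default 0.5, safely above the 0.20
#'   removal threshold even under count overdispersion).
#' @param seed Integer seed; fixes every draw.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples_case = 12, n_samples_control = 9,
                          cells_per_sample = 1000, n_genes = 2000,
                          cell_types = default_cell_types(),
                          subpops = NULL, planted_degs = NULL,
                          nb_dispersion = 0.5,
                          libsize_lognormal_sigma = 0.35,
                          baseline_meanlog = log(0.2), baseline_sdlog = 1,
                          mito_gene_count = 13, mito_fraction_mean = 0.05,
                          debris_fraction = 0.05,
                          debris_high_mito_share = 0.5,
                          debris_mito_fraction = 0.5, seed = 1L) {
  cell_types <- tibble::as_tibble(cell_types)
  if (is.null(subpops)) {
    subpops <- tibble::tibble(cell_type = character(), name = character(),
                              baseline_share_within_type = numeric(),
                              case_share_within_type = numeric())
  }
  subpops <- tibble::as_tibble(subpops)
  if (!"marker_genes" %in% names(subpops))
    subpops$marker_genes <- rep(0L, nrow(subpops))
  if (!"marker_log2fc" %in% names(subpops))
    subpops$marker_log2fc <- rep(1, nrow(subpops))
  if (!"marker_base_mean" %in% names(subpops))
    subpops$marker_base_mean <- rep(NA_real_, nrow(subpops))
  if (is.null(planted_degs)) {
    planted_degs <- tibble::tibble(cell_type = character(),
                                   subpop = character(),
                                   gene_count = integer(),
                                   log2fc = numeric())
  }
  planted_degs <- tibble::as_tibble(planted_degs)
  if (!"subpop" %in% names(planted_degs) && nrow(planted_degs))
    planted_degs$subpop <- "all"

  cfg <- structure(
    list(n_samples_case = as.integer(n_samples_case),
         n_samples_control = as.integer(n_samples_control),
         cells_per_sample = as.integer(cells_per_sample),
         n_genes = as.integer(n_genes), cell_types = cell_types,
         subpops = subpops, planted_degs = planted_degs,
         nb_dispersion = nb_dispersion,
         libsize_lognormal_sigma = libsize_lognormal_sigma,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         mito_gene_count = as.integer(mito_gene_count),
         mito_fraction_mean = mito_fraction_mean,
         debris_fraction = debris_fraction,
         debris_high_mito_share = debris_high_mito_share,
         debris_mito_fraction = debris_mito_fraction,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  ct <- cfg$cell_types
  if (abs(sum(ct$baseline_proportion) - 1) > 1e-6)
    stop("cell-type baseline proportions must sum to 1", call. = FALSE)
  sp <- cfg$subpops
  if (nrow(sp)) {
    if (!all(sp$cell_type %in% ct$name))
      stop("subpops reference unknown cell types", call. = FALSE)
    chk <- dplyr::summarise(
      dplyr::group_by(sp, .data$cell_type),
      b = sum(.data$baseline_share_within_type),
      a = sum(.data$case_share_within_type))
    if (any(abs(chk$b - 1) > 1e-6) || any(abs(chk$a - 1) > 1e-6))
      stop("within each cell type, subpopulation shares must sum to 1 ",
           "under both conditions", call. = FALSE)
  }
  pd <- cfg$planted_degs
  if (nrow(pd)) {
    if (!all(pd$cell_type %in% ct$name))
      stop("planted_degs reference unknown cell types", call. = FALSE)
    known <- paste(sp$cell_type, sp$name)
    bad <- pd$subpop != "all" &
      !(paste(pd$cell_type, pd$subpop) %in% known)
    if (any(bad))
      stop("planted_degs reference unknown subpopulations", call. = FALSE)
  }
  budget <- cfg$mito_gene_count + sum(ct$marker_genes) +
    sum(sp$marker_genes) + sum(pd$gene_count)
  if (budget > cfg$n_genes)
    stop("infeasible config: ", budget, " special genes exceed n_genes = ",
         cfg$n_genes, call. = FALSE)
  if (cfg$nb_dispersion <= 0 || cfg$debris_fraction < 0 ||
      cfg$debris_fraction >= 1 || cfg$libsize_lognormal_sigma < 0)
    stop("infeasible config: dispersion must be > 0, debris_fraction in ",
         "[0, 1), libsize sigma >= 0", call. = FALSE)
  invisible(cfg)
}

# Assign every gene an id, a symbol and a role (mito / type marker /
# subpop marker / planted DEG / background), disjointly.
build_gene_table <- function(cfg) {
  n <- cfg$n_genes
  genes <- tibble::tibble(
    gene_id = sprintf("ENSG%06d", seq_len(n)),
    symbol = sprintf("GENE%04d", seq_len(n)),
    role = "background",
    marker_of = NA_character_, subpop_marker_of = NA_character_,
    deg_cell_type = NA_character_, deg_subpop = NA_character_,
    deg_log2fc = NA_real_)
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }
  idx <- take(cfg$mito_gene_count)
  genes$role[idx] <- "mito"
  genes$symbol[idx] <- c(mito_symbols,
                         sprintf("MT-X%02d", seq_len(max(
                           0, cfg$mito_gene_count - length(mito_symbols)
                         ))))[seq_len(cfg$mito_gene_count)]
  for (i in seq_len(nrow(cfg$cell_types))) {
    tname <- cfg$cell_types$name[i]
    k <- cfg$cell_types$marker_genes[i]
    if (k == 0) next
    idx <- take(k)
    genes$role[idx] <- "marker"
    genes$marker_of[idx] <- tname
    canon <- type_marker_symbols[[tname]] %||%
      paste0(toupper(substr(tname, 1, 3)), "MK1")
    syms <- c(canon, sprintf("%s-M%02d", toupper(substr(tname, 1, 4)),
                             seq_len(max(0, k - length(canon)))))
    genes$symbol[idx] <- syms[seq_len(k)]
  }
  for (i in seq_len(nrow(cfg$subpops))) {
    k <- cfg$subpops$marker_genes[i]
    if (k == 0) next
    idx <- take(k)
    genes$role[idx] <- "subpop_marker"
    tag <- paste0(cfg$subpops$cell_type[i], ":", cfg$subpops$name[i])
    genes$subpop_marker_of[idx] <- tag
    genes$symbol[idx] <- sprintf("SPM-%s-%02d", gsub("[^A-Za-z0-9]", "",
                                                     toupper(tag)),
                                 seq_len(k))
  }
  for (i in seq_len(nrow(cfg$planted_degs))) {
    k <- cfg$planted_degs$gene_count[i]
    if (k == 0) next
    idx <- take(k)
    genes$role[idx] <- "deg"
    genes$deg_cell_type[idx] <- cfg$planted_degs$cell_type[i]
    genes$deg_subpop[idx] <- cfg$planted_degs$subpop[i]
    genes$deg_log2fc[idx] <- cfg$planted_degs$log2fc[i]
  }
  genes
}

# Multiplicative 2^log2fc effect vector over genes for one cell group.
group_effect <- function(genes, cfg, type, subpop, condition) {
  eff <- rep(1, nrow(genes))
  row <- which(cfg$cell_types$name == type)
  is_mk <- !is.na(genes$marker_of) & genes$marker_of == type
  eff[is_mk] <- eff[is_mk] * 2^cfg$cell_types$marker_log2fc[row]
  tag <- paste0(type, ":", subpop)
  is_sp <- !is.na(genes$subpop_marker_of) & genes$subpop_marker_of == tag
  if (any(is_sp)) {
    lfc <- cfg$subpops$marker_log2fc[cfg$subpops$cell_type == type &
                                       cfg$subpops$name == subpop]
    eff[is_sp] <- eff[is_sp] * 2^lfc
  }
  if (condition == "AD") {
    is_deg <- !is.na(genes$deg_cell_type) & genes$deg_cell_type == type &
      (genes$deg_subpop == "all" | genes$deg_subpop == subpop)
    eff[is_deg] <- eff[is_deg] * 2^genes$deg_log2fc[is_deg]
  }
  eff
}

#' Generate a synthetic case/control snRNA-seq cohort
#'
#' Draws per-sample UMI count matrices under the model described in
#' [cohort_config()], together with sample metadata (Braak-consistent
#' conditions, age, sex, postmortem delay) and the full ground truth
#' needed to benchmark recovery: per-cell type/subpopulation/debris
#' assignments, per-gene roles with signed effect sizes, and the planted
#' within-type proportion shifts.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list: `matrices` (named list of [count_matrix], one
#'   per sample), `samples` (metadata tibble), `truth` (list with `cells`,
#'   `genes`, `subpop_shifts` tibbles), `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  genes <- build_gene_table(config)
  n_genes <- config$n_genes

  base <- stats::rlnorm(n_genes, config$baseline_meanlog,
                        config$baseline_sdlog)
  # Subpopulation program genes may be pinned to the expressed stratum
  # (signature genes of real subpopulations are well-expressed genes).
  for (i in seq_len(nrow(sp_cfg <- config$subpops))) {
    bm <- sp_cfg$marker_base_mean[i]
    if (is.na(bm)) next
    tag <- paste0(sp_cfg$cell_type[i], ":", sp_cfg$name[i])
    idx <- which(!is.na(genes$subpop_marker_of) &
                   genes$subpop_marker_of == tag)
    base[idx] <- stats::rlnorm(length(idx), log(bm), 0.25)
  }
  # Mitochondrial means are set so the expected mito share of a healthy
  # nucleus equals mito_fraction_mean.
  mito <- genes$role == "mito"
  if (any(mito)) {
    f <- config$mito_fraction_mean
    base[mito] <- f / (1 - f) * sum(base[!mito]) / sum(mito)
  }

  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(config$n_samples_case +
                                           config$n_samples_control)),
    condition = rep(c("AD", "NC"), c(config$n_samples_case,
                                     config$n_samples_control)))
  samples$braak_stage <- ifelse(samples$condition == "AD",
                                sample(4:6, nrow(samples), replace = TRUE),
                                sample(0:2, nrow(samples), replace = TRUE))
  samples$age_years <- round(stats::rnorm(
    nrow(samples), ifelse(samples$condition == "AD", 74.6, 85.4), 5), 1)
  samples$sex <- sample(c("M", "F"), nrow(samples), replace = TRUE,
                        prob = c(2, 1) / 3)
  samples$postmortem_delay_hours <- round(pmin(120, stats::rlnorm(
    nrow(samples), log(24), 0.5)), 1)
  validate_sample_metadata(samples)

  sp <- config$subpops
  size <- 1 / config$nb_dispersion
  matrices <- list()
  cell_rows <- list()

  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    cond <- samples$condition[s]
    n_cells <- config$cells_per_sample
    type <- sample(config$cell_types$name, n_cells, replace = TRUE,
                   prob = config$cell_types$baseline_proportion)
    subpop <- rep("s1", n_cells)
    for (tname in unique(sp$cell_type)) {
      rows <- sp[sp$cell_type == tname, ]
      share <- if (cond == "AD") rows$case_share_within_type else
        rows$baseline_share_within_type
      sel <- type == tname
      if (any(sel))
        subpop[sel] <- sample(rows$name, sum(sel), replace = TRUE,
                              prob = share)
    }
    n_debris <- round(config$debris_fraction * n_cells)
    debris_idx <- sample.int(n_cells, n_debris)
    n_himito <- round(config$debris_high_mito_share * n_debris)
    debris_kind <- rep("none", n_cells)
    debris_kind[debris_idx] <-
      rep(c("high_mito", "low_umi"),
          c(n_himito, n_debris - n_himito))[sample.int(n_debris)]

    sigma <- config$libsize_lognormal_sigma
    libf <- stats::rlnorm(n_cells, -sigma^2 / 2, sigma)
    # Low-UMI debris: library collapsed to an expected total of ~60 UMIs,
    # far below the 200-detected-gene QC floor.
    low <- debris_kind == "low_umi"
    libf[low] <- 60 / sum(base)

    mu <- matrix(0, n_genes, n_cells)
    for (grp in split(seq_len(n_cells), paste(type, subpop))) {
      eff <- group_effect(genes, config, type[grp[1]], subpop[grp[1]], cond)
      mu[, grp] <- (base * eff) %o% libf[grp]
    }
    him <- debris_kind == "high_mito"
    if (any(him) && any(mito)) {
      f <- config$mito_fraction_mean
      fd <- config$debris_mito_fraction
      mu[mito, him] <- mu[mito, him, drop = FALSE] *
        (fd / (1 - fd)) / (f / (1 - f))
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = size), n_genes, n_cells)
    barcodes <- sprintf("BC%05d", seq_len(n_cells))
    matrices[[sid]] <- count_matrix(counts, genes$gene_id, genes$symbol,
                                    barcodes)
    cell_rows[[sid]] <- tibble::tibble(
      cell_id = paste0(sid, ":", barcodes), barcode = barcodes,
      sample_id = sid, condition = cond, cell_type = type,
      subpop = subpop, is_debris = debris_kind != "none",
      debris_kind = debris_kind)
  }

  shifts <- if (nrow(sp)) {
    dplyr::mutate(
      sp[, c("cell_type", "name", "baseline_share_within_type",
             "case_share_within_type")],
      delta_pp = 100 * (.data$case_share_within_type -
                          .data$baseline_share_within_type))
  } else {
    tibble::tibble(cell_type = character(), name = character(),
                   baseline_share_within_type = numeric(),
                   case_share_within_type = numeric(), delta_pp = numeric())
  }

  structure(list(matrices = matrices, samples = samples,
                 truth = list(cells = dplyr::bind_rows(cell_rows),
                              genes = genes, subpop_shifts = shifts),
                 config = config),
            class = "cohort")
}

#' Generate a matched null cohort
#'
#' Same generative model as [generate_cohort()] but with every condition
#' effect removed: no planted DEGs and identical within-type
#' subpopulation shares in cases and controls. The substrate for type-I
#' error checks.
#'
#' @param config A [cohort_config()].
#' @return A `cohort`, as [generate_cohort()].
#' @export
null_cohort <- function(config) {
  config$planted_degs <- config$planted_degs[0, ]
  if (nrow(config$subpops))
    config$subpops$case_share_within_type <-
      config$subpops$baseline_share_within_type
  generate_cohort(config)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$matrices), " samples (",
      sum(x$samples$condition == "AD"), " AD / ",
      sum(x$samples$condition == "NC"), " NC), ",
      x$config$cells_per_sample, " cells/sample, ",
      x$config$n_genes, " genes, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Pool per-sample matrices into one cohort matrix
#'
#' Column-binds the per-sample count matrices after namespacing barcodes
#' as `"<sample_id>:<barcode>"`, so the pooled matrix has globally unique
#' cell identifiers matching the truth's `cell_id`.
#'
#' @param matrices Named list of [count_matrix] (names = sample ids).
#' @return A single [count_matrix].
#' @export
bind_cohort <- function(matrices) {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  ref <- matrices[[1]]$gene_ids
  for (m in matrices)
    if (!identical(m$gene_ids, ref))
      stop("all samples must share the same gene axis", call. = FALSE)
  prefixed <- purrr::imap(matrices, ~ prefix_barcodes(.x, .y))
  values <- do.call(cbind, purrr::map(prefixed, "values"))
  count_matrix(values, ref, matrices[[1]]$gene_symbols,
               unlist(purrr::map(prefixed, "cell_barcodes"),
                      use.names = FALSE))
}

#' Deterministic quality-control fixture
#'
#' Builds, by direct construction (no sampling), a count matrix with an
#' exactly known set of QC violators under the default thresholds
#' (detected genes <= 200, total UMIs >= 20,000, mito fraction >= 0.20),
#' including boundary cases sitting exactly on each threshold.
#'
#' @param n_keep Cells passing all filters.
#' @param n_low_gene Cells with 150 detected genes (fail gene floor).
#' @param n_boundary_gene Cells with exactly 200 detected genes (fail:
#'   the floor is inclusive of 200).
#' @param n_high_umi Cells with exactly 20,000 UMIs (fail: inclusive).
#' @param n_high_mito Cells with mito fraction exactly 0.20 (fail:
#'   inclusive).
#' @return List with `matrix` ([count_matrix]) and `keep_expected`
#'   (logical vector).
#' @export
make_qc_fixture <- function(n_keep = 463, n_low_gene = 10,
                            n_boundary_gene = 9, n_high_umi = 9,
                            n_high_mito = 9) {
  n_genes <- 600L
  symbols <- c("MT-ND1", sprintf("GENE%04d", seq_len(n_genes - 1)))
  kinds <- rep(c("keep", "low_gene", "boundary_gene", "high_umi",
                 "high_mito"),
               c(n_keep, n_low_gene, n_boundary_gene, n_high_umi,
                 n_high_mito))
  cols <- lapply(kinds, function(kind) {
    v <- integer(n_genes)
    switch(kind,
      keep = {            # 401 genes, 402 UMIs, mito 2/402 < 0.2
        v[2:401] <- 1L; v[1] <- 2L
      },
      low_gene = {        # 150 genes detected <= 200
        v[2:151] <- 1L
      },
      boundary_gene = {   # exactly 200 genes detected
        v[2:201] <- 1L
      },
      high_umi = {        # 500 genes, exactly 20,000 UMIs
        v[2:501] <- 40L
      },
      high_mito = {       # 500 UMIs of which 100 mitochondrial = 0.20
        v[2:401] <- 1L; v[1] <- 100L
      })
    v
  })
  m <- count_matrix(do.call(cbind, cols), sprintf("QG%04d", seq_len(n_genes)),
                    symbols, sprintf("QC%04d", seq_along(kinds)))
  list(matrix = m, keep_expected = kinds == "keep")
}
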