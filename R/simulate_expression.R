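#' Simulate a cells-by-genes count matrix with planted cluster programs
#'
#' Draws negative-binomial counts for the cohort's cells over the synthetic
#' gene panel. Each tumor subcluster carries a planted expression program:
#' a block of `program_size` genes upshifted by `2^program_log2fc` in that
#' cluster's cells. Mitochondrial genes contribute roughly 5% of a normal
#' cell's counts. Four extra cells violating attainable quality-control
#' thresholds are appended (low counts, low gene diversity, excessive UMIs,
#' high mitochondrial fraction) so downstream QC filtering is exercised.
#'
#' @param cfg A [sim_config()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay; `colData` carries `sample_id`, `case_id`, `cluster`,
#'   `cell_type`, `group` and `qc_planted` (the intended QC violation, `NA`
#'   for regular cells); `rowData` carries the gene panel plus the planted
#'   `program` assignment; `metadata(sce)$programs` lists the planted
#'   program genes per cluster.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- simulate_cells(cfg)
  panel <- gene_panel(cfg)
  n_genes <- nrow(panel)
  withr::with_seed(.stage_seed(cfg, "expression"), {
    w <- stats::rgamma(n_genes, shape = 0.8, rate = 1) + 1e-4
    mito <- panel$mito_flag
    # scale mitochondrial weights to ~5% of library
    w[mito] <- w[mito] / sum(w[mito]) * (0.05 / 0.95) * sum(w[!mito])
    base_mu <- w / sum(w) * cfg$base_depth

    fill_idx <- setdiff(which(!panel$mito_flag), seq_len(nrow(.driver_genes)))
    programs <- lapply(seq_len(cfg$n_clusters), function(k) {
      idx <- fill_idx[((k - 1L) * cfg$program_size + 1L):(k * cfg$program_size)]
      panel$symbol[idx]
    })
    names(programs) <- sprintf("C%d", seq_len(cfg$n_clusters))
    # program genes have a low, fixed baseline outside their cluster
    # (cluster markers are genes mostly off elsewhere); the planted
    # upshift then moves both detection fraction and fold change
    base_mu[match(unlist(programs), panel$symbol)] <- 1.0

    n_cells <- nrow(cells)
    mu <- matrix(base_mu, nrow = n_genes, ncol = n_cells)
    for (k in names(programs)) {
      j <- which(cells$cluster == k)
      i <- match(programs[[k]], panel$symbol)
      mu[i, j] <- mu[i, j] * 2^cfg$program_log2fc
    }

    # planted QC violators (panel too small for the >10,000-genes branch)
    qc_mu <- cbind(
      base_mu / sum(base_mu) * 100,                        # min-counts
      {m <- numeric(n_genes)
       keep <- which(!mito)[1:100]
       m[keep] <- base_mu[keep]
       m / sum(m) * 1500},                                 # min-genes
      base_mu / sum(base_mu) * 20000,                      # max-umis
      {m <- base_mu
       m[mito] <- m[mito] / sum(m[mito]) * (0.30 / 0.70) * sum(m[!mito])
       m / sum(m) * 2500})                                 # max-mito
    mu <- cbind(mu, qc_mu)
    qc_cells <- data.frame(
      cell_barcode = sprintf("QC%03d", 1:4),
      group = "tumor", cell_type = "tumor", case_id = "CASE1",
      cluster = "C1", sample_id = cfg$samples$sample_id[1L],
      stringsAsFactors = FALSE)
    meta <- rbind(cells[, names(qc_cells)], qc_cells)
    meta$qc_planted <- c(rep(NA_character_, n_cells),
                         c("min-counts", "min-genes", "max-umis", "max-mito"))

    counts <- matrix(stats::rnbinom(length(mu), size = cfg$nb_dispersion,
                                    mu = as.numeric(mu)),
                     nrow = n_genes,
                     dimnames = list(panel$symbol, meta$cell_barcode))
    panel$program <- NA_character_
    for (k in names(programs))
      panel$program[match(programs[[k]], panel$symbol)] <- k
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(meta, row.names = meta$cell_barcode),
      rowData = S4Vectors::DataFrame(panel, row.names = panel$symbol))
    S4Vectors::metadata(sce)$programs <- programs
    S4Vectors::metadata(sce)$program_log2fc <- cfg$program_log2fc
    sce
  })
}

#' Simulate a gene-level copy-number matrix with planted arm/focal events
#'
#' Produces a cells-by-genes matrix on a copy-number-like scale (1.0 =
#' neutral, i.e. two copies) with Gaussian noise. Configured arm events
#' shift every gene on the arm in the designated group's cells; focal
#' events plant deep gains/losses at single driver genes in a random
#' fraction of the group's cells.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (cells x genes), `gene_meta`, and `truth`
#'   (planted arm shifts and the exact cells carrying each focal event).
#' @export
simulate_cnv_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- simulate_cells(cfg)
  panel <- gene_panel(cfg)
  arm <- ifelse(is.na(panel$band), NA_character_,
                paste0(panel$chrom, substr(panel$band, 1L, 1L)))
  withr::with_seed(.stage_seed(cfg, "cnv"), {
    m <- matrix(1 + stats::rnorm(nrow(cells) * nrow(panel),
                                 sd = cfg$cnv_noise_sd),
                nrow = nrow(cells),
                dimnames = list(cells$cell_barcode, panel$symbol))
    for (ev in cfg$arm_events) {
      j <- which(!is.na(arm) & arm == ev$arm)
      if (!length(j)) stop("arm event on unknown arm: ", ev$arm)
      i <- which(cells$group %in% ev$group)
      m[i, j] <- m[i, j] + ev$shift
    }
    focal_truth <- lapply(cfg$focal_events, function(ev) {
      j <- match(ev$gene, panel$symbol)
      if (is.na(j)) stop("focal event on unknown gene: ", ev$gene)
      pool <- which(cells$group %in% ev$group)
      i <- sort(sample(pool, round(ev$fraction * length(pool))))
      m[i, j] <<- m[i, j] + ev$shift
      list(gene = ev$gene, shift = ev$shift, group = ev$group,
           cells = cells$cell_barcode[i])
    })
    list(matrix = m, gene_meta = cbind(panel, arm = arm),
         truth = list(arm_events = cfg$arm_events, focal = focal_truth))
  })
}

#' Gene-to-cytoband table for the synthetic panel
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with `gene`, `chrom`, `band` (band `NA` for
#'   mitochondrial genes, which therefore stay unmapped at arm level).
#' @export
band_table <- function(cfg) {
  panel <- gene_panel(cfg)
  data.frame(gene = panel$symbol, chrom = panel$chrom, band = panel$band,
             stringsAsFactors = FALSE)
}

#' Simulate the complete synthetic cohort
#'
#' Runs every generator stage under the config's seed and returns all
#' pipeline inputs together with their ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `cfg`, `cells`, `variants`, `observations`,
#'   `obs_truth`, `somatic_calls`, `germline_calls`, `sce`, `cnv`,
#'   `band_table`, `samples`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  obs <- simulate_read_observations(cfg)
  list(cfg = cfg,
       cells = obs$cells,
       variants = obs$variants,
       observations = obs$observations,
       obs_truth = obs$truth,
       somatic_calls = simulate_somatic_callsets(cfg),
       germline_calls = simulate_germline_callsets(cfg),
       sce = simulate_expression(cfg),
       cnv = simulate_cnv_matrix(cfg),
       band_table = band_table(cfg),
       samples = cfg$samples)
}
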