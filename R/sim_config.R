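#' Simulation configuration for the synthetic PDAC-like cohort
#'
#' Builds a validated configuration object that fully determines every
#' synthetic input the pipeline consumes: barcoded read observations at
#' variant sites, multi-caller somatic/germline call sets, a cells-by-genes
#' expression matrix with planted cluster programs, and a gene-level
#' copy-number matrix with planted arm and focal events. A given `seed`
#' yields byte-identical outputs on rerun.
#'
#' The default settings emulate a multi-sample pancreatic cohort with
#' tumor, PanIN, ADM (acinar-to-ductal metaplasia), normal duct and acinar
#' compartments. Mutation-supporting molecules are observed per cell with
#' group-specific probability (`mapping_rate`), highest in tumor cells and
#' near the noise floor in normal compartments, so that mutations
#' preferentially map to neoplastic cells by construction.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_cells_per_group Named integer vector of cells per compartment.
#'   Must contain at least `tumor`, `panin`, `adm`, `normal_duct`, `acinar`.
#' @param mapping_rate Named numeric vector in `[0,1]`: per-cell probability
#'   that a variant-supporting molecule is observed at a site.
#' @param background_ref_rate Expected number of reference-supporting
#'   molecules per cell per site (Poisson rate); keeps total coverage
#'   nonzero so proportions are defined.
#' @param umi_dup_rate Probability in `[0,1)` that a molecule yields more
#'   than one read; duplicate count is `1 + Geometric`.
#' @param allele_error_rate Per-read probability that the observed allele
#'   flips to one of the other two categories (`ref`/`alt`/`other`),
#'   creating within-UMI conflicts for the consensus rule.
#' @param n_variants Number of variant sites traced to cells.
#' @param n_somatic_records,n_germline_records Sizes of the simulated
#'   multi-caller call sets (noise calls spanning every filter branch).
#' @param n_genes Expression/CNV panel size.
#' @param n_clusters Number of tumor subclusters with planted programs.
#' @param program_size Genes per planted cluster program.
#' @param program_log2fc Planted log2 fold change of program genes in their
#'   cluster.
#' @param nb_dispersion Negative-binomial size parameter for counts.
#' @param base_depth Expected per-cell total counts.
#' @param n_mito_genes Number of mitochondrially flagged genes in the panel.
#' @param cnv_noise_sd Gaussian noise sd of the copy-number-like matrix
#'   around the neutral value 1.
#' @param arm_events List of `list(arm=, shift=, group=)` arm-level shifts.
#' @param focal_events List of `list(gene=, shift=, group=, fraction=)`
#'   deep focal events planted in a random fraction of a group's cells.
#' @param samples `data.frame` with `sample_id`, `x_mm`, `y_mm`: spatial
#'   sampling sites in millimetres.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_group = c(tumor = 1000L, panin = 600L,
                                             adm = 400L, normal_duct = 600L,
                                             acinar = 400L),
                       mapping_rate = c(tumor = 0.30, panin = 0.15,
                                        adm = 0.05, normal_duct = 0.01,
                                        acinar = 0.01),
                       background_ref_rate = 0.5,
                       umi_dup_rate = 0.3,
                       allele_error_rate = 0.01,
                       n_variants = 8L,
                       n_somatic_records = 200L,
                       n_germline_records = 200L,
                       n_genes = 500L,
                       n_clusters = 4L,
                       program_size = 50L,
                       program_log2fc = 2,
                       nb_dispersion = 2,
                       base_depth = 2500,
                       n_mito_genes = 20L,
                       cnv_noise_sd = 0.1,
                       arm_events = list(
                         list(arm = "8q",  shift = +0.5, group = "tumor"),
                         list(arm = "18q", shift = -0.3, group = "tumor")),
                       focal_events = list(
                         list(gene = "AKT2",  shift = +1.5, group = "tumor",
                              fraction = 0.3),
                         list(gene = "SMAD4", shift = -1.2, group = "tumor",
                              fraction = 0.2)),
                       samples = data.frame(
                         sample_id = c("S1", "S2", "S3"),
                         x_mm = c(0, 10, 12), y_mm = c(0, 0, 0))) {
  required_groups <- c("tumor", "panin", "adm", "normal_duct", "acinar")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!all(required_groups %in% names(n_cells_per_group)))
    stop("n_cells_per_group must name all of: ",
         paste(required_groups, collapse = ", "))
  if (any(n_cells_per_group <= 0) ||
      any(n_cells_per_group != round(n_cells_per_group)))
    stop("n_cells_per_group entries must be positive integers")
  if (!all(names(n_cells_per_group) %in% names(mapping_rate)))
    stop("mapping_rate must cover every group in n_cells_per_group")
  .check_prob <- function(x, what, open_right = FALSE) {
    bad <- !is.finite(x) | x < 0 | x > 1 | (open_right & x >= 1)
    if (any(bad)) stop(what, " must be a probability in [0,",
                       if (open_right) "1)" else "1]")
  }
  .check_prob(mapping_rate, "mapping_rate")
  .check_prob(umi_dup_rate, "umi_dup_rate", open_right = TRUE)
  .check_prob(allele_error_rate, "allele_error_rate")
  if (background_ref_rate < 0) stop("background_ref_rate must be >= 0")
  for (n in c(n_variants, n_somatic_records, n_germline_records, n_genes,
              n_clusters, program_size, n_mito_genes))
    if (n <= 0 || n != round(n)) stop("counts must be positive integers")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cnv_noise_sd < 0) stop("cnv_noise_sd must be >= 0")
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "x_mm", "y_mm") %in% names(samples)))
  cfg <- list(seed = as.integer(seed),
              n_cells_per_group = n_cells_per_group,
              mapping_rate = mapping_rate,
              background_ref_rate = background_ref_rate,
              umi_dup_rate = umi_dup_rate,
              allele_error_rate = allele_error_rate,
              n_variants = as.integer(n_variants),
              n_somatic_records = as.integer(n_somatic_records),
              n_germline_records = as.integer(n_germline_records),
              n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              program_size = as.integer(program_size),
              program_log2fc = program_log2fc,
              nb_dispersion = nb_dispersion,
              base_depth = base_depth,
              n_mito_genes = as.integer(n_mito_genes),
              cnv_noise_sd = cnv_noise_sd,
              arm_events = arm_events,
              focal_events = focal_events,
              samples = samples)
  class(cfg) <- "sim_config"
  cfg
}

# Fixed offsets decouple the per-stage RNG streams so each simulate_* call
# is deterministic regardless of call order. Kept well below 2^31.
.seed_offsets <- c(cells = 11L, reads = 23L, somatic = 37L, germline = 41L,
                   expression = 53L, cnv = 71L)

.stage_seed <- function(cfg, stage) {
  (cfg$seed %% 2000000000L) + .seed_offsets[[stage]]
}
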