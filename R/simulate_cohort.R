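# Synthetic cohort generator. Every stage draws from its own seeded RNG
# stream (see .stage_seed) so outputs are byte-identical under a fixed
# config seed and independent of call order.

.driver_genes <- data.frame(
  symbol = c("KRAS", "CDKN2A", "SMAD4", "TP53", "AKT2", "MYC", "GATA6"),
  chrom  = c("12", "9", "18", "17", "19", "8", "18"),
  band   = c("p12.1", "p21.3", "q21.2", "p13.1", "q13.2", "q24.21", "q11.2"),
  stringsAsFactors = FALSE)

#' Gene panel of the synthetic cohort
#'
#' Deterministic (seed-independent) gene annotation used by the expression
#' and CNV generators: PDAC driver genes with their true cytobands, a block
#' of mitochondrially encoded genes (chromosome `MT`, no band, hence
#' unmappable to arms), and filler genes distributed across autosome arms.
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with `symbol`, `chrom`, `band`, `mito_flag`,
#'   `length_bp`.
#' @export
gene_panel <- function(cfg) {
  n_fill <- cfg$n_genes - nrow(.driver_genes) - cfg$n_mito_genes
  if (n_fill < cfg$n_clusters * cfg$program_size)
    stop("n_genes too small for the requested cluster programs")
  mito <- data.frame(symbol = sprintf("MT-G%02d", seq_len(cfg$n_mito_genes)),
                     chrom = "MT", band = NA_character_)
  i <- seq_len(n_fill)
  fill <- data.frame(symbol = sprintf("GENE%04d", i),
                     chrom = as.character(((i - 1L) %% 22L) + 1L),
                     band = ifelse(i %% 2L == 0L, "q22", "p13"))
  panel <- rbind(.driver_genes, mito, fill)
  panel$mito_flag <- panel$chrom == "MT"
  panel$length_bp <- 500L + (seq_len(nrow(panel)) * 137L) %% 5000L
  rownames(panel) <- NULL
  panel
}

#' Variant sites traced to single cells
#'
#' The first four sites sit in the canonical PDAC drivers (KRAS, CDKN2A,
#' SMAD4, TP53); remaining sites are assigned to further panel genes.
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with `site_id`, `chrom`, `pos`, `ref`, `alt`, `gene`.
#' @export
variant_panel <- function(cfg) {
  panel <- gene_panel(cfg)
  genes <- panel[!panel$mito_flag, , drop = FALSE]
  if (cfg$n_variants > nrow(genes))
    stop("n_variants exceeds the non-mitochondrial gene panel")
  g <- genes[seq_len(cfg$n_variants), ]
  bases <- c("A", "C", "G", "T")
  ref <- bases[((seq_len(cfg$n_variants) - 1L) %% 4L) + 1L]
  alt <- bases[(seq_len(cfg$n_variants) %% 4L) + 1L]
  data.frame(site_id = sprintf("V%02d", seq_len(cfg$n_variants)),
             chrom = g$chrom,
             pos = 1000000L + seq_len(cfg$n_variants) * 1000L,
             ref = ref, alt = alt, gene = g$symbol,
             stringsAsFactors = FALSE)
}

#' Per-cell metadata of the synthetic cohort
#'
#' Assigns each cell a compartment (`group`), a spatial sample of origin
#' and, for tumor cells, an expression subcluster. Cells of subcluster `C1`
#' originate almost exclusively (98%) from sample `S1`, which by default
#' lies more than 6 mm from the other samples, planting one spatially
#' distinct tumor subcluster.
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with `cell_barcode`, `group`, `cell_type`,
#'   `sample_id`, `case_id`, `cluster`.
#' @export
simulate_cells <- function(cfg) {
  withr::with_seed(.stage_seed(cfg, "cells"), {
    groups <- rep(names(cfg$n_cells_per_group), cfg$n_cells_per_group)
    n <- length(groups)
    cells <- data.frame(
      cell_barcode = sprintf("CB%05d", seq_len(n)),
      group = groups,
      cell_type = groups,
      case_id = "CASE1",
      stringsAsFactors = FALSE)
    cells$cluster <- cells$group
    is_tum <- cells$group == "tumor"
    cells$cluster[is_tum] <- sprintf(
      "C%d", sample.int(cfg$n_clusters, sum(is_tum), replace = TRUE))
    smp <- cfg$samples$sample_id
    cells$sample_id <- sample(smp, n, replace = TRUE)
    c1 <- cells$cluster == "C1"
    cells$sample_id[c1] <- ifelse(stats::runif(sum(c1)) < 0.98, smp[1L],
                                  sample(smp, sum(c1), replace = TRUE))
    cells
  })
}

#' Simulate barcoded, UMI-tagged allele observations at variant sites
#'
#' Each cell draws variant-supporting molecules `Bernoulli(mapping_rate[group])`
#' per site and reference-supporting molecules at a fixed Poisson background
#' rate. Every molecule is emitted as `1 + Geometric` duplicate reads that
#' share a (cell, UMI) pair; each duplicate read may flip to another allele
#' category with probability `allele_error_rate`, creating within-UMI
#' conflicts the downstream consensus rule must resolve.
#'
#' @param cfg A [sim_config()].
#' @return List with `observations` (one row per read: `chrom`, `pos`,
#'   `ref`, `alt`, `cell_barcode`, `umi`, `observed_allele`), `cells`,
#'   `variants`, and `truth` (per cell x site true molecule counts).
#' @export
simulate_read_observations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- simulate_cells(cfg)
  variants <- variant_panel(cfg)
  withr::with_seed(.stage_seed(cfg, "reads"), {
    pairs <- data.table::CJ(cell_barcode = cells$cell_barcode,
                            site_id = variants$site_id, sorted = TRUE)
    pairs <- merge(pairs,
                   data.table::as.data.table(cells[, c("cell_barcode", "group")]),
                   by = "cell_barcode")
    data.table::setorderv(pairs, c("cell_barcode", "site_id"))
    rate <- cfg$mapping_rate[pairs$group]
    pairs[, `:=`(true_alt = stats::rbinom(.N, 1L, rate),
                 true_ref = stats::rpois(.N, cfg$background_ref_rate))]
    mol <- data.table::rbindlist(list(
      pairs[rep(seq_len(.N), true_alt), .(cell_barcode, site_id, allele = "alt")],
      pairs[rep(seq_len(.N), true_ref), .(cell_barcode, site_id, allele = "ref")]))
    data.table::setorderv(mol, c("cell_barcode", "site_id", "allele"))
    mol[, umi := sprintf("U%04d", seq_len(.N)), by = .(cell_barcode, site_id)]
    n_reads <- if (cfg$umi_dup_rate > 0)
      1L + stats::rgeom(nrow(mol), prob = 1 - cfg$umi_dup_rate)
    else rep(1L, nrow(mol))
    reads <- mol[rep(seq_len(.N), n_reads)]
    data.table::setnames(reads, "allele", "observed_allele")
    if (cfg$allele_error_rate > 0 && nrow(reads) > 0) {
      flip <- stats::runif(nrow(reads)) < cfg$allele_error_rate
      if (any(flip)) {
        cats <- c("ref", "alt", "other")
        cur <- match(reads$observed_allele[flip], cats)
        step <- sample(1:2, sum(flip), replace = TRUE)
        reads$observed_allele[flip] <- cats[((cur - 1L + step) %% 3L) + 1L]
      }
    }
    obs <- merge(reads, data.table::as.data.table(variants), by = "site_id")
    data.table::setorderv(obs, c("cell_barcode", "site_id", "umi"))
    obs <- obs[, .(chrom, pos, ref, alt, cell_barcode, umi, observed_allele)]
    truth <- pairs[, .(cell_barcode, site_id, group,
                       true_ref_molecules = true_ref,
                       true_alt_molecules = true_alt)]
    list(observations = as.data.frame(obs),
         cells = cells, variants = variants,
         truth = as.data.frame(truth))
  })
}

.somatic_rules <- c("caller-support", "tumor-depth", "normal-depth",
                    "tumor-vaf", "normal-vaf", "indel-length",
                    "not-exonic", "dbsnp-not-cosmic")

#' Simulate a multi-caller somatic call set spanning every filter branch
#'
#' Each random record independently violates each consensus-filter rule
#' with probability 0.15, with field values constructed so the intended
#' pass/fail status is known (`truth_pass`, `planted_reasons`).
#' A deterministic block of boundary records (tumor VAF exactly 0.05,
#' normal VAF exactly 0.02, depths exactly 14/8, indel lengths 99/100,
#' zero-depth samples, single-caller and dbSNP-not-COSMIC calls) is
#' always appended.
#'
#' @param cfg A [sim_config()].
#' @param n_records Number of random records (defaults to the config value).
#' @return `data.frame` of somatic call records with planted ground truth.
#' @export
simulate_somatic_callsets <- function(cfg, n_records = cfg$n_somatic_records) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(.stage_seed(cfg, "somatic"), {
    n <- n_records
    cls <- sample(c("SNV", "indel"), n, replace = TRUE, prob = c(0.7, 0.3))
    viol <- matrix(stats::runif(n * 8L) < 0.15, nrow = n,
                   dimnames = list(NULL, .somatic_rules))
    viol[, "indel-length"] <- viol[, "indel-length"] & cls == "indel"

    td <- ifelse(viol[, "tumor-depth"], sample(0:13, n, TRUE),
                 sample(14:60, n, TRUE))
    ta <- integer(n)
    ok <- td > 0 & !viol[, "tumor-vaf"]
    ta[ok] <- pmin(td[ok], pmax(ceiling(0.05 * td[ok]),
                                round(stats::runif(sum(ok), 0.05, 0.6) * td[ok])))
    bad <- td > 0 & viol[, "tumor-vaf"]
    ta[bad] <- floor(0.0499 * td[bad])

    nd <- ifelse(viol[, "normal-depth"], sample(0:7, n, TRUE),
                 sample(8:40, n, TRUE))
    na <- integer(n)
    ok <- nd > 0 & !viol[, "normal-vaf"]
    na[ok] <- floor(stats::runif(sum(ok)) * (floor(0.02 * nd[ok]) + 1L))
    bad <- nd > 0 & viol[, "normal-vaf"]
    na[bad] <- pmax(1L, ceiling(0.0201 * nd[bad]))

    caller_sets <- list(SNV = c("strelka", "varscan", "mutect"),
                        indel = c("strelka", "varscan", "pindel"))
    callers <- vapply(seq_len(n), function(i) {
      allowed <- caller_sets[[cls[i]]]
      k <- if (viol[i, "caller-support"]) 1L else sample(2:3, 1L)
      paste(sort(sample(allowed, k)), collapse = "|")
    }, character(1))

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    is_ind <- cls == "indel"
    ind_len <- integer(n)
    ind_len[is_ind] <- ifelse(viol[is_ind, "indel-length"],
                              sample(100:140, sum(is_ind), TRUE),
                              sample(1:99, sum(is_ind), TRUE))
    ref[is_ind] <- paste0("A", strrep("T", ind_len[is_ind]))
    alt[is_ind] <- "A"

    dbsnp_ok <- sample(c("FF", "FT", "TT"), n, TRUE)
    in_dbsnp <- ifelse(viol[, "dbsnp-not-cosmic"], TRUE,
                       substr(dbsnp_ok, 1, 1) == "T")
    in_cosmic <- ifelse(viol[, "dbsnp-not-cosmic"], FALSE,
                        substr(dbsnp_ok, 2, 2) == "T")

    no_depth <- td == 0 | nd == 0
    reasons <- apply(cbind(viol, `no-depth` = no_depth), 1L,
                     function(v) paste(colnames(viol)[v[1:8]], collapse = ";"))
    reasons[no_depth] <- vapply(which(no_depth), function(i)
      paste(c(.somatic_rules[viol[i, ]], "no-depth"), collapse = ";"),
      character(1))

    rec <- data.frame(
      chrom = sample(as.character(1:22), n, TRUE),
      pos = 2000000L + seq_len(n) * 100L,
      ref = ref, alt = alt, variant_class = cls, callers = callers,
      tumor_ref_count = td - ta, tumor_alt_count = ta,
      normal_ref_count = nd - na, normal_alt_count = na,
      exonic = !viol[, "not-exonic"],
      in_dbsnp = in_dbsnp, in_cosmic = in_cosmic,
      truth_pass = rowSums(viol) == 0 & !no_depth,
      planted_reasons = reasons,
      stringsAsFactors = FALSE)

    rbind(rec, .somatic_boundary_records())
  })
}

# Deterministic boundary records exercising every threshold exactly.
.somatic_boundary_records <- function() {
  rec <- function(class, callers, tr, ta, nr, na, exonic = TRUE,
                  dbsnp = FALSE, cosmic = FALSE, ref = "G", alt = "A",
                  pass, reasons = "") {
    data.frame(chrom = "12", pos = 0L, ref = ref, alt = alt,
               variant_class = class, callers = callers,
               tumor_ref_count = tr, tumor_alt_count = ta,
               normal_ref_count = nr, normal_alt_count = na,
               exonic = exonic, in_dbsnp = dbsnp, in_cosmic = cosmic,
               truth_pass = pass, planted_reasons = reasons,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    # tumor VAF exactly 0.05 at depth 20: boundary inclusive -> pass
    rec("SNV", "strelka|varscan", 19L, 1L, 10L, 0L, pass = TRUE),
    # normal VAF exactly 0.02 at depth 50 -> pass
    rec("SNV", "strelka|varscan", 30L, 10L, 49L, 1L, pass = TRUE),
    # depths exactly at 14 / 8 -> pass
    rec("SNV", "mutect|varscan", 12L, 2L, 8L, 0L, pass = TRUE),
    # indel length 99 (< 100) -> pass; 100 -> fail
    rec("indel", "pindel|varscan", 20L, 10L, 12L, 0L,
        ref = paste0("A", strrep("T", 99L)), alt = "A", pass = TRUE),
    rec("indel", "pindel|varscan", 20L, 10L, 12L, 0L,
        ref = paste0("A", strrep("T", 100L)), alt = "A", pass = FALSE,
        reasons = "indel-length"),
    # single caller -> fail
    rec("SNV", "mutect", 30L, 10L, 12L, 0L, pass = FALSE,
        reasons = "caller-support"),
    # in dbSNP but not COSMIC -> fail; in both -> pass
    rec("SNV", "strelka|mutect", 30L, 10L, 12L, 0L, dbsnp = TRUE,
        pass = FALSE, reasons = "dbsnp-not-cosmic"),
    rec("SNV", "strelka|mutect", 30L, 10L, 12L, 0L, dbsnp = TRUE,
        cosmic = TRUE, pass = TRUE),
    # zero-depth samples -> no-depth
    rec("SNV", "strelka|mutect", 0L, 0L, 12L, 0L, pass = FALSE,
        reasons = "tumor-depth;no-depth"),
    rec("SNV", "strelka|mutect", 30L, 10L, 0L, 0L, pass = FALSE,
        reasons = "normal-depth;no-depth"))
  out$pos <- 3000000L + seq_len(nrow(out)) * 10L
  out
}

.germline_rules <- c("allelic-depth", "allele-frequency", "non-coding",
                     "population-frequency")

#' Simulate a germline call set spanning every filter branch
#'
#' Random records independently violate the allelic-depth, allele-frequency,
#' coding-region and population-frequency rules; deterministic boundary
#' records (allele fraction exactly 0.20, alt depth exactly 5, population
#' frequency exactly 0.05%) are appended.
#'
#' @param cfg A [sim_config()].
#' @param n_records Number of random records.
#' @return `data.frame` of germline call records with planted ground truth.
#' @export
simulate_germline_callsets <- function(cfg, n_records = cfg$n_germline_records) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(.stage_seed(cfg, "germline"), {
    n <- n_records
    viol <- matrix(stats::runif(n * 4L) < 0.15, nrow = n,
                   dimnames = list(NULL, .germline_rules))
    draw_pair <- function(bad_depth, bad_af) {
      a <- ifelse(bad_depth, sample(0:4, n, TRUE), sample(5:30, n, TRUE))
      r <- ifelse(bad_af, 4L * pmax(a, 1L) + sample(1:20, n, TRUE),
                  floor(stats::runif(n) * (4L * a + 1L)))
      list(alt = a, ref = r)
    }
    # a violated rule applies to at least one sample; both samples redrawn
    tum <- draw_pair(viol[, "allelic-depth"], viol[, "allele-frequency"])
    nrm <- draw_pair(FALSE, FALSE)
    pop <- ifelse(viol[, "population-frequency"],
                  0.0005 + stats::runif(n) * 0.05,
                  stats::runif(n) * 0.00049)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    rec <- data.frame(
      chrom = sample(as.character(1:22), n, TRUE),
      pos = 4000000L + seq_len(n) * 100L,
      ref = ref, alt = alt,
      tumor_ref_count = tum$ref, tumor_alt_count = tum$alt,
      normal_ref_count = nrm$ref, normal_alt_count = nrm$alt,
      pop_af = pop,
      in_coding_region = !viol[, "non-coding"],
      truth_pass = rowSums(viol) == 0,
      planted_reasons = apply(viol, 1L, function(v)
        paste(.germline_rules[v], collapse = ";")),
      stringsAsFactors = FALSE)
    bd <- function(tr, ta, nr, na, pop, coding = TRUE, pass, reasons = "") {
      data.frame(chrom = "13", pos = 0L, ref = "G", alt = "A",
                 tumor_ref_count = tr, tumor_alt_count = ta,
                 normal_ref_count = nr, normal_alt_count = na,
                 pop_af = pop, in_coding_region = coding,
                 truth_pass = pass, planted_reasons = reasons,
                 stringsAsFactors = FALSE)
    }
    bnd <- rbind(
      # AF exactly 0.20 and alt depth exactly 5 in both samples -> pass
      bd(20L, 5L, 20L, 5L, 0, pass = TRUE),
      # population frequency exactly 0.05% -> fail (rule is >= 0.0005)
      bd(20L, 10L, 20L, 10L, 0.0005, pass = FALSE,
         reasons = "population-frequency"),
      # normal alt count 4 -> fail allelic depth
      bd(20L, 10L, 16L, 4L, 0, pass = FALSE, reasons = "allelic-depth"),
      # zero-depth tumor sample -> no-depth (alt depth necessarily fails too)
      bd(0L, 0L, 20L, 10L, 0, pass = FALSE,
         reasons = "allelic-depth;no-depth"))
    bnd$pos <- 5000000L + seq_len(nrow(bnd)) * 10L
    rbind(rec, bnd)
  })
}
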