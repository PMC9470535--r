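# Per-cell mutation mapping: trace cell barcodes and UMIs through the
# read observations at high-confidence variant sites, collapse reads to
# molecules by strict per-UMI majority (ties and "other"-majority UMIs are
# discarded but accounted for), classify cells and apply the hierarchical
# alteration labeling used for single-cell mutation/CNV display.

#' Collapse reads to per-cell molecule counts by UMI consensus
#'
#' Reads sharing (cell barcode, site, UMI) collapse to one molecule whose
#' allele is the strict majority of its reads' alleles; an exact tie, or a
#' majority of `other`, discards the molecule (counted in
#' `discarded_umis`). With `collapse = FALSE` every read is treated as its
#' own molecule (`other` reads are discarded).
#'
#' @param obs Observation `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   `cell_barcode`, `umi`, `observed_allele`); restrict rows to the
#'   high-confidence variant list before calling.
#' @param collapse Collapse UMI duplicates (default) or count raw reads.
#' @return `data.frame` with one row per (cell, site) carrying any UMI:
#'   `cell_barcode`, `chrom`, `pos`, `ref`, `alt`, `ref_molecules`,
#'   `alt_molecules`, `discarded_umis`.
#' @export
dedup_umis <- function(obs, collapse = TRUE) {
  empty <- data.frame(cell_barcode = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      ref_molecules = integer(), alt_molecules = integer(),
                      discarded_umis = integer(), stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) return(empty)
  dt <- data.table::as.data.table(obs)
  key <- c("cell_barcode", "chrom", "pos", "ref", "alt")
  if (collapse) {
    per_umi <- dt[, .(
      n_ref = sum(observed_allele == "ref"),
      n_alt = sum(observed_allele == "alt"),
      n_other = sum(observed_allele == "other")),
      by = c(key, "umi")]
    per_umi[, consensus := data.table::fifelse(
      n_ref > pmax(n_alt, n_other), "ref",
      data.table::fifelse(n_alt > pmax(n_ref, n_other), "alt", "discard"))]
    counts <- per_umi[, .(
      ref_molecules = sum(consensus == "ref"),
      alt_molecules = sum(consensus == "alt"),
      discarded_umis = sum(consensus == "discard")),
      by = key]
  } else {
    counts <- dt[, .(
      ref_molecules = sum(observed_allele == "ref"),
      alt_molecules = sum(observed_allele == "alt"),
      discarded_umis = sum(observed_allele == "other")),
      by = key]
  }
  data.table::setorderv(counts, key)
  as.data.frame(counts)
}

#' Classify cells by supporting molecules at each site
#'
#' Cells with both reference- and variant-supporting molecules are labeled
#' `variant_reference`; with only variant support, `variant`; with only
#' reference support, `reference`; with neither (after the minimum-molecule
#' threshold), `none`.
#'
#' @param counts Output of [dedup_umis()].
#' @param min_molecules Minimum molecules for an allele to count as
#'   supported (default 1).
#' @return `counts` with a `label` column.
#' @export
classify_cells <- function(counts, min_molecules = 1L) {
  ref_sup <- counts$ref_molecules >= min_molecules
  alt_sup <- counts$alt_molecules >= min_molecules
  counts$label <- ifelse(ref_sup & alt_sup, "variant_reference",
                  ifelse(alt_sup, "variant",
                  ifelse(ref_sup, "reference", "none")))
  counts
}

#' Hierarchical single-alteration label per cell
#'
#' Each cell with at least one alteration event receives exactly one
#' display label: mutations outrank copy-number events; within a kind the
#' highest-ranked gene wins (default hierarchy KRAS > CDKN2A > SMAD4 >
#' TP53; genes outside the hierarchy rank after it, alphabetically).
#'
#' @param events `data.frame` with `cell_barcode`, `gene`, `kind`
#'   (`mutation`, `cnv_gain`, `cnv_loss`).
#' @param gene_order Character vector defining the gene hierarchy.
#' @return `data.frame` with `cell_barcode`, `gene`, `kind`,
#'   `display_label` (one row per labeled cell).
#' @export
label_cells_hierarchical <- function(events,
                                     gene_order = c("KRAS", "CDKN2A",
                                                    "SMAD4", "TP53")) {
  if (nrow(events) == 0L)
    return(data.frame(cell_barcode = character(), gene = character(),
                      kind = character(), display_label = character(),
                      stringsAsFactors = FALSE))
  stopifnot(all(events$kind %in% c("mutation", "cnv_gain", "cnv_loss")))
  dt <- data.table::as.data.table(events)
  extra <- sort(setdiff(unique(dt$gene), gene_order))
  full_order <- c(gene_order, extra)
  dt[, rank_kind := data.table::fifelse(kind == "mutation", 1L, 2L)]
  dt[, rank_gene := match(gene, full_order)]
  # deterministic tie-break between gain and loss on the same gene
  dt[, rank_cnv := match(kind, c("mutation", "cnv_gain", "cnv_loss"))]
  data.table::setorderv(dt, c("cell_barcode", "rank_kind", "rank_gene",
                              "rank_cnv"))
  top <- dt[, utils::head(.SD, 1L), by = cell_barcode]
  top[, display_label := paste(gene, kind)]
  as.data.frame(top[, .(cell_barcode, gene, kind, display_label)])
}

#' Mutation events from per-cell genotype labels
#'
#' Converts cells supporting the variant allele (`variant` or
#' `variant_reference`) at a site into `mutation` events for the site's
#' gene, ready for [label_cells_hierarchical()].
#'
#' @param labels Output of [classify_cells()].
#' @param variants Variant table with `chrom`, `pos`, `ref`, `alt`, `gene`.
#' @return `data.frame` with `cell_barcode`, `gene`, `kind`.
#' @export
mutation_events <- function(labels, variants) {
  hit <- labels[labels$label %in% c("variant", "variant_reference"), ,
                drop = FALSE]
  m <- merge(hit, variants[, c("chrom", "pos", "ref", "alt", "gene")],
             by = c("chrom", "pos", "ref", "alt"))
  data.frame(cell_barcode = m$cell_barcode, gene = m$gene,
             kind = "mutation", stringsAsFactors = FALSE)
}

#' Detect minority hotspot mutations per sample
#'
#' Runs the same UMI-consensus pipeline restricted to hotspot sites (e.g.
#' the nine bases of KRAS codons G12/G13/Q61) and reports, per sample and
#' site, the aggregate VAF of pooled molecules alongside the per-cell
#' counts. Sites with no molecule coverage in a sample are reported with
#' `vaf = NA` (no coverage for mutant or reference allele).
#'
#' @param obs Observation `data.frame`.
#' @param hotspot_sites `data.frame` with `chrom`, `pos` (and optionally
#'   `ref`, `alt`) defining the hotspot loci.
#' @param cell_samples `data.frame` mapping `cell_barcode` to `sample_id`.
#' @param collapse Passed to [dedup_umis()].
#' @return List with `cell_counts` (per-cell molecule counts at hotspot
#'   sites) and `sample_vafs` (`sample_id`, `chrom`, `pos`, pooled
#'   `alt_molecules`, `ref_molecules`, `n_cells_covered`, `n_cells_alt`,
#'   `vaf`).
#' @export
detect_minority_hotspots <- function(obs, hotspot_sites, cell_samples,
                                     collapse = TRUE) {
  stopifnot(all(c("chrom", "pos") %in% names(hotspot_sites)),
            all(c("cell_barcode", "sample_id") %in% names(cell_samples)))
  keep <- paste(obs$chrom, obs$pos) %in%
    paste(hotspot_sites$chrom, hotspot_sites$pos)
  counts <- dedup_umis(obs[keep, , drop = FALSE], collapse = collapse)
  counts <- merge(counts, cell_samples[, c("cell_barcode", "sample_id")],
                  by = "cell_barcode")
  grid <- merge(unique(cell_samples[, "sample_id", drop = FALSE]),
                hotspot_sites[, c("chrom", "pos")])
  if (nrow(counts)) {
    dt <- data.table::as.data.table(counts)
    agg <- dt[, .(alt_molecules = sum(alt_molecules),
                  ref_molecules = sum(ref_molecules),
                  n_cells_covered = sum(ref_molecules + alt_molecules > 0),
                  n_cells_alt = sum(alt_molecules > 0)),
              by = .(sample_id, chrom, pos)]
    agg <- as.data.frame(agg)
  } else {
    agg <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), alt_molecules = integer(),
                      ref_molecules = integer(), n_cells_covered = integer(),
                      n_cells_alt = integer(), stringsAsFactors = FALSE)
  }
  out <- merge(grid, agg, by = c("sample_id", "chrom", "pos"), all.x = TRUE)
  zero <- is.na(out$alt_molecules)
  out[zero, c("alt_molecules", "ref_molecules", "n_cells_covered",
              "n_cells_alt")] <- 0L
  tot <- out$alt_molecules + out$ref_molecules
  out$vaf <- ifelse(tot > 0, out$alt_molecules / tot, NA_real_)
  out <- out[order(out$sample_id, out$chrom, out$pos), ]
  rownames(out) <- NULL
  list(cell_counts = counts, sample_vafs = out)
}
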