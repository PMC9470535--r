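# Droplet cell QC and depth normalization. In 3' droplet data total
# transcript counts and UMIs are the same quantity; both printed
# thresholds (<300 counts, <1,000 UMIs) are applied independently as
# stated, so the effective lower floor is 1,000.

#' Default cell quality-control thresholds
#'
#' A cell is removed iff it violates any rule: total counts < 300, genes
#' expressed < 200, UMIs < 1,000, genes expressed > 10,000, UMIs > 10,000,
#' or mitochondrial fraction > 0.10 (strictly greater).
#'
#' @param min_counts,min_genes,min_umis,max_genes,max_umis,max_mito
#'   Threshold values.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(min_counts = 300, min_genes = 200,
                          min_umis = 1000, max_genes = 10000,
                          max_umis = 10000, max_mito = 0.10) {
  list(min_counts = min_counts, min_genes = min_genes, min_umis = min_umis,
       max_genes = max_genes, max_umis = max_umis, max_mito = max_mito)
}

#' Per-cell QC metrics
#'
#' @param sce `SingleCellExperiment` with a `counts` assay;
#'   `rowData(sce)$mito_flag` marks mitochondrial genes (absent: symbols
#'   starting `MT-` are used).
#' @return `data.frame` with `cell_barcode`, `total_counts`, `n_genes`,
#'   `n_umis`, `pct_mito`.
#' @export
cell_qc_metrics <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$mito_flag
  if (is.null(mito)) mito <- grepl("^MT-", rownames(counts))
  total <- Matrix::colSums(counts)
  data.frame(
    cell_barcode = colnames(counts),
    total_counts = as.numeric(total),
    n_genes = as.numeric(Matrix::colSums(counts > 0)),
    n_umis = as.numeric(total),
    pct_mito = ifelse(total > 0,
                      as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) /
                        pmax(total, 1), 0),
    stringsAsFactors = FALSE)
}

#' Filter cells on quality-control thresholds
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param thresholds See [qc_thresholds()].
#' @return List with `kept` (the filtered object) and `report` (per-cell
#'   metrics, `removed` flag and semicolon-separated `reasons`).
#' @export
qc_filter_cells <- function(sce, thresholds = qc_thresholds()) {
  th <- thresholds
  qc <- cell_qc_metrics(sce)
  viol <- cbind(
    `min-counts` = qc$total_counts < th$min_counts,
    `min-genes` = qc$n_genes < th$min_genes,
    `min-umis` = qc$n_umis < th$min_umis,
    `max-genes` = qc$n_genes > th$max_genes,
    `max-umis` = qc$n_umis > th$max_umis,
    `max-mito` = qc$pct_mito > th$max_mito)
  qc$removed <- rowSums(viol) > 0
  qc$reasons <- apply(viol, 1L, function(v)
    paste(colnames(viol)[v], collapse = ";"))
  list(kept = sce[, !qc$removed], report = qc)
}

#' Median-depth log normalization
#'
#' Scales each cell's counts to the median total depth of the matrix and
#' applies `log1p`; a deterministic depth normalization used as the
#' expression layer for differential expression and pathway scoring.
#' All-zero cells stay all-zero.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @return `sce` with an added `logcounts` assay.
#' @export
normalize_log <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  depth <- Matrix::colSums(counts)
  target <- stats::median(depth[depth > 0])
  sf <- ifelse(depth > 0, depth / target, 1)
  norm <- counts %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(norm)
  sce
}
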