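# Arm-level summarization of gene-level copy-number matrices and deep
# event calling. The upstream copy-number inference is consumed as input
# on a declared scale; this module only maps genes to chromosome arms,
# averages per arm, and thresholds deep events.

#' Map genes to chromosome arms via a cytoband table
#'
#' The arm is the first character of the cytoband (`p` or `q`);
#' alternatively, with coordinate input, genes starting before the
#' centromere map to `p`. Genes absent from the table (or with a missing
#' band) are reported unmapped; contradictory rows for one gene raise an
#' error naming the gene.
#'
#' @param genes Character vector of gene symbols to map.
#' @param band_table `data.frame` with either `gene`, `chrom`, `band`
#'   columns or `gene`, `chrom`, `start` plus a `centromeres` table.
#' @param centromeres Optional `data.frame` with `chrom`,
#'   `centromere_pos`, required for coordinate input.
#' @return List with `map` (`gene`, `chrom`, `arm`, `arm_id`) and
#'   `unmapped` (character vector).
#' @export
map_genes_to_arms <- function(genes, band_table, centromeres = NULL) {
  stopifnot("gene" %in% names(band_table), "chrom" %in% names(band_table))
  tb <- band_table[band_table$gene %in% genes, , drop = FALSE]
  if ("band" %in% names(tb)) {
    # empty strings arise when a missing band round-trips through TSV
    tb <- tb[!is.na(tb$band) & nzchar(tb$band), , drop = FALSE]
    tb$arm <- substr(tb$band, 1L, 1L)
  } else if ("start" %in% names(tb)) {
    if (is.null(centromeres))
      stop("coordinate band tables require a centromeres table")
    cen <- centromeres$centromere_pos[match(tb$chrom, centromeres$chrom)]
    if (anyNA(cen)) stop("centromere position missing for chromosome(s): ",
                         paste(unique(tb$chrom[is.na(cen)]), collapse = ", "))
    tb$arm <- ifelse(tb$start < cen, "p", "q")
  } else stop("band_table needs either a 'band' or a 'start' column")
  if (!all(tb$arm %in% c("p", "q")))
    stop("cytobands must start with 'p' or 'q'")
  tb$arm_id <- paste0(tb$chrom, tb$arm)
  dup <- unique(tb$gene[duplicated(tb$gene)])
  for (g in dup)
    if (length(unique(tb$arm_id[tb$gene == g])) > 1L)
      stop("contradictory arm assignment for gene: ", g)
  tb <- tb[!duplicated(tb$gene), c("gene", "chrom", "arm", "arm_id")]
  rownames(tb) <- NULL
  list(map = tb, unmapped = setdiff(genes, tb$gene))
}

#' Arm-level means of a gene-level CNV matrix
#'
#' Unweighted mean over each arm's mapped genes, per cell. Arms with no
#' mapped gene are omitted; unmapped genes are excluded from every mean.
#'
#' @param mat Cells x genes numeric matrix (colnames = genes).
#' @param arm_map Output of [map_genes_to_arms()] (or its `map` element).
#' @return Cells x arms numeric matrix.
#' @export
arm_level_means <- function(mat, arm_map) {
  map <- if (is.list(arm_map) && !is.data.frame(arm_map)) arm_map$map
         else arm_map
  map <- map[map$gene %in% colnames(mat), , drop = FALSE]
  if (!nrow(map)) stop("no genes of the matrix are mapped to arms")
  arms <- sort(unique(map$arm_id))
  out <- vapply(arms, function(a) {
    g <- map$gene[map$arm_id == a]
    rowMeans(mat[, g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), arms))
  out
}

#' Call deep copy-number events
#'
#' Thresholds a copy-number-like matrix (1.0 = neutral, two copies) into
#' per-cell gain/loss events deeper than one copy; with log-ratio input
#' the matrix is first converted as `2^x`. Defaults are deliberately
#' conservative on the continuous expression-derived scale: gains at
#' values `>= gain_threshold` (default 2.0) and losses at values
#' `<= loss_threshold` (default 0.1).
#'
#' @param mat Cells x genes (or cells x arms) numeric matrix.
#' @param gain_threshold,loss_threshold Event thresholds.
#' @param scale `"copy"` (default) or `"log-ratio"`.
#' @return `data.frame` with `cell_barcode`, `gene`, `kind`
#'   (`cnv_gain`/`cnv_loss`), `value` -- ready for
#'   [label_cells_hierarchical()].
#' @export
call_deep_events <- function(mat, gain_threshold = 2.0,
                             loss_threshold = 0.1,
                             scale = c("copy", "log-ratio")) {
  scale <- match.arg(scale)
  if (scale == "log-ratio") mat <- 2^mat
  stopifnot(gain_threshold > loss_threshold)
  gains <- which(mat >= gain_threshold, arr.ind = TRUE)
  losses <- which(mat <= loss_threshold, arr.ind = TRUE)
  mk <- function(idx, kind) {
    if (!nrow(idx))
      return(data.frame(cell_barcode = character(), gene = character(),
                        kind = character(), value = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(cell_barcode = rownames(mat)[idx[, 1L]],
               gene = colnames(mat)[idx[, 2L]], kind = kind,
               value = mat[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(mk(gains, "cnv_gain"), mk(losses, "cnv_loss"))
  out <- out[order(out$cell_barcode, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
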