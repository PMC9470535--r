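# Hypergeometric over-representation of marker lists against gene-set
# collections, and the tumor-subcluster pathway score: per pathway, the
# union of overlap genes from significant enrichments across clusters is
# averaged on the normalized layer per cluster, then each pathway row is
# centered and scaled (sample sd) across clusters.

#' Hypergeometric gene-set over-representation
#'
#' For each set, the upper-tail probability `P(X >= k)` of drawing `k`
#' set members among `|deg|` draws from a universe containing
#' `|set & universe|` members. Genes outside the universe are dropped with
#' a warning; P values are BH-adjusted across sets.
#'
#' @param deg_genes Character vector of genes of interest (e.g. a
#'   cluster's markers).
#' @param sets Named list of gene vectors (see [read_gmt()]).
#' @param universe Background gene universe.
#' @return `data.frame` with `pathway`, `set_size` (in-universe),
#'   `overlap`, `p`, `p_adj` and an `overlap_genes` list column.
#' @export
ora_hypergeometric <- function(deg_genes, sets, universe) {
  stopifnot(length(universe) > 0, length(sets) > 0,
            !is.null(names(sets)))
  universe <- unique(universe)
  deg_genes <- unique(deg_genes)
  outside <- setdiff(deg_genes, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the universe dropped")
    deg_genes <- intersect(deg_genes, universe)
  }
  if (!length(deg_genes))
    return(data.frame(pathway = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), p_adj = numeric(),
                      overlap_genes = I(list())))
  n_u <- length(universe)
  n_d <- length(deg_genes)
  hits <- lapply(sets, function(s) intersect(deg_genes, intersect(s, universe)))
  set_size <- vapply(sets, function(s) length(intersect(s, universe)),
                     integer(1))
  k <- lengths(hits)
  p <- stats::phyper(k - 1L, set_size, n_u - set_size, n_d,
                     lower.tail = FALSE)
  out <- data.frame(pathway = names(sets), set_size = set_size,
                    overlap = k, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$overlap_genes <- I(unname(hits))
  rownames(out) <- NULL
  out
}

#' Run over-representation per cluster on a DEG table
#'
#' @param degs Output of [find_degs()].
#' @param sets,universe As in [ora_hypergeometric()].
#' @return Combined `data.frame` with a `cluster` column.
#' @export
ora_by_cluster <- function(degs, sets, universe) {
  out <- lapply(sort(unique(degs$cluster)), function(cl) {
    res <- ora_hypergeometric(degs$gene[degs$cluster == cl], sets, universe)
    if (nrow(res)) cbind(cluster = cl, res) else NULL
  })
  do.call(rbind, out)
}

#' Tumor-subcluster pathway scores
#'
#' Clusters holding fewer than `min_cluster_frac` of all cells are
#' excluded. For each pathway, the member genes are the union over
#' clusters of the overlap genes behind a significant enrichment
#' (`p_adj < alpha`); the pathway's score in a cluster is the mean
#' normalized expression of the member genes over the cluster's cells,
#' after which each pathway row is centered and scaled (sample sd) across
#' clusters. Pathways are ranked by the number of clusters in which they
#' were significant and the top `top_k` retained. Constant rows score 0
#' and are flagged.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay.
#' @param clusters Cluster label per cell (defaults to `colData$cluster`).
#' @param enrichment Output of [ora_by_cluster()].
#' @param alpha Significance cutoff on `p_adj`.
#' @param min_cluster_frac Minimum fraction of total cells per cluster.
#' @param top_k Number of pathways retained (default all significant).
#' @param whole_set Use the full in-universe gene set instead of the
#'   overlap union as pathway members.
#' @param sets Required when `whole_set = TRUE`.
#' @return List with `scores` (pathways x clusters matrix),
#'   `member_genes` (list), `constant` (logical per pathway) and
#'   `excluded_clusters`.
#' @export
pathway_scores <- function(sce, clusters = NULL, enrichment,
                           alpha = 0.05, min_cluster_frac = 0.001,
                           top_k = Inf, whole_set = FALSE, sets = NULL) {
  if (is.null(clusters)) clusters <- SummarizedExperiment::colData(sce)$cluster
  stopifnot("logcounts" %in% SummarizedExperiment::assayNames(sce),
            length(clusters) == ncol(sce))
  tab <- table(clusters)
  keep_cl <- names(tab)[tab / length(clusters) >= min_cluster_frac]
  excluded <- setdiff(names(tab), keep_cl)
  enr <- enrichment[enrichment$cluster %in% keep_cl, , drop = FALSE]
  sig <- enr[enr$p_adj < alpha & enr$overlap > 0, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(scores = matrix(numeric(0), nrow = 0,
                                ncol = length(keep_cl),
                                dimnames = list(NULL, sort(keep_cl))),
                member_genes = list(), constant = logical(0),
                excluded_clusters = excluded))
  occurrence <- sort(table(sig$pathway), decreasing = TRUE)
  pathways <- names(occurrence)[seq_len(min(top_k, length(occurrence)))]
  member_genes <- lapply(pathways, function(pw) {
    if (whole_set) {
      if (is.null(sets)) stop("sets required when whole_set = TRUE")
      intersect(sets[[pw]], rownames(sce))
    } else {
      sort(unique(unlist(sig$overlap_genes[sig$pathway == pw])))
    }
  })
  names(member_genes) <- pathways
  X <- SummarizedExperiment::assay(sce, "logcounts")
  keep_cells <- clusters %in% keep_cl
  cl_names <- sort(unique(clusters[keep_cells]))
  cluster_means <- vapply(cl_names, function(cl) {
    Matrix::rowMeans(X[, clusters == cl & keep_cells, drop = FALSE])
  }, numeric(nrow(X)))
  raw <- t(vapply(member_genes, function(g)
    colMeans(cluster_means[g, , drop = FALSE]), numeric(length(cl_names))))
  sd_row <- apply(raw, 1L, stats::sd)
  constant <- sd_row == 0 | !is.finite(sd_row)
  scores <- (raw - rowMeans(raw)) / ifelse(constant, 1, sd_row)
  scores[constant, ] <- 0
  dimnames(scores) <- list(pathways, cl_names)
  list(scores = scores, member_genes = member_genes,
       constant = stats::setNames(constant, pathways),
       excluded_clusters = excluded)
}
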