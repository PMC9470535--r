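# Cluster marker detection: one-vs-rest two-sided Wilcoxon rank-sum on the
# normalized layer with a tie-corrected normal approximation, Seurat-style
# expression-fraction prefilters and positive-direction-only reporting.

# Tie-corrected rank-sum z and two-sided p per row of X (genes x cells),
# comparing columns idx1 against the rest. No continuity correction.
.rank_sum_test <- function(X, idx1) {
  n <- ncol(X)
  n1 <- length(idx1)
  n2 <- n - n1
  out <- vapply(seq_len(nrow(X)), function(r) {
    x <- X[r, ]
    rk <- rank(x)
    U <- sum(rk[idx1]) - n1 * (n1 + 1) / 2
    tie <- table(rk)
    tie_term <- sum(tie^3 - tie)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(c(z = 0, p = 1))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  }, numeric(2))
  list(z = out["z", ], p = out["p", ])
}

#' Cluster differential expression (positive markers)
#'
#' For each cluster, genes pass an expression-fraction prefilter
#' (`max(pct_in, pct_out) >= min_pct`; under the `subcluster` profile also
#' `pct_in - pct_out >= min_diff_pct`) and a positive log fold change, and
#' are then tested one-vs-rest with a two-sided Wilcoxon rank-sum on the
#' normalized layer (tie-corrected normal approximation). P values are
#' Bonferroni-adjusted against the full panel size by default. The
#' `global` profile uses `min_pct = 0.25`; the `subcluster` profile uses
#' `min_pct = 0.1` with `min_diff_pct = 0.1`.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay (see
#'   [normalize_log()]).
#' @param clusters Cluster label per cell (defaults to
#'   `colData(sce)$cluster`).
#' @param profile `"global"` or `"subcluster"` prefilter profile.
#' @param min_pct,min_diff_pct Override the profile's fractions.
#' @param adjust_method `"bonferroni"` (default) or any
#'   [stats::p.adjust()] method.
#' @param alpha Adjusted-P cutoff for reported markers.
#' @param significant_only Return only `p_adj < alpha` rows (default);
#'   `FALSE` returns every tested gene.
#' @param fc_base Base of the reported fold change (default `exp(1)`:
#'   natural log of the ratio of mean `expm1` expression + 1).
#' @return `data.frame` with `cluster`, `gene`, `log_fc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj`, sorted by descending `log_fc` within
#'   cluster.
#' @export
find_degs <- function(sce, clusters = NULL,
                      profile = c("global", "subcluster"),
                      min_pct = NULL, min_diff_pct = NULL,
                      adjust_method = "bonferroni", alpha = 0.05,
                      significant_only = TRUE, fc_base = exp(1)) {
  profile <- match.arg(profile)
  if (is.null(min_pct)) min_pct <- if (profile == "global") 0.25 else 0.1
  if (is.null(min_diff_pct))
    min_diff_pct <- if (profile == "global") -Inf else 0.1
  if (is.null(clusters)) clusters <- SummarizedExperiment::colData(sce)$cluster
  stopifnot(!is.null(clusters), length(clusters) == ncol(sce),
            "logcounts" %in% SummarizedExperiment::assayNames(sce))
  X <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  n_total_genes <- nrow(X)
  detected <- X > 0
  out <- list()
  for (cl in sort(unique(clusters))) {
    idx1 <- which(clusters == cl)
    idx2 <- which(clusters != cl)
    if (length(idx1) < 2L || length(idx2) < 2L) {
      warning("cluster ", cl, " has fewer than 2 cells on one side; skipped")
      next
    }
    pct_in <- Matrix::rowMeans(detected[, idx1, drop = FALSE])
    pct_out <- Matrix::rowMeans(detected[, idx2, drop = FALSE])
    log_fc <- log(Matrix::rowMeans(expm1(X[, idx1, drop = FALSE])) + 1) -
      log(Matrix::rowMeans(expm1(X[, idx2, drop = FALSE])) + 1)
    if (fc_base != exp(1)) log_fc <- log_fc / log(fc_base)
    keep <- pmax(pct_in, pct_out) >= min_pct &
      (pct_in - pct_out) >= min_diff_pct & log_fc > 0
    if (!any(keep)) next
    ts <- .rank_sum_test(X[keep, , drop = FALSE], idx1)
    p_adj <- pmin(1, stats::p.adjust(ts$p, method = adjust_method,
                                     n = max(length(ts$p), n_total_genes)))
    res <- data.frame(cluster = cl, gene = rownames(X)[keep],
                      log_fc = log_fc[keep], pct_in = pct_in[keep],
                      pct_out = pct_out[keep], p = ts$p, p_adj = p_adj,
                      stringsAsFactors = FALSE)
    if (significant_only) res <- res[res$p_adj < alpha, , drop = FALSE]
    out[[length(out) + 1L]] <- res[order(-res$log_fc), , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
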