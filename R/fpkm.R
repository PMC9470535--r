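#' Upper-quartile FPKM with log2 transform
#'
#' GDC-style FPKM-UQ for bulk counts:
#' `FPKM-UQ(g,s) = count(g,s) * 1e9 / (length(g) * UQ(s))`, where `UQ(s)`
#' is the 75th percentile of the sample's counts over protein-coding genes
#' with a positive count. The returned value is `log2(FPKM-UQ + 1)`.
#' Samples with a zero upper quartile are reported unusable (all-`NA`
#' column, with a warning).
#'
#' @param counts Genes x samples integer matrix (rownames = genes).
#' @param lengths_bp Gene lengths in bp, named by gene or aligned to rows.
#' @param protein_coding Logical per gene; genes used for the upper
#'   quartile (default all).
#' @return Genes x samples matrix of `log2(FPKM-UQ + 1)`.
#' @export
fpkm_uq_transform <- function(counts, lengths_bp, protein_coding = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts)))
    lengths_bp <- lengths_bp[rownames(counts)]
  stopifnot(length(lengths_bp) == nrow(counts))
  if (any(!is.finite(lengths_bp) | lengths_bp <= 0))
    stop("gene lengths must be positive")
  if (is.null(protein_coding)) protein_coding <- rep(TRUE, nrow(counts))
  out <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    x <- counts[protein_coding, s]
    x <- x[x > 0]
    uq <- if (length(x)) stats::quantile(x, 0.75, names = FALSE) else 0
    if (uq == 0) {
      warning("sample ", colnames(counts)[s] %||% s,
              " has zero upper quartile; reported unusable")
      next
    }
    out[, s] <- log2(counts[, s] * 1e9 / (lengths_bp * uq) + 1)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
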