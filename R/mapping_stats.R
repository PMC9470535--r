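# Difference-of-proportions test for preferential mutation mapping.
#
# With X_T variant-supporting and N_T total (variant + reference) molecule
# counts in the test group, and X_N / N_N in the comparison group,
#   P_T = X_T/N_T, P_N = X_N/N_N,
#   P_avg = (X_T + X_N)/(N_T + N_N), Q_avg = 1 - P_avg,
#   Z = (|P_T - P_N| - (1/N_T + 1/N_N)/2) / (P_avg * Q_avg * sqrt(1/N_T + 1/N_N))
# and the one-sided P value is the upper-tail standard-normal probability
# of Z. The pooled product P_avg * Q_avg sits OUTSIDE the square root in
# the denominator; the textbook pooled form
# sqrt(P_avg * Q_avg * (1/N_T + 1/N_N)) is available via `variance_form`.
# The test is only performed when P_T > P_N is actually observed; skipped
# comparisons are excluded from FDR adjustment.

#' Continuity-corrected two-proportion Z test for mutation mapping
#'
#' Vectorized over inputs. Comparisons are skipped (with a reason) when a
#' group has no coverage, when `P_T <= P_N`, or when the pooled proportion
#' is degenerate (0 or 1). `normal_approx_ok` reports the classical
#' heuristic `N * P_avg * Q_avg >= 5` in both groups; failing it flags but
#' does not suppress the test.
#'
#' @param x_t,n_t Variant-supporting and total counts in the test group.
#' @param x_n,n_n Same for the comparison group.
#' @param variance_form `"printed"` (default; pooled product outside the
#'   square root) or `"pooled"` (textbook pooled standard error).
#' @return `data.frame` with `X_T`, `N_T`, `X_N`, `N_N`, `P_T`, `P_N`,
#'   `P_avg`, `Q_avg`, `Z`, `p`, `performed`, `reason`,
#'   `normal_approx_ok`.
#' @export
compute_mapping_z <- function(x_t, n_t, x_n, n_n,
                              variance_form = c("printed", "pooled")) {
  variance_form <- match.arg(variance_form)
  k <- max(length(x_t), length(n_t), length(x_n), length(n_n))
  x_t <- rep_len(x_t, k); n_t <- rep_len(n_t, k)
  x_n <- rep_len(x_n, k); n_n <- rep_len(n_n, k)
  if (any(x_t < 0 | x_n < 0 | n_t < 0 | n_n < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(x_t > n_t | x_n > n_n, na.rm = TRUE))
    stop("variant count cannot exceed total count")

  p_t <- ifelse(n_t > 0, x_t / n_t, NA_real_)
  p_n <- ifelse(n_n > 0, x_n / n_n, NA_real_)
  p_avg <- ifelse(n_t + n_n > 0, (x_t + x_n) / (n_t + n_n), NA_real_)
  q_avg <- 1 - p_avg

  reason <- rep(NA_character_, k)
  reason[n_t == 0 | n_n == 0] <- "no-coverage"
  skip <- is.na(reason) & p_t <= p_n
  reason[skip] <- "not-greater"
  degen <- is.na(reason) & (p_avg <= 0 | p_avg >= 1)
  reason[degen] <- "degenerate-proportion"
  performed <- is.na(reason)

  z <- p <- rep(NA_real_, k)
  if (any(performed)) {
    i <- which(performed)
    inv <- 1 / n_t[i] + 1 / n_n[i]
    num <- abs(p_t[i] - p_n[i]) - inv / 2
    den <- if (variance_form == "printed")
      p_avg[i] * q_avg[i] * sqrt(inv)
    else
      sqrt(p_avg[i] * q_avg[i] * inv)
    z[i] <- num / den
    p[i] <- stats::pnorm(z[i], lower.tail = FALSE)
  }
  ok <- n_t * p_avg * q_avg >= 5 & n_n * p_avg * q_avg >= 5
  data.frame(X_T = x_t, N_T = n_t, X_N = x_n, N_N = n_n,
             P_T = p_t, P_N = p_n, P_avg = p_avg, Q_avg = q_avg,
             Z = z, p = p, performed = performed, reason = reason,
             normal_approx_ok = ok)
}

#' Group-level mapping-enrichment tests with FDR control
#'
#' Pools variant and reference molecule counts over cells and sites within
#' each group, runs the continuity-corrected Z test for every contrast,
#' and adjusts the performed tests' P values by Benjamini-Hochberg
#' (skipped contrasts are excluded from the adjustment, consistent with
#' the skip rule's FDR motivation).
#'
#' @param counts Per-cell allele counts from [dedup_umis()].
#' @param groups `data.frame` mapping `cell_barcode` to `group`; every
#'   counted cell must map to exactly one group.
#' @param contrasts List of `list(t = , n = )` entries; each side is one
#'   group name or a character vector of groups to pool (e.g. all
#'   nontumor compartments).
#' @return One row per contrast: `contrast`, the full Z-test columns and
#'   BH `q` (NA for skipped tests).
#' @export
run_group_tests <- function(counts, groups, contrasts) {
  stopifnot(all(c("cell_barcode", "group") %in% names(groups)))
  if (anyDuplicated(groups$cell_barcode))
    stop("each cell must be assigned exactly one group")
  m <- merge(counts, groups[, c("cell_barcode", "group")], by = "cell_barcode")
  dt <- data.table::as.data.table(m)
  pooled <- dt[, .(x = sum(alt_molecules),
                   n = sum(alt_molecules + ref_molecules)), by = group]
  side <- function(gs) {
    rows <- pooled[group %in% gs]
    c(x = sum(rows$x), n = sum(rows$n))
  }
  known <- unique(groups$group)
  for (ct in contrasts)
    if (!all(c(ct$t, ct$n) %in% known))
      stop("contrast references unknown group(s): ",
           paste(setdiff(c(ct$t, ct$n), known), collapse = ", "))
  tt <- vapply(contrasts, function(ct) side(ct$t), numeric(2))
  nn <- vapply(contrasts, function(ct) side(ct$n), numeric(2))
  res <- compute_mapping_z(tt["x", ], tt["n", ], nn["x", ], nn["n", ])
  res$contrast <- vapply(contrasts, function(ct)
    paste(paste(ct$t, collapse = "+"), "vs", paste(ct$n, collapse = "+")),
    character(1))
  res$q <- NA_real_
  res$q[res$performed] <- stats::p.adjust(res$p[res$performed], method = "BH")
  res[, c("contrast", setdiff(names(res), c("contrast", "q")), "q")]
}
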