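#' Spatially distinct tumor-cluster assignment
#'
#' A cluster is spatially distinct iff at least `min_fraction` (default
#' 95%) of its cells originate from a single sample AND that sample lies
#' at least `min_dist_mm` (default 6 mm) from every other sample
#' contributing cells to the case. Both boundaries are inclusive.
#'
#' @param clusters Cluster label per cell.
#' @param cell_samples Sample of origin per cell (same length).
#' @param geography `data.frame` with `sample_id`, `x_mm`, `y_mm`.
#' @param min_fraction Dominant-sample fraction threshold.
#' @param min_dist_mm Distance threshold in millimetres.
#' @return `data.frame` with `cluster`, `dominant_sample`, `fraction`,
#'   `min_distance_mm`, `distinct`.
#' @export
spatial_distinct_clusters <- function(clusters, cell_samples, geography,
                                      min_fraction = 0.95,
                                      min_dist_mm = 6) {
  stopifnot(length(clusters) == length(cell_samples),
            all(c("sample_id", "x_mm", "y_mm") %in% names(geography)))
  missing <- setdiff(unique(cell_samples), geography$sample_id)
  if (length(missing))
    stop("sample(s) missing coordinates: ", paste(missing, collapse = ", "))
  coords <- geography[match(unique(geography$sample_id),
                            geography$sample_id), ]
  dist_between <- function(a, b) {
    pa <- coords[coords$sample_id == a, ]
    pb <- coords[coords$sample_id == b, ]
    sqrt((pa$x_mm - pb$x_mm)^2 + (pa$y_mm - pb$y_mm)^2)
  }
  contributing <- unique(cell_samples)
  out <- lapply(sort(unique(clusters)), function(cl) {
    smp <- cell_samples[clusters == cl]
    tab <- sort(table(smp), decreasing = TRUE)
    dom <- names(tab)[1L]
    frac <- tab[[1L]] / length(smp)
    others <- setdiff(contributing, dom)
    min_d <- if (length(others))
      min(vapply(others, dist_between, numeric(1), a = dom)) else Inf
    data.frame(cluster = cl, dominant_sample = dom, fraction = frac,
               min_distance_mm = min_d,
               distinct = frac >= min_fraction & min_d >= min_dist_mm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
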