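make_sce <- function(counts, mito_flag = rep(FALSE, nrow(counts)),
                     cluster = NULL) {
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(mito_flag = mito_flag))
  if (!is.null(cluster)) SummarizedExperiment::colData(sce)$cluster <- cluster
  sce
}

test_that("cell QC removes violators with per-rule reasons", {
  n_genes <- 400
  mito <- c(rep(TRUE, 20), rep(FALSE, n_genes - 20))
  mk_cell <- function(depth, n_expr, mito_frac) {
    x <- numeric(n_genes)
    idx <- seq(21, 20 + n_expr)
    x[idx] <- diff(round(seq(0, depth * (1 - mito_frac), length.out = n_expr + 1)))
    x[1:20] <- diff(round(seq(0, depth * mito_frac, length.out = 21)))
    x
  }
  counts <- cbind(
    good = mk_cell(2000, 350, 0.05),
    low_genes = mk_cell(2000, 150, 0.05),
    low_counts = mk_cell(250, 200, 0),
    mito_exact = mk_cell(2000, 300, 0),   # raised to exactly 0.10 below
    mito_high = mk_cell(2000, 300, 0.2))
  # build a cell with mitochondrial fraction exactly 0.10
  counts[, "mito_exact"] <- 0
  counts[1, "mito_exact"] <- 200
  counts[21:320, "mito_exact"] <- 6  # 1800 non-mito
  rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  sce <- make_sce(counts, mito)
  out <- qc_filter_cells(sce)
  rep <- out$report
  expect_false(rep$removed[rep$cell_barcode == "good"])
  expect_match(rep$reasons[rep$cell_barcode == "low_genes"], "min-genes")
  expect_match(rep$reasons[rep$cell_barcode == "low_counts"], "min-counts")
  expect_match(rep$reasons[rep$cell_barcode == "low_counts"], "min-umis")
  # the mito rule is strictly > 10%: exactly 0.10 is kept
  expect_equal(rep$pct_mito[rep$cell_barcode == "mito_exact"], 0.10)
  expect_false(grepl("max-mito", rep$reasons[rep$cell_barcode == "mito_exact"]))
  expect_match(rep$reasons[rep$cell_barcode == "mito_high"], "max-mito")
  expect_equal(sort(colnames(out$kept)), sort(c("good", "mito_exact")))
  # kept/removed partition the cells and reasons reproduce the decision
  expect_equal(ncol(out$kept) + sum(rep$removed), ncol(sce))
  expect_identical(rep$removed, nzchar(rep$reasons))
})

test_that("the upper gene-diversity threshold is enforced", {
  n_genes <- 10001
  counts <- Matrix::sparseMatrix(
    i = c(seq_len(n_genes), 1:300),
    j = c(rep(1L, n_genes), rep(2L, 300)),
    x = 1, dims = c(n_genes, 2))
  counts[1, ] <- counts[1, ] + 2000  # keep totals above the floors
  rownames(counts) <- sprintf("G%05d", seq_len(n_genes))
  colnames(counts) <- c("busy", "normal")
  sce <- make_sce(counts)
  rep <- qc_filter_cells(sce)$report
  expect_match(rep$reasons[rep$cell_barcode == "busy"], "max-genes")
  expect_false(rep$removed[rep$cell_barcode == "normal"])
})

test_that("median-depth log normalization is deterministic and depth-invariant", {
  counts <- cbind(a = c(10, 0, 5), b = c(20, 0, 10), c = c(0, 0, 0),
                  d = c(4, 4, 4))
  rownames(counts) <- c("g1", "g2", "g3")
  sce <- normalize_log(make_sce(counts))
  norm <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  # independent recomputation
  depth <- colSums(counts)
  target <- median(depth[depth > 0])
  expected <- log1p(sweep(counts, 2, ifelse(depth > 0, depth / target, 1), "/"))
  expect_equal(norm, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # all-zero cell stays all-zero
  expect_true(all(norm[, "c"] == 0))
  # doubling a cell's counts leaves its profile unchanged
  expect_equal(norm[, "a"], norm[, "b"], tolerance = 1e-12)
})

test_that("DEG p-values match wilcox.test and prefilters apply", {
  set.seed(101)
  n1 <- 40; n2 <- 60
  counts <- matrix(rnbinom(30 * (n1 + n2), mu = 8, size = 2), nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30), NULL))
  counts[1:5, seq_len(n1)] <- counts[1:5, seq_len(n1)] + 20
  colnames(counts) <- sprintf("c%03d", seq_len(n1 + n2))
  cl <- rep(c("A", "B"), c(n1, n2))
  sce <- normalize_log(make_sce(counts, cluster = cl))
  degs <- find_degs(sce, profile = "global", significant_only = FALSE)
  X <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  for (i in seq_len(nrow(degs))) {
    g <- degs$gene[i]
    idx <- which(cl == degs$cluster[i])
    w <- wilcox.test(X[g, idx], X[g, -idx], exact = FALSE, correct = FALSE)
    expect_equal(degs$p[i], w$p.value, tolerance = 1e-8)
  }
  # Bonferroni against the full panel and positive direction only
  expect_true(all(degs$p_adj >= pmin(1, degs$p * nrow(sce)) - 1e-12))
  expect_true(all(degs$log_fc > 0))

  # a gene detected in 5% of cells on both sides is excluded under global
  sparse_counts <- matrix(0, nrow = 2, ncol = 100,
                          dimnames = list(c("rare", "common"), NULL))
  sparse_counts["rare", c(1:3, 51:52)] <- 5
  sparse_counts["common", ] <- rnbinom(100, mu = 10, size = 2) + 1
  colnames(sparse_counts) <- sprintf("s%03d", 1:100)
  sce2 <- normalize_log(make_sce(sparse_counts,
                                 cluster = rep(c("A", "B"), each = 50)))
  d2 <- find_degs(sce2, profile = "global", significant_only = FALSE)
  expect_false("rare" %in% d2$gene)
})

test_that("planted programs are recovered and permuted labels yield none", {
  # recovery property holds at >= 100 cells per cluster and log2FC 2
  cfg <- small_cfg(seed = 61, n_cells_per_group = c(
    tumor = 300L, panin = 20L, adm = 10L, normal_duct = 20L, acinar = 10L))
  sce <- simulate_expression(cfg)
  keep <- qc_filter_cells(sce)$kept
  tum <- normalize_log(keep[, SummarizedExperiment::colData(keep)$group == "tumor"])
  cl <- SummarizedExperiment::colData(tum)$cluster
  degs <- find_degs(tum, clusters = cl, profile = "subcluster")
  programs <- S4Vectors::metadata(sce)$programs
  for (k in names(programs)) {
    hit <- mean(programs[[k]] %in% degs$gene[degs$cluster == k])
    expect_gte(hit, 0.9)
  }
  # permuted labels: expected significant count ~ 0
  perm <- withr::with_seed(1, sample(cl))
  d0 <- find_degs(tum, clusters = perm, profile = "subcluster")
  expect_lte(nrow(d0), 3L)
})

test_that("hypergeometric ORA is exact and handles degenerate inputs", {
  universe <- sprintf("u%02d", 1:10)
  sets <- list(S = universe[1:5])
  # overlap 4 of 4 drawn from universe 10 with 5 marked: 5/210
  res <- ora_hypergeometric(universe[1:4], sets, universe)
  expect_equal(res$p, 5 / 210, tolerance = 1e-14)
  expect_equal(res$overlap, 4L)
  expect_equal(res$overlap_genes[[1]], universe[1:4])
  # deg = universe forces every overlap: p = 1
  res <- ora_hypergeometric(universe, sets, universe)
  expect_equal(res$p, 1)
  # zero overlap is never enriched
  res <- ora_hypergeometric(universe[6:9], sets, universe)
  expect_gte(res$p, 1 - 1e-12)
  # genes outside the universe are dropped with a warning
  expect_warning(ora_hypergeometric(c("alien", universe[1]), sets, universe),
                 "outside the universe")
  # empty deg list gives an empty result
  expect_equal(nrow(suppressWarnings(
    ora_hypergeometric(character(), sets, universe))), 0L)
})

test_that("pathway scores are centered/scaled and peak in the planted cluster", {
  # center/scale arithmetic: cluster means (1,2,3) -> (-1,0,1)
  n_cells <- 30
  cl <- rep(c("C1", "C2", "C3"), each = 10)
  X <- matrix(0, nrow = 2, ncol = n_cells,
              dimnames = list(c("gA", "gB"), sprintf("c%02d", 1:n_cells)))
  X[, cl == "C1"] <- expm1(1); X[, cl == "C2"] <- expm1(2)
  X[, cl == "C3"] <- expm1(3)
  counts <- matrix(1, 2, n_cells, dimnames = dimnames(X))
  sce <- make_sce(counts, cluster = cl)
  SummarizedExperiment::assay(sce, "logcounts") <- log1p(X)
  enr <- data.frame(cluster = "C1", pathway = c("P", "FLAT"),
                    p_adj = 0.001, overlap = 2L)
  enr$overlap_genes <- list(c("gA", "gB"), c("gA", "gB"))
  ps <- pathway_scores(sce, enrichment = enr)
  expect_equal(unname(ps$scores["P", c("C1", "C2", "C3")]), c(-1, 0, 1))
  # constant rows score zero and are flagged
  sce0 <- sce
  SummarizedExperiment::assay(sce0, "logcounts")[] <- 1
  ps0 <- pathway_scores(sce0, enrichment = enr)
  expect_true(all(ps0$scores == 0))
  expect_true(all(ps0$constant))

  # planted program attains its maximum score in the planted cluster
  cfg <- small_cfg(seed = 71)
  full <- simulate_expression(cfg)
  keep <- qc_filter_cells(full)$kept
  tum <- normalize_log(keep[, SummarizedExperiment::colData(keep)$group == "tumor"])
  clu <- SummarizedExperiment::colData(tum)$cluster
  degs <- find_degs(tum, clusters = clu, profile = "subcluster")
  programs <- S4Vectors::metadata(full)$programs
  sets <- c(stats::setNames(programs, paste0("HALLMARK_", names(programs))),
            list(HALLMARK_RANDOM = rownames(tum)[1:30]))
  enr <- ora_by_cluster(degs, sets, universe = rownames(tum))
  ps <- pathway_scores(tum, clusters = clu, enrichment = enr)
  for (k in names(programs)) {
    pw <- paste0("HALLMARK_", k)
    expect_equal(names(which.max(ps$scores[pw, ])), k)
  }
  # contract: non-constant rows have mean 0 and sample sd 1
  nc <- ps$scores[!ps$constant, , drop = FALSE]
  expect_true(all(abs(rowMeans(nc)) < 1e-9))
  expect_true(all(abs(apply(nc, 1, sd) - 1) < 1e-9))
})

test_that("spatially distinct clusters require 95% dominance and 6 mm", {
  geo <- data.frame(sample_id = c("P1", "P2"), x_mm = c(0, 6), y_mm = 0)
  mk <- function(n1, n2) c(rep("P1", n1), rep("P2", n2))
  # 96/100 from P1 at exactly 6 mm: distinct (both boundaries inclusive)
  out <- spatial_distinct_clusters(rep("k", 100), mk(96, 4), geo)
  expect_true(out$distinct)
  expect_equal(out$dominant_sample, "P1")
  # 94/100 fails the fraction rule
  expect_false(spatial_distinct_clusters(rep("k", 100), mk(94, 6), geo)$distinct)
  # 98/100 but only 2 mm apart fails the distance rule
  geo2 <- data.frame(sample_id = c("P1", "P2"), x_mm = c(0, 2), y_mm = 0)
  expect_false(spatial_distinct_clusters(rep("k", 100), mk(98, 2), geo2)$distinct)
  # missing coordinates are an error naming the sample
  expect_error(spatial_distinct_clusters(rep("k", 2), c("P1", "P9"), geo),
               "P9")
})

test_that("FPKM-UQ follows the GDC formula and is depth-invariant", {
  counts <- cbind(s1 = c(100, 0, 1000, 2000), s2 = c(200, 0, 2000, 4000))
  rownames(counts) <- c("g1", "g2", "g3", "g4")
  lengths <- c(g1 = 1000, g2 = 500, g3 = 2000, g4 = 1500)
  out <- fpkm_uq_transform(counts, lengths)
  uq1 <- quantile(c(100, 1000, 2000), 0.75, names = FALSE)
  expect_equal(out["g1", "s1"], log2(100 * 1e9 / (1000 * uq1) + 1))
  # zero count maps to log2(1) = 0
  expect_equal(out["g2", "s1"], 0)
  # doubling all counts of a sample leaves FPKM-UQ unchanged
  expect_equal(out[, "s1"], out[, "s2"], tolerance = 1e-12)
  # the worked example: count 100, length 1,000 bp, UQ 1,000
  one <- fpkm_uq_transform(matrix(c(100, 1000, 1000, 1000), 4, 1,
                                  dimnames = list(c("a", "b", "c", "d"), "s")),
                           c(a = 1000, b = 3000, c = 3000, d = 3000))
  expect_equal(one["a", "s"], log2(1e5 + 1))
  # a zero-UQ sample is reported unusable
  expect_warning(z <- fpkm_uq_transform(matrix(0, 2, 1), c(100, 100)),
                 "unusable")
  expect_true(all(is.na(z)))
})
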