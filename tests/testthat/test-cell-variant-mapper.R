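obs_row <- function(cell, umi, allele, chrom = "12", pos = 100L) {
  data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
             cell_barcode = cell, umi = umi, observed_allele = allele,
             stringsAsFactors = FALSE)
}

test_that("UMI consensus collapses duplicates by strict majority", {
  obs <- rbind(obs_row("cellA", "u1", "alt"), obs_row("cellA", "u1", "alt"),
               obs_row("cellA", "u2", "ref"))
  out <- dedup_umis(obs)
  expect_equal(out$alt_molecules, 1L)
  expect_equal(out$ref_molecules, 1L)
  expect_equal(out$discarded_umis, 0L)
  expect_equal(classify_cells(out)$label, "variant_reference")

  # exact tie discards the molecule but keeps the accounting
  tie <- rbind(obs_row("cellA", "u1", "alt"), obs_row("cellA", "u1", "ref"))
  out <- dedup_umis(tie)
  expect_equal(out$discarded_umis, 1L)
  expect_equal(out$ref_molecules + out$alt_molecules, 0L)

  # a majority of "other" also discards
  oth <- rbind(obs_row("cellA", "u1", "other"), obs_row("cellA", "u1", "other"),
               obs_row("cellA", "u1", "alt"))
  expect_equal(dedup_umis(oth)$discarded_umis, 1L)

  # without collapsing, every read is a molecule
  raw <- dedup_umis(obs, collapse = FALSE)
  expect_equal(raw$alt_molecules, 2L)
  expect_equal(raw$ref_molecules, 1L)

  expect_equal(nrow(dedup_umis(obs[0, ])), 0L)
})

test_that("molecule accounting conserves distinct UMIs", {
  cfg <- small_cfg(seed = 17, allele_error_rate = 0.15, umi_dup_rate = 0.5)
  sim <- simulate_read_observations(cfg)
  counts <- dedup_umis(sim$observations)
  umis <- aggregate(
    umi ~ cell_barcode + chrom + pos,
    data = unique(sim$observations[, c("cell_barcode", "chrom", "pos", "umi")]),
    FUN = length)
  m <- merge(counts, umis, by = c("cell_barcode", "chrom", "pos"))
  expect_equal(nrow(m), nrow(counts))
  expect_equal(m$ref_molecules + m$alt_molecules + m$discarded_umis, m$umi)
})

test_that("counts recover generator truth exactly at zero error rate", {
  cfg <- small_cfg(seed = 19, allele_error_rate = 0)
  sim <- simulate_read_observations(cfg)
  counts <- dedup_umis(sim$observations)
  v <- sim$variants
  counts$site_id <- v$site_id[match(paste(counts$chrom, counts$pos),
                                    paste(v$chrom, v$pos))]
  m <- merge(sim$truth, counts, by = c("cell_barcode", "site_id"),
             all.x = TRUE)
  m$ref_molecules[is.na(m$ref_molecules)] <- 0L
  m$alt_molecules[is.na(m$alt_molecules)] <- 0L
  expect_true(all(m$ref_molecules == m$true_ref_molecules))
  expect_true(all(m$alt_molecules == m$true_alt_molecules))
})

test_that("classification is invariant to row permutation", {
  cfg <- small_cfg(seed = 23)
  sim <- simulate_read_observations(cfg)
  a <- dedup_umis(sim$observations)
  perm <- sim$observations[sample(nrow(sim$observations)), ]
  b <- dedup_umis(perm)
  expect_identical(a, b)
})

test_that("cells are classified by supporting molecules", {
  counts <- data.frame(cell_barcode = c("a", "b", "c", "d"),
                       chrom = "1", pos = 1L, ref = "G", alt = "A",
                       ref_molecules = c(3L, 0L, 1L, 0L),
                       alt_molecules = c(0L, 2L, 1L, 0L),
                       discarded_umis = 0L)
  lab <- classify_cells(counts)
  expect_equal(lab$label, c("reference", "variant", "variant_reference",
                            "none"))
  # a higher molecule threshold demotes single-molecule support
  lab2 <- classify_cells(counts, min_molecules = 2L)
  expect_equal(lab2$label, c("reference", "variant", "none", "none"))
})

test_that("hierarchical labels rank mutations above CNVs and KRAS first", {
  ev <- data.frame(
    cell_barcode = c("c1", "c1", "c2", "c2", "c3", "c4", "c4"),
    gene = c("CDKN2A", "KRAS", "KRAS", "TP53", "SMAD4", "ZFP1", "AKT2"),
    kind = c("mutation", "cnv_gain", "mutation", "mutation", "cnv_loss",
             "mutation", "mutation"),
    stringsAsFactors = FALSE)
  out <- label_cells_hierarchical(ev)
  lab <- setNames(out$display_label, out$cell_barcode)
  # a mutation beats a copy-number event even for a higher-ranked gene
  expect_equal(lab[["c1"]], "CDKN2A mutation")
  # KRAS outranks TP53 within mutations
  expect_equal(lab[["c2"]], "KRAS mutation")
  # single event labels directly
  expect_equal(lab[["c3"]], "SMAD4 cnv_loss")
  # genes outside the hierarchy rank after it, alphabetically
  expect_equal(lab[["c4"]], "AKT2 mutation")
  expect_equal(nrow(out), 4L)
})

test_that("minority hotspot detection reports aggregate VAFs and NA coverage", {
  obs <- rbind(obs_row("c1", "u1", "alt"), obs_row("c1", "u2", "ref"),
               obs_row("c2", "u1", "ref"), obs_row("c3", "u1", "ref"),
               obs_row("c4", "u1", "ref", pos = 101L))
  sites <- data.frame(chrom = "12", pos = c(100L, 102L))
  samples <- data.frame(cell_barcode = c("c1", "c2", "c3", "c4"),
                        sample_id = c("S1", "S1", "S2", "S1"))
  out <- detect_minority_hotspots(obs, sites, samples)
  s1 <- out$sample_vafs[out$sample_vafs$sample_id == "S1" &
                          out$sample_vafs$pos == 100L, ]
  expect_equal(s1$vaf, 1 / 3)            # 1 alt / (1 alt + 2 ref) pooled
  expect_equal(s1$n_cells_alt, 1L)
  s2 <- out$sample_vafs[out$sample_vafs$sample_id == "S2" &
                          out$sample_vafs$pos == 100L, ]
  expect_equal(s2$vaf, 0)                # all-reference coverage
  # site 102 has no coverage anywhere: NA, and off-target site 101 ignored
  nc <- out$sample_vafs[out$sample_vafs$pos == 102L, ]
  expect_true(all(is.na(nc$vaf)))
  expect_false(101L %in% out$sample_vafs$pos)
})
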