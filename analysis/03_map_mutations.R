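#!/usr/bin/env Rscript
# Stage 3: trace cell barcodes and UMIs through the read observations at
# the high-confidence variant sites, collapse to molecules by per-UMI
# majority consensus, classify cells as reference / variant /
# variant_reference, and scan hotspot sites for minority mutations.

suppressMessages(library(scvarmap))

obs <- read_observations("results/cohort/observations.tsv")
cells <- as.data.frame(data.table::fread("results/cohort/cells.tsv"))
variants <- as.data.frame(data.table::fread(
  "results/cohort/variants.tsv", colClasses = list(character = "chrom")))

counts <- dedup_umis(obs)
labels <- classify_cells(counts)
cat("cell x site pairs with coverage:", nrow(counts), "\n")
cat("molecules discarded by UMI-consensus ties:",
    sum(counts$discarded_umis), "\n")
print(table(labels$label))

data.table::fwrite(counts, "results/cell_allele_counts.tsv", sep = "\t")
data.table::fwrite(labels, "results/cell_genotype_labels.tsv", sep = "\t")

# minority-variant scan restricted to the first variant site per gene
hot_sites <- variants[variants$gene %in% c("KRAS"), c("chrom", "pos")]
mh <- detect_minority_hotspots(obs, hot_sites,
                               cells[, c("cell_barcode", "sample_id")])
cat("\nper-sample aggregate VAF at the KRAS site:\n")
print(mh$sample_vafs)
data.table::fwrite(mh$sample_vafs, "results/hotspot_sample_vafs.tsv",
                   sep = "\t")
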