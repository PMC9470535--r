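#!/usr/bin/env Rscript
# Stage 6: summarize the gene-level CNV matrix to chromosome arms, call
# deep (more-than-one-copy) events, and give each altered cell a single
# hierarchical display label (mutations over CNVs; KRAS > CDKN2A > SMAD4
# > TP53).

suppressMessages(library(scvarmap))

cnv <- as.data.frame(data.table::fread("results/cohort/cnv_matrix.tsv"))
mat <- as.matrix(cnv[, -1])
rownames(mat) <- cnv$cell_barcode
bands <- as.data.frame(data.table::fread(
  "results/cohort/band_table.tsv", colClasses = list(character = "chrom")))
cells <- as.data.frame(data.table::fread("results/cohort/cells.tsv"))

am <- map_genes_to_arms(colnames(mat), bands)
cat("genes mapped to arms:", nrow(am$map), "; unmapped:",
    length(am$unmapped), "(mitochondrial, no cytoband)\n")
arms <- arm_level_means(mat, am)
by_group <- aggregate(arms[, c("8q", "18q", "9p")],
                      by = list(group = cells$group[
                        match(rownames(arms), cells$cell_barcode)]), mean)
cat("\nmean arm value by compartment (1.0 = neutral):\n")
print(by_group, digits = 3)
write.table(arms, "results/arm_cnv.tsv", sep = "\t", quote = FALSE,
            col.names = NA)

deep <- call_deep_events(mat)
cat("\ndeep events:", nrow(deep), "\n")
print(table(deep$gene, deep$kind))
data.table::fwrite(deep, "results/deep_events.tsv", sep = "\t")

counts <- as.data.frame(data.table::fread(
  "results/cell_allele_counts.tsv", colClasses = list(character = "chrom")))
variants <- as.data.frame(data.table::fread(
  "results/cohort/variants.tsv", colClasses = list(character = "chrom")))
muts <- mutation_events(classify_cells(counts), variants)
disp <- label_cells_hierarchical(
  rbind(muts, deep[, c("cell_barcode", "gene", "kind")]))
cat("\nhierarchical display labels:\n")
print(sort(table(disp$display_label), decreasing = TRUE))
data.table::fwrite(disp, "results/cell_display_labels.tsv", sep = "\t")
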