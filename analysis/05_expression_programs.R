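#!/usr/bin/env Rscript
# Stage 5: cell QC, depth normalization, tumor-subcluster marker genes,
# hallmark-style over-representation, pathway scoring across subclusters
# and the spatially-distinct-cluster call.

suppressMessages(library(scvarmap))

sce <- read_expression_mtx("results/cohort/expression")
qc <- qc_filter_cells(sce)
cat(sprintf("QC: %d of %d cells removed\n", sum(qc$report$removed),
            ncol(sce)))
print(table(unlist(strsplit(qc$report$reasons[qc$report$removed], ";"))))
data.table::fwrite(qc$report, "results/qc_report.tsv", sep = "\t")

cd <- SummarizedExperiment::colData(qc$kept)
tum <- normalize_log(qc$kept[, cd$group == "tumor"])
cl <- SummarizedExperiment::colData(tum)$cluster

degs <- find_degs(tum, clusters = cl, profile = "subcluster")
cat("\nsubcluster markers (adjusted P < 0.05):", nrow(degs), "genes;",
    "top by fold change per cluster:\n")
print(do.call(rbind, lapply(split(degs, degs$cluster), head, 2)),
      digits = 3)
data.table::fwrite(degs, "results/subcluster_degs.tsv", sep = "\t")

# gene sets: the planted cluster programs act as the hallmark collection
# on synthetic data (plus a random decoy set)
programs <- S4Vectors::metadata(
  read_expression_mtx("results/cohort/expression"))$programs
features <- as.data.frame(data.table::fread(
  "results/cohort/expression/features.tsv", na.strings = ""))
sets <- lapply(split(features$symbol[!is.na(features$program)],
                     features$program[!is.na(features$program)]), identity)
names(sets) <- paste0("HALLMARK_", names(sets))
sets$HALLMARK_DECOY <- utils::tail(
  features$symbol[is.na(features$program)], 40)
write_gmt(sets, "results/gene_sets.gmt")
sets <- read_gmt("results/gene_sets.gmt")

universe <- rownames(tum)
enr <- ora_by_cluster(degs, sets, universe)
data.table::fwrite(enr[, setdiff(names(enr), "overlap_genes")],
                   "results/ora.tsv", sep = "\t")

ps <- pathway_scores(tum, clusters = cl, enrichment = enr)
cat("\npathway scores (centered/scaled across clusters):\n")
print(round(ps$scores, 2))
write.table(ps$scores, "results/pathway_scores.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

geo <- as.data.frame(data.table::fread("results/cohort/samples.tsv"))
cdt <- SummarizedExperiment::colData(tum)
sp <- spatial_distinct_clusters(cdt$cluster, cdt$sample_id, geo)
cat("\nspatially distinct subclusters (>=95% from one sample >=6 mm away):\n")
print(sp)
data.table::fwrite(sp, "results/spatial_distinct.tsv", sep = "\t")
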