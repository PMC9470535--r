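#!/usr/bin/env Rscript
# Stage 4: do mutations preferentially map to neoplastic cells? Pools
# molecule counts per compartment and applies the continuity-corrected
# difference-of-proportions Z test (one-sided, skipping contrasts where
# the test-group proportion does not exceed the comparison group), with
# BH adjustment over the performed tests.

suppressMessages(library(scvarmap))

counts <- as.data.frame(data.table::fread(
  "results/cell_allele_counts.tsv", colClasses = list(character = "chrom")))
cells <- as.data.frame(data.table::fread("results/cohort/cells.tsv"))

nontumor <- c("normal_duct", "acinar", "adm")
res <- run_group_tests(counts, cells[, c("cell_barcode", "group")],
                       list(list(t = "tumor", n = nontumor),
                            list(t = "panin", n = nontumor),
                            list(t = "tumor", n = "panin"),
                            list(t = "adm",   n = c("normal_duct", "acinar")),
                            list(t = "normal_duct", n = "acinar")))
print(res[, c("contrast", "X_T", "N_T", "X_N", "N_N", "P_T", "P_N", "Z",
              "p", "q", "performed", "reason")], digits = 4)
cat("\nOrdering of mapped-mutation proportions:",
    sprintf("tumor %.3f > PanIN %.3f > nontumor %.3f\n",
            res$P_T[1], res$P_T[2], res$P_N[1]))
data.table::fwrite(res, "results/mapping_enrichment.tsv", sep = "\t")
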