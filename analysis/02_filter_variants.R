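#!/usr/bin/env Rscript
# Stage 2: consensus filtering of the multi-caller somatic VCF and the
# germline call table, plus KRAS-hotspot-style VAF genotyping from base
# readcounts. Writes pass/fail tables with per-rule reasons.

suppressMessages(library(scvarmap))

som <- read_somatic_vcf("results/cohort/somatic.vcf")
fs <- filter_somatic(som)
cat(sprintf("somatic: %d records -> %d pass, %d fail\n",
            nrow(som), nrow(fs$pass), nrow(fs$fail)))
print(sort(table(unlist(strsplit(fs$fail$reasons, ";"))), decreasing = TRUE))
data.table::fwrite(fs$pass, "results/somatic_pass.tsv", sep = "\t")
data.table::fwrite(fs$fail, "results/somatic_fail.tsv", sep = "\t")

germ <- as.data.frame(data.table::fread("results/cohort/germline.tsv"))
fg <- filter_germline(germ)
cat(sprintf("germline: %d records -> %d pass, %d fail\n",
            nrow(germ), nrow(fg$pass), nrow(fg$fail)))
data.table::fwrite(fg$pass, "results/germline_pass.tsv", sep = "\t")
data.table::fwrite(fg$fail, "results/germline_fail.tsv", sep = "\t")

# hotspot VAF genotyping on an illustrative readcount table for the nine
# bases of KRAS codons G12/G13/Q61 (coordinates are configuration, not
# hard-coded; these are the GRCh38 positions)
hot <- data.frame(
  chrom = "12",
  pos = c(25245349:25245351, 25245346:25245348, 25227341:25227343),
  ref_base = c("C", "C", "G", "C", "T", "G", "T", "T", "G"),
  A = c(0L, 12L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
  C = c(188L, 180L, 0L, 190L, 0L, 0L, 0L, 0L, 0L),
  G = c(0L, 0L, 195L, 0L, 0L, 201L, 0L, 0L, 175L),
  T = c(0L, 0L, 0L, 0L, 199L, 0L, 185L, 180L, 0L))
hv <- hotspot_vafs(hot)
print(hv[!is.na(hv$vaf), ])
data.table::fwrite(hv, "results/hotspot_vafs.tsv", sep = "\t")
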