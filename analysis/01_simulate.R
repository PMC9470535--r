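#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-sample cohort (tumor / PanIN / ADM /
# normal duct / acinar compartments with planted mutation-mapping rates,
# multi-caller variant calls, cluster expression programs and CNV events)
# and write every pipeline input as plain text under results/cohort/.

suppressMessages(library(scvarmap))

cfg <- sim_config(seed = 1L)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("cells:           ", nrow(cohort$cells), "\n")
cat("  per group:     ",
    paste(names(table(cohort$cells$group)), table(cohort$cells$group),
          collapse = ", "), "\n")
cat("variant sites:   ", nrow(cohort$variants), "\n")
cat("read observations:", nrow(cohort$observations), "\n")
cat("somatic call set: ", nrow(cohort$somatic_calls), "records\n")
cat("germline call set:", nrow(cohort$germline_calls), "records\n")
cat("expression matrix:", nrow(cohort$sce), "genes x", ncol(cohort$sce),
    "cells\n")
cat("written to results/cohort/\n")
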