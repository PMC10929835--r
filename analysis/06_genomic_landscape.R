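#!/usr/bin/env Rscript
# Mutation and copy-number landscape of the cuproptosis regulators:
# the worked 390-sample fixture, the simulated cohort's MAF/CNV tables,
# pairwise mutual exclusivity, and PPI classification of regulator
# neighbours on a toy confidence-filtered edge list.

library(cupscore)

dir.create("results/landscape", showWarnings = FALSE)

## worked fixture (printed landscape)
ms <- mutation_summary(worked_mutation_fixture(), cuproptosis_panel, 390)
cat(sprintf("worked fixture: %d/%d samples carry a panel mutation (%.2f%%, %d events)\n",
            ms$panel_mutated_samples, ms$n_samples_total,
            ms$panel_alteration_freq_pct, ms$panel_mutation_events))
cat("most mutated regulator:", ms$per_gene$gene[1], "\n")
utils::write.table(ms$per_gene, "results/landscape/fixture_per_gene.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## simulated cohort
maf <- read_maf("results/cohort/mutations.maf")
cnv <- read_cnv("results/cohort/cnv_calls.tsv")
n_total <- 450
sim <- mutation_summary(maf, cuproptosis_panel, n_total)
cat(sprintf("simulated cohort: panel alteration %.2f%%; median TMB %d\n",
            sim$panel_alteration_freq_pct, stats::median(sim$tmb)))
fr <- cnv_frequency(cnv)
cat("CNV: amplification-led genes:",
    paste(fr$gene[fr$amp_pct > fr$del_pct], collapse = ", "), "\n")
utils::write.table(fr, "results/landscape/cnv_frequency.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

me <- mutual_exclusivity(maf, c(cuproptosis_panel[c(4, 12, 13)], "TP53"),
                         n_total)
cat("top mutual-exclusivity pair:\n")
print(me[which.min(me$p), c("gene_a", "gene_b", "odds_ratio", "p", "adj_p",
                            "direction")])
utils::write.table(me, "results/landscape/mutual_exclusivity.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## PPI classification on a toy confidence-filtered edge list
edges <- edge_table(
  gene_a = c("FDX1", "FDX1", "DLD", "DLAT", "SLC30A7", "GLUL", "ATP7A",
             "PGK1", "FDX1"),
  gene_b = c("SLC30A7", "GLUL", "PGK1", "PDHA1", "MT1X", "GS1", "ATP7B",
             "ENO1", "LIAS"),
  score = c(0.92, 0.85, 0.78, 0.95, 0.81, 0.75, 0.9, 0.72, 0.6))
cls <- ppi_classify(edges, cuproptosis_panel)
cat("direct regulators:", paste(cls$direct, collapse = ", "), "\n")
cat("indirect regulators:", paste(cls$indirect, collapse = ", "), "\n")
jsonlite::write_json(cls[c("direct", "indirect")],
                     "results/landscape/ppi_classes.json")
write_manifest("results/landscape/manifest.json",
               inputs = list(maf = "results/cohort/mutations.maf",
                             cnv = "results/cohort/cnv_calls.tsv"),
               params = list(min_score = 0.7, n_samples_total = n_total))
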