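#!/usr/bin/env Rscript
# Simulate the default synthetic glioblastoma-like cohort (450 samples,
# 3000 genes, three planted regulator-driven patterns, ~30% censoring) and
# write every artefact in its standard on-disk format.

library(cupscore)

seed <- 1L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()
coh <- generate_cohort(cfg, seed = seed)

write_expression(coh$expr, file.path(out_dir, "expression.tsv"))
write_clinical(coh$clinical, file.path(out_dir, "clinical.tsv"))
write_maf(coh$maf, file.path(out_dir, "mutations.maf"))
write_cnv(coh$cnv, file.path(out_dir, "cnv_calls.tsv"))
jsonlite::write_json(
  list(cluster = as.list(coh$truth$cluster),
       deg = coh$truth$deg, hazard_beta = coh$truth$hazard_beta,
       batch = as.list(coh$truth$batch)),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
write_manifest(file.path(out_dir, "manifest.json"),
               inputs = list(generator = "synthetic_config() defaults"),
               params = cfg[c("n_samples", "n_genes", "n_clusters", "sigma",
                              "censoring_rate")],
               seed = seed)

cat(sprintf("cohort: %d genes x %d samples; clusters %s; %.1f%% censored\n",
            length(coh$expr$gene_ids), length(coh$expr$sample_ids),
            paste(table(coh$truth$cluster), collapse = "/"),
            100 * mean(coh$clinical$event == 0)))
cat("artefacts written to", out_dir, "\n")
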