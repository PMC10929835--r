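#!/usr/bin/env Rscript
# Consensus-cluster the cohort on the 13-gene cuproptosis regulator panel,
# select k by PAC, and compare the patterns' survival by log-rank.

library(cupscore)

seed <- 1L
expr <- read_expression("results/cohort/expression.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json")
dir.create("results/patterns", showWarnings = FALSE)

cons <- consensus_cluster(expr, cuproptosis_panel, k_range = 2:6,
                          n_resamples = 1000, seed = seed)
print(cons)
cat("ARI vs planted truth:",
    round(adjusted_rand_index(cons$assignment,
                              unlist(truth$cluster)[names(cons$assignment)]),
          3), "\n")

tab <- cluster_survival_table(cons$assignment, clinical)
lr <- logrank(tab$groups)
cat(sprintf("cluster sizes %s (total %d); log-rank chisq %.1f, p %.2e\n",
            paste(tab$sizes, collapse = "/"), tab$total, lr$chisq, lr$p))

utils::write.table(
  data.frame(sample_id = names(cons$assignment),
             cupcluster = LETTERS[cons$assignment]),
  "results/patterns/assignment.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
jsonlite::write_json(
  list(pac = as.list(cons$pac), delta_area = as.list(cons$delta_area),
       chosen_k = cons$chosen_k, cluster_sizes = as.list(tab$sizes),
       logrank_chisq = lr$chisq, logrank_p = lr$p),
  "results/patterns/diagnostics.json", auto_unbox = TRUE, digits = NA)
for (k in names(cons$per_k))
  cupscore:::.write_matrix_tsv(cons$per_k[[k]]$matrix,
                               sprintf("results/patterns/consensus_k%s.tsv", k),
                               id_col = "sample_id")
write_manifest("results/patterns/manifest.json",
               inputs = list(expr = "results/cohort/expression.tsv"),
               params = list(k_range = "2:6", n_resamples = 1000,
                             subsample_frac = 0.8,
                             base = "hclust, 1-Pearson, average linkage"),
               seed = seed)
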