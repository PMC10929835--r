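#!/usr/bin/env Rscript
# Build the CupScore: univariate-Cox prognostic filtering of the overlap
# pool, LASSO-Cox sparsification, PCA scoring, maximally selected cutpoint,
# and the survival contrast of the low/high groups.

library(cupscore)

seed <- 1L
expr <- read_expression("results/cohort/expression.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
overlap <- readLines("results/degs/overlap_pool.txt")
truth <- jsonlite::read_json("results/cohort/truth.json")
dir.create("results/cupscore", showWarnings = FALSE)

prog <- prognostic_filter(expr$values[overlap, , drop = FALSE], clinical,
                          p_cut = 0.05)
cat(sprintf("prognostic filter: %d of %d overlap genes at Cox p < 0.05\n",
            length(prog$genes), length(overlap)))
utils::write.table(prog$fits, "results/cupscore/univariate_cox.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

pool <- lasso_select(expr$values[prog$genes, , drop = FALSE], clinical,
                     seed = seed)
cat(sprintf("LASSO support: %d genes%s\n", length(pool),
            if (attr(pool, "skipped")) " (selection skipped)" else ""))

model <- fit_cupscore(expr, as.character(pool),
                      orient_by = colMeans(expr$values[cuproptosis_panel, ]))
scores <- score_samples(model, expr)
groups <- assign_groups(scores, "auto", clinical, n_perm = 1000, seed = seed)
print(groups)
cat(sprintf("cutpoint %.4f (max standardized log-rank %.2f, perm p %.3g)\n",
            groups$cutpoint$threshold, groups$cutpoint$statistic,
            groups$cutpoint$p))

common <- intersect(names(scores), clinical$sample_id)
cl <- clinical[match(common, clinical$sample_id), ]
surv <- data.frame(time = cl$time, event = cl$event)
lr <- logrank(split(surv, groups$group[common]))
cat(sprintf("low vs high survival: log-rank chisq %.1f, p %.2e\n",
            lr$chisq, lr$p))
# horizons chosen inside the cohort's follow-up range
for (h in c(180, 365, 545)) {
  auc <- td_roc(scores[common], surv, h)$auc
  cat(sprintf("AUC(%d d) = %.3f\n", h, auc))
}
med <- tapply(scores, unlist(truth$cluster)[names(scores)], median)
cat("median CupScore by planted cluster:",
    paste(LETTERS[as.integer(names(med))], round(med, 2), sep = "=",
          collapse = ", "), "\n")

utils::write.table(
  data.frame(sample_id = names(scores), cupscore = scores,
             group = as.character(groups$group[names(scores)])),
  "results/cupscore/scores.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
jsonlite::write_json(
  list(genes = model$genes, mu = as.list(model$mu),
       sigma = as.list(model$sigma), w1 = as.list(model$w1),
       w2 = as.list(model$w2), cutoff = groups$cutoff,
       orientation = model$orientation),
  "results/cupscore/model.json", auto_unbox = TRUE, digits = NA)
write_manifest("results/cupscore/manifest.json",
               inputs = list(expr = "results/cohort/expression.tsv",
                             pool = "results/degs/overlap_pool.txt"),
               params = list(lasso = TRUE, cutoff = "auto", n_perm = 1000),
               seed = seed)
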