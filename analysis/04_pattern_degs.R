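#!/usr/bin/env Rscript
# Pattern DEG discovery: pairwise moderated-t between the consensus
# clusters (|log2FC| > 0.7, p < 0.05), the stricter adjusted-p overlap
# pool feeding the CupScore, and over-representation of the overlap pool
# in the synthetic signature sets.

library(cupscore)

expr <- read_expression("results/cohort/expression.tsv")
assign_tab <- utils::read.delim("results/patterns/assignment.tsv")
dir.create("results/degs", showWarnings = FALSE)

assignment <- stats::setNames(match(assign_tab$cupcluster, LETTERS),
                              assign_tab$sample_id)
pd <- pattern_degs(expr, assignment, lfc_cut = 0.7, p_cut = 0.05)
for (nm in names(pd$pairs)) {
  cat(sprintf("pair %s: %d genes pass |log2FC|>0.7 & p<0.05\n",
              nm, length(pd$pass[[nm]])))
  utils::write.table(pd$pairs[[nm]], sprintf("results/degs/deg_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("union of pairwise DEGs:", length(pd$union), "genes\n")

overlap <- overlap_degs(pd$pairs, adj_p_cut = 0.001)
cat("overlap pool (adj p < 0.001 in every pair):", length(overlap),
    "genes\n")
writeLines(overlap, "results/degs/overlap_pool.txt")

sets <- read_gmt("results/tme/signatures_synthetic.gmt")
enrich <- ora(overlap, sets, expr$gene_ids)
cat("over-representation of the overlap pool:\n")
print(enrich[, c("set", "overlap", "set_size", "p", "adj_p")])
utils::write.table(enrich, "results/degs/overlap_ora.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_manifest("results/degs/manifest.json",
               inputs = list(expr = "results/cohort/expression.tsv",
                             assignment = "results/patterns/assignment.tsv"),
               params = list(lfc_cut = 0.7, p_cut = 0.05, adj_p_cut = 0.001,
                             overlap = "intersection"))
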