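# Numeric mutation and copy-number landscape summaries, pairwise
# mutual-exclusivity testing, and PPI-based regulator classification.

#' Mutation landscape summary for a gene panel
#'
#' Samples absent from the MAF count as unmutated, so `n_samples_total`
#' may exceed the number of distinct samples carrying records. The panel
#' alteration frequency is the percentage of all samples carrying at least
#' one mutation in a panel gene (reported rounded to 2 decimals); the
#' number of panel mutation events is reported separately since a sample
#' can carry several.
#'
#' @param maf a `MafTable`.
#' @param panel character vector of panel genes (non-empty).
#' @param n_samples_total cohort size (>= distinct samples in the MAF).
#' @param capture_size_mb optional capture size to report TMB per megabase.
#' @return `MutationSummary` list: `per_gene` (count + frequency, ranked,
#'   ties alphabetical), `tmb` (per-sample mutation counts),
#'   `panel_mutated_samples`, `panel_mutation_events`,
#'   `panel_alteration_freq_pct` (rounded), `panel_alteration_freq_raw`.
#' @export
mutation_summary <- function(maf, panel, n_samples_total,
                             capture_size_mb = NULL) {
  if (length(panel) == 0) stopf("panel must be non-empty")
  n_obs <- length(unique(maf$sample_id))
  if (n_samples_total < n_obs)
    stopf("n_samples_total (%d) < distinct samples in MAF (%d)",
          n_samples_total, n_obs)
  in_panel <- maf$gene %in% panel
  per_gene <- data.frame(gene = panel, stringsAsFactors = FALSE)
  per_gene$mutated_samples <- vapply(panel, function(g)
    length(unique(maf$sample_id[maf$gene == g])), 0L)
  per_gene$freq_pct <- 100 * per_gene$mutated_samples / n_samples_total
  per_gene <- per_gene[order(-per_gene$mutated_samples, per_gene$gene), ]
  rownames(per_gene) <- NULL
  tmb <- table(maf$sample_id)
  tmb <- stats::setNames(as.integer(tmb), names(tmb))
  if (!is.null(capture_size_mb)) tmb <- tmb / capture_size_mb
  mutated <- unique(maf$sample_id[in_panel])
  freq <- 100 * length(mutated) / n_samples_total
  structure(list(per_gene = per_gene, tmb = tmb,
                 panel_mutated_samples = length(mutated),
                 panel_mutation_events = sum(in_panel),
                 panel_alteration_freq_pct = round(freq, 2),
                 panel_alteration_freq_raw = freq,
                 n_samples_total = n_samples_total),
            class = "MutationSummary")
}

#' Copy-number amplification/deletion frequencies
#'
#' @param cnv a `CnvCallTable` (genes x samples, calls in \{-1, 0, +1\}).
#' @return `CnvFrequency` data.frame: gene, amp_pct, del_pct.
#' @export
cnv_frequency <- function(cnv) {
  mat <- unclass(cnv)
  out <- data.frame(gene = rownames(mat),
                    amp_pct = 100 * rowMeans(mat == 1),
                    del_pct = 100 * rowMeans(mat == -1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CnvFrequency", "data.frame")
  out
}

#' Pairwise mutation mutual exclusivity / co-occurrence
#'
#' Two-sided Fisher exact test on the 2x2 mutated/unmutated table for each
#' gene pair, BH-adjusted across pairs. The direction comes from the
#' sample odds ratio: below 1 is mutually exclusive, above 1 co-occurring.
#' An infinite odds ratio (no discordant cells) is capped at 1e6 and
#' flagged.
#'
#' @param maf a `MafTable`.
#' @param genes >= 2 genes to test pairwise.
#' @param n_samples_total cohort size (unmutated samples included).
#' @return `CoOccurrence` data.frame: gene_a, gene_b, n11, n10, n01, n00,
#'   odds_ratio, or_capped, p, adj_p, direction.
#' @export
mutual_exclusivity <- function(maf, genes, n_samples_total) {
  if (length(genes) < 2) stopf(">= 2 genes required")
  n_obs <- length(unique(maf$sample_id))
  if (n_samples_total < n_obs)
    stopf("n_samples_total < distinct samples in MAF")
  mut <- lapply(genes, function(g) unique(maf$sample_id[maf$gene == g]))
  names(mut) <- genes
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- mut[[pr[1]]]; b <- mut[[pr[2]]]
    n11 <- length(intersect(a, b))
    n10 <- length(setdiff(a, b))
    n01 <- length(setdiff(b, a))
    n00 <- n_samples_total - n11 - n10 - n01
    tab <- matrix(c(n11, n10, n01, n00), 2)
    p <- stats::fisher.test(tab)$p.value
    or <- if (n10 * n01 == 0 && n11 * n00 == 0) 1
          else if (n10 * n01 == 0) Inf
          else n11 * n00 / (n10 * n01)
    capped <- is.infinite(or)
    data.frame(gene_a = pr[1], gene_b = pr[2], n11 = n11, n10 = n10,
               n01 = n01, n00 = n00,
               odds_ratio = if (capped) 1e6 else or, or_capped = capped,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, "BH")
  out$direction <- ifelse(out$odds_ratio < 1, "exclusive",
                          ifelse(out$odds_ratio > 1, "co-occurring", "none"))
  rownames(out) <- NULL
  class(out) <- c("CoOccurrence", "data.frame")
  out
}

#' Classify PPI neighbours of a seed panel
#'
#' One-hop neighbours of the seed genes are "direct" regulators; one-hop
#' neighbours of the direct genes that are neither seeds nor direct are
#' "indirect". The three classes are disjoint by construction, with
#' direct taking precedence, and the result does not depend on edge-list
#' row order. Edges are assumed already confidence-filtered by the reader.
#'
#' @param edges an `EdgeTable`.
#' @param seeds non-empty character vector of seed genes.
#' @return `PpiClassification` list: `seeds`, `direct`, `indirect`
#'   (sorted).
#' @export
ppi_classify <- function(edges, seeds) {
  if (length(seeds) == 0) stopf("seeds must be non-empty")
  seeds <- unique(seeds)
  neighbours <- function(of) {
    hit_a <- edges$gene_a %in% of
    hit_b <- edges$gene_b %in% of
    unique(c(edges$gene_b[hit_a], edges$gene_a[hit_b]))
  }
  direct <- sort(setdiff(neighbours(seeds), seeds))
  indirect <- sort(setdiff(neighbours(direct), c(seeds, direct)))
  structure(list(seeds = sort(seeds), direct = direct, indirect = indirect),
            class = "PpiClassification")
}
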