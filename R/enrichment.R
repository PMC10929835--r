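# Single-sample gene-set enrichment (ssGSEA) with unity normalisation,
# composite immune/stromal scores, and hypergeometric over-representation
# testing. Signature-set ssGSEA stands in for both per-cell-type
# deconvolution and pathway-level scoring; run manifests record the
# substitution.

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression in descending order (ties
#' broken by gene id for determinism). Walking down the ranked list, the
#' in-set cumulative weight \eqn{P_{in}(i)} accumulates rank weights
#' \eqn{r_g^\alpha} (r = rank position counted from the bottom of the
#' list) over set members seen so far, normalised by the set's total
#' weight, while \eqn{P_{out}(i)} is the fraction of non-members seen so
#' far. The raw enrichment score is \eqn{\sum_i (P_{in}(i) - P_{out}(i))}.
#' Raw scores are then min-max rescaled per set across samples to [0, 1]
#' ("normalised to a unity distribution"); a set with identical raw scores
#' in every sample maps to 0.5 by convention.
#'
#' Sets intersecting the matrix in fewer than 2 genes are skipped with a
#' warning; a set covering every gene in the matrix has no out-of-set walk
#' and is rejected.
#'
#' @param expr an [expression_matrix()].
#' @param gene_sets a `GeneSetCollection` (named list of gene ids).
#' @param alpha rank-weight exponent (0 = unweighted ranks; default 0.25).
#' @return an `EnrichmentMatrix`: list with `raw` and `norm` (sets x
#'   samples matrices) and `alpha`.
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25) {
  assert_expression_matrix(expr)
  if (length(gene_sets) == 0) stopf("empty gene-set collection")
  genes <- expr$gene_ids
  N <- length(genes)
  sets <- lapply(gene_sets, intersect, genes)
  sizes <- lengths(sets)
  if (any(sizes == N))
    stopf("set(s) covering the whole gene universe are not scoreable: %s",
          paste(names(sets)[sizes == N], collapse = ", "))
  skip <- sizes < 2
  if (any(skip)) {
    warnf("skipping %d set(s) with < 2 genes in the matrix: %s",
          sum(skip), paste(names(sets)[skip], collapse = ", "))
    sets <- sets[!skip]
  }
  if (length(sets) == 0) stopf("all gene sets were skipped")

  raw <- matrix(NA_real_, length(sets), ncol(expr$values),
                dimnames = list(names(sets), expr$sample_ids))
  member <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expr$values))) {
    x <- expr$values[, j]
    ord <- order(-x, genes)              # descending, gene-id tie-break
    r <- N:1                             # rank from the bottom at position i
    w <- r^alpha
    for (si in seq_along(sets)) {
      inset <- member[[si]][ord]
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / (N - sum(inset))
      raw[si, j] <- sum(p_in - p_out)
    }
  }
  rng_min <- apply(raw, 1, min)
  rng_max <- apply(raw, 1, max)
  span <- rng_max - rng_min
  norm <- (raw - rng_min) / ifelse(span > 0, span, 1)
  norm[span == 0, ] <- 0.5
  structure(list(raw = raw, norm = norm, alpha = alpha),
            class = "EnrichmentMatrix")
}

#' Composite enrichment score over a group of sets
#'
#' Per-sample mean of the normalised enrichment scores across the named
#' sets; with immune or stromal signature collections this yields the
#' immune and stromal composite scores used for tumour-microenvironment
#' characterisation.
#'
#' @param enrichment an `EnrichmentMatrix` from [ssgsea()].
#' @param set_group character vector of set names (subset of scored sets).
#' @return named per-sample numeric vector.
#' @export
composite_score <- function(enrichment, set_group) {
  if (length(set_group) == 0) stopf("set group is empty")
  missing <- setdiff(set_group, rownames(enrichment$norm))
  if (length(missing))
    stopf("set(s) not in the enrichment matrix: %s",
          paste(missing, collapse = ", "))
  colMeans(enrichment$norm[set_group, , drop = FALSE])
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p for each set's overlap with a query gene
#' list, Benjamini-Hochberg adjusted across sets. Query genes outside the
#' universe are dropped with a warning; sets with no member in the
#' universe are skipped.
#'
#' @param query_genes character vector of query gene ids.
#' @param gene_sets `GeneSetCollection`.
#' @param universe character vector of background gene ids.
#' @return `OraResult` data.frame: set, overlap, set_size, universe_size,
#'   p, adj_p; sorted by p.
#' @export
ora <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  U <- length(universe)
  q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    if (length(s) == 0) return(NULL)
    ov <- length(intersect(query, s))
    p <- stats::phyper(ov - 1, length(s), U - length(s), q,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               universe_size = U, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stopf("no set intersects the universe")
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("OraResult", "data.frame")
  out
}
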