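# Empirical-Bayes moderated two-group differential expression, threshold
# filtering of pattern DEGs, and the cross-pattern overlap-DEG extraction
# feeding the CupScore gene pool.

# invert the trigamma function by Newton iteration on 1/trigamma
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

.as_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x)) x
  else stopf("expected a matrix or ExpressionMatrix")
}

#' Moderated two-group t-test
#'
#' Per gene: ordinary mean difference (group1 - group2 on the log2 scale)
#' and pooled residual variance; gene-wise variances are shrunk toward a
#' common prior by empirical Bayes. The prior degrees of freedom d0 and
#' prior variance s0^2 are estimated by moment matching on the
#' log-variances (digamma/trigamma inversion); the posterior variance is
#' \eqn{(d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} and the moderated t is
#' referred to a t distribution on \eqn{d_0 + d_g} df, BH-adjusted across
#' genes.
#'
#' @param x genes x samples matrix or [expression_matrix()].
#' @param group_labels per-sample labels; exactly 2 groups, each >= 2
#'   samples. Fold changes are first level minus second (levels in the
#'   order of `unique(group_labels)`).
#' @param prior_df NULL (default) to estimate d0; 0 forces the ordinary
#'   pooled two-sample t; Inf fully shrinks to the common prior variance.
#' @return `DegTable` data.frame: gene, log2fc, t, p, adj_p, with
#'   attributes `d0`, `s0sq`.
#' @export
moderated_t <- function(x, group_labels, prior_df = NULL) {
  vals <- .as_values(x)
  lev <- unique(as.character(group_labels))
  if (length(lev) != 2) stopf("exactly 2 groups required, got %d", length(lev))
  i1 <- which(group_labels == lev[1])
  i2 <- which(group_labels == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 samples (got %d, %d)",
                              n1, n2)
  m1 <- rowMeans(vals[, i1, drop = FALSE])
  m2 <- rowMeans(vals[, i2, drop = FALSE])
  delta <- m1 - m2
  ss1 <- rowSums((vals[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((vals[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg

  if (is.null(prior_df)) {
    ok <- s2 > 0
    if (sum(ok) < 2) {
      d0 <- 0; s0sq <- NA_real_
    } else {
      z <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
      v <- stats::var(z)
      excess <- v - trigamma(dg / 2)
      if (is.na(excess) || excess <= 0) {
        d0 <- Inf
        s0sq <- exp(mean(z))
      } else {
        d0 <- 2 * .trigamma_inverse(excess)
        s0sq <- exp(mean(z) + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    d0 <- prior_df
    s0sq <- if (d0 > 0) exp(mean(log(s2[s2 > 0]))) else NA_real_
  }

  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0 & delta == 0] <- 1
  out <- data.frame(gene = rownames(vals), log2fc = delta, t = tstat, p = p,
                    adj_p = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "groups") <- lev
  class(out) <- c("DegTable", "data.frame")
  out
}

#' Pairwise pattern DEGs
#'
#' Runs the moderated t between every pair of clusters and filters each
#' pair at |log2FC| > `lfc_cut` and raw p < `p_cut`. Pairs involving a
#' single-sample cluster are skipped with a warning.
#'
#' @param x genes x samples matrix or [expression_matrix()].
#' @param assignment named cluster labels covering the samples of `x`.
#' @param lfc_cut absolute log2 fold-change threshold (default 0.7).
#' @param p_cut raw p threshold (default 0.05).
#' @return list with `pairs` (named list of `DegTable`s), `pass` (named
#'   list of passing gene vectors) and `union` (character vector).
#' @export
pattern_degs <- function(x, assignment, lfc_cut = 0.7, p_cut = 0.05) {
  vals <- .as_values(x)
  if (is.null(names(assignment))) stopf("assignment must be a named vector")
  common <- intersect(colnames(vals), names(assignment))
  vals <- vals[, common, drop = FALSE]
  lab <- assignment[common]
  lev <- sort(unique(lab))
  if (length(lev) < 2) stopf(">= 2 clusters required")
  pairs <- utils::combn(as.character(lev), 2, simplify = FALSE)
  tables <- list(); pass <- list()
  for (pr in pairs) {
    nm <- paste(pr, collapse = "_vs_")
    sel <- lab %in% pr
    if (min(table(lab[sel])) < 2) {
      warnf("pair %s skipped: a cluster has < 2 samples", nm)
      next
    }
    tab <- moderated_t(vals[, sel, drop = FALSE], lab[sel])
    tables[[nm]] <- tab
    pass[[nm]] <- tab$gene[abs(tab$log2fc) > lfc_cut & tab$p < p_cut]
  }
  if (length(tables) == 0) stopf("no comparable cluster pair")
  list(pairs = tables, pass = pass,
       union = sort(unique(unlist(pass, use.names = FALSE))))
}

#' Overlap DEGs across all pairwise comparisons
#'
#' Genes significant at BH-adjusted p < `adj_p_cut` in every pairwise
#' table (intersection semantics), sorted by their worst (maximum)
#' adjusted p ascending. An empty intersection is valid and returns an
#' empty vector with a warning.
#'
#' @param per_pair_tables list of `DegTable`s (>= 2).
#' @param adj_p_cut adjusted-p threshold (default 0.001).
#' @param method `"intersection"` (default) or `"union"` across pairs.
#' @return character vector of gene ids.
#' @export
overlap_degs <- function(per_pair_tables, adj_p_cut = 0.001,
                         method = c("intersection", "union")) {
  method <- match.arg(method)
  if (length(per_pair_tables) < 2) stopf(">= 2 per-pair tables required")
  sig <- lapply(per_pair_tables, function(tab)
    tab$gene[tab$adj_p < adj_p_cut])
  genes <- if (method == "intersection") Reduce(intersect, sig)
           else Reduce(union, sig)
  if (length(genes) == 0) {
    warnf("empty overlap DEG set")
    return(character())
  }
  adj_mat <- matrix(vapply(per_pair_tables, function(tab)
    tab$adj_p[match(genes, tab$gene)], numeric(length(genes))),
    nrow = length(genes))
  worst <- apply(adj_mat, 1, function(r) max(r, na.rm = TRUE))
  genes[order(worst, genes)]
}
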