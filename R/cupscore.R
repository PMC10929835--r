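# The CupScore: optional LASSO-Cox sparsification of the prognostic DEG
# pool, PCA of the z-scored pool, and the per-sample score defined as the
# sum of the sample's projections onto the first two principal axes,
# CupScore_s = sum_i (w1_i + w2_i) z_si.

#' LASSO-penalised Cox gene selection
#'
#' L1-penalised proportional-hazards coefficient path (cyclic coordinate
#' descent, via glmnet) with the penalty chosen by K-fold cross-validated
#' partial-likelihood deviance under the 1-SE rule. Returns the genes with
#' non-zero coefficients; if the chosen penalty leaves no gene, the full
#' input set is returned with a warning (selection stage skipped).
#'
#' @param x genes x samples matrix or [expression_matrix()].
#' @param clinical `ClinicalTable` sharing samples with `x`.
#' @param lambda_grid optional penalty grid (glmnet chooses its own path
#'   by default).
#' @param n_folds cross-validation folds (default 10).
#' @param seed fold-assignment seed.
#' @return character vector of selected genes (attribute `lambda` records
#'   the chosen penalty, `skipped` whether selection fell through).
#' @export
lasso_select <- function(x, clinical, lambda_grid = NULL, n_folds = 10,
                         seed = 1) {
  vals <- .as_values(x)
  if (nrow(vals) < 2) stopf(">= 2 genes required")
  common <- intersect(colnames(vals), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  if (sum(cl$event) < n_folds) stopf("need >= n_folds events")
  xmat <- t(vals[, common, drop = FALSE])
  y <- survival::Surv(cl$time, cl$event)
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(n_folds), length.out = length(common)))
  cv <- glmnet::cv.glmnet(xmat, y, family = "cox", foldid = foldid,
                          lambda = lambda_grid)
  support_at <- function(s) {
    beta <- as.matrix(stats::coef(cv, s = s))
    rownames(beta)[beta[, 1] != 0]
  }
  lambda <- cv$lambda.1se
  genes <- support_at("lambda.1se")
  if (length(genes) == 0) {           # 1-SE over-shrunk; fall back to the CV minimum
    genes <- support_at("lambda.min")
    lambda <- cv$lambda.min
  }
  skipped <- FALSE
  if (length(genes) == 0) {
    warnf("LASSO left an empty support at every candidate penalty; returning the full gene set")
    genes <- rownames(vals)
    skipped <- TRUE
  }
  attr(genes, "lambda") <- lambda
  attr(genes, "skipped") <- skipped
  genes
}

#' Fit the CupScore model
#'
#' z-scores each pool gene across training samples and takes the first two
#' right singular axes of the standardised samples x genes array. Each
#' axis is oriented so its largest-magnitude loading is positive; if
#' `orient_by` is supplied (typically the per-sample mean expression of
#' the regulator panel) and the resulting training score correlates
#' negatively with it, both axes are flipped together so a high score
#' means high regulator activity. Constant genes are dropped with a
#' warning.
#'
#' @param x genes x samples matrix or [expression_matrix()] (training).
#' @param gene_pool genes to build the score on (>= 2 after dropping
#'   constants; all must be present).
#' @param orient_by optional per-sample numeric used to fix the overall
#'   sign of the score.
#' @return `CupScoreModel`: genes, mu, sigma, w1, w2, sdev (singular
#'   values / sqrt(n-1)), `orientation` record.
#' @export
fit_cupscore <- function(x, gene_pool, orient_by = NULL) {
  vals <- .as_values(x)
  missing <- setdiff(gene_pool, rownames(vals))
  if (length(missing))
    stopf("pool genes missing from matrix: %s", paste(missing, collapse = ", "))
  if (ncol(vals) < 3) stopf(">= 3 samples required")
  sub <- vals[gene_pool, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant gene(s) from the pool", sum(sds == 0))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < 2) stopf("pool collapsed below 2 usable genes")
  mu <- rowMeans(sub)
  Z <- t((sub - mu) / sds)                      # samples x genes
  sv <- svd(Z)
  w1 <- sv$v[, 1]
  w2 <- if (ncol(sv$v) >= 2) sv$v[, 2] else rep(0, nrow(sub))
  flip_axis <- function(w) if (w[which.max(abs(w))] < 0) -w else w
  w1 <- flip_axis(w1); w2 <- flip_axis(w2)
  flipped <- FALSE
  if (!is.null(orient_by)) {
    s <- drop(Z %*% (w1 + w2))
    if (stats::cor(s, orient_by) < 0) {
      w1 <- -w1; w2 <- -w2; flipped <- TRUE
    }
  }
  structure(list(genes = rownames(sub), mu = mu, sigma = sds,
                 w1 = stats::setNames(w1, rownames(sub)),
                 w2 = stats::setNames(w2, rownames(sub)),
                 sdev = sv$d / sqrt(max(1, ncol(sub) - 1)),
                 orientation = list(rule = "largest-loading-positive",
                                    panel_flip = flipped)),
            class = "CupScoreModel")
}

#' Score samples with a CupScore model
#'
#' Applies the training centering/scaling, then
#' \eqn{score_s = \sum_i (w1_i + w2_i) z_{si}} - the sum of the sample's
#' projections onto the two leading axes. New cohorts are scored with the
#' training mu and sigma, so the model is portable.
#'
#' @param model a `CupScoreModel`.
#' @param x genes x samples matrix or [expression_matrix()].
#' @return named per-sample numeric score vector.
#' @export
score_samples <- function(model, x) {
  vals <- .as_values(x)
  missing <- setdiff(model$genes, rownames(vals))
  if (length(missing))
    stopf("model genes missing from matrix: %s", paste(missing, collapse = ", "))
  Z <- (vals[model$genes, , drop = FALSE] - model$mu) / model$sigma
  drop(crossprod(Z, model$w1 + model$w2))
}

#' Assign low/high score groups
#'
#' Samples with score strictly above the cutoff are "high". With
#' `cutoff = "auto"` the threshold comes from [best_cutpoint()] against
#' the supplied survival data.
#'
#' @param scores named per-sample scores.
#' @param cutoff numeric threshold or `"auto"`.
#' @param clinical `ClinicalTable` (required for `"auto"`), aligned by
#'   sample id.
#' @param ... passed to [best_cutpoint()].
#' @return `CupScoreResult`: scores, group factor (low/high), cutoff,
#'   sizes, and the `CutpointResult` when auto.
#' @export
assign_groups <- function(scores, cutoff, clinical = NULL, ...) {
  cut_res <- NULL
  if (identical(cutoff, "auto")) {
    if (is.null(clinical)) stopf("cutoff = 'auto' needs clinical data")
    common <- intersect(names(scores), clinical$sample_id)
    cl <- clinical[match(common, clinical$sample_id), ]
    cut_res <- best_cutpoint(scores[common],
                             data.frame(time = cl$time, event = cl$event),
                             ...)
    cutoff <- cut_res$threshold
  }
  if (!is.numeric(cutoff)) stopf("cutoff must be numeric or 'auto'")
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  sizes <- c(low = sum(group == "low"), high = sum(group == "high"))
  stopifnot(sum(sizes) == length(scores))
  structure(list(scores = scores, group = stats::setNames(group, names(scores)),
                 cutoff = cutoff, sizes = sizes, cutpoint = cut_res),
            class = "CupScoreResult")
}

#' @export
print.CupScoreResult <- function(x, ...) {
  cat(sprintf("CupScoreResult: %d low / %d high at cutoff %.4f (total %d)\n",
              x$sizes["low"], x$sizes["high"], x$cutoff, sum(x$sizes)))
  invisible(x)
}

#' Run the full cuproptosis-pattern pipeline on one cohort
#'
#' Consensus-clusters the cohort on the regulator panel, finds pairwise
#' pattern DEGs, extracts the overlap DEGs (adjusted p intersection),
#' filters them for prognosis by univariate Cox, optionally sparsifies by
#' LASSO-Cox, fits the CupScore model (oriented so high score tracks high
#' regulator expression), scores every sample, splits at the maximally
#' selected cutpoint and tests the split by log-rank.
#'
#' @param expr an [expression_matrix()].
#' @param clinical a `ClinicalTable`.
#' @param panel regulator gene panel.
#' @param k_range candidate cluster counts.
#' @param n_resamples consensus resamples.
#' @param seed seed driving consensus resampling, LASSO folds and the
#'   cutpoint permutations.
#' @param lasso run the LASSO stage (default TRUE).
#' @param lfc_cut,p_cut pairwise DEG thresholds.
#' @param adj_p_cut overlap-DEG adjusted-p threshold.
#' @param prog_p_cut prognostic-filter threshold.
#' @param n_perm cutpoint permutations.
#' @return list with `consensus`, `cluster_table`, `degs`, `overlap`,
#'   `prognostic`, `pool`, `model`, `scores`, `groups`, `logrank`.
#' @export
run_cupscore_pipeline <- function(expr, clinical, panel = cuproptosis_panel,
                                  k_range = 2:6, n_resamples = 200, seed = 1,
                                  lasso = TRUE, lfc_cut = 0.7, p_cut = 0.05,
                                  adj_p_cut = 0.001, prog_p_cut = 0.05,
                                  n_perm = 200) {
  cons <- consensus_cluster(expr, panel, k_range = k_range,
                            n_resamples = n_resamples, seed = seed)
  ctab <- cluster_survival_table(cons$assignment, clinical)
  degs <- pattern_degs(expr, cons$assignment, lfc_cut = lfc_cut, p_cut = p_cut)
  overlap <- overlap_degs(degs$pairs, adj_p_cut = adj_p_cut)
  if (length(overlap) < 2)
    stopf("overlap DEG pool too small (%d genes)", length(overlap))
  prog <- prognostic_filter(expr$values[overlap, , drop = FALSE], clinical,
                            p_cut = prog_p_cut)
  pool <- prog$genes
  if (length(pool) < 2) {
    warnf("prognostic filter left %d gene(s); falling back to the overlap pool",
          length(pool))
    pool <- overlap
  }
  if (lasso && length(pool) > 2) {
    pool2 <- lasso_select(expr$values[pool, , drop = FALSE], clinical,
                          seed = seed)
    if (length(pool2) >= 2) pool <- as.character(pool2)
  }
  panel_mean <- colMeans(panel_submatrix(expr, panel))
  model <- fit_cupscore(expr, pool, orient_by = panel_mean)
  scores <- score_samples(model, expr)
  groups <- assign_groups(scores, "auto", clinical, n_perm = n_perm,
                          seed = seed)
  common <- intersect(names(scores), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  lr <- logrank(split(data.frame(time = cl$time, event = cl$event),
                      groups$group[common]))
  list(consensus = cons, cluster_table = ctab, degs = degs,
       overlap = overlap, prognostic = prog, pool = pool, model = model,
       scores = scores, groups = groups, logrank = lr)
}
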