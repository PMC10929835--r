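# Resampling-based consensus clustering of samples on a gene panel, with
# PAC-based selection of the cluster count and stability diagnostics.

#' Consensus clustering on a gene panel
#'
#' For each of `n_resamples` resamples, a fraction of samples is drawn
#' without replacement and clustered on the panel submatrix (agglomerative,
#' distance 1 - Pearson correlation between sample profiles, average
#' linkage by default; k-means on the panel profiles as an alternative).
#' The consensus index of a sample pair is the number of times it
#' co-clustered divided by the number of times it was co-sampled. The
#' cluster count is chosen by minimising PAC = CDF(0.9) - CDF(0.1) of the
#' consensus entries over `k_range`; the delta-area series of the
#' consensus CDF is reported alongside. The final assignment comes from
#' average-linkage clustering of 1 - consensus at the chosen k, with
#' cluster labels relabelled so mean panel expression rises with the label
#' (label 1 = lowest regulator expression, label k = highest).
#'
#' @param expr an [expression_matrix()] (log2 scale).
#' @param panel_genes gene panel to cluster on (>= 2 genes, all present).
#' @param k_range integer vector of candidate cluster counts.
#' @param n_resamples number of resampling iterations (>= 2; 1000 mirrors
#'   the usual practice for a stable classification).
#' @param subsample_frac fraction of samples drawn per resample (0 < f < 1).
#' @param seed integer seed; fixes the resampling stream.
#' @param base_method `"hclust"` (default) or `"kmeans"`.
#' @return a `ConsensusResult`: `per_k` (per-k consensus matrix, co-sample
#'   counts, CDF grid, PAC), `pac`, `delta_area`, `chosen_k`, `assignment`
#'   (named integer vector).
#' @export
consensus_cluster <- function(expr, panel_genes, k_range = 2:6,
                              n_resamples = 1000, subsample_frac = 0.8,
                              seed = 1,
                              base_method = c("hclust", "kmeans")) {
  base_method <- match.arg(base_method)
  X <- panel_submatrix(expr, panel_genes)
  if (length(panel_genes) < 2) stopf("panel must contain >= 2 genes")
  if (n_resamples < 2) stopf("n_resamples must be >= 2")
  if (subsample_frac <= 0 || subsample_frac >= 1)
    stopf("subsample_frac must lie in (0, 1)")
  n <- ncol(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= n) stopf("k_max (%d) must be < n_samples (%d)",
                               max(k_range), n)
  m <- ceiling(subsample_frac * n)

  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)

  set.seed(as.integer(seed))
  for (r in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    sub <- X[, idx, drop = FALSE]
    if (base_method == "hclust") {
      hc <- stats::hclust(stats::as.dist(1 - stats::cor(sub)),
                          method = "average")
      labels_by_k <- lapply(k_range, function(k) stats::cutree(hc, k))
    } else {
      labels_by_k <- lapply(k_range, function(k)
        stats::kmeans(t(sub), centers = k, nstart = 3)$cluster)
    }
    for (ki in seq_along(k_range)) {
      lab <- labels_by_k[[ki]]
      for (g in unique(lab)) {
        mem <- idx[lab == g]
        co_clustered[[ki]][mem, mem] <- co_clustered[[ki]][mem, mem] + 1
      }
    }
  }

  per_k <- list()
  pac <- numeric(length(k_range))
  area <- numeric(length(k_range))
  ut <- upper.tri(co_sampled)
  for (ki in seq_along(k_range)) {
    cons <- ifelse(co_sampled > 0, co_clustered[[ki]] / pmax(co_sampled, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(expr$sample_ids, expr$sample_ids)
    entries <- sort(cons[ut])
    cdf <- stats::ecdf(entries)
    pac[ki] <- cdf(0.9) - cdf(0.1)
    # area under the consensus CDF over [0, 1]
    xs <- c(0, entries, 1)
    Fx <- c(0, cdf(entries), 1)
    area[ki] <- sum(diff(xs) * Fx[-length(Fx)])
    per_k[[as.character(k_range[ki])]] <- list(
      k = k_range[ki], matrix = cons, co_sampled = co_sampled,
      pac = pac[ki], cdf = cdf)
  }
  delta_area <- c(area[1], diff(area) / area[-length(area)])
  names(pac) <- names(delta_area) <- as.character(k_range)

  # ties in minimal PAC (e.g. perfectly stable coarse merges of clean
  # data give PAC = 0 below the true k as well) resolve to the largest k:
  # the finest partition whose consensus stays unambiguous
  chosen_k <- max(k_range[pac == min(pac)])
  cons <- per_k[[as.character(chosen_k)]]$matrix
  final_hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  assignment <- stats::cutree(final_hc, chosen_k)
  assignment <- .relabel_by_panel_mean(assignment, X)
  names(assignment) <- expr$sample_ids

  structure(list(per_k = per_k, pac = pac, delta_area = delta_area,
                 chosen_k = chosen_k, assignment = assignment,
                 k_range = k_range, n_resamples = n_resamples,
                 subsample_frac = subsample_frac, seed = seed),
            class = "ConsensusResult")
}

# label 1 = lowest mean panel expression ... label k = highest, so the
# last letter carries the most active regulator programme
.relabel_by_panel_mean <- function(assignment, X) {
  sample_means <- colMeans(X)
  cluster_means <- tapply(sample_means, assignment, mean)
  new_label <- rank(cluster_means, ties.method = "first")
  out <- as.integer(new_label[as.character(assignment)])
  stats::setNames(out, names(assignment))
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: chosen k = %d (k range %s, %d resamples)\n",
              x$chosen_k, paste(range(x$k_range), collapse = "-"),
              x$n_resamples))
  cat("PAC:", paste(names(x$pac), signif(x$pac, 3), sep = "=",
                    collapse = ", "), "\n")
  cat("cluster sizes:", paste(table(x$assignment), collapse = "/"), "\n")
  invisible(x)
}

#' Per-cluster sizes and survival inputs
#'
#' Joins a cluster assignment with a clinical table, dropping (with a
#' warning count) samples absent from the clinical data, and emits one
#' survival data set per cluster. Cluster sizes always sum to the number of
#' assigned-and-matched samples (partition conservation).
#'
#' @param assignment named cluster label vector (sample -> cluster).
#' @param clinical a `ClinicalTable`.
#' @return list with `sizes` (named cluster sizes), `total`, and `groups`
#'   (per-cluster data.frames with `time`, `event`).
#' @export
cluster_survival_table <- function(assignment, clinical) {
  if (is.null(names(assignment))) stopf("assignment must be a named vector")
  keep <- names(assignment) %in% clinical$sample_id
  if (any(!keep))
    warnf("%d sample(s) in assignment missing from clinical table; dropped",
          sum(!keep))
  assignment <- assignment[keep]
  idx <- match(names(assignment), clinical$sample_id)
  groups <- lapply(split(idx, assignment), function(i)
    data.frame(sample_id = clinical$sample_id[i], time = clinical$time[i],
               event = clinical$event[i], stringsAsFactors = FALSE))
  sizes <- vapply(groups, nrow, 0L)
  stopifnot(sum(sizes) == length(assignment))
  list(sizes = sizes, total = sum(sizes), groups = groups)
}
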