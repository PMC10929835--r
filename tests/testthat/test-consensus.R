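# two anticorrelated point-mass groups: every resample separates them
.separated_expr <- function(n_per = 20, genes = 10) {
  profile <- seq(-1.5, 1.5, length.out = genes)
  X <- cbind(matrix(profile, genes, n_per),
             matrix(-profile, genes, n_per)) + 5
  toy_expr(X)
}

test_that("perfectly separated groups give an exact 0/1 consensus and PAC 0", {
  em <- .separated_expr()
  res <- consensus_cluster(em, em$gene_ids, k_range = 2, n_resamples = 50,
                           seed = 1)
  cm <- res$per_k[["2"]]$matrix
  within <- rbind(cm[1:20, 1:20], cm[21:40, 21:40])
  between <- cm[1:20, 21:40]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_equal(unname(res$pac["2"]), 0)
  expect_equal(as.integer(table(res$assignment)), c(20L, 20L))
})

test_that("consensus matrices are symmetric with unit diagonal", {
  coh <- generate_cohort(synthetic_config(n_samples = 60, n_genes = 60,
                                          n_deg = 15), seed = 2)
  res <- consensus_cluster(coh$expr, cuproptosis_panel, k_range = 2:4,
                           n_resamples = 25, seed = 2)
  for (pk in res$per_k) {
    expect_identical(pk$matrix, t(pk$matrix))
    expect_true(all(diag(pk$matrix) == 1))
    expect_true(all(pk$matrix >= 0 & pk$matrix <= 1))
  }
})

test_that("the resampling stream is reproducible even at 2 resamples", {
  em <- .separated_expr()
  a <- consensus_cluster(em, em$gene_ids, k_range = 2:3, n_resamples = 2,
                         seed = 9)
  b <- consensus_cluster(em, em$gene_ids, k_range = 2:3, n_resamples = 2,
                         seed = 9)
  expect_identical(a, b)
})

test_that("permuting sample order permutes the assignment identically", {
  em <- .separated_expr()
  res <- consensus_cluster(em, em$gene_ids, k_range = 2, n_resamples = 40,
                           seed = 3)
  perm <- sample(ncol(em$values))
  em2 <- expression_matrix(em$values[, perm])
  res2 <- consensus_cluster(em2, em$gene_ids, k_range = 2, n_resamples = 40,
                            seed = 4)
  expect_equal(unname(res2$assignment[em$sample_ids]),
               unname(res$assignment))
})

test_that("rising noise never increases within-cluster consensus", {
  for (s in 1:3) {
    within <- vapply(c(0.5, 1.5, 3), function(sg) {
      cfg <- synthetic_config(n_samples = 90, n_genes = 120, n_deg = 30,
                              proportions = rep(1 / 3, 3), sigma = sg)
      coh <- generate_cohort(cfg, seed = s)
      res <- consensus_cluster(coh$expr, cuproptosis_panel, k_range = 3,
                               n_resamples = 50, seed = s)
      cm <- res$per_k[["3"]]$matrix
      same <- outer(coh$truth$cluster, coh$truth$cluster, "==") & upper.tri(cm)
      mean(cm[same])
    }, 0)
    expect_true(all(diff(within) <= 1e-8))
  }
})

test_that("pure noise is more ambiguous at k=2 than separated data", {
  noise <- generate_cohort(synthetic_config(n_clusters = 1, n_samples = 60,
                                            n_genes = 60, n_deg = 0),
                           seed = 5)
  pac_noise <- consensus_cluster(noise$expr, cuproptosis_panel, k_range = 2,
                                 n_resamples = 50, seed = 5)$pac["2"]
  pac_sep <- consensus_cluster(.separated_expr(), paste0("g", 1:10),
                               k_range = 2, n_resamples = 50,
                               seed = 5)$pac["2"]
  expect_gt(pac_noise, pac_sep)
})

test_that("labels order clusters by mean panel expression", {
  coh <- generate_cohort(synthetic_config(n_samples = 90, n_genes = 60,
                                          n_deg = 15,
                                          proportions = rep(1 / 3, 3)),
                         seed = 6)
  res <- consensus_cluster(coh$expr, cuproptosis_panel, k_range = 3,
                           n_resamples = 50, seed = 6)
  panel_mean <- colMeans(coh$expr$values[cuproptosis_panel, ])
  cl_means <- tapply(panel_mean, res$assignment, mean)
  expect_true(all(diff(cl_means[order(as.integer(names(cl_means)))]) > 0))
})

test_that("input contracts are enforced", {
  em <- .separated_expr()
  expect_error(consensus_cluster(em, c("g1", "nope"), k_range = 2,
                                 n_resamples = 5),
               "missing from matrix: nope")
  expect_error(consensus_cluster(em, "g1", k_range = 2, n_resamples = 5),
               ">= 2 genes")
  expect_error(consensus_cluster(em, em$gene_ids, k_range = c(2, 40),
                                 n_resamples = 5), "k_max")
  expect_error(consensus_cluster(em, em$gene_ids, k_range = 2,
                                 n_resamples = 1), "n_resamples")
})

test_that("cluster survival tables conserve the partition", {
  sizes <- c(70, 223, 176)
  ids <- sprintf("p%03d", seq_len(sum(sizes)))
  assignment <- stats::setNames(rep(1:3, times = sizes), ids)
  cl <- toy_clinical(rexp(469, 1 / 300) + 1, rbinom(469, 1, 0.7), ids = ids)
  tab <- cluster_survival_table(assignment, cl)
  expect_equal(unname(tab$sizes), c(70L, 223L, 176L))
  expect_equal(tab$total, 469)

  one <- cluster_survival_table(stats::setNames(rep(1, 10), ids[1:10]), cl)
  expect_equal(unname(one$sizes), 10L)

  short <- cl[1:4, ]
  expect_warning(
    dropped <- cluster_survival_table(stats::setNames(rep(1, 5), ids[1:5]),
                                      short),
    "1 sample")
  expect_equal(dropped$total, 4)
})
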