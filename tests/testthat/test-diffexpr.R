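.two_group <- function(ngene = 120, n1 = 6, n2 = 6, seed = 41,
                       shift = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(ngene * (n1 + n2)), ngene, n1 + n2,
              dimnames = list(paste0("g", seq_len(ngene)),
                              paste0("s", seq_len(n1 + n2))))
  if (!is.null(shift)) X[seq_along(shift), seq_len(n1)] <-
    X[seq_along(shift), seq_len(n1)] + shift
  list(X = X, grp = rep(c("A", "B"), c(n1, n2)))
}

test_that("prior_df = 0 reproduces the ordinary pooled t exactly", {
  d <- .two_group()
  mt <- moderated_t(d$X, d$grp, prior_df = 0)
  ref <- apply(d$X, 1, function(r)
    stats::t.test(r[1:6], r[7:12], var.equal = TRUE)$statistic)
  expect_equal(mt$t, unname(ref), tolerance = 1e-12)
})

test_that("prior_df = Inf collapses to the common-variance statistic", {
  d <- .two_group()
  mt <- moderated_t(d$X, d$grp, prior_df = Inf)
  s0 <- attr(mt, "s0sq")
  expect_equal(mt$t, mt$log2fc / sqrt(s0 * (1 / 6 + 1 / 6)),
               tolerance = 1e-12)
})

test_that("estimated hyperparameters and statistics match the established EB fit", {
  skip_if_not_installed("limma")
  set.seed(42)
  ngene <- 400
  s2 <- 2 * 4 / stats::rchisq(ngene, df = 4)   # true d0 = 4, s0^2 = 2
  X <- matrix(stats::rnorm(ngene * 12, 0, sqrt(s2)), ngene, 12,
              dimnames = list(paste0("g", 1:ngene), paste0("s", 1:12)))
  grp <- rep(c("A", "B"), each = 6)
  mt <- moderated_t(X, grp)
  fit <- limma::eBayes(limma::lmFit(X, stats::model.matrix(~factor(grp))))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(mt, "s0sq"), fit$s2.prior, tolerance = 1e-10)
  expect_equal(abs(mt$t), unname(abs(fit$t[, 2])), tolerance = 1e-10)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("swapping group order negates effects and preserves p", {
  d <- .two_group(shift = rep(1, 10))
  a <- moderated_t(d$X, d$grp)
  # groups are first-appearing minus second; presenting B first flips them
  ord <- c(7:12, 1:6)
  b <- moderated_t(d$X[, ord], d$grp[ord])
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("BH adjustment is a monotone step function of raw-p rank", {
  d <- .two_group(shift = seq(0.2, 2, length.out = 30))
  mt <- moderated_t(d$X, d$grp)
  ord <- order(mt$p)
  expect_true(all(diff(mt$adj_p[ord]) >= -1e-15))
  expect_true(all(mt$adj_p >= mt$p))
})

test_that("the global-null false-positive rate is nominal", {
  d <- .two_group(ngene = 1000, n1 = 10, n2 = 10, seed = 43)
  mt <- moderated_t(d$X, d$grp)
  expect_gt(mean(mt$p < 0.05), 0.03)
  expect_lt(mean(mt$p < 0.05), 0.07)
})

test_that("planted-block power matches the analytic computation", {
  # effect ~ N(0.8, 0.2^2), sigma = 1, n = 50+50; the |log2FC| > 0.7 filter
  # binds, so expected pass ~ P(N(0.8, 0.2^2 + 2/50) > 0.7)
  set.seed(44)
  effects <- stats::rnorm(300, 0.8, 0.2)
  d <- .two_group(ngene = 2000, n1 = 50, n2 = 50, seed = 44, shift = effects)
  mt <- moderated_t(d$X, d$grp)
  hit <- abs(mt$log2fc[1:300]) > 0.7 & mt$p[1:300] < 0.05
  # power conditional on the drawn effects: the LFC filter binds, so a gene
  # with true effect e passes with probability P(N(e, 2/50) > 0.7)
  analytic <- mean(1 - stats::pnorm(0.7, effects, sqrt(2 / 50)))
  expect_lt(abs(mean(hit) - analytic), 0.05)
})

test_that("group contracts are enforced", {
  d <- .two_group()
  expect_error(moderated_t(d$X, rep("A", 12)), "exactly 2 groups")
  expect_error(moderated_t(d$X[, 1:3], c("A", "B", "B")), ">= 2 samples")
})

test_that("pairwise pattern DEGs recover planted blocks and respect cuts", {
  coh <- default_cohort()
  pd <- pattern_degs(coh$expr, coh$truth$cluster)
  expect_gte(mean(coh$truth$deg$gene %in% pd$union), 0.8)
  expect_named(pd$pairs, c("1_vs_2", "1_vs_3", "2_vs_3"))

  empty <- pattern_degs(coh$expr, coh$truth$cluster, lfc_cut = Inf)
  expect_length(empty$union, 0)
})

test_that("a near-identical split yields almost no pattern DEGs", {
  set.seed(45)
  X <- matrix(rnorm(2000 * 100), 2000, 100,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:100)))
  lab <- stats::setNames(rep(c(1, 2), 50), colnames(X))
  pd <- pattern_degs(X, lab)
  expect_lt(length(pd$union) / 2000, 0.01)
})

test_that("single-sample clusters are skipped with a warning", {
  set.seed(46)
  X <- matrix(rnorm(50 * 9), 50, 9,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:9)))
  lab <- stats::setNames(c(rep(1, 4), rep(2, 4), 3), colnames(X))
  # both pairs touching the singleton cluster warn
  expect_warning(expect_warning(pd <- pattern_degs(X, lab), "skipped"),
                 "skipped")
  expect_named(pd$pairs, "1_vs_2")
})

test_that("overlap DEGs use intersection semantics", {
  mk <- function(genes, adj) {
    tab <- data.frame(gene = c(genes, "filler"), log2fc = 1, t = 5,
                      p = c(adj, 0.9) / 10, adj_p = c(adj, 0.9))
    class(tab) <- c("DegTable", "data.frame")
    tab
  }
  t1 <- mk(c("x", "y"), c(1e-4, 5e-4))
  t2 <- mk(c("x", "y"), c(2e-4, 0.5))
  t3 <- mk(c("x", "y"), c(3e-4, 1e-5))
  expect_equal(overlap_degs(list(t1, t2, t3)), "x")   # y fails in t2
  expect_equal(overlap_degs(list(t1, t3)), c("x", "y"))
  expect_warning(out <- overlap_degs(list(mk("x", 0.5), mk("x", 0.5))),
                 "empty")
  expect_length(out, 0)
})

test_that("a pairwise-shifted block dominates the overlap intersection", {
  cfg <- synthetic_config(deg_block_design = "graded")
  coh <- generate_cohort(cfg, seed = 1)
  pd <- pattern_degs(coh$expr, coh$truth$cluster)
  ov <- overlap_degs(pd$pairs)
  planted <- c(coh$truth$deg$gene, cuproptosis_panel)
  expect_gt(length(ov), 100)
  expect_gte(mean(ov %in% planted), 0.8)
})
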