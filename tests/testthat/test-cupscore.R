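.surv_fixture <- function(X, beta_genes = NULL, beta = 0.8, seed = 61,
                          h0 = 1 / 365, cens_max = 1500) {
  set.seed(seed)
  lp <- if (is.null(beta_genes)) rep(0, ncol(X))
        else colSums(X[beta_genes, , drop = FALSE] * beta)
  tt <- rexp(ncol(X), h0 * exp(lp))
  cc <- runif(ncol(X), 0, cens_max)
  cupscore:::validate_clinical(
    data.frame(sample_id = colnames(X), time = pmin(tt, cc),
               event = as.integer(tt <= cc), stringsAsFactors = FALSE))
}

test_that("LASSO keeps planted prognostic genes among noise", {
  set.seed(62)
  X <- matrix(rnorm(52 * 450), 52, 450,
              dimnames = list(c("RISK1", "RISK2", sprintf("N%02d", 1:50)),
                              sprintf("s%03d", 1:450)))
  cl <- .surv_fixture(X, c("RISK1", "RISK2"))
  sel <- lasso_select(X, cl, seed = 1)
  expect_true(all(c("RISK1", "RISK2") %in% sel))
  expect_lt(length(sel), 52)
})

test_that("an empty support at every penalty falls back to the full set", {
  set.seed(63)
  X <- matrix(rnorm(5 * 60), 5, 60,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:60)))
  cl <- .surv_fixture(X)
  expect_warning(sel <- lasso_select(X, cl, lambda_grid = c(50, 20, 10),
                                     n_folds = 5, seed = 1),
                 "empty support")
  expect_setequal(as.character(sel), paste0("g", 1:5))
  expect_true(attr(sel, "skipped"))
})

test_that("the penalised path at lambda -> 0 matches the unpenalised fit", {
  set.seed(64)
  X <- matrix(rnorm(3 * 30), 3, 30,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:30)))
  cl <- .surv_fixture(X, "g1", beta = 0.5, cens_max = 1e9)
  cl$time <- cl$time + 1e-9 * seq_len(30)   # guard against ties
  fit <- cox_fit(cbind(cl, t(X)), c("g1", "g2", "g3"))
  g <- glmnet::glmnet(t(X), survival::Surv(cl$time, cl$event),
                      family = "cox", lambda = c(0.5, 0.1, 0.01, 0),
                      thresh = 1e-14)
  expect_equal(as.numeric(stats::coef(g, s = 0)), fit$coef$beta,
               tolerance = 1e-3)
})

test_that("two perfectly correlated genes load equally on a rank-1 axis", {
  x <- rnorm(20)
  X <- rbind(g1 = x, g2 = 2 * x + 3)
  colnames(X) <- paste0("s", 1:20)
  model <- fit_cupscore(X, c("g1", "g2"))
  expect_equal(unname(model$w1), c(1, 1) / sqrt(2), tolerance = 1e-10)
  expect_lt(model$sdev[2], 1e-10)
})

test_that("loadings match an independent eigendecomposition", {
  set.seed(65)
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  model <- fit_cupscore(X, paste0("g", 1:3))
  ev <- eigen(stats::cor(t(X)))$vectors
  fix_sign <- function(w) if (w[which.max(abs(w))] < 0) -w else w
  expect_equal(unname(model$w1), fix_sign(ev[, 1]), tolerance = 1e-8)
  expect_equal(unname(model$w2), fix_sign(ev[, 2]), tolerance = 1e-8)
})

test_that("axes are orthonormal and the fit is bit-reproducible", {
  set.seed(66)
  X <- matrix(rnorm(30 * 25), 30, 25,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:25)))
  m1 <- fit_cupscore(X, paste0("g", 1:30))
  m2 <- fit_cupscore(X, paste0("g", 1:30))
  expect_identical(m1, m2)
  expect_equal(sum(m1$w1^2), 1, tolerance = 1e-12)
  expect_equal(sum(m1$w2^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(m1$w1 * m1$w2)), 1e-8)
})

test_that("gene order does not matter and non-pool genes are ignored", {
  set.seed(67)
  X <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:15)))
  pool <- paste0("g", 1:6)
  base <- score_samples(fit_cupscore(X, pool), X)
  shuf <- score_samples(fit_cupscore(X[sample(10), ], rev(pool)), X)
  expect_equal(shuf, base, tolerance = 1e-12)
  bigger <- rbind(X, extra = rnorm(15))
  expect_equal(score_samples(fit_cupscore(bigger, pool), bigger), base,
               tolerance = 1e-12)
})

test_that("scores are centred, linear, and equal the SVD projections", {
  set.seed(68)
  X <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  model <- fit_cupscore(X, paste0("g", 1:8))
  mean_sample <- matrix(model$mu, 8, 1,
                        dimnames = list(model$genes, "atmean"))
  expect_equal(unname(score_samples(model, mean_sample)), 0,
               tolerance = 1e-12)

  x2 <- cbind(X, doubled = model$mu + 2 * (X[, 3] - model$mu))
  sc <- score_samples(model, x2)
  expect_equal(unname(sc["doubled"]), 2 * unname(sc["s3"]), tolerance = 1e-10)

  Z <- t((X - model$mu) / model$sigma)
  sv <- svd(Z)
  proj <- sv$u[, 1] * sv$d[1] * sign(sum(sv$v[, 1] * model$w1)) +
    sv$u[, 2] * sv$d[2] * sign(sum(sv$v[, 2] * model$w2))
  expect_equal(unname(score_samples(model, X)), proj, tolerance = 1e-8)
})

test_that("constant genes are dropped and thin pools rejected", {
  X <- rbind(g1 = rnorm(10), g2 = rep(1, 10), g3 = rnorm(10))
  colnames(X) <- paste0("s", 1:10)
  expect_warning(m <- fit_cupscore(X, paste0("g", 1:3)), "constant")
  expect_setequal(m$genes, c("g1", "g3"))
  expect_error(suppressWarnings(fit_cupscore(X, c("g1", "g2"))),
               "collapsed below 2")
  expect_error(fit_cupscore(X, c("g1", "missing")), "missing")
  expect_error(score_samples(m, X[1, , drop = FALSE]), "g3")
})

test_that("group assignment conserves the printed partition sizes", {
  scores <- stats::setNames(seq_len(383), sprintf("p%03d", 1:383))
  res <- assign_groups(scores, cutoff = 223)
  expect_equal(unname(res$sizes), c(223L, 160L))
  expect_equal(unname(sum(res$sizes)), 383L)
  expect_true(all((res$group == "high") == (scores > res$cutoff)))

  all_high <- assign_groups(scores, cutoff = min(scores) - 1)
  expect_equal(unname(all_high$sizes["high"]), 383L)
})

test_that("orientation ties high scores to high regulator expression", {
  coh <- default_cohort()
  res <- suppressWarnings(
    run_cupscore_pipeline(coh$expr, coh$clinical, n_resamples = 60,
                          seed = 1, n_perm = 60))
  panel_mean <- colMeans(coh$expr$values[cuproptosis_panel, ])
  expect_gt(stats::cor(res$scores, panel_mean), 0)
})
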