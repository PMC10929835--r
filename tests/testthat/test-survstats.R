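test_that("the product-limit estimate matches hand-computed tables", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  censored <- km_estimate(data.frame(time = c(2, 5, 9), event = 0))
  expect_true(all(censored$surv == 1))

  # events at 1,3,5; censored at 2,4,6:
  # S(1) = 5/6; S(3) = 5/6 * 3/4 = 5/8; S(5) = 5/8 * 1/2 = 5/16
  mixed <- km_estimate(data.frame(time = 1:6, event = rep(c(1, 0), 3)))
  expect_equal(mixed$surv[mixed$time %in% c(1, 3, 5)],
               c(5 / 6, 5 / 8, 5 / 16))
})

test_that("KM with no censoring is one minus the empirical CDF", {
  set.seed(51)
  tt <- rexp(40, 1 / 50)
  km <- km_estimate(data.frame(time = tt, event = 1))
  expect_equal(km$surv, 1 - ecdf(tt)(km$time))
})

test_that("log-rank matches the hand-enumerated risk-set computation", {
  # group1 events at 1,3; group2 at 2,4:
  # O1 - E1 = 2 - (1/2 + 1/3 + 1/2 + 0) = 2/3
  # V = 1/4 + 2/9 + 1/4 = 13/18;  chisq = (2/3)^2 / (13/18) = 8/13
  lr <- logrank(list(a = data.frame(time = c(1, 3), event = 1),
                     b = data.frame(time = c(2, 4), event = 1)))
  expect_equal(lr$chisq, (2 / 3)^2 / (13 / 18), tolerance = 1e-12)

  same <- data.frame(time = c(3, 7, 12), event = c(1, 0, 1))
  dup <- logrank(list(a = same, b = same))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1, tolerance = 1e-12)
})

test_that("log-rank holds its size under the null", {
  set.seed(52)
  rej <- mean(replicate(500, {
    d1 <- data.frame(time = rexp(100, 1 / 100), event = rbinom(100, 1, 0.8))
    d2 <- data.frame(time = rexp(100, 1 / 100), event = rbinom(100, 1, 0.8))
    logrank(list(a = d1, b = d2))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Cox fits recover parameters and handle degeneracies", {
  set.seed(53)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, (1 / 300) * exp(0.5 * x))
  cc <- runif(n, 0, 900)
  d <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc), x = x)
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coef$beta - 0.5), 0.15)
  expect_equal(fit$coef$hr, exp(fit$coef$beta))
  expect_equal(fit$coef$ci_lo, exp(fit$coef$beta - 1.96 * fit$coef$se))
  expect_true(fit$converged)

  zero <- cox_fit(data.frame(time = rexp(30, 1) + 0.1, event = 1, z = 0), "z")
  expect_equal(zero$coef$beta, 0)
  expect_equal(zero$coef$p, 1)

  sep <- cox_fit(data.frame(time = c(1:5, 101:105), event = 1,
                            x = rep(c(1, 0), each = 5)), "x")
  expect_false(sep$converged)
  expect_lte(abs(sep$coef$beta), 15)
})

test_that("the partial likelihood at the fit dominates a grid oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- sample(5:8, 1)
    d <- data.frame(time = sort(rexp(n, 1)), event = 1, x = rnorm(n))
    fit <- cox_fit(d, "x")
    pl <- function(b) {
      lp <- b * d$x
      sum(lp - log(rev(cumsum(rev(exp(lp))))))
    }
    grid <- seq(-4, 4, by = 0.001)
    expect_gte(pl(fit$coef$beta) + 1e-4, max(vapply(grid, pl, 0)))
  }
})

test_that("prognostic filtering is calibrated and catches the risk axis", {
  coh <- default_cohort()
  set.seed(54)
  null_genes <- matrix(rnorm(500 * 450), 500, 450,
                       dimnames = list(paste0("n", 1:500),
                                       coh$clinical$sample_id))
  pf <- prognostic_filter(null_genes, coh$clinical)
  expect_gt(length(pf$genes) / 500, 0.03)
  expect_lt(length(pf$genes) / 500, 0.07)

  risk <- matrix(coh$truth$hazard_beta[coh$truth$cluster] + rnorm(450, 0, 0.2),
                 1, 450, dimnames = list("RISK", coh$clinical$sample_id))
  pf2 <- prognostic_filter(risk, coh$clinical)
  expect_equal(pf2$genes, "RISK")
  expect_gt(pf2$fits$beta, 0)

  expect_length(prognostic_filter(risk, coh$clinical, p_cut = 0)$genes, 0)
})

test_that("the cutpoint statistic agrees exactly with the two-group log-rank", {
  set.seed(55)
  n <- 80
  d <- data.frame(time = rexp(n, 1 / 100), event = rbinom(n, 1, 0.7))
  sc <- rnorm(n)
  cp <- best_cutpoint(sc, d, n_perm = 100, seed = 1)
  lr <- logrank(list(lo = d[sc <= cp$threshold, ], hi = d[sc > cp$threshold, ]))
  expect_equal(cp$statistic^2, lr$chisq, tolerance = 1e-10)
  expect_equal(unname(sum(cp$sizes)), n)
})

test_that("a monotone score-hazard toy is split with a small permutation p", {
  d <- data.frame(time = sort(rexp(50, 1 / 100)), event = 1)
  cp <- best_cutpoint(seq(50, 1), d, n_perm = 200, seed = 1)
  expect_lt(cp$p, 0.01)
})

test_that("the cutpoint permutation test holds its size under the null", {
  set.seed(56)
  rej <- mean(replicate(150, {
    d <- data.frame(time = rexp(50, 1 / 100), event = rbinom(50, 1, 0.8))
    best_cutpoint(rnorm(50), d, n_perm = 99, seed = 1)$p < 0.05
  }))
  expect_lte(rej, 0.08)
})

test_that("degenerate cutpoint inputs are rejected", {
  d <- data.frame(time = rexp(30, 1) + 1, event = 1)
  expect_error(best_cutpoint(rep(1, 30), d), "constant scores")
  expect_error(best_cutpoint(rnorm(10), d[1:10, ]), ">= 20 samples")
})

test_that("time-dependent AUC behaves at its reference points", {
  d <- data.frame(time = sort(rexp(50, 1 / 100)), event = 1)
  expect_equal(td_roc(-d$time, d, median(d$time))$auc, 1)

  set.seed(57)
  null_auc <- replicate(15, {
    big <- data.frame(time = rexp(450, 1 / 300), event = rbinom(450, 1, 0.7))
    td_roc(rnorm(450), big, 365)$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
  big <- data.frame(time = rexp(450, 1 / 300), event = rbinom(450, 1, 0.7))
  sc <- rnorm(450)
  auc <- td_roc(sc, big, 365)$auc
  expect_equal(td_roc(-sc, big, 365)$auc, 1 - auc, tolerance = 1e-12)

  expect_error(td_roc(sc[1:50], d, max(d$time) + 10), "no control")
})

test_that("rank tests match exact enumeration and degenerate limits", {
  w <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(w$p, 0.1)   # 2 of the 20 equally likely assignments as extreme

  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gte(same$p, 0.99)

  k <- group_compare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                     test = "kruskal")
  expect_equal(unname(k$statistic), 0)
  expect_error(group_compare(1:4, rep("a", 4), test = "wilcoxon"),
               "2 groups")
})
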