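# Survival machinery: Kaplan-Meier, log-rank, Cox proportional hazards
# (via the survival package, Efron ties), univariate prognostic filtering,
# maximally selected survival cutpoint with permutation p, IPCW
# time-dependent ROC, and rank-based group comparisons.

.as_survdata <- function(data) {
  if (!all(c("time", "event") %in% colnames(data)))
    stopf("survival data needs 'time' and 'event' columns")
  if (any(data$time <= 0)) stopf("survival times must be positive")
  if (!all(data$event %in% c(0, 1))) stopf("event must be 0/1")
  data
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data data.frame with `time` (> 0) and `event` (0/1).
#' @return `KmCurve` list: `time` (step times), `surv`, `n_risk`,
#'   `n_event`.
#' @export
km_estimate <- function(data) {
  data <- .as_survdata(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event), class = "KmCurve")
}

#' Log-rank test across groups
#'
#' @param groups named list of survival data.frames (`time`, `event`), one
#'   per group.
#' @return `LogRankResult` list: `chisq`, `df`, `p`, `n`.
#' @export
logrank <- function(groups) {
  if (length(groups) < 2) stopf(">= 2 groups required")
  df <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- .as_survdata(groups[[nm]])
    data.frame(time = g$time, event = g$event, group = nm)
  }))
  if (sum(df$event) < 1) stopf("at least one event required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(groups) - 1
  structure(list(chisq = sd$chisq, df = dfree,
                 p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE),
                 n = nrow(df)), class = "LogRankResult")
}

#' Cox proportional-hazards fit
#'
#' Efron tie handling; Wald tests and 95% CIs per covariate. A monotone
#' likelihood (perfect separation) is flagged non-converged with the
#' coefficient capped at |beta| <= 15; a constant covariate gets beta = 0,
#' p = 1.
#'
#' @param data data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @return `CoxFit` list: `coef` data.frame (beta, hr, se, z, p, ci_lo,
#'   ci_hi per covariate), `loglik` (at the fit), `converged`.
#' @export
cox_fit <- function(data, covariates) {
  data <- .as_survdata(data)
  miss <- setdiff(covariates, colnames(data))
  if (length(miss)) stopf("covariate(s) missing: %s", paste(miss, collapse = ", "))
  if (sum(data$event) < length(covariates) + 1)
    stopf("need events >= number of covariates + 1")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  se <- se[names(beta)]
  constant <- is.na(beta)
  beta[constant] <- 0
  se[constant | is.na(se)] <- Inf
  capped <- abs(beta) > 15
  converged <- !warned && !any(capped)
  beta[capped] <- sign(beta[capped]) * 15
  z <- ifelse(is.finite(se), beta / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  coef_tab <- data.frame(
    covariate = covariates, beta = beta, hr = exp(beta), se = se, z = z,
    p = p, ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    stringsAsFactors = FALSE)
  rownames(coef_tab) <- NULL
  structure(list(coef = coef_tab, loglik = fit$loglik[length(fit$loglik)],
                 converged = converged),
            class = "CoxFit")
}

#' Univariate prognostic gene filter
#'
#' Fits a univariate Cox model per gene on z-scored expression (hazard
#' ratios are per expression SD) and keeps genes with Wald p < `p_cut`.
#'
#' @param x genes x samples matrix or [expression_matrix()].
#' @param clinical `ClinicalTable` sharing samples with `x`.
#' @param p_cut Wald p threshold (default 0.05).
#' @return list with `genes` (passing), `fits` (per-gene data.frame with
#'   beta, hr, se, z, p).
#' @export
prognostic_filter <- function(x, clinical, p_cut = 0.05) {
  vals <- .as_values(x)
  common <- intersect(colnames(vals), clinical$sample_id)
  if (length(common) < 3) stopf("too few shared samples")
  vals <- vals[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  rows <- lapply(rownames(vals), function(g) {
    zexpr <- as.numeric(scale(vals[g, ]))
    if (any(is.na(zexpr))) zexpr <- rep(0, length(common))  # constant gene
    d <- data.frame(time = cl$time, event = cl$event, expr = zexpr)
    cf <- cox_fit(d, "expr")$coef
    data.frame(gene = g, beta = cf$beta, hr = cf$hr, se = cf$se, z = cf$z,
               p = cf$p, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  list(genes = fits$gene[fits$p < p_cut], fits = fits)
}

# log-rank decomposition used by the cutpoint scan: for the "low" group of
# the first m score-ordered samples, O - E is the cumulative sum of the
# per-sample log-rank scores (event indicator minus Nelson-Aalen cumulative
# hazard at the sample's time) and the hypergeometric variance is a linear
# + quadratic functional of the at-risk counts.
.logrank_scan <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  E <- length(ev_times)
  dj <- vapply(ev_times, function(t) sum(time == t & event == 1), 0)
  Yj <- vapply(ev_times, function(t) sum(time >= t), 0)
  haz <- dj / Yj
  cumhaz <- cumsum(haz)
  ridx <- findInterval(time, ev_times)           # event times <= T_i
  a <- event - c(0, cumhaz)[ridx + 1]            # log-rank scores
  alpha <- ifelse(Yj > 1, dj * (Yj - dj) / ((Yj - 1) * Yj), 0)
  beta <- ifelse(Yj > 1, alpha / Yj, 0)
  ind <- outer(seq_len(E), ridx, "<=")           # E x n at-risk indicator
  list(a = a, alpha = alpha, beta = beta, ind = ind, E = E)
}

# standardized log-rank statistic for the low group at every prefix size m
# of the given sample order; returns the z vector (NA where variance 0)
.scan_z <- function(scan, ord) {
  a <- scan$a[ord]
  oe <- cumsum(a)
  ind <- scan$ind[, ord, drop = FALSE]
  Ylt <- apply(ind, 1, cumsum)                   # n x E cumulative at-risk
  if (scan$E == 1) Ylt <- matrix(Ylt, ncol = 1)
  v <- drop(Ylt %*% scan$alpha - (Ylt * Ylt) %*% scan$beta)
  ifelse(v > 1e-12, oe / sqrt(v), NA_real_)
}

#' Maximally selected survival cutpoint
#'
#' Scans admissible thresholds of a per-sample score (both groups at least
#' `min_prop` of the samples), maximising the absolute standardized
#' two-group log-rank statistic; significance comes from permuting the
#' score-to-outcome assignment and recording the permutation distribution
#' of the maximal statistic.
#'
#' @param scores named (or aligned) per-sample numeric scores.
#' @param data survival data.frame (`time`, `event`) aligned with scores.
#' @param min_prop minimum group proportion (default 0.1).
#' @param n_perm permutations for the p-value (default 1000).
#' @param seed permutation seed.
#' @return `CutpointResult` list: `threshold` (low group = score <=
#'   threshold), `statistic` (max |standardized log-rank|), `p`, `sizes`.
#' @export
best_cutpoint <- function(scores, data, min_prop = 0.1, n_perm = 1000,
                          seed = 1) {
  data <- .as_survdata(data)
  n <- nrow(data)
  if (length(scores) != n) stopf("scores and data differ in length")
  if (n < 20) stopf(">= 20 samples required")
  if (length(unique(scores)) < 2) stopf("no admissible cutpoint: constant scores")
  scan <- .logrank_scan(data$time, data$event)
  ord <- order(scores)
  srt <- scores[ord]
  lo <- ceiling(min_prop * n)
  hi <- n - lo
  admissible <- seq_len(n - 1) >= lo & seq_len(n - 1) <= hi &
    srt[-n] < srt[-1]                            # cut realisable at ties
  if (!any(admissible)) stopf("no admissible cutpoint under min_prop")
  z <- .scan_z(scan, ord)[seq_len(n - 1)]
  zadm <- abs(z[admissible])
  if (all(is.na(zadm))) stopf("log-rank variance degenerate at every cutpoint")
  best_i <- which(admissible)[which.max(zadm)]
  observed <- abs(z[best_i])
  set.seed(as.integer(seed))
  perm_max <- vapply(seq_len(n_perm), function(i) {
    pz <- .scan_z(scan, sample.int(n))[seq_len(n - 1)]
    # same admissible positions: group sizes constrain m, not score ties
    m_ok <- seq_len(n - 1) >= lo & seq_len(n - 1) <= hi
    max(abs(pz[m_ok]), na.rm = TRUE)
  }, 0)
  pval <- (1 + sum(perm_max >= observed)) / (n_perm + 1)
  structure(list(threshold = srt[best_i], statistic = observed, p = pval,
                 sizes = c(low = best_i, high = n - best_i),
                 n_perm = n_perm),
            class = "CutpointResult")
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at horizon t: cases are samples
#' with an observed event by t, controls are samples still under
#' observation beyond t; both are weighted by inverse probabilities of
#' censoring from the Kaplan-Meier estimate of the censoring distribution.
#'
#' @param scores per-sample risk scores (higher = riskier).
#' @param data survival data.frame (`time`, `event`).
#' @param horizon evaluation time(s), inside the observed time range.
#' @return `TdRocResult` data.frame: horizon, auc, n_case, n_control.
#' @export
td_roc <- function(scores, data, horizon) {
  data <- .as_survdata(data)
  if (length(scores) != nrow(data)) stopf("scores and data differ in length")
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = data)
  G_at <- function(u) c(1, cfit$surv)[findInterval(u, cfit$time) + 1]
  G_before <- function(u)
    c(1, cfit$surv)[findInterval(u, cfit$time, left.open = TRUE) + 1]
  rows <- lapply(horizon, function(t) {
    case <- data$time <= t & data$event == 1
    ctrl <- data$time > t
    if (!any(case)) stopf("no case by horizon %g", t)
    if (!any(ctrl)) stopf("no control beyond horizon %g", t)
    gt <- G_at(t)
    if (gt <= 0) stopf("censoring survival zero at horizon %g", t)
    w_case <- 1 / G_before(data$time[case])
    w_ctrl <- rep(1 / gt, sum(ctrl))
    cmp <- outer(scores[case], scores[ctrl],
                 function(a, b) (a > b) + 0.5 * (a == b))
    auc <- sum((w_case %o% w_ctrl) * cmp) / (sum(w_case) * sum(w_ctrl))
    data.frame(horizon = t, auc = auc, n_case = sum(case),
               n_control = sum(ctrl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("TdRocResult", "data.frame")
  out
}

#' Rank-based group comparison
#'
#' Wilcoxon rank-sum for 2 groups, Kruskal-Wallis for 2 or more; exact
#' rank-sum enumeration when the combined sample size is at most 10 and
#' values are tie-free, the usual large-sample approximation otherwise.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @param test `"wilcoxon"` or `"kruskal"`.
#' @return list: `statistic`, `p`, `test`.
#' @export
group_compare <- function(values, groups, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (test == "wilcoxon") {
    if (nlevels(groups) != 2) stopf("wilcoxon needs exactly 2 groups")
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    exact <- length(values) <= 10 && !anyDuplicated(values)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value, test = "wilcoxon")
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(statistic = unname(kt$statistic), p = kt$p.value, test = "kruskal")
  }
}
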