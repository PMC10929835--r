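# Seeded synthetic multi-omic cohort with planted cuproptosis-pattern
# structure: regulator-driven subtypes, DEG blocks, subtype-dependent
# survival, clinical covariates, and toy mutation/CNV tables. The planted
# truth is the oracle every downstream module is validated against.

#' The 13-gene cuproptosis regulator panel
#' @export
cuproptosis_panel <- c("FDX1", "LIPT1", "LIAS", "DLD", "DLAT", "PDHA1",
                       "PDHB", "DBT", "GCSH", "DLST", "SLC31A1", "ATP7A",
                       "ATP7B")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a merged multi-cohort glioblastoma expression study:
#' three regulator-driven subtypes with unbalanced mixing, a 300-gene DEG
#' block on top of a 3000-gene background, exponential survival whose
#' log-hazard rises across subtypes, ~30% uniform censoring, and toy
#' mutation/CNV models over the regulator panel.
#'
#' @param n_samples,n_genes,n_clusters cohort dimensions.
#' @param proportions cluster mixing proportions (must sum to 1).
#' @param regulator_panel gene names of the regulator panel.
#' @param regulator_shift log2 mean shift amplitude of the panel between
#'   the extreme clusters (cluster 1 mean panel shift = -shift, cluster
#'   `n_clusters` = +shift; each cluster also gets its own zero-mean
#'   direction across the panel so subtypes differ in profile shape, not
#'   only in level).
#' @param n_deg number of planted DEGs; split into `n_clusters` disjoint
#'   blocks.
#' @param deg_effect_mean,deg_effect_sd per-gene log2 effect distribution.
#' @param deg_block_design `"mixed"` (default: cluster-specific blocks plus
#'   one hazard-graded block whose means rise 0, e, 2e, ... across
#'   clusters), `"specific"` (all blocks cluster-specific) or `"graded"`
#'   (all blocks graded).
#' @param sigma residual log2 noise sd.
#' @param baseline_mean,baseline_sd distribution of gene-wise baseline
#'   means.
#' @param n_batches,batch_shift technical batches; batch b is shifted by
#'   `batch_shift * seq(-1, 1)[b]` uniformly across genes.
#' @param h0 baseline hazard (per day).
#' @param beta_cluster per-cluster log-hazard coefficients.
#' @param censoring_rate target fraction censored (uniform censoring
#'   horizon solved to match).
#' @param weibull_shape survival-time shape; 1 = exponential.
#' @param age_mean,age_sd,idh_mut_prob,male_prob,tmz_prob clinical
#'   covariate generators; `idh_mut_prob` is per cluster.
#' @param mutation_rates named per-gene per-sample Bernoulli rates.
#' @param cnv_amp_prob,cnv_del_prob named per-gene call probabilities.
#' @param structure_seed seed for the planted truth (which genes carry
#'   effects and how big they are); fixed by default so different
#'   simulation seeds share an identical truth structure.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_samples = 450, n_genes = 3000, n_clusters = 3,
                             proportions = c(0.15, 0.475, 0.375),
                             regulator_panel = cuproptosis_panel,
                             regulator_shift = 1.5,
                             n_deg = 300,
                             deg_effect_mean = 0.8, deg_effect_sd = 0.2,
                             deg_block_design = c("mixed", "specific", "graded"),
                             sigma = 1.0,
                             baseline_mean = 5, baseline_sd = 2,
                             n_batches = 2, batch_shift = 0.5,
                             h0 = 1 / 365,
                             beta_cluster = c(0, 0.4, 0.9),
                             censoring_rate = 0.3,
                             weibull_shape = 1,
                             age_mean = 60, age_sd = 10,
                             idh_mut_prob = c(0.20, 0.10, 0.05),
                             male_prob = 0.6, tmz_prob = 0.6,
                             mutation_rates = NULL,
                             cnv_amp_prob = NULL, cnv_del_prob = NULL,
                             structure_seed = 20061L) {
  if (n_clusters == 1) {
    if (missing(proportions)) proportions <- 1
    if (missing(beta_cluster)) beta_cluster <- 0
    if (missing(idh_mut_prob)) idh_mut_prob <- 0.1
  }
  cfg <- list(
    n_samples = n_samples, n_genes = n_genes, n_clusters = n_clusters,
    proportions = proportions, regulator_panel = regulator_panel,
    regulator_shift = regulator_shift, n_deg = n_deg,
    deg_effect_mean = deg_effect_mean, deg_effect_sd = deg_effect_sd,
    deg_block_design = match.arg(deg_block_design),
    sigma = sigma, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    n_batches = n_batches, batch_shift = batch_shift,
    h0 = h0, beta_cluster = beta_cluster, censoring_rate = censoring_rate,
    weibull_shape = weibull_shape,
    age_mean = age_mean, age_sd = age_sd, idh_mut_prob = idh_mut_prob,
    male_prob = male_prob, tmz_prob = tmz_prob,
    mutation_rates = if (is.null(mutation_rates)) .default_mutation_rates()
                     else mutation_rates,
    cnv_amp_prob = if (is.null(cnv_amp_prob)) .default_cnv_prob("amp", regulator_panel)
                   else cnv_amp_prob,
    cnv_del_prob = if (is.null(cnv_del_prob)) .default_cnv_prob("del", regulator_panel)
                   else cnv_del_prob,
    structure_seed = as.integer(structure_seed))
  validate_synthetic_config(cfg)
}

.default_mutation_rates <- function() {
  c(ATP7A = 0.012, ATP7B = 0.008, DLD = 0.005, DLAT = 0.005, PDHA1 = 0.004,
    PDHB = 0.004, DBT = 0.003, DLST = 0.003, SLC31A1 = 0.003, LIPT1 = 0.003,
    FDX1 = 0, LIAS = 0, GCSH = 0,
    TP53 = 0.35, EGFR = 0.30, PTEN = 0.30, NF1 = 0.12, RB1 = 0.10)
}

.default_cnv_prob <- function(which, panel) {
  # deletion-biased and amplification-biased regulators mirror the CNV
  # landscape the panel is reported to show in glioblastoma
  amp <- stats::setNames(rep(0.10, length(panel)), panel)
  del <- amp
  del[intersect(c("ATP7B", "DLST", "GCSH"), panel)] <- 0.25
  amp[intersect(c("ATP7B", "DLST", "GCSH"), panel)] <- 0.05
  amp[intersect(c("SLC31A1", "FDX1"), panel)] <- 0.25
  del[intersect(c("SLC31A1", "FDX1"), panel)] <- 0.05
  if (which == "amp") amp else del
}

validate_synthetic_config <- function(cfg) {
  bad <- character()
  if (abs(sum(cfg$proportions) - 1) > 1e-8) bad <- c(bad, "proportions (must sum to 1)")
  if (length(cfg$proportions) != cfg$n_clusters) bad <- c(bad, "proportions (length != n_clusters)")
  if (length(cfg$beta_cluster) != cfg$n_clusters) bad <- c(bad, "beta_cluster (length != n_clusters)")
  if (length(cfg$idh_mut_prob) != cfg$n_clusters) bad <- c(bad, "idh_mut_prob (length != n_clusters)")
  if (cfg$n_deg + length(cfg$regulator_panel) > cfg$n_genes)
    bad <- c(bad, "n_deg (n_deg + panel size exceeds n_genes)")
  rates <- c(cfg$censoring_rate, cfg$male_prob, cfg$tmz_prob,
             cfg$idh_mut_prob, cfg$mutation_rates, cfg$cnv_amp_prob,
             cfg$cnv_del_prob)
  if (any(rates < 0 | rates > 1)) bad <- c(bad, "rates (all must lie in [0,1])")
  if (any(cfg$cnv_amp_prob + cfg$cnv_del_prob > 1))
    bad <- c(bad, "cnv probabilities (amp + del > 1 for some gene)")
  if (cfg$sigma <= 0) bad <- c(bad, "sigma (must be > 0)")
  if (cfg$n_samples < cfg$n_clusters) bad <- c(bad, "n_samples (< n_clusters)")
  if (length(bad))
    stopf("invalid synthetic config field(s): %s", paste(bad, collapse = "; "))
  class(cfg) <- "SyntheticConfig"
  cfg
}

# planted structure drawn from the structure seed only, so two cohorts with
# different simulation seeds share identical truth
.plant_structure <- function(cfg) {
  p <- length(cfg$regulator_panel)
  k <- cfg$n_clusters
  withr_seed <- .Random.seed_exists()
  set.seed(cfg$structure_seed)
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed,
                                           envir = globalenv()))
  # per-cluster panel directions: orthogonal zero-mean shapes + a graded
  # uniform component so mean panel expression rises with cluster index
  D <- matrix(0, p, k, dimnames = list(cfg$regulator_panel, NULL))
  if (k > 1 && cfg$regulator_shift != 0) {
    grad <- seq(-1, 1, length.out = k)
    shapes <- matrix(stats::rnorm(p * k), p, k)
    shapes <- sweep(shapes, 2, colMeans(shapes))
    for (c in seq_len(k)) {
      v <- shapes[, c]
      if (c > 1) for (b in seq_len(c - 1)) {
        u <- shapes[, b]
        v <- v - u * sum(v * u) / sum(u * u)
      }
      shapes[, c] <- v / mean(abs(v))
    }
    D <- (shapes + matrix(grad, p, k, byrow = TRUE)) * cfg$regulator_shift
    # re-assert the graded panel mean exactly (orthogonalisation moves it)
    D <- sweep(D, 2, colMeans(D) - grad * cfg$regulator_shift)
  }
  # DEG blocks over the genes that follow the panel
  others <- sprintf("G%04d", seq_len(cfg$n_genes - p))
  genes <- c(cfg$regulator_panel, others)
  deg_genes <- others[seq_len(cfg$n_deg)]
  effects <- stats::rnorm(cfg$n_deg, cfg$deg_effect_mean, cfg$deg_effect_sd)
  block <- rep(seq_len(k), length.out = cfg$n_deg)
  block <- sort(block)
  M <- matrix(0, cfg$n_deg, k)  # per-cluster effect multipliers
  for (b in seq_len(k)) {
    rows <- block == b
    M[rows, ] <- switch(cfg$deg_block_design,
      specific = { m <- rep(0, k); m[b] <- 1; matrix(m, sum(rows), k, byrow = TRUE) },
      graded = matrix(seq_len(k) - 1, sum(rows), k, byrow = TRUE),
      mixed = if (b < k) { m <- rep(0, k); m[b] <- 1
                           matrix(m, sum(rows), k, byrow = TRUE) }
              else matrix(seq_len(k) - 1, sum(rows), k, byrow = TRUE))
  }
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes
  list(genes = genes, baseline = baseline, panel_shifts = D,
       deg = data.frame(gene = deg_genes, block = block, effect = effects,
                        stringsAsFactors = FALSE),
       deg_multipliers = M)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

# uniform censoring horizon matched to the target censoring fraction
.censoring_horizon <- function(cfg) {
  surv <- function(t, beta)
    exp(-cfg$h0 * exp(beta) * t^cfg$weibull_shape)
  pcens <- function(tmax) {
    s <- vapply(seq_len(cfg$n_clusters), function(c)
      stats::integrate(surv, 0, tmax, beta = cfg$beta_cluster[c])$value / tmax,
      0)
    sum(cfg$proportions * s)
  }
  if (cfg$censoring_rate <= 0) return(Inf)
  stats::uniroot(function(x) pcens(x) - cfg$censoring_rate,
                 interval = c(1e-3, 1e7), tol = 1e-8)$root
}

#' Generate a synthetic multi-omic cohort with planted truth
#'
#' Expression is gene-wise baseline + cluster shifts on the regulator panel
#' and DEG blocks + batch shift + Gaussian noise, on the log2(TPM+1) scale.
#' Survival times are Weibull (exponential by default) with cluster-specific
#' proportional hazards, censored by an independent uniform time whose
#' horizon is solved to hit the configured censoring rate. Cluster and batch
#' labels are assigned deterministically (contiguous blocks / round-robin),
#' so the truth is bit-identical across simulation seeds; the seed drives
#' only noise, survival, clinical covariates and the mutation/CNV draws.
#'
#' @param config a [synthetic_config()].
#' @param seed integer simulation seed.
#' @return list with `expr` ([expression_matrix()]), `clinical`
#'   (`ClinicalTable`), `maf` (`MafTable`), `cnv` (`CnvCallTable`) and
#'   `truth` (`SyntheticTruth`: cluster labels, DEG table, hazard
#'   coefficients, batch labels, panel shifts).
#' @export
generate_cohort <- function(config, seed = 1) {
  cfg <- validate_synthetic_config(config)
  st <- .plant_structure(cfg)
  n <- cfg$n_samples
  k <- cfg$n_clusters
  counts <- diff(round(cumsum(c(0, cfg$proportions)) * n))
  counts[k] <- n - sum(counts[-k])
  cluster <- rep(seq_len(k), times = counts)
  batch <- rep_len(seq_len(cfg$n_batches), n)
  samples <- sprintf("S%03d", seq_len(n))

  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$sigma), cfg$n_genes, n,
              dimnames = list(st$genes, samples))
  X <- X + st$baseline
  X[cfg$regulator_panel, ] <- X[cfg$regulator_panel, ] +
    st$panel_shifts[, cluster, drop = FALSE]
  deg_shift <- st$deg_multipliers * st$deg$effect      # n_deg x k
  X[st$deg$gene, ] <- X[st$deg$gene, ] + deg_shift[, cluster, drop = FALSE]
  batch_offsets <- if (cfg$n_batches > 1)
    seq(-1, 1, length.out = cfg$n_batches) * cfg$batch_shift else 0
  X <- sweep(X, 2, batch_offsets[batch], "+")
  expr <- expression_matrix(X, batch = paste0("batch", batch))

  # survival with cluster-specific proportional hazards
  rate <- cfg$h0 * exp(cfg$beta_cluster[cluster])
  T_ev <- (stats::rexp(n) / rate)^(1 / cfg$weibull_shape)
  tmax <- .censoring_horizon(cfg)
  C <- if (is.finite(tmax)) stats::runif(n, 0, tmax) else rep(Inf, n)
  time <- pmin(T_ev, C)
  event <- as.integer(T_ev <= C)

  subtype_prob <- .subtype_probs(k)
  clinical <- data.frame(
    sample_id = samples, time = time, event = event,
    age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
    sex = ifelse(stats::runif(n) < cfg$male_prob, "male", "female"),
    idh_status = ifelse(stats::runif(n) < cfg$idh_mut_prob[cluster],
                        "mutant", "wildtype"),
    subtype = vapply(cluster, function(c)
      sample(colnames(subtype_prob), 1, prob = subtype_prob[c, ]), ""),
    tmz = ifelse(stats::runif(n) < cfg$tmz_prob, "yes", "no"),
    stringsAsFactors = FALSE)
  clinical <- validate_clinical(clinical)

  maf <- .simulate_maf(cfg, samples)
  cnv <- .simulate_cnv(cfg, samples)

  truth <- structure(list(
    cluster = stats::setNames(cluster, samples),
    deg = st$deg, deg_multipliers = st$deg_multipliers,
    hazard_beta = cfg$beta_cluster,
    batch = stats::setNames(batch, samples),
    panel_shifts = st$panel_shifts,
    censoring_horizon = tmax), class = "SyntheticTruth")
  list(expr = expr, clinical = clinical, maf = maf, cnv = cnv, truth = truth)
}

.subtype_probs <- function(k) {
  # low-index clusters lean proneural, high-index lean mesenchymal
  lev <- c("proneural", "classical", "mesenchymal")
  w <- if (k == 1) matrix(1 / 3, 1, 3) else {
    g <- seq(0, 1, length.out = k)
    t(vapply(g, function(x) {
      p <- c(1 - x, 0.6, x) + 0.2
      p / sum(p)
    }, numeric(3)))
  }
  colnames(w) <- lev
  w
}

.simulate_maf <- function(cfg, samples) {
  rates <- cfg$mutation_rates
  hits <- which(matrix(stats::runif(length(rates) * length(samples)),
                       length(rates)) < rates, arr.ind = TRUE)
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Splice_Site")
  if (nrow(hits) == 0) {
    # guarantee a non-empty table: one background mutation in sample 1
    return(maf_table(samples[1], names(rates)[which.max(rates)],
                     "Missense_Mutation"))
  }
  maf_table(sample_id = samples[hits[, 2]],
            gene = names(rates)[hits[, 1]],
            variant_classification = sample(classes, nrow(hits), TRUE,
                                            prob = c(0.7, 0.1, 0.1, 0.1)))
}

.simulate_cnv <- function(cfg, samples) {
  panel <- cfg$regulator_panel
  amp <- cfg$cnv_amp_prob[panel]
  del <- cfg$cnv_del_prob[panel]
  u <- matrix(stats::runif(length(panel) * length(samples)), length(panel))
  calls <- matrix(0L, length(panel), length(samples),
                  dimnames = list(panel, samples))
  calls[u < amp] <- 1L
  calls[u >= amp & u < amp + del] <- -1L
  cnv_table(calls)
}

#' Worked somatic-mutation fixture
#'
#' A fixed 390-sample MAF in which exactly 9 samples carry one mutation
#' each in the 13-gene cuproptosis regulator panel (panel alteration
#' frequency 9/390 = 2.31%), ATP7A is the most frequently mutated panel
#' gene, FDX1, LIAS and GCSH carry none, and every remaining sample carries
#' a single background TP53 mutation so all 390 samples appear.
#'
#' @return a `MafTable` with 390 distinct samples.
#' @export
worked_mutation_fixture <- function() {
  samples <- sprintf("GBM-%03d", 1:390)
  panel_hits <- data.frame(
    sample_id = samples[1:9],
    gene = c("ATP7A", "ATP7A", "ATP7A", "ATP7B", "ATP7B",
             "DLD", "DLAT", "SLC31A1", "PDHA1"),
    stringsAsFactors = FALSE)
  background <- data.frame(sample_id = samples[10:390], gene = "TP53",
                           stringsAsFactors = FALSE)
  all <- rbind(panel_hits, background)
  maf_table(sample_id = all$sample_id, gene = all$gene,
            variant_classification = "Missense_Mutation")
}
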