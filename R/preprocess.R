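# Expression preprocessing: FPKM -> TPM conversion and multi-cohort
# empirical-Bayes batch correction (ComBat).

#' Convert raw FPKM to log2(TPM+1)
#'
#' Per sample s, \eqn{TPM_{gs} = FPKM_{gs} / \sum_g FPKM_{gs} \times 10^6},
#' then log2(TPM+1). Every pre-log TPM column sums to exactly 1e6, so the
#' transform removes per-sample sequencing-depth differences and makes
#' columns scale-invariant.
#'
#' @param expr an [expression_matrix()] flagged `raw_fpkm`.
#' @return an [expression_matrix()] on the log2(TPM+1) scale.
#' @export
fpkm_to_tpm <- function(expr) {
  assert_expression_matrix(expr)
  vals <- expr$values
  if (any(vals < 0)) stopf("FPKM values must be non-negative")
  csum <- colSums(vals)
  if (any(csum == 0))
    stopf("all-zero FPKM column for sample(s): %s",
          paste(expr$sample_ids[csum == 0], collapse = ", "))
  tpm <- sweep(vals, 2, csum, "/") * 1e6
  expression_matrix(log2(tpm + 1), batch = expr$batch, raw_fpkm = FALSE)
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Location/scale adjustment of per-gene batch effects with parametric
#' priors (normal for the additive effect, inverse-gamma for the
#' multiplicative one), as implemented by `sva::ComBat`, run without model
#' covariates. A single batch passes the matrix through unchanged.
#' Zero-variance genes are passed through unadjusted with a warning, since
#' the standardisation step is undefined for them.
#'
#' @param expr an [expression_matrix()]; batch labels taken from
#'   `batch_labels` if given, else from `expr$batch`.
#' @param batch_labels optional per-sample batch labels overriding
#'   `expr$batch`.
#' @return corrected [expression_matrix()] (batch labels preserved).
#' @export
batch_correct <- function(expr, batch_labels = NULL) {
  assert_expression_matrix(expr)
  batch <- if (is.null(batch_labels)) expr$batch else as.character(batch_labels)
  if (is.null(batch)) stopf("no batch labels available")
  if (length(batch) != length(expr$sample_ids))
    stopf("batch labels do not match sample count")
  tab <- table(batch)
  if (length(tab) == 1) return(expr)
  if (any(tab < 2))
    stopf("batch(es) with a single sample: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  vals <- expr$values
  rv <- apply(vals, 1, stats::var)
  constant <- rv == 0
  if (any(constant))
    warnf("%d constant gene(s) passed through unadjusted", sum(constant))
  out <- vals
  if (sum(!constant) > 0) {
    sub <- vals[!constant, , drop = FALSE]
    utils::capture.output(suppressMessages(
      corrected <- sva::ComBat(dat = sub, batch = factor(batch),
                               par.prior = TRUE, prior.plots = FALSE)))
    out[!constant, ] <- corrected
  }
  expression_matrix(out, batch = batch, raw_fpkm = expr$raw_fpkm)
}
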