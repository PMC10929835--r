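#' @keywords internal
"_PACKAGE"

# internal validators shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_expression_matrix <- function(x) {
  if (!is.matrix(x$values) || !is.numeric(x$values))
    stopf("expression values must be a numeric matrix")
  if (anyDuplicated(x$gene_ids)) stopf("duplicate gene ids")
  if (anyDuplicated(x$sample_ids)) stopf("duplicate sample ids")
  if (nrow(x$values) != length(x$gene_ids) ||
      ncol(x$values) != length(x$sample_ids))
    stopf("matrix dimensions inconsistent with id lists")
  if (!all(is.finite(x$values))) stopf("expression values must be finite")
  invisible(x)
}

#' Construct an expression matrix container
#'
#' Genes are rows, samples are columns, everywhere in this package. Values
#' are log2(TPM+1) unless `raw_fpkm = TRUE`.
#'
#' @param values numeric genes x samples matrix with dimnames.
#' @param batch optional per-sample batch labels (recycled name-checked).
#' @param raw_fpkm logical; TRUE marks the matrix as untransformed FPKM.
#' @return an `ExpressionMatrix` list with fields `gene_ids`, `sample_ids`,
#'   `values`, `batch`, `raw_fpkm`.
#' @export
expression_matrix <- function(values, batch = NULL, raw_fpkm = FALSE) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry gene rownames and sample colnames")
  if (!is.null(batch)) {
    if (length(batch) != ncol(values))
      stopf("batch labels (%d) do not match sample count (%d)",
            length(batch), ncol(values))
    batch <- as.character(batch)
  }
  obj <- structure(list(
    gene_ids = rownames(values), sample_ids = colnames(values),
    values = values, batch = batch, raw_fpkm = isTRUE(raw_fpkm)),
    class = "ExpressionMatrix")
  assert_expression_matrix(obj)
  obj
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$raw_fpkm) "raw FPKM" else "log2(TPM+1)"))
  if (!is.null(x$batch))
    cat("batches:", paste(names(table(x$batch)), table(x$batch),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# subset an ExpressionMatrix to a gene panel, erroring on missing names
panel_submatrix <- function(expr, panel) {
  missing <- setdiff(panel, expr$gene_ids)
  if (length(missing))
    stopf("panel genes missing from matrix: %s",
          paste(missing, collapse = ", "))
  expr$values[panel, , drop = FALSE]
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-model-corrected agreement between two partitions of the same
#' samples; 1 for identical partitions (up to relabelling), ~0 for random.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and package version for a pipeline run,
#' including any method substitutions in force (signature-set ssGSEA in
#' place of CIBERSORT deconvolution and of GSVA pathway scoring).
#'
#' @param path output JSON path.
#' @param inputs named list/character of input descriptions.
#' @param params named list of parameters.
#' @param seed integer seed used, or NULL.
#' @param substitutions character vector of substitution notes.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), params = list(), seed = NULL,
                           substitutions = character()) {
  manifest <- list(
    inputs = inputs, params = params, seed = seed,
    substitutions = substitutions,
    package = "cupscore",
    version = as.character(utils::packageVersion("cupscore")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
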