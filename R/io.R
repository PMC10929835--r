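# Readers and writers for the external formats: expression TSV, GMT,
# clinical TSV, MAF, CNV call TSV, PPI edge TSV. All tables are plain
# tab-separated text with a header row; numerics are written at full
# precision so reader/writer pairs round-trip exactly.

.read_table_chr <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("format error: empty file %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", na.strings = character(0))
}

.as_numeric_body <- function(df, path) {
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("parse error in %s: non-numeric value '%s' at row '%s', column '%s'",
          path, body[bad[1, 1], bad[1, 2]], df[[1]][bad[1, 1]],
          colnames(df)[-1][bad[1, 2]])
  dimnames(num) <- list(df[[1]], colnames(df)[-1])
  num
}

#' Read a gene-expression matrix from TSV/CSV
#'
#' First column holds gene ids (or sample ids when
#' `orientation = "samples_in_rows"`, in which case the matrix is
#' transposed on read so genes are always rows downstream). Duplicate gene
#' ids are collapsed to the single row with the highest mean expression;
#' the number collapsed is reported via `message()`.
#'
#' @param path TSV (or .csv) file with a header row.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param raw_fpkm logical, mark values as untransformed FPKM.
#' @param batch optional per-sample batch labels.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            raw_fpkm = FALSE, batch = NULL) {
  orientation <- match.arg(orientation)
  df <- .read_table_chr(path)
  if (ncol(df) < 2) stopf("format error: %s has no data columns", path)
  vals <- .as_numeric_body(df, path)
  if (orientation == "samples_in_rows") vals <- t(vals)
  if (anyDuplicated(rownames(vals))) {
    means <- rowMeans(vals)
    ord <- order(rownames(vals), -means)
    vals <- vals[ord, , drop = FALSE]
    dup <- duplicated(rownames(vals))
    message(sprintf("collapsed %d duplicate gene rows by max mean expression",
                    sum(dup)))
    vals <- vals[!dup, , drop = FALSE]
  }
  expression_matrix(vals, batch = batch, raw_fpkm = raw_fpkm)
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  .write_matrix_tsv(expr$values, path, id_col = "gene_id")
}

.write_matrix_tsv <- function(mat, path, id_col) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes. Lines with fewer
#' than three fields are a format error; empty sets are not allowed.
#'
#' @param path GMT file.
#' @return a `GeneSetCollection`: named list of gene-id character vectors
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("format error: empty GMT file %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stopf("format error in %s: GMT line %d has %d fields (need >= 3)",
          path, which(nf < 3)[1], nf[nf < 3][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in %s", path)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, "", 2), names(sets))
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a GMT gene-set collection
#' @param sets a `GeneSetCollection` (named list of gene vectors).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id, time, event, age, sex, idh_status, subtype,
#' tmz` (missing optional covariates tolerated; `sample_id`, `time`, `event`
#' required). Survival time is in days; events are 0/1. Missing covariate
#' values stay explicit `NA` and are excluded per analysis, never imputed.
#'
#' @param path TSV file.
#' @return data.frame of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- .read_table_chr(path)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("clinical table missing required columns: %s",
          paste(miss, collapse = ", "))
  out <- data.frame(sample_id = df$sample_id,
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  for (cv in c("age", "sex", "idh_status", "subtype", "tmz"))
    out[[cv]] <- if (cv %in% colnames(df)) {
      v <- df[[cv]]
      v[toupper(trimws(v)) == "NA" | v == ""] <- NA
      if (cv == "age") as.numeric(v) else v
    } else NA
  validate_clinical(out)
}

validate_clinical <- function(out) {
  if (anyDuplicated(out$sample_id)) stopf("duplicate sample_id in clinical table")
  if (any(is.na(out$time)) || any(out$time < 0))
    stopf("survival times must be numeric and >= 0")
  if (!all(out$event %in% c(0L, 1L))) stopf("event must be 0 or 1")
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Write a clinical table as TSV
#' @param clinical a `ClinicalTable`.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  df <- as.data.frame(clinical)
  df$time <- sprintf("%.17g", df$time)
  if (!is.null(df$age)) df$age <- ifelse(is.na(df$age), "NA",
                                         sprintf("%.17g", as.numeric(df$age)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# MAF controlled vocabulary for Variant_Classification
.maf_vocab <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Silent", "Splice_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site", "Nonstop_Mutation", "3'UTR", "5'UTR",
  "3'Flank", "5'Flank", "Intron", "RNA", "Targeted_Region", "IGR")

#' Read a MAF somatic-mutation table
#'
#' Requires at least `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`. Records with a classification outside the MAF
#' controlled vocabulary are kept but flagged in the `flagged` column
#' (with a warning).
#'
#' @param path tab-separated MAF file.
#' @return data.frame of class `MafTable` with columns `sample_id`, `gene`,
#'   `variant_classification`, `flagged`.
#' @export
read_maf <- function(path) {
  df <- .read_table_chr(path)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("MAF missing required columns: %s", paste(miss, collapse = ", "))
  maf_table(gene = df$Hugo_Symbol, sample_id = df$Tumor_Sample_Barcode,
            variant_classification = df$Variant_Classification)
}

#' Construct a MAF table from vectors
#' @param sample_id,gene,variant_classification character vectors of equal
#'   length, one somatic mutation record per element.
#' @return a `MafTable` data.frame.
#' @export
maf_table <- function(sample_id, gene, variant_classification) {
  out <- data.frame(sample_id = as.character(sample_id),
                    gene = as.character(gene),
                    variant_classification = as.character(variant_classification),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sample_id)) || any(!nzchar(out$gene)) ||
      any(!nzchar(out$variant_classification)))
    stopf("MAF fields must be non-empty")
  out$flagged <- !(out$variant_classification %in% .maf_vocab)
  if (any(out$flagged))
    warnf("%d MAF records carry a Variant_Classification outside the controlled vocabulary (kept, flagged)",
          sum(out$flagged))
  class(out) <- c("MafTable", "data.frame")
  out
}

#' Write a MAF table
#' @param maf a `MafTable`.
#' @param path output path.
#' @export
write_maf <- function(maf, path) {
  df <- data.frame(Hugo_Symbol = maf$gene,
                   Tumor_Sample_Barcode = maf$sample_id,
                   Variant_Classification = maf$variant_classification)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a discrete CNV call table
#'
#' Genes x samples TSV whose body may only contain -1 (deletion),
#' 0 (neutral) or +1 (amplification).
#'
#' @param path TSV file.
#' @return integer matrix of class `CnvCallTable`.
#' @export
read_cnv <- function(path) {
  df <- .read_table_chr(path)
  vals <- .as_numeric_body(df, path)
  cnv_table(vals)
}

#' Construct a CNV call table from a matrix
#' @param vals genes x samples matrix of calls in \{-1, 0, +1\}.
#' @return integer matrix of class `CnvCallTable`.
#' @export
cnv_table <- function(vals) {
  if (!all(vals %in% c(-1, 0, 1)))
    stopf("CNV calls must be in {-1, 0, +1}")
  storage.mode(vals) <- "integer"
  class(vals) <- c("CnvCallTable", class(vals))
  vals
}

#' Write a CNV call table
#' @param cnv a `CnvCallTable`.
#' @param path output path.
#' @export
write_cnv <- function(cnv, path) {
  mat <- unclass(cnv)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(rownames(mat),
                   apply(mat, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `score` (confidence in [0, 1]).
#' Self-edges are dropped; edges with `score <= min_score` are dropped
#' (strict inequality, default 0.7); duplicate undirected pairs keep the
#' highest score; the pair is stored in canonical (sorted) order.
#'
#' @param path TSV file.
#' @param min_score confidence threshold, edges kept when score > min_score.
#' @return data.frame of class `EdgeTable`.
#' @export
read_edges <- function(path, min_score = 0.7) {
  df <- .read_table_chr(path)
  need <- c("gene_a", "gene_b", "score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("edge table missing required columns: %s", paste(miss, collapse = ", "))
  edge_table(df$gene_a, df$gene_b, as.numeric(df$score), min_score = min_score)
}

#' Construct an edge table from vectors
#' @param gene_a,gene_b endpoint gene ids.
#' @param score confidence scores in [0, 1].
#' @param min_score strict retention threshold (kept when score > min_score).
#' @return an `EdgeTable` data.frame with canonical undirected pairs.
#' @export
edge_table <- function(gene_a, gene_b, score, min_score = 0.7) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1))
    stopf("edge scores must lie in [0, 1]")
  keep <- gene_a != gene_b & score > min_score
  a <- pmin(gene_a[keep], gene_b[keep])
  b <- pmax(gene_a[keep], gene_b[keep])
  s <- score[keep]
  ord <- order(a, b, -s)
  out <- data.frame(gene_a = a[ord], gene_b = b[ord], score = s[ord],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EdgeTable", "data.frame")
  attr(out, "min_score") <- min_score
  out
}

#' Write an edge table
#' @param edges an `EdgeTable`.
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges)
  df$score <- sprintf("%.17g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
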