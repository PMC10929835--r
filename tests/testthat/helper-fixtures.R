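# shared builders; the default cohort is cached per session since several
# files exercise it

.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1) {
  key <- paste0("cohort", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_cohort(synthetic_config(), seed = seed)
  .fixture_cache[[key]]
}

toy_expr <- function(vals, genes = NULL, samples = NULL, ...) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, ...)
}

toy_clinical <- function(time, event, ids = sprintf("s%d", seq_along(time))) {
  cupscore:::validate_clinical(
    data.frame(sample_id = ids, time = time, event = as.integer(event),
               stringsAsFactors = FALSE))
}

gene_sets <- function(...) {
  sets <- list(...)
  class(sets) <- "GeneSetCollection"
  sets
}
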