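# Small fixture builders shared across the suite.

toy_scores <- function(values = matrix(c(1, -2, NA, 4), 2, 2),
                       queries = NULL, libs = NULL) {
  if (is.null(queries)) queries <- rownames(values)
  if (is.null(queries)) queries <- sprintf("Q%d", seq_len(nrow(values)))
  if (is.null(libs)) libs <- colnames(values)
  if (is.null(libs)) libs <- sprintf("L%d", seq_len(ncol(values)))
  dimnames(values) <- list(queries, libs)
  sscore_matrix(values)
}

toy_expr <- function(values, experiment = "toy") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  expression_matrix(values, experiment = experiment)
}

toy_annotation <- function(...) {
  annotation_table(list(...))
}

# a coexpression_table from explicit pair rows
toy_cc <- function(gene_a, gene_b, cc) {
  df <- data.frame(gene_a = gene_a, gene_b = gene_b, cc = cc,
                   lag = 0L, stringsAsFactors = FALSE)
  combine_experiments(list(toy = df))
}

# fast, small synthetic world for integration-style tests
small_config <- function(seed = 1, ...) {
  args <- list(n_library = 120, n_tfs = 12, n_modules = 6,
               n_experiments = 2, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}
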