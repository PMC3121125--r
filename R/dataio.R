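#' @keywords internal
"_PACKAGE"

# ---- constructors -----------------------------------------------------------

#' S-score matrix of a quantitative genetic-interaction screen
#'
#' Container for an E-MAP-style screen: query genes (rows) crossed against a
#' library of test strains (columns), each cell holding the S-score of the
#' double mutant (positive = alleviating, negative = aggravating/synthetic
#' sick). Missing measurements are `NA`.
#'
#' @param scores numeric matrix with unique, non-empty row and column names.
#' @return An object of class `sscore_matrix`: a list with elements
#'   `queries`, `library` (character vectors) and `scores` (the matrix).
#' @export
sscore_matrix <- function(scores) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  q <- rownames(scores)
  l <- colnames(scores)
  .check_gene_ids(q, "query")
  .check_gene_ids(l, "library")
  if (!any(is.finite(scores))) {
    stop("S-score matrix contains no non-missing entries")
  }
  structure(list(queries = q, library = l, scores = scores),
            class = "sscore_matrix")
}

#' @export
print.sscore_matrix <- function(x, ...) {
  cat(sprintf("S-score matrix: %d queries x %d library strains (%.1f%% measured)\n",
              length(x$queries), length(x$library),
              100 * mean(!is.na(x$scores))))
  invisible(x)
}

#' Time-course expression matrix
#'
#' @param values numeric matrix, genes in rows (named), ordered timepoints in
#'   columns. `NA` marks unobserved values.
#' @param timepoints strictly increasing numeric sampling times; defaults to
#'   `0:(ncol(values)-1)`.
#' @param experiment experiment name used when aggregating across series.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, timepoints = NULL, experiment = "expr") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(timepoints)) timepoints <- seq_len(ncol(values)) - 1
  stopifnot(length(timepoints) == ncol(values))
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing")
  }
  .check_gene_ids(rownames(values), "gene")
  colnames(values) <- NULL  # canonical form: times live in `timepoints`
  structure(list(genes = rownames(values), timepoints = as.numeric(timepoints),
                 values = values, experiment = as.character(experiment)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix '%s': %d genes x %d timepoints (%.1f%% observed)\n",
              x$experiment, nrow(x$values), ncol(x$values),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Gene-to-function annotation table
#'
#' Flat gene -> set-of-terms mapping (GO biological process / MIPS style).
#' Genes absent from the table are treated as unannotated; no term
#' propagation along the ontology graph is performed.
#'
#' @param mapping named list: gene id -> character vector of term ids, or a
#'   two-column data.frame (gene, term).
#' @return Object of class `annotation_table` (named list of term sets).
#' @export
annotation_table <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2)
    mapping <- split(as.character(mapping[[2]]), as.character(mapping[[1]]))
  }
  stopifnot(is.list(mapping))
  .check_gene_ids(names(mapping), "annotated gene", allow_dup = TRUE)
  mapping <- lapply(mapping, function(v) unique(as.character(v)))
  if (any(lengths(mapping) == 0)) {
    stop("every annotated gene must carry at least one term")
  }
  structure(mapping, class = "annotation_table")
}

#' TF -> target binding network (chip-chip style)
#'
#' @param edges data.frame with columns `tf` and `target` (directed, binary).
#' @param tf_universe character vector of all assayed TFs; defaults to the
#'   distinct edge sources.
#' @return Object of class `binding_network`.
#' @export
binding_network <- function(edges, tf_universe = NULL) {
  edges <- data.frame(tf = as.character(edges[[1]]),
                      target = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  if (is.null(tf_universe)) tf_universe <- unique(edges$tf)
  tf_universe <- unique(as.character(tf_universe))
  if (!all(edges$tf %in% tf_universe)) {
    bad <- setdiff(unique(edges$tf), tf_universe)
    stop("edge source(s) not in tf_universe: ", paste(bad, collapse = ", "))
  }
  key <- paste(edges$tf, edges$target, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, tf_universe = tf_universe),
            class = "binding_network")
}

#' @export
print.binding_network <- function(x, ...) {
  cat(sprintf("Binding network: %d edges from %d TFs (%d in universe)\n",
              nrow(x$edges), length(unique(x$edges$tf)), length(x$tf_universe)))
  invisible(x)
}

#' TF -> gene regulatory evidence from wild-type vs TF-mutant comparisons
#'
#' Directed pairs asserting that deleting/perturbing the TF changes the
#' gene's expression; the relation may be indirect (no binding implied).
#'
#' @param pairs data.frame with columns `tf`, `gene`.
#' @return Object of class `regulatory_evidence` (deduplicated data.frame).
#' @export
regulatory_evidence <- function(pairs) {
  pairs <- data.frame(tf = as.character(pairs[[1]]),
                      gene = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  key <- paste(pairs$tf, pairs$gene, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("regulatory_evidence", "data.frame"))
}

#' Benchmark genetic-interaction list with sign classes
#'
#' Unordered gene pairs labelled `"positive"` (phenotypic suppression /
#' synthetic rescue style) or `"negative"` (phenotypic enhancement,
#' synthetic growth defect, synthetic lethality style).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `class`.
#' @return Object of class `benchmark_interactions`.
#' @export
benchmark_interactions <- function(pairs) {
  stopifnot(ncol(pairs) >= 3)
  cls <- as.character(pairs[[3]])
  if (!all(cls %in% c("positive", "negative"))) {
    stop("benchmark class must be 'positive' or 'negative'")
  }
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  swap <- a > b  # canonical unordered order
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, class = cls,
                    stringsAsFactors = FALSE)
  key <- paste(a, b, cls, sep = "\r")
  if (anyDuplicated(key)) {
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("benchmark_interactions", "data.frame"))
}

#' Named gene list (e.g. CDC28 substrates, known cell-cycle genes)
#'
#' @param name label for the list.
#' @param members character vector of gene ids (non-empty).
#' @return Object of class `gene_list`.
#' @export
gene_list <- function(name, members) {
  members <- unique(as.character(members))
  .check_gene_ids(members, name)
  if (length(members) == 0) stop("gene list '", name, "' is empty")
  structure(list(name = as.character(name), members = members),
            class = "gene_list")
}

.check_gene_ids <- function(ids, what, allow_dup = FALSE) {
  if (is.null(ids)) stop(what, " gene identifiers are missing")
  ids <- as.character(ids)
  if (any(is.na(ids) | ids == "" | grepl("[[:space:]]", ids))) {
    stop(what, " identifiers must be non-empty tokens without whitespace")
  }
  if (!allow_dup && anyDuplicated(ids)) {
    stop("duplicate ", what, " identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(ids)
}

# ---- TSV readers / writers --------------------------------------------------

# Shared TSV dialect: header row + first id column for matrices; empty cell or
# literal "NA" marks a missing value; ids are trimmed and compared
# case-sensitively.

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    stringsAsFactors = FALSE)
}

.parse_numeric_cells <- function(raw, what) {
  x <- trimws(as.matrix(raw))
  miss <- x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric %s cell at row %d, column %d: '%s'",
                 what, bad[1, 1], bad[1, 2], x[bad[1, 1], bad[1, 2]]))
  }
  out[miss] <- NA_real_
  matrix(out, nrow = nrow(x), dimnames = dimnames(raw))
}

#' Read an S-score matrix from TSV
#'
#' Expects a header row of library gene ids and a first column of query gene
#' ids. Empty cells or `"NA"` are read as missing (never zero-filled).
#' Duplicate row or column ids and non-numeric cells are hard errors.
#'
#' @param path path to a TSV file.
#' @return An [sscore_matrix].
#' @export
read_score_matrix <- function(path) {
  raw <- .read_tsv(path)
  queries <- trimws(raw[[1]])
  libs <- trimws(colnames(raw)[-1])
  .check_gene_ids(queries, "query")
  .check_gene_ids(libs, "library")
  body <- raw[, -1, drop = FALSE]
  m <- .parse_numeric_cells(body, "S-score")
  dimnames(m) <- list(queries, libs)
  sscore_matrix(m)
}

#' Write an S-score matrix as TSV
#'
#' @param x an [sscore_matrix].
#' @param path output path (parent directory must exist).
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "sscore_matrix"))
  .write_matrix_tsv(x$scores, "query", path)
}

#' Read a time-course expression matrix from TSV
#'
#' Header row holds sampling times (numeric) and the first column gene ids.
#'
#' @param path path to a TSV file.
#' @param experiment experiment name; defaults to the file name without
#'   extension.
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path, experiment = NULL) {
  if (is.null(experiment)) {
    experiment <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- .read_tsv(path)
  genes <- trimws(raw[[1]])
  .check_gene_ids(genes, "gene")
  tps <- suppressWarnings(as.numeric(colnames(raw)[-1]))
  if (anyNA(tps)) stop("expression header must hold numeric timepoints")
  m <- .parse_numeric_cells(raw[, -1, drop = FALSE], "expression")
  dimnames(m) <- list(genes, colnames(raw)[-1])
  expression_matrix(m, timepoints = tps, experiment = experiment)
}

#' Write a time-course expression matrix as TSV
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- x$values
  colnames(m) <- format(x$timepoints, trim = TRUE, scientific = FALSE)
  .write_matrix_tsv(m, "gene", path)
}

.write_matrix_tsv <- function(m, id_label, path) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(m)] <- "NA"
  names(df)[1] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TF -> target edge list (binding network) from TSV
#'
#' Columns: `tf`, `target`. All distinct sources plus any ids passed in
#' `tf_universe` form the TF universe.
#'
#' @param path TSV path.
#' @param tf_universe optional character vector extending the TF universe
#'   beyond the observed edge sources.
#' @return A [binding_network].
#' @export
read_binding_network <- function(path, tf_universe = NULL) {
  raw <- .read_tsv(path)
  edges <- data.frame(tf = trimws(raw[[1]]), target = trimws(raw[[2]]),
                      stringsAsFactors = FALSE)
  binding_network(edges, tf_universe = union(unique(edges$tf), tf_universe))
}

#' Write a binding network as a TSV edge list
#' @param x a [binding_network].
#' @param path output path.
#' @export
write_binding_network <- function(x, path) {
  stopifnot(inherits(x, "binding_network"))
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read TF -> gene regulatory evidence pairs from TSV
#' @param path TSV path with columns `tf`, `gene`.
#' @return A [regulatory_evidence] data.frame.
#' @export
read_regulatory_evidence <- function(path) {
  raw <- .read_tsv(path)
  regulatory_evidence(data.frame(tf = trimws(raw[[1]]),
                                 gene = trimws(raw[[2]]),
                                 stringsAsFactors = FALSE))
}

#' Read benchmark interactions (gene_a, gene_b, class) from TSV
#' @param path TSV path.
#' @return A [benchmark_interactions] data.frame.
#' @export
read_benchmark_interactions <- function(path) {
  raw <- .read_tsv(path)
  benchmark_interactions(data.frame(gene_a = trimws(raw[[1]]),
                                    gene_b = trimws(raw[[2]]),
                                    class = trimws(raw[[3]]),
                                    stringsAsFactors = FALSE))
}

#' Read a two-column gene -> term annotation table from TSV
#' @param path TSV path with columns gene, term.
#' @return An [annotation_table].
#' @export
read_annotation <- function(path) {
  raw <- .read_tsv(path)
  annotation_table(data.frame(gene = trimws(raw[[1]]), term = trimws(raw[[2]]),
                              stringsAsFactors = FALSE))
}

#' Write an annotation table as two-column TSV
#' @param x an [annotation_table].
#' @param path output path.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "annotation_table"))
  df <- data.frame(gene = rep(names(x), lengths(x)),
                   term = unlist(x, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- KNN imputation ---------------------------------------------------------

#' Impute missing expression values by k-nearest-neighbour averaging
#'
#' For each missing cell the k genes closest in Euclidean distance (over the
#' timepoints both genes observe) among genes observed at the target
#' timepoint contribute a weighted mean (weights = inverse distance).
#' Observed values are never altered. Genes missing more than
#' `max_missing_fraction` of their timepoints are dropped before imputation
#' and recorded in the `dropped_genes` attribute.
#'
#' @param expr an [expression_matrix].
#' @param k number of neighbours (default 10, the customary KNN-imputation
#'   default).
#' @param max_missing_fraction per-gene missingness cap above which the gene
#'   is excluded (default 0.5).
#' @return An [expression_matrix] without missing values, with attributes
#'   `dropped_genes` and `degraded_genes` (genes whose fallback was their own
#'   observed mean because no neighbour was usable).
#' @export
knn_impute <- function(expr, k = 10, max_missing_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"), k >= 1)
  m <- expr$values
  frac_missing <- rowMeans(is.na(m))
  dropped <- rownames(m)[frac_missing > max_missing_fraction]
  if (length(dropped) > 0) {
    message("knn_impute: dropping ", length(dropped),
            " gene(s) above missingness cap: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    m <- m[!(rownames(m) %in% dropped), , drop = FALSE]
  }
  degraded <- character(0)
  obs <- m  # imputed values are always computed from observed data only
  need <- which(rowSums(is.na(obs)) > 0)
  for (i in need) {
    miss_t <- which(is.na(obs[i, ]))
    obs_i <- !is.na(obs[i, ])
    for (t in miss_t) {
      cand <- which(!is.na(obs[, t]))
      cand <- setdiff(cand, i)
      d <- rep(NA_real_, length(cand))
      for (j in seq_along(cand)) {
        shared <- obs_i & !is.na(obs[cand[j], ])
        if (any(shared)) {
          d[j] <- sqrt(sum((obs[i, shared] - obs[cand[j], shared])^2))
        }
      }
      ok <- !is.na(d)
      if (!any(ok)) {
        m[i, t] <- mean(obs[i, ], na.rm = TRUE)
        degraded <- union(degraded, rownames(m)[i])
        next
      }
      cand <- cand[ok]; d <- d[ok]
      ord <- order(d, cand)  # deterministic tie-break by row index
      take <- ord[seq_len(min(k, length(ord)))]
      w <- 1 / pmax(d[take], .Machine$double.eps)
      m[i, t] <- sum(w * obs[cand[take], t]) / sum(w)
    }
  }
  if (length(degraded) > 0) {
    message("knn_impute: fell back to own-gene mean for: ",
            paste(degraded, collapse = ", "))
  }
  out <- expression_matrix(m, timepoints = expr$timepoints,
                           experiment = expr$experiment)
  attr(out, "dropped_genes") <- dropped
  attr(out, "degraded_genes") <- degraded
  out
}

# ---- JSON reports -----------------------------------------------------------

REPORT_SCHEMA <- "cyclenet-report/1"

#' Write an analysis report as JSON
#'
#' Wraps the object in an envelope with a schema version field and writes
#' numeric values at full precision.
#'
#' @param obj any report object (lists/data.frames of results).
#' @param path output path; the parent directory must exist.
#' @export
write_report <- function(obj, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  envelope <- list(schema = REPORT_SCHEMA, content = obj)
  jsonlite::write_json(envelope, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report]
#' @param path path to a report file.
#' @return The report content (envelope stripped).
#' @export
read_report <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(env$schema, REPORT_SCHEMA)) {
    stop("unrecognised report schema: ", env$schema)
  }
  env$content
}
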