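# Co-functionality enrichment over (S-score, cc), significance-region
# filtering and extraction of the potential cell-cycle gene set (PCCG).
#
# f = fraction of pairs in a score bin/region sharing an annotation term;
# r = the same fraction over all measured pairs; the enrichment is f/r.

#' Do two genes share an annotation term?
#'
#' @param a,b gene ids.
#' @param ann an [annotation_table].
#' @return `TRUE` iff both genes are annotated and their term sets
#'   intersect; unannotated genes never count as co-functional.
#' @export
cofunctional <- function(a, b, ann) {
  stopifnot(inherits(ann, "annotation_table"))
  ta <- ann[[a]]; tb <- ann[[b]]
  if (is.null(ta) || is.null(tb)) return(FALSE)
  length(intersect(ta, tb)) > 0
}

# vectorized co-functionality over pair columns
.cofunctional_vec <- function(a, b, ann) {
  mapply(function(x, y) {
    tx <- ann[[x]]; ty <- ann[[y]]
    !is.null(tx) && !is.null(ty) && length(intersect(tx, ty)) > 0
  }, a, b, USE.NAMES = FALSE)
}

#' Assemble the measured pair universe of a screen
#'
#' One row per non-missing (query, library) cell of the S-score matrix with
#' its combined co-expression value (`NA` when the pair has no valid
#' correlation in any experiment).
#'
#' @param scores an [sscore_matrix].
#' @param cc a `coexpression_table` (see [coexpression_table]) or `NULL`.
#' @return data.frame with columns `query`, `library`, `s`, `cc`.
#' @export
pair_universe <- function(scores, cc = NULL) {
  stopifnot(inherits(scores, "sscore_matrix"))
  idx <- which(!is.na(scores$scores), arr.ind = TRUE)
  out <- data.frame(query = scores$queries[idx[, 1]],
                    library = scores$library[idx[, 2]],
                    s = scores$scores[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(cc) && nrow(cc) > 0) {
    lut <- .cc_lookup(cc)
    out$cc <- unname(lut[.pair_key(out$query, out$library)])
  } else {
    out$cc <- NA_real_
  }
  out <- out[order(out$query, out$library), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned co-functionality enrichment along one score axis
#'
#' Bins the pairs by S-score or correlation into half-open bins `[lo, hi)`
#' and reports, per bin, the co-functional fraction `f`, the global
#' fraction `r` and the enrichment ratio `f/r`. Empty bins are flagged
#' (`pair_count = 0`, `f`/`ratio` `NA`).
#'
#' @param pairs data.frame from [pair_universe] (columns `query`, `library`
#'   and the chosen axis).
#' @param ann an [annotation_table].
#' @param axis `"sscore"` or `"cc"`.
#' @param bin_size bin width (defaults: 1.5 for S-score, 0.1 for cc).
#' @return data.frame with columns `lo`, `hi`, `pair_count`, `f`, `r`,
#'   `ratio`; attribute `r` holds the global co-functional fraction.
#' @export
enrichment_curve <- function(pairs, ann, axis = c("sscore", "cc"),
                             bin_size = NULL) {
  axis <- match.arg(axis)
  if (is.null(bin_size)) bin_size <- if (axis == "sscore") 1.5 else 0.1
  stopifnot(bin_size > 0)
  v <- if (axis == "sscore") pairs$s else pairs$cc
  keep <- !is.na(v)
  v <- v[keep]
  if (length(v) == 0) stop("no pairs carry a value on axis '", axis, "'")
  cof <- .cofunctional_vec(pairs$query[keep], pairs$library[keep], ann)
  r <- mean(cof)
  if (r == 0) stop("annotation carries no shared terms among measured pairs")
  lo0 <- floor(min(v) / bin_size) * bin_size
  edges <- seq(lo0, max(v) + bin_size, by = bin_size)
  bin <- findInterval(v, edges, rightmost.closed = FALSE)
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1])
  out$pair_count <- vapply(seq_len(nrow(out)),
                           function(i) sum(bin == i), integer(1))
  out$f <- vapply(seq_len(nrow(out)), function(i) {
    if (out$pair_count[i] == 0) NA_real_ else mean(cof[bin == i])
  }, numeric(1))
  out$r <- r
  out$ratio <- out$f / r
  structure(out, r = r, axis = axis)
}

#' Cumulative co-functionality enrichment over joint (S-score, cc) cells
#'
#' For the positive tail a cell `(s*, c*)` aggregates pairs with
#' `s >= s*` and `cc >= c*`; for the negative tail, `s <= s*` and
#' `cc >= c*`. Cells with a correlation threshold above −1 exclude pairs
#' with no measured correlation; at `c* <= -1` the cc constraint is vacuous
#' and such pairs are included, so the loosest cell reproduces the whole
#' measured universe and has ratio exactly 1.
#'
#' @param pairs data.frame from [pair_universe].
#' @param ann an [annotation_table].
#' @param s_grid numeric S-score thresholds (used for both tails, the
#'   negative tail negating where appropriate is the caller's choice).
#' @param cc_grid numeric correlation thresholds.
#' @return data.frame with columns `tail` (`"+"`/`"-"`), `s_threshold`,
#'   `cc_threshold`, `pair_count`, `f`, `ratio`, `empty`.
#' @export
enrichment_surface <- function(pairs, ann, s_grid, cc_grid) {
  stopifnot(length(s_grid) > 0, length(cc_grid) > 0)
  cof <- .cofunctional_vec(pairs$query, pairs$library, ann)
  r <- mean(cof)
  if (r == 0) stop("annotation carries no shared terms among measured pairs")
  grid <- expand.grid(tail = c("+", "-"), s_threshold = s_grid,
                      cc_threshold = cc_grid, stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    st <- grid$s_threshold[i]; ct <- grid$cc_threshold[i]
    in_s <- if (grid$tail[i] == "+") pairs$s >= st else pairs$s <= st
    in_c <- if (ct <= -1) rep(TRUE, nrow(pairs)) else !is.na(pairs$cc) & pairs$cc >= ct
    sel <- in_s & in_c
    cnt <- sum(sel)
    f <- if (cnt == 0) NA_real_ else mean(cof[sel])
    c(cnt, f)
  }, numeric(2)))
  grid$pair_count <- as.integer(res[, 1])
  grid$f <- res[, 2]
  grid$ratio <- grid$f / r
  grid$empty <- grid$pair_count == 0
  structure(grid, r = r, class = c("enrichment_surface", "data.frame"))
}

#' The published significance region for genetically interacting pairs
#'
#' Four conjunctive clauses (strict inequalities) whose union defines a
#' significant pair: `(s > 2.5 & cc > 0.9)`, `s > 6`, `(s < -3 & cc > 0.9)`,
#' `(s < -14 & cc > 0.85)`.
#'
#' @return An `interaction_region`: data.frame with columns `sign`
#'   (`"pos"`/`"neg"`), `s_bound` (strict threshold on s, lower bound for
#'   pos, upper bound for neg), `cc_min` (strict lower bound on cc, `NA` =
#'   no correlation requirement).
#' @export
default_region <- function() {
  interaction_region(data.frame(
    sign = c("pos", "pos", "neg", "neg"),
    s_bound = c(2.5, 6, -3, -14),
    cc_min = c(0.9, NA, 0.9, 0.85),
    stringsAsFactors = FALSE))
}

#' Construct an interaction region from clauses
#'
#' @param clauses data.frame with columns `sign` ("pos"/"neg"), `s_bound`,
#'   `cc_min` (`NA` for clauses without a correlation requirement). A pair
#'   passes the region if it satisfies any clause.
#' @return An `interaction_region` data.frame.
#' @export
interaction_region <- function(clauses) {
  stopifnot(all(c("sign", "s_bound", "cc_min") %in% names(clauses)))
  if (nrow(clauses) > 0) {
    stopifnot(all(clauses$sign %in% c("pos", "neg")),
              all(!is.na(clauses$s_bound) | !is.na(clauses$cc_min)))
  }
  structure(as.data.frame(clauses), class = c("interaction_region",
                                              "data.frame"))
}

# clause satisfaction matrix: rows = pairs, cols = clauses
.region_pass <- function(region, s, cc) {
  sapply(seq_len(nrow(region)), function(i) {
    ok <- if (region$sign[i] == "pos") s > region$s_bound[i]
          else s < region$s_bound[i]
    if (!is.na(region$cc_min[i])) {
      ok <- ok & !is.na(cc) & cc > region$cc_min[i]
    }
    ok & !is.na(s)
  })
}

#' Derive a significance region from an enrichment surface
#'
#' Selects, per tail, the non-empty grid cells whose enrichment ratio
#' exceeds the sign-appropriate minimum (defaults 2 for the positive and 4
#' for the negative tail) and returns the loosest such cells (the Pareto
#' frontier: no selected cell is dominated by a looser selected cell) as
#' region clauses with strict bounds.
#'
#' @param surface an `enrichment_surface` from [enrichment_surface].
#' @param pos_min_ratio minimum enrichment ratio for positive-tail cells
#'   (default 2).
#' @param neg_min_ratio minimum ratio for negative-tail cells (default 4).
#' @return An `interaction_region`; empty (with a warning) when no cell
#'   qualifies.
#' @export
region_from_surface <- function(surface, pos_min_ratio = 2,
                                neg_min_ratio = 4) {
  stopifnot(inherits(surface, "enrichment_surface"))
  pick <- function(tail, min_ratio) {
    cells <- surface[surface$tail == tail & !surface$empty &
                       !is.na(surface$ratio) & surface$ratio > min_ratio, ,
                     drop = FALSE]
    if (nrow(cells) == 0) return(NULL)
    # keep Pareto-loosest cells: nothing selected dominates them from below
    looser_s <- function(a, b) if (tail == "+") a <= b else a >= b
    keep <- vapply(seq_len(nrow(cells)), function(i) {
      !any(looser_s(cells$s_threshold, cells$s_threshold[i]) &
             cells$cc_threshold <= cells$cc_threshold[i] &
             seq_len(nrow(cells)) != i &
             # strict domination in at least one coordinate
             (cells$s_threshold != cells$s_threshold[i] |
                cells$cc_threshold != cells$cc_threshold[i]))
    }, logical(1))
    cells <- cells[keep, , drop = FALSE]
    data.frame(sign = if (tail == "+") "pos" else "neg",
               s_bound = cells$s_threshold,
               cc_min = ifelse(cells$cc_threshold <= -1, NA_real_,
                               cells$cc_threshold),
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick("+", pos_min_ratio), pick("-", neg_min_ratio))
  if (is.null(out) || nrow(out) == 0) {
    warning("no surface cell exceeds the enrichment minima: empty region")
    out <- data.frame(sign = character(0), s_bound = numeric(0),
                      cc_min = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  interaction_region(out)
}

#' Extract the potential cell-cycle gene set (PCCG)
#'
#' Applies an interaction region to all measured (query, library) pairs.
#' Pairs with no measured correlation can still pass clauses without a
#' correlation requirement; the PCCG is the set of library genes in at
#' least one passing pair, split into a positive and a negative part by the
#' sign of the satisfied clause (a gene may sit in both).
#'
#' @param scores an [sscore_matrix].
#' @param cc a `coexpression_table`, or `NULL` when only cc-free clauses
#'   should fire.
#' @param region an `interaction_region` (e.g. [default_region]).
#' @return A `cofunctional_pair_set`: list with `pairs` (data.frame `query`,
#'   `library`, `s`, `cc`, `sign`), `pccg`, `positive_part`,
#'   `negative_part` (character vectors).
#' @export
extract_pccg <- function(scores, cc, region) {
  stopifnot(inherits(region, "interaction_region"))
  pairs <- pair_universe(scores, cc)
  if (nrow(region) == 0) {
    pass <- pairs[0, , drop = FALSE]
    pass$sign <- character(0)
  } else {
    pm <- .region_pass(region, pairs$s, pairs$cc)
    if (is.null(dim(pm))) pm <- matrix(pm, ncol = nrow(region))
    any_pass <- rowSums(pm) > 0
    pos_pass <- rowSums(pm[, region$sign == "pos", drop = FALSE]) > 0
    neg_pass <- rowSums(pm[, region$sign == "neg", drop = FALSE]) > 0
    pass <- pairs[any_pass, , drop = FALSE]
    pass$sign <- ifelse(pos_pass & neg_pass, "both",
                        ifelse(pos_pass, "pos", "neg"))[any_pass]
  }
  rownames(pass) <- NULL
  structure(list(
    pairs = pass,
    pccg = sort(unique(pass$library)),
    positive_part = sort(unique(pass$library[pass$sign %in% c("pos", "both")])),
    negative_part = sort(unique(pass$library[pass$sign %in% c("neg", "both")]))),
    class = "cofunctional_pair_set")
}

#' @export
print.cofunctional_pair_set <- function(x, ...) {
  cat(sprintf("Co-functional pair set: %d passing pairs, %d PCCGs (%d positive / %d negative part)\n",
              nrow(x$pairs), length(x$pccg), length(x$positive_part),
              length(x$negative_part)))
  invisible(x)
}

#' Union of PCCGs and known cell-cycle genes, with overlap bookkeeping
#'
#' @param pccg character vector (or `cofunctional_pair_set`).
#' @param kccg character vector of known cell-cycle (query) genes.
#' @return list with `union`, `overlap`, `n_union`, `n_overlap`,
#'   `n_raw_sum` (|PCCG| + |KCCG|, which double-counts the overlap).
#' @export
pccg_kccg_union <- function(pccg, kccg) {
  if (inherits(pccg, "cofunctional_pair_set")) pccg <- pccg$pccg
  u <- union(pccg, kccg)
  o <- intersect(pccg, kccg)
  list(union = sort(u), overlap = sort(o), n_union = length(u),
       n_overlap = length(o), n_raw_sum = length(pccg) + length(kccg))
}

#' Evaluate predictions against a benchmark interaction list
#'
#' Predicted pairs are the measured pairs passing `region` (optionally by
#' sign class). TP counts predicted pairs present in the benchmark;
#' sensitivity = TP / benchmark pairs among measured; precision =
#' TP / predicted; and the precision p-value is the upper-tail
#' hypergeometric probability of drawing at least TP benchmark pairs in
#' `predicted` draws from the measured-pair population.
#'
#' @param scores an [sscore_matrix].
#' @param region an `interaction_region`, or a length-2 numeric
#'   `c(neg_cut, pos_cut)` meaning `s < neg_cut | s > pos_cut`.
#' @param benchmark a [benchmark_interactions] table.
#' @param cc optional `coexpression_table` for cc-dependent clauses.
#' @param class `"any"`, `"positive"` or `"negative"`: restrict the
#'   benchmark (and, for a region, the clauses) to one sign class.
#' @param universe_size population size override (default: number of
#'   measured pairs).
#' @return list with `TP`, `predicted`, `benchmark_measured`,
#'   `sensitivity`, `precision`, `p_precision`.
#' @export
benchmark_eval <- function(scores, region, benchmark, cc = NULL,
                           class = c("any", "positive", "negative"),
                           universe_size = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(benchmark, "benchmark_interactions"))
  if (is.numeric(region) && length(region) == 2) {
    region <- interaction_region(data.frame(
      sign = c("neg", "pos"), s_bound = sort(region), cc_min = NA_real_))
  }
  if (class != "any") {
    keep <- region$sign == if (class == "positive") "pos" else "neg"
    region <- interaction_region(region[keep, , drop = FALSE])
    benchmark <- benchmark[benchmark$class == class, , drop = FALSE]
  }
  pairs <- pair_universe(scores, cc)
  n_meas <- nrow(pairs)
  if (is.null(universe_size)) universe_size <- n_meas
  key_meas <- .pair_key(pairs$query, pairs$library)
  key_bench <- unique(paste(benchmark$gene_a, benchmark$gene_b, sep = "\r"))
  bench_in <- key_meas %in% key_bench
  pm <- if (nrow(region) == 0) matrix(FALSE, n_meas, 0) else
    .region_pass(region, pairs$s, pairs$cc)
  if (is.null(dim(pm))) pm <- matrix(pm, ncol = max(1, nrow(region)))
  pred <- rowSums(pm) > 0
  TP <- sum(pred & bench_in)
  n_pred <- sum(pred)
  n_bench <- sum(bench_in)
  sens <- if (n_bench > 0) TP / n_bench else NA_real_
  prec <- if (n_pred > 0) TP / n_pred else NA_real_
  if (n_pred == 0) warning("zero predicted pairs: precision undefined")
  p_prec <- if (n_pred > 0)
    hypergeom_upper(TP, n_pred, n_bench, universe_size) else NA_real_
  list(TP = TP, predicted = n_pred, benchmark_measured = n_bench,
       sensitivity = sens, precision = prec, p_precision = p_prec)
}

#' Cross-dataset correlation of significant S-scores
#'
#' Pearson correlation of the two screens' S-scores over the shared
#' measured pairs whose score is significant (|s| beyond
#' `significance_cut`) in either dataset.
#'
#' @param a,b two [sscore_matrix] objects (pair overlap by query/library
#'   ids).
#' @param significance_cut absolute S-score significance cutoff (default
#'   2.5).
#' @return Pearson r (errors with fewer than 3 qualifying shared pairs).
#' @export
cross_dataset_r <- function(a, b, significance_cut = 2.5) {
  stopifnot(inherits(a, "sscore_matrix"), inherits(b, "sscore_matrix"))
  q <- intersect(a$queries, b$queries)
  l <- intersect(a$library, b$library)
  va <- a$scores[q, l, drop = FALSE]
  vb <- b$scores[q, l, drop = FALSE]
  ok <- !is.na(va) & !is.na(vb) &
    (abs(va) > significance_cut | abs(vb) > significance_cut)
  if (sum(ok) < 3) {
    stop("fewer than 3 shared significant pairs between the two datasets")
  }
  stats::cor(va[ok], vb[ok])
}
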