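# Hypergeometric enrichment testing with Bonferroni correction.
#
# The p-value for a term/list asks: drawing n selected genes from a universe
# of N test genes of which M carry the property, how surprising is it to see
# at least m carriers among the selected?

#' Upper-tail hypergeometric probability P(X >= m)
#'
#' X counts property carriers in `n` draws without replacement from a
#' population of `N` genes containing `M` carriers. Computed through
#' `stats::phyper` (log-space internally), so it is stable for extreme
#' tails.
#'
#' @param m observed carriers among the selected genes.
#' @param n number of selected genes.
#' @param M carriers in the universe.
#' @param N universe size.
#' @return P(X >= m) in (0, 1].
#' @export
hypergeom_upper <- function(m, n, M, N) {
  stopifnot(length(m) == 1, length(n) == 1, length(M) == 1, length(N) == 1)
  if (m > n) stop("count ordering violated: m > n (", m, " > ", n, ")")
  if (m > M) stop("count ordering violated: m > M (", m, " > ", M, ")")
  if (n > N) stop("count ordering violated: n > N (", n, " > ", N, ")")
  if (M > N) stop("count ordering violated: M > N (", M, " > ", N, ")")
  if (m < 0) stop("m must be non-negative")
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `q_i = min(1, p_i * length(p))`, order preserved. (The method controls
#' the family-wise error rate; a Benjamini-Hochberg alternative is available
#' via `method = "BH"`.)
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @return Adjusted q-values, same length and order.
#' @export
bonferroni <- function(p_values, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = if (method == "BH") "BH" else "bonferroni")
}

#' Term-by-term enrichment of a gene set
#'
#' Tests every annotation term with at least one selected member by the
#' upper-tail hypergeometric test, corrects across all tested terms and
#' returns the terms passing `q_max`, sorted by q ascending (ties by p, then
#' term id).
#'
#' @param selected gene set of interest (must be contained in `universe`).
#' @param universe background gene set (e.g. all library strains measured in
#'   the screen).
#' @param ann an [annotation_table].
#' @param q_max report terms with q below this (default 0.02, a 98%
#'   confidence level).
#' @param min_term_size terms with fewer universe members than this are
#'   skipped as untestable (default 2).
#' @param method multiple-testing method passed to [bonferroni].
#' @return data.frame with columns `label`, `m`, `n`, `M`, `N`, `p`, `q`.
#'   Attribute `n_tested` records the correction family size.
#' @export
term_enrichment <- function(selected, universe, ann, q_max = 0.02,
                            min_term_size = 2,
                            method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  stopifnot(inherits(ann, "annotation_table"))
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe")
  }
  empty <- data.frame(label = character(0), m = integer(0), n = integer(0),
                      M = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (length(selected) == 0) {
    warning("empty selected set: no terms tested")
    return(structure(empty, n_tested = 0L))
  }
  uni_ann <- ann[intersect(names(ann), universe)]
  term_uni <- table(unlist(uni_ann, use.names = FALSE))
  sel_ann <- ann[intersect(names(ann), selected)]
  term_sel <- table(unlist(sel_ann, use.names = FALSE))
  testable <- names(term_sel)[term_uni[names(term_sel)] >= min_term_size]
  if (length(testable) == 0) return(structure(empty, n_tested = 0L))
  n <- length(selected); N <- length(universe)
  p <- vapply(testable, function(tm) {
    hypergeom_upper(as.integer(term_sel[[tm]]), n,
                    as.integer(term_uni[[tm]]), N)
  }, numeric(1))
  q <- bonferroni(p, method = method)
  out <- data.frame(label = testable,
                    m = as.integer(term_sel[testable]),
                    n = n,
                    M = as.integer(term_uni[testable]),
                    N = N, p = p, q = q, stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$label), , drop = FALSE]
  rownames(out) <- NULL
  structure(out[out$q < q_max, , drop = FALSE], n_tested = length(testable))
}

#' Enrichment of a gene set for membership in a named list
#'
#' Single upper-tail hypergeometric test of a property list (e.g. known
#' cell-cycle genes, CDC28 substrates) among `selected` relative to
#' `universe`.
#'
#' @param selected gene set of interest (subset of `universe`).
#' @param universe background gene set.
#' @param property_list a [gene_list].
#' @return One-row data.frame with columns `label`, `m`, `n`, `M`, `N`, `p`.
#' @export
list_enrichment <- function(selected, universe, property_list) {
  stopifnot(inherits(property_list, "gene_list"))
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe")
  }
  prop <- intersect(property_list$members, universe)
  if (length(prop) == 0) {
    warning("property list '", property_list$name,
            "' is disjoint from the universe: p = 1")
  }
  m <- length(intersect(selected, prop))
  p <- hypergeom_upper(m, length(selected), length(prop), length(universe))
  data.frame(label = property_list$name, m = m, n = length(selected),
             M = length(prop), N = length(universe), p = p,
             stringsAsFactors = FALSE)
}
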