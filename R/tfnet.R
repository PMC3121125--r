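# TF prioritization and the transcriptional network around the PCCGs and
# KCCGs: hypergeometric target enrichment, periodicity, rank multiplication
# (an "or" combination of the two tests), coverage-based TF selection,
# indirect connectivity and binding-profile clustering.

.targets_of <- function(binding, tf) {
  binding$edges$target[binding$edges$tf == tf]
}

#' Enrichment of a TF's targets for the focus gene set
#'
#' Upper-tail hypergeometric test: `m` = TF targets inside the focus set
#' (PCCGs and KCCGs), `n` = focus size, `M` = TF targets in the test-gene
#' universe, `N` = universe size.
#'
#' @param tf TF gene id.
#' @param binding a [binding_network].
#' @param focus focus gene set (PCCG union KCCG), subset of `universe`.
#' @param universe test-gene universe (defaults to all binding-network
#'   targets).
#' @return p-value; a TF with no targets in the universe scores 1 with a
#'   warning.
#' @export
tf_enrichment_test <- function(tf, binding, focus, universe = NULL) {
  stopifnot(inherits(binding, "binding_network"))
  if (is.null(universe)) universe <- unique(binding$edges$target)
  focus <- unique(as.character(focus))
  universe <- unique(as.character(universe))
  if (!all(focus %in% universe)) {
    stop("focus genes must be a subset of the universe")
  }
  targ <- intersect(.targets_of(binding, tf), universe)
  if (length(targ) == 0) {
    warning("TF ", tf, " has no targets in the universe: p = 1")
    return(1)
  }
  hypergeom_upper(length(intersect(targ, focus)), length(focus),
                  length(targ), length(universe))
}

#' Combine enrichment and periodicity tests by rank multiplication
#'
#' Each TF receives its rank (ascending p, average ranks on ties) in the
#' enrichment test and in the periodicity test; the product of the two
#' ranks orders the TFs. A small product needs only one small rank, so the
#' combination behaves as an "or" of the two criteria — a TF significant
#' in either test rises to the top. Final ties are broken by the smaller
#' enrichment p, then lexicographic TF id.
#'
#' @param p_et named numeric vector of enrichment-test p-values.
#' @param p_pt named numeric vector of periodicity p-values over the same
#'   TFs (a TF untested in one source must be given p = 1 by the caller).
#' @return data.frame (`tf_ranking`) with columns `tf`, `p_et`, `p_pt`,
#'   `rank_et`, `rank_pt`, `rank_product`, `final_rank` (dense rank of the
#'   product), ordered best-first.
#' @export
rank_tfs <- function(p_et, p_pt) {
  tfs <- names(p_et)
  if (is.null(tfs) || is.null(names(p_pt))) {
    stop("p_et and p_pt must be named by TF")
  }
  missing_et <- setdiff(names(p_pt), tfs)
  missing_pt <- setdiff(tfs, names(p_pt))
  if (length(missing_et) > 0 || length(missing_pt) > 0) {
    stop("TF universes differ between the two tests: ",
         paste(c(missing_et, missing_pt), collapse = ", "))
  }
  p_pt <- p_pt[tfs]
  rk_et <- rank(p_et, ties.method = "average")
  rk_pt <- rank(p_pt, ties.method = "average")
  prod <- rk_et * rk_pt
  out <- data.frame(tf = tfs, p_et = unname(p_et), p_pt = unname(p_pt),
                    rank_et = unname(rk_et), rank_pt = unname(rk_pt),
                    rank_product = unname(prod), stringsAsFactors = FALSE)
  out <- out[order(out$rank_product, out$p_et, out$tf), , drop = FALSE]
  out$final_rank <- as.integer(match(out$rank_product,
                                     sort(unique(out$rank_product))))
  rownames(out) <- NULL
  structure(out, class = c("tf_ranking", "data.frame"))
}

#' Coverage of focus genes and co-functional pairs by top-ranked TFs
#'
#' For each k, the gene coverage is the fraction of focus genes bound by at
#' least one of the top-k TFs, among focus genes bound by at least one TF
#' in the whole dataset; the pair coverage is the fraction of pairs whose
#' two genes share at least one common top-k TF, among pairs sharing a
#' common TF in the whole dataset.
#'
#' @param ranking a `tf_ranking` from [rank_tfs] (best-first order).
#' @param binding a [binding_network].
#' @param genes focus gene set (PCCG union KCCG).
#' @param pairs data.frame with columns naming two genes per row (e.g. the
#'   passing pairs of [extract_pccg]); may be `NULL`.
#' @return data.frame (`coverage_curve`): columns `k`, `gene_coverage`,
#'   `pair_coverage`; attributes `n_coverable_genes`, `n_coverable_pairs`.
#' @export
coverage_curve <- function(ranking, binding, genes, pairs = NULL) {
  stopifnot(inherits(ranking, "tf_ranking"), inherits(binding, "binding_network"))
  genes <- unique(as.character(genes))
  tf_order <- ranking$tf
  targ <- split(binding$edges$target, binding$edges$tf)
  bound_by <- lapply(stats::setNames(tf_order, tf_order),
                     function(tf) intersect(targ[[tf]], genes))
  coverable_genes <- unique(unlist(bound_by))
  pair_mat <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pair_mat <- cbind(as.character(pairs[[1]]), as.character(pairs[[2]]))
  }
  covered_by_tf <- function(tfset) {
    unique(unlist(bound_by[tfset]))
  }
  pair_covered <- function(tfset) {
    if (is.null(pair_mat)) return(logical(0))
    vapply(seq_len(nrow(pair_mat)), function(i) {
      any(vapply(tfset, function(tf)
        all(pair_mat[i, ] %in% targ[[tf]]), logical(1)))
    }, logical(1))
  }
  coverable_pairs <- which(pair_covered(tf_order))
  ks <- 0:length(tf_order)
  gene_cov <- numeric(length(ks)); pair_cov <- numeric(length(ks))
  covered_g <- character(0)
  covered_p <- rep(FALSE, length(coverable_pairs))
  gene_cov[1] <- 0; pair_cov[1] <- 0
  for (i in seq_along(tf_order)) {
    tf <- tf_order[i]
    covered_g <- union(covered_g, bound_by[[tf]])
    if (length(coverable_pairs) > 0) {
      newly <- vapply(coverable_pairs, function(pi)
        all(pair_mat[pi, ] %in% targ[[tf]]), logical(1))
      covered_p <- covered_p | newly
    }
    gene_cov[i + 1] <- if (length(coverable_genes) > 0)
      length(covered_g) / length(coverable_genes) else 0
    pair_cov[i + 1] <- if (length(coverable_pairs) > 0)
      mean(covered_p) else 0
  }
  structure(data.frame(k = ks, gene_coverage = gene_cov,
                       pair_coverage = pair_cov),
            n_coverable_genes = length(coverable_genes),
            n_coverable_pairs = length(coverable_pairs),
            class = c("coverage_curve", "data.frame"))
}

#' Choose the number of TFs from a coverage curve
#'
#' Explicit `k` is returned as-is. With `k = "auto"` the smallest k is
#' chosen at which both marginal coverage gains of the next step fall below
#' `epsilon`; a curve that keeps climbing returns the maximal k with a
#' warning.
#'
#' @param curve a `coverage_curve`.
#' @param k positive integer or `"auto"`.
#' @param epsilon marginal-gain threshold for the automatic knee (default
#'   0.01).
#' @return Selected k (integer).
#' @export
select_tfs <- function(curve, k = "auto", epsilon = 0.01) {
  stopifnot(inherits(curve, "coverage_curve"), nrow(curve) > 0)
  kmax <- max(curve$k)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    stopifnot(k >= 1)
    return(min(k, kmax))
  }
  dg <- diff(curve$gene_coverage)
  dp <- diff(curve$pair_coverage)
  for (i in seq_len(kmax - 1)) {
    if (dg[i + 1] < epsilon && dp[i + 1] < epsilon) return(curve$k[i + 1])
  }
  warning("coverage keeps increasing: selecting all TFs")
  kmax
}

#' Restrict a binding network to the selected TFs and the focus genes
#'
#' @param binding a [binding_network].
#' @param selected character vector of selected TFs.
#' @param focus gene set (PCCG union KCCG); edges are kept from selected
#'   TFs to `focus` genes or other selected TFs.
#' @return A `transcriptional_network`: [binding_network] subset with extra
#'   fields `selected` and `focus`.
#' @export
transcriptional_network <- function(binding, selected, focus) {
  stopifnot(inherits(binding, "binding_network"))
  selected <- unique(as.character(selected))
  keep_t <- union(unique(as.character(focus)), selected)
  e <- binding$edges
  e <- e[e$tf %in% selected & e$target %in% keep_t, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, tf_universe = binding$tf_universe,
                 selected = selected, focus = unique(as.character(focus))),
            class = c("transcriptional_network", "binding_network"))
}

#' Indirect TF-target connectivity through the binding network
#'
#' Indirect pairs are regulatory-evidence pairs (TF in `selected`, gene in
#' `targets`) with no direct binding edge. For each, the minimal directed
#' path length in the binding network is found by breadth-first search
#' (intermediate nodes are necessarily TFs: only TFs have outgoing edges).
#' With `restrict_to_selected = TRUE` traversal only uses edges whose
#' source TF is selected (the sub-network variant).
#'
#' @param binding a [binding_network].
#' @param evidence a [regulatory_evidence] table.
#' @param selected TFs whose indirect relations are examined.
#' @param targets candidate target genes.
#' @param max_steps maximal path length considered "explained" (default 3).
#' @param restrict_to_selected traverse only selected TFs' edges.
#' @return list (`connectivity_report`): `pairs` (data.frame `tf`, `gene`,
#'   `path_length` with `NA` = unreachable), `n_indirect`,
#'   `explained_by_step` (cumulative counts for steps `1..max_steps`),
#'   `explained_fraction` (cumulative fractions).
#' @export
indirect_connectivity <- function(binding, evidence, selected, targets,
                                  max_steps = 3,
                                  restrict_to_selected = FALSE) {
  stopifnot(inherits(binding, "binding_network"), max_steps >= 1)
  selected <- unique(as.character(selected))
  targets <- unique(as.character(targets))
  ev <- evidence[evidence$tf %in% selected & evidence$gene %in% targets, ,
                 drop = FALSE]
  direct <- paste(binding$edges$tf, binding$edges$target, sep = "\r")
  indirect <- ev[!(paste(ev$tf, ev$gene, sep = "\r") %in% direct), ,
                 drop = FALSE]
  rownames(indirect) <- NULL
  edges <- binding$edges
  if (restrict_to_selected) {
    edges <- edges[edges$tf %in% selected, , drop = FALSE]
  }
  verts <- unique(c(edges$tf, edges$target, indirect$tf, indirect$gene))
  if (nrow(indirect) == 0) {
    lens <- numeric(0)
  } else if (nrow(edges) == 0) {
    lens <- rep(NA_real_, nrow(indirect))
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = verts)
    dmat <- igraph::distances(g, v = unique(indirect$tf),
                              to = unique(indirect$gene), mode = "out")
    lens <- dmat[cbind(match(indirect$tf, rownames(dmat)),
                       match(indirect$gene, colnames(dmat)))]
    lens[!is.finite(lens)] <- NA_real_
  }
  indirect$path_length <- if (nrow(indirect) > 0) lens else numeric(0)
  steps <- seq_len(max_steps)
  cum <- vapply(steps, function(s)
    sum(!is.na(indirect$path_length) & indirect$path_length <= s),
    integer(1))
  structure(list(pairs = indirect, n_indirect = nrow(indirect),
                 explained_by_step = stats::setNames(cum, steps),
                 explained_fraction = stats::setNames(
                   if (nrow(indirect) > 0) cum / nrow(indirect)
                   else rep(NA_real_, max_steps), steps)),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf("Indirect TF-target pairs: %d\n", x$n_indirect))
  for (s in names(x$explained_by_step)) {
    cat(sprintf("  explained within %s step(s): %d (%.1f%%)\n", s,
                x$explained_by_step[[s]],
                100 * x$explained_fraction[[s]]))
  }
  invisible(x)
}

#' Cluster TFs and target genes by their binding profiles
#'
#' Builds the binary TF x target incidence matrix of a transcriptional
#' network and clusters both axes by average-linkage agglomeration on the
#' Jaccard distance between profiles. Nodes with all-zero profiles (which
#' have no defined Jaccard distance) are placed at the maximal distance 1
#' from everything and reported.
#'
#' @param network a `transcriptional_network` (or [binding_network]); needs
#'   at least 2 TFs and 2 targets.
#' @return list (`cluster_tree`) with `tf_tree` and `gene_tree` (hclust
#'   objects), `profile` (the incidence matrix) and `all_zero` (labels that
#'   were outgrouped).
#' @export
cluster_profiles <- function(network) {
  stopifnot(inherits(network, "binding_network"))
  e <- network$edges
  tfs <- sort(unique(e$tf)); targs <- sort(unique(e$target))
  if (length(tfs) < 2 || length(targs) < 2) {
    stop("need at least 2 TFs and 2 target genes to cluster")
  }
  prof <- matrix(0L, length(tfs), length(targs),
                 dimnames = list(tfs, targs))
  prof[cbind(match(e$tf, tfs), match(e$target, targs))] <- 1L
  jacc <- function(m) {
    d <- stats::dist(m, method = "binary")  # Jaccard distance on binaries
    d[is.na(d)] <- 1  # pairs of all-zero profiles: outgroup at max height
    d
  }
  zero_rows <- rownames(prof)[rowSums(prof) == 0]
  zero_cols <- colnames(prof)[colSums(prof) == 0]
  all_zero <- c(zero_rows, zero_cols)
  if (length(all_zero) > 0) {
    message("cluster_profiles: all-zero profile(s) outgrouped: ",
            paste(all_zero, collapse = ", "))
  }
  structure(list(tf_tree = stats::hclust(jacc(prof), method = "average"),
                 gene_tree = stats::hclust(jacc(t(prof)), method = "average"),
                 profile = prof, all_zero = all_zero),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("Binding-profile clustering: %d TFs x %d target genes\n",
              nrow(x$profile), ncol(x$profile)))
  invisible(x)
}
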