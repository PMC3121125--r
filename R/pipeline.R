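# End-to-end orchestration: impute -> co-expression -> enrichment grids ->
# significance region -> PCCG -> part enrichment -> TF ranking ->
# coverage/selection -> network -> indirect connectivity -> clustering.

#' Pipeline configuration
#'
#' @param region `"default"` (the published clause set), `"auto"` (derive
#'   clauses from the enrichment surface via [region_from_surface]) or an
#'   `interaction_region`.
#' @param max_lag time-lagged correlation shift bound (timepoints).
#' @param s_bin,cc_bin bin sizes of the 1-D enrichment curves.
#' @param s_grid,cc_grid thresholds of the cumulative enrichment surface.
#' @param pos_min_ratio,neg_min_ratio enrichment minima for `"auto"` region
#'   derivation.
#' @param q_max q-value cutoff of the GO-style term enrichment.
#' @param k_tfs number of TFs to select, or `"auto"` (coverage knee).
#' @param max_steps path-length bound of the indirect-connectivity
#'   analysis.
#' @param period expression period (timepoints per cycle) for the
#'   periodicity test.
#' @param n_perm permutations of the periodicity test.
#' @param k_impute,max_missing_fraction forwarded to [knn_impute].
#' @param run_clustering set `FALSE` to skip the clustering stage.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(region = "default", max_lag = 2, s_bin = 1.5,
                            cc_bin = 0.1,
                            s_grid = c(0, 2.5, 6, -3, -14),
                            cc_grid = c(-1, 0.85, 0.9),
                            pos_min_ratio = 2, neg_min_ratio = 4,
                            q_max = 0.02, k_tfs = "auto", max_steps = 3,
                            period = 8, n_perm = 499, k_impute = 10,
                            max_missing_fraction = 0.5,
                            run_clustering = TRUE, seed = 1) {
  structure(list(region = region, max_lag = max_lag, s_bin = s_bin,
                 cc_bin = cc_bin, s_grid = s_grid, cc_grid = cc_grid,
                 pos_min_ratio = pos_min_ratio,
                 neg_min_ratio = neg_min_ratio, q_max = q_max,
                 k_tfs = k_tfs, max_steps = max_steps, period = period,
                 n_perm = n_perm, k_impute = k_impute,
                 max_missing_fraction = max_missing_fraction,
                 run_clustering = run_clustering, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file of configuration overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full integrative analysis
#'
#' Takes an input bundle (as produced by [simulate_bundle], or an
#' equivalently shaped list of objects read from disk) and executes every
#' stage, returning a classed result with per-stage summaries. The run is
#' deterministic for a fixed config seed.
#'
#' @param bundle list with elements `scores` ([sscore_matrix]), `exprs`
#'   (list of [expression_matrix]), `annotation` ([annotation_table]),
#'   `binding` ([binding_network]), `evidence` ([regulatory_evidence]),
#'   `kccg` ([gene_list]); optional `benchmark`, `cell_cycle_list`,
#'   `kinase_substrates`, and `periodicity` (precomputed data.frame `gene`,
#'   `p_value` bypassing the built-in test, cyclebase style).
#' @param config a [pipeline_config].
#' @return Object of class `cyclenet_result`.
#' @export
cyclenet_run <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  log_stage <- function(name, note = "") {
    message(sprintf("[cyclenet] %-14s %6.1fs %s", name,
                    proc.time()[["elapsed"]] - t0, note))
  }
  scores <- bundle$scores
  kccg <- if (inherits(bundle$kccg, "gene_list")) bundle$kccg$members
          else as.character(bundle$kccg)

  # -- co-expression ----------------------------------------------------------
  cc <- coexpression_table(bundle$exprs, genes_a = scores$queries,
                           genes_b = scores$library,
                           max_lag = config$max_lag, k = config$k_impute,
                           max_missing_fraction = config$max_missing_fraction)
  stages$coexpression <- list(n_pairs = nrow(cc),
                              experiments = attr(cc, "experiments_used"))
  log_stage("coexpression", sprintf("%d pairs", nrow(cc)))

  # -- enrichment curves and surface -----------------------------------------
  pairs <- pair_universe(scores, cc)
  curve_s <- enrichment_curve(pairs, bundle$annotation, "sscore",
                              config$s_bin)
  curve_c <- tryCatch(enrichment_curve(pairs, bundle$annotation, "cc",
                                       config$cc_bin),
                      error = function(e) NULL)
  surface <- enrichment_surface(pairs, bundle$annotation, config$s_grid,
                                config$cc_grid)
  stages$enrichment_grid <- list(r = attr(surface, "r"),
                                 n_pairs = nrow(pairs))
  log_stage("enrichment", sprintf("r = %.3f", attr(surface, "r")))

  # -- significance region and PCCG ------------------------------------------
  region <- if (inherits(config$region, "interaction_region")) config$region
            else if (identical(config$region, "auto"))
              region_from_surface(surface, config$pos_min_ratio,
                                  config$neg_min_ratio)
            else default_region()
  pccg_set <- extract_pccg(scores, cc, region)
  uni <- pccg_kccg_union(pccg_set, kccg)
  stages$pccg <- list(n_pairs = nrow(pccg_set$pairs),
                      n_pccg = length(pccg_set$pccg),
                      n_positive = length(pccg_set$positive_part),
                      n_negative = length(pccg_set$negative_part),
                      union_with_kccg = uni[c("n_union", "n_overlap",
                                              "n_raw_sum")])
  log_stage("pccg", sprintf("%d pairs -> %d genes", nrow(pccg_set$pairs),
                            length(pccg_set$pccg)))

  # -- functional enrichment of the parts ------------------------------------
  universe_genes <- scores$library
  enr <- list(
    positive = term_enrichment(pccg_set$positive_part, universe_genes,
                               bundle$annotation, q_max = config$q_max),
    negative = term_enrichment(pccg_set$negative_part, universe_genes,
                               bundle$annotation, q_max = config$q_max),
    all = term_enrichment(pccg_set$pccg, universe_genes,
                          bundle$annotation, q_max = config$q_max))
  stages$term_enrichment <- lapply(enr, function(x) x$label)
  log_stage("term-enrich")

  list_tests <- list()
  focus_genes <- union(pccg_set$pccg, kccg)
  if (!is.null(bundle$cell_cycle_list)) {
    list_tests$pccg_cell_cycle <- list_enrichment(
      pccg_set$pccg, universe_genes,
      .restrict_list(bundle$cell_cycle_list, universe_genes))
  }
  if (!is.null(bundle$kinase_substrates)) {
    list_tests$pccg_kinase <- list_enrichment(
      pccg_set$pccg, universe_genes,
      .restrict_list(bundle$kinase_substrates, universe_genes))
  }

  # -- benchmark recovery ----------------------------------------------------
  bench <- NULL
  if (!is.null(bundle$benchmark)) {
    bench <- benchmark_eval(scores, region, bundle$benchmark, cc = cc)
    stages$benchmark <- bench
    log_stage("benchmark", sprintf("TP = %d, precision = %.2f", bench$TP,
                                   bench$precision))
  }

  # -- TF ranking -------------------------------------------------------------
  tf_univ <- bundle$binding$tf_universe
  chip_universe <- unique(bundle$binding$edges$target)
  focus_in_chip <- intersect(focus_genes, chip_universe)
  p_et <- vapply(tf_univ, function(tf) {
    suppressWarnings(tf_enrichment_test(tf, bundle$binding, focus_in_chip,
                                        chip_universe))
  }, numeric(1))
  if (!is.null(bundle$periodicity)) {
    pt <- bundle$periodicity
    p_pt <- stats::setNames(rep(1, length(tf_univ)), tf_univ)
    hit <- intersect(pt$gene, tf_univ)
    p_pt[hit] <- pt$p_value[match(hit, pt$gene)]
    pt_source <- "file"
  } else {
    pt_tab <- periodicity_table(bundle$exprs, period = config$period,
                                genes = tf_univ, n_perm = config$n_perm,
                                seed = config$seed + 1L)
    p_pt <- stats::setNames(rep(1, length(tf_univ)), tf_univ)
    p_pt[pt_tab$gene] <- pt_tab$p_value
    pt_source <- "permutation_test"
  }
  ranking <- rank_tfs(p_et, p_pt)
  stages$tf_ranking <- list(top = utils::head(ranking$tf, 10),
                            periodicity_source = pt_source)
  log_stage("tf-rank", sprintf("top TF: %s", ranking$tf[1]))

  # -- coverage and TF selection ---------------------------------------------
  curve <- coverage_curve(ranking, bundle$binding, focus_genes,
                          pairs = pccg_set$pairs[, c("query", "library")])
  k_sel <- select_tfs(curve, config$k_tfs)
  selected <- ranking$tf[seq_len(k_sel)]
  stages$coverage <- list(
    k = k_sel,
    gene_coverage = curve$gene_coverage[curve$k == k_sel],
    pair_coverage = curve$pair_coverage[curve$k == k_sel],
    n_coverable_genes = attr(curve, "n_coverable_genes"),
    n_coverable_pairs = attr(curve, "n_coverable_pairs"))
  log_stage("coverage", sprintf("k = %d (%.0f%% genes, %.0f%% pairs)",
                                k_sel,
                                100 * stages$coverage$gene_coverage,
                                100 * stages$coverage$pair_coverage))

  if (!is.null(bundle$cell_cycle_list)) {
    list_tests$tf_cell_cycle <- list_enrichment(
      selected, tf_univ, .restrict_list(bundle$cell_cycle_list, tf_univ))
    if (!is.null(bundle$kinase_substrates)) {
      list_tests$tf_kinase <- list_enrichment(
        selected, tf_univ, .restrict_list(bundle$kinase_substrates,
                                          tf_univ))
    }
  }
  stages$list_enrichment <- list_tests

  # -- network, connectivity, clustering -------------------------------------
  network <- transcriptional_network(bundle$binding, selected, focus_genes)
  conn <- NULL
  if (!is.null(bundle$evidence)) {
    conn <- indirect_connectivity(bundle$binding, bundle$evidence, selected,
                                  intersect(focus_genes, chip_universe),
                                  max_steps = config$max_steps)
    stages$connectivity <- list(
      n_indirect = conn$n_indirect,
      explained_fraction = conn$explained_fraction)
    log_stage("connectivity", sprintf("%d indirect pairs", conn$n_indirect))
  } else {
    stages$connectivity <- list(skipped = "no regulatory evidence supplied")
  }
  tree <- NULL
  if (isTRUE(config$run_clustering) && nrow(network$edges) > 0 &&
      length(unique(network$edges$tf)) >= 2 &&
      length(unique(network$edges$target)) >= 2) {
    tree <- suppressMessages(cluster_profiles(network))
    stages$clustering <- list(n_tfs = nrow(tree$profile),
                              n_genes = ncol(tree$profile))
  } else {
    stages$clustering <- list(skipped = if (isTRUE(config$run_clustering))
      "network too small" else "disabled in config")
  }
  log_stage("done")

  structure(list(stages = stages, config = config,
                 coexpression = cc, surface = surface,
                 curves = list(sscore = curve_s, cc = curve_c),
                 region = region, pccg = pccg_set,
                 term_enrichment = enr, list_enrichment = list_tests,
                 benchmark = bench, ranking = ranking,
                 coverage = curve, selected_tfs = selected,
                 network = network, connectivity = conn,
                 cluster_tree = tree,
                 version = as.character(utils::packageVersion("cyclenet"))),
            class = "cyclenet_result")
}

.restrict_list <- function(gl, universe) {
  hit <- intersect(gl$members, universe)
  if (length(hit) == 0) return(gl)  # list_enrichment warns and returns p=1
  gene_list(gl$name, hit)
}

# the set of genes a binding network can talk about
binding_universe <- function(binding) {
  unique(c(binding$edges$tf, binding$edges$target))
}

#' @export
print.cyclenet_result <- function(x, ...) {
  s <- x$stages
  cat("cyclenet integrative analysis\n")
  cat(sprintf("  measured pairs: %d (co-functional background r = %.3f)\n",
              s$enrichment_grid$n_pairs, s$enrichment_grid$r))
  cat(sprintf("  passing pairs:  %d -> %d PCCGs (%d pos / %d neg part)\n",
              s$pccg$n_pairs, s$pccg$n_pccg, s$pccg$n_positive,
              s$pccg$n_negative))
  cat(sprintf("  selected TFs:   %d (gene coverage %.0f%%, pair coverage %.0f%%)\n",
              s$coverage$k, 100 * s$coverage$gene_coverage,
              100 * s$coverage$pair_coverage))
  if (!is.null(x$connectivity)) {
    n <- length(x$connectivity$explained_fraction)
    cat(sprintf("  indirect pairs: %d (%.0f%% explained within %d steps)\n",
                x$connectivity$n_indirect,
                100 * x$connectivity$explained_fraction[[n]], n))
  }
  invisible(x)
}

#' @export
summary.cyclenet_result <- function(object, ...) {
  print(object)
  cat("\nTop-ranked TFs (enrichment x periodicity rank product):\n")
  print(utils::head(as.data.frame(object$ranking), 10))
  cat("\nEnriched terms (negative part):\n")
  print(object$term_enrichment$negative)
  invisible(object)
}

#' Consolidated machine-readable report of a pipeline run
#'
#' @param result a `cyclenet_result`.
#' @return list suitable for [write_report].
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "cyclenet_result"))
  list(version = result$version,
       config = unclass(result$config)[setdiff(names(result$config),
                                               "region")],
       stages = result$stages,
       region = as.data.frame(result$region),
       pccg = result$pccg$pccg,
       positive_part = result$pccg$positive_part,
       negative_part = result$pccg$negative_part,
       selected_tfs = result$selected_tfs,
       ranking = as.data.frame(result$ranking))
}
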