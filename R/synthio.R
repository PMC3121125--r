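# Synthetic-data generator with planted, recoverable structure.
#
# The generator states a small world mirroring the assumptions of the
# analysis: co-functional modules drive extreme S-scores and shared-phase
# periodic expression; cell-cycle TFs bind cell-cycle module genes and are
# themselves periodically expressed. Everything is seeded and bit-exact
# reproducible.

#' Configuration of the synthetic world
#'
#' Defaults describe a reduced-scale screen (48 queries x 300 library
#' strains, 4 time-course experiments of 24 timepoints with an 8-timepoint
#' period, 40 TFs) with 12 planted modules of 4-8 library genes plus 4
#' query genes each, 75% of modules cell-cycle-flagged, planted S-score
#' effects +5 / -8 (noise sd 1), sinusoidal amplitudes ~ |N(1, 0.1)|,
#' expression noise sd 0.2, 5% expression and 8% S-score missingness, 20%
#' of TFs cell-cycle (37/183-like), binding false-negative rate 0.1 and
#' false-positive rate 0.02.
#'
#' @param n_queries,n_library,n_tfs,n_timepoints,n_experiments world sizes.
#' @param n_modules number of planted co-functional modules.
#' @param module_size_range integer range of library genes per module.
#' @param queries_per_module query genes assigned to each module.
#' @param frac_cc_modules fraction of modules flagged cell-cycle.
#' @param s_effect_pos,s_effect_neg planted mean S-scores (pos > 0 > neg).
#' @param s_noise_sd S-score noise standard deviation.
#' @param period expression period in timepoints per cycle.
#' @param amplitude_sd spread of per-gene sinusoid amplitudes around 1.
#' @param expr_noise_sd expression noise standard deviation.
#' @param missing_rate completely-at-random expression missingness.
#' @param s_missing_rate completely-at-random S-score missingness.
#' @param frac_cc_tfs fraction of TFs flagged cell-cycle.
#' @param binding_fpr,binding_fnr spurious-edge and lost-edge rates of the
#'   binding assay.
#' @param tf_tf_rate probability a cell-cycle TF binds another cell-cycle
#'   TF (creates the 2-step indirect paths).
#' @param benchmark_fraction fraction of planted pairs present in the
#'   benchmark list.
#' @param seed integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_queries = 48, n_library = 300, n_tfs = 40,
                             n_timepoints = 24, n_experiments = 4,
                             n_modules = 12, module_size_range = c(4, 8),
                             queries_per_module = 4,
                             frac_cc_modules = 0.75,
                             s_effect_pos = 5, s_effect_neg = -8,
                             s_noise_sd = 1, period = 8,
                             amplitude_sd = 0.1, expr_noise_sd = 0.2,
                             missing_rate = 0.05, s_missing_rate = 0.08,
                             frac_cc_tfs = 0.2, binding_fpr = 0.02,
                             binding_fnr = 0.1, tf_tf_rate = 0.3,
                             benchmark_fraction = 0.5, seed = 1) {
  cfg <- list(n_queries = n_queries, n_library = n_library, n_tfs = n_tfs,
              n_timepoints = n_timepoints, n_experiments = n_experiments,
              n_modules = n_modules,
              module_size_range = as.integer(module_size_range),
              queries_per_module = queries_per_module,
              frac_cc_modules = frac_cc_modules,
              s_effect_pos = s_effect_pos, s_effect_neg = s_effect_neg,
              s_noise_sd = s_noise_sd, period = period,
              amplitude_sd = amplitude_sd, expr_noise_sd = expr_noise_sd,
              missing_rate = missing_rate, s_missing_rate = s_missing_rate,
              frac_cc_tfs = frac_cc_tfs, binding_fpr = binding_fpr,
              binding_fnr = binding_fnr, tf_tf_rate = tf_tf_rate,
              benchmark_fraction = benchmark_fraction, seed = seed)
  props <- c("frac_cc_modules", "missing_rate", "s_missing_rate",
             "frac_cc_tfs", "binding_fpr", "binding_fnr", "tf_tf_rate",
             "benchmark_fraction")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (any(cfg$module_size_range < 2)) stop("module sizes must be >= 2")
  if (!(cfg$s_effect_neg < 0 && cfg$s_effect_pos > 0) &&
      !(cfg$s_effect_neg == 0 && cfg$s_effect_pos == 0)) {
    stop("require s_effect_neg < 0 < s_effect_pos (or both 0 for a null world)")
  }
  stopifnot(cfg$s_noise_sd > 0, cfg$expr_noise_sd > 0, cfg$amplitude_sd > 0,
            cfg$period > 0)
  structure(cfg, class = "synthetic_config")
}

#' Configuration at the published screen's scale
#'
#' Sizes as printed for the real screen: 48 known cell-cycle query genes,
#' a library of 1536 test strains, 8 time-course experiments and 183 TFs
#' (37 of them cell-cycle-annotated).
#'
#' @param ... overrides forwarded to [synthetic_config].
#' @return A `synthetic_config`.
#' @export
default_paper_scale_config <- function(...) {
  args <- list(n_queries = 48, n_library = 1536, n_experiments = 8,
               n_tfs = 183, frac_cc_tfs = 37 / 183, n_modules = 40)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

#' Simulate a full input bundle with planted ground truth
#'
#' Generates every pipeline input: an S-score matrix whose within-module
#' (query, library) pairs are shifted to the module's planted effect; one
#' annotation term per module plus random background terms; sinusoidal
#' expression with module-shared phases for cell-cycle genes and pure noise
#' otherwise, replicated over experiments with fresh noise; a binding
#' network in which cell-cycle TFs bind the genes of their assigned
#' cell-cycle modules (edges dropped at `binding_fnr`, spurious edges added
#' at `binding_fpr`, TF->TF edges among cell-cycle TFs at `tf_tf_rate`);
#' regulatory evidence equal to the direct edges plus all 2-step
#' compositions through TF->TF edges; and a benchmark list holding a
#' seeded fraction of the planted pairs with matching sign class.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `scores`, `exprs` (list of
#'   [expression_matrix]), `annotation`, `binding`, `evidence`,
#'   `benchmark`, `cell_cycle_list`, `kinase_substrates`, `kccg`, and
#'   `truth` (list: `cc_genes`, `cc_tfs`, `pairs`, `regulons`, `modules`).
#' @export
simulate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(cfg$seed)

  queries <- sprintf("Q%03d", seq_len(cfg$n_queries))
  libs <- sprintf("L%04d", seq_len(cfg$n_library))
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  universe <- c(queries, libs, tfs)

  # ---- planted modules ------------------------------------------------------
  sizes <- sample(seq(cfg$module_size_range[1], cfg$module_size_range[2]),
                  cfg$n_modules, replace = TRUE)
  if (sum(sizes) > cfg$n_library) {
    stop("module sizes exceed the library size")
  }
  lib_pool <- sample(libs)
  q_pool <- rep_len(sample(queries), cfg$n_modules * cfg$queries_per_module)
  n_cc_mod <- round(cfg$frac_cc_modules * cfg$n_modules)
  modules <- vector("list", cfg$n_modules)
  off <- 0
  for (i in seq_len(cfg$n_modules)) {
    mlibs <- lib_pool[off + seq_len(sizes[i])]
    off <- off + sizes[i]
    mqs <- q_pool[(i - 1) * cfg$queries_per_module +
                    seq_len(cfg$queries_per_module)]
    modules[[i]] <- list(
      id = sprintf("MOD%02d", i),
      queries = unique(mqs), library = mlibs,
      cc = i <= n_cc_mod,
      sign = sample(c("pos", "neg"), 1),
      phase = stats::runif(1, 0, 2 * pi))
  }

  # ---- S-score matrix -------------------------------------------------------
  scores <- matrix(stats::rnorm(cfg$n_queries * cfg$n_library,
                                0, cfg$s_noise_sd),
                   cfg$n_queries, cfg$n_library,
                   dimnames = list(queries, libs))
  planted_parts <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    eff <- if (m$sign == "pos") cfg$s_effect_pos else cfg$s_effect_neg
    for (q in m$queries) {
      scores[q, m$library] <- stats::rnorm(length(m$library), eff,
                                           cfg$s_noise_sd)
    }
    part <- expand.grid(query = m$queries, library = m$library,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    part$sign <- m$sign
    planted_parts[[i]] <- part
  }
  planted <- do.call(rbind, planted_parts)
  rownames(planted) <- NULL
  miss <- matrix(stats::runif(length(scores)) < cfg$s_missing_rate,
                 nrow(scores))
  scores[miss] <- NA_real_
  # guarantee at least one measured value even under extreme missingness
  if (!any(is.finite(scores))) scores[1, 1] <- 0

  # ---- annotation -----------------------------------------------------------
  ann_map <- list()
  background_terms <- sprintf("BG%02d", seq_len(30))
  for (g in universe) {
    ann_map[[g]] <- sample(background_terms, sample(1:3, 1))
  }
  for (m in modules) {
    for (g in c(m$queries, m$library)) {
      ann_map[[g]] <- c(ann_map[[g]], m$id)
    }
  }
  annotation <- annotation_table(ann_map)

  # ---- expression -----------------------------------------------------------
  cc_mod_genes <- unique(unlist(lapply(modules[vapply(modules, `[[`,
                                                      logical(1), "cc")],
                                       function(m) c(m$queries, m$library))))
  n_cc_tfs <- round(cfg$frac_cc_tfs * cfg$n_tfs)
  cc_tfs <- tfs[seq_len(n_cc_tfs)]
  phase_of <- stats::setNames(rep(NA_real_, length(universe)), universe)
  for (m in modules) {
    if (m$cc) phase_of[c(m$queries, m$library)] <- m$phase
  }
  cc_modules <- which(vapply(modules, `[[`, logical(1), "cc"))
  tf_module <- list()
  for (tf in cc_tfs) {
    tf_module[[tf]] <- sample(cc_modules, min(2, length(cc_modules)))
    # a TF leads its regulon slightly in phase
    phase_of[tf] <- modules[[tf_module[[tf]][1]]]$phase - pi / 8
  }
  amp <- stats::setNames(abs(stats::rnorm(length(universe), 1,
                                          cfg$amplitude_sd)), universe)
  tp <- seq_len(cfg$n_timepoints) - 1
  exprs <- lapply(seq_len(cfg$n_experiments), function(e) {
    vals <- t(vapply(universe, function(g) {
      base <- if (is.na(phase_of[g])) 0 else
        amp[g] * sin(2 * pi * tp / cfg$period + phase_of[g])
      base + stats::rnorm(length(tp), 0, cfg$expr_noise_sd)
    }, numeric(length(tp))))
    vals[matrix(stats::runif(length(vals)) < cfg$missing_rate,
                nrow(vals))] <- NA_real_
    rownames(vals) <- universe
    expression_matrix(vals, timepoints = tp,
                      experiment = sprintf("experiment%d", e))
  })

  # ---- binding network ------------------------------------------------------
  regulons <- list()
  edges <- NULL
  for (tf in cc_tfs) {
    targ <- unique(unlist(lapply(modules[tf_module[[tf]]],
                                 function(m) c(m$queries, m$library))))
    keep <- stats::runif(length(targ)) >= cfg$binding_fnr
    targ <- targ[keep]
    others <- setdiff(cc_tfs, tf)
    tf_targets <- others[stats::runif(length(others)) < cfg$tf_tf_rate]
    regulons[[tf]] <- union(targ, tf_targets)
    if (length(regulons[[tf]]) > 0) {
      edges <- rbind(edges, data.frame(tf = tf, target = regulons[[tf]],
                                       stringsAsFactors = FALSE))
    }
  }
  # spurious edges for every TF
  for (tf in tfs) {
    fp <- universe[stats::runif(length(universe)) < cfg$binding_fpr]
    fp <- setdiff(fp, c(tf, regulons[[tf]]))
    if (length(fp) > 0) {
      edges <- rbind(edges, data.frame(tf = tf, target = fp,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(tf = character(0), target = character(0))
  }
  binding <- binding_network(edges, tf_universe = tfs)

  # ---- regulatory evidence: direct edges + 2-step TF->TF compositions -------
  ev <- binding$edges
  names(ev) <- c("tf", "gene")
  tf_edges <- binding$edges[binding$edges$target %in% tfs, , drop = FALSE]
  if (nrow(tf_edges) > 0) {
    comp <- merge(tf_edges, binding$edges, by.x = "target", by.y = "tf")
    if (nrow(comp) > 0) {
      ev <- rbind(ev, data.frame(tf = comp$tf, gene = comp$target.y,
                                 stringsAsFactors = FALSE))
    }
  }
  ev <- ev[ev$tf != ev$gene, , drop = FALSE]
  evidence <- regulatory_evidence(ev)

  # ---- benchmark ------------------------------------------------------------
  take <- stats::runif(nrow(planted)) < cfg$benchmark_fraction
  bench_src <- planted[take, , drop = FALSE]
  benchmark <- benchmark_interactions(data.frame(
    gene_a = bench_src$query, gene_b = bench_src$library,
    class = ifelse(bench_src$sign == "pos", "positive", "negative"),
    stringsAsFactors = FALSE))

  # ---- orthogonal gene lists ------------------------------------------------
  cc_genes <- union(cc_mod_genes, cc_tfs)
  cc_list <- gene_list("cell_cycle_known", cc_genes)
  kin_core <- cc_genes[stats::runif(length(cc_genes)) < 0.7]
  kin_extra <- setdiff(universe, cc_genes)
  kin_extra <- kin_extra[stats::runif(length(kin_extra)) < 0.05]
  kinase <- gene_list("cdk_substrates_synthetic",
                      union(kin_core, kin_extra))

  list(scores = sscore_matrix(scores), exprs = exprs,
       annotation = annotation, binding = binding, evidence = evidence,
       benchmark = benchmark, cell_cycle_list = cc_list,
       kinase_substrates = kinase,
       kccg = gene_list("kccg", queries),
       truth = list(cc_genes = sort(cc_genes), cc_tfs = sort(cc_tfs),
                    pairs = planted, regulons = regulons,
                    modules = modules),
       config = cfg)
}

#' Write a simulated bundle to disk in the package's TSV/JSON dialect
#'
#' @param bundle output of [simulate_bundle].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_score_matrix(bundle$scores, file.path(dir, "sscores.tsv"))
  for (e in bundle$exprs) {
    write_expression_matrix(e, file.path(dir, paste0(e$experiment, ".tsv")))
  }
  write_annotation(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_binding_network(bundle$binding, file.path(dir, "binding.tsv"))
  utils::write.table(bundle$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$benchmark, file.path(dir, "benchmark.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$cell_cycle_list$members,
             file.path(dir, "cell_cycle_genes.txt"))
  writeLines(bundle$kinase_substrates$members,
             file.path(dir, "kinase_substrates.txt"))
  write_report(list(cc_genes = bundle$truth$cc_genes,
                    cc_tfs = bundle$truth$cc_tfs,
                    pairs = bundle$truth$pairs),
               file.path(dir, "ground_truth.json"))
  invisible(dir)
}
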