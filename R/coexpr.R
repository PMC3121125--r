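# Time-lagged co-expression and periodicity testing.
#
# The similarity between two time-course profiles is the maximum Pearson
# correlation over integer time shifts within [-max_lag, +max_lag], computed
# on the overlapping observed window; across experiments the per-pair score
# is the maximum over experiments ("co-expressed in at least one
# experiment"), a deliberately loose rule because the genetic-interaction
# filter upstream is stringent.

#' Maximum time-lagged Pearson correlation between two series
#'
#' Shifts `b` by every integer lag in `[-max_lag, max_lag]` against `a` and
#' returns the maximum Pearson correlation over the overlapping observed
#' points; at least 3 overlapping, non-constant points are required at some
#' lag. Symmetric in its arguments.
#'
#' @param a,b numeric series on the same experiment's time grid (`NA`
#'   allowed).
#' @param max_lag non-negative integer number of timepoints to shift
#'   (default 2).
#' @return The maximal correlation, with attribute `lag` (a lag achieving
#'   it; smallest |lag| wins ties).
#' @export
time_lagged_cc <- function(a, b, max_lag = 2) {
  stopifnot(length(a) == length(b), max_lag >= 0)
  n <- length(a)
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]  # prefer small |lag| on ties
  best <- -Inf; best_lag <- NA_integer_
  for (l in lags) {
    if (abs(l) >= n) next
    if (l >= 0) {
      x <- a[seq_len(n - l)]; y <- b[seq_len(n - l) + l]
    } else {
      x <- a[seq_len(n + l) - l]; y <- b[seq_len(n + l)]
    }
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    if (r > best) { best <- r; best_lag <- l }
  }
  if (!is.finite(best)) {
    stop(structure(class = c("cyclenet_undefined_cor", "error", "condition"),
                   list(message = "correlation undefined: constant series or insufficient overlap at every lag",
                        call = sys.call(-1))))
  }
  structure(best, lag = best_lag)
}

#' Pairwise time-lagged correlations within one experiment
#'
#' Computes [time_lagged_cc] for every pair in `genes_a` x `genes_b`
#' (complete-data fast path via lagged correlation matrices). Genes absent
#' from the matrix, with fewer than 3 observed points, or constant are
#' skipped; skipped pairs are simply absent from the result.
#'
#' @param expr an [expression_matrix] (ideally imputed; `NA`s tolerated).
#' @param genes_a,genes_b character vectors of gene ids; default all genes.
#' @param max_lag non-negative integer shift bound.
#' @return data.frame with columns `gene_a`, `gene_b`, `cc`, `lag` (one row
#'   per unordered pair, `gene_a < gene_b`; self pairs excluded).
#' @export
coexpression_pairs <- function(expr, genes_a = NULL, genes_b = NULL,
                               max_lag = 2) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- expr$values
  if (is.null(genes_a)) genes_a <- rownames(m)
  if (is.null(genes_b)) genes_b <- rownames(m)
  ga <- intersect(genes_a, rownames(m))
  gb <- intersect(genes_b, rownames(m))
  usable <- function(g) {
    v <- m[g, ]
    sum(!is.na(v)) >= 3 && stats::sd(v, na.rm = TRUE) > 0
  }
  ga <- ga[vapply(ga, usable, logical(1))]
  gb <- gb[vapply(gb, usable, logical(1))]
  if (length(ga) == 0 || length(gb) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      cc = numeric(0), lag = integer(0)))
  }
  n <- ncol(m)
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]
  A <- m[ga, , drop = FALSE]
  B <- m[gb, , drop = FALSE]
  best <- matrix(-Inf, length(ga), length(gb), dimnames = list(ga, gb))
  bestlag <- matrix(NA_integer_, length(ga), length(gb))
  for (l in lags) {
    if (abs(l) >= n) next
    if (l >= 0) { ia <- seq_len(n - l); ib <- ia + l }
    else { ib <- seq_len(n + l); ia <- ib - l }
    r <- suppressWarnings(
      stats::cor(t(A[, ia, drop = FALSE]), t(B[, ib, drop = FALSE]),
                 use = "pairwise.complete.obs"))
    # enforce the >=3-overlap rule of time_lagged_cc
    cnt <- (!is.na(A[, ia, drop = FALSE])) %*% t(!is.na(B[, ib, drop = FALSE]) * 1)
    r[cnt < 3] <- NA
    upd <- !is.na(r) & r > best
    best[upd] <- r[upd]
    bestlag[upd] <- l
  }
  idx <- which(is.finite(best), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      cc = numeric(0), lag = integer(0)))
  }
  out <- data.frame(gene_a = ga[idx[, 1]], gene_b = gb[idx[, 2]],
                    cc = best[idx], lag = bestlag[idx],
                    stringsAsFactors = FALSE)
  out <- out[out$gene_a != out$gene_b, , drop = FALSE]
  swap <- out$gene_a > out$gene_b
  if (any(swap)) {
    tmp <- out$gene_a[swap]
    out$gene_a[swap] <- out$gene_b[swap]
    out$gene_b[swap] <- tmp
    out$lag[swap] <- -out$lag[swap]
  }
  # a pair may appear twice when genes_a and genes_b overlap
  key <- paste(out$gene_a, out$gene_b, sep = "\r")
  dup <- duplicated(key)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-experiment correlation tables by the maximum rule
#'
#' A pair's combined correlation is the maximum over all experiments that
#' produced a value for it; pairs valid in no experiment are absent (never
#' zero-filled).
#'
#' @param tables named list of data.frames as returned by
#'   [coexpression_pairs]; names are experiment labels.
#' @return A `coexpression_table`: data.frame with columns `gene_a`,
#'   `gene_b`, `cc`, `lag`, `experiment` (the argmax experiment), plus
#'   attribute `experiments_used`.
#' @export
combine_experiments <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("experiment", seq_along(tables))
  }
  all <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    if (nrow(t) == 0) return(NULL)
    t$experiment <- nm
    t
  }))
  if (is.null(all) || nrow(all) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      cc = numeric(0), lag = integer(0),
                      experiment = character(0))
  } else {
    swap <- all$gene_a > all$gene_b  # canonical unordered-pair order
    if (any(swap)) {
      tmp <- all$gene_a[swap]
      all$gene_a[swap] <- all$gene_b[swap]
      all$gene_b[swap] <- tmp
      all$lag[swap] <- -all$lag[swap]
    }
    key <- paste(all$gene_a, all$gene_b, sep = "\r")
    ord <- order(key, -all$cc)
    all <- all[ord, , drop = FALSE]
    out <- all[!duplicated(key[ord]), , drop = FALSE]
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("coexpression_table", "data.frame"),
            experiments_used = names(tables))
}

#' Full co-expression workflow across experiments
#'
#' Imputes each experiment, computes pairwise time-lagged correlations and
#' combines them with the max-over-experiments rule.
#'
#' @param exprs list of [expression_matrix] objects.
#' @param genes_a,genes_b gene id vectors restricting the pair universe
#'   (default: all genes present).
#' @param max_lag shift bound in timepoints (default 2).
#' @param k,max_missing_fraction forwarded to [knn_impute]; set `k = 0` to
#'   skip imputation.
#' @return A `coexpression_table` (see [combine_experiments]).
#' @export
coexpression_table <- function(exprs, genes_a = NULL, genes_b = NULL,
                               max_lag = 2, k = 10,
                               max_missing_fraction = 0.5) {
  stopifnot(is.list(exprs), length(exprs) >= 1)
  tabs <- lapply(exprs, function(e) {
    if (k > 0 && anyNA(e$values)) {
      e <- suppressMessages(knn_impute(e, k = k,
                                       max_missing_fraction = max_missing_fraction))
    }
    coexpression_pairs(e, genes_a, genes_b, max_lag = max_lag)
  })
  names(tabs) <- vapply(exprs, function(e) e$experiment, character(1))
  combine_experiments(tabs)
}

# fast lookup helper: named vector cc by "a\rb" (a<b) key
.cc_lookup <- function(cc_table) {
  stats::setNames(cc_table$cc, paste(cc_table$gene_a, cc_table$gene_b,
                                     sep = "\r"))
}

.pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "\r")
}

#' Permutation test for periodic expression
#'
#' The test statistic is the squared magnitude of the discrete Fourier
#' component nearest the frequency `1/period`, divided by the total variance
#' of the series. Significance is assessed by permuting the timepoints:
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @param series numeric expression series with at least 8 observed points
#'   (`NA`s are dropped).
#' @param period period in the series' sampling units (timepoints per
#'   cycle).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed making the permutations reproducible.
#' @return list with `statistic` and `p_value`. Constant series return
#'   `p_value = 1` with a warning.
#' @export
periodicity_test <- function(series, period, n_perm = 999, seed = 1) {
  obs <- !is.na(series)
  x <- series[obs]
  n <- length(x)
  if (n < 8) stop("periodicity_test needs at least 8 observed timepoints")
  if (stats::sd(x) == 0) {
    warning("constant series: periodicity undefined, p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  # Fourier basis vector at the frequency bin nearest 1/period
  freqs <- seq_len(floor(n / 2)) / n
  kbin <- which.min(abs(freqs - 1 / period))
  basis <- exp(-2i * pi * kbin * (seq_len(n) - 1) / n)
  # normalized so a pure sinusoid at an exact bin frequency scores 1/2
  stat_of <- function(v) Mod(sum(v * basis))^2 / (n * sum((v - mean(v))^2))
  observed <- stat_of(x)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) stat_of(x[sample.int(n)]),
                  numeric(1))
  p <- (1 + sum(perms >= observed)) / (n_perm + 1)
  list(statistic = observed, p_value = p)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Periodicity p-values for many genes
#'
#' Applies [periodicity_test] to every gene of one or more experiments and,
#' with several experiments, combines per-experiment p-values by taking the
#' minimum ("periodic in at least one experiment" — the same loose
#' convention as the max-over-experiments correlation rule).
#'
#' @param exprs an [expression_matrix] or list of them.
#' @param period period in timepoints per cycle.
#' @param genes genes to test (default: all genes in any experiment).
#' @param n_perm permutations per test.
#' @param seed integer seed; per-gene seeds are derived deterministically.
#' @return data.frame with columns `gene`, `statistic`, `p_value`.
#' @export
periodicity_table <- function(exprs, period, genes = NULL, n_perm = 999,
                              seed = 1) {
  if (inherits(exprs, "expression_matrix")) exprs <- list(exprs)
  all_genes <- unique(unlist(lapply(exprs, function(e) e$genes)))
  if (is.null(genes)) genes <- all_genes
  genes <- intersect(genes, all_genes)
  res <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    best_p <- NA_real_; best_s <- NA_real_
    for (j in seq_along(exprs)) {
      e <- exprs[[j]]
      if (!(g %in% rownames(e$values))) next
      v <- e$values[g, ]
      if (sum(!is.na(v)) < 8 || stats::sd(v, na.rm = TRUE) == 0) next
      r <- periodicity_test(v, period, n_perm = n_perm,
                            seed = (seed + 131 * i + j) %% .Machine$integer.max)
      if (is.na(best_p) || r$p_value < best_p) {
        best_p <- r$p_value; best_s <- r$statistic
      }
    }
    c(statistic = best_s, p_value = best_p)
  })
  out <- data.frame(gene = genes, do.call(rbind, res),
                    stringsAsFactors = FALSE)
  out$p_value[is.na(out$p_value)] <- 1  # untestable genes: no evidence
  out$statistic[is.na(out$statistic)] <- 0
  rownames(out) <- NULL
  out
}
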