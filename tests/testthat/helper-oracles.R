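# Independent oracles used to validate the package's computations.
# These deliberately use naive exhaustive formulations, never the package's
# own code paths.

# upper-tail hypergeometric by direct summation of the pmf
oracle_hyper <- function(m, n, M, N) {
  js <- m:min(n, M)
  sum(choose(M, js) * choose(N - M, n - js)) / choose(N, n)
}

# minimal directed path length by exhaustive simple-path enumeration
oracle_min_path <- function(edges, from, to, max_len = Inf) {
  if (from == to) return(0)
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best || len >= max_len) return(invisible())
    nxt <- edges$target[edges$tf == node]
    for (v in nxt) {
      if (v == to) {
        best <<- min(best, len + 1)
      } else if (!(v %in% visited)) {
        recurse(v, c(visited, v), len + 1)
      }
    }
  }
  recurse(from, from, 0)
  if (is.finite(best)) best else NA_real_
}

# naive KNN imputation: for each missing cell, rank all other genes observed
# at that timepoint by Euclidean distance over shared observed timepoints and
# average the k nearest with inverse-distance weights
oracle_knn_impute <- function(m, k) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (t in which(is.na(m[i, ]))) {
      ds <- c(); vals <- c(); ids <- c()
      for (j in seq_len(nrow(m))) {
        if (j == i || is.na(m[j, t])) next
        shared <- which(!is.na(m[i, ]) & !is.na(m[j, ]))
        if (length(shared) == 0) next
        ds <- c(ds, sqrt(sum((m[i, shared] - m[j, shared])^2)))
        vals <- c(vals, m[j, t]); ids <- c(ids, j)
      }
      if (length(ds) == 0) {
        out[i, t] <- mean(m[i, ], na.rm = TRUE)
        next
      }
      ord <- order(ds, ids)[seq_len(min(k, length(ds)))]
      w <- 1 / pmax(ds[ord], .Machine$double.eps)
      out[i, t] <- sum(w * vals[ord]) / sum(w)
    }
  }
  out
}

# Pearson correlation at a fixed integer lag on complete series
oracle_lagged_cor <- function(a, b, lag) {
  n <- length(a)
  if (lag >= 0) cor(a[seq_len(n - lag)], b[seq_len(n - lag) + lag])
  else cor(a[seq_len(n + lag) - lag], b[seq_len(n + lag)])
}
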