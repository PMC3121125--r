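test_that("cofunctional is exact set intersection on term sets", {
  ann <- toy_annotation(a = c("t1", "t2"), b = "t2",
                        c = c("u1", "u2", "u3"), d = c("v1", "v2", "v3"))
  expect_true(cofunctional("a", "b", ann))
  expect_false(cofunctional("a", "zz", ann))  # unannotated gene
  expect_false(cofunctional("c", "d", ann))   # disjoint 3-term sets
})

test_that("enrichment_curve computes f, r and their ratio per bin", {
  # 10 pairs in the high bin, all co-functional; 10 in the low bin, none;
  # r = 0.5 so the high bin's ratio is exactly 2
  ann <- toy_annotation(q = "T", hi = "T", lo = "X")
  pairs <- data.frame(
    query = rep("q", 20),
    library = rep(c("hi", "lo"), each = 10),
    s = c(rep(5, 10), rep(0, 10)),
    cc = NA_real_)
  # distinct library ids to keep the pair universe honest
  pairs$library <- paste0(pairs$library, seq_len(20))
  for (g in pairs$library) {
    ann[[g]] <- if (startsWith(g, "hi")) "T" else "X"
  }
  ann <- annotation_table(ann)
  ann[["q"]] <- "T"
  curve <- enrichment_curve(pairs, ann, axis = "sscore", bin_size = 1.5)
  hi_bin <- curve[curve$lo <= 5 & curve$hi > 5, ]
  expect_equal(hi_bin$f, 1)
  expect_equal(hi_bin$r, 0.5)
  expect_equal(hi_bin$ratio, 2)
  # empty bins between the two clusters are flagged, not fabricated
  empty_bins <- curve[curve$pair_count == 0, ]
  expect_true(nrow(empty_bins) > 0 && all(is.na(empty_bins$ratio)))
  # bins are half-open [lo, hi)
  expect_equal(sum(curve$pair_count), 20)
})

test_that("enrichment ratios stay near 1 on unstructured annotation", {
  set.seed(77)
  genes <- sprintf("g%03d", 1:80)
  ann <- annotation_table(stats::setNames(
    lapply(genes, function(g) sample(sprintf("T%d", 1:8), 2)), genes))
  pairs <- data.frame(query = sample(genes, 2000, replace = TRUE),
                      library = sample(genes, 2000, replace = TRUE),
                      s = rnorm(2000, 0, 2), cc = NA_real_)
  pairs <- pairs[pairs$query != pairs$library, ]
  curve <- enrichment_curve(pairs, ann, axis = "sscore", bin_size = 1.5)
  busy <- curve[!is.na(curve$ratio) & curve$pair_count >= 200, ]
  expect_gt(nrow(busy), 0)
  expect_true(all(busy$ratio >= 0.5 & busy$ratio <= 2))
})

test_that("enrichment_surface is 1 on the whole space and nests", {
  set.seed(13)
  b <- simulate_bundle(small_config(seed = 13))
  cc <- coexpression_table(b$exprs, b$scores$queries, b$scores$library,
                           max_lag = 2)
  pairs <- pair_universe(b$scores, cc)
  surf <- enrichment_surface(pairs, b$annotation,
                             s_grid = c(-14, -3, 0, 2.5, 6),
                             cc_grid = c(-1, 0.85, 0.9))
  loosest <- surf[surf$tail == "+" & surf$s_threshold == -14 &
                    surf$cc_threshold == -1, ]
  expect_identical(loosest$pair_count, nrow(pairs))
  expect_equal(loosest$ratio, 1)  # exact identity: f and r share a universe

  # planted signal: the extreme joint cell beats the loose cell
  tight <- surf[surf$tail == "+" & surf$s_threshold == 6 &
                  surf$cc_threshold == 0.9, ]
  loose0 <- surf[surf$tail == "+" & surf$s_threshold == 0 &
                   surf$cc_threshold == -1, ]
  expect_gt(tight$ratio, loose0$ratio)

  # pair counts never increase as either threshold tightens
  for (tl in c("+", "-")) {
    sub <- surf[surf$tail == tl, ]
    for (ct in unique(sub$cc_threshold)) {
      cnt <- sub$pair_count[sub$cc_threshold == ct][
        order(sub$s_threshold[sub$cc_threshold == ct],
              decreasing = (tl == "-"))]
      expect_true(all(diff(cnt) <= 0))
    }
    for (st in unique(sub$s_threshold)) {
      cnt <- sub$pair_count[sub$s_threshold == st][
        order(sub$cc_threshold[sub$s_threshold == st])]
      expect_true(all(diff(cnt) <= 0))
    }
  }
})

test_that("default_region reproduces the published clause logic exactly", {
  reg <- default_region()
  expect_identical(nrow(reg), 4L)
  pass1 <- function(s, cc) nrow(extract_pccg(
    toy_scores(matrix(s, 1, 1, dimnames = list("q", "l"))),
    if (is.na(cc)) NULL else toy_cc("q", "l", cc), reg)$pairs) == 1
  cases <- rbind(
    # s, cc, expected
    c(7,    NA,   TRUE),   # S>6 needs no correlation
    c(6,    NA,   FALSE),  # strict inequality at the boundary
    c(2.6,  0.95, TRUE),   # (S>2.5 & cc>0.9)
    c(2.6,  0.9,  FALSE),  # strict at cc boundary
    c(2.6,  0.85, FALSE),
    c(2.6,  NA,   FALSE),  # missing cc cannot satisfy a cc clause
    c(2.5,  0.95, FALSE),  # strict at s boundary
    c(-3.5, 0.95, TRUE),   # (S<-3 & cc>0.9)
    c(-3.5, 0.88, FALSE),
    c(-15,  0.86, TRUE),   # (S<-14 & cc>0.85)
    c(-15,  0.85, FALSE),
    c(-15,  NA,   FALSE),
    c(-2,   0.99, FALSE))
  for (i in seq_len(nrow(cases))) {
    expect_identical(pass1(cases[i, 1], cases[i, 2]),
                     as.logical(cases[i, 3]),
                     label = sprintf("clause case s=%g cc=%g", cases[i, 1],
                                     cases[i, 2]))
  }
})

test_that("region_from_surface keeps the loosest qualifying cells", {
  # hand-built surface: only the s>=6 column (any cc) clears ratio 2
  surf <- expand.grid(tail = "+", s_threshold = c(0, 2.5, 6),
                      cc_threshold = c(-1, 0.9), stringsAsFactors = FALSE)
  surf$pair_count <- 50L
  surf$f <- ifelse(surf$s_threshold == 6, 0.9, 0.2)
  surf$ratio <- surf$f / 0.2
  surf$empty <- FALSE
  class(surf) <- c("enrichment_surface", "data.frame")
  attr(surf, "r") <- 0.2
  reg <- region_from_surface(surf, pos_min_ratio = 2, neg_min_ratio = 4)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$sign, "pos")
  expect_equal(reg$s_bound, 6)
  expect_true(is.na(reg$cc_min))
  expect_warning(region_from_surface(surf, pos_min_ratio = 100),
                 "empty region")
})

test_that("raising the ratio threshold never enlarges the region", {
  set.seed(5)
  for (rep in 1:10) {
    surf <- expand.grid(tail = c("+", "-"), s_threshold = c(0, 3, 6),
                        cc_threshold = c(-1, 0.8), stringsAsFactors = FALSE)
    surf$pair_count <- sample(0:30, nrow(surf), replace = TRUE)
    surf$f <- runif(nrow(surf))
    surf$ratio <- surf$f / 0.2
    surf$empty <- surf$pair_count == 0
    class(surf) <- c("enrichment_surface", "data.frame")
    attr(surf, "r") <- 0.2
    loose <- suppressWarnings(region_from_surface(surf, 1.5, 3))
    tight <- suppressWarnings(region_from_surface(surf, 2.5, 5))
    # every clause kept at the tighter threshold has a counterpart at least
    # as loose in the looser region: membership can only shrink
    s <- seq(-20, 20, by = 0.5)
    grid <- expand.grid(s = s, cc = c(NA, 0.7, 0.85, 0.95))
    member <- function(region, s, cc) {
      if (nrow(region) == 0) return(rep(FALSE, length(s)))
      any_clause <- rep(FALSE, length(s))
      for (i in seq_len(nrow(region))) {
        ok <- if (region$sign[i] == "pos") s > region$s_bound[i]
              else s < region$s_bound[i]
        if (!is.na(region$cc_min[i])) ok <- ok & !is.na(cc) & cc > region$cc_min[i]
        any_clause <- any_clause | ok
      }
      any_clause
    }
    expect_true(all(!member(tight, grid$s, grid$cc) |
                      member(loose, grid$s, grid$cc)))
  }
})

test_that("extract_pccg handles empty and singleton regions", {
  empty <- interaction_region(data.frame(sign = character(0),
                                         s_bound = numeric(0),
                                         cc_min = numeric(0)))
  sm <- toy_scores(matrix(c(10, 0, 0, 0), 2, 2))
  res0 <- extract_pccg(sm, NULL, empty)
  expect_identical(nrow(res0$pairs), 0L)
  expect_identical(res0$pccg, character(0))

  res1 <- extract_pccg(sm, NULL, default_region())
  expect_identical(res1$pccg, "L1")
  expect_identical(res1$positive_part, "L1")
  expect_identical(res1$negative_part, character(0))
})

test_that("tightening a clause never adds a passing pair", {
  set.seed(99)
  b <- simulate_bundle(small_config(seed = 99))
  cc <- coexpression_table(b$exprs, b$scores$queries, b$scores$library)
  base <- default_region()
  tightened <- base
  tightened$s_bound <- tightened$s_bound +
    ifelse(tightened$sign == "pos", 1, -1)
  p_base <- extract_pccg(b$scores, cc, base)$pairs
  p_tight <- extract_pccg(b$scores, cc, tightened)$pairs
  key <- function(df) paste(df$query, df$library)
  expect_true(all(key(p_tight) %in% key(p_base)))
})

test_that("benchmark_eval counts TP and computes the exact precision p", {
  # population: 2x5 fully measured matrix = 10 pairs; 4 benchmark pairs;
  # region predicts exactly the 3 pairs with s > 6, all in the benchmark
  m <- matrix(c(10, 9, 8, 0, 0, 0, 0, 0, 0, 0), nrow = 2, byrow = FALSE)
  sm <- toy_scores(m, queries = c("q1", "q2"),
                   libs = sprintf("l%d", 1:5))
  bench <- benchmark_interactions(data.frame(
    gene_a = c("q1", "q2", "q1", "q2"),
    gene_b = c("l1", "l1", "l2", "l5"),
    class = "positive"))
  res <- benchmark_eval(sm, c(-6, 6), bench)
  expect_identical(res$TP, 3L)
  expect_identical(res$predicted, 3L)
  expect_equal(res$sensitivity, 3 / 4)
  expect_equal(res$precision, 1)
  expect_equal(res$p_precision, oracle_hyper(3, 3, 4, 10),
               tolerance = 1e-12)
  expect_equal(res$p_precision, 4 / 120, tolerance = 1e-12)
})

test_that("benchmark_eval p_precision matches enumeration on small worlds", {
  set.seed(55)
  for (rep in 1:20) {
    nq <- 2; nl <- sample(3:6, 1)
    m <- matrix(rnorm(nq * nl, 0, 4), nq, nl,
                dimnames = list(paste0("q", 1:nq), paste0("l", 1:nl)))
    sm <- sscore_matrix(m)
    univ <- expand.grid(q = rownames(m), l = colnames(m),
                        stringsAsFactors = FALSE)
    pick <- univ[sample(nrow(univ), sample(2:5, 1)), ]
    bench <- benchmark_interactions(data.frame(gene_a = pick$q,
                                               gene_b = pick$l,
                                               class = "negative"))
    cut <- runif(1, 1, 3)
    res <- suppressWarnings(benchmark_eval(sm, c(-cut, cut), bench))
    if (res$predicted == 0) next
    expect_equal(res$p_precision,
                 oracle_hyper(res$TP, res$predicted,
                              res$benchmark_measured, nq * nl),
                 tolerance = 1e-12)
  }
})

test_that("cross_dataset_r behaves on identity, negation and noisy copies", {
  set.seed(31)
  m <- matrix(rnorm(20 * 30, 0, 4), 20, 30,
              dimnames = list(sprintf("q%d", 1:20), sprintf("l%d", 1:30)))
  a <- sscore_matrix(m)
  expect_equal(cross_dataset_r(a, a), 1)
  expect_equal(cross_dataset_r(a, sscore_matrix(-m)), -1)

  sigma <- 0.8
  b <- sscore_matrix(m + rnorm(length(m), 0, sigma))
  r <- cross_dataset_r(a, b, significance_cut = 2.5)
  sig <- abs(m) > 2.5  # the subset is dominated by a's own significant pairs
  expected <- sd(m[sig]) / sqrt(sd(m[sig])^2 + sigma^2)
  expect_equal(r, expected, tolerance = 0.05)

  tiny <- sscore_matrix(matrix(c(1, 1, 1, 1), 2, 2,
                               dimnames = list(c("q1", "q2"),
                                               c("l1", "l2"))))
  expect_error(cross_dataset_r(tiny, tiny), "fewer than 3")
})
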