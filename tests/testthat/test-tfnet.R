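toy_binding <- function() {
  binding_network(data.frame(
    tf = c("T1", "T1", "T1", "T2", "T2", "T3", "T4", "T4"),
    target = c("a", "b", "c", "a", "b", "d", "c", "d")),
    tf_universe = c("T1", "T2", "T3", "T4", "T5"))
}

test_that("tf_enrichment_test reduces to the plain hypergeometric", {
  bn <- toy_binding()
  universe <- c("a", "b", "c", "d", "e", "f")
  focus <- c("a", "b", "c")
  # T1 targets exactly the focus
  expect_equal(tf_enrichment_test("T1", bn, focus, universe),
               hypergeom_upper(3, 3, 3, 6), tolerance = 1e-12)
  # matches the enumeration oracle for a partial overlap
  expect_equal(tf_enrichment_test("T2", bn, focus, universe),
               oracle_hyper(2, 3, 2, 6), tolerance = 1e-12)
  # zero focus targets is never significant
  expect_equal(tf_enrichment_test("T3", bn, focus, universe), 1)
  expect_warning(p5 <- tf_enrichment_test("T5", bn, focus, universe),
                 "no targets")
  expect_identical(p5, 1)
})

test_that("rank_tfs multiplies average ranks and orders deterministically", {
  # A is extreme in one test only; B is mediocre in both: A must win
  p_et <- c(A = 1e-6, B = 0.04, C = 0.5, D = 0.9)
  p_pt <- c(A = 0.95, B = 0.05, C = 0.5, D = 0.9)
  rk <- rank_tfs(p_et, p_pt)
  # ET ranks: A=1,B=2,C=3,D=4; PT ranks: B=1,C=2,D=3,A=4
  # products: A=4, B=2, C=6, D=12 -> B first, then A
  expect_identical(rk$tf[1:2], c("B", "A"))
  expect_identical(rk$final_rank, 1:4)
  expect_equal(rk$rank_product, c(2, 4, 6, 12))

  # single TF
  one <- rank_tfs(c(X = 0.5), c(X = 0.2))
  expect_identical(one$final_rank, 1L)

  # identical p vectors reproduce the single-test order
  p <- c(u = 0.3, v = 0.1, w = 0.7)
  both <- rank_tfs(p, p)
  expect_identical(both$tf, c("v", "u", "w"))

  # ties share an average rank and a dense final rank
  tie <- rank_tfs(c(a = 0.1, b = 0.1), c(a = 0.5, b = 0.5))
  expect_equal(tie$rank_product, c(2.25, 2.25))
  expect_identical(tie$final_rank, c(1L, 1L))

  expect_error(rank_tfs(c(A = 0.1), c(B = 0.1)), "differ")
})

test_that("the stated rank-product example prefers the one-test specialist", {
  # ranks (1, 100) vs (40, 40): 100 < 1600
  expect_lt(1 * 100, 40 * 40)
  set.seed(40)
  n <- 130
  p_et <- stats::setNames(runif(n), sprintf("TF%03d", 1:n))
  p_pt <- stats::setNames(runif(n), names(p_et))
  # give one TF an Mcm1-like profile: top of ET, bottom of PT
  p_et["TF001"] <- 1e-9; p_pt["TF001"] <- 0.99
  rk <- rank_tfs(p_et, p_pt)
  expect_lte(which(rk$tf == "TF001"), n / 4)
})

test_that("pairwise dominance in both tests forces a better final rank", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 25
    p_et <- stats::setNames(runif(n), sprintf("T%02d", 1:n))
    p_pt <- stats::setNames(runif(n), names(p_et))
    rk <- rank_tfs(p_et, p_pt)
    pos <- match(names(p_et), rk$tf)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (p_et[i] < p_et[j] && p_pt[i] < p_pt[j]) {
        expect_lt(rk$final_rank[pos[i]], rk$final_rank[pos[j]])
      }
    }
  }
})

test_that("coverage_curve matches hand enumeration on a 4-TF toy", {
  bn <- toy_binding()
  ranking <- rank_tfs(
    c(T1 = 0.01, T2 = 0.02, T3 = 0.03, T4 = 0.04),
    c(T1 = 0.01, T2 = 0.02, T3 = 0.03, T4 = 0.04))
  genes <- c("a", "b", "c", "d", "z")  # z unbound, never coverable
  pairs <- data.frame(g1 = c("a", "c"), g2 = c("b", "d"))
  curve <- coverage_curve(ranking, bn, genes, pairs)
  # coverable: genes a,b,c,d; pairs: (a,b) via T1 or T2; (c,d) via T4
  expect_identical(attr(curve, "n_coverable_genes"), 4L)
  expect_identical(attr(curve, "n_coverable_pairs"), 2L)
  expect_equal(curve$gene_coverage, c(0, 3 / 4, 3 / 4, 1, 1))
  expect_equal(curve$pair_coverage, c(0, 1 / 2, 1 / 2, 1 / 2, 1))
  # saturation and k=0 anchors
  expect_equal(curve$gene_coverage[1], 0)
  expect_equal(curve$gene_coverage[nrow(curve)], 1)
  # monotone non-decreasing
  expect_true(all(diff(curve$gene_coverage) >= 0))
  expect_true(all(diff(curve$pair_coverage) >= 0))
})

test_that("select_tfs finds the knee and honours explicit k", {
  curve <- structure(data.frame(
    k = 0:6,
    gene_coverage = c(0, 0.4, 0.7, 0.9, 0.905, 0.907, 0.908),
    pair_coverage = c(0, 0.5, 0.8, 0.95, 0.955, 0.957, 0.958)),
    class = c("coverage_curve", "data.frame"))
  expect_identical(select_tfs(curve, k = 25), 6L)   # capped at max k
  expect_identical(select_tfs(curve, k = 2), 2L)
  expect_identical(select_tfs(curve, "auto", epsilon = 0.01), 3L)
  expect_warning(kmax <- select_tfs(curve, "auto", epsilon = 0),
                 "increasing")
  expect_identical(kmax, 6L)
})

test_that("indirect_connectivity separates direct, indirect and unreachable", {
  bn <- binding_network(data.frame(
    tf = c("T1", "T2", "T2", "T3"),
    target = c("T2", "g", "h", "T1")),
    tf_universe = c("T1", "T2", "T3"))
  ev <- regulatory_evidence(data.frame(
    tf = c("T1", "T2", "T3", "T1"),
    gene = c("g", "g", "h", "x")))
  rep <- indirect_connectivity(bn, ev, selected = c("T1", "T2", "T3"),
                               targets = c("g", "h", "x"), max_steps = 3)
  # (T2, g) is a direct edge: excluded from the indirect set
  expect_false(any(rep$pairs$tf == "T2" & rep$pairs$gene == "g"))
  # chain T1 -> T2 -> g has length 2
  expect_equal(rep$pairs$path_length[rep$pairs$tf == "T1" &
                                       rep$pairs$gene == "g"], 2)
  # T3 -> T1 -> T2 -> h has length 3
  expect_equal(rep$pairs$path_length[rep$pairs$tf == "T3" &
                                       rep$pairs$gene == "h"], 3)
  # x is unreachable and never explained
  expect_true(is.na(rep$pairs$path_length[rep$pairs$gene == "x"]))
  expect_equal(unname(rep$explained_by_step), c(0, 1, 2))
  expect_true(all(diff(rep$explained_fraction) >= 0))
})

test_that("minimal path lengths equal exhaustive enumeration on random graphs", {
  set.seed(23)
  for (rep in 1:30) {
    n_tf <- sample(3:6, 1); n_g <- sample(2:6, 1)
    tfs <- sprintf("T%d", 1:n_tf); gs <- sprintf("g%d", 1:n_g)
    nodes <- c(tfs, gs)
    e <- expand.grid(tf = tfs, target = nodes, stringsAsFactors = FALSE)
    e <- e[e$tf != e$target & runif(nrow(e)) < 0.25, ]
    if (nrow(e) == 0) next
    bn <- binding_network(e, tf_universe = tfs)
    ev <- regulatory_evidence(expand.grid(tf = tfs, gene = gs,
                                          stringsAsFactors = FALSE))
    rep_out <- indirect_connectivity(bn, ev, selected = tfs, targets = gs,
                                     max_steps = 4)
    for (i in seq_len(nrow(rep_out$pairs))) {
      want <- oracle_min_path(bn$edges, rep_out$pairs$tf[i],
                              rep_out$pairs$gene[i])
      expect_equal(rep_out$pairs$path_length[i], want,
                   label = sprintf("path %s->%s (rep %d)",
                                   rep_out$pairs$tf[i],
                                   rep_out$pairs$gene[i], rep))
    }
  }
})

test_that("the sub-network variant only walks selected TFs' edges", {
  bn <- binding_network(data.frame(
    tf = c("T1", "T2", "T2"), target = c("T2", "g", "T3")),
    tf_universe = c("T1", "T2", "T3"))
  ev <- regulatory_evidence(data.frame(tf = "T1", gene = "g"))
  full <- indirect_connectivity(bn, ev, selected = "T1", targets = "g",
                                max_steps = 3)
  expect_equal(full$pairs$path_length, 2)
  sub <- indirect_connectivity(bn, ev, selected = "T1", targets = "g",
                               max_steps = 3, restrict_to_selected = TRUE)
  expect_true(is.na(sub$pairs$path_length))
})

test_that("cluster_profiles reproduces hand-computed Jaccard linkage", {
  bn <- binding_network(data.frame(
    tf = c("T1", "T1", "T2", "T2", "T3", "T4", "T4", "T4"),
    target = c("a", "b", "a", "b", "c", "a", "b", "c")))
  ct <- cluster_profiles(bn)
  # T1 and T2 have identical target sets: merged at height 0
  h <- stats::cophenetic(ct$tf_tree)
  hm <- as.matrix(h)
  expect_equal(hm["T1", "T2"], 0)
  # T3 ({c}) is disjoint from T1/T2 ({a,b}): Jaccard distance 1
  d <- as.matrix(stats::dist(ct$profile, method = "binary"))
  expect_equal(d["T1", "T3"], 1)
  # hand-run average linkage: d(T1,T4)=d(T2,T4)=1/3, d(T3,T4)=2/3
  # merges: (T1,T2)@0, then T4 joins at mean(1/3,1/3)=1/3,
  # then T3 at mean(1, 1, 2/3) = 8/9
  expect_equal(sort(ct$tf_tree$height), c(0, 1 / 3, 8 / 9),
               tolerance = 1e-12)
  expect_true(all(diff(ct$tf_tree$height) >= 0))
  expect_setequal(ct$tf_tree$labels, c("T1", "T2", "T3", "T4"))
  expect_setequal(ct$gene_tree$labels, c("a", "b", "c"))
})

test_that("degenerate clustering inputs are handled", {
  bn <- binding_network(data.frame(tf = "T1", target = c("a", "b")))
  expect_error(cluster_profiles(bn), "at least 2")
})
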