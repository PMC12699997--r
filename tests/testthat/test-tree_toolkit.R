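test_that("NJ recovers the additive 4-taxon tree with exact branch lengths", {
  D <- distance_matrix(matrix(
    c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))))
  tr <- nj_tree(D)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(D), rownames(D)]),
               unname(unclass(D)), tolerance = 1e-9)
  expect_equal(rf_pair(tr, ape::read.tree(text = "((A,B),(C,D));"))$nrf, 0)
})

test_that("3-taxon NJ gives the closed-form star lengths", {
  D <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                              dimnames = list(c("a", "b", "c"),
                                              c("a", "b", "c"))))
  tr <- nj_tree(D)
  # la = (dab + dac - dbc)/2 etc.
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens[["a"]], (2 + 3 - 4) / 2)
  expect_equal(lens[["b"]], (2 + 4 - 3) / 2)
  expect_equal(lens[["c"]], (3 + 4 - 2) / 2)
  expect_error(nj_tree(distance_matrix(matrix(0, 1, 1,
                                              dimnames = list("x", "x")))),
               "at least 3")
})

test_that("NJ is consistent on additive matrices from random trees", {
  for (seed in 1:25) {
    n <- 6 + seed %% 5
    true <- random_binary_tree(n, seed = seed)
    D <- distance_matrix(ape::cophenetic.phylo(true))
    est <- nj_tree(D)
    expect_equal(rf_pair(est, true)$nrf, 0)
    expect_equal(unname(ape::cophenetic.phylo(est)[rownames(D), rownames(D)]),
                 unname(unclass(D)), tolerance = 1e-9)
  }
})

test_that("NJ topology matches the independent ape implementation", {
  for (seed in 1:5) {
    aln <- signal_alignment(7, L = 800, seed = seed)
    D <- alignment_distance_matrix(aln, "p")
    mine <- nj_tree(D)
    theirs <- ape::nj(stats::as.dist(unclass(D)))
    expect_equal(rf_pair(mine, theirs)$nrf, 0)
  }
})

test_that("equal merge choices resolve deterministically", {
  # ultrametric matrix where (a,b) and (c,d) tie at the first join
  m <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[cbind(c("a", "b"), c("b", "a"))] <- 1
  m[cbind(c("c", "d"), c("d", "c"))] <- 1
  diag(m) <- 0
  trees <- replicate(3, nj_tree(distance_matrix(m)), simplify = FALSE)
  expect_equal(rf_pair(trees[[1]], trees[[2]])$nrf, 0)
  expect_identical(ape::write.tree(trees[[1]]), ape::write.tree(trees[[3]]))
  # the rule joins the lexicographically smallest tied pair first: (a,b)
  expect_true("a|b" %in% tree_bipartitions(trees[[1]]) ||
                "c|d" %in% tree_bipartitions(trees[[1]]))
})

test_that("RF examples: identical, one-NNI five-leaf, maximally different", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(rf_pair(t1, t1)$nrf, 0)
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  st <- rf_pair(t1, t2)
  expect_equal(st$rf, 2L)
  expect_equal(st$rf_max, 4L)
  expect_equal(st$nrf, 0.5)
  a <- ape::read.tree(text = "(((A,B),(C,D)),E,F);")
  b <- ape::read.tree(text = "(((A,E),(C,F)),B,D);")
  expect_equal(rf_pair(a, b)$nrf, 1)
  expect_error(rf_pair(ape::read.tree(text = "(A,B,C);"),
                       ape::read.tree(text = "(A,B,C);")), "4 shared")
})

test_that("nRF agrees with phangorn on random binary tree pairs", {
  skip_if_not_installed("phangorn")
  for (seed in 1:50) {
    n <- 5 + seed %% 6
    ta <- random_binary_tree(n, seed = 2 * seed)
    tb <- random_binary_tree(n, seed = 2 * seed + 1)
    mine <- rf_pair(ta, tb)
    oracle <- phangorn::RF.dist(ta, tb, normalize = FALSE)
    expect_equal(mine$rf, oracle)
    expect_equal(mine$rf_max, 2L * (n - 3L))
  }
})

test_that("rf_pair prunes to shared leaves before comparing", {
  ta <- ape::read.tree(text = "(((A,B),(C,D)),(E,X),F);")
  tb <- ape::read.tree(text = "(((A,B),(C,D)),E,(F,Y));")
  st <- rf_pair(ta, tb)
  expect_equal(st$shared_leaves, 6L)
  expect_equal(st$nrf, 0)
})

test_that("RF is a metric on a fixed leaf set", {
  trees <- lapply(1:6, function(s) random_binary_tree(6, seed = 100 + s))
  for (i in 1:4) {
    a <- trees[[i]]; b <- trees[[i + 1]]; c <- trees[[i + 2]]
    dab <- rf_pair(a, b)$rf; dba <- rf_pair(b, a)$rf
    expect_equal(dab, dba)
    expect_equal(rf_pair(a, a)$rf, 0L)
    expect_lte(rf_pair(a, c)$rf, dab + rf_pair(b, c)$rf)
  }
})

test_that("tree-set distance matrix matches pairwise rf_pair", {
  trees <- list(x = random_binary_tree(6, 1), y = random_binary_tree(6, 2),
                z = random_binary_tree(6, 3))
  M <- treeset_distance_matrix(trees)
  expect_equal(M["x", "y"], rf_pair(trees$x, trees$y)$nrf)
  expect_equal(M["y", "z"], rf_pair(trees$y, trees$z)$nrf)
  same <- list(a = trees$x, b = trees$x, c = trees$x)
  expect_true(all(unclass(treeset_distance_matrix(same)) == 0))
})

test_that("bootstrap: clean strong signal gives 100% supports", {
  tr0 <- ape::read.tree(
    text = "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3,(E:0.3,F:0.3):0.3);")
  aln <- evolve_alignment(tr0, 2000, 1, seed = 3, gene_id = "sig")
  tr <- bootstrap_support(aln, "p", replicates = 30, seed = 1)
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup == 100))
})

test_that("bootstrap: replicates = 0 returns a plain point tree", {
  aln <- signal_alignment(5, L = 500, seed = 4)
  tr <- bootstrap_support(aln, "p", replicates = 0, seed = 1)
  expect_null(tr$node.label)
})

test_that("bootstrap: random noise alignments earn low mean support", {
  sups <- vapply(1:8, function(seed) {
    seqs <- stats::setNames(
      vapply(1:8, function(i) random_seq(150, seed * 100 + i), character(1)),
      paste0("s", 1:8))
    mean_support(bootstrap_support(gene_alignment(seqs), "p",
                                   replicates = 20, seed = seed))
  }, numeric(1))
  expect_lt(mean(sups), 80)
})

test_that("Thompson-tau removes the planted outlier and matches the oracle", {
  v <- c(a = 0.10, b = 0.11, c = 0.12, d = 0.11, e = 0.10, f = 0.45)
  res <- tau_outliers(v)
  expect_identical(res$removed, "f")
  expect_setequal(res$kept, c("a", "b", "c", "d", "e"))
  # oracle agreement step by step
  x <- v
  repeat {
    i <- oracle_tau_once(x)
    if (is.na(i)) break
    x <- x[-i]
  }
  expect_setequal(res$kept, names(x))
})

test_that("Thompson-tau: equal values stop immediately; two outliers need two passes", {
  expect_length(tau_outliers(stats::setNames(rep(0.2, 6),
                                             letters[1:6]))$removed, 0)
  v <- c(a = 0.50, b = 0.51, c = 0.49, d = 0.50, e = 0.51, f = 0.50,
         g = 0.05, h = 0.95)
  res <- tau_outliers(v)
  # oracle pass
  x <- v
  repeat { i <- oracle_tau_once(x); if (is.na(i)) break; x <- x[-i] }
  expect_setequal(res$removed, setdiff(names(v), names(x)))
  expect_setequal(res$removed, c("g", "h"))
  expect_equal(nrow(res$trace), 2L)
  expect_error(tau_outliers(c(a = 1, b = 2)), "at least 3")
})

test_that("tau removes few points from i.i.d. tight-uniform samples and matches the oracle", {
  # the iterative test touches a fair share of clean samples (it is a
  # liberal test), but the fraction of points it discards stays small
  removed_frac <- vapply(1:100, function(seed) {
    x <- withr::with_seed(seed, stats::runif(20, 0.45, 0.55))
    names(x) <- paste0("v", 1:20)
    res <- tau_outliers(x)
    # every removal decision must match the independent tabulated-t oracle
    y <- x
    repeat { i <- oracle_tau_once(y); if (is.na(i)) break; y <- y[-i] }
    expect_setequal(res$kept, names(y))
    length(res$removed) / length(x)
  }, numeric(1))
  expect_lt(mean(removed_frac), 0.10)
})

test_that("gene-tree outlier filter removes the conflicting topology only", {
  spec <- simulation_spec(n_taxa = 8, gene_count = 6, gene_length = 1500,
                          rate_multipliers = 0.3, seed = 11)
  sim <- simulate_gene_set(spec)
  gts <- lapply(sim$genes, function(g) {
    nj_tree(alignment_distance_matrix(g, "p"))
  })
  # plant an outlier evolved on an unrelated topology
  alt_tree <- simulate_tree(8, seed = 99)
  alt_aln <- evolve_alignment(alt_tree, 1500, 0.3, seed = 100,
                              gene_id = "alt")
  gts$outlier <- nj_tree(alignment_distance_matrix(alt_aln, "p"))
  res <- gene_tree_outlier_filter(gts)
  expect_identical(res$removed, "outlier")
  expect_setequal(res$retained, names(sim$genes))
})

test_that("gene-tree filter keeps everything on homogeneous simulations", {
  spec <- simulation_spec(n_taxa = 7, gene_count = 5, gene_length = 1500,
                          rate_multipliers = 0.3, seed = 21)
  sim <- simulate_gene_set(spec)
  gts <- lapply(sim$genes, function(g) {
    nj_tree(alignment_distance_matrix(g, "p"))
  })
  res <- gene_tree_outlier_filter(gts, species_tree = sim$tree)
  expect_length(res$removed, 0)
  expect_error(gene_tree_outlier_filter(gts[1:2]), "at least 3")
})

test_that("topology clustering separates two well-separated groups", {
  g1 <- random_binary_tree(8, 1)
  g2 <- random_binary_tree(8, 200)
  stopifnot(rf_pair(g1, g2)$nrf > 0.5)
  trees <- c(replicate(5, g1, simplify = FALSE),
             replicate(5, g2, simplify = FALSE))
  names(trees) <- paste0("t", 1:10)
  rep <- topology_clusters(treeset_distance_matrix(trees), min_pts = 3)
  expect_equal(rep$n_clusters, 2L)
  expect_equal(rep$dominant_cluster_fraction, 0.5)
  lab <- rep$cluster_labels
  expect_length(unique(lab[1:5]), 1L)
  expect_length(unique(lab[6:10]), 1L)
  expect_false(lab[1] == lab[6])
})

test_that("identical topologies form a single cluster", {
  t0 <- random_binary_tree(7, 5)
  trees <- stats::setNames(replicate(6, t0, simplify = FALSE), paste0("t", 1:6))
  rep <- topology_clusters(treeset_distance_matrix(trees), min_pts = 4)
  expect_equal(rep$n_clusters, 1L)
  expect_equal(rep$dominant_cluster_fraction, 1)
})

test_that("MDS embedding preserves rank order on a 1D line fixture", {
  pos <- c(a = 0, b = 1, c = 3, d = 6, e = 10)
  D <- distance_matrix(abs(outer(pos, pos, "-")))
  rep <- topology_clusters(D, min_pts = 2)
  x <- rep$coordinates$x
  # embedded first-axis order reproduces the line order up to reflection
  expect_true(identical(order(x), seq_along(pos)) ||
                identical(order(x), rev(seq_along(pos))))
})

test_that("concordance counts: identical gene trees are fully concordant", {
  sp <- random_binary_tree(7, 9)
  gts <- stats::setNames(replicate(4, sp, simplify = FALSE), paste0("g", 1:4))
  cc <- concordance_counts(sp, gts)
  expect_true(all(cc$concordant == 4L))
  expect_true(all(cc$conflicting == 0L))
  expect_true(all(cc$concordant + cc$conflicting + cc$uninformative == 4L))
})

test_that("one NNI conflicts at exactly the affected edge", {
  sp <- ape::read.tree(text = "(((A,B),(C,D)),E,F);")
  nni <- ape::read.tree(text = "(((A,C),(B,D)),E,F);")
  cc <- concordance_counts(sp, list(g1 = nni))
  # canonical keys store the side away from leaf A
  ab_edge <- cc$bipartition == "C|D|E|F"
  cd_edge <- cc$bipartition == "C|D"
  abcd_edge <- cc$bipartition == "E|F"
  expect_equal(cc$conflicting[ab_edge], 1L)
  expect_equal(cc$conflicting[cd_edge], 1L)
  expect_equal(cc$concordant[abcd_edge], 1L)
})

test_that("a gene tree missing one side's taxa is uninformative there", {
  sp <- ape::read.tree(text = "(((A,B),(C,D)),E,F);")
  gt <- ape::read.tree(text = "((A,B),E,F);")  # C,D absent
  cc <- concordance_counts(sp, list(g1 = gt))
  cd_edge <- cc$bipartition == "C|D"
  expect_equal(cc$uninformative[cd_edge], 1L)
  totals <- cc$concordant + cc$conflicting + cc$uninformative
  expect_true(all(totals == 1L))
})
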