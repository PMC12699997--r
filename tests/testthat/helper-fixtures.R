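# Fixture builders and independent oracles used across the suite.

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# Mutate exactly `k` distinct positions (deterministic given seed); keeps
# the realized p-distance exact, unlike probabilistic mutation.
mutate_k <- function(s, k, seed) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- withr::with_seed(seed, sample(seq_along(chars), k))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- withr::with_seed(seed + p, sample(setdiff(bases, chars[p]), 1))
  }
  paste(chars, collapse = "")
}

# Planted-cluster alignment: `sizes[i]` sequences scattered `intra` exact
# substitutions around center i; centers separated by `inter` substitutions
# from a shared ancestor (so inter-center distance is ~2*inter/L).
planted_clusters <- function(sizes, L = 400L, intra = 4L, inter = 120L,
                             seed = 1L) {
  anc <- random_seq(L, seed)
  seqs <- character(0)
  for (ci in seq_along(sizes)) {
    center <- mutate_k(anc, inter, seed * 1000L + ci)
    for (m in seq_len(sizes[ci])) {
      id <- sprintf("c%d_s%02d", ci, m)
      seqs[[id]] <- if (m == 1L) center else
        mutate_k(center, intra, seed * 100000L + ci * 100L + m)
    }
  }
  gene_alignment(seqs, gene_id = sprintf("planted_%d", seed))
}

# Exhaustive k-medoids: optimal medoid subset by total assigned distance.
brute_force_medoids <- function(D, k) {
  labels <- rownames(D)
  combos <- utils::combn(labels, k, simplify = FALSE)
  objs <- vapply(combos, function(set) {
    sum(apply(unclass(D)[, set, drop = FALSE], 1L, min))
  }, numeric(1))
  best <- which(objs <= min(objs) + 1e-12)
  list(sets = lapply(combos[best], sort), objective = min(objs))
}

# Independent modified-Thompson-tau pass using tabulated two-sided t
# critical values at alpha = 0.05 (df = n - 2).
T_TABLE_975 <- c(`1` = 12.7062047, `2` = 4.3026527, `3` = 3.1824463,
                 `4` = 2.7764451, `5` = 2.5705818, `6` = 2.4469119,
                 `7` = 2.3646243, `8` = 2.3060041, `9` = 2.2621572,
                 `10` = 2.2281389, `11` = 2.2009852, `12` = 2.1788128,
                 `13` = 2.1603687, `14` = 2.1447867, `15` = 2.1314495,
                 `16` = 2.1199053, `17` = 2.1098156, `18` = 2.1009220,
                 `19` = 2.0930241, `20` = 2.0859634)
oracle_tau_once <- function(x) {
  n <- length(x)
  t <- T_TABLE_975[[as.character(n - 2L)]]
  tau <- (t * (n - 1)) / (sqrt(n) * sqrt(n - 2 + t^2))
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  if (dev[i] > tau * stats::sd(x)) i else NA_integer_
}

# blastn-distance oracle: explicit per-column summation.
oracle_blastn <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  s <- 0; L <- 0L
  for (i in seq_along(ca)) {
    if (!(ca[i] %in% acgt) || !(cb[i] %in% acgt)) next
    L <- L + 1L
    s <- s + if (ca[i] == cb[i]) 5 else -4
  }
  min(max(1 - s / (5 * L), 0), 1)
}

# Random binary tree with positive branch lengths (test-only randomness).
random_binary_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
    tr$tip.label <- paste0("L", seq_len(n))
    tr
  })
}

# Alignment with strong clean signal: evolve on a tree whose branches are
# long enough that every split is well supported.
signal_alignment <- function(n_taxa, L = 1200L, seed = 1L) {
  tree <- simulate_tree(n_taxa, birth_rate = 1, seed = seed)
  evolve_alignment(tree, L, rate_multiplier = 0.3, seed = seed,
                   gene_id = "sig")
}
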