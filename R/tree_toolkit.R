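#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the
#' bipartition is stored canonically as the sorted side NOT containing the
#' lexicographically smallest leaf, keyed as a `|`-joined string. Trivial
#' splits (a single leaf on one side) are excluded.
#'
#' @param tree An [ape::phylo] object (unrooted or rooted; a root is
#'   collapsed).
#' @return Character vector of canonical bipartition keys; the names give
#'   the internal node (child end of the edge) each key belongs to.
#' @export
tree_bipartitions <- function(tree) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (i in seq_along(pp)) {
    node <- n + i
    side <- labs[pp[[i]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L) next
    k <- paste(sort(side), collapse = "|")
    names(k) <- node
    keys <- c(keys, k)
  }
  keys[!duplicated(keys)]
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are pruned to their shared leaves (suppressing degree-2
#' nodes), the symmetric difference of their nontrivial bipartition sets is
#' counted, and normalized by the maximum `rf_max` = (nontrivial
#' bipartitions of A) + (nontrivial bipartitions of B). For two binary
#' n-leaf trees this equals 2(n−3).
#'
#' @param t1,t2 [ape::phylo] trees sharing at least 4 leaves.
#' @return One-row tibble: `rf`, `rf_max`, `nrf`, `shared_leaves`.
#' @export
rf_pair <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("fewer than 4 shared leaves")
  p1 <- validate_tree(ape::keep.tip(t1, shared))
  p2 <- validate_tree(ape::keep.tip(t2, shared))
  b1 <- tree_bipartitions(p1)
  b2 <- tree_bipartitions(p2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  rf_max <- length(b1) + length(b2)
  tibble::tibble(rf = rf, rf_max = rf_max,
                 nrf = if (rf_max > 0L) rf / rf_max else 0,
                 shared_leaves = length(shared))
}

#' Pairwise nRF distance matrix over a set of trees
#'
#' @param trees Named list of [ape::phylo] trees; every pair must share at
#'   least 4 leaves.
#' @return A [distance_matrix()] of normalized RF distances.
#' @export
treeset_distance_matrix <- function(trees) {
  stopifnot(length(trees) >= 2L)
  ids <- names(trees)
  if (is.null(ids)) ids <- paste0("tree", seq_along(trees))
  m <- matrix(0, length(trees), length(trees), dimnames = list(ids, ids))
  for (i in seq_len(length(trees) - 1L)) {
    for (j in (i + 1L):length(trees)) {
      st <- tryCatch(rf_pair(trees[[i]], trees[[j]]),
                     error = function(e) stop("pair (", ids[i], ", ", ids[j],
                                              "): ", conditionMessage(e)))
      m[i, j] <- st$nrf; m[j, i] <- st$nrf
    }
  }
  distance_matrix(m)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbor joining with deterministic tie-breaking:
#' when several pairs minimize Q, the pair whose (sorted) representative
#' labels are lexicographically smallest is joined. Negative branch lengths
#' are clamped to 0. On additive distances NJ recovers the generating tree
#' exactly.
#'
#' @param D A [distance_matrix()] with at least 3 labels.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  Dm <- unclass(D)
  labs <- rownames(Dm)
  n <- length(labs)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  nwk <- labs              # growing newick fragment per active node
  key <- labs              # lexicographic representative per active node
  d <- Dm
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\x1f")
    })
    best <- cand[order(pair_keys)[1], ]
    i <- best[[1]]; j <- best[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_key <- min(key[i], key[j])
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    nwk <- c(nwk[others], new_nwk)
    key <- c(key[others], new_key)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  validate_tree(ape::read.tree(text = txt))
}

#' Neighbor-joining tree with bootstrap supports from an alignment
#'
#' Builds the point tree from the full alignment's distance matrix, then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilds the NJ tree on each replicate, and attaches to every internal
#' edge the percentage of replicates containing its bipartition. A
#' replicate whose resampled columns leave some pair without comparable
#' sites is redrawn (up to 10 times).
#'
#' @param aln A [gene_alignment()] with at least 4 rows.
#' @param metric Distance metric, `"p"` or `"blastn"`.
#' @param replicates Bootstrap replicates (0 = point tree only, no
#'   supports).
#' @param seed Integer seed.
#' @return An [ape::phylo] with `node.label` supports in \[0, 100\] (absent
#'   when `replicates = 0`).
#' @export
bootstrap_support <- function(aln, metric = c("p", "blastn"),
                              replicates = 100L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(aln, "gene_alignment"), length(aln$seqs) >= 4L)
  point <- nj_tree(alignment_distance_matrix(aln, metric))
  if (replicates == 0L) return(point)
  chars <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(chars) <- names(aln$seqs)
  L <- ncol(chars)
  rep_bips <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    tr <- NULL
    for (attempt in 1:10) {
      cols <- withr::with_seed(derive_seed(seed, "boot", b, attempt),
                               sample.int(L, L, replace = TRUE))
      seqs <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      tr <- tryCatch(
        nj_tree(alignment_distance_matrix(
          gene_alignment(seqs, aln$gene_id), metric)),
        error = function(e) NULL)
      if (!is.null(tr)) break
    }
    if (is.null(tr)) stop("bootstrap replicate failed after 10 redraws")
    rep_bips[[b]] <- tree_bipartitions(tr)
  }
  point_bips <- tree_bipartitions(point)
  support <- vapply(point_bips, function(k) {
    100 * mean(vapply(rep_bips, function(bs) k %in% bs, logical(1)))
  }, numeric(1))
  node.label <- rep("", point$Nnode)
  nodes <- as.integer(names(point_bips))
  node.label[nodes - ape::Ntip(point)] <- sprintf("%g", support)
  point$node.label <- node.label
  point
}

#' Mean internal-edge bootstrap support of a tree
#' @param tree A tree with numeric `node.label` supports.
#' @return Mean support, or NA when no supports are present.
#' @export
mean_support <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  v <- suppressWarnings(as.numeric(tree$node.label))
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Thompson-tau configuration
#' @param alpha Two-sided significance level (default 0.05).
#' @param min_n Minimum sample size (default 3).
#' @export
tau_config <- function(alpha = 0.05, min_n = 3L) {
  stopifnot(alpha > 0, alpha < 1, min_n >= 3L)
  structure(list(alpha = alpha, min_n = as.integer(min_n)),
            class = "tau_config")
}

#' Iterative modified Thompson-tau outlier removal
#'
#' At each step the rejection threshold is tau·s with
#' tau = t·(n−1) / (sqrt(n)·sqrt(n−2+t²)), t the two-sided Student critical
#' value at `alpha` with n−2 degrees of freedom, and s the sample standard
#' deviation. The single most deviant point (ties: the larger value) is
#' removed if it exceeds the threshold, and the statistics are recomputed;
#' the procedure stops when nothing exceeds the threshold, when s = 0, or
#' when fewer than 3 points remain.
#'
#' @param values Named numeric vector.
#' @param cfg A [tau_config()].
#' @return List with `kept` and `removed` (names) and a `trace` tibble of
#'   removals (id, value, delta, threshold).
#' @export
tau_outliers <- function(values, cfg = tau_config()) {
  stopifnot(!is.null(names(values)))
  if (length(values) < cfg$min_n) {
    stop("need at least ", cfg$min_n, " values")
  }
  x <- values
  trace <- list()
  repeat {
    n <- length(x)
    if (n < 3L) break
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) break
    tcrit <- stats::qt(1 - cfg$alpha / 2, df = n - 2L)
    tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2L + tcrit^2))
    dev <- abs(x - m)
    worst <- which(dev >= max(dev) - 1e-15)
    if (length(worst) > 1L) worst <- worst[which.max(x[worst])]
    if (dev[worst] > tau * s) {
      trace[[length(trace) + 1L]] <- tibble::tibble(
        id = names(x)[worst], value = unname(x[worst]),
        delta = unname(dev[worst]), threshold = tau * s)
      x <- x[-worst]
    } else break
  }
  list(kept = names(x), removed = setdiff(names(values), names(x)),
       trace = if (length(trace) > 0L) dplyr::bind_rows(trace)
               else tibble::tibble(id = character(0), value = numeric(0),
                                   delta = numeric(0),
                                   threshold = numeric(0)))
}

#' Gene-tree outlier filtering by average topological distance
#'
#' Scores each gene tree by its mean nRF distance to every other gene tree
#' (plus the species tree when supplied, as one extra comparator) and
#' removes outliers with [tau_outliers()].
#'
#' @param gene_trees Named list of [ape::phylo] trees.
#' @param species_tree Optional reference tree included as one comparator.
#' @param cfg A [tau_config()].
#' @return List with `retained`, `removed`, `scores` tibble and the tau
#'   `trace`.
#' @export
gene_tree_outlier_filter <- function(gene_trees, species_tree = NULL,
                                     cfg = tau_config()) {
  if (length(gene_trees) < cfg$min_n) {
    stop("need at least ", cfg$min_n, " gene trees")
  }
  ids <- names(gene_trees)
  nrf_m <- unclass(treeset_distance_matrix(gene_trees))
  scores <- vapply(seq_along(ids), function(i) {
    d <- nrf_m[i, -i]
    if (!is.null(species_tree)) {
      d <- c(d, rf_pair(gene_trees[[i]], species_tree)$nrf)
    }
    mean(d)
  }, numeric(1))
  names(scores) <- ids
  res <- tau_outliers(scores, cfg)
  list(retained = res$kept, removed = res$removed,
       scores = tibble::tibble(gene_id = ids, score = unname(scores)),
       trace = res$trace)
}

# Plain DBSCAN on a coordinate matrix (euclidean, eps inclusive).
# Labels: positive integers for clusters, -1 for noise.
dbscan_labels <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- rep(0L, n)   # 0 = unvisited
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (length(neighbors[[i]]) < min_pts) { labels[i] <- -1L; next }
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(neighbors[[i]], i)
    while (length(queue) > 0L) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cluster
      if (labels[j] != 0L) next
      labels[j] <- cluster
      if (length(neighbors[[j]]) >= min_pts) {
        queue <- c(queue, setdiff(neighbors[[j]], which(labels != 0L)))
      }
    }
  }
  labels
}

#' Topology-cluster detection by 2D MDS plus density clustering
#'
#' Embeds a tree-to-tree nRF distance matrix into two dimensions by
#' classical (Torgerson) metric MDS (negative eigenvalues truncated; nRF is
#' not guaranteed Euclidean), then runs density-based clustering on the
#' embedding. `eps` defaults to half the median pairwise embedded distance.
#'
#' @param D A [distance_matrix()] over trees.
#' @param eps Neighborhood radius; NULL = 0.5 × median embedded distance.
#' @param min_pts Core-point threshold (default 4).
#' @return List with `coordinates` tibble (id, x, y, cluster), cluster
#'   labels (−1 = noise), `n_clusters` and `dominant_cluster_fraction`.
#' @export
topology_clusters <- function(D, eps = NULL, min_pts = 4L) {
  Dm <- unclass(D)
  n <- nrow(Dm)
  if (n < min_pts) stop("need at least min_pts = ", min_pts, " trees")
  if (max(Dm) == 0) {
    coords <- matrix(0, n, 2)
  } else {
    mds <- stats::cmdscale(Dm, k = 2, eig = TRUE)
    coords <- mds$points
    if (ncol(coords) < 2L) {
      coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
    }
  }
  if (is.null(eps)) {
    pd <- stats::dist(coords)
    eps <- 0.5 * stats::median(pd)
  }
  labels <- dbscan_labels(coords, eps, min_pts)
  sizes <- table(labels[labels > 0L])
  tib <- tibble::tibble(id = rownames(Dm), x = coords[, 1], y = coords[, 2],
                        cluster = labels)
  list(coordinates = tib, cluster_labels = stats::setNames(labels,
                                                           rownames(Dm)),
       n_clusters = length(sizes),
       dominant_cluster_fraction = if (length(sizes) > 0L)
         max(sizes) / n else 0)
}

# Bipartitions as actual leaf-set pairs on a tree's leaf set.
bip_sides <- function(tree) {
  keys <- tree_bipartitions(tree)
  labs <- tree$tip.label
  lapply(keys, function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(a = side, b = setdiff(labs, side))
  })
}

#' Gene-tree concordance counts per species-tree edge
#'
#' For every nontrivial species-tree bipartition, each gene tree is counted
#' as concordant (after pruning to shared leaves it contains the restricted
#' bipartition), conflicting (it contains an incompatible bipartition), or
#' uninformative (either restricted side has fewer than 2 leaves, or the
#' gene tree is unresolved there). The three counts sum to the number of
#' gene trees at every edge.
#'
#' @param species_tree Reference tree with at least one internal edge.
#' @param gene_trees Named list of gene trees.
#' @return Tibble: edge id, bipartition key, concordant, conflicting,
#'   uninformative.
#' @export
concordance_counts <- function(species_tree, gene_trees) {
  species_tree <- validate_tree(species_tree)
  keys <- tree_bipartitions(species_tree)
  if (length(keys) == 0L) stop("species tree has no internal edge")
  sp_labs <- species_tree$tip.label
  gene_cache <- lapply(gene_trees, function(g) {
    list(tree = g, leaves = g$tip.label)
  })
  rows <- purrr::imap(keys, function(k, nm) {
    side_a <- strsplit(k, "|", fixed = TRUE)[[1]]
    side_b <- setdiff(sp_labs, side_a)
    conc <- 0L; conf <- 0L; unin <- 0L
    for (g in gene_cache) {
      shared <- intersect(g$leaves, sp_labs)
      ra <- intersect(side_a, shared); rb <- intersect(side_b, shared)
      if (length(ra) < 2L || length(rb) < 2L) { unin <- unin + 1L; next }
      pruned <- validate_tree(ape::keep.tip(g$tree, shared))
      gbips <- bip_sides(pruned)
      status <- "uninformative"
      for (bp in gbips) {
        if (setequal(bp$a, ra) || setequal(bp$a, rb)) {
          status <- "concordant"; break
        }
        if (length(intersect(bp$a, ra)) > 0L &&
            length(intersect(bp$a, rb)) > 0L &&
            length(intersect(bp$b, ra)) > 0L &&
            length(intersect(bp$b, rb)) > 0L) {
          status <- "conflicting"
        }
      }
      if (status == "concordant") conc <- conc + 1L
      else if (status == "conflicting") conf <- conf + 1L
      else unin <- unin + 1L
    }
    tibble::tibble(edge = nm, bipartition = k, concordant = conc,
                   conflicting = conf, uninformative = unin)
  })
  dplyr::bind_rows(rows)
}
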