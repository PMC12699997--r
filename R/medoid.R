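#' Configuration for k-medoids representative selection
#'
#' Parameters of the per-gene representative search: sequences are clustered
#' by p-distance and a gene "converges" at the smallest number of medoids k
#' for which at least a fraction `f_conv` of its sequences lie within
#' `d_max` of their medoid.
#'
#' @param d_max Maximum allowed p-distance from a sequence to its medoid
#'   (tested values 0.20, 0.25, 0.30; default 0.25).
#' @param k_max Largest medoid count tried (default 70).
#' @param f_conv Convergence fraction: minimum fraction of sequences within
#'   `d_max` of their medoid (default 0.95).
#' @param restarts Random restarts per k (default 100); each restart draws a
#'   fresh random initial medoid set.
#' @param seed Base seed; restart seeds are derived deterministically from
#'   (seed, gene id, k, restart index).
#' @return A `medoid_config` list.
#' @export
medoid_config <- function(d_max = 0.25, k_max = 70L, f_conv = 0.95,
                          restarts = 100L, seed = 1L) {
  stopifnot(d_max > 0, d_max < 1, k_max >= 1L, f_conv > 0, f_conv <= 1,
            restarts >= 1L)
  structure(list(d_max = d_max, k_max = as.integer(k_max), f_conv = f_conv,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "medoid_config")
}

# Deterministic 31-bit seed derived from a base seed and string parts.
# Plain polynomial rolling hash; platform-independent integer arithmetic
# via doubles below 2^53.
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "\x1f")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

#' One PAM-style k-medoids run
#'
#' Draws k distinct random initial medoids, then alternates (a) assigning
#' each point to its nearest medoid and (b) replacing each cluster's medoid
#' by the member minimizing the within-cluster distance sum, until the
#' medoid set is stable. All ties break to the lexicographically smallest
#' id, so the result is deterministic given (D, k, seed).
#'
#' @param D A [distance_matrix()].
#' @param k Number of medoids, 1 <= k <= nrow(D).
#' @param seed Integer seed for the initial draw.
#' @param d_max Optional distance threshold; when given, `fraction_within`
#'   and `converged` (against `f_conv`) are filled in.
#' @param f_conv Convergence fraction used with `d_max`.
#' @return A `medoid_solution` list: `medoid_ids`, `assignment` (named
#'   character), `dist_to_medoid`, `objective`, `fraction_within`,
#'   `converged`, `k`, `iterations`.
#' @export
kmedoids_once <- function(D, k, seed, d_max = NA_real_, f_conv = 0.95) {
  labels <- rownames(D)
  n <- length(labels)
  if (k <= 0L) stop("k must be positive")
  if (k > n) stop("k exceeds the number of points")
  medoids <- sort(withr::with_seed(seed, sample(labels, k)))
  Dm <- unclass(D)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # nearest medoid; medoids sorted, so which.min takes lexicographic ties
    sub <- Dm[, medoids, drop = FALSE]
    idx <- apply(sub, 1L, which.min)
    assign <- medoids[idx]
    names(assign) <- labels
    new_medoids <- vapply(medoids, function(m) {
      members <- sort(labels[assign == m])
      if (length(members) == 0L) return(m)  # tie at d=0 stole all members
      sums <- colSums(Dm[members, members, drop = FALSE])
      members[which.min(sums)]
    }, character(1))
    new_medoids <- sort(unname(new_medoids))
    if (identical(new_medoids, medoids) || iter >= 200L) break
    medoids <- new_medoids
  }
  dist_to <- Dm[cbind(labels, assign)]
  names(dist_to) <- labels
  frac <- if (is.na(d_max)) NA_real_ else mean(dist_to <= d_max)
  structure(list(gene_id = NA_character_, k = as.integer(k),
                 medoid_ids = medoids, assignment = assign,
                 dist_to_medoid = dist_to, objective = sum(dist_to),
                 fraction_within = frac,
                 converged = if (is.na(d_max)) NA else frac >= f_conv,
                 iterations = iter),
            class = "medoid_solution")
}

#' @export
print.medoid_solution <- function(x, ...) {
  cat(sprintf("<medoid_solution> k=%d, objective=%.4f, fraction_within=%s, converged=%s\n",
              x$k, x$objective,
              ifelse(is.na(x$fraction_within), "NA",
                     sprintf("%.3f", x$fraction_within)),
              x$converged))
  invisible(x)
}

#' Select representative sequences for one gene
#'
#' Builds the p-distance matrix of the alignment and searches k = 1 ..
#' `k_max` in ascending order; for each k it runs `restarts` seeded
#' k-medoids restarts and keeps the best (highest fraction within `d_max`,
#' ties to lower objective then lower restart index). The solution for the
#' smallest convergent k is returned; if no k converges, the best `k_max`
#' solution is returned with `converged = FALSE`.
#'
#' @param aln A [gene_alignment()].
#' @param cfg A [medoid_config()].
#' @return A `medoid_solution` (with `gene_id` filled in).
#' @export
select_representatives <- function(aln, cfg = medoid_config()) {
  stopifnot(inherits(aln, "gene_alignment"))
  if (length(aln$seqs) < 2L) stop("need at least 2 sequences")
  D <- alignment_distance_matrix(aln, "p")
  n <- nrow(D)
  k_top <- min(cfg$k_max, n)
  best_last <- NULL
  for (k in seq_len(k_top)) {
    best <- NULL
    for (r in seq_len(cfg$restarts)) {
      s <- derive_seed(cfg$seed, aln$gene_id, k, r)
      sol <- kmedoids_once(D, k, s, d_max = cfg$d_max, f_conv = cfg$f_conv)
      if (is.null(best) ||
          sol$fraction_within > best$fraction_within ||
          (sol$fraction_within == best$fraction_within &&
           sol$objective < best$objective)) {
        best <- sol
      }
    }
    best$gene_id <- aln$gene_id
    if (best$converged) return(best)
    best_last <- best
  }
  best_last
}

#' Select a gene set by representative-sequence convergence
#'
#' Drops genes whose aligned exon length is below `min_exon_len`, runs
#' [select_representatives()] on the rest, and reports which genes
#' converged (retained), failed to converge, or were dropped short.
#'
#' @param genes Named list of [gene_alignment()] objects.
#' @param cfg A [medoid_config()].
#' @param min_exon_len Minimum aligned length in bp (default 600; shorter
#'   genes are discarded before clustering).
#' @return List with `solutions` (named list of medoid solutions for
#'   clustered genes), `report` (tibble: gene_id, n, length, k,
#'   fraction_within, converged, status) and `retained` (gene ids).
#' @export
select_gene_set <- function(genes, cfg = medoid_config(),
                            min_exon_len = 600L) {
  stopifnot(length(genes) >= 1L)
  rows <- list(); sols <- list()
  for (g in genes) {
    if (g$length < min_exon_len) {
      rows[[g$gene_id]] <- tibble::tibble(
        gene_id = g$gene_id, n = length(g$seqs), length = g$length,
        k = NA_integer_, fraction_within = NA_real_, converged = NA,
        status = "dropped_short")
      next
    }
    sol <- select_representatives(g, cfg)
    sols[[g$gene_id]] <- sol
    rows[[g$gene_id]] <- tibble::tibble(
      gene_id = g$gene_id, n = length(g$seqs), length = g$length,
      k = sol$k, fraction_within = sol$fraction_within,
      converged = sol$converged,
      status = if (sol$converged) "retained" else "not_converged")
  }
  report <- dplyr::bind_rows(rows)
  retained <- report$gene_id[!is.na(report$converged) & report$converged]
  if (length(retained) == 0L) warning("no gene converged; empty retained set")
  list(solutions = sols, report = report, retained = retained)
}

#' Write medoid (representative) sequences and selection report
#'
#' Emits one FASTA of gap-stripped medoid sequences per retained gene plus a
#' TSV report.
#'
#' @param selection Result of [select_gene_set()].
#' @param genes The gene set the selection was computed from.
#' @param dir Output directory.
#' @export
write_representatives <- function(selection, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in selection$retained) {
    sol <- selection$solutions[[gid]]
    seqs <- genes[[gid]]$seqs[sol$medoid_ids]
    seqs <- gsub("-", "", seqs, fixed = TRUE)
    write_fasta(seqs, file.path(dir, paste0(gid, "_medoids.fasta")))
  }
  utils::write.table(selection$report,
                     file.path(dir, "medoid_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a medoid solution into one row per sequence
#' @param x A `medoid_solution`.
#' @param ... Unused.
#' @method tidy medoid_solution
#' @export
tidy.medoid_solution <- function(x, ...) {
  tibble::tibble(sample_id = names(x$assignment),
                 medoid_id = unname(x$assignment),
                 dist_to_medoid = unname(x$dist_to_medoid),
                 is_medoid = names(x$assignment) %in% x$medoid_ids)
}

#' One-row summary of a medoid solution
#' @param x A `medoid_solution`.
#' @param ... Unused.
#' @method glance medoid_solution
#' @export
glance.medoid_solution <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, k = x$k, objective = x$objective,
                 fraction_within = x$fraction_within,
                 converged = x$converged, iterations = x$iterations)
}
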