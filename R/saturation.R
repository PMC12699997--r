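#' Concatenate gene alignments into a supermatrix
#'
#' Rows cover the union of sample ids across the chosen genes (sorted);
#' sample-by-gene blocks missing from a gene are filled with the padding
#' symbol. A partition table records each gene's column interval, 0-based
#' half-open.
#'
#' @param genes Named list of [gene_alignment()] objects.
#' @param gene_ids Ordered subset of genes to concatenate (default: all, in
#'   list order).
#' @param pad Padding for missing sample-by-gene blocks: `"gap"` (`-`) or
#'   `"N"`.
#' @return List with `alignment` (a [gene_alignment()]) and `partitions`
#'   (tibble: gene_id, start, end).
#' @export
concatenate_genes <- function(genes, gene_ids = names(genes),
                              pad = c("gap", "N")) {
  pad <- match.arg(pad)
  pad_char <- if (pad == "gap") "-" else "N"
  if (length(gene_ids) == 0L) stop("empty gene list")
  missing <- setdiff(gene_ids, names(genes))
  if (length(missing) > 0L) {
    stop("unknown genes: ", paste(missing, collapse = ", "))
  }
  samples <- sort(unique(unlist(lapply(genes[gene_ids],
                                       function(g) names(g$seqs)))))
  if (length(samples) == 0L) stop("no samples in the selected genes")
  pieces <- matrix("", nrow = length(samples), ncol = length(gene_ids),
                   dimnames = list(samples, gene_ids))
  starts <- integer(length(gene_ids)); pos <- 0L
  for (i in seq_along(gene_ids)) {
    g <- genes[[gene_ids[i]]]
    starts[i] <- pos
    block <- stats::setNames(rep(strrep(pad_char, g$length),
                                 length(samples)), samples)
    present <- intersect(samples, names(g$seqs))
    block[present] <- g$seqs[present]
    pieces[, i] <- block
    pos <- pos + g$length
  }
  rows <- apply(pieces, 1L, paste, collapse = "")
  lens <- unname(vapply(genes[gene_ids], function(g) g$length, integer(1)))
  list(alignment = gene_alignment(rows, gene_id = "concat"),
       partitions = tibble::tibble(gene_id = gene_ids, start = starts,
                                   end = starts + lens))
}

#' Write a partition table in RAxML-style format
#'
#' Exported as 1-based inclusive intervals (flagged in a header comment),
#' unlike the 0-based half-open convention used everywhere else.
#'
#' @param partitions Tibble from [concatenate_genes()].
#' @param path Output path.
#' @export
write_partition_table <- function(partitions, path) {
  lines <- c("# 1-based inclusive intervals",
             sprintf("DNA, %s = %d-%d", partitions$gene_id,
                     partitions$start + 1L, partitions$end))
  writeLines(lines, path)
  invisible(path)
}

#' Relative substitution-rate surrogate per gene
#'
#' Rate surrogate = mean pairwise p-distance of the gene alignment. Only the
#' ordering of genes matters for rate-ordered saturation analysis, and the
#' surrogate preserves rate order on simulated data. Genes where every pair
#' is undefined are excluded with a warning.
#'
#' @param genes Named list of [gene_alignment()] objects, each with >= 2
#'   rows.
#' @return Tibble (gene_id, rate), sorted ascending by rate then gene_id.
#' @export
gene_rates <- function(genes) {
  rows <- purrr::imap(genes, function(g, id) {
    D <- tryCatch(alignment_distance_matrix(g, "p"), error = function(e) NULL)
    if (is.null(D)) {
      warning("gene ", id, " has undefined distances; excluded")
      return(NULL)
    }
    m <- unclass(D)
    tibble::tibble(gene_id = id, rate = mean(m[upper.tri(m)]))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$rate, .data$gene_id)
}

#' Stepwise gene-addition saturation analysis
#'
#' Adds genes in batches of `step` (in random or ascending-rate order) to a
#' growing concatenated matrix; for each size builds an NJ tree with
#' bootstrap supports and records the nRF distance to the reference
#' topology and the mean internal-edge support. The reference defaults to
#' the full-gene-set tree from the same builder, so the final point has
#' nRF 0 by construction; a user-supplied tree (e.g. a published phylogeny)
#' overrides it.
#'
#' @param genes Named list of [gene_alignment()] objects.
#' @param ordering `"random"` (seeded shuffle) or `"rate"` (ascending
#'   [gene_rates()] surrogate, ties by gene id).
#' @param step Genes added per point (default 20).
#' @param reference Optional reference [ape::phylo].
#' @param replicates Bootstrap replicates per point (default 100).
#' @param seed Integer seed.
#' @param pad Padding for missing blocks (see [concatenate_genes()]).
#' @return A `saturation_curve`: tibble (n_genes, nrf_to_reference,
#'   mean_support) with attributes `ordering`, `seed`, `gene_order`.
#' @export
saturation_analysis <- function(genes, ordering = c("random", "rate"),
                                step = 20L, reference = NULL,
                                replicates = 100L, seed = 1L,
                                pad = "gap") {
  ordering <- match.arg(ordering)
  G <- length(genes)
  stopifnot(G >= 1L, step >= 1L)
  order_ids <- if (ordering == "random") {
    withr::with_seed(derive_seed(seed, "order"), sample(names(genes)))
  } else {
    gene_rates(genes)$gene_id
  }
  sizes <- unique(c(seq.int(min(step, G), G, by = step), G))
  build <- function(ids, tag) {
    cc <- concatenate_genes(genes, ids, pad = pad)
    bootstrap_support(cc$alignment, "p", replicates = replicates,
                      seed = derive_seed(seed, "sat", tag))
  }
  full_tree <- build(order_ids, "full")
  if (is.null(reference)) reference <- full_tree
  pts <- purrr::map(sizes, function(n) {
    tr <- if (n == G) full_tree else build(order_ids[seq_len(n)], n)
    tibble::tibble(n_genes = n,
                   nrf_to_reference = rf_pair(tr, reference)$nrf,
                   mean_support = mean_support(tr))
  })
  curve <- dplyr::bind_rows(pts)
  structure(curve, class = c("saturation_curve", class(curve)),
            ordering = ordering, seed = seed, gene_order = order_ids)
}

#' Write a saturation curve as TSV
#' @param curve A `saturation_curve`.
#' @param path Output path.
#' @export
write_saturation_tsv <- function(curve, path) {
  df <- tibble::as_tibble(curve)
  df$ordering <- attr(curve, "ordering")
  df$seed <- attr(curve, "seed")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-row summary of a saturation curve
#' @param x A `saturation_curve`.
#' @param ... Unused.
#' @method glance saturation_curve
#' @export
glance.saturation_curve <- function(x, ...) {
  tibble::tibble(ordering = attr(x, "ordering"), n_points = nrow(x),
                 final_nrf = x$nrf_to_reference[nrow(x)],
                 final_support = x$mean_support[nrow(x)],
                 max_genes = x$n_genes[nrow(x)])
}
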