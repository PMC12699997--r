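#' Barcode configuration
#'
#' @param m_neighbors Total neighbors skimmed from the database
#'   (default 20).
#' @param per_species_cap Maximum neighbors of one species (default 4).
#' @param block_gap_max Columns with gap fraction above this are removed by
#'   the block filter (default 0.5).
#' @param block_min_len Surviving column runs shorter than this are removed
#'   (default 3).
#' @param seed Integer seed for the tree-building step.
#' @export
barcode_config <- function(m_neighbors = 20L, per_species_cap = 4L,
                           block_gap_max = 0.5, block_min_len = 3L,
                           seed = 1L) {
  stopifnot(per_species_cap <= m_neighbors, per_species_cap >= 1L,
            block_gap_max >= 0, block_gap_max <= 1, block_min_len >= 1L)
  structure(list(m_neighbors = as.integer(m_neighbors),
                 per_species_cap = as.integer(per_species_cap),
                 block_gap_max = block_gap_max,
                 block_min_len = as.integer(block_min_len),
                 seed = as.integer(seed)),
            class = "barcode_config")
}

#' Read a barcode database directory
#'
#' Layout: `genes/<gene_id>.fasta` (aligned, fixed column spaces) plus
#' `species_map.tsv` (sample_id, species). Every sample appearing in a gene
#' must have a species entry.
#'
#' @param dir Database directory.
#' @return List with `genes` (named list of [gene_alignment()]) and
#'   `species` (named character vector).
#' @export
read_barcode_db <- function(dir) {
  genes <- read_alignment_dir(file.path(dir, "genes"))
  species <- read_species_map(file.path(dir, "species_map.tsv"))
  barcode_db(genes, species)
}

#' Assemble a barcode database from in-memory parts
#' @param genes Named list of [gene_alignment()] objects.
#' @param species Named character vector, sample id to species.
#' @export
barcode_db <- function(genes, species) {
  samples <- unique(unlist(lapply(genes, function(g) names(g$seqs))))
  missing <- setdiff(samples, names(species))
  if (length(missing) > 0L) {
    stop("samples without species entry: ",
         paste(missing, collapse = ", "))
  }
  structure(list(genes = genes, species = species), class = "barcode_db")
}

#' @export
print.barcode_db <- function(x, ...) {
  cat(sprintf("<barcode_db> %d genes, %d samples, %d species\n",
              length(x$genes),
              length(unique(unlist(lapply(x$genes,
                                          function(g) names(g$seqs))))),
              length(unique(x$species))))
  invisible(x)
}

#' Align a query into an existing alignment's column space
#'
#' The query is globally aligned (match +1, mismatch −1, gap open 5, extend
#' 1) against the alignment's majority-consensus profile. Query insertions
#' relative to the profile are dropped so the database columns are
#' preserved; the returned row has exactly the alignment's length. When the
#' normalized alignment score is negative (no credible homology) NULL is
#' returned with a warning and the gene is skipped for this query.
#'
#' @param query Unaligned query sequence for this gene.
#' @param gene_aln The gene's [gene_alignment()].
#' @return Aligned query row (character scalar) or NULL.
#' @export
add_query_to_alignment <- function(query, gene_aln) {
  stopifnot(nchar(query) > 0L)
  cons <- consensus_sequence(gene_aln)
  q <- toupper(gsub("-", "", query, fixed = TRUE))
  pa <- Biostrings::pairwiseAlignment(
    q, cons, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  if (Biostrings::score(pa) / nchar(q) < 0) {
    warning("query shows no credible homology to gene ", gene_aln$gene_id,
            "; skipped")
    return(NULL)
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  out <- character(gene_aln$length)
  col <- 0L
  for (i in seq_along(as_)) {
    if (as_[i] == "-") next  # query insertion: dropped
    col <- col + 1L
    out[col] <- if (ap[i] == "-") "-" else ap[i]
  }
  stopifnot(col == gene_aln$length)
  paste(out, collapse = "")
}

# Majority consensus per column over A,C,G,T (ties lexicographic);
# columns without any ACGT become N.
consensus_sequence <- function(aln) {
  chars <- do.call(rbind, strsplit(toupper(aln$seqs), "", fixed = TRUE))
  cons <- apply(chars, 2L, function(col) {
    tab <- table(factor(col[col %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0L) return("N")
    names(tab)[which.max(tab)]
  })
  paste(cons, collapse = "")
}

#' Block-filter an alignment
#'
#' Removes columns whose gap fraction exceeds `block_gap_max`, then removes
#' surviving column runs shorter than `block_min_len`. The original column
#' indices of retained columns are kept in the `columns` attribute
#' (0-based).
#'
#' @param aln A [gene_alignment()].
#' @param cfg A [barcode_config()].
#' @return Filtered [gene_alignment()], or NULL (with a warning) when no
#'   column survives.
#' @export
block_filter <- function(aln, cfg = barcode_config()) {
  chars <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-")
  keep <- gap_frac <= cfg$block_gap_max
  if (any(keep)) {
    runs <- rle(keep)
    drop_short <- runs$values & runs$lengths < cfg$block_min_len
    runs$values[drop_short] <- FALSE
    keep <- inverse.rle(runs)
  }
  if (!any(keep)) {
    warning("block filter removed all columns of gene ", aln$gene_id)
    return(NULL)
  }
  rows <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- gene_alignment(stats::setNames(rows, names(aln$seqs)),
                        gene_id = aln$gene_id)
  attr(out, "columns") <- which(keep) - 1L
  out
}

#' Skim the nearest database neighbors of a query
#'
#' Computes the blastn-score distance from the query row to every database
#' row of a concatenated alignment, sorts ascending (ties by database row
#' order), and greedily selects rows — skipping any that would exceed
#' `per_species_cap` for its species — until `m_neighbors` are taken or the
#' rows are exhausted.
#'
#' @param query_id Row id of the query inside `concat`.
#' @param concat A [gene_alignment()] containing the query and database
#'   rows.
#' @param species Named character vector, sample id to species (database
#'   rows).
#' @param cfg A [barcode_config()].
#' @return Tibble (sample_id, species, distance) sorted ascending, with
#'   attribute `query_id`.
#' @export
skim_neighbors <- function(query_id, concat, species,
                           cfg = barcode_config()) {
  stopifnot(query_id %in% names(concat$seqs))
  db_ids <- setdiff(names(concat$seqs), query_id)
  if (length(db_ids) == 0L) stop("no database rows")
  q <- concat$seqs[[query_id]]
  dist <- vapply(db_ids, function(id) {
    tryCatch(blastn_distance(q, concat$seqs[[id]]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(dist)) {
    warning("undefined distance to rows: ",
            paste(db_ids[is.na(dist)], collapse = ", "), "; skipped")
    db_ids <- db_ids[!is.na(dist)]
    dist <- dist[!is.na(dist)]
  }
  ord <- order(dist)  # stable: ties keep database order
  taken <- character(0); sp_count <- integer(0)
  for (id in db_ids[ord]) {
    sp <- species[[id]]
    cnt <- if (sp %in% names(sp_count)) sp_count[[sp]] else 0L
    if (cnt >= cfg$per_species_cap) next
    taken <- c(taken, id)
    sp_count[[sp]] <- cnt + 1L
    if (length(taken) >= cfg$m_neighbors) break
  }
  out <- tibble::tibble(sample_id = taken,
                        species = unname(species[taken]),
                        distance = unname(dist[taken]))
  attr(out, "query_id") <- query_id
  out
}

# Insert a query into every recoverable gene of the database, block-filter
# and concatenate. Returns the concatenated alignment (query + all db rows)
# or NULL when no gene is recoverable.
insert_and_concat <- function(query, db, cfg, query_id = "QUERY",
                              samples = NULL) {
  pieces <- list()
  for (gid in names(db$genes)) {
    g <- db$genes[[gid]]
    if (!is.null(samples)) {
      keep <- intersect(names(g$seqs), samples)
      if (length(keep) < 2L) next
      g <- gene_alignment(g$seqs[keep], gene_id = gid)
    }
    if (!gid %in% names(query)) next
    qrow <- add_query_to_alignment(query[[gid]], g)
    if (is.null(qrow)) next
    aug <- gene_alignment(c(stats::setNames(qrow, query_id), g$seqs),
                          gene_id = gid)
    filt <- block_filter(aug, cfg)
    if (!is.null(filt)) pieces[[gid]] <- filt
  }
  if (length(pieces) == 0L) return(NULL)
  concatenate_genes(pieces, pad = "gap")$alignment
}

#' Run a multilocus barcode identification
#'
#' Inserts the query into every gene alignment, block-filters and
#' concatenates, skims the nearest neighbors (20 total, at most 4 per
#' species by default), restricts the database to query plus neighbors,
#' re-filters and re-concatenates, builds an NJ tree with bootstrap
#' supports, and reports the species composition of the smallest clade
#' containing the query (rooted at the most distant neighbor).
#'
#' @param query Named character vector of unaligned query sequences, one
#'   per gene (names = gene ids).
#' @param db A [barcode_db()].
#' @param cfg A [barcode_config()].
#' @param replicates Bootstrap replicates for the local tree (default 100).
#' @return A `barcode_report` list: `neighbors` tibble, `tree`, `sister`
#'   (species composition, monophyly of the top-hit species, tie flag),
#'   `query_id`.
#' @export
barcode_run <- function(query, db, cfg = barcode_config(),
                        replicates = 100L) {
  concat <- insert_and_concat(query, db, cfg)
  if (is.null(concat)) stop("no recoverable genes for this query")
  nb <- skim_neighbors("QUERY", concat, db$species, cfg)
  if (nrow(nb) < 2L) stop("fewer than 2 usable neighbors")
  tie <- nrow(nb) >= 2L && length(unique(nb$species[
    nb$distance <= nb$distance[1] + 1e-12])) > 1L
  local_concat <- insert_and_concat(query, db, cfg,
                                    samples = nb$sample_id)
  tree <- if (!is.null(local_concat) &&
              length(local_concat$seqs) >= 4L) {
    bootstrap_support(local_concat, "blastn", replicates = replicates,
                      seed = cfg$seed)
  } else NULL
  top_species <- nb$species[1]
  sister <- list(top_species = top_species, tie = tie,
                 species = character(0), monophyletic = NA)
  if (!is.null(tree)) {
    far <- nb$sample_id[nrow(nb)]
    rooted <- ape::root(tree, outgroup = far, resolve.root = TRUE)
    qtip <- which(rooted$tip.label == "QUERY")
    parent <- rooted$edge[rooted$edge[, 2] == qtip, 1]
    clade_tips <- rooted$tip.label[
      ape::prop.part(rooted)[[parent - ape::Ntip(rooted)]]]
    clade_sp <- unique(unname(db$species[setdiff(clade_tips, "QUERY")]))
    conspecifics <- names(db$species)[db$species == top_species]
    conspecifics <- intersect(conspecifics, tree$tip.label)
    mono <- if (length(conspecifics) >= 2L) {
      ape::is.monophyletic(rooted, c(conspecifics, "QUERY"))
    } else TRUE
    sister$species <- clade_sp
    sister$monophyletic <- mono
  }
  structure(list(query_id = "QUERY", neighbors = nb, tree = tree,
                 sister = sister),
            class = "barcode_report")
}

#' @export
print.barcode_report <- function(x, ...) {
  cat("<barcode_report>\n")
  cat(sprintf("  top hit: %s (%s, d = %.4f)%s\n", x$neighbors$sample_id[1],
              x$neighbors$species[1], x$neighbors$distance[1],
              if (x$sister$tie) " [TIE across species]" else ""))
  if (!is.null(x$tree)) {
    cat(sprintf("  smallest clade with query: %s (top-hit species monophyletic: %s)\n",
                paste(x$sister$species, collapse = ", "),
                x$sister$monophyletic))
  }
  invisible(x)
}

#' Loci-resampling discrimination analysis
#'
#' For each loci count on the grid and each replicate, samples that many
#' genes without replacement, concatenates them, and records the
#' intraspecific and interspecific blastn distances among all individuals
#' of the designated species pairs. Mirrors the precision-gain analysis of
#' distance-based multilocus barcoding: more loci narrow the replicate
#' spread of both distributions.
#'
#' @param db A [barcode_db()].
#' @param species_pairs List of 2-element character vectors of species
#'   names; each species needs >= 2 individuals.
#' @param grid Loci counts (default c(3, 10, 25, 50, 100, 150); values above
#'   the available gene count are clipped with a warning).
#' @param replicates Replicates per loci count (default 5).
#' @param seed Integer seed.
#' @return Tibble: pair, n_loci, replicate, type (intra/inter), id1, id2,
#'   distance.
#' @export
loci_resampling_analysis <- function(db, species_pairs,
                                     grid = c(3L, 10L, 25L, 50L, 100L, 150L),
                                     replicates = 5L, seed = 1L) {
  G <- length(db$genes)
  if (any(grid > G)) {
    warning("loci counts above ", G, " clipped")
    grid <- unique(pmin(grid, G))
  }
  for (pair in species_pairs) {
    for (sp in pair) {
      if (sum(db$species == sp) < 2L) {
        stop("species ", sp, " has fewer than 2 individuals")
      }
    }
  }
  rows <- list()
  for (pair in species_pairs) {
    ids1 <- names(db$species)[db$species == pair[1]]
    ids2 <- names(db$species)[db$species == pair[2]]
    pair_name <- paste(pair, collapse = " vs ")
    for (n in grid) {
      for (rep in seq_len(replicates)) {
        sel <- withr::with_seed(derive_seed(seed, pair_name, n, rep),
                                sample(names(db$genes), n))
        concat <- concatenate_genes(db$genes, sel, pad = "gap")$alignment
        pairs_of <- function(a, b, type) {
          grid_df <- if (type == "intra") {
            rbind(t(utils::combn(a, 2)),
                  if (length(b) >= 2L) t(utils::combn(b, 2)))
          } else as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
          tibble::tibble(
            pair = pair_name, n_loci = n, replicate = rep, type = type,
            id1 = as.character(grid_df[, 1]),
            id2 = as.character(grid_df[, 2]),
            distance = vapply(seq_len(nrow(grid_df)), function(i) {
              blastn_distance(concat$seqs[[grid_df[i, 1]]],
                              concat$seqs[[grid_df[i, 2]]])
            }, numeric(1)))
        }
        rows[[length(rows) + 1L]] <- pairs_of(ids1, ids2, "intra")
        rows[[length(rows) + 1L]] <- pairs_of(ids1, ids2, "inter")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("loci_resampling", class(out)))
}
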