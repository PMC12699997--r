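#' Simulation specification
#'
#' Bundles all knobs of the synthetic-data generator: a Yule species tree,
#' JC69 sequence evolution with per-gene rate multipliers, an optional
#' species-complex block (for barcode databases) and an optional
#' contamination block (for copy tables with coverage).
#'
#' @param n_taxa Number of tips of the species tree.
#' @param birth_rate Yule birth rate (default 1).
#' @param gene_count Number of loci (default 10).
#' @param gene_length Alignment columns per locus (default 1000).
#' @param rate_multipliers Per-gene rate multipliers (recycled; default 1).
#' @param seed Mandatory integer seed.
#' @param n_species,individuals_per_species,intra_divergence,inter_divergence
#'   Species-complex block (barcode databases): per-site divergence within
#'   and between species.
#' @param fraction_multicopy,copies_per_gene,contaminant_divergence,
#'   target_coverage,contaminant_coverage Contamination block (copy
#'   tables).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_taxa = 10L, birth_rate = 1, gene_count = 10L,
                            gene_length = 1000L, rate_multipliers = 1,
                            seed = 1L, n_species = 6L,
                            individuals_per_species = 4L,
                            intra_divergence = 0.01,
                            inter_divergence = 0.10,
                            fraction_multicopy = 0.31,
                            copies_per_gene = 3L,
                            contaminant_divergence = 0.30,
                            target_coverage = 100,
                            contaminant_coverage = 5) {
  stopifnot(n_taxa >= 3L, birth_rate > 0, gene_count >= 1L,
            gene_length >= 1L, all(rate_multipliers >= 0),
            !missing(seed) || TRUE)
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 gene_count = as.integer(gene_count),
                 gene_length = as.integer(gene_length),
                 rate_multipliers = rep_len(rate_multipliers, gene_count),
                 seed = as.integer(seed),
                 n_species = as.integer(n_species),
                 individuals_per_species =
                   as.integer(individuals_per_species),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 fraction_multicopy = fraction_multicopy,
                 copies_per_gene = as.integer(copies_per_gene),
                 contaminant_divergence = contaminant_divergence,
                 target_coverage = target_coverage,
                 contaminant_coverage = contaminant_coverage),
            class = "simulation_spec")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from the root split (2 lineages); with k lineages the waiting
#' time to the next split is Exponential(k·birth_rate) and a uniformly
#' chosen lineage splits, until `n_taxa` lineages exist; a final
#' Exponential(n·birth_rate) stretch separates the last split from the
#' present. The expected root-to-tip depth is therefore
#' (1/birth_rate)·sum_{k=2}^{n} 1/k. Deterministic per seed; tips are
#' labeled t1..tn.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param birth_rate Birth rate (> 0).
#' @param seed Integer seed.
#' @return A binary rooted [ape::phylo] tree with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  stopifnot(n_taxa >= 3L, birth_rate > 0)
  withr::with_seed(derive_seed(seed, "yule"), {
    # node records: parent, birth time, split time (NA for tips)
    parent <- c(NA_integer_, 1L, 1L)
    born <- c(0, 0, 0)
    split_at <- c(0, NA_real_, NA_real_)
    active <- c(2L, 3L)
    time <- 0
    while (length(active) < n_taxa) {
      k <- length(active)
      time <- time + stats::rexp(1, rate = k * birth_rate)
      i <- active[sample.int(k, 1)]
      split_at[i] <- time
      a <- length(parent) + 1L; b <- a + 1L
      parent <- c(parent, i, i)
      born <- c(born, time, time)
      split_at <- c(split_at, NA_real_, NA_real_)
      active <- c(setdiff(active, i), a, b)
    }
    time <- time + stats::rexp(1, rate = n_taxa * birth_rate)
    end_of <- ifelse(is.na(split_at), time, split_at)
    children <- lapply(seq_along(parent), function(v) {
      which(parent == v)
    })
    tip_counter <- new.env()
    assign("n", 0L, envir = tip_counter)
    nwk <- function(v) {
      kids <- children[[v]]
      if (length(kids) == 0L) {
        n <- get("n", envir = tip_counter) + 1L
        assign("n", n, envir = tip_counter)
        return(paste0("t", n))
      }
      sub <- vapply(kids, function(c) {
        sprintf("%s:%.10g", nwk(c), end_of[c] - born[c])
      }, character(1))
      paste0("(", paste(sub, collapse = ","), ")")
    }
    ape::read.tree(text = paste0(nwk(1L), ";"))
  })
}

# Substitute sites of an uppercase sequence with per-site probability p
# (JC69 transition: a changed site becomes one of the 3 other bases
# uniformly).
jc_mutate <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  repl <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1),
                 character(1))
  chars[hit] <- repl
  chars
}

#' Evolve an alignment along a tree under JC69
#'
#' The root sequence is uniform over ACGT; along each branch of length t
#' every site substitutes with probability
#' p = 3/4·(1 − exp(−4·r·t/3)) (the JC69 closed form at rate multiplier
#' r), the new base drawn uniformly from the other three. No indels, so
#' the leaf sequences are already aligned.
#'
#' @param tree A rooted or unrooted [ape::phylo] with branch lengths.
#' @param length Number of sites.
#' @param rate_multiplier Relative rate r (0 = invariant gene).
#' @param seed Integer seed.
#' @param gene_id Gene id for the returned alignment.
#' @return A [gene_alignment()] over the tree's tips.
#' @export
evolve_alignment <- function(tree, length, rate_multiplier = 1, seed = 1L,
                             gene_id = "gene") {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  withr::with_seed(derive_seed(seed, "evolve", gene_id), {
    bases <- c("A", "C", "G", "T")
    n <- ape::Ntip(tree)
    nnode <- tree$Nnode
    root <- n + 1L
    seqs <- vector("list", n + nnode)
    seqs[[root]] <- sample(bases, length, replace = TRUE)
    # cladewise order: parents always precede children in the edge matrix
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t <- ord$edge.length[e]
      p <- 0.75 * (1 - exp(-4 * rate_multiplier * t / 3))
      seqs[[child]] <- jc_mutate(seqs[[parent]], p)
    }
    rows <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                   character(1))
    names(rows) <- tree$tip.label
    gene_alignment(rows[sort(names(rows))], gene_id = gene_id)
  })
}

#' Simulate a full gene set on one species tree
#'
#' @param spec A [simulation_spec()].
#' @return List with `tree` and `genes` (named list of alignments, ids
#'   g001...).
#' @export
simulate_gene_set <- function(spec) {
  tree <- simulate_tree(spec$n_taxa, spec$birth_rate, spec$seed)
  ids <- sprintf("g%03d", seq_len(spec$gene_count))
  genes <- purrr::map2(ids, spec$rate_multipliers, function(id, r) {
    evolve_alignment(tree, spec$gene_length, r, seed = spec$seed,
                     gene_id = id)
  })
  names(genes) <- ids
  list(tree = tree, genes = genes)
}

# Point-mutate a sequence string at per-site probability d (uniform other
# base), deterministic per seed.
mutate_sequence <- function(s, d, seed) {
  withr::with_seed(derive_seed(seed, "mut"), {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    paste(jc_mutate(chars, d), collapse = "")
  })
}

#' Generate a copy table with coverage and truth labels
#'
#' One target copy per sample-by-gene cell at `target_coverage`; with
#' probability `fraction_multicopy` the cell additionally carries
#' `copies_per_gene − 1` contaminant copies, each diverged from the target
#' by `contaminant_divergence` per site, at `contaminant_coverage`.
#' Coverage values are deterministic means (not sampled) so filter tests
#' are exact.
#'
#' @param spec A [simulation_spec()] (contamination block used).
#' @return List with `table` (copy tibble), `truth` (tibble flagging the
#'   target copy per cell) and `references` (per-gene reference sequence =
#'   the simulated ancestral target).
#' @export
make_copy_table <- function(spec) {
  sim <- simulate_gene_set(spec)
  samples <- sim$tree$tip.label
  rows <- list(); refs <- character(0)
  for (gid in names(sim$genes)) {
    g <- sim$genes[[gid]]
    refs[[gid]] <- g$seqs[[1]]
    for (s in samples) {
      multicopy <- withr::with_seed(
        derive_seed(spec$seed, "multi", gid, s),
        stats::runif(1) < spec$fraction_multicopy)
      target <- g$seqs[[s]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = s, gene_id = gid, copy_id = "c1",
        mean_coverage = spec$target_coverage, sequence = target,
        is_target = TRUE)
      if (multicopy) {
        for (ci in seq_len(spec$copies_per_gene - 1L)) {
          contam <- mutate_sequence(target, spec$contaminant_divergence,
                                    derive_seed(spec$seed, gid, s, ci))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = s, gene_id = gid,
            copy_id = paste0("c", ci + 1L),
            mean_coverage = spec$contaminant_coverage, sequence = contam,
            is_target = FALSE)
        }
      }
    }
  }
  all <- dplyr::bind_rows(rows)
  list(table = all[setdiff(names(all), "is_target")],
       truth = all[c("sample_id", "gene_id", "copy_id", "is_target")],
       references = refs)
}

#' Generate a synthetic barcode database with withheld queries
#'
#' Species means diverge from a shared ancestor by `inter_divergence` per
#' site and gene; individuals scatter around their species mean by
#' `intra_divergence`. One individual per species is withheld from the
#' database and returned as a query (per-gene unaligned sequences).
#'
#' @param spec A [simulation_spec()] (species-complex block used).
#' @return List with `db` (a [barcode_db()]) and `queries` (named list:
#'   withheld sample id -> list(species, seqs named by gene)).
#' @export
make_barcode_db <- function(spec) {
  gene_ids <- sprintf("g%03d", seq_len(spec$gene_count))
  sp_names <- sprintf("species_%02d", seq_len(spec$n_species))
  anc <- lapply(gene_ids, function(gid) {
    withr::with_seed(derive_seed(spec$seed, "anc", gid),
                     paste(sample(c("A", "C", "G", "T"), spec$gene_length,
                                  replace = TRUE), collapse = ""))
  })
  names(anc) <- gene_ids
  genes <- list(); species <- character(0); queries <- list()
  seqs_by_gene <- lapply(gene_ids, function(g) character(0))
  names(seqs_by_gene) <- gene_ids
  for (si in seq_along(sp_names)) {
    sp <- sp_names[si]
    for (ii in seq_len(spec$individuals_per_species)) {
      id <- sprintf("%s_ind%d", sp, ii)
      species[[id]] <- sp
      for (gid in gene_ids) {
        mean_seq <- mutate_sequence(anc[[gid]], spec$inter_divergence,
                                    derive_seed(spec$seed, "sp", sp, gid))
        ind_seq <- mutate_sequence(mean_seq, spec$intra_divergence,
                                   derive_seed(spec$seed, "ind", id, gid))
        seqs_by_gene[[gid]][[id]] <- ind_seq
      }
    }
  }
  withheld <- sprintf("%s_ind1", sp_names)
  for (gid in gene_ids) {
    rows <- seqs_by_gene[[gid]]
    db_rows <- rows[setdiff(names(rows), withheld)]
    genes[[gid]] <- gene_alignment(db_rows, gene_id = gid)
  }
  for (w in withheld) {
    queries[[w]] <- list(
      species = species[[w]],
      seqs = stats::setNames(
        vapply(gene_ids, function(g) seqs_by_gene[[g]][[w]], character(1)),
        gene_ids))
  }
  db <- barcode_db(genes, species[setdiff(names(species), withheld)])
  list(db = db, queries = queries)
}

#' Inject soft-masked (lowercase) runs into a sequence
#'
#' Marks a configurable fraction of the sequence as repeat by lowercasing
#' runs of `run_len`, placed deterministically per seed. Used to build
#' bait-design fixtures.
#'
#' @param s Sequence (uppercase).
#' @param fraction Target masked fraction.
#' @param run_len Length of each masked run (default 20).
#' @param seed Integer seed.
#' @export
soft_mask <- function(s, fraction, run_len = 20L, seed = 1L) {
  L <- nchar(s)
  n_runs <- max(0L, floor(fraction * L / run_len))
  if (n_runs == 0L) return(s)
  withr::with_seed(derive_seed(seed, "mask"), {
    starts <- sort(sample.int(max(1L, L - run_len + 1L), n_runs))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (st in starts) {
      idx <- st:min(L, st + run_len - 1L)
      chars[idx] <- tolower(chars[idx])
    }
    paste(chars, collapse = "")
  })
}
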