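small_db <- function(seed = 1, n_species = 4, ind = 3, genes = 5,
                     L = 300, intra = 0.01, inter = 0.12) {
  spec <- simulation_spec(gene_count = genes, gene_length = L, seed = seed,
                          n_species = n_species,
                          individuals_per_species = ind,
                          intra_divergence = intra,
                          inter_divergence = inter)
  make_barcode_db(spec)
}

test_that("a query equal to an ungapped database row aligns onto itself", {
  mk <- small_db(seed = 2)
  g <- mk$db$genes[[1]]
  row_id <- names(g$seqs)[1]
  aligned <- add_query_to_alignment(g$seqs[[row_id]], g)
  expect_identical(aligned, g$seqs[[row_id]])
})

test_that("a truncated query gains leading gaps in the column space", {
  mk <- small_db(seed = 3)
  g <- mk$db$genes[[1]]
  full <- g$seqs[[2]]
  trunc <- substr(full, 11, nchar(full))
  aligned <- add_query_to_alignment(trunc, g)
  expect_equal(nchar(aligned), g$length)
  expect_equal(substr(aligned, 1, 10), strrep("-", 10))
  expect_equal(substr(aligned, 11, g$length), trunc)
})

test_that("a non-homologous random query is skipped with a warning", {
  mk <- small_db(seed = 4)
  g <- mk$db$genes[[1]]
  # poly-purine junk scores far below the floor against any DNA profile
  junk <- strrep("AG", 400)
  expect_warning(res <- add_query_to_alignment(junk, g), "homology")
  expect_null(res)
})

test_that("block filter drops gappy columns and short runs", {
  clean <- gene_alignment(c(a = "ACGTACGT", b = "ACGTACGT"), "clean")
  expect_identical(block_filter(clean)$seqs, clean$seqs)

  # middle column 60% gaps between two clean blocks of length >= 3
  rows <- c(a = "ACG-ACG", b = "ACG-ACG", c = "ACGTACG", d = "ACG-ACG",
            e = "ACGTACG")
  filt <- block_filter(gene_alignment(rows, "mid"))
  expect_equal(filt$length, 6L)
  expect_equal(attr(filt, "columns"), c(0:2, 4:6))

  # alternating clean/gappy columns: surviving runs of 1 all removed
  alt <- c(a = "A-C-G-T", b = "A-C-G-T", c = "A-C-G-T")
  expect_warning(out <- block_filter(gene_alignment(alt, "alt")),
                 "removed all")
  expect_null(out)
})

test_that("skim respects total and per-species caps and sorts ascending", {
  mk <- small_db(seed = 5, n_species = 6, ind = 6, genes = 4, L = 200)
  q <- mk$queries[[1]]
  concat <- phylocap:::insert_and_concat(q$seqs, mk$db, barcode_config())
  nb <- skim_neighbors("QUERY", concat, mk$db$species, barcode_config())
  expect_lte(nrow(nb), 20L)
  expect_true(all(table(nb$species) <= 4L))
  expect_true(!is.unsorted(nb$distance))
  # nearest neighbor always included
  expect_equal(nb$sample_id[1], names(which.min(vapply(
    setdiff(names(concat$seqs), "QUERY"), function(id) {
      blastn_distance(concat$seqs[["QUERY"]], concat$seqs[[id]])
    }, numeric(1)))))
  # conspecific dominance: top hit is the query's own species
  expect_equal(nb$species[1], q$species)
})

test_that("skim is exhausted gracefully on tiny databases", {
  mk <- small_db(seed = 6, n_species = 2, ind = 2, genes = 3, L = 150)
  q <- mk$queries[[1]]
  concat <- phylocap:::insert_and_concat(q$seqs, mk$db, barcode_config())
  nb <- skim_neighbors("QUERY", concat, mk$db$species, barcode_config())
  expect_equal(nrow(nb), 2L)  # 1 remaining individual per species
})

test_that("cap constraints hold on randomized databases", {
  for (seed in 1:5) {
    mk <- small_db(seed = 20 + seed, n_species = 5, ind = 5, genes = 3,
                   L = 150)
    q <- mk$queries[[2]]
    cfg <- barcode_config(m_neighbors = 10, per_species_cap = 2)
    concat <- phylocap:::insert_and_concat(q$seqs, mk$db, cfg)
    nb <- skim_neighbors("QUERY", concat, mk$db$species, cfg)
    expect_lte(nrow(nb), 10L)
    expect_true(all(table(nb$species) <= 2L))
  }
})

test_that("barcode run recovers the planted species as a monophyletic sister", {
  hits <- 0L
  for (seed in 1:5) {
    mk <- small_db(seed = 30 + seed, n_species = 4, ind = 4, genes = 4,
                   L = 250, intra = 0.01, inter = 0.15)
    q <- mk$queries[[1]]
    rep <- barcode_run(q$seqs, mk$db, barcode_config(seed = seed),
                       replicates = 10)
    if (rep$neighbors$species[1] == q$species &&
        isTRUE(rep$sister$monophyletic) &&
        q$species %in% rep$sister$species) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("indistinguishable species produce a flagged tie", {
  # two species share identical sequences: zero inter-divergence
  genes <- list()
  base <- random_seq(200, 51)
  rows <- c(spA_1 = base, spA_2 = base, spB_1 = base, spB_2 = base,
            spC_1 = mutate_k(base, 60, 52), spC_2 = mutate_k(base, 60, 53))
  genes$g1 <- gene_alignment(rows, "g1")
  species <- c(spA_1 = "A", spA_2 = "A", spB_1 = "B", spB_2 = "B",
               spC_1 = "C", spC_2 = "C")
  db <- barcode_db(genes, species)
  rep <- barcode_run(c(g1 = base), db,
                     barcode_config(m_neighbors = 6, seed = 1),
                     replicates = 0)
  expect_true(rep$sister$tie)
})

test_that("barcode run is deterministic and errors without recoverable genes", {
  mk <- small_db(seed = 40)
  q <- mk$queries[[1]]
  r1 <- barcode_run(q$seqs, mk$db, barcode_config(seed = 7), replicates = 5)
  r2 <- barcode_run(q$seqs, mk$db, barcode_config(seed = 7), replicates = 5)
  expect_identical(r1$neighbors, r2$neighbors)
  expect_identical(ape::write.tree(r1$tree), ape::write.tree(r2$tree))
  expect_error(barcode_run(c(nonexistent_gene = "ACGT"), mk$db),
               "no recoverable")
})

test_that("distant species pairs separate already at 3 loci; identical never do", {
  mk <- small_db(seed = 61, n_species = 2, ind = 3, genes = 8, L = 200,
                 intra = 0.005, inter = 0.2)
  pairs <- list(unique(mk$db$species))
  res <- suppressWarnings(loci_resampling_analysis(
    mk$db, pairs, grid = c(3L, 8L), replicates = 3, seed = 1))
  for (n in c(3L, 8L)) {
    intra <- res$distance[res$type == "intra" & res$n_loci == n]
    inter <- res$distance[res$type == "inter" & res$n_loci == n]
    expect_gt(min(inter), max(intra))
  }

  mk0 <- small_db(seed = 62, n_species = 2, ind = 3, genes = 6, L = 200,
                  intra = 0.01, inter = 0)
  res0 <- suppressWarnings(loci_resampling_analysis(
    mk0$db, list(unique(mk0$db$species)), grid = c(3L), replicates = 3,
    seed = 1))
  intra0 <- res0$distance[res0$type == "intra"]
  inter0 <- res0$distance[res0$type == "inter"]
  expect_lt(abs(mean(inter0) - mean(intra0)), 0.02)
})

test_that("replicate spread narrows as loci are added", {
  wins <- 0L
  for (seed in 1:6) {
    mk <- small_db(seed = 70 + seed, n_species = 2, ind = 3, genes = 30,
                   L = 60, intra = 0.02, inter = 0.15)
    res <- loci_resampling_analysis(mk$db, list(unique(mk$db$species)),
                                    grid = c(3L, 30L), replicates = 5,
                                    seed = seed)
    spread <- function(n) {
      reps <- dplyr::summarise(
        dplyr::group_by(res[res$type == "inter" & res$n_loci == n, ],
                        .data$replicate),
        m = mean(.data$distance), .groups = "drop")
      stats::var(reps$m)
    }
    if (spread(30L) <= spread(3L)) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("barcode databases round-trip through the directory layout", {
  mk <- small_db(seed = 80, genes = 3)
  dir <- withr::local_tempdir()
  write_alignment_dir(mk$db$genes, file.path(dir, "genes"))
  utils::write.table(
    data.frame(sample_id = names(mk$db$species),
               species = unname(mk$db$species)),
    file.path(dir, "species_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  back <- read_barcode_db(dir)
  expect_identical(back$genes$g002$seqs, mk$db$genes$g002$seqs)
  expect_identical(sort(names(back$species)), sort(names(mk$db$species)))
})
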