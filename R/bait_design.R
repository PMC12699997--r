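#' Bait design configuration
#'
#' Parameters for tiling 80 bp hybridization baits over representative
#' sequences and for the QC filters applied to each bait window.
#'
#' @param bait_len Bait length in bases (default 80).
#' @param tiling Tiling density; the tile step is `bait_len / tiling`
#'   (default 2, i.e. 40 bp step).
#' @param gc_low,gc_high GC bounds in percent, exclusive: a bait passes only
#'   if `gc_low < GC < gc_high` (defaults 25 and 67).
#' @param repeat_max Maximum tolerated repeat (soft-masked) percentage; a
#'   bait is flagged when strictly above this (default 35).
#' @param n_run_max Maximal N-run length rewritten to T (default 10); longer
#'   runs are left and flag the bait as RESIDUAL_N.
#' @param region_flank Flank in bases added on each side of the window for
#'   the regional repeat check (default 80).
#' @param seed_len Exact-seed length for multi-hit screening (default 16).
#' @param hit_min_len Minimum ungapped overlap for a locus to count
#'   (default 60).
#' @param hit_min_ident Minimum identity over that overlap (default 0.90).
#' @return A `bait_config` list.
#' @export
bait_config <- function(bait_len = 80L, tiling = 2L, gc_low = 25,
                        gc_high = 67, repeat_max = 35, n_run_max = 10L,
                        region_flank = 80L, seed_len = 16L,
                        hit_min_len = 60L, hit_min_ident = 0.90) {
  stopifnot(bait_len %% tiling == 0L, gc_low >= 0, gc_low < gc_high,
            gc_high <= 100, n_run_max >= 1L, seed_len >= 4L)
  structure(list(bait_len = as.integer(bait_len), tiling = as.integer(tiling),
                 step = as.integer(bait_len / tiling), gc_low = gc_low,
                 gc_high = gc_high, repeat_max = repeat_max,
                 n_run_max = as.integer(n_run_max),
                 region_flank = as.integer(region_flank),
                 seed_len = as.integer(seed_len),
                 hit_min_len = as.integer(hit_min_len),
                 hit_min_ident = hit_min_ident),
            class = "bait_config")
}

#' Rewrite short N runs to T
#'
#' Every maximal run of N/n whose length is between 1 and `n_run_max` is
#' replaced by uppercase T; longer runs are left untouched (they later flag
#' the bait as RESIDUAL_N).
#'
#' @param sequence Character scalar.
#' @param n_run_max Longest run still rewritten (default 10).
#' @return The rewritten sequence.
#' @export
rewrite_n_runs <- function(sequence, n_run_max = 10L) {
  m <- gregexpr("[Nn]+", sequence)[[1]]
  if (m[1] == -1L) return(sequence)
  lens <- attr(m, "match.length")
  out <- sequence
  # replace right-to-left so positions stay valid
  for (i in rev(seq_along(m))) {
    if (lens[i] <= n_run_max) {
      substr(out, m[i], m[i] + lens[i] - 1L) <- strrep("T", lens[i])
    }
  }
  out
}

#' Tile bait windows over a source sequence
#'
#' Windows start at 0 with step `bait_len / tiling`; when the last regular
#' window stops short of the sequence end, one flush window
#' `[L - bait_len, L)` is appended. Coordinates are 0-based half-open.
#'
#' @param source_len Length of the (gap-stripped) source.
#' @param cfg A [bait_config()].
#' @return Tibble with `start` and `end`; zero rows when the source is
#'   shorter than one bait.
#' @export
tile_windows <- function(source_len, cfg = bait_config()) {
  L <- as.integer(source_len)
  if (L < cfg$bait_len) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  starts <- seq.int(0L, L - cfg$bait_len, by = cfg$step)
  if (max(starts) + cfg$bait_len < L) starts <- c(starts, L - cfg$bait_len)
  tibble::tibble(start = starts, end = starts + cfg$bait_len)
}

gc_percent <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

softmask_percent <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  100 * sum(chars %in% letters) / length(chars)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Qualifying loci of `bait` in one genome strand under the ungapped-overlap
# definition: a diagonal offset counts when the bait-vs-genome overlap is
# >= min_len and identity over the overlap >= min_ident.
offset_hits <- function(bait_chars, genome_chars, min_len, min_ident,
                        offsets) {
  bl <- length(bait_chars); gl <- length(genome_chars)
  keep <- integer(0)
  for (p in offsets) {  # p = 0-based genome start of bait position 1
    lo <- max(0L, -p); hi <- min(bl - 1L, gl - 1L - p)
    ov <- hi - lo + 1L
    if (ov < min_len) next
    b <- bait_chars[(lo + 1L):(hi + 1L)]
    g <- genome_chars[(p + lo + 1L):(p + hi + 1L)]
    if (sum(b == g) / ov >= min_ident) keep <- c(keep, p)
  }
  keep
}

# Candidate offsets from shared exact seeds of length seed_len.
seed_offsets <- function(bait, genome, seed_len) {
  bl <- nchar(bait); gl <- nchar(genome)
  if (gl < seed_len || bl < seed_len) return(integer(0))
  gpos <- seq_len(gl - seed_len + 1L)
  gk <- substring(genome, gpos, gpos + seed_len - 1L)
  index <- split(gpos - 1L, gk)
  bpos <- seq_len(bl - seed_len + 1L)
  bk <- substring(bait, bpos, bpos + seed_len - 1L)
  offs <- integer(0)
  for (i in seq_along(bk)) {
    hits <- index[[bk[i]]]
    if (!is.null(hits)) offs <- c(offs, hits - (bpos[i] - 1L))
  }
  sort(unique(offs))
}

merge_loci <- function(offsets, bait_len, step) {
  # offsets sorted; loci overlapping by more than `step` collapse to one
  if (length(offsets) == 0L) return(integer(0))
  kept <- offsets[1]
  for (p in offsets[-1]) {
    if (p - kept[length(kept)] < bait_len - step) next
    kept <- c(kept, p)
  }
  kept
}

#' Count genomic loci matching a bait
#'
#' Seed-and-extend screen: exact seeds of `seed_len` shared between the bait
#' and a genome propose diagonals; a diagonal counts as a locus when the
#' ungapped overlap is at least `hit_min_len` with identity at least
#' `hit_min_ident`. Both strands of every genome are scanned and loci
#' overlapping by more than the tile step are merged. Set
#' `brute_force = TRUE` to scan all offsets instead of seeded ones (the
#' reference scan used to validate the seeded screen).
#'
#' @param bait Bait sequence (uppercase).
#' @param genomes Named character vector of genome sequences.
#' @param cfg A [bait_config()].
#' @param brute_force Scan every offset instead of seeded candidates.
#' @return Integer total locus count across genomes and strands.
#' @export
count_hits <- function(bait, genomes, cfg = bait_config(),
                       brute_force = FALSE) {
  bait <- toupper(bait)
  bc <- strsplit(bait, "", fixed = TRUE)[[1]]
  total <- 0L
  for (g in genomes) {
    for (strand_seq in c(toupper(g), toupper(revcomp(g)))) {
      gc <- strsplit(strand_seq, "", fixed = TRUE)[[1]]
      offsets <- if (brute_force) {
        seq.int(-(cfg$bait_len - cfg$hit_min_len),
                length(gc) - cfg$hit_min_len)
      } else {
        seed_offsets(bait, strand_seq, cfg$seed_len)
      }
      hits <- offset_hits(bc, gc, cfg$hit_min_len, cfg$hit_min_ident,
                          offsets)
      total <- total + length(merge_loci(hits, cfg$bait_len, cfg$step))
    }
  }
  total
}

#' QC-annotate one bait window
#'
#' Computes GC, repeat and regional-repeat percentages, residual-N status
#' and the multi-hit count, then sets flags:
#' LOW_GC (`gc_pct <= gc_low`), HIGH_GC (`gc_pct >= gc_high`), REPEAT
#' (`repeat_pct > repeat_max`), REGION_REPEAT (same bound on the window
#' extended by `region_flank` each side), MULTI_HIT (>= 2 loci),
#' RESIDUAL_N (any N left after run rewriting). A bait passes iff no flag
#' is set.
#'
#' @param source Gap-stripped, N-rewritten source sequence with soft-masking
#'   (case) intact.
#' @param start,end 0-based half-open window on `source`.
#' @param genomes Named character vector of genomes (may be empty; then hit
#'   screening is skipped).
#' @param cfg A [bait_config()].
#' @param hit_count Optional precomputed hit count (e.g. from an external
#'   screen); when NA it is computed via [count_hits()].
#' @return One-row tibble of bait annotations.
#' @export
qc_bait <- function(source, start, end, genomes = character(0),
                    cfg = bait_config(), hit_count = NA_integer_) {
  win <- substr(source, start + 1L, end)
  bait_seq <- toupper(win)
  gc <- gc_percent(bait_seq)
  rep_pct <- softmask_percent(win)
  rstart <- max(0L, start - cfg$region_flank)
  rend <- min(nchar(source), end + cfg$region_flank)
  region_pct <- softmask_percent(substr(source, rstart + 1L, rend))
  if (is.na(hit_count)) {
    hit_count <- if (length(genomes) > 0L) count_hits(bait_seq, genomes, cfg)
                 else 0L
  }
  flags <- character(0)
  if (gc <= cfg$gc_low) flags <- c(flags, "LOW_GC")
  if (gc >= cfg$gc_high) flags <- c(flags, "HIGH_GC")
  if (rep_pct > cfg$repeat_max) flags <- c(flags, "REPEAT")
  if (region_pct > cfg$repeat_max) flags <- c(flags, "REGION_REPEAT")
  if (hit_count >= 2L) flags <- c(flags, "MULTI_HIT")
  if (grepl("N", bait_seq, fixed = TRUE)) flags <- c(flags, "RESIDUAL_N")
  ok <- length(flags) == 0L
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 sequence = bait_seq, gc_pct = gc, repeat_pct = rep_pct,
                 region_repeat_pct = region_pct,
                 hit_count = as.integer(hit_count),
                 flags = paste(flags, collapse = ","),
                 passed = ok)
}

#' Design a QC-filtered bait set from representative sequences
#'
#' For each representative: strip alignment gaps, rewrite short N runs to T,
#' tile windows, and QC-annotate every bait. Returns the full annotated
#' table (`baits`), the passing subset (`bait_set`) and a per-source summary
#' (`report`). Sources shorter than one bait are recorded as `too_short`.
#'
#' @param representatives Named character vector of source sequences
#'   (soft-masking honored; may contain alignment gaps).
#' @param genomes Named character vector of reference genome sequences for
#'   multi-hit screening (empty = screening skipped, with a report note).
#' @param cfg A [bait_config()].
#' @return List with `baits`, `bait_set`, `report`.
#' @export
design_bait_set <- function(representatives, genomes = character(0),
                            cfg = bait_config()) {
  stopifnot(length(representatives) >= 1L, !is.null(names(representatives)))
  if (length(genomes) == 0L) {
    warning("no genomes supplied: multi-hit screening skipped")
  }
  per_source <- purrr::imap(representatives, function(s, id) {
    s <- gsub("-", "", s, fixed = TRUE)
    s <- rewrite_n_runs(s, cfg$n_run_max)
    wins <- tile_windows(nchar(s), cfg)
    if (nrow(wins) == 0L) {
      return(list(baits = NULL,
                  report = tibble::tibble(source_id = id, n_baits = 0L,
                                          n_pass = 0L, note = "too_short")))
    }
    baits <- purrr::map2(wins$start, wins$end, function(a, b) {
      qc_bait(s, a, b, genomes, cfg)
    })
    baits <- dplyr::bind_rows(baits)
    baits <- dplyr::mutate(baits, source_id = id,
                           bait_id = paste(id, .data$start, .data$end,
                                           sep = "_"),
                           .before = 1L)
    list(baits = baits,
         report = tibble::tibble(source_id = id, n_baits = nrow(baits),
                                 n_pass = sum(baits$passed),
                                 note = if (length(genomes) == 0L)
                                   "no_hit_screen" else ""))
  })
  baits <- dplyr::bind_rows(purrr::map(per_source, "baits"))
  report <- dplyr::bind_rows(purrr::map(per_source, "report"))
  list(baits = baits,
       bait_set = if (nrow(baits) > 0L) dplyr::filter(baits, .data$passed)
                  else baits,
       report = report)
}

#' Write a designed bait set to FASTA + TSV
#' @param design Result of [design_bait_set()].
#' @param dir Output directory.
#' @export
write_bait_set <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(design$bait_set) > 0L) {
    seqs <- design$bait_set$sequence
    names(seqs) <- design$bait_set$bait_id
    write_fasta(seqs, file.path(dir, "baits.fasta"))
  }
  utils::write.table(design$baits, file.path(dir, "bait_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(design$report, file.path(dir, "bait_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
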