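#' Multiple-copy filter configuration
#'
#' The capture pipeline may extract a gene in several copies per sample
#' (paralogs or contaminant orthologs). The deepest copy is retained when it
#' is at least `r_min` times deeper covered than the next-deepest copy
#' (inclusive bound). In `strict` mode a gene failing the depth condition is
#' dropped entirely; in `default` mode the copy most similar to the gene's
#' reference sequence is retained instead.
#'
#' @param r_min Coverage-ratio threshold (default 10).
#' @param mode `"default"` or `"strict"`.
#' @export
filter_config <- function(r_min = 10, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  stopifnot(r_min > 1)
  structure(list(r_min = r_min, mode = mode), class = "filter_config")
}

#' Read an extracted-copy table from FASTA with structured headers
#'
#' Header format: `sample|gene|copy|cov=<float>`.
#'
#' @param path FASTA path.
#' @return Tibble: sample_id, gene_id, copy_id, mean_coverage, sequence.
#' @export
read_copies_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 4L ||
                  !grepl("^cov=", p[4]), logical(1))
  if (any(bad)) {
    stop("malformed copy header(s): ",
         paste(names(seqs)[bad], collapse = ", "),
         " (expected sample|gene|copy|cov=<float>)")
  }
  tibble::tibble(
    sample_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    copy_id = vapply(parts, `[`, character(1), 3L),
    mean_coverage = as.numeric(sub("^cov=", "",
                                   vapply(parts, `[`, character(1), 4L))),
    sequence = unname(seqs))
}

#' Read an extracted-copy table from TSV
#'
#' Columns: sample_id, gene_id, copy_id, mean_coverage, sequence.
#' @param path TSV path.
#' @export
read_copies_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "copy_id", "mean_coverage", "sequence")
  if (!all(need %in% names(df))) {
    stop("copy TSV must have columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(df[need])
}

# p-identity of a global pairwise alignment (match +1 / mismatch -1,
# affine gaps open 5 extend 1), identity over aligned non-gap columns.
reference_similarity <- function(seq, ref) {
  pa <- Biostrings::pairwiseAlignment(
    toupper(gsub("-", "", seq, fixed = TRUE)),
    toupper(gsub("-", "", ref, fixed = TRUE)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
  if (nm + nmm == 0L) return(0)
  nm / (nm + nmm)
}

#' Resolve the copies of one sample-by-gene cell
#'
#' A single copy is retained as-is. With multiple copies, let c1 be the
#' deepest and c2 the next deepest: the depth condition holds when
#' `c1 >= r_min * c2` (inclusive). In strict mode c1 is retained only when
#' the condition holds, otherwise the gene is dropped; in default mode a
#' failing cell falls back to the copy most similar to the reference
#' (ties: deeper coverage, then copy_id order).
#'
#' @param copies Tibble of copies for one sample-by-gene cell.
#' @param reference Reference sequence for the gene (needed only for the
#'   default-mode similarity fallback).
#' @param cfg A [filter_config()].
#' @return One-row tibble: sample_id, gene_id, copy_id (NA when dropped),
#'   decision, n_copies.
#' @export
resolve_copies <- function(copies, reference = NULL,
                           cfg = filter_config()) {
  stopifnot(nrow(copies) >= 1L)
  out <- function(copy_id, decision) {
    tibble::tibble(sample_id = copies$sample_id[1],
                   gene_id = copies$gene_id[1], copy_id = copy_id,
                   decision = decision, n_copies = nrow(copies))
  }
  if (nrow(copies) == 1L) return(out(copies$copy_id[1], "single"))
  ord <- order(-copies$mean_coverage, copies$copy_id)
  c1 <- copies[ord[1], ]; c2 <- copies[ord[2], ]
  if (c1$mean_coverage >= cfg$r_min * c2$mean_coverage) {
    return(out(c1$copy_id, "depth_ratio"))
  }
  if (cfg$mode == "strict") return(out(NA_character_, "dropped_multicopy"))
  if (is.null(reference)) {
    stop("reference sequence required for similarity fallback (sample ",
         copies$sample_id[1], ", gene ", copies$gene_id[1], ")")
  }
  sim <- vapply(copies$sequence, reference_similarity, numeric(1),
                ref = reference)
  pick <- order(-sim, -copies$mean_coverage, copies$copy_id)[1]
  out(copies$copy_id[pick], "best_similarity")
}

#' Resolve every sample-by-gene cell of a copy table
#'
#' @param table Copy tibble (see [read_copies_fasta()]).
#' @param references Named character vector of per-gene reference sequences
#'   (used only by the default-mode fallback).
#' @param cfg A [filter_config()].
#' @return Decisions tibble, one row per sample-by-gene cell.
#' @export
resolve_copy_table <- function(table, references = NULL,
                               cfg = filter_config()) {
  cells <- dplyr::group_split(dplyr::group_by(table, .data$sample_id,
                                              .data$gene_id))
  rows <- purrr::map(cells, function(cell) {
    resolve_copies(cell, references[[cell$gene_id[1]]], cfg)
  })
  dplyr::bind_rows(rows)
}

#' Completeness matrix of resolved extractions
#'
#' Fraction of the reference length recovered per sample and gene:
#' `min(1, nongap extracted length / reference length)`; absent or dropped
#' cells are 0. The uncapped raw fraction is kept in the long-form tibble.
#'
#' @param table Copy tibble.
#' @param decisions Decisions tibble from [resolve_copy_table()].
#' @param references Named character vector of per-gene references.
#' @return List with `matrix` (samples x genes, capped) and `long` tibble
#'   (sample_id, gene_id, fraction, raw_fraction).
#' @export
completeness_matrix <- function(table, decisions, references) {
  genes <- sort(unique(table$gene_id))
  miss_ref <- setdiff(genes, names(references))
  if (length(miss_ref) > 0L) {
    stop("missing references for genes: ", paste(miss_ref, collapse = ", "))
  }
  ref_len <- vapply(references[genes],
                    function(r) nchar(gsub("-", "", r, fixed = TRUE)),
                    integer(1))
  if (any(ref_len == 0L)) stop("zero-length reference sequence")
  samples <- sort(unique(table$sample_id))
  kept <- dplyr::filter(decisions, !is.na(.data$copy_id))
  kept <- dplyr::left_join(
    kept, table, by = c("sample_id", "gene_id", "copy_id"))
  kept$raw_fraction <- nchar(gsub("-", "", kept$sequence, fixed = TRUE)) /
    unname(ref_len[kept$gene_id])
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(kept$sample_id, kept$gene_id)] <- pmin(1, kept$raw_fraction)
  long <- tidyr::expand_grid(sample_id = samples, gene_id = genes)
  long <- dplyr::left_join(
    long, kept[c("sample_id", "gene_id", "raw_fraction")],
    by = c("sample_id", "gene_id"))
  long$raw_fraction[is.na(long$raw_fraction)] <- 0
  long$fraction <- pmin(1, long$raw_fraction)
  structure(list(matrix = m, long = long), class = "completeness")
}

#' @export
print.completeness <- function(x, ...) {
  cat(sprintf("<completeness> %d samples x %d genes, mean %.3f\n",
              nrow(x$matrix), ncol(x$matrix), mean(x$matrix)))
  invisible(x)
}

#' Per-sample multi-copy summary
#'
#' For each sample: the fraction of its genes extracted in 2+ copies, the
#' mean copy number among those multi-copy genes, and counts per resolution
#' decision.
#'
#' @param table Copy tibble.
#' @param decisions Optional decisions tibble; when given, per-decision
#'   counts are included.
#' @return Tibble, one row per sample.
#' @export
filter_report <- function(table, decisions = NULL) {
  if (nrow(table) == 0L) {
    warning("empty copy table")
    return(tibble::tibble(sample_id = character(0), n_genes = integer(0),
                          multicopy_fraction = numeric(0),
                          mean_copies_multicopy = numeric(0)))
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(table, .data$sample_id, .data$gene_id),
    n_copies = dplyr::n(), .groups = "drop")
  rep <- dplyr::summarise(
    dplyr::group_by(per_gene, .data$sample_id),
    n_genes = dplyr::n(),
    multicopy_fraction = mean(.data$n_copies >= 2L),
    mean_copies_multicopy =
      ifelse(any(.data$n_copies >= 2L),
             mean(.data$n_copies[.data$n_copies >= 2L]), NA_real_),
    .groups = "drop")
  if (!is.null(decisions)) {
    counts <- tidyr::pivot_wider(
      dplyr::count(decisions, .data$sample_id, .data$decision),
      names_from = "decision", values_from = "n", values_fill = 0L)
    rep <- dplyr::left_join(rep, counts, by = "sample_id")
  }
  rep
}
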