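#' Pairwise sequence distances
#'
#' Two metrics over aligned sequences of equal length:
#' * `p_distance()` — uncorrected proportion of differing sites, with
#'   pairwise deletion of columns where either sequence carries a gap or any
#'   non-ACGT symbol (IUPAC ambiguity codes are treated as missing).
#' * `blastn_distance()` — a score-based distance used by the barcode skim:
#'   score S = 5·matches − 4·mismatches over the comparable columns,
#'   distance = 1 − S / (5·L), clamped to \[0, 1\], where L is the number of
#'   comparable columns (5·L is the maximum attainable score).
#'
#' Both error when no comparable column exists (the caller decides what an
#' undefined distance means). Case is ignored: soft-masking does not change
#' base identity.
#'
#' @param a,b Aligned sequences (character scalars) of equal length.
#' @return A distance in \[0, 1\].
#' @name pairwise_distance
NULL

# Encode as integers 1..4 for A,C,G,T; NA for everything else (gaps,
# ambiguity codes). Uppercased first so soft-masking is identity-neutral.
encode_dna <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  x
}

pairwise_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ea <- encode_dna(a); eb <- encode_dna(b)
  comp <- !is.na(ea) & !is.na(eb)
  L <- sum(comp)
  list(L = L, diffs = sum(ea[comp] != eb[comp]))
}

#' @rdname pairwise_distance
#' @export
p_distance <- function(a, b) {
  pc <- pairwise_counts(a, b)
  if (pc$L == 0L) stop("undefined distance: zero comparable columns")
  pc$diffs / pc$L
}

#' @rdname pairwise_distance
#' @param match_score,mismatch_score Scoring scheme (blastn-style defaults
#'   +5 / −4).
#' @export
blastn_distance <- function(a, b, match_score = 5, mismatch_score = -4) {
  stopifnot(match_score > 0, mismatch_score < 0)
  pc <- pairwise_counts(a, b)
  if (pc$L == 0L) stop("undefined distance: zero comparable columns")
  s <- match_score * (pc$L - pc$diffs) + mismatch_score * pc$diffs
  d <- 1 - s / (match_score * pc$L)
  min(max(d, 0), 1)
}

#' Full pairwise distance matrix over an alignment
#'
#' Applies one of the two pairwise metrics to every row pair of a gene
#' alignment and returns a labeled symmetric [distance_matrix()].
#'
#' @param aln A [gene_alignment()] (or named character vector of equal-length
#'   sequences).
#' @param metric `"p"` (uncorrected p-distance) or `"blastn"` (score-based).
#' @return A `distance_matrix` over the row ids.
#' @export
alignment_distance_matrix <- function(aln, metric = c("p", "blastn")) {
  metric <- match.arg(metric)
  seqs <- if (inherits(aln, "gene_alignment")) aln$seqs else aln
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 rows for a distance matrix")
  enc <- lapply(seqs, encode_dna)
  ids <- names(seqs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  bad <- character(0)
  for (i in seq_len(n - 1L)) {
    ei <- enc[[i]]
    for (j in (i + 1L):n) {
      ej <- enc[[j]]
      comp <- !is.na(ei) & !is.na(ej)
      L <- sum(comp)
      if (L == 0L) { bad <- c(bad, paste(ids[i], ids[j], sep = "~")); next }
      diffs <- sum(ei[comp] != ej[comp])
      d <- if (metric == "p") diffs / L else
        min(max(1 - (5 * (L - diffs) - 4 * diffs) / (5 * L), 0), 1)
      m[i, j] <- d; m[j, i] <- d
    }
  }
  if (length(bad) > 0L) {
    stop("undefined distance (no comparable columns) for pairs: ",
         paste(bad, collapse = ", "))
  }
  distance_matrix(m)
}
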