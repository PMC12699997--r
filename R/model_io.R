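#' Read a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector,
#' preserving case: lowercase bases carry soft-masking (repeat annotation)
#' and must survive the round trip. Record ids are the header token up to
#' the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA (sequence before first header): ", path)
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  ids <- vapply(recs, function(x) attr(x, "name"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(recs, function(x) as.character(x)[[1]], character(1))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (case preserved).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Construct a per-gene alignment
#'
#' The basic container for one locus: a named character vector of
#' equal-length aligned sequences keyed by sample id.
#'
#' @param seqs Named character vector; all elements the same length.
#' @param gene_id Locus identifier.
#' @return A `gene_alignment` object.
#' @export
gene_alignment <- function(seqs, gene_id = "gene") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows must have unique sample ids")
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop("alignment rows differ in length for gene ", gene_id, ": ",
         paste(lens, collapse = ", "))
  }
  if (lens < 1L) stop("alignment must have at least 1 column")
  structure(list(gene_id = gene_id, seqs = seqs, length = lens),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d sequences x %d columns\n",
              x$gene_id, length(x$seqs), x$length))
  invisible(x)
}

#' @export
length.gene_alignment <- function(x) x$length

#' Read a directory of per-gene aligned FASTA files
#'
#' One file per gene; the file stem is the gene id.
#'
#' @param dir Directory containing `<gene_id>.fasta` files.
#' @param pattern Filename pattern for alignment files.
#' @return Named list of [gene_alignment()] objects (a gene set).
#' @export
read_alignment_dir <- function(dir, pattern = "\\.fa(sta)?$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  ids <- sub("\\.fa(sta)?$", "", basename(files))
  genes <- purrr::map2(files, ids, function(f, id) {
    gene_alignment(read_fasta(f), gene_id = id)
  })
  names(genes) <- ids
  genes
}

#' Write a gene set to a directory of FASTA files
#' @param genes Named list of [gene_alignment()] objects.
#' @param dir Output directory (created if needed).
#' @export
write_alignment_dir <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genes) write_fasta(g$seqs, file.path(dir, paste0(g$gene_id, ".fasta")))
  invisible(dir)
}

#' Read a Newick tree
#'
#' Parses Newick with optional branch lengths and internal support labels,
#' and returns the tree unrooted (a degree-2 root is collapsed). Supports
#' live on internal edges, attached to the child node as in standard Newick.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object, unrooted.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  validate_tree(tr)
}

#' Validate and canonicalize a phylogenetic tree
#'
#' Checks leaf-label uniqueness and non-negative branch lengths, and
#' unroots the tree (RF and concordance machinery operate on unrooted
#' bipartitions).
#'
#' @param tree An [ape::phylo] object.
#' @return The validated, unrooted tree.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    if (any(tree$edge.length < 0, na.rm = TRUE)) {
      stop("negative branch lengths")
    }
    tree$edge.length[is.na(tree$edge.length)] <- 0  # absent lengths = 0
  }
  if (ape::is.rooted(tree) && ape::Ntip(tree) >= 3L) {
    tree <- ape::unroot(tree)
  }
  tree
}

#' Write a tree to Newick
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a labeled distance matrix
#'
#' Validates symmetry (within 1e-12), a zero diagonal and non-negativity.
#'
#' @param m Square numeric matrix with identical row/column names.
#' @return The validated matrix with class `distance_matrix`.
#' @export
distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("distance matrix needs identical row and column labels")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate labels in distance matrix")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  class(m) <- c("distance_matrix", "matrix", "array")
  m
}

#' Write a labeled matrix as CSV
#'
#' Writes a completeness or distance matrix with a header row of column ids
#' and one row per sample/label; values carry 4 decimal places.
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param row_label Name of the first (row-id) column in the header.
#' @export
write_matrix_csv <- function(m, path, row_label = "sample") {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L) {
    stop("cannot write an empty matrix")
  }
  header <- paste(c(row_label, colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.4f", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a labeled matrix from CSV written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a species map (sample id to species name)
#'
#' @param path TSV with two columns: sample_id, species.
#' @return Named character vector, sample id to species.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("species map needs two columns: sample_id, species")
  sp <- as.character(df[[2]])
  names(sp) <- as.character(df[[1]])
  if (anyDuplicated(names(sp))) stop("duplicate sample ids in species map")
  sp
}
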