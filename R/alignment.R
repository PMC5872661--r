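#' Build an alignment matrix from aligned rows
#'
#' The alignment matrix is the central container for variant calling: equal
#' length rows over `{A,C,G,T,N,-}` plus, per genotype, a column map giving the
#' ungapped 1-based genome coordinate of every alignment column (`NA` at gaps).
#'
#' @param rows Named character vector of aligned sequences (names are genotype
#'   ids).
#' @return An object of class `plast_alignment` with elements `ids`, `rows`,
#'   `mat` (base-by-column character matrix, genotypes in rows), `width`,
#'   `column_map` (list of integer vectors) and `pos_to_col` (list of integer
#'   vectors mapping genome coordinate to alignment column).
#' @export
alignment_matrix <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)), all(nzchar(names(rows))))
  if (anyDuplicated(names(rows))) stop("duplicate alignment ids", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  rows <- toupper(rows)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  column_map <- purrr::map(names(rows), function(id) {
    gap <- mat[id, ] == "-"
    cm <- cumsum(!gap)
    cm[gap] <- NA_integer_
    as.integer(cm)
  })
  names(column_map) <- names(rows)
  pos_to_col <- purrr::map(column_map, ~ which(!is.na(.x)))
  structure(
    list(ids = names(rows), rows = rows, mat = mat, width = widths[[1]],
         column_map = column_map, pos_to_col = pos_to_col),
    class = "plast_alignment"
  )
}

#' @export
print.plast_alignment <- function(x, ...) {
  cat(sprintf("<plast_alignment> %d genotypes x %s columns (%s)\n",
              length(x$ids), format(x$width, big.mark = ","),
              paste(x$ids, collapse = ", ")))
  invisible(x)
}

#' Read a multiple sequence alignment and check it against the genomes
#'
#' Reads an aligned FASTA (e.g. a MAFFT full-plastome alignment of collinear
#' genomes) and verifies that ungapping each row reproduces the corresponding
#' genome sequence exactly.
#'
#' @param path Aligned FASTA path.
#' @param genomes Optional `genome_set`; when given, alignment ids must be a
#'   subset of genome ids and ungapped rows must match the genome sequences.
#' @return A [alignment_matrix()] object.
#' @export
read_alignment <- function(path, genomes = NULL) {
  ss <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(ss))
  names(rows) <- stringr::str_extract(names(ss), "^\\S+")
  aln <- alignment_matrix(rows)
  if (!is.null(genomes)) check_alignment_genomes(aln, genomes)
  aln
}

check_alignment_genomes <- function(aln, genomes) {
  unknown <- setdiff(aln$ids, names(genomes))
  if (length(unknown)) {
    stop("alignment ids not in genome set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (id in aln$ids) {
    ungapped <- gsub("-", "", aln$rows[[id]], fixed = TRUE)
    gseq <- genomes[[id]]$seq
    if (!identical(ungapped, gseq)) {
      diff_at <- which(seq_chars(ungapped)[seq_len(min(nchar(ungapped), nchar(gseq)))] !=
                       seq_chars(gseq)[seq_len(min(nchar(ungapped), nchar(gseq)))])
      first <- if (length(diff_at)) diff_at[[1]] else min(nchar(ungapped), nchar(gseq)) + 1L
      stop(sprintf(
        "ungapped alignment row '%s' differs from its genome at position %d",
        id, first), call. = FALSE)
    }
  }
  invisible(aln)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln A `plast_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Alignment column of genome position `pos` in genotype `id`.
col_of_pos <- function(aln, id, pos) aln$pos_to_col[[id]][pos]

# Genome position at alignment column `col` for genotype `id` (NA at gaps).
pos_at_col <- function(aln, id, col) aln$column_map[[id]][col]
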