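#' Construct a genome record
#'
#' A genome record holds one plastome: a genotype label, an uppercase DNA
#' sequence over `{A,C,G,T,N}`, a circularity flag and an optional feature
#' table (see [feature_table()]).
#'
#' @param id Genotype label, e.g. `"XSW"`.
#' @param seq DNA sequence; lowercase is uppercased, other IUPAC codes are
#'   mapped to `N` with a warning.
#' @param circular Is the molecule circular? Plastomes are; default `TRUE`.
#' @param features Optional feature table (tibble with columns `kind`, `name`,
#'   `start`, `end`, `strand`).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, seq, circular = TRUE, features = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalise_seq(seq, id)
  if (nchar(seq) == 0L) stop("empty sequence for genome '", id, "'", call. = FALSE)
  if (!is.null(features)) features <- validate_features(features, nchar(seq))
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular), features = features),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, GC %.1f%%, %s\n",
              x$id, format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              100 * gc_fraction(x$seq),
              if (is.null(x$features)) "no features"
              else paste(nrow(x$features), "features")))
  invisible(x)
}

#' @export
length.genome_record <- function(x) nchar(x$seq)

#' Tidy a genome set into a per-genotype summary
#'
#' @param x A list of `genome_record` objects as returned by [read_genomes()].
#' @param ... Unused.
#' @return A tibble with one row per genotype: `id`, `length`, `gc`,
#'   `circular`, `n_features`.
#' @method tidy genome_set
#' @export
tidy.genome_set <- function(x, ...) {
  purrr::map_dfr(x, function(g) tibble(
    id = g$id, length = nchar(g$seq), gc = gc_fraction(g$seq),
    circular = g$circular,
    n_features = if (is.null(g$features)) 0L else nrow(g$features)
  ))
}

#' Validate and normalise a feature table
#'
#' Feature tables label genomic context (gene/CDS/tRNA/rRNA/intron/spacer).
#' Multi-interval features (e.g. the trans-spliced rps12) occupy several rows
#' sharing one `name`.
#'
#' @param features A data frame with columns `kind`, `name`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param genome_len Genome length used to range-check spans.
#' @return The validated tibble.
#' @export
feature_table <- function(features, genome_len) validate_features(features, genome_len)

validate_features <- function(features, genome_len) {
  features <- as_tibble(features)
  needed <- c("kind", "name", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing)) stop("feature table lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start < 1L | features$end > genome_len | features$start > features$end
  if (any(bad)) stop("feature spans outside [1, genome length]: rows ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  features
}

#' Read plastome sequences from FASTA or GenBank flat files
#'
#' Each sequence becomes a [genome_record()]; GenBank feature tables are
#' captured verbatim (no re-annotation). Ids must be unique across all files.
#'
#' @param paths Character vector of file paths.
#' @param format `"fasta"` or `"genbank"`.
#' @param circular Circularity flag applied to all records.
#' @return A named list of `genome_record`s (class `genome_set`).
#' @export
read_genomes <- function(paths, format = c("fasta", "genbank"), circular = TRUE) {
  format <- match.arg(format)
  records <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    recs <- switch(format,
      fasta = {
        ss <- Biostrings::readBStringSet(path)
        ids <- stringr::str_extract(names(ss), "^\\S+")
        purrr::map2(ids, as.character(ss), genome_record, circular = circular)
      },
      genbank = {
        gb <- read_genbank(path)
        purrr::map(gb, function(r)
          genome_record(r$id, r$seq, circular = circular, features = r$features))
      }
    )
    records <- c(records, recs)
  }
  ids <- purrr::map_chr(records, "id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(records) <- ids
  structure(records, class = "genome_set")
}

#' Write a genome set to FASTA
#'
#' @param genomes A `genome_set` or list of `genome_record`s.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(purrr::map_chr(genomes, "seq"))
  names(ss) <- purrr::map_chr(genomes, "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 path.
#' @return A feature tibble (`kind`, `name`, `start`, `end`, `strand`,
#'   `seqid`).
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  name <- if (!is.null(md$Name)) as.character(md$Name) else as.character(md$ID)
  tibble(
    kind = as.character(md$type),
    name = name,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    seqid = as.character(GenomicRanges::seqnames(gr))
  )
}
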