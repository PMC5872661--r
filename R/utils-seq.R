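#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join n row_number desc across all_of if_else first rename
#'   count distinct pull slice transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of plain character DNA (vectorised, keeps N).
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

# GC fraction of a DNA string (N excluded from the denominator).
gc_fraction <- function(x) {
  gc <- stringr::str_count(x, "[GCgc]")
  at <- stringr::str_count(x, "[ATat]")
  ifelse(gc + at == 0, NA_real_, gc / (gc + at))
}

# Split a string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Substring by 1-based inclusive interval, with circular wrap when the genome
# is circular and the interval runs off either end.
subseq_circ <- function(seq, start, end) {
  n <- nchar(seq)
  if (start >= 1 && end <= n) return(substr(seq, start, end))
  doubled <- paste0(seq, seq)
  if (start < 1) {
    start <- start + n
    end <- end + n
  }
  substr(doubled, start, end)
}

# Normalise raw sequence text: uppercase, map non-ACGTN IUPAC codes to N.
normalise_seq <- function(x, id = "?") {
  x <- toupper(x)
  if (stringr::str_detect(x, "[^ACGTN]")) {
    n_bad <- stringr::str_count(x, "[^ACGTN]")
    warning(sprintf("%d non-ACGTN residues in '%s' mapped to N", n_bad, id),
            call. = FALSE)
    x <- stringr::str_replace_all(x, "[^ACGTN]", "N")
  }
  x
}

# Rotate a linear representation of a circular sequence so that 1-based
# position `start` becomes position 1.
rotate_seq <- function(seq, start) {
  n <- nchar(seq)
  start <- ((start - 1) %% n) + 1
  if (start == 1) return(seq)
  paste0(substr(seq, start, n), substr(seq, 1, start - 1))
}

#' Convert between 1-based inclusive and BED (0-based half-open) intervals
#'
#' Internal coordinates throughout the package are 1-based inclusive; BED
#' output is 0-based half-open. The two converters are exact inverses.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A two-column tibble `start`, `end` in the target convention.
#' @export
to_bed_interval <- function(start, end) {
  tibble(start = start - 1L, end = as.integer(end))
}

#' @rdname to_bed_interval
#' @export
from_bed_interval <- function(start, end) {
  tibble(start = as.integer(start) + 1L, end = as.integer(end))
}
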