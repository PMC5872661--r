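# Microstructural events from the alignment: indel extraction with
# reference-polarized direction, SSR-related vs common classification, indel
# size spectra, and small-inversion detection with the flanking
# inverted-repeat (stem-loop) rule.

#' Extract indel events from the alignment
#'
#' Maximal runs of contiguous alignment columns with a constant gap/base
#' pattern across genotypes become one event (a gap run shared by several
#' genotypes is a single event). Within a run, columns at which the
#' present (non-gap) genotypes disagree in sequence split the event at the
#' disagreement point; such single columns are flagged `mixed`. Direction
#' is polarized against the standard reference genotype: a genotype carrying
#' sequence where the reference has a gap shows an insertion, a genotype
#' carrying a gap where the reference has sequence shows a deletion.
#'
#' @param aln A [alignment_matrix()].
#' @param ref_id Reference genotype id.
#' @param structure Optional `quadripartite` structure of the reference for
#'   region labels.
#' @param features Optional reference feature table for genic context.
#' @return Tibble with one row per event: `aln_start`, `aln_end`, `size`,
#'   `ref_start`, `ref_end` (1-based inclusive; `ref_end < ref_start` marks a
#'   zero-length reference interval, i.e. an insertion relative to the
#'   reference), `ref_has_seq`, `allele_present`, `gapped_genotypes`,
#'   `polarity` (list column of named per-genotype labels
#'   insertion/deletion/reference-state), `mixed`, `region`, `context`,
#'   `context_name`.
#' @export
extract_indels <- function(aln, ref_id, structure = NULL, features = NULL) {
  stopifnot(inherits(aln, "plast_alignment"), ref_id %in% aln$ids)
  mat <- aln$mat
  gaps <- mat == "-"
  any_gap <- colSums(gaps) > 0L
  if (any(colSums(gaps) == nrow(mat))) {
    stop("malformed alignment: column(s) with gaps in all genotypes: ",
         paste(utils::head(which(colSums(gaps) == nrow(mat)), 5),
               collapse = ", "), call. = FALSE)
  }
  if (!any(any_gap)) return(empty_indel_tibble())

  # per-column key: the gap pattern, bit-packed over genotypes
  pattern_key <- rep(NA_character_, ncol(mat))
  gcols <- which(any_gap)
  pattern_key[gcols] <- apply(gaps[, gcols, drop = FALSE], 2, function(g)
    paste(which(g), collapse = ","))
  # present genotypes must agree per column; disagreement columns split events
  agree <- rep(TRUE, ncol(mat))
  agree[gcols] <- vapply(gcols, function(cc) {
    b <- mat[!gaps[, cc], cc]
    length(unique(b)) == 1L
  }, logical(1))

  run_id <- cumsum(
    c(TRUE, !(any_gap[-1] & any_gap[-length(any_gap)] &
                pattern_key[-1] == pattern_key[-length(pattern_key)] &
                agree[-1] & agree[-length(agree)]))
  )
  events <- list()
  for (piece in split(gcols, run_id[gcols])) {
    c1 <- piece[1]; c2 <- piece[length(piece)]
    events[[length(events) + 1L]] <-
      make_indel_event(aln, ref_id, c1, c2, gaps, agree)
  }
  out <- bind_rows(events)
  anchor <- pmax(out$ref_start, 1L)
  if (!is.null(structure)) {
    out$region <- region_of(pmin(anchor, structure$genome_len), structure,
                            collapse = TRUE)
  } else {
    out$region <- NA_character_
  }
  ctx <- annotate_context(anchor, features,
                          if (is.null(structure)) .Machine$integer.max
                          else structure$genome_len)
  out$context <- ctx$context
  out$context_name <- ctx$context_name
  out
}

make_indel_event <- function(aln, ref_id, c1, c2, gaps, agree) {
  mat <- aln$mat
  ids <- aln$ids
  span <- c1:c2
  gapped <- ids[gaps[, c1]]
  present <- setdiff(ids, gapped)
  mixed <- !all(agree[span])
  allele <- if (mixed || !length(present)) NA_character_
            else paste(mat[present[1], span], collapse = "")
  ref_gapped <- ref_id %in% gapped
  cm <- aln$column_map[[ref_id]]
  if (!ref_gapped) {
    ref_start <- cm[c1]; ref_end <- cm[c2]
  } else {
    prev <- if (c1 > 1L) suppressWarnings(max(cm[1:(c1 - 1L)], na.rm = TRUE)) else 0L
    if (!is.finite(prev)) prev <- 0L
    ref_start <- prev + 1L; ref_end <- prev  # zero-length interval
  }
  polarity <- stats::setNames(rep("reference-state", length(ids)), ids)
  if (ref_gapped) polarity[present] <- "insertion"
  else polarity[gapped] <- "deletion"
  tibble(
    aln_start = c1, aln_end = c2, size = c2 - c1 + 1L,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    ref_has_seq = !ref_gapped,
    allele_present = allele,
    gapped_genotypes = paste(gapped, collapse = ","),
    polarity = list(polarity),
    mixed = mixed
  )
}

empty_indel_tibble <- function() {
  tibble(aln_start = integer(), aln_end = integer(), size = integer(),
         ref_start = integer(), ref_end = integer(), ref_has_seq = logical(),
         allele_present = character(), gapped_genotypes = character(),
         polarity = list(), mixed = logical(), region = character(),
         context = character(), context_name = character())
}

#' Separate SSR-related from common indels
#'
#' An event is SSR-related when (a) its present allele is a whole-number
#' tandem repetition of some rotation of the repeat unit of an SSR locus at
#' the site, and (b) its alignment span overlaps or directly abuts
#' (distance 0) that locus's tract in any genotype. All other events are
#' common indels (the class the size spectrum and indel reports are built
#' from).
#'
#' @param events Indel tibble from [extract_indels()].
#' @param loci SSR locus tibble across all genotypes (as passed to
#'   [compare_ssrs()]).
#' @param aln The [alignment_matrix()] both were derived from.
#' @return List with elements `common` and `ssr_related`; both carry an
#'   `ssr_related` flag column.
#' @export
filter_ssr_indels <- function(events, loci, aln) {
  if (!nrow(events)) {
    events$ssr_related <- logical(0)
    return(list(common = events, ssr_related = events))
  }
  if (nrow(loci)) {
    loci <- loci %>% mutate(
      aln_start = purrr::map2_int(.data$genotype, .data$start,
                                  ~ as.integer(col_of_pos(aln, .x, .y))),
      aln_end = purrr::map2_int(.data$genotype, .data$end,
                                ~ as.integer(col_of_pos(aln, .x, .y)))
    )
  }
  events$ssr_related <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (!nrow(loci) || is.na(ev$allele_present)) return(FALSE)
    near <- loci$aln_start <= ev$aln_end + 1L & loci$aln_end >= ev$aln_start - 1L
    if (!any(near)) return(FALSE)
    any(vapply(which(near), function(j)
      allele_is_unit_multiple(ev$allele_present, loci$motif[j]), logical(1)))
  }, logical(1))
  list(common = events %>% filter(!.data$ssr_related),
       ssr_related = events %>% filter(.data$ssr_related))
}

# Is `allele` a whole-number tandem repetition of some rotation of `motif`?
allele_is_unit_multiple <- function(allele, motif) {
  u <- nchar(motif)
  if (nchar(allele) %% u != 0L) return(FALSE)
  k <- nchar(allele) %/% u
  rots <- vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1, i - 1)), character(1))
  any(vapply(rots, function(m) allele == strrep(m, k), logical(1)))
}

#' Indel size spectrum and regional frequencies
#'
#' @param common Common-indel tibble (e.g. `filter_ssr_indels()$common`).
#' @return Object of class `indel_spectrum` with `by_size` (counts for every
#'   size 1..max observed) and `by_region` (counts and relative frequencies by
#'   collapsed region).
#' @export
indel_size_spectrum <- function(common) {
  if (!nrow(common)) {
    return(structure(list(
      by_size = tibble(size = integer(), count = integer()),
      by_region = tibble(region = character(), count = integer(),
                         freq = numeric())
    ), class = "indel_spectrum"))
  }
  sizes <- tibble(size = seq_len(max(common$size))) %>%
    left_join(common %>% count(.data$size, name = "count"), by = "size") %>%
    mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count)))
  regions <- common %>%
    count(.data$region, name = "count") %>%
    mutate(freq = .data$count / sum(.data$count))
  structure(list(by_size = sizes, by_region = regions),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  total <- sum(x$by_size$count)
  modal <- if (total) x$by_size$size[which.max(x$by_size$count)] else NA
  cat(sprintf("<indel_spectrum> %d common indels, modal size %s bp\n",
              total, modal))
  invisible(x)
}

#' @method tidy indel_spectrum
#' @export
#' @rdname indel_size_spectrum
tidy.indel_spectrum <- function(x, ...) x$by_size

#' Detect small inversions verified by flanking inverted repeats
#'
#' Candidate cores are maximal runs of gap-free mismatch columns between the
#' reference and each genotype (runs separated by at most `merge_gap` matching
#' columns are also considered jointly, since an inverted core may agree with
#' the reference at internally mirrored-complementary positions). A candidate
#' is an inversion when the genotype's core equals the reverse complement of
#' the reference core. Up to `flank_window` bases on each side of the core are
#' then searched for the longest exact inverted-repeat pair bracketing the
#' core; the candidate is reported when that stem is at least `min_stem` bp
#' (the hairpin rule: stem = flanking repeat, loop = inverted core). Mismatch
#' runs failing the reverse-complement test are left to the SNP caller.
#'
#' @param aln A [alignment_matrix()].
#' @param ref_id Reference genotype id.
#' @param min_len,max_len Core length bounds (bp).
#' @param flank_window Bases searched on each side for the stem.
#' @param min_stem Minimum stem (flanking repeat) length in bp.
#' @param merge_gap Maximum internal matching-column gap when joining mismatch
#'   runs into one candidate core.
#' @param structure,features Optional reference structure/features for labels.
#' @return Tibble with one row per inversion: `aln_start`, `aln_end`,
#'   `length`, `ref_start`, `ref_end`, `inverted_genotypes`, `core_ref`,
#'   `core_inverted`, `flank_repeat_len`, `loop_len`, `stem_loop_ok`,
#'   `palindromic_core`, `region`, `context`, `context_name`.
#' @export
detect_inversions <- function(aln, ref_id, min_len = 2L, max_len = 100L,
                              flank_window = 30L, min_stem = 6L,
                              merge_gap = 2L, structure = NULL,
                              features = NULL) {
  stopifnot(inherits(aln, "plast_alignment"), ref_id %in% aln$ids)
  mat <- aln$mat
  ref_row <- mat[ref_id, ]
  ref_seq <- gsub("-", "", aln$rows[[ref_id]], fixed = TRUE)
  cm <- aln$column_map[[ref_id]]
  found <- list()
  for (g in setdiff(aln$ids, ref_id)) {
    q_row <- mat[g, ]
    solid <- ref_row != "-" & q_row != "-" & ref_row %in% DNA_BASES &
      q_row %in% DNA_BASES
    mism <- solid & ref_row != q_row
    cand <- inversion_candidates(mism, solid, merge_gap)
    for (sp in cand) {
      len <- sp[2] - sp[1] + 1L
      if (len < min_len || len > max_len) next
      core_ref <- paste(ref_row[sp[1]:sp[2]], collapse = "")
      core_q <- paste(q_row[sp[1]:sp[2]], collapse = "")
      if (!identical(core_q, revcomp(core_ref))) next
      p1 <- cm[sp[1]]; p2 <- cm[sp[2]]
      stem <- stem_length(ref_seq, p1, p2, flank_window)
      if (stem < min_stem) next
      found[[length(found) + 1L]] <- tibble(
        genotype = g, aln_start = sp[1], aln_end = sp[2], length = len,
        ref_start = as.integer(p1), ref_end = as.integer(p2),
        core_ref = core_ref, core_inverted = core_q,
        flank_repeat_len = stem
      )
    }
  }
  if (!length(found)) return(empty_inversion_tibble())
  out <- bind_rows(found) %>%
    group_by(.data$aln_start, .data$aln_end, .data$length, .data$ref_start,
             .data$ref_end, .data$core_ref, .data$core_inverted,
             .data$flank_repeat_len) %>%
    summarise(inverted_genotypes = paste(sort(.data$genotype), collapse = ","),
              .groups = "drop") %>%
    # overlapping candidates (a merged cluster and its sub-runs can both
    # pass for palindrome-structured cores): keep the longest span
    arrange(desc(.data$length), .data$aln_start)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(out$aln_start[prior] <= out$aln_end[i] &
            out$aln_end[prior] >= out$aln_start[i])) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE] %>%
    mutate(loop_len = .data$length, stem_loop_ok = TRUE,
           palindromic_core = .data$core_ref == revcomp(.data$core_ref))
  if (!is.null(structure)) {
    out$region <- region_of(pmin(out$ref_start, structure$genome_len),
                            structure, collapse = TRUE)
  } else {
    out$region <- NA_character_
  }
  ctx <- annotate_context(out$ref_start, features,
                          if (is.null(structure)) .Machine$integer.max
                          else structure$genome_len)
  out$context <- ctx$context
  out$context_name <- ctx$context_name
  out %>%
    select("aln_start", "aln_end", "length", "ref_start", "ref_end",
           "inverted_genotypes", "core_ref", "core_inverted",
           "flank_repeat_len", "loop_len", "stem_loop_ok", "palindromic_core",
           "region", "context", "context_name") %>%
    arrange(.data$aln_start)
}

empty_inversion_tibble <- function() {
  tibble(aln_start = integer(), aln_end = integer(), length = integer(),
         ref_start = integer(), ref_end = integer(),
         inverted_genotypes = character(), core_ref = character(),
         core_inverted = character(), flank_repeat_len = integer(),
         loop_len = integer(), stem_loop_ok = logical(),
         palindromic_core = logical(), region = character(),
         context = character(), context_name = character())
}

# Candidate core spans: maximal runs of mismatch columns, plus clusters of
# runs whose internal gaps are gap-free matching columns of length <=
# merge_gap. Returns a list of c(start, end) column pairs.
inversion_candidates <- function(mism, solid, merge_gap) {
  r <- rle(mism)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(list())
  spans <- purrr::map(runs, ~ c(starts[.x], ends[.x]))
  if (merge_gap > 0L && length(runs) > 1L) {
    cl_start <- spans[[1]][1]; cl_end <- spans[[1]][2]; cl_n <- 1L
    for (i in seq_along(spans)[-1]) {
      gap_cols <- (cl_end + 1L):(spans[[i]][1] - 1L)
      joinable <- (spans[[i]][1] - cl_end - 1L) <= merge_gap &&
        all(solid[gap_cols])
      if (joinable) {
        cl_end <- spans[[i]][2]; cl_n <- cl_n + 1L
      } else {
        if (cl_n > 1L) spans[[length(spans) + 1L]] <- c(cl_start, cl_end)
        cl_start <- spans[[i]][1]; cl_end <- spans[[i]][2]; cl_n <- 1L
      }
    }
    if (cl_n > 1L) spans[[length(spans) + 1L]] <- c(cl_start, cl_end)
  }
  spans
}

# Longest exact inverted-repeat pair bracketing the reference interval
# [p1, p2]: grows outward base by base while the upstream base equals the
# complement of the downstream base.
stem_length <- function(ref_seq, p1, p2, flank_window) {
  n <- nchar(ref_seq)
  f <- 0L
  while (f < flank_window && p1 - f - 1L >= 1L && p2 + f + 1L <= n) {
    left <- substr(ref_seq, p1 - f - 1L, p1 - f - 1L)
    right <- substr(ref_seq, p2 + f + 1L, p2 + f + 1L)
    if (left == "N" || right != chartr("ACGTN", "TGCAN", left)) break
    f <- f + 1L
  }
  f
}

#' Hairpin (stem-loop) statistics of detected inversions
#'
#' The stem is the flanking inverted repeat, the loop the inverted core; a
#' hairpin is accepted when the stem is at least `min_stem` bp.
#'
#' @param inversions Tibble from [detect_inversions()].
#' @param min_stem Minimum stem length.
#' @return Tibble with `stem_len`, `loop_len`, `stem_loop_ok` per inversion.
#' @export
hairpin_stats <- function(inversions, min_stem = 6L) {
  inversions %>%
    transmute(stem_len = .data$flank_repeat_len, loop_len = .data$loop_len,
              stem_loop_ok = .data$flank_repeat_len >= min_stem)
}
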