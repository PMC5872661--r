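# SSR (microsatellite) mining with MISA-style per-motif-length unit-count
# thresholds, overlap deduplication, compound-locus merging and cross-genotype
# polymorphism calling anchored through the multiple alignment.

#' Default SSR unit-count thresholds
#'
#' Minimum numbers of repeat units for mono- through hexanucleotide motifs
#' (MISA convention: a qualifying mononucleotide tract has >= 10 units =
#' 10 bp, a pentanucleotide tract >= 3 units = 15 bp).
#' @export
SSR_THRESHOLDS <- c(10L, 5L, 4L, 3L, 3L, 3L)

#' Mine perfect and compound SSR loci from one genome
#'
#' Finds all maximal perfect tandem repeats of unit length 1-6 meeting the
#' per-unit-length thresholds. Repeats whose unit is itself a tandem
#' repetition of a shorter unit are reported at the shorter unit length only;
#' overlapping loci are resolved by [deduplicate_ssrs()]; qualifying repeats
#' separated by at most `compound_max_gap` bases are merged into one compound
#' locus (e.g. `(ATA)4g(TAA)6`, interruption in lowercase). When a structure
#' is supplied, loci entirely inside IRa are suppressed so each IR locus is
#' counted once, and loci are labeled with their collapsed region.
#'
#' @param genome A [genome_record()] (canonicalized if a structure is given).
#' @param thresholds Integer vector of six minimum unit counts for unit
#'   lengths 1-6.
#' @param compound_max_gap Maximum interruption (bp) between two qualifying
#'   repeats merged into one compound locus.
#' @param structure Optional `quadripartite` structure for region labels and
#'   IRa suppression.
#' @param features Optional feature table for genic context.
#' @return Tibble with one row per locus: `genotype`, `start`, `end`,
#'   `tract_len`, `motif`, `unit_len`, `n_units`, `n_parts`, `compound`,
#'   `ssr_type`, `canonical_class`, `region`, `context`, `context_name`.
#' @export
detect_ssrs <- function(genome, thresholds = SSR_THRESHOLDS,
                        compound_max_gap = 100L, structure = NULL,
                        features = NULL) {
  stopifnot(inherits(genome, "genome_record"), length(thresholds) == 6L)
  runs <- mine_perfect_repeats(genome$seq, thresholds)
  runs <- deduplicate_ssrs(runs)
  loci <- merge_compound_loci(genome$seq, runs, compound_max_gap)
  loci$genotype <- genome$id
  if (!is.null(structure) && structure$has_ir) {
    ira <- structure$regions[structure$regions$region == "IRa", ]
    loci <- loci %>% filter(!(.data$start >= ira$start & .data$end <= ira$end))
    loci$region <- region_of(pmin(loci$start, structure$genome_len), structure,
                             collapse = TRUE)
  } else {
    loci$region <- if (is.null(structure)) NA_character_ else "whole"
  }
  feats <- if (is.null(features)) genome$features else features
  ctx <- annotate_context(loci$start, feats, nchar(genome$seq))
  loci$context <- ctx$context
  loci$context_name <- ctx$context_name
  loci %>% select("genotype", "start", "end", "tract_len", "motif", "unit_len",
                  "n_units", "n_parts", "compound", "ssr_type",
                  "canonical_class", "region", "context", "context_name")
}

# All maximal perfect tandem repeats with primitive motifs meeting the
# thresholds, one row per repeat (no dedup, no compounds).
mine_perfect_repeats <- function(seq, thresholds) {
  n <- nchar(seq)
  chars <- seq_chars(seq)
  ok <- chars %in% DNA_BASES
  out <- list()
  for (u in 1:6) {
    if (n < u * thresholds[u]) next
    eq <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
      ok[seq_len(n - u)] & ok[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) %/% u >= thresholds[u])
    for (h in hit) {
      i <- starts[h]
      n_units <- (r$lengths[h] + u) %/% u
      motif <- substr(seq, i, i + u - 1L)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- list(start = i, end = i + n_units * u - 1L,
                                      unit_len = u, n_units = n_units,
                                      motif = motif)
    }
  }
  if (!length(out)) return(empty_repeat_tibble())
  tibble(
    start = vapply(out, function(x) as.integer(x$start), integer(1)),
    end = vapply(out, function(x) as.integer(x$end), integer(1)),
    unit_len = vapply(out, function(x) as.integer(x$unit_len), integer(1)),
    n_units = vapply(out, function(x) as.integer(x$n_units), integer(1)),
    motif = vapply(out, function(x) x$motif, character(1))
  ) %>% mutate(tract_len = .data$end - .data$start + 1L)
}

empty_repeat_tibble <- function() {
  tibble(start = integer(), end = integer(), unit_len = integer(),
         n_units = integer(), motif = character(), tract_len = integer())
}

# A motif is primitive when it is not a whole-number repetition of any
# shorter unit.
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && motif == strrep(substr(motif, 1L, d), u %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Resolve overlapping SSR loci
#'
#' Overlaps are resolved by keeping the locus with the greater tract length;
#' ties go to the smaller unit length, remaining ties to the leftmost locus.
#'
#' @param loci Repeat tibble for one genotype (columns `start`, `end`,
#'   `unit_len`, `tract_len`, ...).
#' @return The overlap-free subset, ordered by `start`.
#' @export
deduplicate_ssrs <- function(loci) {
  if (!nrow(loci)) return(loci)
  ord <- order(-loci$tract_len, loci$unit_len, loci$start)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(loci$start[kept] <= loci$end[i] &
                 loci$end[kept] >= loci$start[i])
    if (!clash) kept <- c(kept, i)
  }
  loci[sort(kept), , drop = FALSE] %>% arrange(.data$start)
}

# Merge qualifying repeats separated by <= compound_max_gap bases into
# compound loci and format the MISA-like ssr_type string.
merge_compound_loci <- function(seq, runs, compound_max_gap) {
  if (!nrow(runs)) {
    return(tibble(start = integer(), end = integer(), tract_len = integer(),
                  motif = character(), unit_len = integer(),
                  n_units = integer(), n_parts = integer(),
                  compound = logical(), ssr_type = character(),
                  canonical_class = character()))
  }
  runs <- runs %>% arrange(.data$start)
  gap_prev <- c(Inf, runs$start[-1] - runs$end[-nrow(runs)] - 1L)
  grp <- cumsum(gap_prev > compound_max_gap)
  purrr::map_dfr(split(runs, grp), function(g) {
    parts <- purrr::map_chr(seq_len(nrow(g)), function(i) {
      sprintf("(%s)%d", g$motif[i], g$n_units[i])
    })
    inter <- if (nrow(g) > 1L) {
      purrr::map_chr(seq_len(nrow(g) - 1L), function(i) {
        if (g$start[i + 1L] - g$end[i] == 1L) ""
        else tolower(substr(seq, g$end[i] + 1L, g$start[i + 1L] - 1L))
      })
    } else character(0)
    type <- paste0(parts[1],
                   paste0(inter, parts[-1], collapse = ""), collapse = "")
    cls <- sort(unique(vapply(g$motif, canonical_motif_class, character(1))))
    tibble(
      start = g$start[1], end = g$end[nrow(g)],
      tract_len = g$end[nrow(g)] - g$start[1] + 1L,
      motif = g$motif[1], unit_len = g$unit_len[1], n_units = g$n_units[1],
      n_parts = nrow(g), compound = nrow(g) > 1L, ssr_type = type,
      canonical_class = paste(cls, collapse = "+")
    )
  }) %>% arrange(.data$start)
}

#' Canonical motif class
#'
#' Collapses a repeat motif over its rotations and reverse complement, so that
#' e.g. `A` and `T` tracts share class `"A/T"` and `AT`/`TA` share `"AT"`.
#'
#' @param motif Repeat unit as found on the forward strand.
#' @return Class label string.
#' @export
canonical_motif_class <- function(motif) {
  rots <- function(m) {
    u <- nchar(m)
    vapply(seq_len(u), function(i) paste0(substr(m, i, u), substr(m, 1, i - 1)),
           character(1))
  }
  fwd <- min(rots(motif))
  rev <- min(rots(revcomp(motif)))
  paste(sort(unique(c(fwd, rev))), collapse = "/")
}

#' Call cross-genotype SSR length polymorphisms
#'
#' Loci mined per genotype are matched across genotypes through the alignment:
#' loci with the same canonical motif class whose tracts overlap in alignment
#' columns form one locus cluster. Per-genotype tract lengths are tabulated; a
#' genotype lacking a qualifying tract at an anchored locus is measured anyway
#' and recorded with its actual (sub-threshold) tract length. A locus is
#' polymorphic when the genotypes carrying a tract show at least two distinct
#' tract lengths.
#'
#' @param loci Tibble of SSR loci for all genotypes ([detect_ssrs()] rows
#'   bound together, `genotype` column set).
#' @param aln A [alignment_matrix()] covering every genotype in `loci`.
#' @param genomes Optional `genome_set` used to measure sub-threshold tracts
#'   in genotypes lacking a qualifying locus.
#' @return Tibble with one row per locus cluster: `locus_key`,
#'   `canonical_class`, `motif`, `ssr_type`, `aln_start`, `aln_end`, `region`,
#'   `context`, `context_name`, `n_carriers`, `is_polymorphic`, and
#'   `tract_lengths` / `unit_counts` (list columns of named per-genotype
#'   integers; 0 = locus absent).
#' @export
compare_ssrs <- function(loci, aln, genomes = NULL) {
  stopifnot(inherits(aln, "plast_alignment"))
  if (!nrow(loci)) {
    return(tibble(locus_key = character(), canonical_class = character(),
                  motif = character(), ssr_type = character(),
                  aln_start = integer(), aln_end = integer(),
                  region = character(), context = character(),
                  context_name = character(), n_carriers = integer(),
                  is_polymorphic = logical(), tract_lengths = list(),
                  unit_counts = list()))
  }
  missing_ids <- setdiff(unique(loci$genotype), aln$ids)
  if (length(missing_ids)) {
    stop("loci reference genotypes absent from the alignment: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  loci <- loci %>% mutate(
    aln_start = purrr::map2_int(.data$genotype, .data$start,
                                ~ as.integer(col_of_pos(aln, .x, .y))),
    aln_end = purrr::map2_int(.data$genotype, .data$end,
                              ~ as.integer(col_of_pos(aln, .x, .y)))
  )
  clusters <- loci %>%
    arrange(.data$canonical_class, .data$aln_start) %>%
    group_by(.data$canonical_class) %>%
    mutate(cluster = cumsum(c(TRUE, .data$aln_start[-1] >
                                      cummax(.data$aln_end)[-n()]))) %>%
    ungroup()
  all_ids <- aln$ids
  purrr::map_dfr(
    split(clusters, paste(clusters$canonical_class, clusters$cluster)),
    function(cl) {
      dup <- cl$genotype[duplicated(cl$genotype)]
      if (length(dup)) {
        stop("anchor collision: genotype(s) ", paste(dup, collapse = ", "),
             " carry two same-class loci at alignment columns ",
             min(cl$aln_start), "-", max(cl$aln_end), call. = FALSE)
      }
      span <- c(min(cl$aln_start), max(cl$aln_end))
      lens <- stats::setNames(rep(0L, length(all_ids)), all_ids)
      units <- lens
      lens[cl$genotype] <- cl$tract_len
      units[cl$genotype] <- cl$n_units
      absent <- setdiff(all_ids, cl$genotype)
      if (length(absent) && !is.null(genomes)) {
        for (g in absent) {
          m <- measure_tract(genomes[[g]]$seq, aln, g, span, cl$motif[1])
          lens[g] <- m$tract_len
          units[g] <- m$n_units
        }
      }
      carriers <- lens[lens > 0L]
      ref_row <- which.max(cl$tract_len)
      tibble(
        locus_key = paste0(
          ifelse(is.na(cl$context_name[ref_row]), "anon",
                 cl$context_name[ref_row]),
          ":", cl$canonical_class[ref_row], "@", span[1]),
        canonical_class = cl$canonical_class[ref_row],
        motif = cl$motif[ref_row],
        ssr_type = cl$ssr_type[ref_row],
        aln_start = span[1], aln_end = span[2],
        region = cl$region[ref_row],
        context = cl$context[ref_row],
        context_name = cl$context_name[ref_row],
        n_carriers = length(carriers),
        is_polymorphic = length(unique(carriers)) >= 2L,
        tract_lengths = list(lens),
        unit_counts = list(units)
      )
    }) %>% arrange(.data$aln_start)
}

# Longest tandem run of any rotation of `motif` in the genome window that the
# alignment-column span projects onto for genotype `id`.
measure_tract <- function(seq, aln, id, span, motif) {
  u <- nchar(motif)
  pos <- aln$column_map[[id]][span[1]:span[2]]
  pos <- pos[!is.na(pos)]
  if (!length(pos)) return(list(tract_len = 0L, n_units = 0L))
  lo <- max(1L, min(pos) - u)
  hi <- min(nchar(seq), max(pos) + u)
  window <- substr(seq, lo, hi)
  rots <- unique(vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1, i - 1)), character(1)))
  best <- 0L
  for (m in rots) {
    hits <- gregexpr(sprintf("(?:%s)+", m), window)[[1]]
    if (hits[1] == -1L) next
    lens <- attr(hits, "match.length")
    best <- max(best, max(lens %/% u))
  }
  list(tract_len = as.integer(best * u), n_units = as.integer(best))
}

#' Extract SSR flanking sequences
#'
#' Returns the `flank_len` bases on either side of each locus on the forward
#' strand, ready for an external primer designer. Flanks running off the
#' linearized genome end wrap through the circular origin.
#'
#' @param genome The [genome_record()] the loci were mined from.
#' @param loci Locus tibble with `start`/`end` columns.
#' @param flank_len Flank length in bp (0 gives empty strings).
#' @return `loci` with `left_flank` and `right_flank` columns appended.
#' @export
extract_flanks <- function(genome, loci, flank_len = 250L) {
  stopifnot(inherits(genome, "genome_record"), flank_len >= 0L)
  n <- nchar(genome$seq)
  if (flank_len == 0L) {
    return(loci %>% mutate(left_flank = "", right_flank = ""))
  }
  if (!genome$circular && (any(loci$start - flank_len < 1L) ||
                           any(loci$end + flank_len > n))) {
    stop("flank runs off the end of a linear genome", call. = FALSE)
  }
  loci %>% mutate(
    left_flank = purrr::map_chr(.data$start, function(s)
      subseq_circ(genome$seq, s - flank_len, s - 1L)),
    right_flank = purrr::map_chr(.data$end, function(e)
      subseq_circ(genome$seq, e + 1L, e + flank_len))
  )
}
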