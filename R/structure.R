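# Quadripartite structure: exact inverted-repeat pair detection on the circle,
# canonical rotation/orientation, and region lookup.

#' Delimit the quadripartite structure of a plastome
#'
#' Finds the maximal pair of disjoint, exactly reverse-complementary repeats of
#' length at least `min_ir_len` (the inverted repeats IRb/IRa), assigns the two
#' single-copy arcs so the shorter is SSC, and expresses the result on the
#' canonical rotation: LSC starting at position 1, order LSC, IRb, SSC, IRa.
#' When the orientation is otherwise undetermined the canonical strand is the
#' one whose LSC sequence is lexicographically no greater than its reverse
#' complement, which makes the result deterministic without annotation.
#'
#' Detection seeds `seed_k`-mers of the genome against its reverse complement
#' and extends seed diagonals to maximal exact matches; wrap-around is handled
#' on a doubled sequence, so a rotated input (origin inside any region, even an
#' IR) yields the same structure.
#'
#' @param genome A [genome_record()].
#' @param min_ir_len Minimum IR length in bp. Plastome IRs are typically
#'   >20 kb; the default 1000 only excludes small dispersed repeats.
#' @param seed_k Seed k-mer length (balance between seed uniqueness and
#'   sensitivity).
#' @param canonical Express the result on the canonical rotation/strand
#'   (default). With `canonical = FALSE` the region spans are reported in the
#'   input genome's own coordinates (required when the genome underlies a
#'   multiple alignment whose coordinates must not move); this mode requires
#'   the input to already be region-contiguous, i.e. to start at the LSC
#'   start.
#' @return An object of class `quadripartite` with elements `genome_id`,
#'   `genome_len`, `regions` (tibble: `region`, `start`, `end`, `length`, `gc`
#'   in canonical 1-based inclusive coordinates), `strand` (`"+"` or `"-"`),
#'   `origin` (coordinate on the working strand that becomes canonical
#'   position 1) and `has_ir`. If no inverted repeat of at least `min_ir_len`
#'   exists the result has `has_ir = FALSE` and a single region `"whole"`, and
#'   downstream region labels become `"whole"`.
#' @export
detect_quadripartite <- function(genome, min_ir_len = 1000L, seed_k = 25L,
                                 canonical = TRUE) {
  stopifnot(inherits(genome, "genome_record"))
  s <- genome$seq
  n <- nchar(s)
  if (n <= 2L * min_ir_len) {
    stop("genome length ", n, " is not > 2 * min_ir_len", call. = FALSE)
  }
  pair <- find_ir_pair(s, min_ir_len = min_ir_len, seed_k = seed_k)
  if (is.null(pair)) {
    return(structure(list(
      genome_id = genome$id, genome_len = n,
      regions = tibble(region = "whole", start = 1L, end = n, length = n,
                       gc = gc_fraction(s)),
      strand = "+", origin = 1L, has_ir = FALSE
    ), class = "quadripartite"))
  }
  if (canonical) build_quadripartite(genome$id, s, pair)
  else build_input_structure(genome$id, s, pair)
}

# Structure in the input genome's own coordinates (no rotation, no flip);
# the IR copy following the LSC in input order is IRb.
build_input_structure <- function(id, s, pair) {
  n <- nchar(s)
  res <- orient_spans(s, pair)
  lsc_start <- res$lsc_start
  if (lsc_start != 1L) {
    stop("genome is not region-contiguous (LSC starts at ", lsc_start,
         "); canonicalize it before building input-coordinate structure",
         call. = FALSE)
  }
  lens <- c(res$lsc_len, res$ir_len, res$ssc_len, res$ir_len)
  ends <- cumsum(lens)
  starts <- c(1L, ends[-4] + 1L)
  regions <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(lens),
    gc = vapply(seq_len(4),
                function(i) gc_fraction(substr(s, starts[i], ends[i])),
                numeric(1))
  )
  structure(list(genome_id = id, genome_len = n, regions = regions,
                 strand = "+", origin = 1L, has_ir = TRUE),
            class = "quadripartite")
}

# Assemble the canonical structure object from an IR pair given as
# list(a_start, b_start, len) in circular 1-based coordinates of `s`.
build_quadripartite <- function(id, s, pair) {
  n <- nchar(s)
  res <- orient_spans(s, pair)
  canon <- rotate_seq(if (res$strand == "-") revcomp(s) else s, res$origin)
  lens <- c(res$lsc_len, res$ir_len, res$ssc_len, res$ir_len)
  ends <- cumsum(lens)
  starts <- c(1L, ends[-4] + 1L)
  regions <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(lens),
    gc = vapply(seq_len(4),
                function(i) gc_fraction(substr(canon, starts[i], ends[i])),
                numeric(1))
  )
  structure(list(
    genome_id = id, genome_len = n, regions = regions,
    strand = res$strand, origin = res$origin, has_ir = TRUE
  ), class = "quadripartite")
}

# Decide arcs, strand and rotation for an IR pair. Returns lsc/ssc/ir lengths,
# strand, and the 1-based origin on the working strand (position that becomes
# canonical position 1 = LSC start).
orient_spans <- function(s, pair) {
  n <- nchar(s)
  L <- pair$len
  # circular arc from end of one IR copy to start of the other
  arc <- function(from_end, to_start) ((to_start - from_end - 1L) %% n)
  a <- pair$a_start; b <- pair$b_start
  a_end <- ((a + L - 2L) %% n) + 1L
  b_end <- ((b + L - 2L) %% n) + 1L
  arc_ab <- arc(a_end, b)   # arc after copy A, before copy B
  arc_ba <- arc(b_end, a)
  if (arc_ab == arc_ba) stop("single-copy arcs are of equal length; ",
                             "cannot assign LSC/SSC", call. = FALSE)
  if (arc_ab > arc_ba) {
    lsc_start <- (a_end %% n) + 1L; lsc_len <- arc_ab; ssc_len <- arc_ba
  } else {
    lsc_start <- (b_end %% n) + 1L; lsc_len <- arc_ba; ssc_len <- arc_ab
  }
  lsc_fwd <- subseq_circ(s, lsc_start, lsc_start + lsc_len - 1L)
  if (lsc_fwd <= revcomp(lsc_fwd)) {
    return(list(strand = "+", origin = lsc_start, lsc_start = lsc_start,
                lsc_len = lsc_len, ssc_len = ssc_len, ir_len = L))
  }
  # flip: coordinates p on s map to n - p + 1 on revcomp(s); the LSC interval
  # [lsc_start, lsc_start + lsc_len - 1] maps to an interval starting at
  # n - (lsc_start + lsc_len - 1) + 1 (circularly).
  lsc_end <- ((lsc_start + lsc_len - 2L) %% n) + 1L
  origin_flip <- ((n - lsc_end) %% n) + 1L
  list(strand = "-", origin = origin_flip, lsc_start = lsc_start,
       lsc_len = lsc_len, ssc_len = ssc_len, ir_len = L)
}

# Find the maximal disjoint exact inverted-repeat pair on the circular
# sequence `s`. Returns list(a_start, b_start, len) in 1-based circular
# coordinates (a_start < b_start by circular canonical key), or NULL if no
# pair of length >= min_ir_len exists. Errors if two distinct pairs tie at
# the maximal length.
find_ir_pair <- function(s, min_ir_len, seed_k) {
  n <- nchar(s)
  s2 <- paste0(s, s)
  rc2 <- revcomp(s2)
  m2 <- 2L * n
  nk <- m2 - seed_k + 1L
  km_s <- substring(s2, 1:nk, seed_k:(m2))
  km_r <- substring(rc2, 1:nk, seed_k:(m2))
  hit <- match(km_r, km_s)
  valid <- !is.na(hit)
  if (!any(valid)) return(NULL)
  diag <- hit - seq_len(nk)
  key <- ifelse(valid, diag, NA_integer_)
  r <- rle(key)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- !is.na(r$values) & (r$lengths + seed_k - 1L) >= min(min_ir_len, 2L * seed_k)
  if (!any(keep)) {
    # fall back: any seed run at all can still extend to >= min_ir_len only if
    # long enough; runs shorter than 2k are kept when min_ir_len is small
    keep <- !is.na(r$values)
  }
  cands <- list()
  seen <- character(0)
  for (ri in which(keep)) {
    j0 <- run_start[ri]; len0 <- r$lengths[ri] + seed_k - 1L
    i0 <- hit[j0]
    # map the rc2 interval [j0, j0+len0-1] back to s2 coordinates
    b_end2 <- m2 - j0 + 1L
    b_start2 <- b_end2 - len0 + 1L
    ext <- extend_ir_match(s, i0, b_start2, len0)
    if (is.null(ext) || ext$len < min_ir_len) next
    k <- pair_key(ext$a_start, ext$b_start, ext$len, n)
    if (k %in% seen) next
    seen <- c(seen, k)
    cands[[length(cands) + 1L]] <- ext
  }
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, function(x) x$len, integer(1))
  best <- which(lens == max(lens))
  if (length(best) > 1L) {
    desc <- vapply(cands[best], function(x)
      sprintf("[%d,+%d] ~ [%d,+%d]", x$a_start, x$len, x$b_start, x$len),
      character(1))
    stop("ambiguous inverted-repeat pair: multiple candidates of maximal ",
         "length ", max(lens), ": ", paste(desc, collapse = "; "),
         call. = FALSE)
  }
  cands[[best]]
}

# Canonical key for a circular interval pair (order-insensitive).
pair_key <- function(a_start, b_start, len, n) {
  a <- ((a_start - 1L) %% n) + 1L
  b <- ((b_start - 1L) %% n) + 1L
  paste(sort(c(a, b)), len, collapse = "|")
}

# Extend a candidate match to the maximal exact inverted repeat. `i0` is the
# start of copy A and `b_start2` the start of copy B, both on the doubled
# sequence; copy B read forward equals revcomp of copy A read forward.
extend_ir_match <- function(s, i0, b_start2, len0) {
  n <- nchar(s)
  at <- function(p) substr(s, ((p - 1L) %% n) + 1L, ((p - 1L) %% n) + 1L)
  comp1 <- function(x) chartr("ACGTN", "TGCAN", x)
  a_lo <- i0; a_hi <- i0 + len0 - 1L
  b_lo <- b_start2; b_hi <- b_start2 + len0 - 1L
  # verify the seed-derived match before extending
  a_seq <- subseq_circ(s, ((a_lo - 1L) %% n) + 1L, ((a_lo - 1L) %% n) + len0)
  b_seq <- subseq_circ(s, ((b_lo - 1L) %% n) + 1L, ((b_lo - 1L) %% n) + len0)
  if (!identical(b_seq, revcomp(a_seq))) return(NULL)
  # extend right end of A together with left end of B
  while ((a_hi - a_lo + 1L) < n && at(a_hi + 1L) == comp1(at(b_lo - 1L)) &&
         at(a_hi + 1L) != "N") {
    a_hi <- a_hi + 1L; b_lo <- b_lo - 1L
    if (intervals_touch(a_lo, a_hi, b_lo, b_hi, n)) {
      a_hi <- a_hi - 1L; b_lo <- b_lo + 1L; break
    }
  }
  # extend left end of A together with right end of B
  while ((a_hi - a_lo + 1L) < n && at(a_lo - 1L) == comp1(at(b_hi + 1L)) &&
         at(a_lo - 1L) != "N") {
    a_lo <- a_lo - 1L; b_hi <- b_hi + 1L
    if (intervals_touch(a_lo, a_hi, b_lo, b_hi, n)) {
      a_lo <- a_lo + 1L; b_hi <- b_hi - 1L; break
    }
  }
  len <- a_hi - a_lo + 1L
  a_start <- ((a_lo - 1L) %% n) + 1L
  b_start <- ((b_lo - 1L) %% n) + 1L
  if (a_start == b_start) return(NULL)
  if (circ_overlap(a_start, b_start, len, n)) return(NULL)
  if (b_start < a_start) { tmp <- a_start; a_start <- b_start; b_start <- tmp }
  list(a_start = a_start, b_start = b_start, len = len)
}

intervals_touch <- function(a_lo, a_hi, b_lo, b_hi, n) {
  circ_overlap(((a_lo - 1L) %% n) + 1L, ((b_lo - 1L) %% n) + 1L,
               max(a_hi - a_lo, b_hi - b_lo) + 1L, n)
}

# Do two circular intervals of common length `len` overlap?
circ_overlap <- function(a_start, b_start, len, n) {
  if (2L * len > n) return(TRUE)
  d <- (b_start - a_start) %% n
  d < len || (n - d) < len
}

#' Rotate (and flip) a genome into its canonical quadripartite orientation
#'
#' Applies the transform recorded in a [detect_quadripartite()] result so the
#' genome reads LSC, IRb, SSC, IRa with LSC at position 1. Feature coordinates
#' are remapped; a feature that ends up spanning the new origin is split into
#' two rows sharing its name.
#'
#' @param genome The [genome_record()] the structure was detected on.
#' @param structure A `quadripartite` object.
#' @return A new `genome_record` in canonical orientation.
#' @export
canonicalize_orientation <- function(genome, structure) {
  stopifnot(inherits(genome, "genome_record"), inherits(structure, "quadripartite"))
  n <- nchar(genome$seq)
  if (n != structure$genome_len) stop("structure was detected on a genome of ",
                                      "different length", call. = FALSE)
  if (!structure$has_ir) return(genome)
  s <- genome$seq
  feats <- genome$features
  if (structure$strand == "-") {
    s <- revcomp(s)
    if (!is.null(feats)) {
      feats <- feats %>% mutate(
        start2 = n - .data$end + 1L, end2 = n - .data$start + 1L,
        strand = ifelse(.data$strand == "+", "-",
                        ifelse(.data$strand == "-", "+", .data$strand)),
        start = .data$start2, end = .data$end2
      ) %>% select(-"start2", -"end2")
    }
  }
  org <- structure$origin
  s <- rotate_seq(s, org)
  if (!is.null(feats) && org != 1L) {
    remap <- function(p) ((p - org) %% n) + 1L
    feats <- feats %>% mutate(start = remap(.data$start), end = remap(.data$end))
    wraps <- feats$start > feats$end
    if (any(wraps)) {
      head_part <- feats[wraps, ] %>% mutate(end = n)
      tail_part <- feats[wraps, ] %>% mutate(start = 1L)
      feats <- bind_rows(feats[!wraps, ], head_part, tail_part) %>%
        arrange(.data$start)
    }
  }
  genome_record(genome$id, s, circular = genome$circular, features = feats)
}

#' Region membership of genome positions
#'
#' @param position Integer vector of 1-based positions on the canonicalized
#'   genome.
#' @param structure A `quadripartite` object.
#' @param collapse Collapse `IRb`/`IRa` to a single `IR` label (the convention
#'   under which IR variants are counted once).
#' @return Character vector of region labels (`LSC`, `IRb`, `SSC`, `IRa`, or
#'   `IR` when collapsed; `whole` for a no-IR structure).
#' @export
region_of <- function(position, structure, collapse = FALSE) {
  stopifnot(inherits(structure, "quadripartite"))
  if (any(position < 1L | position > structure$genome_len)) {
    stop("position out of range [1, ", structure$genome_len, "]", call. = FALSE)
  }
  if (!structure$has_ir) return(rep("whole", length(position)))
  idx <- findInterval(position, structure$regions$start)
  lab <- structure$regions$region[idx]
  if (collapse) lab <- ifelse(lab %in% c("IRb", "IRa"), "IR", lab)
  lab
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("<quadripartite> %s (%s bp, strand %s)\n", x$genome_id,
              format(x$genome_len, big.mark = ","), x$strand))
  print(x$regions)
  invisible(x)
}

#' Tidy a quadripartite structure into its region table
#'
#' @param x A `quadripartite` object.
#' @param ... Unused.
#' @return Tibble with `genotype`, `region`, `start`, `end`, `length`, `gc`.
#' @method tidy quadripartite
#' @export
tidy.quadripartite <- function(x, ...) {
  x$regions %>% mutate(genotype = x$genome_id, .before = 1)
}

#' One-row summary of a quadripartite structure
#'
#' @param x A `quadripartite` object.
#' @param ... Unused.
#' @return Tibble with genome length, per-region lengths and overall GC.
#' @method glance quadripartite
#' @export
glance.quadripartite <- function(x, ...) {
  if (!x$has_ir) {
    return(tibble(genotype = x$genome_id, length = x$genome_len,
                  lsc_len = NA_integer_, ssc_len = NA_integer_,
                  ir_len = NA_integer_, gc = x$regions$gc[[1]]))
  }
  r <- x$regions
  tibble(
    genotype = x$genome_id, length = x$genome_len,
    lsc_len = r$length[r$region == "LSC"],
    ssc_len = r$length[r$region == "SSC"],
    ir_len = r$length[r$region == "IRb"],
    gc = sum(r$length * r$gc) / sum(r$length)
  )
}
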