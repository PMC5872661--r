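# Independent oracles and small fixture builders. The oracles deliberately
# use different algorithmic routes from the package (regex backreferences for
# SSR enumeration, an O(n^2) diagonal scan for inverted repeats) so that
# agreement is evidence, not tautology.

ORACLE_THRESHOLDS <- c(10L, 5L, 4L, 3L, 3L, 3L)

oracle_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && motif == strrep(substr(motif, 1L, d), u %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}

# Exhaustive maximal perfect tandem repeats via greedy backreference regex.
oracle_enumerate_repeats <- function(seq, thresholds = ORACLE_THRESHOLDS) {
  rows <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thresholds[u] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      n_units <- lens[k] %/% u
      motif <- substr(seq, m[k], m[k] + u - 1L)
      if (!oracle_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = as.integer(m[k]), end = as.integer(m[k] + n_units * u - 1L),
        unit_len = u, n_units = n_units, motif = motif,
        tract_len = n_units * u, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_len = integer(), n_units = integer(),
                      motif = character(), tract_len = integer()))
  }
  do.call(rbind, rows)
}

# Overlap resolution and compound merging re-implemented plainly (quadratic).
oracle_ssr_loci <- function(seq, thresholds = ORACLE_THRESHOLDS,
                            compound_max_gap = 100L) {
  reps <- oracle_enumerate_repeats(seq, thresholds)
  if (!nrow(reps)) {
    return(data.frame(start = integer(), end = integer(),
                      ssr_type = character()))
  }
  ord <- order(-reps$tract_len, reps$unit_len, reps$start)
  kept <- reps[0, ]
  for (i in ord) {
    ov <- FALSE
    if (nrow(kept)) {
      ov <- any(kept$start <= reps$end[i] & kept$end >= reps$start[i])
    }
    if (!ov) kept <- rbind(kept, reps[i, ])
  }
  kept <- kept[order(kept$start), ]
  # compound merge
  out <- list()
  i <- 1L
  while (i <= nrow(kept)) {
    j <- i
    while (j < nrow(kept) &&
           kept$start[j + 1L] - kept$end[j] - 1L <= compound_max_gap) {
      j <- j + 1L
    }
    parts <- character(0)
    for (k in i:j) {
      if (k > i) {
        gap <- substr(seq, kept$end[k - 1L] + 1L, kept$start[k] - 1L)
        parts <- c(parts, tolower(gap))
      }
      parts <- c(parts, sprintf("(%s)%d", kept$motif[k], kept$n_units[k]))
    }
    out[[length(out) + 1L]] <- data.frame(
      start = kept$start[i], end = kept$end[j],
      ssr_type = paste(parts, collapse = ""), stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# O(n^2) longest disjoint inverted-repeat pair: scan every diagonal of
# sequence vs reverse complement, track the longest run whose interval pair
# is disjoint. Returns list(len, a_start, b_start) or len = 0.
oracle_longest_ir <- function(seq) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  rc <- strsplit(stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq)),
                 "")[[1]]
  best <- list(len = 0L, a_start = NA_integer_, b_start = NA_integer_)
  for (d in (-(n - 1L)):(n - 1L)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, n - d)
    if (i2 - i1 + 1L <= best$len) next
    eq <- s[i1:i2] == rc[(i1:i2) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths > best$len)) {
      L <- r$lengths[k]
      i0 <- i1 + ends[k] - L
      j0 <- i0 + d
      a <- c(i0, i0 + L - 1L)
      b <- c(n - (j0 + L - 1L) + 1L, n - j0 + 1L)
      if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
      if (a[2] >= b[1]) next  # overlapping (palindrome-style) match
      best <- list(len = L, a_start = a[1], b_start = b[1])
    }
  }
  best
}

# Small screened quadripartite toy built by the simulator (planted region
# lengths are ground truth by construction).
toy_plastome <- function(lsc, ir, ssc, seed, gc = 0.37) {
  p <- sim_params(lsc_len = lsc, ir_len = ir, ssc_len = ssc, gc = gc,
                  n_snps = 0, n_ssr_tracts = 0, n_ssr_polymorphic = 0,
                  n_indels = 0, n_inversions = 0, seed = seed)
  simulate_reference(p)
}

# Degenerate "whole genome" structure for tests that need region labels but
# no IR (e.g. strand-symmetry checks on tiny alignments).
whole_structure <- function(genome) {
  n <- nchar(genome$seq)
  structure(list(
    genome_id = genome$id, genome_len = n,
    regions = tibble::tibble(region = "whole", start = 1L, end = n,
                             length = n, gc = 0.5),
    strand = "+", origin = 1L, has_ir = FALSE
  ), class = "quadripartite")
}

# Random DNA string helper for unit tests.
rand_seq <- function(n, seed, gc = 0.37) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

# Small default simulation used by several test files.
quick_sim <- function(seed = 7, ...) {
  defaults <- list(lsc_len = 9000, ir_len = 2000, ssc_len = 3000,
                   n_snps = 30, n_ssr_tracts = 8, n_ssr_polymorphic = 5,
                   n_indels = 8, n_inversions = 2, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  simulate_plastomes(do.call(sim_params, args))
}
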