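# Plastome simulator: quadripartite reference genomes with screened
# backgrounds, planted SNP/SSR/indel/inversion events across a genotype set,
# the TRUE alignment built from the edit script (no aligner), and a
# ground-truth ledger for recovery testing.

#' Simulation parameters
#'
#' Defaults emulate the study conditions of a six-genotype plastome
#' comparison: ~153 kb genomes with LSC/IRb/SSC/IRa structure at 37% GC,
#' 141 biallelic SNPs at a transition:transversion budget of 88:53, 66 SSR
#' tracts of which 24 are length-polymorphic across genotypes, 44 common
#' indels of 1-28 bp in noncoding regions, and 5 small inversions with
#' 2-51 bp cores flanked by 6-22 bp inverted repeats. All events are placed
#' non-overlapping with at least 50 bp separation.
#'
#' @param lsc_len,ir_len,ssc_len Region lengths in bp (SSC must be shorter
#'   than LSC).
#' @param gc Target GC fraction of the single-copy background.
#' @param n_genotypes Number of genotypes; genotype `G1` is the unmutated
#'   standard reference, events affect subsets of the others.
#' @param n_snps Total planted SNPs.
#' @param ts_tv_ratio Transition:transversion ratio; transition count is
#'   `round(n_snps * r / (1 + r))`.
#' @param n_ssr_tracts Planted SSR tracts (all above threshold).
#' @param n_ssr_polymorphic How many tracts carry a cross-genotype unit-count
#'   change.
#' @param ssr_unit_lens,ssr_unit_weights Unit lengths of planted tracts and
#'   their mix (defaults follow the observed plastome SSR mix,
#'   mononucleotide-heavy: 37 mono, 11 di, 7 tri, 4 tetra, 7 penta). When the
#'   weights sum to `n_ssr_tracts` they are used as exact per-unit-length
#'   counts; otherwise they are sampling weights.
#' @param ssr_extra_units Per-tract unit counts are drawn between the
#'   threshold and threshold + `ssr_extra_units`.
#' @param n_indels Planted non-SSR ("common") indels.
#' @param indel_size_range Indel sizes (bp), inclusive. Sizes are drawn with
#'   geometrically decaying weights so 1 bp indels are the most common, and
#'   one indel is planted at the range maximum so the stated size range is
#'   realized.
#' @param n_inversions Planted inversions.
#' @param inversion_core_range,inversion_flank_range Core and flanking-repeat
#'   lengths (bp), inclusive.
#' @param noncoding_only Restrict indels, SSR tracts and inversions to
#'   intergenic spacers.
#' @param gene_len,spacer_len Block lengths (bp) of the toy alternating
#'   gene/spacer feature layout used for context labeling.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(lsc_len = 83000L, ir_len = 25500L, ssc_len = 19000L,
                       gc = 0.37, n_genotypes = 6L,
                       n_snps = 141L, ts_tv_ratio = 88 / 53,
                       n_ssr_tracts = 66L, n_ssr_polymorphic = 24L,
                       ssr_unit_lens = 1:5,
                       ssr_unit_weights = c(37, 11, 7, 4, 7),
                       ssr_extra_units = 4L,
                       n_indels = 44L, indel_size_range = c(1L, 28L),
                       n_inversions = 5L,
                       inversion_core_range = c(2L, 51L),
                       inversion_flank_range = c(6L, 22L),
                       noncoding_only = TRUE, gene_len = 900L,
                       spacer_len = 600L, seed = 20180314L) {
  p <- list(lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
            ssc_len = as.integer(ssc_len), gc = gc,
            n_genotypes = as.integer(n_genotypes),
            n_snps = as.integer(n_snps), ts_tv_ratio = ts_tv_ratio,
            n_ssr_tracts = as.integer(n_ssr_tracts),
            n_ssr_polymorphic = as.integer(n_ssr_polymorphic),
            ssr_unit_lens = as.integer(ssr_unit_lens),
            ssr_unit_weights = ssr_unit_weights,
            ssr_extra_units = as.integer(ssr_extra_units),
            n_indels = as.integer(n_indels),
            indel_size_range = as.integer(indel_size_range),
            n_inversions = as.integer(n_inversions),
            inversion_core_range = as.integer(inversion_core_range),
            inversion_flank_range = as.integer(inversion_flank_range),
            noncoding_only = isTRUE(noncoding_only),
            gene_len = as.integer(gene_len),
            spacer_len = as.integer(spacer_len), seed = as.integer(seed))
  stopifnot(p$ssc_len < p$lsc_len, p$gc > 0, p$gc < 1, p$n_genotypes >= 2L,
            p$n_ssr_polymorphic <= p$n_ssr_tracts,
            all(c(p$n_snps, p$n_ssr_tracts, p$n_indels, p$n_inversions) >= 0L),
            length(p$ssr_unit_weights) == length(p$ssr_unit_lens))
  structure(p, class = "sim_params")
}

# sample() treats a length-1 vector as 1:n; guard every range draw
sample_range <- function(lo, hi) if (lo >= hi) as.integer(lo) else sample(lo:hi, 1L)

sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = prob)
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tandem repeats meeting per-unit thresholds, found by backreference regex
# (independent of the rle-based miner). Returns tibble(start, len, unit_len).
regex_tandem_hits <- function(seq, thresholds = SSR_THRESHOLDS) {
  out <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGTN]{%d})\\1{%d,}", u, thresholds[u] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    out[[length(out) + 1L]] <- tibble(start = as.integer(m),
                                      len = attr(m, "match.length"),
                                      unit_len = u)
  }
  bind_rows(out)
}

# Overlap-merged count of qualifying tandem tracts (a mononucleotide run also
# matches the dinucleotide pattern; merging counts it once).
count_tandem_clusters <- function(seq, thresholds = SSR_THRESHOLDS) {
  hits <- regex_tandem_hits(seq, thresholds)
  if (!nrow(hits)) return(0L)
  hits <- hits %>% arrange(.data$start)
  ends <- hits$start + hits$len - 1L
  sum(c(TRUE, hits$start[-1] > cummax(ends)[-nrow(hits)]))
}

# Repair a random background so it contains no threshold-qualifying tandem
# repeat: break each offending repeat by resampling its middle base.
screen_background <- function(seq, gc, thresholds = SSR_THRESHOLDS,
                              max_rounds = 60L) {
  chars <- seq_chars(seq)
  for (round in seq_len(max_rounds)) {
    hits <- regex_tandem_hits(chars_to_seq(chars), thresholds)
    if (!nrow(hits)) return(chars_to_seq(chars))
    for (i in seq_len(nrow(hits))) {
      at <- hits$start[i] + hits$len[i] %/% 2L
      chars[at] <- sample(setdiff(DNA_BASES, chars[at]), 1L)
    }
  }
  stop("background screening did not converge; use a longer genome or ",
       "looser screen", call. = FALSE)
}

#' Simulate a screened quadripartite reference plastome
#'
#' Generates random LSC and SSC backgrounds at the target GC, one random IR
#' copied in reverse complement (so IRa is exactly the reverse complement of
#' IRb), screens the background free of threshold-qualifying tandem repeats,
#' fixes the region junctions so the IR pair is exactly `ir_len` (no
#' accidental extension), and lays down a toy feature table of alternating
#' gene/spacer blocks for context labeling.
#'
#' @param params A [sim_params()] list.
#' @return List with `genome` (reference [genome_record()], id `"G1"`),
#'   `structure` (`quadripartite`) and `features` (tibble).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, simulate_reference_impl(params))
}

simulate_reference_impl <- function(params) {
  lsc <- screen_background(random_dna(params$lsc_len, params$gc), params$gc)
  ssc <- screen_background(random_dna(params$ssc_len, params$gc), params$gc)
  ir <- screen_background(random_dna(params$ir_len, params$gc), params$gc)
  seq <- paste0(lsc, ir, ssc, revcomp(ir))
  chars <- seq_chars(seq)
  n <- nchar(seq)
  b1 <- params$lsc_len + 1L               # IRb start
  b2 <- params$lsc_len + params$ir_len    # IRb end
  a1 <- b2 + params$ssc_len + 1L          # IRa start
  a2 <- n                                 # IRa end
  # forbid IR extension: first SSC base vs last SSC base, and last LSC base
  # vs first LSC base (circular junction)
  if (chars[b2 + 1L] == complement(chars[a1 - 1L])) {
    chars[b2 + 1L] <- sample(setdiff(DNA_BASES, c(chars[b2 + 1L],
                                                  complement(chars[a1 - 1L]))), 1L)
  }
  if (chars[b1 - 1L] == complement(chars[1L])) {
    chars[b1 - 1L] <- sample(setdiff(DNA_BASES, c(chars[b1 - 1L],
                                                  complement(chars[1L]))), 1L)
  }
  seq <- chars_to_seq(chars)
  genome <- genome_record("G1", seq, circular = TRUE)
  structure_obj <- quadripartite_from_lengths("G1", seq, params$lsc_len,
                                              params$ir_len, params$ssc_len)
  features <- toy_feature_table(n, gene_len = params$gene_len,
                                spacer_len = params$spacer_len)
  genome$features <- features
  list(genome = genome, structure = structure_obj, features = features)
}

# Build a quadripartite object from known region lengths (canonical layout).
quadripartite_from_lengths <- function(id, seq, lsc_len, ir_len, ssc_len) {
  build_quadripartite(id, seq,
                      list(a_start = lsc_len + 1L,
                           b_start = lsc_len + ir_len + ssc_len + 1L,
                           len = ir_len))
}

# Alternating gene/spacer blocks: 900 bp genes separated by 600 bp spacers.
toy_feature_table <- function(genome_len, gene_len = 900L, spacer_len = 600L) {
  starts <- seq(spacer_len + 1L, genome_len - gene_len, by = gene_len + spacer_len)
  tibble(
    kind = "gene",
    name = sprintf("gene%03d", seq_along(starts)),
    start = as.integer(starts),
    end = as.integer(starts + gene_len - 1L),
    strand = rep(c("+", "-"), length.out = length(starts))
  )
}

#' Plant mutation events across a genotype set
#'
#' Derives `n_genotypes` genotypes from the reference, planting SNPs (classes
#' drawn to meet the transition:transversion budget exactly), SSR unit-count
#' polymorphisms, insertions/deletions, and inversions (reverse-complemented
#' cores with flanking inverted repeats written into the reference so the stem
#' is shared by all genotypes). The true alignment is constructed directly
#' from the edit script; no aligner is involved. Genotype `G1` is the
#' unmutated reference; every event affects a random nonempty subset of the
#' other genotypes.
#'
#' @param ref,structure,features Output of [simulate_reference()].
#' @param params The same [sim_params()].
#' @return List with `genomes` (a `genome_set` of per-genotype
#'   [genome_record()]s), `alignment` (a [alignment_matrix()]), and `truth`
#'   (the planted-event tibble: `kind`, `ref_start`, `ref_end`, `size`,
#'   `genotypes`, plus per-kind payload columns).
#' @export
mutate_genotypes <- function(ref, structure, features, params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed + 1L,
                   mutate_genotypes_impl(ref, structure, features, params))
}

mutate_genotypes_impl <- function(ref, structure, features, params) {
  n <- nchar(ref$seq)
  chars <- seq_chars(ref$seq)
  ids <- paste0("G", seq_len(params$n_genotypes))
  alt_ids <- ids[-1]

  reg <- structure$regions
  margin <- 80L
  sc_mask <- rep(FALSE, n)
  for (rg in c("LSC", "SSC")) {
    rr <- reg[reg$region == rg, ]
    sc_mask[(rr$start + margin):(rr$end - margin)] <- TRUE
  }
  spacer_mask <- rep(FALSE, n)
  sp <- derive_spacers(features, n)
  for (i in seq_len(nrow(sp))) spacer_mask[sp$start[i]:sp$end[i]] <- TRUE
  event_mask <- if (params$noncoding_only) sc_mask & spacer_mask else sc_mask
  free <- rep(TRUE, n)

  claim <- function(x1, x2) {
    free[max(1L, x1 - 50L):min(n, x2 + 50L)] <<- FALSE
  }
  place <- function(extent, mask) {
    ok <- which(mask & free)
    if (!length(ok)) stop("event placement exhausted free space; enlarge ",
                          "the genome or reduce event budgets", call. = FALSE)
    for (try in seq_len(2000L)) {
      x1 <- ok[[sample.int(length(ok), 1L)]]
      x2 <- x1 + extent - 1L
      if (x2 > n) next
      if (all(mask[x1:x2] & free[x1:x2])) return(x1)
    }
    stop("event placement exhausted free space; enlarge the genome or ",
         "reduce event budgets", call. = FALSE)
  }
  pick_genotypes <- function() {
    k <- sample.int(length(alt_ids), 1L)
    sort(sample(alt_ids, k))
  }
  # number of distinct (overlap-merged) qualifying tandem tracts in a window
  # around a planted event must equal what was planted there
  local_ok <- function(x1, x2, expected) {
    win <- chars_to_seq(chars[max(1L, x1 - 30L):min(n, x2 + 30L)])
    count_tandem_clusters(win) == expected
  }

  truth <- list()
  edits <- list()

  # -- inversions: flank + mirror-complement-free core + revcomp(flank)
  # written into the reference; inverted genotypes carry revcomp(core)
  for (i in seq_len(params$n_inversions)) {
    repeat {
      core_len <- sample_range(params$inversion_core_range[1], params$inversion_core_range[2])
      flank_len <- sample_range(params$inversion_flank_range[1], params$inversion_flank_range[2])
      extent <- core_len + 2L * flank_len
      x1 <- place(extent, event_mask)
      flank <- random_dna(flank_len, params$gc)
      core <- mirror_free_core(core_len, params$gc)
      scaffold <- seq_chars(paste0(flank, core, revcomp(flank)))
      old <- chars[x1:(x1 + extent - 1L)]
      old_l <- if (x1 > 1L) chars[x1 - 1L] else NA
      chars[x1:(x1 + extent - 1L)] <- scaffold
      # stem must not extend past the written flank
      if (x1 > 1L && x1 + extent <= n &&
          chars[x1 - 1L] == complement(chars[x1 + extent])) {
        chars[x1 - 1L] <- sample(setdiff(DNA_BASES,
                                         complement(chars[x1 + extent])), 1L)
      }
      if (local_ok(x1, x1 + extent - 1L, 0L)) break
      chars[x1:(x1 + extent - 1L)] <- old
      if (x1 > 1L) chars[x1 - 1L] <- old_l
    }
    gts <- pick_genotypes()
    core_start <- x1 + flank_len
    core_end <- core_start + core_len - 1L
    claim(x1, x1 + extent - 1L)
    edits[[length(edits) + 1L]] <- list(
      kind = "inversion", ref_start = core_start, ref_end = core_end,
      genotypes = gts, core = core)
    truth[[length(truth) + 1L]] <- tibble(
      kind = "inversion", ref_start = core_start, ref_end = core_end,
      size = core_len, genotypes = paste(gts, collapse = ","),
      subst_class = NA, motif = NA, n_units_ref = NA, n_units_alt = NA,
      direction = NA, allele = core, flank_len = flank_len)
  }

  # -- SSR tracts (monomorphic + polymorphic unit-count changes)
  poly_flags <- c(rep(TRUE, params$n_ssr_polymorphic),
                  rep(FALSE, params$n_ssr_tracts - params$n_ssr_polymorphic))
  unit_alloc <- if (sum(params$ssr_unit_weights) == params$n_ssr_tracts) {
    sample(rep(params$ssr_unit_lens, times = params$ssr_unit_weights))
  } else NULL
  for (i in seq_len(params$n_ssr_tracts)) {
    repeat {
      u <- if (!is.null(unit_alloc)) unit_alloc[[i]]
           else sample_one(params$ssr_unit_lens,
                           prob = params$ssr_unit_weights)
      thr <- SSR_THRESHOLDS[u]
      n0 <- thr + sample.int(params$ssr_extra_units + 1L, 1L) - 1L
      motif <- make_primitive_motif(u, params$gc)
      tract_len <- n0 * u
      x1 <- place(tract_len, event_mask)
      x2 <- x1 + tract_len - 1L
      old <- chars[x1:x2]
      old_l <- if (x1 > 1L) chars[x1 - 1L] else NA
      old_r <- if (x2 < n) chars[x2 + 1L] else NA
      chars[x1:x2] <- seq_chars(strrep(motif, n0))
      # break the repeat phase at both boundaries so the tract is maximal
      if (x1 > 1L) chars[x1 - 1L] <- non_extending_base(chars, x1 - 1L, u, n)
      if (x2 < n) chars[x2 + 1L] <- non_extending_base(chars, x2 + 1L, -u, n)
      if (local_ok(x1, x2, 1L)) break
      chars[x1:x2] <- old
      if (x1 > 1L) chars[x1 - 1L] <- old_l
      if (x2 < n) chars[x2 + 1L] <- old_r
    }
    # extra padding: tracts closer than the compound-merge distance (100 bp)
    # to any other event would be reported as one compound locus, and a
    # unit-count insertion (up to 3 units) shrinks the gap further
    claim(x1 - 70L, x2 + 70L)
    if (poly_flags[i]) {
      gts <- pick_genotypes()
      d_units <- sample.int(3L, 1L)
      gain <- stats::runif(1) < 0.5 || n0 - d_units < SSR_THRESHOLDS[u]
      n1 <- if (gain) n0 + d_units else n0 - d_units
      if (n1 > n0) {
        edits[[length(edits) + 1L]] <- list(
          kind = "ssr_ins", ref_start = x2 + 1L, ref_end = x2,
          genotypes = gts, allele = strrep(motif, n1 - n0))
      } else {
        edits[[length(edits) + 1L]] <- list(
          kind = "ssr_del", ref_start = x2 - (n0 - n1) * u + 1L, ref_end = x2,
          genotypes = gts)
      }
      truth[[length(truth) + 1L]] <- tibble(
        kind = "ssr_polymorphism", ref_start = x1, ref_end = x2,
        size = abs(n1 - n0) * u, genotypes = paste(gts, collapse = ","),
        subst_class = NA, motif = motif, n_units_ref = n0, n_units_alt = n1,
        direction = ifelse(n1 > n0, "insertion", "deletion"),
        allele = strrep(motif, abs(n1 - n0)), flank_len = NA)
    } else {
      truth[[length(truth) + 1L]] <- tibble(
        kind = "ssr_tract", ref_start = x1, ref_end = x2,
        size = tract_len, genotypes = paste(ids, collapse = ","),
        subst_class = NA, motif = motif, n_units_ref = n0, n_units_alt = n0,
        direction = NA, allele = NA, flank_len = NA)
    }
  }

  # -- common (non-SSR) indels: geometric size decay (1 bp modal), with the
  # range maximum realized once
  size_pool <- params$indel_size_range[1]:params$indel_size_range[2]
  size_w <- 0.65^(size_pool - size_pool[1])
  indel_sizes <- if (params$n_indels > 0L) {
    c(params$indel_size_range[2],
      if (params$n_indels > 1L)
        sample(size_pool, params$n_indels - 1L, replace = TRUE, prob = size_w))
  } else integer(0)
  for (i in seq_len(params$n_indels)) {
    size <- indel_sizes[[i]]
    deletion <- stats::runif(1) < 0.5
    gts <- pick_genotypes()
    if (deletion) {
      repeat {
        x1 <- place(size, event_mask)
        x2 <- x1 + size - 1L
        joined <- paste0(chars_to_seq(chars[max(1L, x1 - 30L):(x1 - 1L)]),
                         chars_to_seq(chars[(x2 + 1L):min(n, x2 + 30L)]))
        if (count_tandem_clusters(joined) == 0L) break
      }
      claim(x1, x2)
      allele <- chars_to_seq(chars[x1:x2])
      edits[[length(edits) + 1L]] <- list(kind = "del", ref_start = x1,
                                          ref_end = x2, genotypes = gts)
      truth[[length(truth) + 1L]] <- tibble(
        kind = "indel", ref_start = x1, ref_end = x2, size = size,
        genotypes = paste(gts, collapse = ","), subst_class = NA, motif = NA,
        n_units_ref = NA, n_units_alt = NA, direction = "deletion",
        allele = allele, flank_len = NA)
    } else {
      x1 <- place(2L, event_mask)  # insertion point between x1 and x1+1
      claim(x1, x1 + 1L)
      repeat {
        allele <- random_dna(size, params$gc)
        joined <- paste0(chars_to_seq(chars[max(1L, x1 - 30L):x1]), allele,
                         chars_to_seq(chars[(x1 + 1L):min(n, x1 + 30L)]))
        if (nrow(regex_tandem_hits(joined)) == 0L) break
      }
      edits[[length(edits) + 1L]] <- list(kind = "ins", ref_start = x1 + 1L,
                                          ref_end = x1, genotypes = gts,
                                          allele = allele)
      truth[[length(truth) + 1L]] <- tibble(
        kind = "indel", ref_start = x1 + 1L, ref_end = x1, size = size,
        genotypes = paste(gts, collapse = ","), subst_class = NA, motif = NA,
        n_units_ref = NA, n_units_alt = NA, direction = "insertion",
        allele = allele, flank_len = NA)
    }
  }

  # -- SNPs: exact transition/transversion budget
  r <- params$ts_tv_ratio
  n_ts <- as.integer(round(params$n_snps * r / (1 + r)))
  is_ts <- sample(c(rep(TRUE, n_ts), rep(FALSE, params$n_snps - n_ts)))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(params$n_snps)) {
    repeat {
      x1 <- place(1L, sc_mask)
      b <- chars[x1]
      alt <- if (is_ts[i]) transition_of[[b]]
             else sample(setdiff(DNA_BASES, c(b, transition_of[[b]])), 1L)
      win <- chars[max(1L, x1 - 15L):min(n, x1 + 15L)]
      win[x1 - max(1L, x1 - 15L) + 1L] <- alt
      if (count_tandem_clusters(chars_to_seq(win)) == 0L) break
    }
    claim(x1, x1)
    gts <- pick_genotypes()
    edits[[length(edits) + 1L]] <- list(kind = "snp", ref_start = x1,
                                        ref_end = x1, genotypes = gts,
                                        allele = alt)
    truth[[length(truth) + 1L]] <- tibble(
      kind = "snp", ref_start = x1, ref_end = x1, size = 1L,
      genotypes = paste(gts, collapse = ","),
      subst_class = canonical_subst_class(b, alt), motif = NA,
      n_units_ref = NA, n_units_alt = NA, direction = NA, allele = alt,
      flank_len = NA)
  }

  ref_seq <- chars_to_seq(chars)
  built <- build_true_alignment(ref_seq, ids, edits)
  genomes <- purrr::map(ids, function(g) {
    genome_record(g, gsub("-", "", built$rows[[g]], fixed = TRUE),
                  circular = TRUE, features = if (g == "G1") features else NULL)
  })
  names(genomes) <- ids
  class(genomes) <- "genome_set"
  truth_tbl <- if (length(truth)) {
    bind_rows(truth) %>% arrange(.data$ref_start)
  } else {
    tibble(kind = character(), ref_start = integer(), ref_end = integer(),
           size = integer(), genotypes = character(),
           subst_class = character(), motif = character(),
           n_units_ref = integer(), n_units_alt = integer(),
           direction = character(), allele = character(),
           flank_len = integer())
  }
  list(genomes = genomes, alignment = alignment_matrix(built$rows),
       truth = truth_tbl,
       reference = genome_record("G1", ref_seq, circular = TRUE,
                                 features = features))
}

# A base for position `at` that does not continue the repeat period in the
# direction of the adjacent tract (`u` > 0: tract to the right; < 0: left).
non_extending_base <- function(chars, at, u, n) {
  partner <- at + abs(u) * sign(u)
  avoid <- chars[at]
  if (partner >= 1L && partner <= n) avoid <- c(avoid, chars[partner])
  # also avoid matching the immediate neighbours (no new mono run)
  for (nb in c(at - 1L, at + 1L)) {
    if (nb >= 1L && nb <= n) avoid <- c(avoid, chars[nb])
  }
  pool <- setdiff(DNA_BASES, avoid)
  if (!length(pool)) pool <- setdiff(DNA_BASES, chars[partner])
  sample(pool, 1L)
}

# Random primitive motif of length u that is not a single-base run and reads
# differently from its periodic rotations.
make_primitive_motif <- function(u, gc) {
  repeat {
    m <- random_dna(u, gc)
    if (is_primitive_motif(m)) return(m)
  }
}

# A core such that no position equals the complement of its mirror position,
# so an inverted copy mismatches the reference at every column.
mirror_free_core <- function(len, gc) {
  chars <- seq_chars(random_dna(len, gc))
  for (i in seq_len(ceiling(len / 2))) {
    j <- len - i + 1L
    while (chars[i] == complement(chars[j])) {
      chars[i] <- sample(DNA_BASES, 1L)
    }
  }
  chars_to_seq(chars)
}

# Assemble aligned rows for all genotypes from the edit script.
build_true_alignment <- function(ref_seq, ids, edits) {
  ord <- order(vapply(edits, function(e) e$ref_start, numeric(1)),
               vapply(edits, function(e) e$ref_end, numeric(1)))
  edits <- edits[ord]
  pieces <- stats::setNames(replicate(length(ids), list(), simplify = FALSE), ids)
  push <- function(g, txt) pieces[[g]][[length(pieces[[g]]) + 1L]] <<- txt
  cursor <- 1L
  for (e in edits) {
    if (e$ref_start > cursor) {
      chunk <- substr(ref_seq, cursor, e$ref_start - 1L)
      for (g in ids) push(g, chunk)
    }
    affected <- e$genotypes
    if (e$kind == "snp") {
      b <- substr(ref_seq, e$ref_start, e$ref_start)
      for (g in ids) push(g, if (g %in% affected) e$allele else b)
      cursor <- e$ref_start + 1L
    } else if (e$kind == "inversion") {
      core <- substr(ref_seq, e$ref_start, e$ref_end)
      for (g in ids) push(g, if (g %in% affected) revcomp(core) else core)
      cursor <- e$ref_end + 1L
    } else if (e$kind %in% c("del", "ssr_del")) {
      seg <- substr(ref_seq, e$ref_start, e$ref_end)
      gap <- strrep("-", nchar(seg))
      for (g in ids) push(g, if (g %in% affected) gap else seg)
      cursor <- e$ref_end + 1L
    } else if (e$kind %in% c("ins", "ssr_ins")) {
      gap <- strrep("-", nchar(e$allele))
      for (g in ids) push(g, if (g %in% affected) e$allele else gap)
      cursor <- e$ref_start
    }
  }
  if (cursor <= nchar(ref_seq)) {
    chunk <- substr(ref_seq, cursor, nchar(ref_seq))
    for (g in ids) push(g, chunk)
  }
  rows <- vapply(pieces, function(p) paste(unlist(p), collapse = ""),
                 character(1))
  list(rows = rows)
}

#' Simulate a full genotype set with ground truth
#'
#' Convenience wrapper running [simulate_reference()] then
#' [mutate_genotypes()].
#'
#' @param params A [sim_params()] list.
#' @return An object of class `plastome_sim`: `genomes`, `alignment`, `truth`,
#'   `structure`, `features`, `params`.
#' @export
simulate_plastomes <- function(params = sim_params()) {
  ref <- simulate_reference(params)
  mut <- mutate_genotypes(ref$genome, ref$structure, ref$features, params)
  structure(list(genomes = mut$genomes, alignment = mut$alignment,
                 truth = mut$truth, structure = ref$structure,
                 features = ref$features, params = params),
            class = "plastome_sim")
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf(paste0("<plastome_sim> %d genotypes, %s bp reference, ",
                     "%d planted events\n"),
              length(x$genomes), format(x$structure$genome_len, big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated genotype set to disk as a reusable fixture
#'
#' Emits one FASTA per genotype, the true alignment as aligned FASTA, the toy
#' features as GFF3 and the truth table as TSV. Re-running with the same
#' parameters and seed reproduces identical files.
#'
#' @param sim A `plastome_sim` from [simulate_plastomes()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
emit_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "plastome_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (g in names(sim$genomes)) {
    p <- file.path(outdir, paste0(g, ".fasta"))
    write_genomes(sim$genomes[g], p)
    paths[paste0("fasta_", g)] <- p
  }
  aln_path <- file.path(outdir, "alignment.fasta")
  write_alignment(sim$alignment, aln_path)
  paths["alignment"] <- aln_path
  gff_path <- file.path(outdir, "features.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = "G1",
    ranges = IRanges::IRanges(start = sim$features$start, end = sim$features$end),
    strand = sim$features$strand,
    type = sim$features$kind, Name = sim$features$name,
    ID = sim$features$name, source = "plastmine")
  rtracklayer::export(gr, gff_path, format = "gff3")
  paths["features"] <- gff_path
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_path)
  paths["truth"] <- truth_path
  paths
}
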