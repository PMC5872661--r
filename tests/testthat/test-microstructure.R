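test_that("indel events follow the constant-pattern run definition", {
  base <- rand_seq(40, 201)
  rows <- stats::setNames(rep(base, 6), paste0("G", 1:6))
  # 3 bp deletion in G3 at columns 11-13
  rows[["G3"]] <- paste0(substr(base, 1, 10), "---", substr(base, 14, 40))
  aln <- alignment_matrix(rows)
  ev <- extract_indels(aln, "G1")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$size, 3L)
  expect_identical(ev$ref_start, 11L)
  expect_identical(ev$ref_end, 13L)
  expect_identical(ev$gapped_genotypes, "G3")
  pol <- ev$polarity[[1]]
  expect_identical(unname(pol["G3"]), "deletion")
  expect_true(all(pol[setdiff(names(pol), "G3")] == "reference-state"))
  expect_identical(ev$allele_present, substr(base, 11, 13))

  # a gap run shared by two genotypes is one event
  rows[["G5"]] <- rows[["G3"]]
  ev2 <- extract_indels(alignment_matrix(rows), "G1")
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$gapped_genotypes, "G3,G5")

  # insertion relative to the reference: zero-length reference interval
  rows3 <- stats::setNames(rep(paste0(substr(base, 1, 20), "--",
                                      substr(base, 21, 40)), 6),
                           paste0("G", 1:6))
  rows3[["G2"]] <- paste0(substr(base, 1, 20), "CA", substr(base, 21, 40))
  ev3 <- extract_indels(alignment_matrix(rows3), "G1")
  expect_identical(nrow(ev3), 1L)
  expect_false(ev3$ref_has_seq)
  expect_identical(ev3$ref_start, 21L)
  expect_identical(ev3$ref_end, 20L)
  expect_identical(unname(ev3$polarity[[1]]["G2"]), "insertion")

  # an all-gap column is a malformed alignment
  rows4 <- stats::setNames(rep("AC-GT", 3), c("a", "b", "c"))
  expect_error(extract_indels(alignment_matrix(rows4), "a"), "malformed")
})

test_that("swapping the reference flips polarity but not spans or sizes", {
  sim <- quick_sim(211, n_indels = 10, n_snps = 0, n_inversions = 0,
                   n_ssr_tracts = 0, n_ssr_polymorphic = 0)
  a <- extract_indels(sim$alignment, "G1")
  b <- extract_indels(sim$alignment, "G2")
  expect_identical(a$aln_start, b$aln_start)
  expect_identical(a$aln_end, b$aln_end)
  expect_identical(a$size, b$size)
  flip <- c(insertion = "deletion", deletion = "insertion",
            `reference-state` = "reference-state")
  for (i in seq_len(nrow(a))) {
    pa <- a$polarity[[i]]; pb <- b$polarity[[i]]
    g2_differs <- pa[["G2"]] != "reference-state"
    if (g2_differs) {
      # G2 carries the non-reference state: every label flips through G2's eyes
      expect_identical(unname(pb[["G1"]]), unname(flip[[pa[["G2"]]]]))
    } else {
      expect_identical(pb, pa)
    }
  }
})

test_that("planted indels are recovered with exact size and polarity", {
  sim <- quick_sim(221, n_indels = 12, n_snps = 0, n_inversions = 0,
                   n_ssr_tracts = 0, n_ssr_polymorphic = 0,
                   indel_size_range = c(1, 28))
  ev <- extract_indels(sim$alignment, "G1")
  truth <- sim$truth[sim$truth$kind == "indel", ]
  expect_identical(nrow(ev), 12L)
  expect_identical(sort(ev$size), sort(truth$size))
  key_t <- paste(truth$ref_start, truth$size)
  key_e <- paste(ev$ref_start, ev$size)
  expect_setequal(key_e, key_t)
  for (i in seq_len(nrow(truth))) {
    e <- ev[key_e == key_t[i], ]
    affected <- strsplit(truth$genotypes[i], ",")[[1]]
    pol <- e$polarity[[1]]
    expect_true(all(pol[affected] == truth$direction[i]))
    expect_true(all(pol[setdiff(names(pol), affected)] == "reference-state"))
    expect_identical(e$allele_present, truth$allele[i])
  }
})

test_that("SSR-related indels are separated from common ones by the unit rule", {
  base <- plastmine:::screen_background(rand_seq(120, 231), 0.37)
  tract <- strrep("TA", 7)
  seq_ref <- paste0(substr(base, 1, 50), "GG", tract, "GG",
                    substr(base, 51, 120))
  # genotype with one fewer TA unit (2 bp gap inside the tract), plus an
  # unrelated 1 bp deletion in a tract-free region
  gstart <- 53L  # tract begins after 50 bp + "GG"
  rows <- c(
    G1 = paste0(substr(seq_ref, 1, gstart + 13), "--",
                substr(seq_ref, gstart + 14, nchar(seq_ref))),
    G2 = paste0(substr(seq_ref, 1, gstart + 13), "TA",
                substr(seq_ref, gstart + 14, nchar(seq_ref))))
  rows <- vapply(rows, function(r) paste0(r, "X"), character(1))
  rows <- gsub("X", "", rows)  # no-op, keep as plain character
  del_at <- 20L
  rows[["G2"]] <- paste0(substr(rows[["G2"]], 1, del_at - 1), "-",
                         substr(rows[["G2"]], del_at + 1, nchar(rows[["G2"]])))
  aln <- alignment_matrix(rows)
  genomes <- structure(list(
    G1 = genome_record("G1", gsub("-", "", rows[["G1"]])),
    G2 = genome_record("G2", gsub("-", "", rows[["G2"]]))),
    class = "genome_set")
  loci <- purrr::map_dfr(genomes, detect_ssrs)
  ev <- extract_indels(aln, "G1")
  split <- filter_ssr_indels(ev, loci, aln)
  expect_identical(nrow(split$ssr_related), 1L)
  expect_identical(split$ssr_related$allele_present, "TA")
  expect_identical(nrow(split$common), 1L)
  expect_identical(split$common$size, 1L)
  # the two sets partition the events
  expect_identical(nrow(split$common) + nrow(split$ssr_related), nrow(ev))
  expect_length(intersect(split$common$aln_start,
                          split$ssr_related$aln_start), 0)
})

test_that("the simulated mix partitions exactly into SSR-related and common", {
  sim <- quick_sim(241, n_indels = 10, n_ssr_tracts = 10,
                   n_ssr_polymorphic = 10, n_snps = 0, n_inversions = 0)
  loci <- purrr::map_dfr(sim$genomes, detect_ssrs)
  ev <- extract_indels(sim$alignment, "G1")
  split <- filter_ssr_indels(ev, loci, sim$alignment)
  expect_identical(nrow(split$common), 10L)
  expect_identical(nrow(split$ssr_related), 10L)
})

test_that("indel size spectrum bins sizes and regions", {
  empty <- indel_size_spectrum(plastmine:::empty_indel_tibble())
  expect_identical(nrow(empty$by_size), 0L)
  df <- tibble::tibble(size = c(1L, 1L, 2L, 28L),
                       region = c("LSC", "LSC", "SSC", "LSC"))
  sp <- indel_size_spectrum(df)
  expect_identical(sp$by_size$count[sp$by_size$size == 1], 2L)
  expect_identical(sp$by_size$count[sp$by_size$size == 2], 1L)
  expect_identical(sp$by_size$count[sp$by_size$size == 28], 1L)
  expect_identical(sum(sp$by_size$count), 4L)
  expect_equal(sp$by_region$freq[sp$by_region$region == "LSC"], 0.75)
})

test_that("inversions are verified by the flanking inverted-repeat rule", {
  pad1 <- plastmine:::screen_background(rand_seq(60, 251), 0.37)
  pad2 <- plastmine:::screen_background(rand_seq(60, 252), 0.37)
  core <- "AAGG"  # revcomp CCTT; mismatches the reference at every position
  ref <- paste0(pad1, "AAGCTG", core, "CAGCTT", pad2)
  qry <- paste0(pad1, "AAGCTG", plastmine:::revcomp(core), "CAGCTT", pad2)
  aln <- alignment_matrix(c(G1 = ref, G2 = qry))
  inv <- detect_inversions(aln, "G1")
  expect_identical(nrow(inv), 1L)
  expect_identical(inv$length, 4L)
  expect_identical(inv$flank_repeat_len, 6L)
  expect_true(inv$stem_loop_ok)
  expect_identical(inv$core_ref, core)
  expect_identical(inv$inverted_genotypes, "G2")
  expect_identical(inv$ref_start, 67L)

  # a stem below min_stem is not reported (left to the SNP caller)
  ref5 <- paste0(pad1, "TAGCTG", core, "CAGCTT", pad2)  # only 5 bp pair
  qry5 <- paste0(pad1, "TAGCTG", plastmine:::revcomp(core), "CAGCTT", pad2)
  expect_identical(nrow(detect_inversions(
    alignment_matrix(c(G1 = ref5, G2 = qry5)), "G1")), 0L)

  # a single-column mismatch is never an inversion candidate
  qry1 <- paste0(substr(ref, 1, 9), "T", substr(ref, 11, nchar(ref)))
  qry1 <- if (substr(ref, 10, 10) == "T")
    paste0(substr(ref, 1, 9), "G", substr(ref, 11, nchar(ref))) else qry1
  expect_identical(nrow(detect_inversions(
    alignment_matrix(c(G1 = ref, G2 = qry1)), "G1")), 0L)
})

test_that("hairpin statistics mirror the stem/loop definition", {
  inv <- tibble::tibble(flank_repeat_len = c(13L, 5L), loop_len = c(51L, 4L))
  hs <- hairpin_stats(inv, min_stem = 6L)
  expect_identical(hs$stem_len, c(13L, 5L))
  expect_identical(hs$loop_len, c(51L, 4L))
  expect_identical(hs$stem_loop_ok, c(TRUE, FALSE))
})

test_that("planted inversions recover cores, flanks and genotype sets", {
  sim <- quick_sim(261, n_inversions = 3, n_snps = 0, n_indels = 0,
                   n_ssr_tracts = 0, n_ssr_polymorphic = 0,
                   inversion_core_range = c(51, 51),
                   inversion_flank_range = c(13, 13))
  inv <- detect_inversions(sim$alignment, "G1")
  truth <- sim$truth[sim$truth$kind == "inversion", ]
  expect_identical(nrow(inv), 3L)
  expect_identical(inv$length, rep(51L, 3))
  expect_identical(inv$flank_repeat_len, rep(13L, 3))
  expect_identical(sort(inv$ref_start), sort(truth$ref_start))
  ord <- match(inv$ref_start, truth$ref_start)
  expect_identical(inv$inverted_genotypes, truth$genotypes[ord])
  expect_identical(inv$core_ref, truth$allele[ord])

  # symmetry: detecting with an inverted genotype as reference reports the
  # same alignment spans with the genotype set complemented
  g <- strsplit(truth$genotypes[ord][1], ",")[[1]][1]
  inv2 <- detect_inversions(sim$alignment, g)
  expect_identical(sort(inv2$aln_start), sort(inv$aln_start))
  row2 <- inv2[inv2$aln_start == inv$aln_start[1], ]
  expect_identical(
    sort(strsplit(row2$inverted_genotypes, ",")[[1]]),
    sort(setdiff(paste0("G", 1:6),
                 strsplit(inv$inverted_genotypes[1], ",")[[1]])))
})
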