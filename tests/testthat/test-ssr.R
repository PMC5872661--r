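embed_in <- function(core, seed = 1, pad = 60, breaker = "GG") {
  # screened random padding, with breaker bases (chosen disjoint from the
  # planted motif alphabet) so the padding cannot extend the planted repeat
  left <- plastmine:::screen_background(rand_seq(pad, seed), 0.37)
  right <- plastmine:::screen_background(rand_seq(pad, seed + 1000), 0.37)
  paste0(left, breaker, core, breaker, right)
}

test_that("unit-count thresholds gate loci at the boundary", {
  g_no <- genome_record("x", embed_in(strrep("G", 9), seed = 2, breaker = "TT"))
  expect_identical(nrow(detect_ssrs(g_no)), 0L)
  g_yes <- genome_record("x", embed_in(strrep("A", 10), seed = 3))
  loci <- detect_ssrs(g_yes)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_units, 10L)
  expect_identical(loci$unit_len, 1L)
  expect_identical(loci$ssr_type, "(A)10")
  expect_identical(loci$canonical_class, "A/T")
  # penta threshold is 3 units (15 bp), hexa is searched too
  g_penta <- genome_record("x", embed_in(strrep("AATAC", 3), seed = 4))
  expect_identical(detect_ssrs(g_penta)$n_units, 3L)
  g_hexa <- genome_record("x", embed_in(strrep("AATACC", 3), seed = 5, breaker = "GG"))
  expect_identical(detect_ssrs(g_hexa)$unit_len, 6L)
})

test_that("adjacent qualifying repeats merge into a compound locus", {
  core <- paste0(strrep("ATA", 4), "g", strrep("TAA", 6))
  g <- genome_record("x", embed_in(toupper(core), seed = 7))
  loci <- detect_ssrs(g)
  expect_identical(nrow(loci), 1L)
  expect_true(loci$compound)
  expect_identical(loci$ssr_type, "(ATA)4g(TAA)6")
  expect_identical(loci$n_parts, 2L)
  expect_identical(loci$tract_len, nchar(core))
  # far-apart loci stay separate
  core2 <- paste0(strrep("A", 10), "GG",
                  plastmine:::screen_background(rand_seq(120, 9), 0.37),
                  "GG", strrep("AT", 6))
  g2 <- genome_record("x", embed_in(core2, seed = 8))
  expect_identical(nrow(detect_ssrs(g2)), 2L)
})

test_that("overlap resolution keeps longer tracts, then smaller units, then leftmost", {
  # A mononucleotide run is reported at unit length 1 only (unit reduction)
  g <- genome_record("x", embed_in(strrep("A", 12), seed = 11))
  loci <- detect_ssrs(g)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$unit_len, 1L)

  # explicit dedup contract on a hand-built locus table
  tbl <- tibble::tibble(start = c(1L, 5L, 30L), end = c(12L, 16L, 39L),
                        unit_len = c(2L, 1L, 1L), n_units = c(6L, 12L, 10L),
                        motif = c("AT", "A", "T"),
                        tract_len = c(12L, 12L, 10L))
  kept <- deduplicate_ssrs(tbl)
  # tie on tract length 12 -> smaller unit_len wins; disjoint locus kept
  expect_identical(kept$start, c(5L, 30L))
  expect_identical(kept$unit_len, c(1L, 1L))

  # randomized overlapping sets: output is overlap-free and every dropped
  # locus overlaps a kept locus of at least its tract length
  for (seed in c(21, 22)) {
    tbl2 <- withr::with_seed(seed, {
      s <- sample.int(200, 30, replace = TRUE)
      u <- sample.int(3, 30, replace = TRUE)
      nu <- sample(3:12, 30, replace = TRUE)
      tibble::tibble(start = as.integer(s),
                     end = as.integer(s + u * nu - 1L),
                     unit_len = as.integer(u), n_units = as.integer(nu),
                     motif = strrep("A", u), tract_len = as.integer(u * nu))
    })
    kept2 <- deduplicate_ssrs(tbl2)
    ov <- function(a, b) a$start <= b$end & a$end >= b$start
    for (i in seq_len(nrow(kept2))) {
      for (j in seq_len(nrow(kept2))) {
        if (i < j) expect_false(ov(kept2[i, ], kept2[j, ]))
      }
    }
    dropped <- dplyr::anti_join(tbl2, kept2,
                                by = c("start", "end", "unit_len"))
    for (i in seq_len(nrow(dropped))) {
      hits <- kept2[ov(kept2, dropped[i, ]), ]
      expect_true(any(hits$tract_len >= dropped$tract_len[i]))
    }
  }
})

test_that("the miner equals the exhaustive regex oracle on random sequence", {
  for (seed in c(31, 32)) {
    seq <- rand_seq(10000, seed)
    got <- detect_ssrs(genome_record("x", seq))
    want <- oracle_ssr_loci(seq)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$ssr_type, want$ssr_type)
  }
})

test_that("every reported locus re-validates against its sequence", {
  seq <- toupper(paste0(rand_seq(6000, 41),
                        embed_in(paste0(strrep("AT", 7), "C", strrep("A", 11)),
                                 seed = 42),
                        rand_seq(6000, 43)))
  loci <- detect_ssrs(genome_record("x", seq))
  plain <- loci[!loci$compound, ]
  for (i in seq_len(nrow(plain))) {
    expect_identical(substr(seq, plain$start[i], plain$end[i]),
                     strrep(plain$motif[i], plain$n_units[i]))
  }
  expect_gt(nrow(loci), 0L)
  # compound loci re-validate through their type string
  comp <- loci[loci$compound, ]
  expect_gt(nrow(comp), 0L)
  for (i in seq_len(nrow(comp))) {
    rebuilt <- gsub("\\(([ACGT]+)\\)(\\d+)", "\\1{\\2}", comp$ssr_type[i])
    parts <- stringr::str_match_all(comp$ssr_type[i],
                                    "\\(([ACGT]+)\\)(\\d+)|([acgtn]+)")[[1]]
    txt <- paste(apply(parts, 1, function(p) {
      if (!is.na(p[2])) strrep(p[2], as.integer(p[3])) else toupper(p[4])
    }), collapse = "")
    expect_identical(substr(seq, comp$start[i], comp$end[i]), txt)
  }
})

test_that("mining the reverse complement preserves counts and classes", {
  seq <- rand_seq(10000, 51)
  fwd <- detect_ssrs(genome_record("x", seq))
  rc <- detect_ssrs(genome_record("x", plastmine:::revcomp(seq)))
  expect_identical(nrow(fwd), nrow(rc))
  expect_identical(sort(fwd$canonical_class), sort(rc$canonical_class))
  expect_identical(sort(fwd$tract_len), sort(rc$tract_len))
})

test_that("planted well-separated tracts are recovered exactly, IRa suppressed", {
  sim <- quick_sim(61, n_ssr_tracts = 10, n_ssr_polymorphic = 0,
                   n_snps = 0, n_indels = 0, n_inversions = 0)
  st <- detect_quadripartite(sim$genomes$G1, canonical = FALSE)
  loci <- detect_ssrs(sim$genomes$G1, structure = st,
                      features = sim$features)
  truth <- sim$truth[sim$truth$kind == "ssr_tract", ]
  expect_identical(nrow(loci), 10L)
  expect_identical(sort(loci$start), sort(truth$ref_start))
  expect_identical(sort(loci$end), sort(truth$ref_end))
  expect_true(all(loci$context == "spacer"))
})

test_that("cross-genotype comparison flags exactly the planted polymorphisms", {
  sim <- quick_sim(62, n_ssr_tracts = 8, n_ssr_polymorphic = 4,
                   n_snps = 0, n_indels = 0, n_inversions = 0)
  loci <- purrr::map_dfr(sim$genomes, detect_ssrs)
  polys <- compare_ssrs(loci, sim$alignment, genomes = sim$genomes)
  expect_identical(nrow(polys), 8L)
  expect_identical(sum(polys$is_polymorphic), 4L)
  truth <- sim$truth[sim$truth$kind == "ssr_polymorphism", ]
  # per-genotype tract lengths match the planted unit counts
  polys_p <- polys[polys$is_polymorphic, ]
  for (i in seq_len(nrow(truth))) {
    row <- polys_p[vapply(polys_p$tract_lengths, function(v)
      v[["G1"]] == truth$ref_end[i] - truth$ref_start[i] + 1L, logical(1)), ]
    expect_identical(nrow(row), 1L)
    lens <- row$tract_lengths[[1]]
    u <- nchar(truth$motif[i])
    affected <- strsplit(truth$genotypes[i], ",")[[1]]
    expect_true(all(lens[affected] == truth$n_units_alt[i] * u))
    others <- setdiff(names(lens), affected)
    expect_true(all(lens[others] == truth$n_units_ref[i] * u))
  }
  # six identical genotypes -> nothing polymorphic
  mono <- quick_sim(63, n_ssr_tracts = 5, n_ssr_polymorphic = 0,
                    n_snps = 0, n_indels = 0, n_inversions = 0)
  loci_m <- purrr::map_dfr(mono$genomes, detect_ssrs)
  polys_m <- compare_ssrs(loci_m, mono$alignment, genomes = mono$genomes)
  expect_identical(sum(polys_m$is_polymorphic), 0L)
})

test_that("flank extraction respects coordinates and circular wrap", {
  seq <- rand_seq(2000, 71)
  g <- genome_record("x", seq, circular = TRUE)
  loci <- tibble::tibble(start = 1001L, end = 1012L)
  fl <- extract_flanks(g, loci, flank_len = 50L)
  expect_identical(fl$left_flank, substr(seq, 951, 1000))
  expect_identical(fl$right_flank, substr(seq, 1013, 1062))
  # zero-length flanks
  fl0 <- extract_flanks(g, loci, flank_len = 0L)
  expect_identical(fl0$left_flank, "")
  # wrap through the origin
  near <- tibble::tibble(start = 5L, end = 16L)
  flw <- extract_flanks(g, near, flank_len = 10L)
  expect_identical(flw$left_flank, paste0(substr(seq, 1995, 2000),
                                          substr(seq, 1, 4)))
  # linear genomes refuse to wrap
  glin <- genome_record("x", seq, circular = FALSE)
  expect_error(extract_flanks(glin, near, flank_len = 10L), "linear")
})
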