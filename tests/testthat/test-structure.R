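test_that("quadripartite spans are exact on constructed toys", {
  toy <- toy_plastome(lsc = 1000, ir = 300, ssc = 200, seed = 101)
  st <- detect_quadripartite(toy$genome, min_ir_len = 100, canonical = FALSE)
  expect_true(st$has_ir)
  expect_identical(st$regions$region, c("LSC", "IRb", "SSC", "IRa"))
  expect_identical(st$regions$start, c(1L, 1001L, 1301L, 1501L))
  expect_identical(st$regions$end, c(1000L, 1300L, 1500L, 1800L))
  # IRa is exactly the reverse complement of IRb
  irb <- substr(toy$genome$seq, 1001, 1300)
  ira <- substr(toy$genome$seq, 1501, 1800)
  expect_identical(ira, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(irb))))
})

test_that("detection agrees with the O(n^2) brute-force inverted-repeat scan", {
  for (seed in c(11, 12, 13)) {
    ir_len <- 250 + seed
    toy <- toy_plastome(lsc = 2600, ir = ir_len, ssc = 700, seed = seed)
    st <- detect_quadripartite(toy$genome, min_ir_len = 150, canonical = FALSE)
    oracle <- oracle_longest_ir(toy$genome$seq)
    expect_identical(oracle$len, as.integer(ir_len))
    reg <- st$regions
    expect_identical(reg$length[reg$region == "IRb"], as.integer(ir_len))
    expect_identical(reg$start[reg$region == "IRb"], oracle$a_start)
    expect_identical(reg$start[reg$region == "IRa"], oracle$b_start)
  }
})

test_that("rotation and reverse-complement round-trip to one canonical form", {
  toy <- toy_plastome(lsc = 2000, ir = 400, ssc = 600, seed = 21)
  g <- toy$genome
  st <- detect_quadripartite(g, min_ir_len = 200)
  canon <- canonicalize_orientation(g, st)
  # canonicalizing the canonical form is the identity
  st2 <- detect_quadripartite(canon, min_ir_len = 200)
  canon2 <- canonicalize_orientation(canon, st2)
  expect_identical(canon2$seq, canon$seq)
  expect_identical(st2$regions, st$regions)

  # rotated input recovers the same canonical sequence
  rot <- genome_record(g$id, paste0(substr(g$seq, 1201, nchar(g$seq)),
                                    substr(g$seq, 1, 1200)))
  st_rot <- detect_quadripartite(rot, min_ir_len = 200)
  expect_identical(canonicalize_orientation(rot, st_rot)$seq, canon$seq)

  # reverse-complemented input too
  rc <- genome_record(g$id, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$seq))))
  st_rc <- detect_quadripartite(rc, min_ir_len = 200)
  expect_identical(canonicalize_orientation(rc, st_rc)$seq, canon$seq)
  # and region lengths are strand-invariant
  expect_identical(st_rc$regions$length, st$regions$length)
})

test_that("a rotation that puts the origin inside an IR is still resolved", {
  toy <- toy_plastome(lsc = 2000, ir = 400, ssc = 600, seed = 22)
  g <- toy$genome
  canon <- canonicalize_orientation(g, detect_quadripartite(g, min_ir_len = 200))
  cut <- 2200  # inside IRb
  rot <- genome_record(g$id, paste0(substr(g$seq, cut, nchar(g$seq)),
                                    substr(g$seq, 1, cut - 1)))
  st_rot <- detect_quadripartite(rot, min_ir_len = 200)
  expect_identical(sort(st_rot$regions$length), sort(c(2000L, 400L, 600L, 400L)))
  expect_identical(canonicalize_orientation(rot, st_rot)$seq, canon$seq)
})

test_that("region lookup matches a linear scan and respects boundaries", {
  toy <- toy_plastome(lsc = 1500, ir = 350, ssc = 400, seed = 31)
  st <- detect_quadripartite(toy$genome, min_ir_len = 200, canonical = FALSE)
  expect_identical(region_of(1L, st), "LSC")
  expect_identical(region_of(1500L, st), "LSC")
  expect_identical(region_of(1501L, st), "IRb")   # first base past the LSC
  expect_identical(region_of(st$genome_len, st), "IRa")
  expect_identical(region_of(1501L, st, collapse = TRUE), "IR")
  expect_error(region_of(0L, st), "out of range")
  expect_error(region_of(st$genome_len + 1L, st), "out of range")

  pos <- withr::with_seed(1, sample.int(st$genome_len, 200))
  scan <- vapply(pos, function(p) {
    r <- st$regions
    r$region[r$start <= p & r$end >= p]
  }, character(1))
  expect_identical(region_of(pos, st), scan)
})

test_that("region lengths sum to the genome and GC aggregates by length", {
  toy <- toy_plastome(lsc = 1800, ir = 300, ssc = 500, seed = 41)
  st <- detect_quadripartite(toy$genome, min_ir_len = 150, canonical = FALSE)
  expect_identical(sum(st$regions$length), st$genome_len)
  whole_gc <- sum(st$regions$length * st$regions$gc) / st$genome_len
  observed <- glance(st)$gc
  expect_equal(observed, whole_gc, tolerance = 1e-12)
  # and the length-weighted mean equals the direct whole-genome GC
  gc_direct <- mean(strsplit(toy$genome$seq, "")[[1]] %in% c("G", "C"))
  expect_equal(whole_gc, gc_direct, tolerance = 1e-12)
})

test_that("a genome without a long inverted repeat gets the structured no-IR result", {
  g <- genome_record("plain", rand_seq(3000, 51))
  st <- detect_quadripartite(g, min_ir_len = 500)
  expect_false(st$has_ir)
  expect_identical(st$regions$region, "whole")
  expect_identical(region_of(c(1L, 1500L, 3000L), st),
                   rep("whole", 3))
  # canonicalization is then the identity
  expect_identical(canonicalize_orientation(g, st)$seq, g$seq)
  # and the precondition on genome length is enforced
  expect_error(detect_quadripartite(g, min_ir_len = 2000), "min_ir_len")
})
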