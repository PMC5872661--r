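ref_of <- function(aln, id = "G1") genome_record(id, gsub("-", "", aln$rows[[id]]))

test_that("SNP calling implements the column contract", {
  base <- rand_seq(60, 61)
  rows <- c(G1 = base, G2 = base, G3 = base, G4 = base, G5 = base, G6 = base)
  aln <- alignment_matrix(rows)
  st <- whole_structure(ref_of(aln))
  expect_identical(nrow(call_snps(aln, st, "G1")), 0L)  # identical rows

  # single A/G column is one transition SNP
  sub <- function(x, i, b) { substr(x, i, i) <- b; x }
  rows2 <- rows
  rows2[["G4"]] <- sub(rows2[["G4"]], 10, if (substr(base, 10, 10) == "A") "G" else "A")
  if (!substr(base, 10, 10) %in% c("A", "G")) {
    rows2[["G4"]] <- sub(rows2[["G1"]], 10, "A")
    for (g in names(rows2)) rows2[[g]] <- sub(rows2[[g]], 10, if (g == "G4") "G" else "A")
  }
  aln2 <- alignment_matrix(rows2)
  snps <- call_snps(aln2, st, "G1")
  expect_identical(nrow(snps), 1L)
  expect_identical(snps$subst_class, "A-G")
  expect_true(snps$is_transition)
  expect_identical(snps$ref_pos, 10L)

  # a gap anywhere in the column excludes it
  rows3 <- rows2
  rows3[["G6"]] <- sub(rows3[["G6"]], 10, "-")
  expect_identical(nrow(call_snps(alignment_matrix(rows3),
                                  whole_structure(ref_of(aln)), "G1")), 0L)

  # N alleles are ignored: one non-N state left is not a SNP
  rows4 <- rows
  rows4[["G2"]] <- sub(rows4[["G2"]], 20, "N")
  expect_identical(nrow(call_snps(alignment_matrix(rows4), st, "G1")), 0L)

  # multiallelic columns are counted once but excluded from the spectrum
  rows5 <- rows2
  alt2 <- setdiff(c("A", "C", "G", "T"),
                  c(substr(rows2[["G1"]], 10, 10), substr(rows2[["G4"]], 10, 10)))[1]
  rows5[["G5"]] <- sub(rows5[["G5"]], 10, alt2)
  snps5 <- call_snps(alignment_matrix(rows5), st, "G1")
  expect_identical(nrow(snps5), 1L)
  expect_true(snps5$multiallelic)
  sp5 <- substitution_spectrum(snps5)
  expect_identical(sp5$ts_total + sp5$tv_total, 0L)
  expect_identical(sp5$n_multiallelic, 1L)
})

test_that("the six-class spectrum books transitions and transversions", {
  sim <- quick_sim(71, n_snps = 60)
  rep <- run_pipeline(sim$genomes, sim$alignment, reference = "G1",
                      features = sim$features)
  sp <- rep$spectrum
  expect_identical(sp$ts_total + sp$tv_total, nrow(rep$snps))
  cls <- tidy(sp)
  expect_identical(sum(cls$count[cls$subst_class %in% c("A-G", "C-T")]),
                   sp$ts_total)
  expect_equal(sp$tv_ts_ratio, sp$tv_total / sp$ts_total)
  # planted class counts recovered exactly from the truth table
  truth_cls <- table(factor(sim$truth$subst_class[sim$truth$kind == "snp"],
                            levels = cls$subst_class))
  expect_identical(cls$count, as.integer(truth_cls))
  # no transitions -> ratio undefined
  empty_sp <- substitution_spectrum(rep$snps[0, ])
  expect_true(is.na(empty_sp$tv_ts_ratio))
})

test_that("IR-mirrored variants are counted once", {
  toy <- toy_plastome(lsc = 1200, ir = 400, ssc = 300, seed = 81)
  g <- toy$genome
  st <- detect_quadripartite(g, min_ir_len = 200, canonical = FALSE)
  reg <- st$regions
  irb_pos <- reg$start[2] + 100L
  ira_pos <- reg$start[4] + (reg$end[4] - reg$start[4]) - 100L  # mirror
  s2 <- strsplit(g$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # substitute base in IRb and the complementary base at the IRa mirror
  old <- s2[irb_pos]
  new <- if (old == "A") "G" else "A"
  s2[irb_pos] <- new
  expect_identical(s2[ira_pos], comp[[old]])  # sanity: exact mirror
  s2[ira_pos] <- comp[[new]]
  rows <- c(G1 = g$seq, G2 = paste(s2, collapse = ""))
  snps <- call_snps(alignment_matrix(rows), st, "G1")
  expect_identical(nrow(snps), 1L)
  expect_identical(snps$region, "IR")
  # per-region counts still sum to the total
  expect_identical(sum(table(snps$region)), nrow(snps))
})

test_that("spectrum is strand-symmetric in its directed base-pair types", {
  sim <- quick_sim(91, n_snps = 40, n_indels = 0, n_inversions = 0,
                   n_ssr_tracts = 0, n_ssr_polymorphic = 0)
  aln <- sim$alignment
  st_f <- whole_structure(ref_of(aln))
  fwd <- substitution_spectrum(call_snps(aln, st_f, "G1"))
  rc_rows <- vapply(aln$rows, function(r)
    stringi::stri_reverse(chartr("ACGTN-", "TGCAN-", r)), character(1))
  aln_rc <- alignment_matrix(rc_rows)
  st_r <- whole_structure(ref_of(aln_rc))
  rev <- substitution_spectrum(call_snps(aln_rc, st_r, "G1"))
  # the directed base-pair types pool each substitution with its complement
  # and are therefore identical on either strand, as are the Ts/Tv totals
  expect_identical(fwd$pair_classes, rev$pair_classes)
  expect_identical(c(fwd$ts_total, fwd$tv_total),
                   c(rev$ts_total, rev$tv_total))
  # the unordered classes map onto each other in complement pairs
  cf <- tidy(fwd); cr <- tidy(rev)
  comp_of <- c("A-G" = "C-T", "C-T" = "A-G", "A-T" = "A-T",
               "A-C" = "G-T", "G-T" = "A-C", "G-C" = "G-C")
  expect_identical(cf$count,
                   cr$count[match(comp_of[cf$subst_class], cr$subst_class)])
})

test_that("variable and parsimony-informative sites match their definitions", {
  aln <- alignment_matrix(c(a = "AAAG", b = "AAAG", c = "AGAG", d = "AGCG"))
  # col2 A,A,G,G: variable + informative; col3 A,A,A,C: variable only;
  # col1/col4 invariant
  got <- count_site_classes(aln)
  expect_identical(got$variable_sites, 2L)
  expect_identical(got$parsimony_informative_sites, 1L)

  # exhaustive per-column oracle on random small alignments
  for (seed in c(5, 6)) {
    rows <- withr::with_seed(seed, {
      m <- matrix(sample(c("A", "C", "G", "T", "-"), 6 * 80, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), nrow = 6)
      apply(m, 1, paste, collapse = "")
    })
    names(rows) <- paste0("G", 1:6)
    aln2 <- alignment_matrix(rows)
    mat <- aln2$mat
    oracle <- c(0L, 0L)
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      if (any(col == "-")) next
      states <- table(col[col %in% c("A", "C", "G", "T")])
      if (length(states) >= 2) oracle[1] <- oracle[1] + 1L
      if (sum(states >= 2) >= 2) oracle[2] <- oracle[2] + 1L
    }
    got2 <- count_site_classes(aln2)
    expect_identical(c(got2$variable_sites, got2$parsimony_informative_sites),
                     oracle)
  }
})
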