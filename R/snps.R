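# SNP calling from the multiple alignment: gap-free variable columns, IR
# deduplication, genomic/genic context, and the six-class substitution
# spectrum with transition/transversion accounting.

SUBST_CLASSES <- c("A-G", "C-T", "A-T", "A-C", "G-T", "G-C")
TRANSITIONS <- c("A-G", "C-T")

# Per-column base-count matrix (4 x width, rows A,C,G,T).
column_base_counts <- function(mat) {
  out <- matrix(0L, nrow = 4L, ncol = ncol(mat),
                dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) out[b, ] <- colSums(mat == b)
  out
}

#' Call SNPs from a multiple alignment
#'
#' A SNP is an alignment column with no gap in any genotype and at least two
#' distinct non-N bases. Columns inside IRa whose mirrored IRb column carries
#' the complementary variant are excluded, so each IR variant is counted once.
#' Columns listed in `mask_cols` (e.g. the cores of detected inversions, which
#' are a different event class) are skipped.
#'
#' The reference having a gap at a variable column cannot occur here: columns
#' containing any gap are excluded from calling altogether (they are indel
#' territory, handled by [extract_indels()]).
#'
#' @param aln A [alignment_matrix()].
#' @param structure `quadripartite` structure of the canonicalized reference
#'   genotype.
#' @param ref_id Reference genotype id (the standard genotype all coordinates
#'   are reported on).
#' @param features Optional feature table of the reference genome for genic
#'   context.
#' @param mask_cols Optional integer vector of alignment columns to exclude.
#' @return Tibble with one row per SNP: `aln_col`, `ref_pos`, `region`
#'   (collapsed, IR counted once), `context`, `context_name`, `n_alleles`,
#'   `alleles`, `ref_allele`, `subst_class` (`NA` for multiallelic columns),
#'   `is_transition`, `multiallelic`, and `genotype_alleles` (list column of
#'   named per-genotype bases).
#' @export
call_snps <- function(aln, structure, ref_id, features = NULL,
                      mask_cols = NULL) {
  stopifnot(inherits(aln, "plast_alignment"), ref_id %in% aln$ids)
  mat <- aln$mat
  gapfree <- colSums(mat == "-") == 0L
  bc <- column_base_counts(mat)
  n_states <- colSums(bc > 0L)
  candidate <- gapfree & n_states >= 2L
  if (!is.null(mask_cols)) candidate[mask_cols] <- FALSE
  cols <- which(candidate)
  if (!length(cols)) return(empty_snp_tibble())

  ref_pos <- aln$column_map[[ref_id]][cols]
  keep <- collapse_ir_columns(aln, structure, ref_id, cols, ref_pos)
  cols <- cols[keep]
  ref_pos <- ref_pos[keep]

  genotype_alleles <- purrr::map(cols, function(cc) mat[, cc])
  allele_sets <- purrr::map(genotype_alleles,
                            function(a) sort(unique(a[a %in% DNA_BASES])))
  n_alleles <- lengths(allele_sets)
  subst_class <- purrr::map_chr(allele_sets, function(a) {
    if (length(a) != 2L) return(NA_character_)
    canonical_subst_class(a[1], a[2])
  })
  ref_allele <- mat[ref_id, cols]
  out <- tibble(
    aln_col = cols,
    ref_pos = as.integer(ref_pos),
    region = region_of(ref_pos, structure, collapse = TRUE),
    n_alleles = as.integer(n_alleles),
    alleles = purrr::map_chr(allele_sets, paste, collapse = "/"),
    ref_allele = ref_allele,
    subst_class = subst_class,
    pair_class = purrr::map2_chr(allele_sets, ref_allele, pair_class_of),
    is_transition = subst_class %in% TRANSITIONS,
    multiallelic = n_alleles > 2L,
    genotype_alleles = genotype_alleles
  )
  ctx <- annotate_context(out$ref_pos, features, structure$genome_len)
  out$context <- ctx$context
  out$context_name <- ctx$context_name
  out %>% select("aln_col", "ref_pos", "region", "context", "context_name",
                 dplyr::everything())
}

empty_snp_tibble <- function() {
  tibble(aln_col = integer(), ref_pos = integer(), region = character(),
         context = character(), context_name = character(),
         n_alleles = integer(), alleles = character(),
         ref_allele = character(), subst_class = character(),
         pair_class = character(), is_transition = logical(),
         multiallelic = logical(), genotype_alleles = list())
}

PAIR_CLASSES <- c("AT>GC", "GC>AT", "AT>CG", "GC>TA", "AT>TA", "GC>CG")

# Directed, strand-symmetric base-pair substitution type for a biallelic
# site, polarized by the reference allele: complementary substitutions (e.g.
# C->T and G->A) pool into one type (GC>AT), so the six types are invariant
# under reverse-complementing the genome set. NA for multiallelic sites or a
# reference N.
pair_class_of <- function(alleles, ref_allele) {
  if (length(alleles) != 2L || !ref_allele %in% alleles) return(NA_character_)
  alt <- setdiff(alleles, ref_allele)
  b <- ref_allele
  if (b %in% c("T", "C")) {  # orient the strand so the source reads A or G
    b <- complement(b)
    alt <- complement(alt)
  }
  src <- if (b == "A") "AT" else "GC"
  dst <- switch(alt, A = "AT", T = "TA", G = "GC", C = "CG")
  paste0(src, ">", dst)
}

# Canonical unordered label for a biallelic substitution.
canonical_subst_class <- function(b1, b2) {
  pair <- paste(sort(c(b1, b2)), collapse = "-")
  # map the sorted pair onto the six canonical labels
  switch(pair,
         "A-G" = "A-G", "C-T" = "C-T", "A-T" = "A-T",
         "A-C" = "A-C", "G-T" = "G-T", "C-G" = "G-C",
         stop("not a base pair: ", pair))
}

# Keep-mask implementing "IR variants counted once": drop a variable column
# whose reference position lies in IRa when the mirrored IRb position is also
# a variable column carrying the complementary alleles genotype-by-genotype.
collapse_ir_columns <- function(aln, structure, ref_id, cols, ref_pos) {
  keep <- rep(TRUE, length(cols))
  if (!structure$has_ir) return(keep)
  reg <- structure$regions
  ira <- reg[reg$region == "IRa", ]
  irb <- reg[reg$region == "IRb", ]
  in_ira <- ref_pos >= ira$start & ref_pos <= ira$end
  if (!any(in_ira)) return(keep)
  col_set <- cols
  for (i in which(in_ira)) {
    mirror_pos <- irb$start + (ira$end - ref_pos[i])
    mcol <- aln$pos_to_col[[ref_id]][mirror_pos]
    j <- match(mcol, col_set)
    if (is.na(j)) next
    here <- aln$mat[, cols[i]]
    there <- aln$mat[, cols[j]]
    if (all(there == complement(here))) keep[i] <- FALSE
  }
  keep
}

#' Six-class substitution spectrum with Ts/Tv accounting
#'
#' Tallies biallelic SNPs into substitution classes in two presentations: the
#' six unordered base-pair classes (`A-G`, `C-T`, `A-T`, `A-C`, `G-T`, `G-C`;
#' the transition/transversion arithmetic lives here) and the six directed,
#' strand-symmetric base-pair types polarized by the reference allele
#' (`AT>GC`, `GC>AT`, ...), in which complementary substitutions such as
#' C-to-T and G-to-A pool into one type. Reverse-complementing every genome
#' leaves the directed-pair table and the Ts/Tv totals unchanged, while the
#' unordered classes map onto each other in complement pairs (A-G with C-T,
#' A-C with G-T). Multiallelic sites are counted in a separate overflow
#' bucket and excluded from the transition/transversion totals.
#'
#' @param snps SNP tibble from [call_snps()].
#' @return An object of class `snp_spectrum`: `classes` and `pair_classes`
#'   count tables plus `ts_total`, `tv_total`, `tv_ts_ratio` (`NA` when there
#'   are no transitions) and `n_multiallelic`.
#' @export
substitution_spectrum <- function(snps) {
  bi <- snps %>% filter(!.data$multiallelic)
  counts <- table(factor(bi$subst_class, levels = SUBST_CLASSES))
  classes <- tibble(
    subst_class = SUBST_CLASSES,
    count = as.integer(counts),
    is_transition = SUBST_CLASSES %in% TRANSITIONS
  )
  pair_counts <- table(factor(bi$pair_class, levels = PAIR_CLASSES))
  pair_classes <- tibble(
    pair_class = PAIR_CLASSES,
    count = as.integer(pair_counts),
    is_transition = PAIR_CLASSES %in% c("AT>GC", "GC>AT")
  )
  ts_total <- sum(classes$count[classes$is_transition])
  tv_total <- sum(classes$count[!classes$is_transition])
  structure(list(
    classes = classes,
    pair_classes = pair_classes,
    ts_total = ts_total,
    tv_total = tv_total,
    tv_ts_ratio = if (ts_total == 0L) NA_real_ else tv_total / ts_total,
    n_multiallelic = sum(snps$multiallelic)
  ), class = "snp_spectrum")
}

#' @export
print.snp_spectrum <- function(x, ...) {
  cat(sprintf("<snp_spectrum> %d biallelic SNPs: %d Ts + %d Tv (Tv/Ts = %s)",
              x$ts_total + x$tv_total, x$ts_total, x$tv_total,
              format(x$tv_ts_ratio, digits = 3)))
  if (x$n_multiallelic > 0) cat(sprintf(" + %d multiallelic", x$n_multiallelic))
  cat("\n")
  print(x$classes)
  invisible(x)
}

#' @method tidy snp_spectrum
#' @export
#' @rdname substitution_spectrum
tidy.snp_spectrum <- function(x, ...) x$classes

#' @method glance snp_spectrum
#' @export
#' @rdname substitution_spectrum
glance.snp_spectrum <- function(x, ...) {
  tibble(n_snps = x$ts_total + x$tv_total + x$n_multiallelic,
         ts_total = x$ts_total, tv_total = x$tv_total,
         tv_ts_ratio = x$tv_ts_ratio, n_multiallelic = x$n_multiallelic)
}

#' Count variable and parsimony-informative sites
#'
#' Variable sites are gap-free columns with at least two distinct non-N bases;
#' parsimony-informative sites additionally require at least two states each
#' present in at least two genotypes.
#'
#' @param aln A [alignment_matrix()] with at least two rows.
#' @return One-row tibble: `variable_sites`, `parsimony_informative_sites`.
#' @export
count_site_classes <- function(aln) {
  stopifnot(inherits(aln, "plast_alignment"), length(aln$ids) >= 2L)
  mat <- aln$mat
  gapfree <- colSums(mat == "-") == 0L
  bc <- column_base_counts(mat)
  variable <- gapfree & colSums(bc > 0L) >= 2L
  informative <- variable & colSums(bc >= 2L) >= 2L
  tibble(variable_sites = sum(variable),
         parsimony_informative_sites = sum(informative))
}
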