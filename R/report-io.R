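# Report writers: TSV (1-based inclusive, stated in a header comment), VCF
# 4.2 for SNPs, BED6 (0-based half-open) for event spans, and a summary table.

TSV_COMMENT <- "# coordinates: 1-based inclusive"
BED_COMMENT <- "# coordinates: 0-based half-open (BED)"

write_tsv_commented <- function(df, path, comment = TSV_COMMENT) {
  writeLines(comment, path)
  # flatten list columns for the flat-file view
  flat <- df %>% mutate(across(
    dplyr::where(is.list),
    ~ purrr::map_chr(.x, function(v) {
      if (is.null(v) || !length(v)) return("")
      if (!is.null(names(v))) paste(names(v), v, sep = "=", collapse = ";")
      else paste(v, collapse = ";")
    })))
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_bed6 <- function(df, path, name, score = 0L, strand = ".") {
  writeLines(BED_COMMENT, path)
  bed <- tibble(
    chrom = df$chrom,
    start = df$start - 1L,       # 1-based inclusive -> 0-based half-open
    end = as.integer(df$end),
    name = if (length(name)) name else character(0),
    score = score, strand = strand
  )
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

# Minimal VCF 4.2 for the SNP table (reference genotype is the VCF contig).
write_snp_vcf <- function(snps, ref_id, genome_len, ids, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=plastmine",
    sprintf("##contig=<ID=%s,length=%d>", ref_id, genome_len),
    "##INFO=<ID=RG,Number=1,Type=String,Description=\"Collapsed plastome region\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  if (nrow(snps)) {
    body <- vapply(seq_len(nrow(snps)), function(i) {
      ref <- snps$ref_allele[i]
      geno <- snps$genotype_alleles[[i]][ids]
      alts <- setdiff(sort(unique(geno[geno %in% DNA_BASES])), ref)
      if (!length(alts)) alts <- "."
      gt <- vapply(geno, function(b) {
        if (!b %in% DNA_BASES) "."
        else if (b == ref) "0"
        else as.character(match(b, alts))
      }, character(1))
      paste(c(ref_id, snps$ref_pos[i], ".", ref,
              paste(alts, collapse = ","), ".", "PASS",
              paste0("RG=", snps$region[i]), "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write all report files for a marker report
#'
#' Emits SNPs as VCF (reference genotype as contig) and TSV; SSR loci,
#' polymorphisms, indels and inversions as TSV; SSR/indel/inversion spans as
#' BED6 (0-based half-open); a genotype-by-locus SSR tract-length matrix; and
#' a one-row summary TSV. Every TSV states its coordinate convention in a
#' header comment. Empty result sets give headered, body-less files.
#'
#' @param report A `marker_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of paths written.
#' @export
write_reports <- function(report, outdir) {
  stopifnot(inherits(report, "marker_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- report$reference
  ref_len <- report$structures[[ref]]$genome_len
  ids <- sort(unique(report$structure_table$genotype))
  p <- function(f) file.path(outdir, f)
  paths <- c(structure = p("structure.tsv"), snps = p("snps.tsv"),
             snps_vcf = p("snps.vcf"), spectrum = p("spectrum.tsv"),
             ssr_loci = p("ssr_loci.tsv"), ssr_bed = p("ssr_loci.bed"),
             ssr_poly = p("ssr_polymorphisms.tsv"),
             ssr_matrix = p("ssr_tract_matrix.tsv"),
             indels_common = p("indels_common.tsv"),
             indels_ssr = p("indels_ssr_related.tsv"),
             indels_bed = p("indels.bed"),
             inversions = p("inversions.tsv"),
             inversions_bed = p("inversions.bed"),
             summary = p("summary.tsv"))

  write_tsv_commented(report$structure_table, paths["structure"])
  write_tsv_commented(report$snps %>% select(-"genotype_alleles"),
                      paths["snps"])
  write_snp_vcf(report$snps, ref, ref_len, ids, paths["snps_vcf"])
  write_tsv_commented(tidy(report$spectrum), paths["spectrum"])

  write_tsv_commented(report$ssr_loci, paths["ssr_loci"])
  write_bed6(report$ssr_loci %>% rename(chrom = "genotype"),
             paths["ssr_bed"], name = report$ssr_loci$ssr_type)
  write_tsv_commented(report$ssr_polymorphisms %>%
                        select(-"tract_lengths", -"unit_counts"),
                      paths["ssr_poly"])
  write_tsv_commented(ssr_tract_matrix(report$ssr_polymorphisms),
                      paths["ssr_matrix"], comment = "# tract lengths in bp")

  for (what in c("indels_common", "indels_ssr")) {
    write_tsv_commented(report[[what]], paths[what])
  }
  all_indels <- bind_rows(report$indels_common, report$indels_ssr) %>%
    mutate(chrom = ref, start = pmin(.data$ref_start, .data$ref_end),
           end = pmax(.data$ref_start, .data$ref_end))
  write_bed6(all_indels, paths["indels_bed"],
             name = paste0("indel_", all_indels$size, "bp"))
  write_tsv_commented(report$inversions, paths["inversions"])
  write_bed6(report$inversions %>%
               mutate(chrom = ref, start = .data$ref_start,
                      end = .data$ref_end),
             paths["inversions_bed"],
             name = paste0("inversion_", report$inversions$length, "bp"))
  write_tsv_commented(glance(report), paths["summary"])
  paths
}

#' Genotype-by-locus SSR tract-length matrix
#'
#' @param polymorphisms Tibble from [compare_ssrs()].
#' @return Tibble with one row per locus and one `len_<genotype>` column per
#'   genotype (0 = absent).
#' @export
ssr_tract_matrix <- function(polymorphisms) {
  if (!nrow(polymorphisms)) {
    return(tibble(locus_key = character(), is_polymorphic = logical()))
  }
  wide <- purrr::map_dfr(polymorphisms$tract_lengths, function(v)
    as_tibble(as.list(stats::setNames(as.integer(v),
                                      paste0("len_", names(v))))))
  bind_cols(polymorphisms %>% select("locus_key", "canonical_class",
                                     "region", "context", "context_name",
                                     "is_polymorphic"),
            wide)
}
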