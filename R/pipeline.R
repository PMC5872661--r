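# End-to-end orchestration: structure -> inversions -> SNPs -> SSRs ->
# indels on a genome set plus alignment, collected into one marker report.

#' Run the full marker-mining pipeline
#'
#' Executes quadripartite structure delimitation per genotype, inversion
#' detection, SNP calling (inversion cores masked: they are their own event
#' class, not columns of point substitutions), SSR mining and cross-genotype
#' polymorphism calling, and indel extraction with SSR-related/common
#' classification — all against one standard reference genotype.
#'
#' Input genomes must be collinear with the alignment (region-contiguous,
#' LSC first), as a whole-plastome alignment presumes.
#'
#' @param genomes A `genome_set` from [read_genomes()] or a simulation.
#' @param alignment A [alignment_matrix()] over the same genotypes.
#' @param reference Reference genotype id. Defaults to the lexicographically
#'   first id, with a loud message.
#' @param features Optional reference feature table (defaults to the
#'   reference genome's own features, if any).
#' @param ssr_thresholds,compound_max_gap SSR mining parameters
#'   (see [detect_ssrs()]).
#' @param min_ir_len Minimum IR length for structure detection.
#' @param inversion_min_len,inversion_max_len,flank_window,min_stem Inversion
#'   parameters (see [detect_inversions()]).
#' @return An object of class `marker_report` bundling every result table;
#'   see [glance.marker_report()] for the one-row summary.
#' @export
run_pipeline <- function(genomes, alignment, reference = NULL,
                         features = NULL,
                         ssr_thresholds = SSR_THRESHOLDS,
                         compound_max_gap = 100L, min_ir_len = 1000L,
                         inversion_min_len = 2L, inversion_max_len = 100L,
                         flank_window = 30L, min_stem = 6L) {
  if (!length(genomes)) stop("empty genotype set", call. = FALSE)
  stopifnot(inherits(alignment, "plast_alignment"))
  ids <- purrr::map_chr(genomes, "id")
  if (is.null(reference)) {
    reference <- sort(ids)[[1]]
    message("no reference genotype given; using lexicographically first id '",
            reference, "' as the standard reference")
  }
  if (!reference %in% ids) stop("reference '", reference,
                                "' not in genome set", call. = FALSE)
  check_alignment_genomes(alignment, genomes)
  if (is.null(features)) features <- genomes[[reference]]$features

  structures <- purrr::map(genomes, detect_quadripartite,
                           min_ir_len = min_ir_len, canonical = FALSE)
  ref_structure <- structures[[reference]]

  inversions <- detect_inversions(
    alignment, reference, min_len = inversion_min_len,
    max_len = inversion_max_len, flank_window = flank_window,
    min_stem = min_stem, structure = ref_structure, features = features)
  mask <- if (nrow(inversions)) {
    unlist(purrr::map2(inversions$aln_start, inversions$aln_end, seq))
  } else NULL

  snps <- call_snps(alignment, ref_structure, reference, features = features,
                    mask_cols = mask)
  spectrum <- substitution_spectrum(snps)
  site_classes <- count_site_classes(alignment)

  ssr_loci <- purrr::map_dfr(ids, function(g) {
    detect_ssrs(genomes[[g]], thresholds = ssr_thresholds,
                compound_max_gap = compound_max_gap,
                structure = structures[[g]],
                features = if (g == reference) features else NULL)
  })
  ssr_polymorphisms <- compare_ssrs(ssr_loci, alignment, genomes = genomes)

  indels <- extract_indels(alignment, reference, structure = ref_structure,
                           features = features)
  indel_split <- filter_ssr_indels(indels, ssr_loci, alignment)
  spectrum_indels <- indel_size_spectrum(indel_split$common)

  structure_table <- purrr::map_dfr(structures, tidy)

  structure(list(
    reference = reference,
    structure_table = structure_table,
    structures = structures,
    snps = snps,
    spectrum = spectrum,
    site_classes = site_classes,
    ssr_loci = ssr_loci,
    ssr_polymorphisms = ssr_polymorphisms,
    indels_common = indel_split$common,
    indels_ssr = indel_split$ssr_related,
    indel_spectrum = spectrum_indels,
    inversions = inversions,
    params = list(ssr_thresholds = ssr_thresholds,
                  compound_max_gap = compound_max_gap,
                  min_ir_len = min_ir_len,
                  inversion_min_len = inversion_min_len,
                  inversion_max_len = inversion_max_len,
                  flank_window = flank_window, min_stem = min_stem)
  ), class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<marker_report> reference %s\n",
    "  %d genotypes | %d SNPs (%d Ts + %d Tv) | %d SSR loci on reference",
    " (%d polymorphic) |\n  %d common + %d SSR-related indels | %d inversions\n"),
    x$reference, g$n_genotypes, g$n_snps, g$ts_total, g$tv_total,
    g$n_ssr_reference, g$n_ssr_polymorphic, g$n_common_indels,
    g$n_ssr_indels, g$n_inversions))
  invisible(x)
}

#' One-row summary of a marker report
#'
#' @param x A `marker_report` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble of the headline counts: genotypes, SNP totals and
#'   Ts/Tv split, SSR locus counts (on the reference genotype and polymorphic
#'   across genotypes), common and SSR-related indel counts, largest common
#'   indel, and inversion count.
#' @method glance marker_report
#' @export
glance.marker_report <- function(x, ...) {
  tibble(
    reference = x$reference,
    n_genotypes = length(unique(x$structure_table$genotype)),
    n_snps = nrow(x$snps),
    ts_total = x$spectrum$ts_total,
    tv_total = x$spectrum$tv_total,
    tv_ts_ratio = x$spectrum$tv_ts_ratio,
    variable_sites = x$site_classes$variable_sites,
    parsimony_informative_sites = x$site_classes$parsimony_informative_sites,
    n_ssr_reference = sum(x$ssr_loci$genotype == x$reference),
    n_ssr_union = nrow(x$ssr_polymorphisms),
    n_ssr_polymorphic = sum(x$ssr_polymorphisms$is_polymorphic),
    n_common_indels = nrow(x$indels_common),
    n_ssr_indels = nrow(x$indels_ssr),
    max_indel_size = if (nrow(x$indels_common)) max(x$indels_common$size)
                     else NA_integer_,
    n_inversions = nrow(x$inversions)
  )
}

#' Tidy a marker report into one long event table
#'
#' @param x A `marker_report`.
#' @param ... Unused.
#' @return Tibble with one row per marker (`kind` in snp/ssr/indel/inversion)
#'   and the shared columns `ref_start`, `ref_end`, `region`, `context`,
#'   `context_name`.
#' @method tidy marker_report
#' @export
tidy.marker_report <- function(x, ...) {
  ref <- x$reference
  bind_rows(
    x$snps %>% transmute(kind = "snp", ref_start = .data$ref_pos,
                         ref_end = .data$ref_pos, region = .data$region,
                         context = .data$context,
                         context_name = .data$context_name,
                         detail = .data$subst_class),
    x$ssr_loci %>% filter(.data$genotype == ref) %>%
      transmute(kind = "ssr", ref_start = .data$start, ref_end = .data$end,
                region = .data$region, context = .data$context,
                context_name = .data$context_name, detail = .data$ssr_type),
    x$indels_common %>%
      transmute(kind = "indel", ref_start = .data$ref_start,
                ref_end = .data$ref_end, region = .data$region,
                context = .data$context, context_name = .data$context_name,
                detail = paste0(.data$size, "bp")),
    x$inversions %>%
      transmute(kind = "inversion", ref_start = .data$ref_start,
                ref_end = .data$ref_end, region = .data$region,
                context = .data$context, context_name = .data$context_name,
                detail = paste0(.data$length, "bp core/",
                                .data$flank_repeat_len, "bp stem"))
  )
}
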