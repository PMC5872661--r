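# Genic-context labeling: coding / intron / spacer, with spacer names derived
# from flanking genes ("geneA-geneB"). Annotation is taken verbatim from the
# input feature table; nothing is re-annotated.

GENIC_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "exon")

#' Derive intergenic spacers from a feature table
#'
#' Spacers are the maximal intervals not covered by any gene feature, named
#' `"geneA-geneB"` after the flanking genes (circularly, so the interval after
#' the last gene wraps to the first).
#'
#' @param features Feature tibble (`kind`, `name`, `start`, `end`, `strand`).
#' @param genome_len Genome length.
#' @return Tibble of spacer rows in the same layout, `kind = "spacer"`.
#' @export
derive_spacers <- function(features, genome_len) {
  genes <- features %>%
    filter(.data$kind == "gene") %>%
    arrange(.data$start)
  if (!nrow(genes)) {
    genes <- features %>%
      filter(.data$kind %in% GENIC_KINDS) %>%
      arrange(.data$start)
  }
  if (!nrow(genes)) {
    return(tibble(kind = "spacer", name = "intergenic", start = 1L,
                  end = as.integer(genome_len), strand = "+"))
  }
  # merge overlapping gene spans into blocks; a block is flanked-gene-named by
  # its first gene (right flank of a spacer) and last-ending gene (left flank)
  blocks <- list()
  cur <- list(start = genes$start[1], end = genes$end[1],
              first = genes$name[1], last = genes$name[1])
  for (i in seq_len(nrow(genes))[-1]) {
    if (genes$start[i] <= cur$end + 1L) {
      if (genes$end[i] > cur$end) {
        cur$end <- genes$end[i]
        cur$last <- genes$name[i]
      }
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- list(start = genes$start[i], end = genes$end[i],
                  first = genes$name[i], last = genes$name[i])
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  merged <- tibble(
    start = vapply(blocks, function(b) as.integer(b$start), integer(1)),
    end = vapply(blocks, function(b) as.integer(b$end), integer(1)),
    name_first = vapply(blocks, function(b) b$first, character(1)),
    name_last = vapply(blocks, function(b) b$last, character(1))
  )
  k <- nrow(merged)
  out <- list()
  for (i in seq_len(k)) {
    nxt <- if (i == k) 1L else i + 1L
    gap_start <- merged$end[i] + 1L
    gap_end <- if (i == k) genome_len else merged$start[nxt] - 1L
    nm <- paste0(merged$name_last[i], "-", merged$name_first[nxt])
    if (i == k && merged$start[1] > 1L) {
      # wrap: emit tail and head pieces under the same wrapped-spacer name
      if (gap_start <= genome_len) {
        out[[length(out) + 1L]] <- tibble(kind = "spacer", name = nm,
                                          start = gap_start,
                                          end = as.integer(genome_len),
                                          strand = "+")
      }
      out[[length(out) + 1L]] <- tibble(kind = "spacer", name = nm, start = 1L,
                                        end = merged$start[1] - 1L, strand = "+")
    } else if (gap_start <= gap_end) {
      out[[length(out) + 1L]] <- tibble(kind = "spacer", name = nm,
                                        start = as.integer(gap_start),
                                        end = as.integer(gap_end), strand = "+")
    }
  }
  bind_rows(out) %>% filter(.data$start <= .data$end)
}

# Label positions with (context, context_name). Explicit intron features win
# over gene bodies; genic kinds are "coding"; everything else is "spacer".
annotate_context <- function(position, features, genome_len) {
  if (is.null(features)) {
    return(tibble(context = NA_character_, context_name = NA_character_,
                  .rows = length(position)))
  }
  introns <- features %>% filter(.data$kind == "intron")
  genic <- features %>% filter(.data$kind %in% GENIC_KINDS)
  spacers <- derive_spacers(features, genome_len)
  ctx <- rep("spacer", length(position))
  nm <- rep(NA_character_, length(position))
  hit_in <- interval_hit(position, spacers)
  nm <- ifelse(is.na(hit_in), nm, spacers$name[hit_in])
  hit_g <- interval_hit(position, genic)
  ctx[!is.na(hit_g)] <- "coding"
  nm[!is.na(hit_g)] <- genic$name[hit_g[!is.na(hit_g)]]
  hit_i <- interval_hit(position, introns)
  ctx[!is.na(hit_i)] <- "intron"
  nm[!is.na(hit_i)] <- introns$name[hit_i[!is.na(hit_i)]]
  tibble(context = ctx, context_name = nm)
}

# Index of the first interval row containing each position (NA if none).
interval_hit <- function(position, intervals) {
  if (!nrow(intervals)) return(rep(NA_integer_, length(position)))
  vapply(position, function(p) {
    i <- which(intervals$start <= p & intervals$end >= p)
    if (length(i)) i[[1]] else NA_integer_
  }, integer(1))
}
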