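# ggplot2 views of the main result tables.

#' Plot the six-class substitution spectrum
#'
#' Bars for the six non-strand-specific base-substitution types, transitions
#' highlighted.
#'
#' @param spectrum A `snp_spectrum` from [substitution_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- tidy(spectrum) %>%
    mutate(type = ifelse(.data$is_transition, "transition", "transversion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subst_class, y = .data$count,
                                   fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution type", y = "SNPs", fill = NULL,
                  title = sprintf("%d Ts + %d Tv", spectrum$ts_total,
                                  spectrum$tv_total)) +
    ggplot2::theme_minimal()
}

#' @method autoplot snp_spectrum
#' @export
autoplot.snp_spectrum <- function(object, ...) plot_spectrum(object)

#' Plot SSR counts by motif length, region and context
#'
#' @param loci SSR locus tibble from [detect_ssrs()] (one or more genotypes).
#' @param by One of `"unit_len"`, `"region"`, `"context"`.
#' @return A ggplot object.
#' @export
plot_ssr_summary <- function(loci, by = c("unit_len", "region", "context")) {
  by <- match.arg(by)
  df <- loci %>%
    mutate(unit_len = factor(.data$unit_len, levels = 1:6,
                             labels = c("mono", "di", "tri", "tetra",
                                        "penta", "hexa"))) %>%
    count(.data$genotype, .data[[by]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[by]], y = .data$n,
                                   fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = by, y = "SSR loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the common-indel size spectrum
#'
#' @param spectrum An `indel_spectrum` from [indel_size_spectrum()].
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum$by_size,
                  ggplot2::aes(x = .data$size, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "indel size (bp)", y = "common indels") +
    ggplot2::theme_minimal()
}

#' @method autoplot indel_spectrum
#' @export
autoplot.indel_spectrum <- function(object, ...) plot_indel_spectrum(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
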