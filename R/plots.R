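#' @importFrom ggplot2 ggplot aes geom_point geom_segment geom_col
#'   geom_hline facet_wrap labs theme_minimal position_dodge autoplot
NULL

#' Plot a copy-number profile
#'
#' Window-level normalised ratios with segment medians overlaid; the
#' characteristic chromothripsis oscillation between two copy states is
#' immediately visible on the shattered chromosome.
#'
#' @param profile A segmented `sv_cnprofile`.
#' @param chrom Optional chromosome subset.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(profile, chrom = NULL) {
  w <- profile$windows
  s <- profile$segments
  if (!is.null(chrom)) {
    w <- w |> filter(.data$chrom %in% !!chrom)
    s <- s |> filter(.data$chrom %in% !!chrom)
  }
  p <- ggplot(w, aes(x = (.data$start + .data$end) / 2e6,
                     y = .data$normalized_ratio)) +
    geom_point(size = 0.4, alpha = 0.4, colour = "grey40") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "normalized ratio") +
    theme_minimal()
  if (!is.null(s)) {
    p <- p + geom_segment(
      data = s,
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$ratio_median, yend = .data$ratio_median,
          colour = factor(.data$state)),
      linewidth = 1.2, inherit.aes = FALSE
    ) + labs(colour = "copy state")
  }
  p
}

#' @rdname plot_copy_number
#' @param object An `sv_cnprofile`.
#' @param ... Passed to [plot_copy_number()].
#' @export
autoplot.sv_cnprofile <- function(object, ...) {
  plot_copy_number(object, ...)
}

#' Plot observed vs theoretical microhomology spectra
#'
#' Side-by-side bars of observed junction microhomology frequencies per
#' stratum against the closed-form null expectation.
#'
#' @param report An `sv_mh_report` from [stratified_report()].
#' @param max_m Largest length shown.
#' @return A ggplot object.
#' @export
plot_mh_spectrum <- function(report, max_m = 15) {
  h <- report$histogram |>
    filter(.data$m <= max_m) |>
    tidyr::pivot_longer(c("observed", "theoretical"),
                        names_to = "series", values_to = "frequency")
  ggplot(h, aes(x = .data$m, y = .data$frequency, fill = .data$series)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~stratum) +
    labs(x = "microhomology length (bp)", y = "frequency") +
    theme_minimal()
}

#' @rdname plot_mh_spectrum
#' @param object An `sv_mh_report`.
#' @param ... Passed to [plot_mh_spectrum()].
#' @export
autoplot.sv_mh_report <- function(object, ...) {
  plot_mh_spectrum(object, ...)
}

#' Plot SV links along the genome
#'
#' A linear link plot: each link end is a point at its genomic position,
#' ends of a link joined by a segment, coloured by PEM type — a flat
#' stand-in for the usual circular rearrangement plot.
#'
#' @param links An `sv_links` tibble.
#' @param chrom_lengths Named chromosome lengths (or an `sv_genome`) for
#'   panel scaling.
#' @return A ggplot object.
#' @export
plot_links <- function(links, chrom_lengths = NULL) {
  if (inherits(chrom_lengths, "sv_genome")) {
    chrom_lengths <- genome_lengths(chrom_lengths)
  }
  chroms <- sort(unique(c(links$chrom1, links$chrom2)))
  d <- links |>
    mutate(x1 = (.data$start1 + .data$end1) / 2e6,
           x2 = (.data$start2 + .data$end2) / 2e6,
           y1 = match(.data$chrom1, chroms),
           y2 = match(.data$chrom2, chroms))
  ggplot(d) +
    geom_segment(aes(x = .data$x1, xend = .data$x2, y = .data$y1,
                     yend = .data$y2, colour = .data$pem_type,
                     linewidth = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_y_continuous(breaks = seq_along(chroms),
                                labels = chroms) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    labs(x = "position (Mb)", y = NULL, colour = "PEM type") +
    theme_minimal()
}

#' @rdname plot_links
#' @param object An `sv_links` tibble.
#' @param ... Passed to [plot_links()].
#' @export
autoplot.sv_links <- function(object, ...) {
  plot_links(object, ...)
}
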