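#' Score chromosomes for chromothripsis
#'
#' Chromothripsis leaves a characteristic joint signature: tens of copy
#' state switches confined to one chromosome (or one inter-linked
#' chromosome pair), oscillation between two dominant copy states, and
#' geographic concentration of the sample's SV breakpoints on the same
#' chromosome. Each chromosome is scored on all components and flagged
#' only when every threshold is met. Chromosome pairs connected by at
#' least `joint_min_links` inter-chromosomal links are additionally
#' evaluated as a joined unit, capturing two-chromosome shattering.
#'
#' @param profile A segmented `sv_cnprofile`.
#' @param links An `sv_links` tibble from [cluster_links()] for the same
#'   sample.
#' @param min_switches Minimum number of adjacent-segment state switches.
#' @param max_states Maximum number of distinct copy states.
#' @param min_two_state_share Minimum share of segments in the two most
#'   common states.
#' @param min_end_fraction Minimum share of all SV link ends on the
#'   chromosome (or joined pair).
#' @param joint_min_links Inter-chromosomal link count that triggers
#'   joint evaluation of a chromosome pair.
#' @param min_segment_windows Segments narrower than this many windows
#'   are ignored by the state statistics: below that scale, segments are
#'   almost always boundary slivers (a window mixing two true states) or
#'   read-depth chatter, and copy-number segments are only reliably
#'   recovered from five windows upward.
#' @return An `sv_ctx_report`: tibble with one row per evaluated unit
#'   (`chrom`, possibly `"chrA+chrB"`), `n_state_switches`,
#'   `n_distinct_states`, `oscillation_fraction`, `sv_end_fraction`,
#'   `flag`.
#' @export
chromothripsis_score <- function(profile, links,
                                 min_switches = 10,
                                 max_states = 3,
                                 min_two_state_share = 0.9,
                                 min_end_fraction = 0.5,
                                 joint_min_links = 5,
                                 min_segment_windows = 5) {
  assert_that(!is.null(profile$segments),
              "profile must be segmented (run normalize_and_segment()).")
  segs <- profile$segments
  link_chroms <- c(links$chrom1, links$chrom2)
  assert_that(all(link_chroms %in% unique(segs$chrom)) || nrow(links) == 0,
              "profile/links chromosome-name mismatch.")
  n_ends <- length(link_chroms)
  units <- as.list(unique(segs$chrom))
  if (nrow(links) > 0) {
    inter <- links |>
      filter(.data$inter) |>
      count(.data$chrom1, .data$chrom2) |>
      filter(.data$n >= joint_min_links)
    for (i in seq_len(nrow(inter))) {
      units[[length(units) + 1]] <- c(inter$chrom1[i], inter$chrom2[i])
    }
  }
  rows <- purrr::map_dfr(units, function(chs) {
    s <- segs |>
      filter(.data$chrom %in% chs,
             .data$n_windows >= min_segment_windows) |>
      # dropping slivers can leave equal states adjacent: re-merge
      group_by(.data$chrom) |>
      mutate(grp = cumsum(c(1L, diff(.data$state) != 0))) |>
      group_by(.data$chrom, .data$grp) |>
      summarise(n_windows = sum(.data$n_windows),
                state = .data$state[1], .groups = "drop_last")
    switches <- s |>
      summarise(k = sum(diff(.data$state) != 0), .groups = "drop") |>
      pull(.data$k) |>
      sum()
    s <- ungroup(s)
    tab <- sort(tapply(s$n_windows, s$state, sum), decreasing = TRUE)
    osc <- if (nrow(s)) sum(head(tab, 2)) / sum(s$n_windows) else 0
    endf <- if (n_ends) sum(link_chroms %in% chs) / n_ends else 0
    tibble(
      chrom = paste(chs, collapse = "+"),
      n_state_switches = switches,
      n_distinct_states = length(tab),
      oscillation_fraction = osc,
      sv_end_fraction = endf,
      flag = switches >= min_switches &&
        length(tab) <= max_states &&
        osc >= min_two_state_share &&
        endf >= min_end_fraction
    )
  })
  out <- rows |> arrange(dplyr::desc(.data$flag), .data$chrom)
  attr(out, "thresholds") <- list(
    min_switches = min_switches, max_states = max_states,
    min_two_state_share = min_two_state_share,
    min_end_fraction = min_end_fraction, joint_min_links = joint_min_links
  )
  class(out) <- c("sv_ctx_report", class(out))
  out
}

#' Flagged chromosomes of a chromothripsis report
#' @param x An `sv_ctx_report`.
#' @param ... Unused.
#' @return One-row tibble: number of evaluated units, number flagged, and
#'   the flagged unit names.
#' @export
glance.sv_ctx_report <- function(x, ...) {
  tibble(n_units = nrow(x), n_flagged = sum(x$flag),
         flagged = paste(x$chrom[x$flag], collapse = ","))
}
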