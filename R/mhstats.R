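#' Closed-form null model for junction microhomology
#'
#' Under independent joining of two unrelated sequences, the breakpoint
#' can slide left and right by geometrically distributed extensions with
#' per-base match probability `p = sum(f^2)` over the base frequencies
#' `f`. The total microhomology `M` (sum of the two extensions) has
#' probability mass `P(M = m) = (m + 1) p^m (1 - p)^2`. With uniform
#' composition `p = 1/4` and `P(M >= 1) = 7/16`.
#'
#' @param base_frequencies Length-4 A/C/G/T frequency vector summing
#'   to 1.
#' @param max_m Largest tabulated microhomology length.
#' @return An `sv_mh_null`: list with `p`, and `pmf` (tibble `m`,
#'   `prob`); the tail beyond `max_m` is carried by the analytic form,
#'   not truncated.
#' @export
mh_null <- function(base_frequencies = rep(0.25, 4), max_m = 40) {
  assert_that(length(base_frequencies) == 4 &&
                abs(sum(base_frequencies) - 1) <= 1e-9,
              "`base_frequencies` must be 4 values summing to 1.")
  assert_that(all(base_frequencies < 1),
              "degenerate frequency vector (single-base genome).")
  p <- sum(base_frequencies^2)
  m <- 0:max_m
  structure(
    list(p = p,
         base_frequencies = base_frequencies,
         pmf = tibble(m = m, prob = (m + 1) * p^m * (1 - p)^2)),
    class = "sv_mh_null"
  )
}

#' @export
print.sv_mh_null <- function(x, ...) {
  cat(sprintf("<sv_mh_null> p = %.4f, P(M >= 1) = %.4f\n",
              x$p, 1 - x$pmf$prob[1]))
  invisible(x)
}

#' @rdname mh_null
#' @param x An `sv_mh_null`.
#' @param ... Unused.
#' @export
tidy.sv_mh_null <- function(x, ...) x$pmf

# P(M >= k) under the null
mh_null_tail <- function(null, k) {
  if (k <= 0) return(1)
  p <- null$p
  # sum_{m>=k} (m+1) p^m (1-p)^2  (closed form)
  p^k * (1 - p)^2 * ((k + 1) / (1 - p) + p / (1 - p)^2)
}

#' Chi-square goodness-of-fit test of microhomology lengths
#'
#' Compares observed junction microhomology lengths with the closed-form
#' null, binning lengths as `0, 1, ..., K-1, >= K` with `K` chosen so all
#' expected counts are at least one and at least 80 percent are at least
#' five (Cochran's rule). Insertion-class junctions carry no
#' microhomology and must be excluded before testing.
#'
#' @param observed Integer vector of microhomology lengths (0 = blunt).
#' @param null An `sv_mh_null`.
#' @param max_bins Upper bound on the number of non-pooled bins.
#' @return An `sv_mh_test`: list with `statistic`, `df`, `p_value`, `n`,
#'   and the binned `table` (tibble `bin`, `observed`, `expected`).
#' @export
mh_chisq <- function(observed, null, max_bins = 30) {
  assert_that(length(observed) >= 1, "empty observation list.")
  n <- length(observed)
  # largest K with pooled-tail expectation >= 1
  K <- 1L
  while (K < max_bins && n * mh_null_tail(null, K + 1L) >= 1) K <- K + 1L
  repeat {
    probs <- c(null$pmf$prob[seq_len(K)], mh_null_tail(null, K))
    expected <- n * probs
    if (K == 1L || (min(expected) >= 1 &&
                    mean(expected >= 5) >= 0.8)) break
    K <- K - 1L
  }
  obs_counts <- c(vapply(0:(K - 1L), function(m) sum(observed == m),
                         numeric(1)),
                  sum(observed >= K))
  stat <- sum((obs_counts - expected)^2 / expected)
  df <- K
  structure(
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE), n = n,
         table = tibble(
           bin = c(as.character(0:(K - 1L)), paste0(">=", K)),
           observed = obs_counts, expected = expected
         )),
    class = "sv_mh_test"
  )
}

#' @export
print.sv_mh_test <- function(x, ...) {
  cat(sprintf("<sv_mh_test> X-squared = %.2f, df = %d, p = %.3g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' @rdname mh_chisq
#' @param x An `sv_mh_test`.
#' @param ... Unused.
#' @export
glance.sv_mh_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value, n = x$n)
}

#' @rdname mh_chisq
#' @export
tidy.sv_mh_test <- function(x, ...) x$table

#' Stratified microhomology report
#'
#' Splits junction calls by chromothripsis status, tests each stratum's
#' microhomology spectrum against the null, and tabulates per-sample
#' junction patterns (microhomology / blunt / insertion counts).
#' Insertion-class junctions (including shards and templated insertions)
#' are excluded from the microhomology test.
#'
#' @param calls Junction-call tibble with columns `mh_len`, `class`,
#'   `sample`, `chromothripsis` (logical).
#' @param null An `sv_mh_null`; by default built from uniform
#'   composition — pass a composition measured around the breakpoints
#'   for a composition-matched null.
#' @return An `sv_mh_report`: list with `histogram` (observed vs
#'   theoretical frequencies per stratum), `tests` (one chi-square test
#'   per stratum) and `sample_summary` (per-sample pattern counts).
#' @export
stratified_report <- function(calls, null = mh_null()) {
  need <- c("mh_len", "class", "sample", "chromothripsis")
  assert_that(all(need %in% names(calls)),
              paste("calls need columns:", paste(need, collapse = ", ")))
  assert_that(!any(is.na(calls$chromothripsis) | is.na(calls$sample)),
              "unlabeled sample.")
  calls <- calls |>
    mutate(stratum = ifelse(.data$chromothripsis, "chromothripsis",
                            "non-chromothripsis"),
           pattern = dplyr::case_when(
             .data$class %in% c("insertion", "shard", "templated") ~
               "insertion",
             .data$mh_len >= 1 ~ "microhomology",
             TRUE ~ "blunt"
           ))
  mh_calls <- calls |> filter(.data$pattern != "insertion")
  tests <- mh_calls |>
    group_by(.data$stratum) |>
    dplyr::group_map(function(d, key) {
      t <- mh_chisq(d$mh_len, null)
      bind_cols(tibble(stratum = key$stratum), glance(t))
    }) |>
    bind_rows()
  histogram <- mh_calls |>
    group_by(.data$stratum) |>
    dplyr::group_modify(function(d, key) {
      mmax <- max(d$mh_len, null$pmf$m)
      obs <- vapply(0:mmax, function(m) sum(d$mh_len == m), numeric(1))
      theo <- (0:mmax + 1) * null$p^(0:mmax) * (1 - null$p)^2
      tibble(m = 0:mmax, observed = obs / sum(obs), theoretical = theo)
    }) |>
    ungroup()
  sample_summary <- calls |>
    count(.data$sample, .data$pattern, name = "n_junctions") |>
    tidyr::pivot_wider(names_from = "pattern",
                       values_from = "n_junctions", values_fill = 0L)
  structure(list(histogram = histogram, tests = tests,
                 sample_summary = sample_summary, null = null),
            class = "sv_mh_report")
}

#' @export
print.sv_mh_report <- function(x, ...) {
  cat("<sv_mh_report>\n")
  print(x$tests)
  invisible(x)
}
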