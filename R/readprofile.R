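#' Windowed read counts
#'
#' Counts mapped read starts (both ends of every pair) in fixed,
#' chromosome-tiling windows — the raw material for read-depth
#' copy-number profiling.
#'
#' @param pairs Read-pair tibble.
#' @param window_size Window size in bp (>= 1 kb; default 30 kb).
#' @param chrom_lengths Named vector of chromosome lengths, or an
#'   `sv_genome` to take them from.
#' @return An `sv_cnprofile` object: a list with `windows` (tibble
#'   `chrom`, `start`, `end`, `raw_count`), `window_size`, and empty
#'   `segments` until [normalize_and_segment()] is run.
#' @export
window_counts <- function(pairs, window_size = 30000, chrom_lengths) {
  assert_that(window_size >= 1000, "`window_size` must be >= 1 kb.")
  assert_that(nrow(pairs) > 0, "empty read-pair input.")
  if (inherits(chrom_lengths, "sv_genome")) {
    chrom_lengths <- genome_lengths(chrom_lengths)
  }
  starts <- tibble(
    chrom = c(pairs$chrom1, pairs$chrom2),
    pos = c(pairs$pos1, pairs$pos2)
  )
  windows <- purrr::imap_dfr(as.list(chrom_lengths), function(len, ch) {
    ws <- seq(1L, len, by = window_size)
    tibble(chrom = ch, start = ws,
           end = pmin(ws + window_size - 1L, len))
  })
  counts <- starts |>
    mutate(start = (.data$pos - 1L) %/% window_size * window_size + 1L) |>
    count(.data$chrom, .data$start, name = "raw_count")
  windows <- windows |>
    left_join(counts, by = c("chrom", "start")) |>
    mutate(raw_count = dplyr::coalesce(.data$raw_count, 0L))
  structure(list(windows = windows, window_size = window_size,
                 segments = NULL, ploidy = NA_integer_),
            class = "sv_cnprofile")
}

#' @export
print.sv_cnprofile <- function(x, ...) {
  cat("<sv_cnprofile> ", nrow(x$windows), " windows of ", x$window_size,
      " bp", sep = "")
  if (!is.null(x$segments)) {
    cat("; ", nrow(x$segments), " segments (ploidy ", x$ploidy, ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Normalise window counts and segment the copy-number profile
#'
#' Normalises counts to a ratio with genome-wide median one, segments
#' each chromosome by recursive binary splitting that accepts a split
#' only if it reduces the squared error by more than
#' `penalty * sigma2 * log(n)` (sigma2 estimated robustly from
#' window-to-window differences), rounds segment medians to integer copy
#' states relative to `ploidy`, and merges adjacent segments with equal
#' state.
#'
#' @param profile An `sv_cnprofile` from [window_counts()].
#' @param ploidy Baseline copy number of the genome-wide median ratio.
#' @param penalty Split penalty multiplier; `NULL` selects it by 2-fold
#'   (odd/even window) cross-validation over a small grid.
#' @param purity Tumour-cell fraction; ratios are rescaled as
#'   `1 + (ratio - 1) / purity` before state calling so admixture with
#'   normal cells does not shrink the called states.
#' @return The profile with `normalized_ratio` added to `windows` and a
#'   `segments` tibble (`chrom`, `start`, `end`, `n_windows`,
#'   `ratio_median`, `state`).
#' @export
normalize_and_segment <- function(profile, ploidy = 2, penalty = NULL,
                                  purity = 1) {
  w <- profile$windows
  assert_that(all(table(w$chrom) >= 10),
              "need >= 10 windows per chromosome.")
  med <- median(w$raw_count)
  assert_that(med > 0, "all-zero profile.")
  w$normalized_ratio <- w$raw_count / med
  if (purity < 1) {
    w$normalized_ratio <- 1 + (w$normalized_ratio - 1) / purity
  }
  if (is.null(penalty)) {
    penalty <- pick_penalty_cv(w)
  }
  segs <- w |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      x <- d$normalized_ratio
      sigma2 <- max(1e-8, 0.5 * median(diff(x)^2) / 0.4549)
      bounds <- segment_binary(x, penalty * sigma2 * log(length(x)))
      purrr::map_dfr(seq_len(nrow(bounds)), function(i) {
        i0 <- bounds$from[i]; i1 <- bounds$to[i]
        tibble(start = d$start[i0], end = d$end[i1],
               n_windows = i1 - i0 + 1L,
               ratio_median = median(x[i0:i1]))
      })
    }) |>
    ungroup()
  # Integer anchoring: with an even split between two copy states the
  # window median can land between them, so calibrate a global scale
  # that moves segment ratios onto the integer copy grid (preferring the
  # scale closest to 1 when several fit).
  s_grid <- seq(0.6, 1.5, by = 0.005)
  cost <- vapply(s_grid, function(s) {
    v <- ploidy * segs$ratio_median * s
    sum(segs$n_windows * (v - round(v))^2)
  }, numeric(1))
  best <- s_grid[cost <= min(cost) * 1.05 + 1e-9]
  scale <- best[which.min(abs(best - 1))]
  segs <- segs |>
    mutate(state = pmax(0L, as.integer(round(ploidy * .data$ratio_median *
                                               scale))))
  segs <- segs |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(c(1L, diff(.data$state) != 0))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = sum(.data$n_windows),
              ratio_median = median(rep(.data$ratio_median,
                                        .data$n_windows)),
              state = .data$state[1], .groups = "drop") |>
    select("chrom", "start", "end", "n_windows", "ratio_median",
           "state") |>
    arrange(.data$chrom, .data$start)
  structure(list(windows = w, window_size = profile$window_size,
                 segments = segs, ploidy = ploidy, penalty = penalty),
            class = "sv_cnprofile")
}

# recursive binary segmentation on squared-error gain
segment_binary <- function(x, threshold) {
  n <- length(x)
  split_gain <- function(i0, i1) {
    xs <- x[i0:i1]
    m <- length(xs)
    if (m < 2) return(c(NA, -Inf))
    cs <- cumsum(xs)
    tot <- cs[m]
    k <- seq_len(m - 1)
    sse_gain <- (cs[k] - k * tot / m)^2 * m / (k * (m - k))
    kbest <- which.max(sse_gain)
    c(kbest, sse_gain[kbest])
  }
  segments <- list(c(1L, n))
  out <- list()
  while (length(segments)) {
    seg <- segments[[1]]
    segments <- segments[-1]
    g <- split_gain(seg[1], seg[2])
    if (is.finite(g[2]) && g[2] > threshold) {
      k <- seg[1] + g[1] - 1L
      segments <- c(segments, list(c(seg[1], k)), list(c(k + 1L, seg[2])))
    } else {
      out[[length(out) + 1]] <- seg
    }
  }
  b <- do.call(rbind, out)
  b <- b[order(b[, 1]), , drop = FALSE]
  tibble(from = b[, 1], to = b[, 2])
}

# 2-fold (odd/even windows) cross-validation of the split penalty
pick_penalty_cv <- function(w, grid = c(0.5, 1, 2, 3, 5, 8)) {
  score <- vapply(grid, function(pen) {
    sse <- 0
    for (ch in unique(w$chrom)) {
      x <- w$normalized_ratio[w$chrom == ch]
      odd <- x[seq(1, length(x), by = 2)]
      even <- x[seq(2, length(x), by = 2)]
      sigma2 <- max(1e-8, 0.5 * median(diff(odd)^2) / 0.4549)
      bounds <- segment_binary(odd, pen * sigma2 * log(length(odd)))
      fit <- rep(NA_real_, length(odd))
      for (i in seq_len(nrow(bounds))) {
        fit[bounds$from[i]:bounds$to[i]] <-
          mean(odd[bounds$from[i]:bounds$to[i]])
      }
      m <- min(length(even), length(fit))
      sse <- sse + sum((even[seq_len(m)] - fit[seq_len(m)])^2)
    }
    sse
  }, numeric(1))
  grid[which.min(score)]
}

#' Tidy a copy-number profile
#' @param x An `sv_cnprofile`.
#' @param ... Unused.
#' @return The segments tibble (if segmented) or the windows tibble.
#' @export
tidy.sv_cnprofile <- function(x, ...) {
  if (!is.null(x$segments)) x$segments else x$windows
}
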