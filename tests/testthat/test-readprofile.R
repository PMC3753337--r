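test_that("window counts tile chromosomes and are Poisson-like on flat coverage", {
  g <- small_genome(13, c(3e5, 2e5))
  d <- list(reference = g, derived = g,
            map = tibble::tibble(der_chrom = names(g$seqs), der_start = 1L,
                                 der_end = unname(genome_lengths(g)),
                                 chrom = names(g$seqs), start = 1L,
                                 end = unname(genome_lengths(g)),
                                 orient = "+"),
            truth = NULL, states = NULL, plans = list(),
            replaced = character(0))
  class(d) <- "sv_derived"
  pairs <- simulate_mate_pairs(d, pairs_for_coverage(10, 5e5), seed = 15)
  prof <- window_counts(pairs, 30000, g)
  w <- prof$windows
  # tiling
  expect_equal(sum(w$end - w$start + 1), 5e5)
  # flat 10X: CV below 0.2 at 30 kb (drop edge windows depleted by the
  # fragment-placement boundary)
  inner <- w |> dplyr::group_by(chrom) |>
    dplyr::filter(start > min(start), end < max(end)) |> dplyr::ungroup()
  expect_lt(sd(inner$raw_count) / mean(inner$raw_count), 0.2)
  expect_error(window_counts(pairs[0, ], 30000, g), "empty")
  expect_error(window_counts(pairs, 500, g), "1 kb")
})

test_that("a flat chromosome segments into a single diploid segment", {
  g <- small_genome(14, c(3e5))
  d <- list(reference = g, derived = g,
            map = tibble::tibble(der_chrom = "chr1", der_start = 1L,
                                 der_end = 3e5L, chrom = "chr1",
                                 start = 1L, end = 3e5L, orient = "+"),
            truth = NULL, states = NULL, plans = list(),
            replaced = character(0))
  class(d) <- "sv_derived"
  pairs <- simulate_mate_pairs(d, pairs_for_coverage(12, 3e5), seed = 19)
  prof <- normalize_and_segment(window_counts(pairs, 10000, g))
  expect_equal(nrow(prof$segments), 1)
  expect_equal(prof$segments$state, 2L)
  expect_equal(median(prof$windows$normalized_ratio), 1, tolerance = 1e-6)
})

test_that("chromothripsis copy states are recovered segment by segment", {
  g <- simulate_genome(2, c(1e6, 25e4), seed = 41)
  ct <- plan_rearrangements(g, "chromothripsis", n_events = 8, seed = 43,
                            min_segment = 4e4)
  d <- render_derived_genome(g, ct)
  pairs <- simulate_mate_pairs(
    d, pairs_for_coverage(12, 2 * sum(genome_lengths(g))), seed = 47,
    include_reference_homolog = TRUE)
  prof <- normalize_and_segment(window_counts(pairs, 5000, g))
  segs <- prof$segments |> dplyr::filter(chrom == "chr1")
  truth <- d$states
  # state at the midpoint of every true segment spanning >= 5 windows
  for (i in seq_len(nrow(truth))) {
    if (truth$end[i] - truth$start[i] + 1 < 5 * 5000) next
    mid <- (truth$start[i] + truth$end[i]) / 2
    called <- segs$state[segs$start <= mid & segs$end >= mid]
    expect_equal(called, truth$state[i])
  }
})

test_that("purity rescaling restores integer states under admixture", {
  # synthetic windows: 50% tumour cells halve the deviation from 1
  w <- tibble::tibble(
    chrom = "chr1",
    start = seq(1, by = 1e4, length.out = 60),
    end = seq(1e4, by = 1e4, length.out = 60),
    raw_count = rep(c(100, 75, 100), each = 20)  # states 2,1,2 at purity 0.5
  )
  prof <- structure(list(windows = w, window_size = 1e4, segments = NULL,
                         ploidy = NA), class = "sv_cnprofile")
  seg <- normalize_and_segment(prof, penalty = 3, purity = 0.5)
  expect_equal(seg$segments$state, c(2L, 1L, 2L))
})

test_that("segment boundaries land within one window of planted breakpoints", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = seq(1, by = 1e4, length.out = 90),
    end = seq(1e4, by = 1e4, length.out = 90),
    raw_count = rep(c(100L, 50L, 100L), each = 30L)
  )
  set.seed(5)
  w$raw_count <- rpois(90, w$raw_count)
  prof <- structure(list(windows = w, window_size = 1e4, segments = NULL,
                         ploidy = NA), class = "sv_cnprofile")
  seg <- normalize_and_segment(prof, penalty = 3)$segments
  expect_equal(nrow(seg), 3)
  expect_lt(abs(seg$end[1] - 30e4), 1e4 + 1)
  expect_lt(abs(seg$end[2] - 60e4), 1e4 + 1)
})
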