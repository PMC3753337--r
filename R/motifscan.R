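#' Default breakpoint motif catalog
#'
#' A small, editable catalog of sequence motifs repeatedly proposed to
#' promote rearrangement: an AT-rich scaffold/matrix-attachment-region
#' (S/MAR) rule, topoisomerase I and II cleavage consensus sites,
#' translin binding sites, the deletion-hotspot consensus, an
#' immunoglobulin switch-repeat and a chi-like element. Patterns are
#' IUPAC; `max_mismatch` allows degenerate matching. The scanning and
#' enrichment machinery is catalog-agnostic — supply your own tibble or
#' TSV with the same columns to scan any motif set.
#'
#' @return A tibble: `name`, `pattern`, `max_mismatch`.
#' @export
default_motif_catalog <- function() {
  tibble(
    name = c("SMAR_AT_rich", "topoisomerase_I", "topoisomerase_II",
             "translin_1", "translin_2", "deletion_hotspot",
             "Ig_switch_repeat", "chi_like", "alternating_RY_tract",
             "A_tract"),
    pattern = c("AATATATTT", "CTY", "RNYNNCNNGYNGKTNYNY",
                "ATGCAG", "GCCCWSSW", "TGRRKM",
                "TGGGG", "GCWGGWGG", "RYRYRYRYRY", "AAAAAA"),
    max_mismatch = c(1L, 0L, 4L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  )
}

#' Read a motif catalog from TSV
#' @param path TSV with columns name, pattern, max_mismatch.
#' @return A catalog tibble.
#' @export
read_motif_catalog <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  as_tibble(x)
}

# positions on a chromosome whose centered window of size w contains at
# least one match of the motif (either strand), as reduced IRanges
motif_hit_ranges <- function(chrom_seq, pattern, max_mismatch, w) {
  pat <- Biostrings::DNAString(pattern)
  half_lo <- w %/% 2 - 1L   # window = [pos - w/2 + 1, pos + w/2]
  half_hi <- w %/% 2
  collect <- function(p) {
    m <- Biostrings::matchPattern(p, chrom_seq, fixed = FALSE,
                                  max.mismatch = max_mismatch)
    if (!length(m)) return(IRanges::IRanges())
    IRanges::IRanges(Biostrings::start(m) - half_hi,
                     Biostrings::end(m) + half_lo)
  }
  IRanges::reduce(c(collect(pat),
                    collect(Biostrings::reverseComplement(pat))))
}

#' Scan breakpoint windows for motif hits
#'
#' A breakpoint is a hit for a motif if at least one match (on either
#' strand, within the allowed mismatches) falls inside the window of
#' `window` bp centered on the breakpoint.
#'
#' @param breakpoints Tibble with `chrom`, `pos`.
#' @param genome An `sv_genome`.
#' @param windows Window sizes in bp (even; the convention pairs a
#'   40 bp immediate-proximity window with a 250 bp short-proximity
#'   window — 250 is rounded up to the next even size internally).
#' @param catalog Motif catalog tibble (default
#'   [default_motif_catalog()]).
#' @return A tibble: `motif`, `window`, `n_hits`, `n_breakpoints`, plus
#'   a `hits` list-column of per-breakpoint logical vectors (used by
#'   [motif_enrichment()]).
#' @export
scan_motifs <- function(breakpoints, genome, windows = c(40, 250),
                        catalog = default_motif_catalog()) {
  assert_that(all(breakpoints$chrom %in% names(genome$seqs)),
              "breakpoint outside reference bounds.")
  lens <- genome_lengths(genome)
  assert_that(all(breakpoints$pos >= 1 &
                    breakpoints$pos <= lens[breakpoints$chrom]),
              "breakpoint outside reference bounds.")
  windows <- as.integer(windows + windows %% 2)  # force even
  out <- list()
  for (w in windows) {
    for (k in seq_len(nrow(catalog))) {
      hits <- rep(FALSE, nrow(breakpoints))
      for (ch in unique(breakpoints$chrom)) {
        rng <- motif_hit_ranges(genome$seqs[[ch]], catalog$pattern[k],
                                catalog$max_mismatch[k], w)
        sel <- breakpoints$chrom == ch
        hits[sel] <- in_ranges(breakpoints$pos[sel], rng)
      }
      out[[length(out) + 1]] <- tibble(
        motif = catalog$name[k], window = w, n_hits = sum(hits),
        n_breakpoints = nrow(breakpoints), hits = list(hits)
      )
    }
  }
  bind_rows(out)
}

#' Empirical motif enrichment around breakpoints
#'
#' Compares observed per-motif hit counts with `n_background` random
#' breakpoint sets matched per chromosome (same number of positions on
#' each chromosome as the observed set). The empirical p-value uses
#' add-one smoothing, `p = (1 + #[background >= observed]) /
#' (1 + n_background)`, and Benjamini-Hochberg adjustment across
#' motif-window combinations.
#'
#' @inheritParams scan_motifs
#' @param n_background Number of background position sets (default
#'   1000).
#' @param seed Integer seed for background sampling.
#' @return A tibble: `motif`, `window`, `observed`, `bg_mean`,
#'   `p_value`, `q_value`.
#' @export
motif_enrichment <- function(breakpoints, genome, windows = c(40, 250),
                             catalog = default_motif_catalog(),
                             n_background = 1000, seed) {
  assert_that(n_background >= 1, "`n_background` must be >= 1.")
  lens <- genome_lengths(genome)
  assert_that(all(lens >= max(windows)),
              "reference shorter than the scan window.")
  windows <- as.integer(windows + windows %% 2)
  per_chrom <- table(breakpoints$chrom)
  half <- max(windows) %/% 2
  bg_counts <- matrix(0L, nrow = nrow(catalog) * length(windows),
                      ncol = n_background)
  obs <- numeric(nrow(catalog) * length(windows))
  key <- tibble(motif = rep(catalog$name, times = length(windows)),
                window = rep(windows, each = nrow(catalog)))
  row_i <- 0L
  with_seed(seed, {
    # pre-draw all background positions per chromosome
    bg_pos <- lapply(names(per_chrom), function(ch) {
      matrix(sample(seq(half + 1L, lens[[ch]] - half),
                    per_chrom[[ch]] * n_background, replace = TRUE),
             nrow = per_chrom[[ch]])
    })
    names(bg_pos) <- names(per_chrom)
    for (w in windows) {
      for (k in seq_len(nrow(catalog))) {
        row_i <- row_i + 1L
        for (ch in names(per_chrom)) {
          rng <- motif_hit_ranges(genome$seqs[[ch]], catalog$pattern[k],
                                  catalog$max_mismatch[k], w)
          sel <- breakpoints$chrom == ch
          obs_hit <- in_ranges(breakpoints$pos[sel], rng)
          obs[row_i] <- obs[row_i] + sum(obs_hit)
          hit_mat <- matrix(in_ranges(as.vector(bg_pos[[ch]]), rng),
                            nrow = per_chrom[[ch]])
          bg_counts[row_i, ] <- bg_counts[row_i, ] + colSums(hit_mat)
        }
      }
    }
  })
  p <- vapply(seq_len(nrow(key)), function(i) {
    (1 + sum(bg_counts[i, ] >= obs[i])) / (1 + n_background)
  }, numeric(1))
  key |>
    mutate(observed = obs, bg_mean = rowMeans(bg_counts),
           p_value = p, q_value = p.adjust(p, method = "BH"))
}

in_ranges <- function(pos, rng) {
  if (length(rng) == 0) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(IRanges::IRanges(pos, width = 1L), rng)
}

#' Sequence-composition statistics around breakpoints
#'
#' For each breakpoint window: GC content, maximal polypurine run,
#' maximal polypyrimidine run and maximal alternating
#' purine/pyrimidine run, with z-scores of the observed means against
#' chromosome-matched random background windows.
#'
#' @inheritParams scan_motifs
#' @param window Single window size in bp.
#' @param n_background Number of background windows per breakpoint set.
#' @param seed Integer seed.
#' @return A list with `per_breakpoint` (one row per breakpoint) and
#'   `summary` (observed means, background means/SDs and z-scores of
#'   the observed mean).
#' @export
composition_stats <- function(breakpoints, genome, window = 250,
                              n_background = 200, seed) {
  lens <- genome_lengths(genome)
  assert_that(all(breakpoints$chrom %in% names(lens)) &&
                all(breakpoints$pos >= 1 &
                      breakpoints$pos <= lens[breakpoints$chrom]),
              "breakpoint outside reference bounds.")
  window <- as.integer(window + window %% 2)
  half <- window %/% 2
  win_seq <- function(ch, pos) {
    s <- max(1L, pos - half + 1L)
    e <- min(lens[[ch]], pos + half)
    genome_seq(genome, ch, s, e)
  }
  metrics <- function(seqs) {
    purrr::map_dfr(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      pur <- b %in% c("A", "G")
      tibble(
        gc = mean(b %in% c("G", "C")),
        max_purine_run = max_run(pur),
        max_pyrimidine_run = max_run(!pur),
        max_alternating_run = max_alt_run(pur)
      )
    })
  }
  obs_seqs <- purrr::map2_chr(breakpoints$chrom, breakpoints$pos, win_seq)
  per_bp <- bind_cols(breakpoints, metrics(obs_seqs))
  per_chrom <- table(breakpoints$chrom)
  bg_means <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_background), function(i) {
      pos <- purrr::imap(as.list(per_chrom), function(n, ch) {
        sample(seq(half + 1L, lens[[ch]] - half), n, replace = TRUE)
      })
      seqs <- unlist(purrr::imap(pos, function(p, ch) {
        vapply(p, function(x) win_seq(ch, x), character(1))
      }))
      colMeans(metrics(seqs))
    })
  })
  obs_mean <- colMeans(per_bp[, c("gc", "max_purine_run",
                                  "max_pyrimidine_run",
                                  "max_alternating_run")])
  summary <- tibble(
    metric = names(obs_mean),
    observed_mean = as.numeric(obs_mean),
    bg_mean = as.numeric(colMeans(bg_means)),
    bg_sd = as.numeric(apply(bg_means, 2, sd)),
  ) |>
    mutate(z = (.data$observed_mean - .data$bg_mean) / .data$bg_sd)
  list(per_breakpoint = per_bp, summary = summary)
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# longest stretch of strictly alternating purine/pyrimidine
max_alt_run <- function(pur) {
  n <- length(pur)
  if (n <= 1) return(n)
  alt <- pur[-1] != pur[-n]
  r <- rle(alt)
  best <- r$lengths[r$values]
  if (length(best) == 0) 1L else max(best) + 1L
}
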