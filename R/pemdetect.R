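#' Fit the concordant insert-size model
#'
#' Estimates the insert-size distribution of a mate-pair library from
#' same-chromosome, outward-oriented pairs, robustly (median / MAD) so
#' that a moderate fraction of discordant contamination does not bias the
#' estimates. The concordant ("normal") window is
#' `mu +/- k_sigma * sigma`.
#'
#' @param pairs Read-pair tibble (see [simulate_mate_pairs()] /
#'   [read_bedpe()]).
#' @param k_sigma Window half-width in units of sigma (default 4: a
#'   Gaussian tail of ~6e-5 keeps false discordant pairs rare).
#' @param min_pairs Minimum number of outward same-chromosome pairs.
#' @return An object of class `sv_insert_model` with `mu`, `sigma`,
#'   `k_sigma` and `n_pairs`.
#' @export
fit_insert_model <- function(pairs, k_sigma = 4, min_pairs = 100) {
  p <- canonicalize_pairs(pairs)
  conc <- p |>
    filter(.data$chrom1 == .data$chrom2, .data$strand1 == "-",
           .data$strand2 == "+")
  ins <- conc$pos2 + conc$read_len - conc$pos1
  ins <- ins[ins > 0]
  assert_that(length(ins) >= min_pairs,
              "too few concordant pairs to fit the insert model.")
  mu <- median(ins)
  sigma <- mad(ins)
  if (sigma > 0) {
    # one trimming pass: discordant contamination (e.g. stretched inserts
    # over deletions) is excluded before the final estimate
    keep <- abs(ins - mu) <= k_sigma * sigma
    mu <- median(ins[keep])
    sigma <- mad(ins[keep])
  }
  if (sigma <= 0) {
    abort("degenerate insert-size distribution (sigma = 0).")
  }
  structure(list(mu = mu, sigma = sigma, k_sigma = k_sigma,
                 n_pairs = length(ins)),
            class = "sv_insert_model")
}

#' @export
print.sv_insert_model <- function(x, ...) {
  cat(sprintf("<sv_insert_model> mu = %.0f bp, sigma = %.0f bp (n = %d), window = [%.0f, %.0f]\n",
              x$mu, x$sigma, x$n_pairs, x$mu - x$k_sigma * x$sigma,
              x$mu + x$k_sigma * x$sigma))
  invisible(x)
}

#' @rdname fit_insert_model
#' @param x An `sv_insert_model`.
#' @param ... Unused.
#' @export
tidy.sv_insert_model <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, k_sigma = x$k_sigma,
         window_lo = x$mu - x$k_sigma * x$sigma,
         window_hi = x$mu + x$k_sigma * x$sigma,
         n_pairs = x$n_pairs)
}

# canonical end order: end1 before end2 in (chrom, pos) order
canonicalize_pairs <- function(pairs) {
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos2 < pairs$pos1)
  out <- pairs
  out$chrom1 <- ifelse(swap, pairs$chrom2, pairs$chrom1)
  out$pos1 <- ifelse(swap, pairs$pos2, pairs$pos1)
  out$strand1 <- ifelse(swap, pairs$strand2, pairs$strand1)
  out$chrom2 <- ifelse(swap, pairs$chrom1, pairs$chrom2)
  out$pos2 <- ifelse(swap, pairs$pos1, pairs$pos2)
  out$strand2 <- ifelse(swap, pairs$strand1, pairs$strand2)
  out
}

#' Remove PCR duplicates
#'
#' Pairs with identical mapped coordinates and strands at both ends are
#' collapsed to one.
#'
#' @param pairs Read-pair tibble.
#' @return Deduplicated tibble.
#' @export
dedup_pairs <- function(pairs) {
  canonicalize_pairs(pairs) |>
    distinct(.data$chrom1, .data$pos1, .data$strand1,
             .data$chrom2, .data$pos2, .data$strand2, .keep_all = TRUE)
}

#' Classify read pairs as concordant or discordant
#'
#' A pair is concordant ("normal") iff both ends map to the same
#' chromosome in outward orientation (leftmost read on `-`, rightmost on
#' `+`) with an insert inside the model window. Every other pair is
#' discordant, labelled with its raw paired-end-mapping signature:
#' orientation pattern plus insert-size deviation, and whether the two
#' ends are on different chromosomes.
#'
#' @param pairs Read-pair tibble.
#' @param model An `sv_insert_model`.
#' @return The canonicalised tibble with added columns `insert`, `inter`,
#'   `orientation` (`outward`, `inward`, `same-`, `same+`), `deviation`
#'   (`within`, `stretched`, `shrunk`; `NA` between chromosomes),
#'   `status` (`normal`/`abnormal`) and `signature`.
#' @export
classify_pairs <- function(pairs, model) {
  p <- canonicalize_pairs(pairs)
  p <- p |>
    mutate(
      inter = .data$chrom1 != .data$chrom2,
      insert = ifelse(.data$inter, NA_real_,
                      .data$pos2 + .data$read_len - .data$pos1),
      orientation = dplyr::case_when(
        .data$strand1 == "-" & .data$strand2 == "+" ~ "outward",
        .data$strand1 == "+" & .data$strand2 == "-" ~ "inward",
        .data$strand1 == "-" ~ "same-",
        TRUE ~ "same+"
      ),
      deviation = dplyr::case_when(
        .data$inter ~ NA_character_,
        .data$insert > model$mu + model$k_sigma * model$sigma ~ "stretched",
        .data$insert < model$mu - model$k_sigma * model$sigma ~ "shrunk",
        TRUE ~ "within"
      ),
      status = ifelse(!.data$inter & .data$orientation == "outward" &
                        .data$deviation == "within", "normal", "abnormal"),
      signature = dplyr::case_when(
        status == "normal" ~ "normal",
        inter ~ paste0("inter_", orientation),
        orientation == "outward" ~ paste0("outward_", deviation),
        TRUE ~ orientation
      )
    )
  p
}

#' Cluster discordant pairs into SV links
#'
#' Single-linkage clustering of discordant pairs sharing the same
#' signature whose two ends each fall within `window` of one another.
#' Clusters with fewer than `min_support` pairs are discarded. Input
#' order does not matter: pairs are deduplicated, canonicalised and
#' sorted before clustering.
#'
#' @param pairs Read-pair tibble (raw or already classified).
#' @param model An `sv_insert_model`.
#' @param min_support Minimum pair support per link (default 2).
#' @param window Clustering window in bp (default
#'   `mu + k_sigma * sigma`).
#' @param dedup Collapse PCR duplicates first (default `TRUE`).
#' @return A link tibble of class `sv_links`: `link_id`, end intervals
#'   (`chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`), dominant
#'   strands, `n_pairs`, `signature`, `inter`, `span` (distance between
#'   end midpoints for same-chromosome links; `NA` otherwise) and
#'   `pem_type` (see [assign_pem_type()]).
#' @export
cluster_links <- function(pairs, model, min_support = 2, window = NULL,
                          dedup = TRUE) {
  window <- window %||% (model$mu + model$k_sigma * model$sigma)
  if (dedup) pairs <- dedup_pairs(pairs)
  if (!"status" %in% names(pairs)) pairs <- classify_pairs(pairs, model)
  ab <- pairs |>
    filter(.data$status == "abnormal") |>
    arrange(.data$chrom1, .data$chrom2, .data$signature, .data$pos1,
            .data$pos2, .data$id)
  if (nrow(ab) == 0) return(empty_links())
  ab$cluster <- NA_integer_
  next_id <- 0L
  groups <- split(seq_len(nrow(ab)),
                  paste(ab$chrom1, ab$chrom2, ab$signature))
  for (idx in groups) {
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    pos1 <- ab$pos1[idx]; pos2 <- ab$pos2[idx]
    for (i in seq_along(idx)[-1]) {
      j <- i - 1L
      while (j >= 1 && pos1[i] - pos1[j] <= window) {
        if (abs(pos2[i] - pos2[j]) <= window) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
        j <- j - 1L
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    ab$cluster[idx] <- next_id + as.integer(factor(roots))
    next_id <- next_id + length(unique(roots))
  }
  links <- ab |>
    group_by(.data$cluster) |>
    summarise(
      chrom1 = .data$chrom1[1], start1 = min(.data$pos1),
      end1 = max(.data$pos1 + .data$read_len),
      strand1 = names(which.max(table(.data$strand1))),
      chrom2 = .data$chrom2[1], start2 = min(.data$pos2),
      end2 = max(.data$pos2 + .data$read_len),
      strand2 = names(which.max(table(.data$strand2))),
      n_pairs = dplyr::n(),
      signature = .data$signature[1],
      inter = .data$inter[1],
      insert_median = median(.data$insert),
      .groups = "drop"
    ) |>
    filter(.data$n_pairs >= min_support) |>
    mutate(
      span = ifelse(.data$inter, NA_real_,
                    (.data$start2 + .data$end2) / 2 -
                      (.data$start1 + .data$end1) / 2)
    ) |>
    arrange(.data$chrom1, .data$start1, .data$chrom2, .data$start2) |>
    mutate(link_id = sprintf("link%04d", row_number())) |>
    select("link_id", dplyr::everything(), -"cluster")
  links <- assign_pem_type(links, model, window = window)
  class(links) <- c("sv_links", class(links))
  links
}

empty_links <- function() {
  out <- tibble(link_id = character(), chrom1 = character(),
                start1 = numeric(), end1 = numeric(), strand1 = character(),
                chrom2 = character(), start2 = numeric(), end2 = numeric(),
                strand2 = character(), n_pairs = integer(),
                signature = character(), inter = logical(),
                insert_median = numeric(), span = numeric(),
                pem_type = character(), size_class = character())
  class(out) <- c("sv_links", class(out))
  out
}

#' Assign paired-end-mapping signature types to links
#'
#' Maps the (inter/intra, orientation, insert-deviation,
#' reciprocal-cluster) combination of each link to one of the PEM
#' categories: `DELETION`, `INS_FRAGMT`, `INV_INS_FRAGMT`,
#' `INV_FRAGMENT`, `INVERSION`, `LARGE_DUPLICATION`, `TRANSLOCATION`,
#' `INTER`. Same-strand links with a reciprocal same-strand cluster of
#' the opposite sign at the same locus pair are inversions confirmed at
#' both ends (`INV_FRAGMENT`); without one, `INVERSION`. Combinations
#' outside the table are labelled `UNDEFINED`.
#'
#' @param links Link tibble from [cluster_links()].
#' @param model An `sv_insert_model`.
#' @param window Reciprocal-cluster matching window (bp).
#' @param large_sv Span threshold (bp) separating large from short
#'   intra-chromosomal links (default 50 kb).
#' @return `links` with `pem_type` and `size_class` columns.
#' @export
assign_pem_type <- function(links, model, window = NULL, large_sv = 5e4) {
  window <- window %||% (model$mu + model$k_sigma * model$sigma)
  if (nrow(links) == 0) {
    links$pem_type <- character(0)
    links$size_class <- character(0)
    return(links)
  }
  mid1 <- (links$start1 + links$end1) / 2
  mid2 <- (links$start2 + links$end2) / 2
  has_reciprocal <- vapply(seq_len(nrow(links)), function(i) {
    if (!links$signature[i] %in% c("same-", "same+")) return(FALSE)
    other <- setdiff(c("same-", "same+"), links$signature[i])
    any(links$signature == other &
          links$chrom1 == links$chrom1[i] &
          links$chrom2 == links$chrom2[i] &
          abs(mid1 - mid1[i]) <= 2 * window &
          abs(mid2 - mid2[i]) <= 2 * window)
  }, logical(1))
  links |>
    mutate(
      pem_type = dplyr::case_when(
        .data$inter & .data$signature == "inter_outward" ~ "TRANSLOCATION",
        .data$inter ~ "INTER",
        .data$signature == "outward_stretched" ~ "DELETION",
        .data$signature == "outward_shrunk" ~ "INS_FRAGMT",
        .data$signature %in% c("same-", "same+") &
          abs(.data$span) <= large_sv ~ "INV_INS_FRAGMT",
        .data$signature %in% c("same-", "same+") & has_reciprocal ~
          "INV_FRAGMENT",
        .data$signature %in% c("same-", "same+") ~ "INVERSION",
        .data$signature == "inward" & abs(.data$span) > model$mu ~
          "LARGE_DUPLICATION",
        TRUE ~ "UNDEFINED"
      ),
      size_class = dplyr::case_when(
        .data$inter ~ "inter",
        abs(.data$span) > large_sv ~ "large",
        TRUE ~ "short"
      )
    )
}

#' Effective (clone) coverage
#'
#' The fraction of the genome physically spanned by mate-pair clones:
#' `n_normal_pairs * insert_mean / genome_size`.
#'
#' @param n_normal_pairs Number of concordant pairs.
#' @param insert_mean Mean insert size (bp).
#' @param genome_size Genome size (bp); use the diploid size for a
#'   diploid sample.
#' @return Fold coverage (numeric).
#' @examples
#' effective_coverage(20e6, 3000, 6e9)  # 10
#' @export
effective_coverage <- function(n_normal_pairs, insert_mean, genome_size) {
  assert_that(genome_size > 0, "`genome_size` must be positive.")
  assert_that(insert_mean > 0, "`insert_mean` must be positive.")
  n_normal_pairs * insert_mean / genome_size
}
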