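make_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                       read_len = 50L) {
  tibble::tibble(
    id = sprintf("p%03d", seq_along(pos1)),
    chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
    chrom2 = chrom2, pos2 = as.integer(pos2), strand2 = strand2,
    read_len = read_len
  )
}

gauss_pairs <- function(n, mu = 3000, sd = 300, seed = 1, chrom = "chr1") {
  set.seed(seed)
  start <- sample.int(5e6, n)
  ins <- round(rnorm(n, mu, sd))
  make_pairs(chrom, start, "-", chrom, start + ins - 50L, "+")
}

test_that("insert model recovers a Gaussian insert distribution", {
  p <- gauss_pairs(10000, seed = 5)
  m <- fit_insert_model(p)
  expect_lt(abs(m$mu - 3000), 10)
  expect_lt(abs(m$sigma - 300), 15)
  expect_equal(tidy(m)$window_hi, m$mu + 4 * m$sigma)
})

test_that("insert model resists discordant contamination and rejects degeneracy", {
  p <- gauss_pairs(9500, seed = 7)
  contam <- make_pairs("chr1", seq(1e6, by = 1e4, length.out = 500), "-",
                       "chr1", seq(1e6, by = 1e4, length.out = 500) + 8e4,
                       "+")
  m <- fit_insert_model(dplyr::bind_rows(p, contam))
  expect_lt(abs(m$mu - 3000), 15)
  # constant inserts: sigma = 0 is degenerate
  flat <- make_pairs("chr1", 1:200 * 1000, "-", "chr1",
                     1:200 * 1000 + 2950, "+")
  expect_error(fit_insert_model(flat), "degenerate")
  expect_error(fit_insert_model(p[1:50, ]), "too few")
})

test_that("classification partitions every pair into exactly one label", {
  p <- gauss_pairs(2000, seed = 9)
  abn <- make_pairs(c("chr1", "chr2"), c(100, 200), c("-", "+"),
                    c("chr2", "chr2"), c(5000, 9000), c("+", "+"))
  m <- fit_insert_model(p)
  cls <- classify_pairs(dplyr::bind_rows(p, abn), m)
  expect_equal(nrow(cls), 2002)
  expect_true(all(cls$status %in% c("normal", "abnormal")))
  expect_equal(sum(cls$status == "normal") + sum(cls$status == "abnormal"),
               nrow(cls))
})

test_that("raw signatures follow orientation and insert deviation", {
  m <- structure(list(mu = 3000, sigma = 300, k_sigma = 4, n_pairs = 1000),
                 class = "sv_insert_model")
  cls <- classify_pairs(make_pairs(
    c("chr1", "chr1", "chr1", "chr2"),
    c(1000, 1000, 1000, 1000),
    c("-", "-", "-", "-"),
    c("chr1", "chr1", "chr1", "chr3"),
    c(3950, 81000, 3950, 4000),
    c("+", "+", "-", "+")
  ), m)
  expect_equal(cls$status, c("normal", "abnormal", "abnormal", "abnormal"))
  expect_equal(cls$signature[2], "outward_stretched")
  expect_equal(cls$signature[3], "same-")
  expect_equal(cls$signature[4], "inter_outward")
})

test_that("clustering respects the support threshold and keeps distant events apart", {
  m <- structure(list(mu = 3000, sigma = 300, k_sigma = 4, n_pairs = 1000),
                 class = "sv_insert_model")
  # 8 pairs over one translocation
  tra <- make_pairs("chr1", 5000 + (1:8) * 100, "-",
                    "chr2", 90000 + (1:8) * 100, "+")
  links <- cluster_links(tra, m)
  expect_equal(nrow(links), 1)
  expect_equal(links$n_pairs, 8L)
  expect_equal(links$pem_type, "TRANSLOCATION")
  # single pair below min_support
  single <- make_pairs("chr1", 5000, "-", "chr2", 90000, "+")
  expect_equal(nrow(cluster_links(single, m)), 0)
  # two deletions 10 Mb apart never merge
  del1 <- make_pairs("chr1", 1e6 + (1:4) * 200, "-",
                     "chr1", 1e6 + 8e4 + (1:4) * 200, "+")
  del2 <- make_pairs("chr1", 11e6 + (1:4) * 200, "-",
                     "chr1", 11e6 + 8e4 + (1:4) * 200, "+")
  links2 <- cluster_links(dplyr::bind_rows(del1, del2), m)
  expect_equal(nrow(links2), 2)
  expect_true(all(links2$pem_type == "DELETION"))
})

test_that("link calling is invariant to swapping the two ends of every pair", {
  m <- structure(list(mu = 3000, sigma = 300, k_sigma = 4, n_pairs = 1000),
                 class = "sv_insert_model")
  p <- make_pairs("chr1", 5000 + (1:6) * 100, "-",
                  "chr2", 90000 + (1:6) * 100, "+")
  swapped <- p |>
    dplyr::rename(chrom1 = chrom2, pos1 = pos2, strand1 = strand2,
                  chrom2 = chrom1, pos2 = pos1, strand2 = strand1)
  l1 <- cluster_links(p, m)
  l2 <- cluster_links(swapped, m)
  expect_equal(l1$chrom1, l2$chrom1)
  expect_equal(l1$start1, l2$start1)
  expect_equal(l1$pem_type, l2$pem_type)
})

test_that("PCR duplicates collapse to a single pair", {
  p <- make_pairs("chr1", rep(1000, 5), "-", "chr1", rep(84000, 5), "+")
  expect_equal(nrow(dedup_pairs(p)), 1)
})

test_that("the PEM decision table reproduces all link categories", {
  m <- structure(list(mu = 3000, sigma = 300, k_sigma = 4, n_pairs = 1000),
                 class = "sv_insert_model")
  mk <- function(pos1, s1, pos2, s2, chrom2 = "chr1") {
    make_pairs("chr1", pos1 + (1:3) * 150, s1, chrom2, pos2 + (1:3) * 150,
               s2)
  }
  pairs <- dplyr::bind_rows(
    mk(1e6, "-", 1e6 + 2e5, "+"),                  # DELETION
    mk(2e6, "-", 2e6 + 1200, "+"),                 # INS_FRAGMT (shrunk)
    mk(3e6, "-", 3e6 + 2e5, "-"),                  # INVERSION (one side)
    mk(5e6, "-", 5e6 + 2e5, "-"),                  # INV_FRAGMENT pair...
    mk(5e6 + 2000, "+", 5e6 + 2e5 + 2000, "+"),    # ...reciprocal cluster
    mk(7e6, "+", 7e6 + 2e5, "-"),                  # LARGE_DUPLICATION
    mk(8e6, "-", 8e6 + 3e4, "-"),                  # INV_INS_FRAGMT (short)
    mk(9e6, "-", 9e6, "+", chrom2 = "chr2"),       # TRANSLOCATION
    mk(10e6, "+", 10e6, "+", chrom2 = "chr2")      # INTER
  )
  links <- cluster_links(pairs, m)
  expect_setequal(links$pem_type,
                  c("DELETION", "INS_FRAGMT", "INVERSION", "INV_FRAGMENT",
                    "LARGE_DUPLICATION", "INV_INS_FRAGMT", "TRANSLOCATION",
                    "INTER"))
  inv <- links[links$chrom1 == "chr1" & links$start1 > 4.9e6 &
                 links$start1 < 5.3e6, ]
  expect_true(all(inv$pem_type == "INV_FRAGMENT"))
})

test_that("effective coverage follows the clone-coverage formula", {
  expect_equal(effective_coverage(20e6, 3000, 6e9), 10)
  expect_equal(effective_coverage(16e6, 3000, 6e9), 8)
  expect_equal(effective_coverage(0, 3000, 6e9), 0)
  expect_error(effective_coverage(1, 3000, 0), "positive")
})
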