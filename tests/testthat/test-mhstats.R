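test_that("null pmf matches outcome-pattern enumeration exactly for m <= 3", {
  # independent oracle: enumerate match/mismatch patterns of the first
  # four base comparisons on each side of the junction; each comparison
  # of two independent bases matches with probability p = sum(f^2)
  enum_pmf <- function(f, m_max = 3) {
    p <- sum(f^2)
    k <- 4
    probs <- rep(0, m_max + 1)
    for (code in 0:(2^(2 * k) - 1)) {
      bits <- as.integer(intToBits(code))[1:(2 * k)]
      left <- bits[1:k]
      right <- bits[(k + 1):(2 * k)]
      u <- match(0, left, nomatch = k + 1) - 1
      v <- match(0, right, nomatch = k + 1) - 1
      m <- u + v
      if (m <= m_max && u < k + 1 && v < k + 1 && u < k && v < k) {
        pr <- p^sum(bits) * (1 - p)^(2 * k - sum(bits))
        probs[m + 1] <- probs[m + 1] + pr
      }
    }
    probs
  }
  for (f in list(rep(0.25, 4), c(0.2, 0.3, 0.3, 0.2))) {
    null <- mh_null(f)
    expect_equal(null$pmf$prob[1:4], enum_pmf(f), tolerance = 1e-12)
  }
})

test_that("uniform composition gives the closed-form landmarks", {
  null <- mh_null()
  expect_equal(null$p, 0.25)
  expect_equal(null$pmf$prob[1], 9 / 16)
  expect_equal(1 - null$pmf$prob[1], 7 / 16)
  # GC-shifted composition
  gcr <- mh_null(c(0.2, 0.3, 0.3, 0.2))
  expect_equal(gcr$p, 0.26)
  expect_equal(gcr$pmf$prob[1], 0.74^2)
  # normalisation including the analytic tail
  tail40 <- svbreaks:::mh_null_tail(null, 41)
  expect_equal(sum(null$pmf$prob) + tail40, 1, tolerance = 1e-12)
  expect_error(mh_null(c(1, 0, 0, 0)), "degenerate")
})

test_that("Monte-Carlo of independent flank pairs matches the pmf", {
  n <- 30000
  mh <- mc_mh_lengths(n, seed = 7)
  null <- mh_null()
  for (m in 0:3) {
    se <- sqrt(null$pmf$prob[m + 1] * (1 - null$pmf$prob[m + 1]) / n)
    expect_lt(abs(mean(mh == m) - null$pmf$prob[m + 1]), 3 * se)
  }
})

test_that("chi-square binning follows Cochran's rule and detects enrichment", {
  null <- mh_null()
  t0 <- mh_chisq(rep(0:2, c(30, 20, 9)), null)
  expect_true(all(t0$table$expected >= 1))
  expect_gte(mean(t0$table$expected >= 5), 0.8)
  expect_equal(t0$df, nrow(t0$table) - 1L)
  # all junctions with m >= 4: overwhelming rejection
  t1 <- mh_chisq(rep(4:9, length.out = 59), null)
  expect_lt(t1$p_value, 1e-30)
  expect_error(mh_chisq(integer(0), null), "empty")
  # glance/tidy accessors
  expect_equal(glance(t1)$p.value, t1$p_value)
  expect_equal(sum(tidy(t1)$observed), 59)
})

test_that("the test statistic grows monotonically with planted effect size", {
  null <- mh_null()
  shift <- function(delta, seed) {
    mh <- pmin(mc_mh_lengths(59, seed = seed) + delta, 28L)
    mh_chisq(mh, null)$statistic
  }
  # same base sample, increasing upward shift of the spectrum; the
  # statistic saturates once all mass leaves the pooled bins, so the
  # property is non-decreasing with a strict first step
  s <- vapply(c(0L, 1L, 2L, 4L), shift, numeric(1), seed = 13)
  expect_true(all(diff(s) >= 0))
  expect_gt(s[2], s[1])
  # and the statistic is invariant to observation order
  mh <- pmin(mc_mh_lengths(59, seed = 19) + 1L, 28L)
  expect_equal(mh_chisq(mh, null)$statistic,
               mh_chisq(rev(mh), null)$statistic)
})

test_that("stratified report tabulates patterns per sample and tests per stratum", {
  set.seed(29)
  calls <- tibble::tibble(
    mh_len = c(pmin(mc_mh_lengths(40, seed = 3) + 2L, 28L), rep(0L, 12),
               rep(0L, 7)),
    class = rep(c("microhomology", "blunt", "insertion"), c(40, 12, 7)),
    sample = rep(c("s1", "s2", "s3", "s4"), length.out = 59),
    chromothripsis = rep(c(FALSE, TRUE), length.out = 59)
  )
  rpt <- stratified_report(calls)
  expect_equal(nrow(rpt$tests), 2)
  expect_equal(sum(rpt$sample_summary$microhomology) +
                 sum(rpt$sample_summary$blunt) +
                 sum(rpt$sample_summary$insertion), 59)
  # insertion junctions are excluded from the tested counts
  expect_equal(sum(rpt$tests$n), 52)
  # per-stratum histograms are frequency-normalised
  freq_sums <- rpt$histogram |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(s = sum(observed))
  expect_equal(freq_sums$s, rep(1, 2))
  expect_error(stratified_report(dplyr::mutate(calls, sample = NA)),
               "unlabeled")
})

test_that("identical planted spectra give concordant stratum tests", {
  mh <- pmin(mc_mh_lengths(60, seed = 17), 28L)
  calls <- tibble::tibble(
    mh_len = rep(mh, 2),
    class = ifelse(rep(mh, 2) >= 1, "microhomology", "blunt"),
    sample = "s",
    chromothripsis = rep(c(TRUE, FALSE), each = 60)
  )
  rpt <- stratified_report(calls)
  expect_equal(rpt$tests$statistic[1], rpt$tests$statistic[2],
               tolerance = 1e-12)
})
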