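test_that("measure_microhomology matches the brute-force slide oracle", {
  # deterministic example: donor A continues with "TTAC" after the break
  # and donor B starts with the same word, so the join can slide by 4
  expect_equal(
    measure_microhomology("GGGGCTTAC", "ACGTTACG", break_a = 5,
                          break_b = 4), 4)
  expect_equal(brute_force_mh("GGGGCTTAC", "ACGTTACG", 5, 4), 4)
  # random cases against the exhaustive split-point search
  set.seed(101)
  for (i in 1:200) {
    fa <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
    fb <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
    expect_equal(measure_microhomology(fa, fb, 12, 13),
                 brute_force_mh(fa, fb, 12, 13))
  }
})

test_that("matrix Monte-Carlo agrees with measure_microhomology case by case", {
  # the helper used for large-n calibration must agree with the
  # exported measurement on explicit flank pairs
  set.seed(11)
  depth <- 12
  for (i in 1:100) {
    a_left <- sample(c("A", "C", "G", "T"), depth, TRUE)
    b_left <- sample(c("A", "C", "G", "T"), depth, TRUE)
    a_right <- sample(c("A", "C", "G", "T"), depth, TRUE)
    b_right <- sample(c("A", "C", "G", "T"), depth, TRUE)
    fa <- paste(c(a_left, a_right), collapse = "")
    fb <- paste(c(b_left, b_right), collapse = "")
    got <- measure_microhomology(fa, fb, depth, depth + 1)
    # direct run-length evaluation of the two extensions
    u <- 0
    while (u < depth && a_left[depth - u] == b_left[depth - u]) u <- u + 1
    v <- 0
    while (v < depth && a_right[v + 1] == b_right[v + 1]) v <- v + 1
    expect_equal(got, u + v)
  }
})

test_that("resolve_junction recovers planted junctions of every class", {
  # microhomology
  d <- render_one_junction(seed = 201, type = "microhomology", mh = 5)
  call <- resolve_junction(d$truth$region_seq[1], d$reference)
  expect_equal(call$class, "microhomology")
  expect_equal(call$mh_len, 5L)
  expect_equal(call$posA, d$truth$posA[1])
  expect_equal(call$posB, d$truth$posB[1])
  # blunt
  db <- render_one_junction(seed = 205, type = "blunt")
  cb <- resolve_junction(db$truth$region_seq[1], db$reference)
  expect_equal(cb$class, "blunt")
  expect_equal(cb$mh_len, 0L)
  # templated: three segments, two calls, templated first
  dt <- render_one_junction(seed = 209, type = "templated")
  ct <- resolve_junction(dt$truth$region_seq[1], dt$reference)
  expect_equal(nrow(ct), 2)
  expect_equal(ct$class[1], "templated")
  expect_lte(ct$frag_distance[1], 1e4)
  # shard: fragment donor far away
  ds <- render_one_junction(seed = 213, type = "shard")
  cs <- resolve_junction(ds$truth$region_seq[1], ds$reference)
  expect_equal(cs$class[1], "shard")
  expect_gt(cs$frag_distance[1], 1e4)
})

test_that("resolution is coordinate-consistent under reverse complement", {
  d <- render_one_junction(seed = 217, type = "microhomology", mh = 7)
  fwd <- resolve_junction(d$truth$region_seq[1], d$reference)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(d$truth$region_seq[1])))
  rev <- resolve_junction(rc, d$reference)
  # A and B swap, strands flip, homology length is preserved
  expect_equal(rev$mh_len, fwd$mh_len)
  expect_equal(rev$chromA, fwd$chromB)
  expect_equal(rev$chromB, fwd$chromA)
  expect_equal(rev$strandA, flip <- ifelse(fwd$strandB == "+", "-", "+"))
  expect_equal(rev$strandB, ifelse(fwd$strandA == "+", "-", "+"))
  expect_equal(rev$posA, fwd$posB)
  expect_equal(rev$posB, fwd$posA)
})

test_that("unmappable and non-unique reads error; batch wrapper reports status", {
  g <- small_genome(15)
  random_read <- paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                       collapse = "")
  # a read that exists nowhere errors as unmappable at one anchor or the
  # other
  expect_error(resolve_junction(random_read, g))
  expect_error(resolve_junction("ACGTACGT", g), "min_anchor")
  # a duplicated locus makes the anchor non-unique
  dup <- genome_seq(g, "chr1", 1001, 1100)
  gdup <- svbreaks:::genome_replace(g, "chr2", 2001, dup)
  read <- paste0(dup, genome_seq(g, "chr1", 5001, 5100))
  expect_error(resolve_junction(read, gdup), "non-unique")
  batch <- resolve_junctions(c(ok = read, bad = random_read), g)
  expect_equal(batch$status[batch$read_id == "bad"], "unmappable")
})

test_that("a collinear read yields no junction call", {
  g <- small_genome(16)
  read <- genome_seq(g, "chr1", 2001, 2150)
  out <- resolve_junction(read, g)
  expect_equal(nrow(out), 0)
})

test_that("mh_len and insertion_seq are mutually exclusive", {
  for (seed in c(301, 305, 309)) {
    for (type in c("microhomology", "blunt", "insertion")) {
      d <- render_one_junction(seed = seed, type = type)
      call <- resolve_junction(d$truth$region_seq[1], d$reference)
      expect_false(call$mh_len > 0 && nzchar(call$insertion_seq))
    }
  }
})

test_that("complexity counting separates simple from complex rearrangements", {
  calls <- tibble::tibble(
    rearrangement = c("sv1", "sv2", "sv2", "sv3"),
    class = c("blunt", "templated", "microhomology", "microhomology")
  )
  cx <- count_rearrangement_complexity(calls)
  expect_equal(cx$complexity[cx$rearrangement == "sv1"], "simple")
  expect_equal(cx$complexity[cx$rearrangement == "sv2"], "complex")
  expect_equal(cx$n_junctions[cx$rearrangement == "sv2"], 2L)
  expect_error(count_rearrangement_complexity(calls, group = "missing"),
               "not found")
})
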