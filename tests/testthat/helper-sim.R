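# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

small_genome <- function(seed = 1, lengths = c(15e4, 12e4)) {
  simulate_genome(length(lengths), lengths, seed = seed)
}

# one rendered deletion with a prescribed junction class
render_one_junction <- function(seed, type = "microhomology", mh = 5,
                                ins_len = 8, glen = 2e5) {
  cfg <- switch(type,
    microhomology = junction_config(type_probs = c(microhomology = 1),
                                    mh_lengths = mh),
    blunt = junction_config(type_probs = c(blunt = 1)),
    insertion = junction_config(type_probs = c(insertion = 1),
                                ins_lengths = ins_len),
    shard = junction_config(type_probs = c(shard = 1)),
    templated = junction_config(type_probs = c(templated = 1))
  )
  g <- simulate_genome(2, c(glen, 6e4), seed = seed)
  p <- plan_rearrangements(g, "simple", n_events = 1,
                           sv_types = "deletion", junction_spec = cfg,
                           seed = seed + 1, size_range = c(5e4, 7e4))
  render_derived_genome(g, p)
}

# a toy gene-model table built by hand (one gene per chromosome)
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("GX", "GY"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "+"),
    tss = c(10000L, 20000L),
    tx_end = c(30000L, 44000L),
    exons = list(
      tibble::tibble(start = c(10000L, 15000L, 25000L),
                     end = c(10500L, 15500L, 30000L)),
      tibble::tibble(start = c(20000L, 30000L, 40000L),
                     end = c(20800L, 31000L, 44000L))
    )
  )
}

# an annotated inter-chromosomal link joining 5' GX to 3' GY
toy_chimera_link <- function() {
  l <- tibble::tibble(
    link_id = "L1", chrom1 = "chr1", start1 = 17000, end1 = 17400,
    strand1 = "-", chrom2 = "chr2", start2 = 33000, end2 = 33400,
    strand2 = "+", n_pairs = 8L, signature = "inter_outward",
    inter = TRUE, insert_median = NA_real_, span = NA_real_,
    pem_type = "TRANSLOCATION", size_class = "inter"
  )
  annotate_links(l, toy_genes())
}

# brute-force slide oracle: number of alternative split points giving
# the same joined sequence
brute_force_mh <- function(flank_a, flank_b, break_a, break_b) {
  a <- strsplit(flank_a, "")[[1]]
  b <- strsplit(flank_b, "")[[1]]
  joined <- c(a[seq_len(break_a)], b[break_b:length(b)])
  count <- 0L
  for (s in seq(-break_a + 1L, length(a) - break_a)) {
    ba <- break_a + s
    bb <- break_b + s
    if (bb < 1L || bb > length(b) + 1L) next
    if (s == 0) next
    cand <- c(a[seq_len(ba)], if (bb <= length(b)) b[bb:length(b)])
    if (length(cand) == length(joined) && all(cand == joined)) {
      count <- count + 1L
    }
  }
  count
}

# Monte-Carlo microhomology of unrelated flank pairs via matrix ops
# (validated against measure_microhomology in tests)
mc_mh_lengths <- function(n, depth = 30, base_freq = rep(0.25, 4), seed) {
  with_seed <- get("with_seed", asNamespace("svbreaks"))
  with_seed(seed, {
    draw <- function() matrix(sample(c("A", "C", "G", "T"), n * depth,
                                     replace = TRUE, prob = base_freq),
                              nrow = n)
    run_len <- function(cmp) {
      acc <- rep(1L, nrow(cmp))
      out <- rep(0L, nrow(cmp))
      for (j in seq_len(ncol(cmp))) {
        acc <- acc * cmp[, j]
        out <- out + acc
      }
      out
    }
    u <- run_len(draw() == draw())
    v <- run_len(draw() == draw())
    u + v
  })
}
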