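#' Simulate mate-pair read pairs from a derived genome
#'
#' Draws mate-pair fragments uniformly along the derived sequences and
#' reports both reads in reference coordinates. Concordant pairs follow
#' the outward orientation convention of circularised mate-pair
#' libraries: the leftmost read is stored on the `-` strand and the
#' rightmost on `+`. Pairs whose fragment spans a rearrangement junction
#' become discordant by construction; a read overlapping a junction (or
#' an untemplated insertion) is unmappable and the pair is dropped,
#' mirroring unique end-mapping.
#'
#' @param derived An `sv_derived` from [render_derived_genome()].
#' @param n_pairs Number of fragments to draw (before dropping unmappable
#'   pairs). See [pairs_for_coverage()] to convert a target effective
#'   coverage into a pair count.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp;
#'   the study design this emulates uses ~3 kb inserts.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @param include_reference_homolog If `TRUE`, an intact reference copy of
#'   every replaced chromosome is added to the template pool and all
#'   untouched chromosomes are counted twice, emulating a diploid tumour
#'   genome in which rearrangements sit on one homolog. Retained
#'   chromothripsis fragments then have copy state two and lost fragments
#'   state one.
#' @return A read-pair tibble: `id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `read_len`, `source` (`"normal"` or
#'   `"sv:<junction_id>"` for junction-spanning fragments). Positions are
#'   the 1-based leftmost mapped base of each read.
#' @export
simulate_mate_pairs <- function(derived, n_pairs,
                                insert_mean = 3000, insert_sd = 300,
                                read_len = 50, seed,
                                include_reference_homolog = FALSE) {
  assert_that(insert_mean > 2 * read_len,
              "`insert_mean` must exceed twice the read length.")
  pool <- template_pool(derived, include_reference_homolog)
  min_len <- insert_mean + 6 * insert_sd
  assert_that(all(pool$length >= min_len),
              "derived sequence shorter than insert_mean + 6*insert_sd.")
  with_seed(seed, {
    tpl <- sample(nrow(pool), n_pairs, replace = TRUE,
                  prob = pool$length * pool$weight)
    ins <- pmax(2L * read_len + 2L, round(rnorm(n_pairs, insert_mean,
                                                insert_sd)))
    len <- pool$length[tpl]
    ins <- pmin(ins, len - 1L)
    start <- floor(runif(n_pairs, 1, len - ins + 1))
    p1 <- as.integer(start)                      # leftmost read, '-' strand
    p2 <- as.integer(start + ins - read_len)     # rightmost read, '+' strand
    m1 <- map_to_reference(derived$map, pool$map_chrom[tpl], p1, read_len)
    m2 <- map_to_reference(derived$map, pool$map_chrom[tpl], p2, read_len)
    ok <- m1$ok & m2$ok
    src <- pair_source(derived$truth, pool$map_chrom[tpl], m1$piece, m2$piece,
                       derived$map)
    tibble(
      id = sprintf("pair%07d", seq_len(n_pairs)),
      chrom1 = m1$chrom, pos1 = m1$pos,
      strand1 = flip_strand("-", m1$flip),
      chrom2 = m2$chrom, pos2 = m2$pos,
      strand2 = flip_strand("+", m2$flip),
      read_len = as.integer(read_len),
      source = src
    )[ok, ]
  })
}

flip_strand <- function(strand, flip) {
  ifelse(flip, ifelse(strand == "+", "-", "+"), strand)
}

template_pool <- function(derived, include_reference_homolog) {
  map <- derived$map
  ders <- unique(map$der_chrom)
  pool <- tibble(
    map_chrom = ders,
    length = vapply(ders, function(d) max(map$der_end[map$der_chrom == d]),
                    numeric(1)),
    weight = 1
  )
  if (include_reference_homolog) {
    # intact homolog of each replaced chromosome, plus double weight for
    # untouched chromosomes (two identical copies)
    repl <- derived$replaced
    ref_lens <- genome_lengths(derived$reference)
    extra <- tibble(map_chrom = paste0("ref::", repl),
                    length = as.numeric(ref_lens[repl]), weight = 1)
    untouched <- setdiff(names(ref_lens), repl)
    pool$weight[pool$map_chrom %in% untouched] <- 2
    pool <- bind_rows(pool, extra)
  }
  pool
}

# Map reads given by derived coordinates back to the reference. Template
# names "ref::<chrom>" denote intact reference homologs (identity map).
map_to_reference <- function(map, der_chrom, pos, read_len) {
  n <- length(pos)
  out <- list(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
              flip = rep(FALSE, n), ok = rep(FALSE, n),
              piece = rep(NA_integer_, n))
  is_ref <- startsWith(der_chrom, "ref::")
  if (any(is_ref)) {
    out$chrom[is_ref] <- sub("^ref::", "", der_chrom[is_ref])
    out$pos[is_ref] <- pos[is_ref]
    out$ok[is_ref] <- TRUE
    out$piece[is_ref] <- 0L
  }
  for (d in unique(der_chrom[!is_ref])) {
    rows <- which(map$der_chrom == d)
    sel <- which(der_chrom == d & !is_ref)
    idx <- findInterval(pos[sel], map$der_start[rows])
    valid <- idx >= 1
    r <- rows[pmax(idx, 1L)]
    inside <- valid & pos[sel] + read_len - 1L <= map$der_end[r] &
      !is.na(map$chrom[r])
    fwd <- map$orient[r] == "+"
    refpos <- ifelse(fwd,
                     map$start[r] + (pos[sel] - map$der_start[r]),
                     map$end[r] - (pos[sel] - map$der_start[r]) -
                       (read_len - 1L))
    out$chrom[sel] <- map$chrom[r]
    out$pos[sel] <- as.integer(refpos)
    out$flip[sel] <- !fwd
    out$ok[sel] <- inside
    out$piece[sel] <- r
  }
  out
}

# Label each pair with the junction its fragment spans ("normal" if both
# reads sit in the same map piece).
pair_source <- function(truth, der_chrom, piece1, piece2, map) {
  src <- rep("normal", length(piece1))
  spans <- !is.na(piece1) & !is.na(piece2) & piece1 != piece2
  if (!any(spans) || is.null(truth) || nrow(truth) == 0) return(src)
  for (i in which(spans)) {
    d <- der_chrom[i]
    lo <- min(map$der_end[piece1[i]], map$der_end[piece2[i]])
    hi <- max(map$der_start[piece1[i]], map$der_start[piece2[i]])
    hit <- truth$der_chrom == d & truth$der_pos >= lo - 1L &
      truth$der_pos <= hi
    src[i] <- if (any(hit)) {
      paste0("sv:", paste(truth$junction_id[hit], collapse = "+"))
    } else {
      "sv:?"
    }
  }
  src
}

#' Pair count needed for a target effective coverage
#'
#' Effective (clone) coverage is `n_pairs * insert_mean / genome_size`:
#' the fraction of the genome physically spanned by mate-pair clones.
#'
#' @param coverage Target effective coverage (fold).
#' @param genome_size Genome size in bp (use the total template pool size).
#' @param insert_mean Mean insert size in bp.
#' @return Number of pairs (integer).
#' @export
pairs_for_coverage <- function(coverage, genome_size, insert_mean = 3000) {
  as.integer(ceiling(coverage * genome_size / insert_mean))
}
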