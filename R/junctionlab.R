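#' Measure junction microhomology between two donor flanks
#'
#' Microhomology at a junction is the number of bases over which the
#' breakpoint can slide without changing the joined sequence: the sum of
#' a left extension (terminal bases of the donor-A flank that reappear
#' immediately before the donor-B start) and a right extension (donor-A
#' continuation bases that reappear at the donor-B start).
#'
#' @param flank_a Donor-A sequence around the breakpoint; the junction
#'   falls immediately after position `break_a`.
#' @param flank_b Donor-B sequence around the breakpoint; segment B
#'   starts at position `break_b`.
#' @param break_a,break_b Junction positions within the two flanks
#'   (defaults: midpoints).
#' @return Integer microhomology length (0 for a blunt junction).
#' @examples
#' # donor A continues with "TTAC" beyond the break and donor B starts
#' # with the same word: the join slides over 4 bases
#' measure_microhomology("GGGGCTTAC", "ACGTTACG", break_a = 5, break_b = 4)
#' @export
measure_microhomology <- function(flank_a, flank_b,
                                  break_a = nchar(flank_a) %/% 2,
                                  break_b = nchar(flank_b) %/% 2 + 1L) {
  a <- strsplit(flank_a, "")[[1]]
  b <- strsplit(flank_b, "")[[1]]
  u <- 0L
  while (break_a - u >= 1 && break_b - u - 1L >= 1 &&
         a[break_a - u] == b[break_b - u - 1L]) {
    u <- u + 1L
  }
  v <- 0L
  while (break_a + v + 1L <= length(a) && break_b + v <= length(b) &&
         a[break_a + v + 1L] == b[break_b + v]) {
    v <- v + 1L
  }
  u + v
}

# ---- exact anchoring against a reference -------------------------------

ref_cache <- function(genome) {
  list(chrs = setNames(as.character(genome$seqs), names(genome$seqs)),
       dna = genome$seqs)
}

# all exact occurrences of `pattern` in the genome, both strands
anchor_hits <- function(pattern, cache) {
  pat <- Biostrings::DNAString(pattern)
  rcp <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (ch in names(cache$dna)) {
    f <- Biostrings::matchPattern(pat, cache$dna[[ch]])
    if (length(f)) {
      hits[[length(hits) + 1]] <- tibble(
        chrom = ch, start = Biostrings::start(f), end = Biostrings::end(f),
        strand = "+"
      )
    }
    r <- Biostrings::matchPattern(rcp, cache$dna[[ch]])
    if (length(r)) {
      hits[[length(hits) + 1]] <- tibble(
        chrom = ch, start = Biostrings::start(r), end = Biostrings::end(r),
        strand = "-"
      )
    }
  }
  if (length(hits)) bind_rows(hits) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character())
}

# donor position of read index r for an anchored, gap-free alignment
donor_pos <- function(aln, r) {
  if (aln$strand == "+") aln$ref0 + (r - aln$read0)
  else aln$ref0 - (r - aln$read0)
}

ref_base_matches <- function(cache, chrom, pos, strand, read_char) {
  if (pos < 1 || pos > nchar(cache$chrs[[chrom]])) return(FALSE)
  b <- substr(cache$chrs[[chrom]], pos, pos)
  if (strand == "-") b <- complement_base(b)
  b == read_char
}

# Maximal ungapped extension of an anchored k-mer in both directions.
# Returns alignment: chrom, strand, read_lo, read_hi, ref0 (donor position
# of read index read0).
extend_anchor <- function(read_chars, cache, hit, read_from, read_to) {
  aln <- list(chrom = hit$chrom, strand = hit$strand,
              read0 = read_from,
              ref0 = if (hit$strand == "+") hit$start else hit$end)
  lo <- read_from
  while (lo - 1L >= 1 &&
         ref_base_matches(cache, aln$chrom, donor_pos(aln, lo - 1L),
                          aln$strand, read_chars[lo - 1L])) {
    lo <- lo - 1L
  }
  hi <- read_to
  while (hi + 1L <= length(read_chars) &&
         ref_base_matches(cache, aln$chrom, donor_pos(aln, hi + 1L),
                          aln$strand, read_chars[hi + 1L])) {
    hi <- hi + 1L
  }
  c(aln, list(read_lo = lo, read_hi = hi))
}

locate_unique <- function(read, cache, from, to) {
  hits <- anchor_hits(substr(read, from, to), cache)
  if (nrow(hits) == 0) return(list(status = "unmappable"))
  if (nrow(hits) > 1) return(list(status = "non-unique"))
  list(status = "ok", hit = hits[1, ])
}

#' Resolve a junction sequence against the reference
#'
#' Anchors a junction read (e.g. a Sanger sequence of a PCR product
#' spanning a rearrangement) from both ends with exact `min_anchor`-mers,
#' extends each anchor without mismatch, and reads the junction structure
#' off the two alignments: their overlap on the read is the
#' microhomology, a gap is a candidate insertion. A gap that maps
#' uniquely back to the reference is a genomic shard (donor farther than
#' `shard_min` from both breakpoints) or a templated insertion of nearby
#' sequence (donor within `shard_min`); such reads resolve to three
#' segments and yield one call per adjacent segment pair.
#'
#' @param read A junction-spanning DNA string (length at least
#'   `2 * min_anchor`).
#' @param reference An `sv_genome` (use the `reference` element of an
#'   [render_derived_genome()] result when resolving simulated reads).
#' @param min_anchor Anchor seed length (bp); 20 gives effectively unique
#'   seeds in genomes far larger than those simulated here.
#' @param shard_min Shard/templated distance threshold (bp); keep equal to
#'   the planning value.
#' @return A tibble with one row per junction: donor coordinates and
#'   strands of both partners (`chromA`, `posA`, `strandA`, `chromB`,
#'   `posB`, `strandB`), `mh_len`, `insertion_seq`, `class`
#'   (`microhomology`, `blunt`, `insertion`, `shard` or `templated`) and
#'   fragment fields for shard/templated calls. Coordinates follow the
#'   maximal-prefix convention: microhomology bases are assigned to
#'   segment A. Zero rows are returned for a read collinear with the
#'   reference (no junction).
#' @export
resolve_junction <- function(read, reference, min_anchor = 20L,
                             shard_min = 1e4) {
  assert_that(nchar(read) >= 2 * min_anchor,
              "read shorter than 2 * min_anchor.")
  cache <- ref_cache(reference)
  read_chars <- strsplit(read, "")[[1]]
  L <- length(read_chars)

  pre <- locate_unique(read, cache, 1L, min_anchor)
  if (pre$status != "ok") abort(paste0(pre$status, " prefix anchor."))
  suf <- locate_unique(read, cache, L - min_anchor + 1L, L)
  if (suf$status != "ok") abort(paste0(suf$status, " suffix anchor."))

  paln <- extend_anchor(read_chars, cache, pre$hit, 1L, min_anchor)
  saln <- extend_anchor(read_chars, cache, suf$hit, L - min_anchor + 1L, L)
  prefix_end <- paln$read_hi
  suffix_start <- saln$read_lo

  # collinear (no junction)?
  if (paln$chrom == saln$chrom && paln$strand == saln$strand) {
    dp <- donor_pos(paln, prefix_end)
    ds <- donor_pos(saln, suffix_start)
    step <- if (paln$strand == "+") 1L else -1L
    if ((ds - dp) * step == suffix_start - prefix_end &&
        prefix_end >= suffix_start - 1L) {
      return(junction_call_tbl()[0, ])
    }
  }

  gap <- suffix_start - prefix_end - 1L
  pos_a <- donor_pos(paln, prefix_end)
  pos_b <- donor_pos(saln, suffix_start)
  if (gap <= 0) {
    m <- -gap
    return(junction_call_tbl(
      chromA = paln$chrom, posA = pos_a, strandA = paln$strand,
      chromB = saln$chrom, posB = pos_b, strandB = saln$strand,
      mh_len = m, insertion_seq = "",
      class = if (m >= 1) "microhomology" else "blunt"
    ))
  }

  gap_seq <- substr(read, prefix_end + 1L, suffix_start - 1L)
  frag <- NULL
  if (nchar(gap_seq) >= 15) {
    hits <- anchor_hits(gap_seq, cache)
    if (nrow(hits) == 1) frag <- hits[1, ]
  }
  if (is.null(frag)) {
    return(junction_call_tbl(
      chromA = paln$chrom, posA = pos_a, strandA = paln$strand,
      chromB = saln$chrom, posB = pos_b, strandB = saln$strand,
      mh_len = 0L, insertion_seq = gap_seq, class = "insertion"
    ))
  }

  faln <- extend_anchor(read_chars, cache, frag,
                        prefix_end + 1L, suffix_start - 1L)
  mh1 <- max(0L, prefix_end - faln$read_lo + 1L)
  mh2 <- max(0L, faln$read_hi - suffix_start + 1L)
  fd1 <- donor_pos(faln, faln$read_lo)
  fd2 <- donor_pos(faln, faln$read_hi)
  frag_start <- min(fd1, fd2)
  frag_end <- max(fd1, fd2)
  dist <- Inf
  if (frag$chrom == paln$chrom) {
    dist <- min(dist, abs(c(frag_start, frag_end) - pos_a))
  }
  if (frag$chrom == saln$chrom) {
    dist <- min(dist, abs(c(frag_start, frag_end) - pos_b))
  }
  cls1 <- if (dist <= shard_min) "templated" else "shard"
  bind_rows(
    junction_call_tbl(
      chromA = paln$chrom, posA = pos_a, strandA = paln$strand,
      chromB = frag$chrom, posB = fd1, strandB = frag$strand,
      mh_len = mh1, insertion_seq = "", class = cls1,
      frag_chrom = frag$chrom, frag_start = frag_start,
      frag_end = frag_end, frag_strand = frag$strand,
      frag_distance = dist
    ),
    junction_call_tbl(
      chromA = frag$chrom, posA = fd2, strandA = frag$strand,
      chromB = saln$chrom, posB = pos_b, strandB = saln$strand,
      mh_len = mh2, insertion_seq = "",
      class = if (mh2 >= 1) "microhomology" else "blunt"
    )
  )
}

junction_call_tbl <- function(chromA = character(), posA = integer(),
                              strandA = character(), chromB = character(),
                              posB = integer(), strandB = character(),
                              mh_len = integer(), insertion_seq = character(),
                              class = character(),
                              frag_chrom = NA_character_,
                              frag_start = NA_integer_,
                              frag_end = NA_integer_,
                              frag_strand = NA_character_,
                              frag_distance = NA_real_) {
  tibble(chromA = chromA, posA = as.integer(posA), strandA = strandA,
         chromB = chromB, posB = as.integer(posB), strandB = strandB,
         mh_len = as.integer(mh_len), insertion_seq = insertion_seq,
         class = class,
         frag_chrom = if (length(chromA)) frag_chrom else character(),
         frag_start = if (length(chromA)) as.integer(frag_start) else integer(),
         frag_end = if (length(chromA)) as.integer(frag_end) else integer(),
         frag_strand = if (length(chromA)) frag_strand else character(),
         frag_distance = if (length(chromA)) frag_distance else numeric())
}

#' Resolve a batch of junction reads
#'
#' Vectorised wrapper around [resolve_junction()] that never errors on a
#' single read: anchoring failures are reported in a `status` column.
#'
#' @param reads Named character vector of junction reads (names become
#'   `read_id`), or a path to a FASTA file.
#' @inheritParams resolve_junction
#' @return A tibble of junction calls with `read_id` and `status`
#'   (`"ok"`, `"unmappable"`, `"non-unique"` or `"no junction"`).
#' @export
resolve_junctions <- function(reads, reference, min_anchor = 20L,
                              shard_min = 1e4) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    ss <- Biostrings::readDNAStringSet(reads)
    reads <- setNames(as.character(ss), names(ss))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%04d", seq_along(reads))
  }
  purrr::imap_dfr(reads, function(r, id) {
    res <- tryCatch(resolve_junction(r, reference, min_anchor, shard_min),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      status <- if (grepl("non-unique", res)) "non-unique" else "unmappable"
      return(tibble(read_id = id, status = status))
    }
    if (nrow(res) == 0) {
      return(tibble(read_id = id, status = "no junction"))
    }
    mutate(res, read_id = id, status = "ok", .before = 1)
  })
}

#' Per-rearrangement junction counts and complexity
#'
#' A rearrangement resolved into two or more junctions (for example via a
#' genomic shard or a templated insertion of nearby sequence) is labelled
#' complex.
#'
#' @param calls A junction-call tibble with a grouping column naming the
#'   rearrangement each call belongs to.
#' @param group Name of the grouping column (default `"rearrangement"`).
#' @return A tibble with one row per rearrangement: `n_junctions` and
#'   `complexity` (`"simple"` or `"complex"`).
#' @export
count_rearrangement_complexity <- function(calls, group = "rearrangement") {
  assert_that(group %in% names(calls),
              paste0("grouping column `", group, "` not found."))
  calls |>
    group_by(rearrangement = .data[[group]]) |>
    summarise(n_junctions = dplyr::n(), .groups = "drop") |>
    mutate(complexity = ifelse(.data$n_junctions >= 2, "complex", "simple"))
}
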