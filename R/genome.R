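#' Simulate a random genome
#'
#' Generates a synthetic genome of independent random bases with a requested
#' base composition. The result stands in for a real reference genome in all
#' downstream simulations: rearrangement planning, derived-genome rendering,
#' read-pair simulation and junction resolution all operate on it.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths in bp (recycled to
#'   `n_chrom`); each must be at least 10 kb.
#' @param base_frequencies Length-4 numeric vector of A, C, G, T frequencies
#'   summing to 1.
#' @param seed Integer seed; the same seed always yields the same genome.
#'
#' @return An object of class `sv_genome`: a list with elements
#'   `seqs` (a named [Biostrings::DNAStringSet]) and `base_frequencies`
#'   (the empirical A/C/G/T composition of the generated sequence).
#' @examples
#' g <- simulate_genome(2, c(5e4, 5e4), seed = 1)
#' genome_lengths(g)
#' @export
simulate_genome <- function(n_chrom, lengths,
                            base_frequencies = rep(0.25, 4), seed) {
  assert_that(n_chrom >= 1, "`n_chrom` must be >= 1.")
  lengths <- rep_len(as.integer(lengths), n_chrom)
  assert_that(all(lengths >= 1e4), "chromosome lengths must be >= 10 kb.")
  assert_that(all(lengths > 0), "chromosome lengths must be positive.")
  assert_that(length(base_frequencies) == 4 && all(base_frequencies >= 0),
              "`base_frequencies` must be 4 non-negative values.")
  assert_that(abs(sum(base_frequencies) - 1) <= 1e-9,
              "`base_frequencies` must sum to 1.")
  seqs <- with_seed(seed, {
    vapply(lengths, random_dna, character(1), base_freq = base_frequencies)
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  new_sv_genome(Biostrings::DNAStringSet(seqs))
}

new_sv_genome <- function(dss) {
  freq <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  tot <- colSums(freq[, DNA_BASES, drop = FALSE])
  structure(
    list(seqs = dss, base_frequencies = tot / sum(tot)),
    class = "sv_genome"
  )
}

#' @export
print.sv_genome <- function(x, ...) {
  cat("<sv_genome> ", length(x$seqs), " chromosome(s), ",
      format(sum(genome_lengths(x)), big.mark = ","), " bp total\n", sep = "")
  cat("  base frequencies (ACGT):",
      paste(sprintf("%.3f", x$base_frequencies), collapse = " "), "\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome An `sv_genome`.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Base composition of a genome
#' @param genome An `sv_genome`.
#' @return Named numeric vector of A, C, G, T frequencies (sums to 1).
#' @export
base_frequencies <- function(genome) {
  setNames(as.numeric(genome$base_frequencies), DNA_BASES)
}

#' Extract genomic sequence
#'
#' @param genome An `sv_genome`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed coordinates.
#' @param strand `"+"` for the forward sequence, `"-"` for its reverse
#'   complement.
#' @return A character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  assert_that(chrom %in% names(genome$seqs),
              paste0("unknown chromosome: ", chrom))
  len <- length(genome$seqs[[chrom]])
  assert_that(start >= 1 && end <= len && start <= end,
              "coordinates outside chromosome bounds.")
  s <- as.character(Biostrings::subseq(genome$seqs[[chrom]], start, end))
  if (strand == "-") s <- reverse_complement(s)
  s
}

# In-place single/multi-base overwrite of a chromosome (planning-time edits
# made before any sequence is rendered, so reference and derived stay
# consistent).
genome_replace <- function(genome, chrom, start, replacement) {
  seqs <- genome$seqs
  x <- as.character(seqs[[chrom]])
  substr(x, start, start + nchar(replacement) - 1L) <- replacement
  seqs[[chrom]] <- Biostrings::DNAString(x)
  new_sv_genome(seqs)
}

#' Summarise a genome as a tibble
#'
#' @param x An `sv_genome`.
#' @param ... Unused.
#' @return A tibble with one row per chromosome: `chrom`, `length`, `gc`.
#' @export
tidy.sv_genome <- function(x, ...) {
  freq <- Biostrings::alphabetFrequency(x$seqs, baseOnly = TRUE)
  tibble(
    chrom = names(x$seqs),
    length = Biostrings::width(x$seqs),
    gc = (freq[, "C"] + freq[, "G"]) / rowSums(freq[, DNA_BASES, drop = FALSE])
  )
}

#' Write a genome to FASTA
#' @param genome An `sv_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return An `sv_genome`.
#' @export
read_genome_fasta <- function(path) {
  new_sv_genome(Biostrings::readDNAStringSet(path))
}
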