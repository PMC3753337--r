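# BEDPE and TSV readers/writers. External files are 1-based closed in
# reports and 0-based half-open in BEDPE, per the usual conventions;
# conversion happens only here.

#' Write read pairs or SV links as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score strand1
#' strand2 (0-based half-open intervals), followed by any extra columns
#' present (e.g. `pem_type`, `n_pairs`, `span` for link tables).
#'
#' @param x A read-pair tibble (`pos1`/`pos2` + `read_len`) or a link
#'   tibble (`start1`/`end1`/`start2`/`end2`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  if ("pos1" %in% names(x)) {
    out <- tibble(
      chrom1 = x$chrom1, start1 = x$pos1 - 1L, end1 = x$pos1 + x$read_len - 1L,
      chrom2 = x$chrom2, start2 = x$pos2 - 1L, end2 = x$pos2 + x$read_len - 1L,
      name = x$id %||% paste0("pair", seq_len(nrow(x))), score = 1L,
      strand1 = x$strand1, strand2 = x$strand2
    )
  } else {
    out <- tibble(
      chrom1 = x$chrom1, start1 = x$start1 - 1L, end1 = x$end1,
      chrom2 = x$chrom2, start2 = x$start2 - 1L, end2 = x$end2,
      name = x$link_id %||% paste0("link", seq_len(nrow(x))),
      score = x$n_pairs %||% 1L,
      strand1 = x$strand1 %||% ".", strand2 = x$strand2 %||% "."
    )
    extra <- intersect(c("pem_type", "n_pairs", "span"), names(x))
    for (col in extra) out[[col]] <- x[[col]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read read pairs from BEDPE
#'
#' Expects the 10-column dialect written by [write_bedpe()]; returns
#' 1-based leftmost-mapped-base positions.
#'
#' @param path BEDPE file path.
#' @return A read-pair tibble (`id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `read_len`).
#' @export
read_bedpe <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  tibble(
    id = as.character(x[[7]]),
    chrom1 = as.character(x[[1]]), pos1 = x[[2]] + 1L,
    strand1 = as.character(x[[9]]),
    chrom2 = as.character(x[[4]]), pos2 = x[[5]] + 1L,
    strand2 = as.character(x[[10]]),
    read_len = x[[3]] - x[[2]]
  )
}

#' Write a tibble as TSV
#' @param x A data frame; list-columns are dropped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth junctions (TSV + junction-region FASTA)
#'
#' @param truth Truth table from [render_derived_genome()].
#' @param tsv_path,fasta_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_truth_junctions <- function(truth, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- c("junction_id", "chromA", "posA", "strandA",
              "chromB", "posB", "strandB", "class", "mh_len",
              "insertion_seq")
    write_tsv_table(truth[, cols], tsv_path)
  }
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(setNames(truth$region_seq,
                                            truth$junction_id))
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(c(tsv_path, fasta_path))
}
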