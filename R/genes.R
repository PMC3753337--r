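#' Simulate gene models on a genome
#'
#' Places non-overlapping multi-exon gene models on a genome. Coordinates are
#' 1-based closed. `tss` and `tx_end` are strand-resolved: `tss` is the
#' transcription start in genome coordinates, so `tss < tx_end` on the `+`
#' strand and `tss > tx_end` on the `-` strand.
#'
#' @param genome An `sv_genome`.
#' @param n_genes Number of genes to place.
#' @param gene_length Range (min, max) of gene span in bp.
#' @param n_exons Range (min, max) of exon count per gene.
#' @param seed Integer seed.
#' @return A gene-model tibble: `gene_id`, `chrom`, `strand`, `tss`,
#'   `tx_end`, and `exons`, a list-column of tibbles with `start`, `end`
#'   (sorted, non-overlapping, in genome coordinates).
#' @export
simulate_gene_models <- function(genome, n_genes,
                                 gene_length = c(5e3, 4e4),
                                 n_exons = c(2, 8), seed) {
  lens <- genome_lengths(genome)
  with_seed(seed, {
    rows <- vector("list", n_genes)
    # track occupied intervals per chromosome to keep genes disjoint
    occupied <- lapply(lens, function(...) IRanges::IRanges())
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:50) {
        chrom <- sample(names(lens), 1)
        glen <- round(runif(1, gene_length[1], gene_length[2]))
        if (lens[[chrom]] < glen + 2) next
        start <- sample.int(lens[[chrom]] - glen, 1)
        cand <- IRanges::IRanges(start, start + glen - 1L)
        if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) > 0) next
        occupied[[chrom]] <- c(occupied[[chrom]], cand)
        strand <- sample(c("+", "-"), 1)
        k <- sample(seq(n_exons[1], n_exons[2]), 1)
        # split the span into 2k-1 alternating exon/intron blocks
        cuts <- sort(sample(seq_len(glen - 1), 2L * k - 2L))
        bounds <- c(0L, cuts, glen)
        block_start <- start + head(bounds, -1L)
        block_end <- start + tail(bounds, -1L) - 1L
        blocks <- tibble(start = block_start, end = block_end)
        exons <- blocks[seq(1, nrow(blocks), by = 2), ]
        tss <- if (strand == "+") start else start + glen - 1L
        tx_end <- if (strand == "+") start + glen - 1L else start
        rows[[i]] <- tibble(
          gene_id = sprintf("gene%03d", i), chrom = chrom, strand = strand,
          tss = tss, tx_end = tx_end, exons = list(exons)
        )
        placed <- TRUE
        break
      }
      if (!placed) abort("could not place all genes; genome too small.")
    }
    bind_rows(rows)
  })
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tx_end", "exons")
  assert_that(all(need %in% names(genes)),
              paste("gene models need columns:", paste(need, collapse = ", ")))
  ok_dir <- ifelse(genes$strand == "+", genes$tss < genes$tx_end,
                   genes$tss > genes$tx_end)
  assert_that(all(ok_dir), "tss/tx_end must be strand-resolved.")
  invisible(genes)
}

gene_span <- function(genes) {
  genes |>
    mutate(span_start = pmin(.data$tss, .data$tx_end),
           span_end = pmax(.data$tss, .data$tx_end))
}

#' Write gene models as BED12
#'
#' @param genes Gene-model tibble (see [simulate_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed12 <- function(genes, path) {
  g <- gene_span(validate_gene_models(genes))
  lines <- purrr::pmap_chr(g, function(gene_id, chrom, strand, tss, tx_end,
                                        exons, span_start, span_end) {
    ex <- dplyr::arrange(exons, start)
    paste(chrom, span_start - 1L, span_end, gene_id, 0, strand,
          span_start - 1L, span_end, "0",
          nrow(ex),
          paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
          paste0(paste(ex$start - span_start, collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED12
#'
#' @param path BED12 file path.
#' @return A gene-model tibble (see [simulate_gene_models()]).
#' @export
read_genes_bed12 <- function(path) {
  f <- strsplit(readLines(path), "\t")
  rows <- purrr::map(f, function(x) {
    start0 <- as.integer(x[2])
    end <- as.integer(x[3])
    strand <- x[6]
    sizes <- as.integer(strsplit(x[11], ",")[[1]])
    offs <- as.integer(strsplit(x[12], ",")[[1]])
    exons <- tibble(start = start0 + offs + 1L,
                    end = start0 + offs + sizes)
    tibble(
      gene_id = x[4], chrom = x[1], strand = strand,
      tss = if (strand == "+") start0 + 1L else end,
      tx_end = if (strand == "+") end else start0 + 1L,
      exons = list(exons)
    )
  })
  bind_rows(rows)
}
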