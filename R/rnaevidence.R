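# Transcript models are ordered tibbles of genomic segments
# (chrom, start, end, strand) in transcription order; RNA-seq fragments
# are drawn in transcript coordinates and mapped back to the genome.

transcript_segments <- function(gene_models, gene_id) {
  g <- gene_models[gene_models$gene_id == gene_id, ]
  assert_that(nrow(g) == 1, paste0("gene absent from models: ", gene_id))
  ex <- dplyr::arrange(g$exons[[1]], start)
  if (g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  tibble(chrom = g$chrom, start = ex$start, end = ex$end,
         strand = g$strand)
}

#' Build a chimeric (fusion) transcript model
#'
#' Joins the exons of the 5' gene upstream of its breakpoint to the
#' exons of the 3' gene downstream of its breakpoint (both in
#' transcription direction). With `intron_retained = TRUE` the portion
#' of the 3' gene's breakpoint-containing intron between the breakpoint
#' and the next exon is kept in the transcript, emulating fusion
#' transcripts that read into the intron.
#'
#' @param gene_models Gene-model tibble.
#' @param gene5,gene3 Gene ids of the 5' and 3' partners.
#' @param bp5,bp3 Genomic breakpoint positions inside each gene.
#' @param intron_retained Keep the 3' breakpoint intron portion.
#' @return A transcript segment tibble.
#' @export
make_fusion_transcript <- function(gene_models, gene5, bp5, gene3, bp3,
                                   intron_retained = FALSE) {
  s5 <- transcript_segments(gene_models, gene5)
  s3 <- transcript_segments(gene_models, gene3)
  up <- if (s5$strand[1] == "+") s5[s5$end < bp5, ] else s5[s5$start > bp5, ]
  down <- if (s3$strand[1] == "+") s3[s3$start > bp3, ] else
    s3[s3$end < bp3, ]
  assert_that(nrow(up) > 0 && nrow(down) > 0,
              "breakpoints leave no exon on one side of the fusion.")
  mid <- NULL
  if (intron_retained) {
    mid <- if (s3$strand[1] == "+") {
      tibble(chrom = s3$chrom[1], start = bp3,
             end = down$start[1] - 1L, strand = "+")
    } else {
      tibble(chrom = s3$chrom[1], start = down$end[1] + 1L,
             end = bp3, strand = "-")
    }
  }
  bind_rows(up, mid, down)
}

#' Build an exon-deletion transcript model
#'
#' @param gene_models Gene-model tibble.
#' @param gene Gene id.
#' @param del_start,del_end Deleted genomic interval; exons inside it are
#'   dropped from the transcript.
#' @return A transcript segment tibble.
#' @export
make_exon_deletion_transcript <- function(gene_models, gene, del_start,
                                          del_end) {
  s <- transcript_segments(gene_models, gene)
  kept <- s[s$end < del_start | s$start > del_end, ]
  assert_that(nrow(kept) >= 2, "deletion removes too many exons.")
  kept
}

#' Simulate RNA-seq read pairs over normal and abnormal transcripts
#'
#' Draws paired-end fragments along spliced transcripts proportionally
#' to `expression` weights and reports the two read ends in genome
#' coordinates (reads crossing a splice boundary are dropped, as in
#' genome-projected alignments). Strands are reported in the sense of
#' transcription. Normal transcripts are built for every gene in the
#' models; abnormal transcripts (chimeras, exon deletions) are supplied
#' as segment tibbles.
#'
#' @param gene_models Gene-model tibble.
#' @param abnormal Named list of abnormal transcript segment tibbles
#'   (see [make_fusion_transcript()]).
#' @param expression Named weights (>= 0) over gene ids and abnormal
#'   transcript names; anything unnamed gets weight 0.
#' @param n_pairs Number of fragments to draw.
#' @param seed Integer seed.
#' @param read_len,insert_mean,insert_sd Fragment geometry in bp.
#' @return A read-pair tibble with a `source` column naming the
#'   transcript of origin.
#' @export
simulate_rnaseq_pairs <- function(gene_models, abnormal = list(),
                                  expression, n_pairs, seed,
                                  read_len = 50, insert_mean = 250,
                                  insert_sd = 30) {
  assert_that(all(expression >= 0), "expression weights must be >= 0.")
  txs <- c(
    setNames(lapply(gene_models$gene_id, transcript_segments,
                    gene_models = gene_models), gene_models$gene_id),
    abnormal
  )
  unknown <- setdiff(names(expression), names(txs))
  assert_that(length(unknown) == 0,
              paste0("gene absent from models: ",
                     paste(unknown, collapse = ", ")))
  w <- setNames(rep(0, length(txs)), names(txs))
  w[names(expression)] <- expression
  tx_len <- vapply(txs, function(s) sum(s$end - s$start + 1), numeric(1))
  usable <- w > 0 & tx_len >= insert_mean + 4 * insert_sd
  if (!any(usable)) {
    return(tibble(id = character(), chrom1 = character(), pos1 = integer(),
                  strand1 = character(), chrom2 = character(),
                  pos2 = integer(), strand2 = character(),
                  read_len = integer(), source = character()))
  }
  with_seed(seed, {
    pick <- sample(names(txs)[usable], n_pairs, replace = TRUE,
                   prob = (w * tx_len)[usable])
    rows <- purrr::map_dfr(seq_len(n_pairs), function(i) {
      s <- txs[[pick[i]]]
      L <- sum(s$end - s$start + 1)
      ins <- max(2L * read_len + 2L,
                 min(L, round(rnorm(1, insert_mean, insert_sd))))
      a <- sample.int(L - ins + 1L, 1)
      r1 <- tx_to_genome(s, a, read_len)
      r2 <- tx_to_genome(s, a + ins - read_len, read_len)
      if (is.null(r1) || is.null(r2)) return(NULL)
      tibble(chrom1 = r1$chrom, pos1 = r1$pos, strand1 = r1$strand,
             chrom2 = r2$chrom, pos2 = r2$pos, strand2 = r2$strand,
             source = pick[i])
    })
    rows |>
      mutate(id = sprintf("rna%06d", row_number()),
             read_len = as.integer(read_len),
             .before = 1)
  })
}

# map a transcript-coordinate read [a, a+len-1] to the genome; NULL if it
# crosses a segment boundary
tx_to_genome <- function(segs, a, len) {
  widths <- segs$end - segs$start + 1
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  i <- findInterval(a, starts)
  if (a + len - 1 > ends[i]) return(NULL)
  off <- a - starts[i]
  if (segs$strand[i] == "+") {
    list(chrom = segs$chrom[i], pos = as.integer(segs$start[i] + off),
         strand = "+")
  } else {
    list(chrom = segs$chrom[i],
         pos = as.integer(segs$end[i] - off - (len - 1)),
         strand = "-")
  }
}

RNA_ELIGIBLE <- c("Possible chimera", "May change function")

#' Supporting RNA-seq pairs for one predicted SV
#'
#' A pair supports an SV if one end maps within the 5' partner gene on
#' the retained side of its breakpoint (in an exon, or in the intron
#' containing the breakpoint) and the other end maps within the 3'
#' partner downstream of its breakpoint under the same rule, with read
#' strands matching the transcription sense of each partner (anti-sense
#' pairs are not support). Only SVs annotated `Possible chimera` or
#' `May change function` are eligible.
#'
#' @param link One row of an annotated link tibble
#'   (see [annotate_links()]).
#' @param rna_pairs RNA-seq read-pair tibble.
#' @param gene_models Gene-model tibble.
#' @param check_strand Require sense-strand consistency (default TRUE).
#' @return The supporting pairs with per-end context columns
#'   `context1`, `context2` (`"exon"`/`"intron"`).
#' @export
support_pairs <- function(link, rna_pairs, gene_models,
                          check_strand = TRUE) {
  assert_that(link$category %in% RNA_ELIGIBLE,
              "SV not eligible for expression testing.")
  bp1 <- (link$start1 + link$end1) / 2
  bp2 <- (link$start2 + link$end2) / 2
  genes <- strsplit(link$genes_hit, ",")[[1]]
  if (link$category == "May change function") {
    gene_x <- gene_y <- genes[1]
  } else {
    ctx1 <- locate_end(gene_models, link$chrom1, link$start1, link$end1)
    gx <- intersect(genes, ctx1$gene_id)
    gene_x <- gx[1]
    gene_y <- setdiff(genes, gene_x)[1]
  }
  gmx <- gene_models[gene_models$gene_id == gene_x, ]
  gmy <- gene_models[gene_models$gene_id == gene_y, ]
  side1 <- retained_side(link$strand1)
  side2 <- retained_side(link$strand2)
  ok1 <- end_supports(rna_pairs$chrom1, rna_pairs$pos1, rna_pairs$strand1,
                      rna_pairs$read_len, gmx, bp1, side1, check_strand)
  ok2 <- end_supports(rna_pairs$chrom2, rna_pairs$pos2, rna_pairs$strand2,
                      rna_pairs$read_len, gmy, bp2, side2, check_strand)
  # either read order
  ok1b <- end_supports(rna_pairs$chrom2, rna_pairs$pos2, rna_pairs$strand2,
                       rna_pairs$read_len, gmx, bp1, side1, check_strand)
  ok2b <- end_supports(rna_pairs$chrom1, rna_pairs$pos1, rna_pairs$strand1,
                       rna_pairs$read_len, gmy, bp2, side2, check_strand)
  sel <- (ok1$ok & ok2$ok) | (ok1b$ok & ok2b$ok)
  out <- rna_pairs[sel, ]
  swapped <- (ok1b$ok & ok2b$ok)[sel] & !(ok1$ok & ok2$ok)[sel]
  out$context1 <- ifelse(swapped, ok1b$context[sel], ok1$context[sel])
  out$context2 <- ifelse(swapped, ok2b$context[sel], ok2$context[sel])
  out
}

# does a read end support the retained side of a gene around bp?
end_supports <- function(chrom, pos, strand, read_len, gm, bp, side,
                         check_strand) {
  n <- length(pos)
  if (nrow(gm) == 0) {
    return(list(ok = rep(FALSE, n), context = rep(NA_character_, n)))
  }
  lo <- min(gm$tss, gm$tx_end)
  hi <- max(gm$tss, gm$tx_end)
  in_gene <- chrom == gm$chrom & pos >= lo & pos + read_len - 1 <= hi
  on_side <- if (side == "left") pos + read_len - 1 <= bp else pos >= bp
  ex <- gm$exons[[1]]
  mid <- pos + read_len / 2
  in_exon <- purrr::map_lgl(mid, function(x) {
    any(ex$start <= x & ex$end >= x)
  })
  # the breakpoint-containing intron is also allowed
  intr_lo <- max(c(ex$end[ex$end < bp], lo - 1)) + 1
  intr_hi <- min(c(ex$start[ex$start > bp], hi + 1)) - 1
  in_bp_intron <- mid >= intr_lo & mid <= intr_hi & !in_exon
  strand_ok <- if (check_strand) strand == gm$strand else TRUE
  ok <- in_gene & strand_ok & ((in_exon & on_side) | in_bp_intron)
  list(ok = ok, context = ifelse(in_exon, "exon", "intron"))
}

#' Expression evidence for annotated SVs
#'
#' Applies the two-read-pair rule to every eligible SV: an SV is
#' expressed iff at least two RNA-seq read pairs span its junction.
#' Pattern strings follow the 5'/3'/intron grammar, e.g.
#' `"5'geneA->3'geneB (2 pairs)"`.
#'
#' @param annotated Annotated link tibble ([annotate_links()]).
#' @param rna_pairs RNA-seq read-pair tibble.
#' @param gene_models Gene-model tibble.
#' @param min_pairs Support threshold (default 2).
#' @return A tibble: `sv_id`, `genes`, `n_support_pairs`, `expressed`,
#'   `pattern`.
#' @export
transcript_evidence <- function(annotated, rna_pairs, gene_models,
                                min_pairs = 2) {
  eligible <- annotated |> filter(.data$category %in% RNA_ELIGIBLE)
  purrr::map_dfr(seq_len(nrow(eligible)), function(i) {
    l <- eligible[i, ]
    sp <- support_pairs(l, rna_pairs, gene_models)
    genes <- strsplit(l$genes_hit, ",")[[1]]
    pattern <- ""
    if (nrow(sp) > 0) {
      if (l$category == "May change function") {
        lab <- paste0("exon-deletion ", genes[1])
        pattern <- paste0(lab, " (", nrow(sp), " pairs)")
      } else {
        labs <- paste0(
          ifelse(sp$context1 == "exon", "5'", "intron "),
          genes[1], "->",
          ifelse(sp$context2 == "exon", "3'", "intron "),
          genes[min(2, length(genes))]
        )
        tab <- sort(table(labs), decreasing = TRUE)
        pattern <- paste(sprintf("%s (%d pairs)", names(tab), tab),
                         collapse = "; ")
      }
    }
    tibble(sv_id = l$link_id, genes = paste(genes, collapse = "///"),
           n_support_pairs = nrow(sp),
           expressed = nrow(sp) >= min_pairs, pattern = pattern)
  })
}

#' Three-way expression summary over eligible SVs
#'
#' Partitions eligible SVs into: expressed (two or more supporting
#' pairs), silent genes (one of the partner genes has no RNA-seq pairs
#' at all), and unsupported (genes expressed but the junction is not).
#'
#' @param evidence Output of [transcript_evidence()].
#' @param rna_pairs RNA-seq read-pair tibble.
#' @param gene_models Gene-model tibble.
#' @return A list with `per_sv` (class per SV) and `counts`.
#' @export
expression_summary <- function(evidence, rna_pairs, gene_models) {
  gene_counts <- vapply(gene_models$gene_id, function(g) {
    gm <- gene_models[gene_models$gene_id == g, ]
    lo <- min(gm$tss, gm$tx_end)
    hi <- max(gm$tss, gm$tx_end)
    sum((rna_pairs$chrom1 == gm$chrom & rna_pairs$pos1 >= lo &
           rna_pairs$pos1 <= hi) |
          (rna_pairs$chrom2 == gm$chrom & rna_pairs$pos2 >= lo &
             rna_pairs$pos2 <= hi))
  }, numeric(1))
  per_sv <- evidence |>
    mutate(class = purrr::map2_chr(.data$genes, .data$expressed,
                                   function(g, e) {
      if (e) return("expressed")
      gs <- strsplit(g, "///")[[1]]
      if (any(gene_counts[gs] == 0)) "silent genes" else "unsupported"
    }))
  list(per_sv = per_sv,
       counts = per_sv |> count(.data$class, name = "n_svs"))
}
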