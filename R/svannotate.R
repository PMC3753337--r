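#' Locate a breakpoint interval against gene models
#'
#' A link end falls in a gene if its interval overlaps the region between
#' the gene's transcription start site and transcription end; within a
#' gene it is exonic if it touches any exon, intronic otherwise. An end
#' within 2 kb upstream of a TSS (strand-aware) and outside every gene is
#' a promoter hit; anything else is intergenic.
#'
#' @param gene_models Gene-model tibble (see [simulate_gene_models()]).
#' @param chrom Chromosome of the interval.
#' @param start,end 1-based closed interval (a single position if `end`
#'   is omitted).
#' @param promoter_bp Promoter window upstream of the TSS (default 2 kb).
#' @return A tibble with one row per overlapped gene (`gene_id`,
#'   `context` = `"exon"` or `"intron"`), or a single row with
#'   `context = "promoter"` (gene named) or `"intergenic"` (`gene_id`
#'   `NA`).
#' @export
locate_end <- function(gene_models, chrom, start, end = start,
                       promoter_bp = 2000) {
  g <- gene_span(validate_gene_models(gene_models)) |>
    filter(.data$chrom == !!chrom)
  hit <- g |> filter(.data$span_start <= end, .data$span_end >= start)
  if (nrow(hit) > 0) {
    ctx <- purrr::map_chr(seq_len(nrow(hit)), function(i) {
      ex <- hit$exons[[i]]
      if (any(ex$start <= end & ex$end >= start)) "exon" else "intron"
    })
    return(tibble(gene_id = hit$gene_id, context = ctx))
  }
  prom <- g |>
    mutate(p_start = ifelse(.data$strand == "+", .data$tss - promoter_bp,
                            .data$tss + 1L),
           p_end = ifelse(.data$strand == "+", .data$tss - 1L,
                          .data$tss + promoter_bp)) |>
    filter(.data$p_start <= end, .data$p_end >= start)
  if (nrow(prom) > 0) {
    return(tibble(gene_id = prom$gene_id[1], context = "promoter"))
  }
  tibble(gene_id = NA_character_, context = "intergenic")
}

# retained side of a link end: cluster strand '-' means the reads sit
# left of (and the derivative retains) the sequence left of the
# breakpoint; '+' retains the right side
retained_side <- function(strand) ifelse(strand == "-", "left", "right")

# does the retained side at this end keep the gene's 5' (TSS) part?
keeps_five_prime <- function(gene_strand, side) {
  (gene_strand == "+" & side == "left") |
    (gene_strand == "-" & side == "right")
}

# ... or the gene's 3' (transcription end) part?
keeps_three_prime <- function(gene_strand, side) {
  (gene_strand == "+" & side == "right") |
    (gene_strand == "-" & side == "left")
}

#' Annotate SV links with functional-impact categories
#'
#' Assigns each link exactly one of the seven impact categories from the
#' breakpoint contexts and the link geometry:
#'
#' * `Does not change function` — both ends in the same gene with no
#'   exon inside the affected interval (fully intronic event);
#' * `May change function` — both ends in the same gene and at least one
#'   exon removed/inverted between them;
#' * `Possible chimera` — ends in two genes joined so that the 5' part
#'   of one continues into the 3' part of the other in compatible
#'   transcriptional orientation;
#' * `May not change function` — tandem duplication touching genes
#'   (intact original copies remain);
#' * `Truncated` — any other link with at least one genic end;
#' * `Promoter` — no genic end, at least one promoter end;
#' * `Intergenic` — everything else.
#'
#' The damaging rollup covers `Truncated`, `Possible chimera` and
#' `May change function`.
#'
#' @param links `sv_links` tibble.
#' @param gene_models Gene-model tibble.
#' @return `links` with `end1_context`, `end2_context`, `genes_hit`
#'   (comma-separated), `category` and `damaging` columns.
#' @export
annotate_links <- function(links, gene_models) {
  validate_gene_models(gene_models)
  rows <- purrr::map_dfr(seq_len(nrow(links)), function(i) {
    l <- links[i, ]
    c1 <- locate_end(gene_models, l$chrom1, l$start1, l$end1)
    c2 <- locate_end(gene_models, l$chrom2, l$start2, l$end2)
    categorize_link(l, c1, c2, gene_models)
  })
  out <- bind_cols(links, rows)
  class(out) <- class(links)
  out
}

categorize_link <- function(l, c1, c2, gene_models) {
  g1 <- c1$gene_id[c1$context %in% c("exon", "intron")]
  g2 <- c2$gene_id[c2$context %in% c("exon", "intron")]
  genes_hit <- unique(c(g1, g2))
  side1 <- retained_side(l$strand1)
  side2 <- retained_side(l$strand2)
  category <- NULL
  common <- intersect(g1, g2)
  if (!l$inter && length(common) > 0 &&
      !l$pem_type %in% c("LARGE_DUPLICATION")) {
    # event contained in one gene: exon content of the affected interval
    lo <- (l$start1 + l$end1) / 2
    hi <- (l$start2 + l$end2) / 2
    gm <- gene_models |> filter(.data$gene_id %in% common)
    exon_hit <- any(purrr::map_lgl(gm$exons, function(ex) {
      any(ex$start <= hi & ex$end >= lo)
    }))
    category <- if (exon_hit) "May change function" else
      "Does not change function"
  } else if (length(g1) > 0 && length(g2) > 0 &&
             length(setdiff(g1, g2)) > 0 && length(setdiff(g2, g1)) > 0) {
    s1 <- gene_models$strand[match(g1, gene_models$gene_id)]
    s2 <- gene_models$strand[match(g2, gene_models$gene_id)]
    fusion_12 <- any(keeps_five_prime(s1, side1)) &&
      any(keeps_three_prime(s2, side2))
    fusion_21 <- any(keeps_five_prime(s2, side2)) &&
      any(keeps_three_prime(s1, side1))
    category <- if (fusion_12 || fusion_21) "Possible chimera" else
      "Truncated"
  }
  if (is.null(category)) {
    if (l$pem_type == "LARGE_DUPLICATION" && length(genes_hit) > 0) {
      category <- "May not change function"
    } else if (length(genes_hit) > 0) {
      category <- "Truncated"
    } else if ("promoter" %in% c(c1$context, c2$context)) {
      category <- "Promoter"
    } else {
      category <- "Intergenic"
    }
  }
  tibble(
    end1_context = context_label(c1),
    end2_context = context_label(c2),
    genes_hit = paste(genes_hit, collapse = ","),
    category = category,
    damaging = category %in% c("Truncated", "Possible chimera",
                               "May change function")
  )
}

context_label <- function(ctx) {
  if (all(ctx$context == "intergenic")) return("intergenic")
  paste(ifelse(is.na(ctx$gene_id), ctx$context,
               paste0(ctx$context, "(", ctx$gene_id, ")")),
        collapse = ";")
}

#' Impact-category counts for a link set
#'
#' @param annotated Output of [annotate_links()].
#' @return A tibble of category counts split by inter-chromosomal vs
#'   large/short intra-chromosomal links; categories always partition
#'   the link set.
#' @export
impact_summary <- function(annotated) {
  annotated |>
    as_tibble() |>
    count(.data$size_class, .data$category, name = "n_links") |>
    arrange(.data$size_class, dplyr::desc(.data$n_links))
}
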