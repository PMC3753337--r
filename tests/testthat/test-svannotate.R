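test_that("breakpoint location follows the TSS/promoter rules exactly", {
  genes <- toy_genes()
  # 1.5 kb upstream of the TSS, outside every gene: promoter
  expect_equal(locate_end(genes, "chr1", 8500)$context, "promoter")
  # 2001 bp upstream: intergenic (boundary)
  expect_equal(locate_end(genes, "chr1", 7999)$context, "intergenic")
  expect_equal(locate_end(genes, "chr1", 8000)$context, "promoter")
  # inside intron 1
  loc <- locate_end(genes, "chr1", 12000)
  expect_equal(loc$context, "intron")
  expect_equal(loc$gene_id, "GX")
  # touching an exon
  expect_equal(locate_end(genes, "chr1", 15200)$context, "exon")
  expect_error(locate_end(dplyr::mutate(toy_genes(), tss = tx_end),
                          "chr1", 1), "strand-resolved")
})

test_that("link categories follow the decision table", {
  genes <- toy_genes()
  chim <- toy_chimera_link()
  expect_equal(chim$category, "Possible chimera")
  expect_true(chim$damaging)
  # incompatible orientation: truncation
  trunc <- annotate_links(
    dplyr::mutate(tibble::as_tibble(toy_chimera_link()[, 1:16]),
                  strand2 = "-"), genes)
  expect_equal(trunc$category, "Truncated")
  # one genic end, one intergenic end
  l <- tibble::as_tibble(toy_chimera_link()[, 1:16]) |>
    dplyr::mutate(chrom2 = "chr1", start2 = 100000, end2 = 100400,
                  inter = FALSE, span = 83000, pem_type = "DELETION",
                  signature = "outward_stretched")
  expect_equal(annotate_links(l, genes)$category, "Truncated")
  # fully intronic deletion within one gene
  intra <- l |>
    dplyr::mutate(start1 = 11000, end1 = 11400, start2 = 13000,
                  end2 = 13400, span = 2000)
  expect_equal(annotate_links(intra, genes)$category,
               "Does not change function")
  # deletion removing an exon of the same gene
  exdel <- l |>
    dplyr::mutate(start1 = 12000, end1 = 12400, start2 = 20000,
                  end2 = 20400, span = 8000)
  expect_equal(annotate_links(exdel, genes)$category,
               "May change function")
  # tandem duplication over a gene
  dup <- l |>
    dplyr::mutate(start1 = 12000, end1 = 12400, start2 = 20000,
                  end2 = 20400, strand1 = "+", strand2 = "-",
                  pem_type = "LARGE_DUPLICATION", signature = "inward")
  expect_equal(annotate_links(dup, genes)$category,
               "May not change function")
  # both ends intergenic
  ig <- l |>
    dplyr::mutate(start1 = 60000, end1 = 60400, start2 = 100000,
                  end2 = 100400)
  expect_equal(annotate_links(ig, genes)$category, "Intergenic")
})

test_that("categories partition any simulated link set", {
  g <- small_genome(21, c(4e5, 3e5))
  genes <- simulate_gene_models(g, 20, seed = 8)
  plans <- plan_rearrangements(g, "simple", n_events = 3, seed = 55,
                               size_range = c(5e4, 1e5))
  d <- render_derived_genome(g, plans)
  pairs <- simulate_mate_pairs(d, pairs_for_coverage(10, 7e5), seed = 57)
  links <- cluster_links(pairs, fit_insert_model(pairs))
  ann <- annotate_links(links, genes)
  cats <- c("Intergenic", "Promoter", "Truncated", "Possible chimera",
            "May change function", "May not change function",
            "Does not change function")
  expect_true(all(ann$category %in% cats))
  expect_equal(sum(table(ann$category)), nrow(links))
  expect_equal(sum(impact_summary(ann)$n_links), nrow(links))
  # damaging rollup is exactly the three damaging categories
  expect_equal(ann$damaging,
               ann$category %in% c("Truncated", "Possible chimera",
                                   "May change function"))
})

test_that("shrinking a breakpoint interval never turns intergenic into genic", {
  genes <- toy_genes()
  wide <- locate_end(genes, "chr1", 5000, 9000)
  narrow <- locate_end(genes, "chr1", 6000, 6400)
  if (all(wide$context == "intergenic")) {
    expect_true(all(narrow$context == "intergenic"))
  }
  # and a narrow interval inside a wide genic one stays genic or less
  wide2 <- locate_end(genes, "chr1", 9000, 16000)
  expect_true(any(wide2$context %in% c("exon", "intron")))
})
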