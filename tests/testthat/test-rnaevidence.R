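test_that("the expressed call flips exactly at two supporting pairs", {
  genes <- toy_genes()
  link <- toy_chimera_link()
  fus <- make_fusion_transcript(genes, "GX", 17200, "GY", 33200)
  rna <- simulate_rnaseq_pairs(genes, abnormal = list(fus = fus),
                               expression = c(GX = 1, GY = 1, fus = 4),
                               n_pairs = 3000, seed = 5)
  sp <- support_pairs(link, rna, genes)
  expect_gt(nrow(sp), 2)
  # exactly 2 supporting pairs: expressed; remove one: not expressed
  two <- dplyr::bind_rows(rna[!rna$id %in% sp$id, ], sp[1:2, ])
  ev2 <- transcript_evidence(link, two, genes)
  expect_true(ev2$expressed)
  expect_equal(ev2$n_support_pairs, 2L)
  one <- dplyr::bind_rows(rna[!rna$id %in% sp$id, ], sp[1, ])
  ev1 <- transcript_evidence(link, one, genes)
  expect_false(ev1$expressed)
  expect_equal(ev1$n_support_pairs, 1L)
})

test_that("silent fusions produce no support and land in the silent-gene class", {
  genes <- toy_genes()
  link <- toy_chimera_link()
  fus <- make_fusion_transcript(genes, "GX", 17200, "GY", 33200)
  # the chimera and its partner genes have weight zero
  rna <- simulate_rnaseq_pairs(genes, abnormal = list(fus = fus),
                               expression = c(GX = 0, GY = 0, fus = 0),
                               n_pairs = 500, seed = 7)
  ev <- transcript_evidence(link, rna, genes)
  expect_equal(ev$n_support_pairs, 0L)
  expect_false(ev$expressed)
  summ <- expression_summary(ev, rna, genes)
  expect_equal(summ$per_sv$class, "silent genes")
})

test_that("expressed genes without junction support are 'unsupported'", {
  genes <- toy_genes()
  link <- toy_chimera_link()
  rna <- simulate_rnaseq_pairs(genes, expression = c(GX = 2, GY = 2),
                               n_pairs = 2000, seed = 9)
  ev <- transcript_evidence(link, rna, genes)
  expect_false(ev$expressed)
  summ <- expression_summary(ev, rna, genes)
  expect_equal(summ$per_sv$class, "unsupported")
})

test_that("intron-retained fusions are reported with the intron pattern grammar", {
  genes <- toy_genes()
  link <- toy_chimera_link()
  fus_i <- make_fusion_transcript(genes, "GX", 17200, "GY", 33200,
                                  intron_retained = TRUE)
  rna <- simulate_rnaseq_pairs(genes, abnormal = list(fus_i = fus_i),
                               expression = c(fus_i = 5),
                               n_pairs = 1500, seed = 11)
  ev <- transcript_evidence(link, rna, genes)
  expect_true(ev$expressed)
  expect_match(ev$pattern, "intron GY")
  expect_match(ev$pattern, "5'GX")
})

test_that("eligibility and antisense rules are enforced", {
  genes <- toy_genes()
  link <- toy_chimera_link()
  ineligible <- dplyr::mutate(link, category = "Truncated")
  expect_error(support_pairs(ineligible, tibble::tibble(), genes),
               "not eligible")
  fus <- make_fusion_transcript(genes, "GX", 17200, "GY", 33200)
  rna <- simulate_rnaseq_pairs(genes, abnormal = list(fus = fus),
                               expression = c(fus = 5), n_pairs = 800,
                               seed = 13)
  # flip both read strands: anti-sense pairs are not support
  anti <- dplyr::mutate(rna,
                        strand1 = ifelse(strand1 == "+", "-", "+"),
                        strand2 = ifelse(strand2 == "+", "-", "+"))
  expect_equal(nrow(support_pairs(link, anti, genes)), 0)
  expect_gt(nrow(support_pairs(link, rna, genes)), 0)
})

test_that("exon-deletion transcripts link the flanking exons", {
  genes <- toy_genes()
  # delete exon 2 of GX (15000-15500)
  tx <- make_exon_deletion_transcript(genes, "GX", 14000, 16000)
  expect_equal(nrow(tx), 2)
  rna <- simulate_rnaseq_pairs(genes, abnormal = list(del = tx),
                               expression = c(del = 5), n_pairs = 1500,
                               seed = 17, insert_mean = 400,
                               insert_sd = 40)
  # pairs spanning the removed exon: end1 in exon 1, end2 in exon 3
  spanning <- rna$pos1 <= 10500 & rna$pos2 >= 25000
  expect_gt(sum(spanning), 0)
  expect_error(make_exon_deletion_transcript(genes, "GX", 9000, 31000),
               "too many")
  expect_error(simulate_rnaseq_pairs(genes, expression = c(nope = 1),
                                     n_pairs = 10, seed = 1),
               "absent")
})
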