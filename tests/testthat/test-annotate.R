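test_that("feature_set merges overlapping intervals, sorted half-open", {
  fs <- feature_set("exon", tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    start = c(100, 150, 0, 500),
    end = c(200, 300, 50, 600)))
  expect_s3_class(fs, "feature_set")
  expect_equal(fs$intervals$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(fs$intervals$start, c(100, 500, 0))
  expect_equal(fs$intervals$end, c(300, 600, 50))
  expect_error(feature_set("bad", tibble::tibble(
    chrom = "chr1", start = 10, end = 10)))
})

test_that("feature_coverage is the percent of regions overlapping >= 1 bp", {
  feats <- feature_set("f", tibble::tibble(chrom = "chr1",
                                           start = 1000, end = 2000))
  regions <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr2"),
                            start = c(0, 1999, 2000, 1500),
                            end = c(500, 2100, 2500, 1600))
  # half-open: [2000, 2500) does not touch [1000, 2000)
  expect_equal(feature_coverage(regions, feats), 25)
  expect_equal(feature_coverage(regions[2, ], feats), 100)
  expect_error(feature_coverage(regions[0, ], feats), "empty")
})

test_that("chromosome_occupancy normalizes by chromosome share and sums to 1", {
  layout <- genome_layout(c(chr1 = 3e6, chr2 = 1e6), 5000, 200)
  # placement proportional to length -> equal normalized occupancy
  regions <- tibble::tibble(chrom = c(rep("chr1", 6), rep("chr2", 2)))
  occ <- chromosome_occupancy(regions, layout)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["chr1"]), unname(occ["chr2"]))
  # all regions on the short chromosome -> it dominates
  occ2 <- chromosome_occupancy(tibble::tibble(chrom = rep("chr2", 5)),
                               layout)
  expect_equal(unname(occ2["chr2"]), 1)
})

test_that("regulatory_domains implement basal-plus-extension", {
  genes <- tibble::tibble(gene = c("a", "b"), chrom = "chr1",
                          tss = c(10000, 50000), strand = c("+", "-"))
  dom <- regulatory_domains(genes, basal_up = 5000, basal_down = 1000,
                            max_ext = 20000)
  a <- dom[dom$gene == "a", ]; b <- dom[dom$gene == "b", ]
  # basal: a (+): [5000, 11000]; b (-): [49000, 55000]
  expect_equal(c(a$basal_start, a$basal_end), c(5000, 11000))
  expect_equal(c(b$basal_start, b$basal_end), c(49000, 55000))
  # extension: a extends right to min(tss+max_ext, b's basal start)
  expect_equal(a$end, 30000)
  # b extends left to max(tss-max_ext, a's basal end)
  expect_equal(b$start, 30000)
  # a extends left to max(tss-max_ext, 0) with no left neighbor... capped
  expect_equal(a$start, 0)
  expect_equal(b$end, 70000)
})

test_that("assign_to_genes assigns regions overlapping domains by >= 1 bp", {
  genes <- tibble::tibble(gene = c("a", "b"), chrom = "chr1",
                          tss = c(10000, 50000), strand = c("+", "-"))
  regions <- tibble::tibble(chrom = c("chr1", "chr1", "chr1"),
                            start = c(8000, 29000, 200000),
                            end = c(9000, 31000, 201000))
  asg <- assign_to_genes(regions, genes, max_ext = 20000)
  # region 1 in a's basal; region 2 straddles the a/b boundary -> both
  expect_equal(sort(asg$gene[asg$start == 8000]), "a")
  expect_equal(sort(asg$gene[asg$start == 29000]), c("a", "b"))
  expect_false(200000 %in% asg$start)  # beyond max extension
  expect_error(assign_to_genes(regions, dplyr::mutate(genes, strand = ".")),
               "strand")
})

test_that("average_fold_change aggregates per gene", {
  asg <- tibble::tibble(gene = c("a", "a", "b", "b"),
                        log2_fold_change = c(1, 3, -2, NA))
  out <- average_fold_change(asg)
  expect_equal(out$mean_log2_fold_change[out$gene == "a"], 2)
  expect_equal(out$n_dmers[out$gene == "a"], 2L)
  expect_equal(out$n_dmers[out$gene == "b"], 1L)
})
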