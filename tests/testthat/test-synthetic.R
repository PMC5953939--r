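test_that("archetype templates are in range and flip/shift identifiable", {
  lib <- archetype_library(25)
  expect_length(lib, 6L)
  for (a in lib) {
    expect_s3_class(a, "archetype")
    expect_equal(rownames(a$profile), mark_levels())
    expect_true(all(a$profile >= 0 & a$profile <= 1))
  }
  # identifiability: no template may match its own mirror (any shift)
  # or a one-bin translate of itself better than the planting noise
  # floor 2*noise_sd^2 allows distinguishing
  noise_floor <- 2 * 0.05^2
  for (a in lib) {
    sc <- episigr:::cpp_align_scores(a$profile, a$profile, 10)
    flip_best <- max(sc[2, ])
    shift_gap <- sc[1, 11] - max(sc[1, -11])
    expect_lt(flip_best, -noise_floor / 3)
    expect_gt(shift_gap, noise_floor / 3)
  }
})

test_that("make_landscape plants archetypes with recorded shifts and flips", {
  ls <- small_landscape()
  expect_equal(nrow(ls$truth), 60L)
  expect_true(all(abs(ls$truth$shift) <= 5))
  expect_true(all(ls$truth$archetype %in% 1:3))
  # planted windows are spaced: never adjacent
  t2 <- dplyr::arrange(ls$truth, chrom, start)
  gap <- tapply(t2$start, t2$chrom, function(s) min(diff(s)))
  expect_true(all(gap >= 2 * ls$layout$window_bp))
  # track set: 9 marks x 6 samples + input per sample
  expect_equal(length(ls$tracks), (length(mark_levels()) + 1) * 6)
  # a planted window's signal beats background in the archetype's mark
  r <- which(ls$truth$archetype == 1)[1]
  idx <- episigr:::window_bin_indices(ls$layout, ls$truth$chrom[r],
                                      ls$truth$start[r])
  tr <- ls$tracks[["case_01:H3K4me3"]]
  expect_gt(max(tr$values[idx]), 2 * median(tr$values))
})

test_that("make_landscape is reproducible and seed-sensitive", {
  a <- make_landscape(chrom_sizes = c(chr1 = 1e6), n_archetypes = 2,
                      regions_per_archetype = 5, samples_per_group = 2,
                      rng_seed = 42)
  b <- make_landscape(chrom_sizes = c(chr1 = 1e6), n_archetypes = 2,
                      regions_per_archetype = 5, samples_per_group = 2,
                      rng_seed = 42)
  c <- make_landscape(chrom_sizes = c(chr1 = 1e6), n_archetypes = 2,
                      regions_per_archetype = 5, samples_per_group = 2,
                      rng_seed = 43)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tracks[[1]]$values, b$tracks[[1]]$values)
  expect_false(identical(a$truth$start, c$truth$start) &&
                 identical(a$tracks[[1]]$values, c$tracks[[1]]$values))
})

test_that("written landscape round-trips through the track-io readers", {
  ls <- fixture("disk_landscape", function()
    make_landscape(chrom_sizes = c(chr1 = 8e5), n_archetypes = 2,
                   regions_per_archetype = 4, samples_per_group = 2,
                   rng_seed = 3, out_dir = file.path(tempdir(), "lsdisk")))
  layout <- genome_layout(ls$files$chrom_sizes)
  expect_equal(layout$chrom_sizes, ls$layout$chrom_sizes)
  tr <- read_bedgraph(ls$files$tracks[["case_01:H3K27ac"]], layout,
                      track_key("case_01", "H3K27ac", "case"))
  expect_equal(tr$values, ls$tracks[["case_01:H3K27ac"]]$values)
  truth <- tibble::as_tibble(data.table::fread(ls$files$truth))
  expect_equal(truth$start, ls$truth$start)
})

test_that("make_counts plants the promised fold changes", {
  cnt <- make_counts(n_genes = 300, samples_per_group = 6, frac_de = 0.2,
                     fc = 4, rng_seed = 1)
  expect_equal(dim(cnt$counts), c(300L, 12L))
  expect_true(all(cnt$counts >= 0))
  expect_equal(sum(cnt$truth$is_de), 60L)
  # empirical fold change of planted over-expressed genes is near 4
  over <- cnt$truth$gene[cnt$truth$is_de & cnt$truth$direction == "over"]
  fc <- rowMeans(cnt$counts[over, cnt$groups == "case"]) /
    pmax(1, rowMeans(cnt$counts[over, cnt$groups == "control"]))
  expect_gt(median(fc), 2.5)
  expect_identical(cnt$counts,
                   make_counts(n_genes = 300, samples_per_group = 6,
                               frac_de = 0.2, fc = 4, rng_seed = 1)$counts)
})

test_that("alignment_recovery scores frame-consistent fits as perfect", {
  ls <- small_landscape()
  tens <- small_prep()$tensor
  # construct a synthetic "fit" that reproduces the planted alignment
  # exactly (offset = shift, flip = flip, one cluster per archetype):
  # in-frame members must all score as recovered
  key <- paste(tens$regions$chrom, tens$regions$start)
  tkey <- paste(ls$truth$chrom, ls$truth$start)
  idx <- match(tkey, key)
  clusters <- lapply(1:3, function(a) {
    sel <- ls$truth$archetype == a
    episigr:::new_epi_cluster(a, tibble::tibble(
      region_index = idx[sel],
      # aligning to the unshifted template: a flipped member's
      # self-consistent found offset is -shift, an unflipped one's +shift
      offset = ifelse(ls$truth$flip[sel], -ls$truth$shift[sel],
                      ls$truth$shift[sel]),
      flip = ls$truth$flip[sel]), matrix(0, 1, 1), -1)
  })
  fake <- structure(list(clusters = clusters, unassigned = integer(),
                         config = episig_config(), regions = tens$regions,
                         layout = tens$layout,
                         n_regions = nrow(tens$regions)),
                    class = "episig_fit")
  rec <- alignment_recovery(fake, ls$truth)
  expect_equal(rec$fraction_recovered, 1)
  # a shared frame transform (global flip + constant registration shift)
  # still counts as perfect: clusters define their own frame
  clusters2 <- lapply(clusters, function(cl) {
    cl$members$offset <- cl$members$offset + 2L
    cl
  })
  fake2 <- fake; fake2$clusters <- clusters2
  expect_equal(alignment_recovery(fake2, ls$truth)$fraction_recovered, 1)
  # breaking one member's registration costs exactly one region
  clusters3 <- clusters
  clusters3[[1]]$members$offset[1] <- clusters3[[1]]$members$offset[1] + 3L
  fake3 <- fake; fake3$clusters <- clusters3
  expect_equal(alignment_recovery(fake3, ls$truth)$fraction_recovered,
               59 / 60)
})
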