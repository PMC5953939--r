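test_that("read_bedgraph computes length-weighted bin means and masks gaps", {
  layout <- tiny_layout()
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("track type=bedGraph",
               "# comment",
               "chrA\t0\t100\t2",      # half of bin 1 at 2
               "chrA\t100\t300\t4",    # other half of bin 1 + bin 2 at 4
               "chrB\t0\t200\t7"),     # chrB bin 1
             f)
  tr <- read_bedgraph(f, layout, track_key("s1", "H3K27ac", "case"))
  expect_s3_class(tr, "binned_track")
  # bin 1: (100*2 + 100*4)/200 = 3; bin 2: 4
  expect_equal(tr$values[1], 3)
  expect_equal(tr$values[2], 4)
  expect_equal(tr$values[101], 7)  # chrB offset = 100
  expect_true(tr$mask[3])          # uncovered bin masked
  expect_equal(sum(!tr$mask), 3L)
})

test_that("read_bedgraph validates records and warns on unknown chromosomes", {
  layout <- tiny_layout()
  key <- track_key("s1", "H3K27ac", "case")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrA\t100\t100\t1", f)
  expect_error(read_bedgraph(f, layout, key), "end <= start")
  writeLines("chrA\t0\tx\t1", f)
  expect_error(read_bedgraph(f, layout, key), "malformed")
  writeLines("chrA\t0\t100", f)
  expect_error(read_bedgraph(f, layout, key), "fields")
  writeLines(c("chrZ\t0\t100\t1", "chrA\t0\t200\t5"), f)
  expect_warning(tr <- read_bedgraph(f, layout, key), "chrZ")
  expect_equal(tr$values[1], 5)
})

test_that("subtract_input depth-scales, floors at zero and unions masks", {
  layout <- tiny_layout()
  k <- track_key("s1", "H3K27ac", "case")
  nb <- layout$total_bins
  tv <- rep(2, nb); iv <- rep(2, nb)
  tv[1] <- 10; iv[2] <- 6; tv[3] <- NA; iv[4] <- NA
  tr <- subtract_input(binned_track(k, tv, layout),
                       binned_track(k, iv, layout))
  f <- sum(tv, na.rm = TRUE) / sum(iv, na.rm = TRUE)  # depth ratio
  expect_equal(tr$values[1], 10 - f * 2)
  expect_equal(tr$values[2], 0)                        # floored
  expect_true(tr$mask[3] && tr$mask[4])                # union of masks
  expect_true(all(tr$values[!tr$mask] >= 0))
})

test_that("read_methylation averages betas per bin and validates range", {
  layout <- tiny_layout()
  key <- track_key("s1", "METH", "case")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t10\t11\t0.2", "chrA\t150\t151\t0.8",
               "chrA\t250\t251\t0.5"), f)
  tr <- read_methylation(f, layout, key)
  expect_equal(tr$values[1], 0.5)   # mean(0.2, 0.8), both in bin 1
  expect_equal(tr$values[2], 0.5)
  expect_true(tr$mask[3])
  writeLines("chrA\t10\t11\t1.2", f)
  expect_error(read_methylation(f, layout, key), "beta")
})

test_that("cluster BED round-trips losslessly through write/read", {
  ls <- small_landscape()
  fit <- small_fit()
  expect_gt(length(fit$clusters), 0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_cluster_bed(fit, fit$regions, fit$layout, f)
  back <- read_cluster_bed(f)
  want <- tidy(fit)
  want <- want[!is.na(want$cluster), ]
  want <- want[order(want$cluster, want$region_index), ]
  got <- dplyr::arrange(back, cluster, chrom, start)
  want <- dplyr::arrange(
    dplyr::mutate(want, end = start + fit$layout$window_bp),
    cluster, chrom, start)
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, as.integer(want$start))
  expect_equal(got$end, as.integer(want$end))
  expect_equal(got$cluster, as.integer(want$cluster))
  expect_equal(got$offset, as.integer(want$offset))
  expect_equal(got$flip, want$flip)
})

test_that("sample sheet loading reads, input-subtracts and names tracks", {
  dir <- withr::local_tempdir()
  ls <- fixture("disk_landscape", function()
    make_landscape(chrom_sizes = c(chr1 = 8e5), n_archetypes = 2,
                   regions_per_archetype = 4, samples_per_group = 2,
                   rng_seed = 3, out_dir = file.path(tempdir(), "lsdisk")))
  sheet <- read_sample_sheet(ls$files$sample_sheet)
  expect_true(all(c("sample_id", "group", "mark", "path", "input_path")
                  %in% names(sheet)))
  layout <- genome_layout(ls$files$chrom_sizes)
  one <- sheet[sheet$sample_id == "case_01", ]
  tracks <- load_tracks(one, layout)
  expect_named(tracks, paste("case_01", one$mark, sep = ":"))
  # histone marks are input-subtracted: must differ from the raw file
  raw <- read_bedgraph(one$path[one$mark == "H3K27ac"], layout,
                       track_key("case_01", "H3K27ac", "case"))
  expect_false(isTRUE(all.equal(tracks[["case_01:H3K27ac"]]$values,
                                raw$values)))
  # METH round-trips the generated betas exactly (written as %.17g)
  expect_equal(tracks[["case_01:METH"]]$values,
               ls$tracks[["case_01:METH"]]$values)
})
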