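test_that("bh_adjust matches the brute-force step-up oracle", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # hand-checkable: p = (0.01, 0.04, 0.03, 0.005), m = 4
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_adjust(p), c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0,1\\]")
})

test_that("hypergeometric enrichment matches the exact enumeration oracle", {
  for (i in 1:30) {
    set.seed(i)
    N <- sample(10:60, 1); K <- sample(0:N, 1)
    n <- sample(1:N, 1); k <- sample(0:min(n, K), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 oracle_hyper_upper(k, K, N, n))
  }
})

test_that("worked example: N=10, K=5, n=4, k=4 gives p = 5/210", {
  expect_equal(phyper(4 - 1, 5, 5, 4, lower.tail = FALSE), 5 / 210)
  expect_equal(oracle_hyper_upper(4, 5, 10, 4), 5 / 210)
  # the same number via the enrichment pipeline on a toy fit
  mk_cluster <- function(id, idx) episigr:::new_epi_cluster(
    id, tibble::tibble(region_index = idx, offset = 0L, flip = FALSE),
    matrix(0, 1, 1), -1)
  clusters <- list(mk_cluster(1L, 1:4), mk_cluster(2L, 5:10))
  dmers <- tibble::tibble(region_index = 1:10, mark = "H3K27ac",
                          q = c(rep(0.001, 5), rep(0.9, 5)),
                          is_dmer = c(rep(TRUE, 5), rep(FALSE, 5)))
  res <- hypergeom_enrichment(clusters, dmers, dmer_q_strict = 0.01)
  r1 <- res[res$cluster == 1, ]
  expect_equal(r1$n_regions_in_cluster, 4L)
  expect_equal(r1$n_dmers_in_cluster, 4L)
  expect_equal(r1$p, 5 / 210)
})

test_that("call_dmers detects planted two-fold effects and respects thresholds", {
  ls <- fixture("dmer_landscape", function()
    make_landscape(chrom_sizes = c(chr1 = 2.5e6), n_archetypes = 1,
                   regions_per_archetype = 30, samples_per_group = 6,
                   frac_differential = 0.4, rng_seed = 7))
  prep <- fixture("dmer_prep", function()
    prepare_tensor(ls$tracks, ls$layout))
  dm <- call_dmers(prep$tensor)
  expect_true(all(c("region_index", "mark", "log2_fold_change",
                    "p", "q", "is_dmer") %in% names(dm)))
  expect_true(all(dm$q >= dm$p))
  # planted differential regions are preferentially called: the calls
  # must be enriched in the differential set (exact power is the
  # acceptance criterion's business at 11v11 scale)
  key <- paste(prep$tensor$regions$chrom, prep$tensor$regions$start)
  tkey <- paste(ls$truth$chrom, ls$truth$start)
  diff_idx <- which(key %in% tkey[ls$truth$is_differential])
  eff <- dm[dm$mark != "METH", ]
  called <- unique(eff$region_index[eff$is_dmer])
  expect_gt(length(intersect(called, diff_idx)), 0)
  prec <- length(intersect(called, diff_idx)) / length(called)
  base <- length(diff_idx) / nrow(prep$tensor$regions)
  expect_gt(prec, 5 * base)
  # non-METH calls use q < q_max
  expect_true(all(dm$q[dm$is_dmer & dm$mark != "METH"] < 0.05))
  # METH calls require both the delta and the strict q
  meth <- dm[dm$mark == "METH" & dm$is_dmer, ]
  if (nrow(meth) > 0)
    expect_true(all(abs(meth$delta_beta) > 0.05 & meth$q < 0.0015))
})

test_that("call_degs recovers planted differential genes", {
  cnt <- make_counts(n_genes = 400, samples_per_group = 8, frac_de = 0.1,
                     fc = 4, rng_seed = 2)
  degs <- call_degs(cnt$counts, cnt$groups)
  j <- dplyr::inner_join(degs, cnt$truth, by = "gene")
  sens <- mean(j$is_deg[j$is_de])
  fdp <- if (sum(j$is_deg) > 0) mean(!j$is_de[j$is_deg]) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.1)
  # direction matches the planted sign
  d <- j[j$is_deg & j$is_de, ]
  expect_true(all(d$direction.x == d$direction.y))
})

test_that("select_clusters applies both the q and the gene-count filter", {
  res <- tibble::tibble(cluster = 1:3, q = c(0.01, 0.2, 0.01))
  genes <- tibble::tibble(cluster = 1:3, n_genes = c(500, 500, 10))
  expect_equal(select_clusters(res, genes), 1L)
  expect_equal(select_clusters(res, genes, q_max = 0.5, min_genes = 5), 1:3)
})

test_that("dmer_composition percentages sum to 100 over marks", {
  cl <- episigr:::new_epi_cluster(
    1L, tibble::tibble(region_index = 1:4, offset = 0L, flip = FALSE),
    matrix(0, 1, 1), -1)
  dmers <- tibble::tibble(region_index = c(1, 2, 3, 3, 9),
                          mark = c("ATAC", "ATAC", "METH", "ATAC", "ATAC"),
                          is_dmer = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  comp <- dmer_composition(cl, dmers)
  expect_equal(sum(comp), 100)
  expect_equal(unname(comp["ATAC"]), 100 * 2 / 3)
})
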