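test_that("intra_entropy matches hand-computed values", {
  # uniform over T*B cells -> log2(T*B) bits
  u <- matrix(1, 4, 8)
  expect_equal(intra_entropy(u), log2(32))
  # one hot cell -> 0 bits
  z <- matrix(0, 2, 5); z[1, 3] <- 7
  expect_equal(intra_entropy(z), 0)
  # {1/2, 1/4, 1/4} -> 1.5 bits
  expect_equal(intra_entropy(matrix(c(2, 1, 1), 1)), 1.5)
  # scale invariance
  m <- matrix(runif(12), 3)
  expect_equal(intra_entropy(10 * m), intra_entropy(m))
  expect_error(intra_entropy(matrix(-1, 2, 2)), "negative")
  expect_error(intra_entropy(matrix(0, 2, 2)), "all-zero")
})

test_that("inter_entropy is a symmetric divergence, zero iff equal", {
  a <- matrix(runif(20), 4); b <- matrix(runif(20), 4)
  expect_equal(inter_entropy(a, a), 0)
  expect_equal(inter_entropy(a, 3 * a), 0)  # normalization invariance
  expect_gt(inter_entropy(a, b), 0)
  expect_equal(inter_entropy(a, b), inter_entropy(b, a))
  expect_error(inter_entropy(a, matrix(0, 2, 2)), "dimension")
})

test_that("align_score is the overlap-mean MSD with documented conventions", {
  prof <- matrix(c(1, 0, 0, 0,
                   0, 1, 0, 0), nrow = 2, byrow = TRUE)
  # identical at offset 0
  expect_equal(align_score(prof, prof, 0), 0)
  # slice shifted right by 1: profile col j vs slice col j+1
  sl <- prof[, c(4, 1, 2, 3)]
  expect_equal(align_score(sl, prof, 1, max_shift = 3), 0)
  # flip reverses bin order before shifting
  expect_equal(align_score(prof[, 4:1], prof, 0, flip = TRUE), 0)
  # hand value: one mismatching cell pair over a 2x3 overlap at offset 1
  p2 <- matrix(0, 1, 3); p2[1, 1] <- 1
  s2 <- matrix(0, 1, 3); s2[1, 3] <- 1
  # offset 1: profile cols 1:2 vs slice cols 2:3 -> diffs (1-0), (0-1)
  expect_equal(align_score(s2, p2, 1, max_shift = 2), -(1 + 1) / 2)
  expect_error(align_score(prof, prof, 5, max_shift = 3), "range")
})

test_that("best_alignment equals the exhaustive R oracle with tie-breaks", {
  set.seed(7)
  for (i in 1:25) {
    sl <- matrix(runif(24), 3); pr <- matrix(runif(24), 3)
    got <- best_alignment(sl, pr, max_shift = 4)
    want <- oracle_best_alignment(sl, pr, 4)
    expect_identical(got[c("offset", "flip")], want[c("offset", "flip")])
    expect_equal(got$score, want$score)
  }
  # deliberate tie: symmetric slice/profile prefer |offset| 0, no flip
  sym <- matrix(1, 2, 5)
  got <- best_alignment(sym, sym, max_shift = 3)
  expect_identical(got$offset, 0L)
  expect_false(got$flip)
})

test_that("flip alignment is an involution: flipping both cancels", {
  set.seed(11)
  sl <- matrix(runif(40), 4); pr <- matrix(runif(40), 4)
  B <- ncol(sl)
  a <- align_score(sl, pr, 0, flip = TRUE)
  b <- align_score(sl[, B:1], pr, 0, flip = FALSE)
  expect_equal(a, b)
})

test_that("select_seed picks the max-entropy head and its nearest partners", {
  tens <- small_prep()$tensor
  cfg <- episig_config(rng_seed = 1)
  un <- seq_len(dim(tens$tensor)[1])
  seed <- select_seed(tens, un, cfg)
  expect_length(seed, cfg$seed_k)
  expect_false(anyDuplicated(seed) > 0)
  h <- episigr:::cpp_intra_entropies(tens$tensor, un)
  expect_equal(seed[1], un[which.max(h)])
  # blacklisting the head forces a different one
  seed2 <- select_seed(tens, un, cfg, blacklist = seed[1])
  expect_false(seed2[1] == seed[1])
  expect_error(select_seed(tens, 1:3, cfg), class = "episig_no_seed")
})

test_that("gibbs_cluster grows a cluster from a planted seed", {
  ls <- small_landscape()
  prep <- small_prep()
  tens <- prep$tensor
  cfg <- episig_config(rng_seed = 1)
  arch <- planted_archetype(tens, ls$truth)
  un <- seq_len(dim(tens$tensor)[1])
  # background heads are common at the permissive scan defaults, and
  # gibbs_cluster returns NULL for them: iterate with a blacklist the way
  # run_episig does until a cluster grows
  cl <- NULL; blacklist <- integer(); it <- 0L
  while (is.null(cl) && it < 200L) {
    it <- it + 1L
    seed <- select_seed(tens, un, cfg, blacklist)
    cl <- gibbs_cluster(tens, seed, un, cfg, iteration = it)
    if (is.null(cl)) blacklist <- union(blacklist, seed)
  }
  expect_s3_class(cl, "epi_cluster")
  expect_gte(nrow(cl$members), cfg$min_cluster_size)
  # members are (nearly) pure in one planted archetype
  got <- arch[cl$members$region_index]
  expect_gte(max(table(got)) / nrow(cl$members), 0.9)
  expect_true(all(abs(cl$members$offset) <= cfg$max_shift))
  expect_equal(dim(cl$profile), dim(tens$tensor)[2:3])
})

test_that("run_episig recovers the planted archetypes on a small landscape", {
  ls <- small_landscape()
  tens <- small_prep()$tensor
  fit <- small_fit()
  expect_s3_class(fit, "episig_fit")
  arch <- planted_archetype(tens, ls$truth)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_regions)
  # every planted region assigned, each cluster pure in one archetype
  m <- td[!is.na(td$cluster), ]
  tab <- table(arch[m$region_index], m$cluster, useNA = "no")
  expect_equal(length(fit$clusters), 3L)
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)
  # background stays out
  expect_lte(sum(is.na(arch[m$region_index])), 2)
  g <- glance(fit)
  expect_equal(g$n_assigned + g$n_unassigned, g$n_regions)
  expect_equal(g$n_clusters, 3L)
})

test_that("run_episig is deterministic given the config seed", {
  tens <- small_prep()$tensor
  f1 <- small_fit()
  f2 <- run_episig(tens, episig_config(rng_seed = 1))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(lapply(f1$clusters, `[[`, "profile"),
                   lapply(f2$clusters, `[[`, "profile"))
})
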