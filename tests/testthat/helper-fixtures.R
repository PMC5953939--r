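# Shared fixtures, memoized per test session so expensive synthetic
# landscapes are generated once.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_layout <- function() genome_layout(c(chrA = 20000, chrB = 11000),
                                        window_bp = 5000, bin_bp = 200)

# A small but complete landscape: 3 archetypes x 20 regions, 3 vs 3
# samples on a 5 Mb genome.
small_landscape <- function() fixture("small_landscape", function() {
  make_landscape(chrom_sizes = c(chr1 = 3e6, chr2 = 2e6),
                 n_archetypes = 3, regions_per_archetype = 20,
                 samples_per_group = 3, rng_seed = 1)
})

small_prep <- function() fixture("small_prep", function() {
  ls <- small_landscape()
  prepare_tensor(ls$tracks, ls$layout)
})

small_fit <- function() fixture("small_fit", function() {
  run_episig(small_prep()$tensor, episig_config(rng_seed = 1))
})

# Map tensor region index -> planted archetype id (NA for background).
planted_archetype <- function(tensor, truth) {
  key <- paste(tensor$regions$chrom, tensor$regions$start)
  tkey <- paste(truth$chrom, truth$start)
  truth$archetype[match(key, tkey)]
}

# Independent R oracle for best_alignment: direct exhaustive search via
# align_score (which is itself hand-checkable), with the documented
# tie-breaking.
oracle_best_alignment <- function(slice, profile, max_shift) {
  grid <- expand.grid(offset = -max_shift:max_shift, flip = c(FALSE, TRUE))
  grid$score <- mapply(function(o, f)
    align_score(slice, profile, o, f, max_shift),
    grid$offset, grid$flip)
  grid <- grid[order(-grid$score, abs(grid$offset), grid$flip,
                     grid$offset), ]
  list(offset = grid$offset[1], flip = grid$flip[1], score = grid$score[1])
}

# Brute-force BH step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact hypergeometric upper tail by enumeration of the pmf.
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}
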