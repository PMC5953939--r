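#' Configuration for the clustering engine
#'
#' Hyperparameters of the iterative seed-and-assign clustering. Defaults
#' are chosen for 25-bin windows of sigmoid-normalized signal.
#'
#' @param max_shift Maximum alignment shift, in bins (default 10).
#' @param min_cluster_size Smallest acceptable cluster (default 10).
#' @param seed_k Seed-set size: the entropy-selected head plus its
#'   `seed_k - 1` nearest regions (default 5).
#' @param n_sweeps Number of stochastic assignment sweeps (default 3).
#' @param temperature Acceptance softness: membership is accepted with
#'   probability `sigmoid((score - threshold) / temperature)`; at 0 the
#'   rule is the deterministic `score >= threshold` (default 5e-4, small
#'   relative to typical score gaps on normalized data: scores are negative
#'   mean squared differences of values in \[0, 1\], so gaps between
#'   matching and background regions are of order 0.01-0.1).
#' @param rng_seed Integer seed; every stochastic step derives from it
#'   (default 0).
#' @param max_clusters Cap on extracted clusters (default 50).
#' @param n_background Background regions sampled to set the per-seed
#'   acceptance threshold (default 200).
#' @return An `episig_config` list.
#' @export
episig_config <- function(max_shift = 10, min_cluster_size = 10, seed_k = 5,
                          n_sweeps = 3, temperature = 5e-4, rng_seed = 0,
                          max_clusters = 50, n_background = 200) {
  stopifnot(max_shift >= 1, min_cluster_size >= 1, seed_k >= 2,
            n_sweeps >= 1, temperature >= 0, max_clusters >= 1,
            n_background >= 2)
  structure(list(max_shift = as.integer(max_shift),
                 min_cluster_size = as.integer(min_cluster_size),
                 seed_k = as.integer(seed_k),
                 n_sweeps = as.integer(n_sweeps),
                 temperature = temperature,
                 rng_seed = as.integer(rng_seed),
                 max_clusters = as.integer(max_clusters),
                 n_background = as.integer(n_background)),
            class = "episig_config")
}

#' Intra-region entropy
#'
#' Shannon entropy (bits) of a region's signal slice viewed as a
#' probability distribution over its track-by-bin cells. High entropy means
#' signal spread over many cells; a single hot cell gives 0.
#'
#' @param region_slice Tracks x bins matrix, values >= 0, not all zero.
#' @return Entropy in \[0, log2(T*B)\].
#' @export
intra_entropy <- function(region_slice) {
  region_slice <- as.matrix(region_slice)
  if (any(region_slice < 0)) stop("negative signal in region slice")
  tot <- sum(region_slice)
  if (tot <= 0) stop("no signal: all-zero slice")
  p <- as.vector(region_slice) / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Inter-region entropy
#'
#' Symmetric cross-entropy distance between two same-shape slices:
#' `D = 1/2 [H(p,q) + H(q,p)] - 1/2 [H(p) + H(q)]`, i.e. the symmetrized
#' Kullback-Leibler divergence in bits, after adding a pseudocount
#' `eps` per cell and normalizing each slice to sum 1. `D >= 0`, with 0
#' iff the normalized slices are identical.
#'
#' @param a,b Tracks x bins matrices of the same shape.
#' @param eps Per-cell pseudocount (default 1e-6).
#' @return Non-negative divergence in bits.
#' @export
inter_entropy <- function(a, b, eps = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("dimension error: slices have different shapes")
  p <- (as.vector(a) + eps); p <- p / sum(p)
  q <- (as.vector(b) + eps); q <- q / sum(q)
  hpq <- -sum(p * log2(q)); hqp <- -sum(q * log2(p))
  hp <- -sum(p * log2(p)); hq <- -sum(q * log2(q))
  0.5 * (hpq + hqp) - 0.5 * (hp + hq)
}

#' Alignment score of a region against a profile
#'
#' Negative mean squared difference between the profile and the region
#' slice shifted by `offset` bins (a flip reverses bin order jointly across
#' all tracks before shifting). Profile column `j` is compared with slice
#' column `j + offset`; overhanging columns are excluded from the mean.
#' 0 is a perfect match; more negative is less similar.
#'
#' @param region_slice,profile Tracks x bins matrices of the same shape.
#' @param offset Shift in bins, `|offset| <= max_shift`.
#' @param flip Logical.
#' @param max_shift Allowed shift range (default 10).
#' @return Score `<= 0` (`-Inf` when the alignment has no overlap).
#' @export
align_score <- function(region_slice, profile, offset, flip = FALSE,
                        max_shift = 10) {
  region_slice <- as.matrix(region_slice); profile <- as.matrix(profile)
  if (!all(dim(region_slice) == dim(profile)))
    stop("dimension error: slice and profile shapes differ")
  if (abs(offset) > max_shift)
    stop("offset out of range [-", max_shift, ", ", max_shift, "]")
  B <- ncol(region_slice)
  s2 <- if (flip) region_slice[, rev(seq_len(B)), drop = FALSE]
        else region_slice
  j <- seq.int(max(1, 1 - offset), min(B, B - offset))
  if (length(j) == 0 || j[1] > j[length(j)]) return(-Inf)
  -mean((profile[, j, drop = FALSE] - s2[, j + offset, drop = FALSE])^2)
}

#' Best alignment of a region against a profile
#'
#' Exhaustive search over offsets in `[-max_shift, max_shift]` and both
#' orientations. Ties are broken toward smaller `|offset|`, then no flip,
#' then the smaller signed offset.
#'
#' @inheritParams align_score
#' @param cfg An [episig_config()] (only `max_shift` is used), or `NULL`
#'   with `max_shift` given directly.
#' @return List with `offset`, `flip`, `score`.
#' @export
best_alignment <- function(region_slice, profile, cfg = NULL,
                           max_shift = if (is.null(cfg)) 10 else cfg$max_shift) {
  region_slice <- as.matrix(region_slice); profile <- as.matrix(profile)
  sc <- cpp_align_scores(region_slice, profile, as.integer(max_shift))
  offs <- rep(-max_shift:max_shift, each = 2)
  flips <- rep(c(FALSE, TRUE), times = 2 * max_shift + 1)
  scores <- as.vector(sc)  # column-major: (flip0, flip1) per offset
  ord <- order(-scores, abs(offs), flips, offs)
  i <- ord[1]
  list(offset = offs[i], flip = flips[i], score = scores[i])
}

# -- cluster container ------------------------------------------------------

new_epi_cluster <- function(id, members, profile, score_threshold) {
  structure(list(id = id, members = members, profile = profile,
                 score_threshold = score_threshold), class = "epi_cluster")
}

#' @export
print.epi_cluster <- function(x, ...) {
  cat("<epi_cluster> id ", x$id, ": ", nrow(x$members), " members, ",
      "threshold ", signif(x$score_threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Entropy-based seed selection
#'
#' The seed head is the unassigned region with maximum intra-region
#' entropy (ties go to the lowest genomic coordinate); the remaining
#' `seed_k - 1` seeds are the unassigned regions with the smallest
#' alignment-minimized inter-region entropy to the head.
#'
#' @param tensor A `region_tensor`.
#' @param unassigned Integer vector of candidate region indices.
#' @param cfg An [episig_config()].
#' @param blacklist Region indices excluded from being the head.
#' @param entropy Optional precomputed per-region intra-entropy vector
#'   (length = number of tensor regions); computed on the fly when `NULL`.
#'   [run_episig()] passes a cached vector so repeated seed selections do
#'   not recompute it.
#' @return Integer vector of `seed_k` region indices (head first).
#' @export
select_seed <- function(tensor, unassigned, cfg, blacklist = integer(),
                        entropy = NULL) {
  unassigned <- sort(unique(as.integer(unassigned)))
  if (length(unassigned) < cfg$seed_k)
    stop_no_seed("too few unassigned regions for a seed")
  heads <- setdiff(unassigned, blacklist)
  if (length(heads) == 0) stop_no_seed("all candidate heads blacklisted")
  h <- if (is.null(entropy)) cpp_intra_entropies(tensor$tensor, heads)
       else entropy[heads]
  head <- heads[which.max(h)]  # regions sorted genomically: first max wins
  others <- setdiff(unassigned, head)
  d <- cpp_partner_divergences(tensor$tensor, head, others,
                               cfg$max_shift, 1e-6)
  partners <- others[order(d, others)][seq_len(cfg$seed_k - 1)]
  c(head, partners)
}

stop_no_seed <- function(msg) {
  stop(structure(class = c("episig_no_seed", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Running aligned-profile state: per-cell sum and per-column member count.
profile_add <- function(state, slice, offset, flip) {
  B <- ncol(state$sum)
  s2 <- if (flip) slice[, rev(seq_len(B)), drop = FALSE] else slice
  j <- seq.int(max(1, 1 - offset), min(B, B - offset))
  state$sum[, j] <- state$sum[, j] + s2[, j + offset, drop = FALSE]
  state$count[j] <- state$count[j] + 1L
  state
}

# Background-extended alignment score at one specific (offset, flip):
# both windows are embedded in an infinite background at the per-track
# `fill` values, so profile columns not covered by the offset are compared
# against background, the slice's own overhanging columns are likewise
# compared against background, and the mean runs over the union of both
# windows. Mirrors the fill mode of cpp_best_alignments() exactly (keep
# the two in sync); used where a handful of specific candidates are
# scored and the exhaustive C++ search would be wasted work.
align_score_extended <- function(slice, profile, offset, flip, fill) {
  B <- ncol(slice)
  s2 <- if (flip) slice[, rev(seq_len(B)), drop = FALSE] else slice
  j <- seq.int(max(1, 1 - offset), min(B, B - offset))
  ss <- sum((profile[, j, drop = FALSE] - s2[, j + offset, drop = FALSE])^2)
  ex_cols <- setdiff(seq_len(B), j)
  ex <- if (length(ex_cols))
    sum((profile[, ex_cols, drop = FALSE] - fill)^2) else 0
  vis <- if (flip) B + 1 - (j + offset) else j + offset
  un <- setdiff(seq_len(B), vis)
  me <- if (length(un)) sum((slice[, un, drop = FALSE] - fill)^2) else 0
  -(ss + ex + me) / (nrow(slice) * (B + abs(offset)))
}

profile_sub <- function(state, slice, offset, flip) {
  B <- ncol(state$sum)
  s2 <- if (flip) slice[, rev(seq_len(B)), drop = FALSE] else slice
  j <- seq.int(max(1, 1 - offset), min(B, B - offset))
  state$sum[, j] <- state$sum[, j] - s2[, j + offset, drop = FALSE]
  state$count[j] <- state$count[j] - 1L
  state
}

profile_matrix <- function(state) {
  sweep(state$sum, 2, pmax(state$count, 1L), "/")
}

rebuild_profile <- function(tensor, members) {
  d <- dim(tensor$tensor)
  state <- list(sum = matrix(0, d[2], d[3]), count = integer(d[3]))
  for (i in seq_len(nrow(members)))
    state <- profile_add(state, region_slice(tensor, members$region_index[i]),
                         members$offset[i], members$flip[i])
  state
}

#' Gibbs-sampling-like cluster growth around a seed
#'
#' The seed head anchors the cluster's alignment frame (offset 0, no
#' flip); the remaining seed regions are best-aligned to the head before
#' the profile is first computed, so the seed is coherent from the start.
#' Growth then alternates stochastic admission with profile
#' re-estimation. In each of `n_sweeps` sweeps every remaining unassigned
#' region is best-aligned against the current profile and admitted with
#' probability `sigmoid((score - threshold) / temperature)`
#' (deterministically `score >= threshold` when `temperature` is 0); the
#' profile is then rebuilt as the per-bin mean over aligned members, all
#' member alignments are re-estimated against it, and members whose
#' re-estimated score falls below the threshold are evicted back to the
#' pool (the seed head is never evicted). A seed whose membership falls
#' below `min_cluster_size` after a sweep's eviction is abandoned
#' immediately. A final deterministic pass
#' accepts any remaining region scoring at or above the threshold. The
#' threshold is an empirical null, re-estimated against the current
#' profile whenever it is used, from the best-alignment scores of up to
#' `n_background` non-seed regions sampled once per call: the midpoint of
#' the member and background mean scores, floored at the background mean
#' plus two standard deviations.
#'
#' Admission decisions use the plain overlap-mean score of
#' [align_score()]. Registration — the initial alignment of seed partners
#' to the head, and a final sequential leave-one-out refinement — instead
#' ranks alignments with a background-extended score: the region window is
#' notionally extended with per-track expected background values (the
#' track's median over all tensor cells), so profile columns left
#' uncovered by an offset are compared against background rather than
#' dropped and every candidate is averaged over the same number of cells.
#' The plain overlap-mean systematically favors large offsets, because
#' shifting noisy columns out of the overlap lowers the mean squared
#' difference even when it misregisters the pattern; the extension removes
#' that bias so recovered offsets and flips reflect the true registration.
#' The final refinement realigns each member against the profile with its
#' own contribution removed, which collapses profiles smeared across two
#' adjacent registrations into a single consensus registration.
#'
#' @param tensor A `region_tensor`.
#' @param seed Integer vector of seed region indices (all unassigned).
#' @param unassigned Integer vector of unassigned region indices
#'   (including the seed).
#' @param cfg An [episig_config()].
#' @param iteration Extraction-iteration counter; the RNG stream is seeded
#'   with `cfg$rng_seed + iteration` so the call is reproducible.
#' @return An `epi_cluster`, or `NULL` when the grown cluster is smaller
#'   than `min_cluster_size` (the caller should blacklist the seed head).
#' @export
gibbs_cluster <- function(tensor, seed, unassigned, cfg, iteration = 0L) {
  g <- gibbs_grow(tensor, seed, unassigned, cfg, iteration)
  if (nrow(g$members) < cfg$min_cluster_size) return(NULL)
  new_epi_cluster(NA_integer_, g$members, g$profile, g$theta)
}

# Engine behind gibbs_cluster: always returns the grown membership (plus
# profile and threshold) so the extraction loop can blacklist the members
# of a failed cluster. Seeds whose membership falls below min_cluster_size
# after a sweep's eviction are abandoned early: with eviction active, a
# seed that cannot hold min_cluster_size members is not resurrected by
# further sweeps, and abandoning it cheaply matters because background
# seed heads are common.
gibbs_grow <- function(tensor, seed, unassigned, cfg, iteration = 0L) {
  stopifnot(all(seed %in% unassigned))
  arr <- tensor$tensor
  withr::with_seed(cfg$rng_seed + as.integer(iteration), {
    head_slice <- region_slice(tensor, seed[1])
    # empirical null from background regions sampled from the whole tensor
    # (not the unassigned pool, whose composition drifts across iterations
    # and would inflate the null sd)
    pool <- setdiff(seq_len(dim(arr)[1]), seed)
    if (length(pool) == 0) pool <- seed
    bg <- if (length(pool) <= cfg$n_background) pool
          else sample(pool, cfg$n_background)
    # Registration (seed alignment and the leave-one-out refinement below)
    # extends each region window with per-track expected background values
    # (the track's median over all tensor cells), so profile columns left
    # uncovered by an offset are compared against background rather than
    # dropped and every candidate offset is scored over the same number of
    # cells. The plain overlap-mean is biased toward large offsets
    # (clipping noisy columns out of the overlap lowers the mean even when
    # it misregisters the pattern), which corrupts the recovered offsets
    # and flips. Admission scoring below stays on the plain overlap-mean
    # scale, where the member-vs-other-archetype margin is widest.
    fill <- apply(arr, 2, stats::median)
    seed_aln <- cpp_best_alignments(arr, as.integer(seed[-1]), head_slice,
                                    cfg$max_shift, fill)
    members <- tibble::tibble(
      region_index = as.integer(seed),
      offset = c(0L, as.integer(seed_aln[, 1])),
      flip = c(FALSE, seed_aln[, 2] > 0))
    state <- rebuild_profile(tensor, members)
    prof <- profile_matrix(state)
    # the threshold is re-estimated against the current profile at each
    # use: accepted members reshape the profile, and a threshold frozen
    # against the seed profile would drift away from what it calibrates.
    # theta is the midpoint between the members own mean score and the
    # background mean (a two-sided discriminant: a background-only null
    # admits anything merely better than background, which merges distinct
    # archetypes), floored at background mean + 2 sd so that a weak seed
    # never opens the cluster to bulk background.
    est_theta <- function(prof, member_idx) {
      bg_scores <- cpp_best_alignments(arr, as.integer(bg), prof,
                                       cfg$max_shift)[, 3]
      mem_scores <- cpp_best_alignments(arr, as.integer(member_idx), prof,
                                        cfg$max_shift)[, 3]
      floor_bg <- mean(bg_scores) +
        2 * (if (length(bg_scores) > 1) stats::sd(bg_scores) else 0)
      max(0.5 * (mean(mem_scores) + mean(bg_scores)), floor_bg)
    }
    accept_prob <- function(score, theta) {
      if (cfg$temperature <= 0) return(as.numeric(score >= theta))
      1 / (1 + exp(-(score - theta) / cfg$temperature))
    }
    # Re-center the cluster frame at the median member offset. Realignment
    # passes let the frame drift away from the seed head; unchecked drift
    # pushes the offsets some members need beyond max_shift, where they
    # get clamped at the boundary and misregister. Translating the profile
    # adds a constant to every member offset, so subtracting the rounded
    # median and rebuilding keeps alignments intact while restoring the
    # full offset budget.
    recenter <- function(members) {
      med <- as.integer(round(stats::median(members$offset)))
      if (med != 0L) members$offset <- members$offset - med
      members
    }
    for (sweep in seq_len(cfg$n_sweeps)) {
      theta <- est_theta(prof, members$region_index)
      cand <- setdiff(unassigned, members$region_index)
      if (length(cand) > 0) {
        ba <- cpp_best_alignments(arr, as.integer(cand), prof,
                                  cfg$max_shift)
        acc <- stats::runif(length(cand)) < accept_prob(ba[, 3], theta)
        if (any(acc)) {
          members <- dplyr::bind_rows(members, tibble::tibble(
            region_index = as.integer(cand[acc]),
            offset = as.integer(ba[acc, 1]),
            flip = ba[acc, 2] > 0))
          state <- rebuild_profile(tensor, members)
          prof <- profile_matrix(state)
        }
      }
      # re-estimate member alignments and evict background-level members
      theta <- est_theta(prof, members$region_index)
      mba <- cpp_best_alignments(arr, members$region_index, prof,
                                 cfg$max_shift)
      members$offset <- as.integer(mba[, 1])
      members$flip <- mba[, 2] > 0
      keep <- mba[, 3] >= theta | members$region_index == seed[1]
      members <- recenter(members[keep, , drop = FALSE])
      state <- rebuild_profile(tensor, members)
      prof <- profile_matrix(state)
      if (nrow(members) < cfg$min_cluster_size)
        return(list(members = members, profile = prof, theta = theta))
    }
    # final deterministic pass
    theta <- est_theta(prof, members$region_index)
    rest <- setdiff(unassigned, members$region_index)
    if (length(rest) > 0) {
      ba <- cpp_best_alignments(arr, as.integer(rest), prof, cfg$max_shift)
      acc <- ba[, 3] >= theta
      if (any(acc)) {
        members <- dplyr::bind_rows(members, tibble::tibble(
          region_index = as.integer(rest[acc]),
          offset = as.integer(ba[acc, 1]),
          flip = ba[acc, 2] > 0))
      }
    }
    members <- recenter(members)
    state <- rebuild_profile(tensor, members)
    prof <- profile_matrix(state)
    # Registration reset: realign every member directly to the head slice.
    # Growth-time alignments accumulate against evolving mixture profiles;
    # for self-similar templates (e.g. two similar peaks several bins
    # apart) a contaminated profile sustains secondary registration modes
    # far from the true one. The head is a single uncontaminated exemplar,
    # so anchoring to it confines errors to small +/- 1 bin scatter that
    # the refinement below collapses.
    mba <- cpp_best_alignments(arr, members$region_index, head_slice,
                               cfg$max_shift, fill)
    members$offset <- as.integer(mba[, 1])
    members$flip <- mba[, 2] > 0
    members <- recenter(members)
    state <- rebuild_profile(tensor, members)
    # Two-stage registration refinement, repeated for two rounds.
    #
    # Stage 1 (batch): every member is realigned against the full rebuilt
    # profile until a fixed point. Batch moves against a fixed profile
    # cannot cascade, so this stage is stable, and it corrects flip errors
    # left by the noisy single-slice head anchoring. Its fixed points can
    # however be smeared across two adjacent registrations: each member
    # then ties between the modes in expectation and locks to whichever
    # its own noise favors.
    #
    # Stage 2 (constrained leave-one-out): members are realigned one at a
    # time against the profile with their own contribution removed, with
    # moves restricted to one bin and the orientation frozen. The
    # leave-one-out mixture always leans away from the member's current
    # mode by one membership share, so the first defections snowball and
    # the adjacent-registration smear collapses into a single consensus.
    # The restriction matters: unconstrained sequential moves let the
    # whole frame walk and, for self-similar templates, scatter members
    # across distant registration modes.
    for (round in 1:2) {
      for (pass in seq_len(8L)) {
        mba <- cpp_best_alignments(arr, members$region_index, prof,
                                   cfg$max_shift, fill)
        changed <- any(mba[, 1] != members$offset |
                         (mba[, 2] > 0) != members$flip)
        members$offset <- as.integer(mba[, 1])
        members$flip <- mba[, 2] > 0
        members <- recenter(members)
        state <- rebuild_profile(tensor, members)
        prof <- profile_matrix(state)
        if (!changed) break
      }
      for (pass in seq_len(8L)) {
        changed <- FALSE
        for (i in seq_len(nrow(members))) {
          slice <- region_slice(tensor, members$region_index[i])
          state <- profile_sub(state, slice, members$offset[i],
                               members$flip[i])
          ploo <- profile_matrix(state)
          cand <- members$offset[i] + (-1L:1L)
          cand <- cand[abs(cand) <= cfg$max_shift]
          scs <- vapply(cand, function(o)
            align_score_extended(slice, ploo, o, members$flip[i], fill), 0)
          off <- cand[which.max(scs)]
          if (off != members$offset[i]) {
            changed <- TRUE
            members$offset[i] <- off
          }
          state <- profile_add(state, slice, off, members$flip[i])
        }
        med <- as.integer(round(stats::median(members$offset)))
        if (med != 0L) {
          members <- recenter(members)
          state <- rebuild_profile(tensor, members)
          changed <- TRUE
        }
        if (!changed) break
      }
      prof <- profile_matrix(state)
    }
    list(members = members, profile = prof, theta = theta)
  })
}

#' Iterative cluster extraction
#'
#' Repeats seed selection and Gibbs-like growth, removing each accepted
#' cluster's members from the unassigned pool, until too few regions
#' remain, no valid seed exists, or `max_clusters` is reached. When a seed
#' fails (grown cluster below `min_cluster_size`), the whole seed set and
#' whatever members the failed cluster still held are blacklisted from
#' future headship (they remain eligible as members), so the loop
#' terminates without retrying each near-duplicate of a failed head.
#' Per-region intra-entropies are computed once and reused across seed
#' selections. Every region belongs to at most one cluster; clusters are
#' numbered in extraction order.
#'
#' @param tensor A `region_tensor`.
#' @param cfg An [episig_config()].
#' @return An `episig_fit`: list with `clusters` (list of `epi_cluster`),
#'   `unassigned` (region indices), `config`, and the tensor's `regions`
#'   and `layout`.
#' @export
run_episig <- function(tensor, cfg = episig_config()) {
  stopifnot(inherits(tensor, "region_tensor"))
  n <- dim(tensor$tensor)[1]
  unassigned <- seq_len(n)
  blacklist <- integer()
  clusters <- list()
  iteration <- 0L
  entropy <- numeric(n)
  entropy[] <- cpp_intra_entropies(tensor$tensor, seq_len(n))
  while (length(clusters) < cfg$max_clusters &&
         length(unassigned) >= max(cfg$min_cluster_size, cfg$seed_k)) {
    iteration <- iteration + 1L
    seed <- tryCatch(select_seed(tensor, unassigned, cfg, blacklist,
                                 entropy),
                     episig_no_seed = function(e) NULL)
    if (is.null(seed)) break
    g <- gibbs_grow(tensor, seed, unassigned, cfg, iteration)
    if (nrow(g$members) < cfg$min_cluster_size) {
      blacklist <- union(blacklist, c(seed, g$members$region_index))
      next
    }
    cl <- new_epi_cluster(length(clusters) + 1L, g$members, g$profile,
                          g$theta)
    clusters[[cl$id]] <- cl
    unassigned <- setdiff(unassigned, cl$members$region_index)
    blacklist <- intersect(blacklist, unassigned)
  }
  structure(list(clusters = clusters, unassigned = unassigned,
                 config = cfg, regions = tensor$regions,
                 layout = tensor$layout, n_regions = n),
            class = "episig_fit")
}

#' @export
print.episig_fit <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$members), integer(1))
  cat("<episig_fit> ", length(x$clusters), " clusters over ", x$n_regions,
      " regions (", sum(sizes), " assigned, ", length(x$unassigned),
      " unassigned)\n", sep = "")
  invisible(x)
}

#' Per-region cluster assignments of a fit
#'
#' @param x An `episig_fit`.
#' @param ... Unused.
#' @return Tibble with one row per region: `chrom`, `start`,
#'   `region_index`, `cluster` (NA when unassigned), `offset`, `flip`.
#' @export
tidy.episig_fit <- function(x, ...) {
  asg <- purrr::map_dfr(x$clusters, function(cl)
    dplyr::mutate(cl$members, cluster = cl$id))
  out <- tibble::tibble(region_index = seq_len(x$n_regions),
                        chrom = x$regions$chrom,
                        start = x$regions$start)
  out <- dplyr::left_join(out, asg, by = "region_index")
  dplyr::select(out, "chrom", "start", "region_index", "cluster",
                "offset", "flip")
}

#' One-row summary of a fit
#'
#' @param x An `episig_fit`.
#' @param ... Unused.
#' @return Tibble with `n_regions`, `n_clusters`, `n_assigned`,
#'   `n_unassigned`, `mean_cluster_size`.
#' @export
glance.episig_fit <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$members), integer(1))
  tibble::tibble(n_regions = x$n_regions,
                 n_clusters = length(x$clusters),
                 n_assigned = sum(sizes),
                 n_unassigned = length(x$unassigned),
                 mean_cluster_size = if (length(sizes)) mean(sizes) else NA_real_)
}
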