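#' Mark-level feature vector of a cluster
#'
#' Summarizes a cluster's aligned profile as one value per mark type: the
#' profile rows of all samples sharing a mark are averaged together with
#' the bins, giving a short vector in \[0, 1\] (one coordinate per mark
#' present in the track index). Sections are characterized by mark-level
#' combinations, so this is the feature the self-organizing map consumes.
#'
#' @param cluster An `epi_cluster`.
#' @param track_index Tibble with a `mark` column, one row per tensor
#'   track, in profile row order (e.g. `tensor$track_index`).
#' @return Named numeric vector, ordered by [mark_levels()].
#' @export
cluster_feature <- function(cluster, track_index) {
  stopifnot(inherits(cluster, "epi_cluster"),
            nrow(track_index) == nrow(cluster$profile))
  marks <- intersect(mark_levels(), unique(track_index$mark))
  vapply(marks, function(m) {
    mean(cluster$profile[track_index$mark == m, , drop = FALSE])
  }, numeric(1))
}

#' Fit a self-organizing map over cluster features
#'
#' Batch SOM on a rectangular grid: the codebook is initialized by seeded
#' sampling of the input rows; each epoch assigns every row to its
#' best-matching unit (BMU, Euclidean distance) and re-estimates each node
#' as the Gaussian-neighborhood-weighted mean of the rows, blended into
#' the previous codebook with a linearly decaying learning rate. The
#' neighborhood radius decays linearly to zero, so late epochs perform
#' plain k-means refinement. The map is trained `n_starts` times from
#' different seeded initializations and the start with the lowest final
#' quantization error is kept: a map that lets two distinct feature rows
#' share a node always scores a strictly higher quantization error than
#' one that separates them, so restart selection suppresses occasional
#' node collapse without any tunable threshold. Deterministic given
#' `rng_seed`.
#'
#' @param features Numeric matrix, one row per cluster (row names become
#'   cluster ids).
#' @param grid `c(rows, cols)` of the node grid (default `c(3, 3)`, nine
#'   sections).
#' @param epochs Training epochs (default 50).
#' @param rng_seed Integer seed (default 0).
#' @param n_starts Number of seeded restarts (default 5); the start with
#'   the lowest final quantization error wins, first on ties.
#' @return A `section_map`: list with `grid`, `assignment` (tibble
#'   `cluster`, `section`), `codebook` (nodes x features matrix) and
#'   `quantization_error` (per-epoch trace of the winning start, measured
#'   before each update).
#' @export
som_fit <- function(features, grid = c(3, 3), epochs = 50, rng_seed = 0,
                    n_starts = 5) {
  features <- as.matrix(features)
  if (nrow(features) < 1) stop("empty feature matrix")
  if (is.null(rownames(features)))
    rownames(features) <- seq_len(nrow(features))
  n_nodes <- prod(grid)
  node_pos <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                    col = seq_len(grid[2])))
  grid_d2 <- as.matrix(stats::dist(node_pos))^2
  one_start <- function(start_seed) {
    withr::with_seed(as.integer(start_seed), {
      init <- sample.int(nrow(features), n_nodes,
                         replace = nrow(features) < n_nodes)
      codebook <- features[init, , drop = FALSE]
      rownames(codebook) <- NULL
      r0 <- max(grid) / 2
      qe <- numeric(epochs)
      for (e in seq_len(epochs)) {
        frac <- (e - 1) / max(1, epochs - 1)
        radius <- r0 * (1 - frac)
        alpha <- 0.5 * (1 - frac) + 0.01 * frac
        d2 <- outer(rowSums(features^2), rowSums(codebook^2), "+") -
          2 * features %*% t(codebook)
        bmu <- max.col(-d2, ties.method = "first")
        qe[e] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(features)), bmu)], 0)))
        h <- exp(-grid_d2[bmu, , drop = FALSE] /
                   (2 * max(radius, 0.01)^2))       # rows x nodes weights
        wsum <- colSums(h)
        target <- t(h) %*% features / pmax(wsum, .Machine$double.eps)
        upd <- wsum > 0
        codebook[upd, ] <- (1 - alpha) * codebook[upd, , drop = FALSE] +
          alpha * target[upd, , drop = FALSE]
      }
      d2 <- outer(rowSums(features^2), rowSums(codebook^2), "+") -
        2 * features %*% t(codebook)
      bmu <- max.col(-d2, ties.method = "first")
      final_qe <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(features)), bmu)], 0)))
      list(codebook = codebook, bmu = bmu, qe = qe, final_qe = final_qe)
    })
  }
  starts <- lapply(seq_len(max(1L, n_starts)) - 1L,
                   function(k) one_start(as.integer(rng_seed) + k))
  best <- starts[[which.min(vapply(starts, `[[`, numeric(1), "final_qe"))]]
  structure(list(
    grid = grid,
    assignment = tibble::tibble(cluster = rownames(features),
                                section = as.integer(best$bmu)),
    codebook = best$codebook,
    node_pos = node_pos,
    quantization_error = best$qe), class = "section_map")
}

#' @export
print.section_map <- function(x, ...) {
  cat("<section_map> ", x$grid[1], "x", x$grid[2], " grid, ",
      nrow(x$assignment), " clusters in ",
      length(unique(x$assignment$section)), " sections\n", sep = "")
  invisible(x)
}

#' BMU assignment of feature rows to a fixed codebook
#'
#' @param features Numeric matrix of feature rows.
#' @param codebook Nodes x features matrix (e.g. from a `section_map`).
#' @return Integer vector of node ids.
#' @export
som_assign <- function(features, codebook) {
  features <- as.matrix(features)
  d2 <- outer(rowSums(features^2), rowSums(codebook^2), "+") -
    2 * features %*% t(codebook)
  max.col(-d2, ties.method = "first")
}

#' Section clusters of a fit
#'
#' Convenience wrapper: computes [cluster_feature()] for every cluster of
#' an `episig_fit` and fits the SOM.
#'
#' @param fit An `episig_fit`.
#' @param track_index Tensor track index (tibble with `mark`).
#' @inheritParams som_fit
#' @return A `section_map`.
#' @export
section_clusters <- function(fit, track_index, grid = c(3, 3), epochs = 50,
                             rng_seed = 0, n_starts = 5) {
  stopifnot(length(fit$clusters) > 0)
  feats <- t(vapply(fit$clusters, cluster_feature,
                    numeric(length(intersect(
                      mark_levels(), unique(track_index$mark)))),
                    track_index = track_index))
  rownames(feats) <- vapply(fit$clusters, function(cl) as.character(cl$id),
                            character(1))
  som_fit(feats, grid = grid, epochs = epochs, rng_seed = rng_seed,
          n_starts = n_starts)
}
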