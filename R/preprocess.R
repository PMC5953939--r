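#' Sigmoid-normalize a binned track
#'
#' Maps read-depth signal into (0, 1) with a logistic curve centered on the
#' track's typical covered signal: `y = 1 / (1 + exp(-(x - m) / s))` with
#' `m` the median and `s = 1.4826 * MAD` of the unmasked non-zero bins
#' (`s` floored at a machine-epsilon guard so constant tracks still map
#' through a step-like curve). METH tracks pass through unchanged: beta
#' values are already bounded in \[0, 1\] and comparable across samples.
#'
#' @param track A [binned_track()]; non-METH unmasked values must be >= 0.
#' @return A [binned_track()] flagged as normalized; masked bins stay
#'   masked.
#' @export
sigmoid_normalize <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  ok <- !track$mask
  if (!any(ok)) stop("empty track: all bins masked")
  if (track$key$mark == "METH") {
    out <- binned_track(track$key, track$values, track$layout,
                        normalized = TRUE)
    return(out)
  }
  x <- track$values
  nz <- ok & x > 0
  ref <- if (any(nz)) x[nz] else x[ok]
  m <- stats::median(ref)
  s <- 1.4826 * stats::median(abs(ref - m))
  s <- max(s, sqrt(.Machine$double.eps))
  y <- rep(NA_real_, length(x))
  y[ok] <- 1 / (1 + exp(-(x[ok] - m) / s))
  binned_track(track$key, y, track$layout, normalized = TRUE)
}

# Window-mean matrix: windows x tracks, NA where a window is fully masked
# in a track. Tracks must share the layout.
window_means <- function(tracks, layout) {
  anchors <- window_anchors(layout)
  B <- layout$bins_per_window
  idx <- matrix(0L, nrow = nrow(anchors), ncol = B)
  for (i in seq_len(nrow(anchors)))
    idx[i, ] <- window_bin_indices(layout, anchors$chrom[i], anchors$start[i])
  wm <- vapply(tracks, function(tr) {
    v <- matrix(tr$values[idx], nrow = nrow(anchors))
    rowMeans(v, na.rm = TRUE)
  }, numeric(nrow(anchors)))
  wm[is.nan(wm)] <- NA_real_
  list(anchors = anchors, means = matrix(wm, nrow = nrow(anchors)))
}

#' Scan for signal-enriched windows
#'
#' A window is enriched when, in at least `min_tracks` tracks, its mean
#' normalized signal exceeds that track's genome-wide window-mean median by
#' at least `z_min` robust z-units (MAD-scaled). Tracks whose window means
#' have zero MAD contribute no calls. The result is deterministic and
#' invariant to track order.
#'
#' @param tracks Named list of normalized [binned_track()]s on one layout.
#' @param layout A [genome_layout()].
#' @param z_min Robust z threshold (default 2).
#' @param min_tracks Minimum number of tracks that must pass (default 1).
#' @return Tibble of enriched window anchors (`chrom`, `start`), sorted by
#'   (chrom, start); may be empty.
#' @export
scan_enriched_windows <- function(tracks, layout, z_min = 2, min_tracks = 1) {
  stopifnot(length(tracks) > 0)
  if (!all(vapply(tracks, function(t) isTRUE(t$normalized), logical(1))))
    stop("tracks must be normalized before scanning")
  wm <- window_means(tracks, layout)
  hits <- matrix(FALSE, nrow = nrow(wm$anchors), ncol = length(tracks))
  for (j in seq_along(tracks)) {
    v <- wm$means[, j]
    med <- stats::median(v, na.rm = TRUE)
    s <- 1.4826 * stats::median(abs(v - med), na.rm = TRUE)
    if (!is.finite(s) || s <= 0) next
    hits[, j] <- !is.na(v) & (v - med) / s >= z_min
  }
  enriched <- rowSums(hits) >= min_tracks
  out <- wm$anchors[enriched, , drop = FALSE]
  dplyr::arrange(tibble::as_tibble(out), .data$chrom, .data$start)
}

#' Assemble the concatenated region tensor
#'
#' Extracts, for each enriched window, the normalized signal of every track
#' over the window's bins, yielding a regions x tracks x bins array: the
#' concatenated multi-assay data window that the clustering engine aligns.
#' Masked bins are imputed with the track's median normalized value.
#'
#' @param windows Tibble of window anchors (`chrom`, `start`), e.g. from
#'   [scan_enriched_windows()].
#' @param tracks Named list of normalized [binned_track()]s.
#' @param layout A [genome_layout()].
#' @return A `region_tensor`: list with `regions` (tibble), `tensor`
#'   (3-d array, values in \[0, 1\]) and `track_index` (tibble of
#'   `sample_id`, `mark`, `group` in tensor track order).
#' @export
build_region_tensor <- function(windows, tracks, layout) {
  stopifnot(nrow(windows) >= 0, length(tracks) > 0)
  if (!all(vapply(tracks, function(t) isTRUE(t$normalized), logical(1))))
    stop("tracks must be normalized")
  B <- layout$bins_per_window
  R <- nrow(windows)
  bad <- windows$start < 0 |
    windows$start + layout$window_bp > layout$chrom_sizes[windows$chrom] |
    !(windows$chrom %in% names(layout$chrom_sizes))
  if (any(bad, na.rm = TRUE) || anyNA(bad))
    stop("bounds error: window outside chromosome")
  tens <- array(NA_real_, dim = c(R, length(tracks), B))
  if (R > 0) {
    idx <- matrix(0L, nrow = R, ncol = B)
    for (i in seq_len(R))
      idx[i, ] <- window_bin_indices(layout, windows$chrom[i],
                                     windows$start[i])
    for (j in seq_along(tracks)) {
      v <- tracks[[j]]$values
      med <- stats::median(v, na.rm = TRUE)
      slice <- matrix(v[idx], nrow = R)
      slice[is.na(slice)] <- med
      tens[, j, ] <- slice
    }
  }
  track_index <- purrr::map_dfr(tracks, function(tr)
    tibble::tibble(sample_id = tr$key$sample_id, mark = tr$key$mark,
                   group = tr$key$group))
  structure(list(regions = tibble::as_tibble(windows[, c("chrom", "start")]),
                 tensor = tens, track_index = track_index, layout = layout),
            class = "region_tensor")
}

#' @export
print.region_tensor <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<region_tensor> ", d[1], " regions x ", d[2], " tracks x ", d[3],
      " bins\n", sep = "")
  invisible(x)
}

# T x B slice of one region.
region_slice <- function(tensor, i) {
  matrix(tensor$tensor[i, , ], nrow = dim(tensor$tensor)[2])
}
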