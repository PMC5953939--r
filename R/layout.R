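#' Canonical mark names
#'
#' The nine assay types a track can carry: six histone modifications,
#' open chromatin (ATAC), RNA coverage and DNA methylation (beta values).
#'
#' @return Character vector of mark names.
#' @export
mark_levels <- function() {
  c("H3K4me1", "H3K4me3", "H3K9me3", "H3K27ac", "H3K27me3", "H3K36me3",
    "ATAC", "RNA", "METH")
}

#' Histone marks (the subset that gets input subtraction)
#' @return Character vector.
#' @export
histone_marks <- function() mark_levels()[1:6]

#' Define a binned genome layout
#'
#' Partitions each chromosome into fixed-width bins (tiling from 0; the last
#' bin may be partial) and into equal-width analysis windows. Windows are
#' half-open, non-overlapping and tile each chromosome from 0; a partial
#' terminal window (chromosome length not divisible by `window_bp`) is
#' dropped so every window has the same number of bins.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp), a
#'   two-column data frame (chrom, size), or a path to a two-column
#'   `chrom.sizes` TSV.
#' @param window_bp Window width in bp; must be a positive multiple of
#'   `bin_bp`. Default 5000.
#' @param bin_bp Sub-bin width in bp. Default 200.
#'
#' @return An object of class `genome_layout`.
#' @examples
#' layout <- genome_layout(c(chr1 = 1e5, chr2 = 5e4))
#' layout$bins_per_window
#' @export
genome_layout <- function(chrom_sizes, window_bp = 5000, bin_bp = 200) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    tab <- utils::read.table(chrom_sizes, header = FALSE, sep = "\t",
                             col.names = c("chrom", "size"),
                             colClasses = c("character", "numeric"))
    chrom_sizes <- stats::setNames(tab$size, tab$chrom)
  } else if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]),
                                   as.character(chrom_sizes[[1]]))
  }
  stopifnot(length(chrom_sizes) > 0, all(chrom_sizes > 0),
            !is.null(names(chrom_sizes)))
  window_bp <- as.integer(window_bp); bin_bp <- as.integer(bin_bp)
  if (window_bp <= 0 || bin_bp <= 0 || window_bp %% bin_bp != 0)
    stop("window_bp must be a positive multiple of bin_bp")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_bp))
  n_windows <- as.integer(floor(chrom_sizes / window_bp))
  structure(list(
    chrom_sizes = chrom_sizes,
    window_bp = window_bp,
    bin_bp = bin_bp,
    bins_per_window = window_bp %/% bin_bp,
    n_bins = stats::setNames(n_bins, names(chrom_sizes)),
    bin_offset = stats::setNames(cumsum(c(0L, n_bins[-length(n_bins)])),
                                 names(chrom_sizes)),
    total_bins = sum(n_bins),
    n_windows = stats::setNames(n_windows, names(chrom_sizes))
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_sizes), " chromosomes, ",
      x$total_bins, " bins of ", x$bin_bp, " bp, ",
      sum(x$n_windows), " windows of ", x$window_bp, " bp\n", sep = "")
  invisible(x)
}

#' All full windows of a layout
#'
#' @param layout A [genome_layout()].
#' @return Tibble with columns `chrom`, `start` (0-based window anchors),
#'   sorted by (chrom, start) in layout chromosome order.
#' @export
window_anchors <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  chroms <- names(layout$chrom_sizes)
  purrr::map_dfr(chroms, function(ch) {
    nw <- layout$n_windows[[ch]]
    if (nw == 0) return(tibble::tibble(chrom = character(), start = integer()))
    tibble::tibble(chrom = ch,
                   start = as.integer(seq_len(nw) - 1L) * layout$window_bp)
  })
}

# Global bin indices (1-based) covered by a window anchored at (chrom, start).
window_bin_indices <- function(layout, chrom, start) {
  b0 <- layout$bin_offset[[chrom]] + start %/% layout$bin_bp
  as.integer(b0 + seq_len(layout$bins_per_window))
}

# Chromosome of each global bin, and the bin's start coordinate.
bin_table <- function(layout) {
  chroms <- names(layout$chrom_sizes)
  tibble::tibble(
    chrom = rep(chroms, layout$n_bins[chroms]),
    start = unlist(lapply(chroms, function(ch)
      (seq_len(layout$n_bins[[ch]]) - 1L) * layout$bin_bp), use.names = FALSE)
  )
}

#' Construct a track key
#'
#' Identifies one signal track: which sample, which mark, which group.
#'
#' @param sample_id Sample identifier.
#' @param mark One of [mark_levels()].
#' @param group `"case"` or `"control"`.
#' @return A `track_key` object.
#' @export
track_key <- function(sample_id, mark, group = c("case", "control")) {
  mark <- match.arg(mark, mark_levels())
  group <- match.arg(group)
  structure(list(sample_id = as.character(sample_id), mark = mark,
                 group = group), class = "track_key")
}

#' @export
format.track_key <- function(x, ...) {
  paste0(x$sample_id, ":", x$mark, " (", x$group, ")")
}

#' @export
print.track_key <- function(x, ...) {
  cat("<track_key>", format(x), "\n"); invisible(x)
}

#' Construct a binned track
#'
#' One sample-by-mark signal vector over the fixed-width bins of a layout.
#' Bins with no data are masked (`NA` in `values`, `TRUE` in the mask).
#'
#' @param key A [track_key()].
#' @param values Numeric vector, length `layout$total_bins`; `NA` where
#'   masked. Unmasked METH values must lie in \[0, 1\]; unmasked values of
#'   other marks must be non-negative (before normalization).
#' @param layout The [genome_layout()] the values are binned on.
#' @param normalized Logical; `TRUE` once the track has been
#'   sigmoid-normalized.
#' @return A `binned_track`.
#' @export
binned_track <- function(key, values, layout, normalized = FALSE) {
  stopifnot(inherits(key, "track_key"), inherits(layout, "genome_layout"))
  values <- as.numeric(values)
  if (length(values) != layout$total_bins)
    stop("values length (", length(values), ") != total bins (",
         layout$total_bins, ")")
  ok <- !is.na(values)
  if (!normalized) {
    if (key$mark == "METH") {
      if (any(values[ok] < 0 | values[ok] > 1))
        stop("METH values must lie in [0,1]")
    } else if (any(values[ok] < 0)) {
      stop("non-METH values must be >= 0 before normalization")
    }
  }
  structure(list(key = key, values = values, mask = !ok, layout = layout,
                 normalized = normalized), class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("<binned_track> ", format(x$key), ", ", length(x$values), " bins (",
      sum(x$mask), " masked)", if (x$normalized) ", normalized", "\n",
      sep = "")
  invisible(x)
}
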