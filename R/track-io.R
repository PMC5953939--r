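#' Read a bedGraph file onto a binned layout
#'
#' Records are `(chrom, start, end, value)` in 0-based half-open
#' coordinates. Each bin's value is the length-weighted mean of the record
#' values overlapping it; bins with no overlapping record are masked.
#' Chromosomes absent from the layout are skipped with a warning.
#'
#' @param path bedGraph file (4 columns, no header; `track`/`#` lines are
#'   ignored).
#' @param layout A [genome_layout()].
#' @param key A [track_key()].
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, key) {
  stopifnot(inherits(layout, "genome_layout"), inherits(key, "track_key"))
  df <- read_bed_like(path, 4L, c("chrom", "start", "end", "value"))
  vals <- rep(NA_real_, layout$total_bins)
  if (nrow(df) > 0) {
    keep <- df$chrom %in% names(layout$chrom_sizes)
    if (!all(keep)) {
      warning("skipping ", sum(!keep), " record(s) on chromosome(s) ",
              paste(unique(df$chrom[!keep]), collapse = ", "),
              " absent from layout")
      df <- df[keep, , drop = FALSE]
    }
  }
  if (nrow(df) > 0) {
    binned <- bin_records(df, layout, weight = df$value)
    covered <- binned$len > 0
    vals[covered] <- binned$sum[covered] / binned$len[covered]
  }
  binned_track(key, vals, layout)
}

# Shared bed-like reader with per-line validation.
read_bed_like <- function(path, min_cols, col_names) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = min_cols)),
                           col_names))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < min_cols)
  if (length(bad) > 0)
    stop("malformed line ", lineno[bad[1]], " in ", path, ": expected >= ",
         min_cols, " tab-separated fields")
  get <- function(i) vapply(parts, `[[`, "", i)
  df <- data.frame(chrom = get(1),
                   start = suppressWarnings(as.numeric(get(2))),
                   end = suppressWarnings(as.numeric(get(3))),
                   stringsAsFactors = FALSE)
  # a 4-column file is bedGraph-like (numeric value); in BED6 the 4th
  # column is the free-text name
  if (min_cols == 4) df$value <- suppressWarnings(as.numeric(get(4)))
  if (min_cols >= 6) {
    df$value <- get(4)
    df$score <- get(5)
    df$strand <- get(6)
  }
  bad <- which(is.na(df$start) | is.na(df$end) |
                 (min_cols == 4 & is.na(df$value)))
  if (length(bad) > 0)
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinate or value")
  bad <- which(df$end <= df$start)
  if (length(bad) > 0)
    stop("record error at line ", lineno[bad[1]], " in ", path,
         ": end <= start")
  names(df)[seq_along(col_names)] <- col_names
  df
}

# Length-weighted accumulation of records into layout bins via run-length
# coverage: per base, sum of weights and covered length, then per-bin sums.
bin_records <- function(df, layout, weight) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = NULL)
  sizes <- layout$chrom_sizes
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- as.integer(sizes))
  # clip records past the chromosome end
  gr <- GenomicRanges::trim(gr)
  cov_w <- GenomicRanges::coverage(gr, weight = weight)
  cov_n <- GenomicRanges::coverage(gr)
  sums <- numeric(layout$total_bins)
  lens <- numeric(layout$total_bins)
  for (ch in names(sizes)) {
    nb <- layout$n_bins[[ch]]
    starts <- (seq_len(nb) - 1L) * layout$bin_bp + 1L
    ends <- pmin(starts + layout$bin_bp - 1L, as.integer(sizes[[ch]]))
    idx <- layout$bin_offset[[ch]] + seq_len(nb)
    sums[idx] <- IRanges::viewSums(IRanges::Views(cov_w[[ch]], starts, ends))
    lens[idx] <- IRanges::viewSums(IRanges::Views(cov_n[[ch]], starts, ends))
  }
  list(sum = sums, len = lens)
}

#' Subtract an input (control) track from a treatment track
#'
#' Applies to histone marks: the input is depth-scaled so both tracks carry
#' equal total unmasked signal (the input keeps the treatment's scale), then
#' subtracted per bin and floored at zero. The result's mask is the union of
#' both masks.
#'
#' @param treatment,input_ctrl [binned_track()]s on the same layout.
#' @return A [binned_track()] with the treatment's key.
#' @export
subtract_input <- function(treatment, input_ctrl) {
  stopifnot(inherits(treatment, "binned_track"),
            inherits(input_ctrl, "binned_track"))
  if (length(treatment$values) != length(input_ctrl$values))
    stop("dimension error: tracks are binned on different layouts")
  t_tot <- sum(treatment$values[!treatment$mask])
  i_tot <- sum(input_ctrl$values[!input_ctrl$mask])
  f <- if (i_tot > 0) t_tot / i_tot else 0
  vals <- pmax(0, treatment$values - f * input_ctrl$values)
  vals[treatment$mask | input_ctrl$mask] <- NA_real_
  binned_track(treatment$key, vals, treatment$layout)
}

#' Read a per-locus methylation table onto a binned layout
#'
#' BED-like rows `(chrom, start, end, beta)` with beta in \[0, 1\] (e.g.
#' per-CpG methylation fractions). A bin's beta is the coverage-unweighted
#' mean of the betas of loci whose start falls in the bin; bins with no loci
#' are masked.
#'
#' @inheritParams read_bedgraph
#' @return A [binned_track()] (mark should be METH).
#' @export
read_methylation <- function(path, layout, key) {
  stopifnot(inherits(layout, "genome_layout"), inherits(key, "track_key"))
  df <- read_bed_like(path, 4L, c("chrom", "start", "end", "beta"))
  if (nrow(df) > 0 && any(df$beta < 0 | df$beta > 1))
    stop("beta outside [0,1] in ", path)
  vals <- rep(NA_real_, layout$total_bins)
  df <- df[df$chrom %in% names(layout$chrom_sizes) &
             df$start < layout$chrom_sizes[df$chrom], , drop = FALSE]
  if (nrow(df) > 0) {
    bin <- layout$bin_offset[df$chrom] + df$start %/% layout$bin_bp + 1L
    agg <- rowsum(cbind(df$beta, 1), group = bin)
    idx <- as.integer(rownames(agg))
    vals[idx] <- agg[, 1] / agg[, 2]
  }
  binned_track(key, vals, layout)
}

#' Write clusters to a BED6 file
#'
#' One line per member region: `name` is the cluster id, `score` the cluster
#' size, `strand` the member orientation (`-` when flipped). The member's
#' alignment offset (in bins) is appended to the name as `|off=<k>` so the
#' file round-trips losslessly through [read_cluster_bed()].
#'
#' @param clusters A list of `epi_cluster` objects (or an `episig_fit`).
#' @param regions Tibble of region anchors (`chrom`, `start`) indexed by the
#'   clusters' `region_index`, e.g. `tensor$regions`.
#' @param layout The [genome_layout()] (for the window width).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_cluster_bed <- function(clusters, regions, layout, path) {
  if (inherits(clusters, "episig_fit")) clusters <- clusters$clusters
  rows <- purrr::map_dfr(clusters, function(cl) {
    m <- cl$members
    tibble::tibble(
      chrom = regions$chrom[m$region_index],
      start = regions$start[m$region_index],
      end = regions$start[m$region_index] + layout$window_bp,
      name = sprintf("cluster%d|off=%d", cl$id, m$offset),
      score = nrow(m),
      strand = ifelse(m$flip, "-", "+"))
  })
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read clusters back from a BED6 file written by [write_cluster_bed()]
#'
#' @param path BED6 file.
#' @return Tibble with columns `chrom`, `start`, `end`, `cluster`,
#'   `size`, `offset`, `flip`.
#' @export
read_cluster_bed <- function(path) {
  df <- read_bed_like(path, 6L,
                      c("chrom", "start", "end", "name", "score", "strand"))
  name <- df$name
  tibble::tibble(
    chrom = df$chrom,
    start = as.integer(df$start),
    end = as.integer(df$end),
    cluster = as.integer(sub("^cluster(\\d+)\\|.*$", "\\1", name)),
    size = as.integer(df$score),
    offset = as.integer(sub("^.*\\|off=(-?\\d+)$", "\\1", name)),
    flip = df$strand == "-")
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group`, `mark`, `path` and optional
#' `input_path` (for histone marks).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- tibble::as_tibble(utils::read.table(
    path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  need <- c("sample_id", "group", "mark", "path")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (!all(df$mark %in% mark_levels()))
    stop("unknown mark(s): ",
         paste(setdiff(df$mark, mark_levels()), collapse = ", "))
  df
}

#' Load all tracks listed in a sample sheet
#'
#' Reads each listed file ([read_bedgraph()] for signal marks,
#' [read_methylation()] for METH) and subtracts the matched input from
#' histone-mark tracks when `input_path` is given.
#'
#' @param sheet Tibble from [read_sample_sheet()] (or equivalent).
#' @param layout A [genome_layout()].
#' @return Named list of [binned_track()]s (`sample_id:mark`).
#' @export
load_tracks <- function(sheet, layout) {
  tracks <- purrr::pmap(sheet, function(sample_id, group, mark, path, ...) {
    key <- track_key(sample_id, mark, group)
    tr <- if (mark == "METH") read_methylation(path, layout, key)
          else read_bedgraph(path, layout, key)
    dots <- list(...)
    ip <- dots$input_path
    if (!is.null(ip) && !is.na(ip) && nzchar(ip) && mark %in% histone_marks()) {
      tr <- subtract_input(tr, read_bedgraph(ip, layout, key))
    }
    tr
  })
  names(tracks) <- paste(sheet$sample_id, sheet$mark, sep = ":")
  tracks
}
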