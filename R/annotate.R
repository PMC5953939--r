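# Regions tibble (chrom, start, end) -> GRanges (0-based half-open input).
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

#' Build a feature set
#'
#' Sorted, merged half-open interval set for one genomic feature class
#' (exon, intron, intergenic, UTRs, TSS, CpG island, gene body, ...).
#'
#' @param name Feature name.
#' @param intervals Tibble/data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A `feature_set`: list with `name` and merged `intervals`.
#' @export
feature_set <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$end > intervals$start))
  gr <- GenomicRanges::reduce(regions_to_granges(intervals))
  merged <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  merged <- dplyr::arrange(merged, .data$chrom, .data$start)
  structure(list(name = name, intervals = merged), class = "feature_set")
}

#' Member regions of a cluster, as genomic intervals
#'
#' @param cluster An `epi_cluster`.
#' @param regions Region-anchor tibble indexed by `region_index`
#'   (e.g. `tensor$regions` or `fit$regions`).
#' @param layout A [genome_layout()].
#' @return Tibble `chrom`, `start`, `end`, `strand`.
#' @export
cluster_regions <- function(cluster, regions, layout) {
  m <- cluster$members
  tibble::tibble(chrom = regions$chrom[m$region_index],
                 start = regions$start[m$region_index],
                 end = regions$start[m$region_index] + layout$window_bp,
                 strand = ifelse(m$flip, "-", "+"))
}

#' Feature coverage of a cluster
#'
#' Percentage of the cluster's member regions overlapping the feature set
#' by at least 1 bp.
#'
#' @param regions Tibble of member intervals (`chrom`, `start`, `end`),
#'   e.g. from [cluster_regions()].
#' @param features A [feature_set()] (or plain interval tibble).
#' @return Percentage in \[0, 100\].
#' @export
feature_coverage <- function(regions, features) {
  if (inherits(features, "feature_set")) features <- features$intervals
  if (nrow(regions) == 0) stop("empty cluster")
  if (nrow(features) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(regions_to_granges(regions),
                                       regions_to_granges(features))
  100 * mean(hits > 0)
}

#' Chromosome occupancy of a cluster
#'
#' Fraction of member regions per chromosome, normalized for chromosome
#' length and cluster size: `raw_c = n_c / n`, divided by the
#' chromosome's share of the genome, then re-normalized to sum 1. Under a
#' uniform genome-wide placement every chromosome scores the same.
#'
#' @param regions Tibble of member intervals (`chrom`, ...).
#' @param layout A [genome_layout()].
#' @return Named numeric vector over the layout's chromosomes, summing
#'   to 1 (all zeros for an empty cluster).
#' @export
chromosome_occupancy <- function(regions, layout) {
  chroms <- names(layout$chrom_sizes)
  n <- nrow(regions)
  raw <- table(factor(regions$chrom, levels = chroms)) / max(n, 1)
  share <- layout$chrom_sizes / sum(layout$chrom_sizes)
  norm <- as.vector(raw) / share
  tot <- sum(norm)
  if (tot > 0) norm <- norm / tot
  stats::setNames(as.vector(norm), chroms)
}

#' Assign regions to genes by regulatory domains
#'
#' Basal-plus-extension rule: each gene owns a strand-aware basal domain
#' (`basal_up` bp upstream to `basal_down` bp downstream of its TSS),
#' extended outward to the basal domain of the nearest neighboring gene
#' (by TSS order on the chromosome) but no further than `max_ext` bp from
#' the TSS; the gene's own basal domain is always retained. A region is
#' assigned to every gene whose regulatory domain it overlaps by >= 1 bp.
#'
#' @param regions Tibble of intervals (`chrom`, `start`, `end`).
#' @param genes Tibble with `gene`, `chrom`, `tss`, `strand` (`+`/`-`).
#' @param basal_up,basal_down Basal domain extent (default 5000 / 1000 bp).
#' @param max_ext Maximum extension from the TSS (default 1e6 bp).
#' @return Tibble (`chrom`, `start`, `end`, `gene`), one row per
#'   region-gene assignment; regions with no gene are absent.
#' @export
assign_to_genes <- function(regions, genes, basal_up = 5000,
                            basal_down = 1000, max_ext = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-")))
    stop("missing or invalid strand")
  dom <- regulatory_domains(genes, basal_up, basal_down, max_ext)
  if (nrow(regions) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene = character()))
  ov <- GenomicRanges::findOverlaps(
    regions_to_granges(regions),
    regions_to_granges(dom[, c("chrom", "start", "end")]))
  tibble::tibble(
    chrom = regions$chrom[S4Vectors::queryHits(ov)],
    start = regions$start[S4Vectors::queryHits(ov)],
    end = regions$end[S4Vectors::queryHits(ov)],
    gene = dom$gene[S4Vectors::subjectHits(ov)])
}

#' Regulatory domains of genes (basal plus extension)
#'
#' @inheritParams assign_to_genes
#' @return Tibble `gene`, `chrom`, `start`, `end`, `basal_start`,
#'   `basal_end`.
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               max_ext = 1e6) {
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$chrom, .data$tss)
  basal_start <- ifelse(genes$strand == "+",
                        genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(genes$strand == "+",
                      genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(basal_start, 0)
  out <- genes
  out$basal_start <- basal_start
  out$basal_end <- basal_end
  parts <- split(seq_len(nrow(out)), out$chrom)
  start <- numeric(nrow(out)); end <- numeric(nrow(out))
  for (idx in parts) {
    bs <- out$basal_start[idx]; be <- out$basal_end[idx]
    tss <- out$tss[idx]
    n <- length(idx)
    prev_end <- c(0, be[-n])                # nearest preceding basal edge
    next_start <- c(bs[-1], Inf)            # nearest following basal edge
    left <- pmin(bs, pmax(tss - max_ext, prev_end))
    right <- pmax(be, pmin(tss + max_ext, next_start))
    start[idx] <- pmax(left, 0)
    end[idx] <- right
  }
  out$start <- start
  out$end <- end
  out[, c("gene", "chrom", "start", "end", "basal_start", "basal_end")]
}

#' Average fold change of DMERs per gene
#'
#' Arithmetic mean of the log2 fold changes of all DMERs assigned to each
#' gene; genes with no assigned DMER are omitted.
#'
#' @param assignments Tibble with `gene` and `log2_fold_change`, e.g. the
#'   join of [assign_to_genes()] output with [call_dmers()] records.
#' @return Tibble `gene`, `mean_log2_fold_change`, `n_dmers`.
#' @export
average_fold_change <- function(assignments) {
  stopifnot(all(c("gene", "log2_fold_change") %in% names(assignments)))
  assignments |>
    dplyr::filter(!is.na(.data$log2_fold_change)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mean_log2_fold_change = mean(.data$log2_fold_change),
                     n_dmers = dplyr::n(), .groups = "drop")
}
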