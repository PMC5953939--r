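# Welch t-test p-value from two sample vectors, robust to zero variance.
welch_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if ((vx + vy) < 1e-20) return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially modified regions between groups, per mark
#'
#' For each region and mark, the per-sample mean normalized window signal
#' is compared between case and control with a Welch t-test;
#' Benjamini-Hochberg adjustment is applied across regions within each
#' mark. A region is a DMER for a non-METH mark when `q < q_max`; for
#' METH when `|delta_beta| > meth_delta` and `q < meth_q` (the
#' methylation call mirrors the stricter differential-methylation
#' thresholds). Marks with fewer than 2 samples in either group are
#' skipped with a warning.
#'
#' @param tensor A `region_tensor` whose `track_index` carries `group`.
#' @param q_max FDR threshold for non-METH marks (default 0.05).
#' @param meth_delta Minimum |delta beta| for METH (default 0.05).
#' @param meth_q FDR threshold for METH (default 0.0015).
#' @return Tibble with one row per region x tested mark: `chrom`, `start`,
#'   `region_index`, `mark`, `log2_fold_change`, `delta_beta` (METH only,
#'   else NA), `p`, `q`, `is_dmer`.
#' @export
call_dmers <- function(tensor, q_max = 0.05, meth_delta = 0.05,
                       meth_q = 0.0015) {
  stopifnot(inherits(tensor, "region_tensor"))
  ti <- tensor$track_index
  R <- dim(tensor$tensor)[1]
  if (R == 0) return(tibble::tibble())
  # per-sample mean window signal: regions x tracks
  m <- apply(tensor$tensor, c(1, 2), mean)
  m <- matrix(m, nrow = R)
  out <- purrr::map_dfr(intersect(mark_levels(), unique(ti$mark)),
                        function(mk) {
    case <- which(ti$mark == mk & ti$group == "case")
    ctrl <- which(ti$mark == mk & ti$group == "control")
    if (length(case) < 2 || length(ctrl) < 2) {
      warning("mark ", mk, " skipped: fewer than 2 samples in a group")
      return(tibble::tibble())
    }
    mc <- m[, case, drop = FALSE]; mo <- m[, ctrl, drop = FALSE]
    mu_c <- rowMeans(mc); mu_o <- rowMeans(mo)
    p <- vapply(seq_len(R), function(r) welch_p(mc[r, ], mo[r, ]),
                numeric(1))
    q <- bh_adjust(p)
    lfc <- log2((mu_c + 1e-6) / (mu_o + 1e-6))
    delta <- if (mk == "METH") mu_c - mu_o else NA_real_
    is_dmer <- if (mk == "METH") abs(delta) > meth_delta & q < meth_q
               else q < q_max
    tibble::tibble(chrom = tensor$regions$chrom,
                   start = tensor$regions$start,
                   region_index = seq_len(R), mark = mk,
                   log2_fold_change = lfc, delta_beta = delta,
                   p = p, q = q, is_dmer = is_dmer)
  })
  out
}

#' Call differentially expressed genes from a count matrix
#'
#' Counts are library-size normalized by the median-of-ratios method
#' (size factor = median ratio of a sample's counts to the per-gene
#' geometric mean over genes with all-positive counts), then tested per
#' gene with a Welch t-test on `log2(normalized + 1)`. A gene is a DEG
#' when its fold change is at least `fc_min` (in either direction) and
#' the BH-adjusted p-value is below `q_max`. Genes with all-zero counts
#' are excluded with a message.
#'
#' @param counts Non-negative gene x sample count matrix (row names =
#'   gene ids).
#' @param groups Character/factor vector per sample, values `"case"` /
#'   `"control"`.
#' @param fc_min Minimum fold change (default 2, i.e. two-fold).
#' @param q_max FDR threshold (default 0.05).
#' @return Tibble per tested gene: `gene`, `log2_fold_change`,
#'   `p`, `q`, `is_deg`, `direction` (`"over"` / `"under"` expressed in
#'   the case group).
#' @export
call_degs <- function(counts, groups, fc_min = 2, q_max = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(groups), all(counts >= 0))
  groups <- as.character(groups)
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero counts excluded")
    counts <- counts[!zero, , drop = FALSE]
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    stats::median(col / geo))
  norm <- sweep(counts, 2, sf, "/")
  lx <- log2(norm + 1)
  case <- groups == "case"; ctrl <- groups == "control"
  if (sum(case) < 2 || sum(ctrl) < 2)
    stop("need >= 2 samples per group")
  lfc <- rowMeans(lx[, case, drop = FALSE]) -
    rowMeans(lx[, ctrl, drop = FALSE])
  p <- vapply(seq_len(nrow(lx)), function(g)
    welch_p(lx[g, case], lx[g, ctrl]), numeric(1))
  q <- bh_adjust(p)
  tibble::tibble(gene = rownames(counts),
                 log2_fold_change = lfc, p = p, q = q,
                 is_deg = abs(lfc) >= log2(fc_min) & q < q_max,
                 direction = ifelse(lfc >= 0, "over", "under"))
}

#' Hypergeometric DMER enrichment of clusters
#'
#' The universe is the set of clustered regions; `K` of them carry at
#' least one DMER passing the stringent threshold (`q < dmer_q_strict`; a
#' region with strict DMERs in several marks counts once). For a cluster
#' of `n` regions with `k` DMER regions, the p-value is the exact
#' upper-tail hypergeometric probability `P(X >= k)`; q-values are BH
#' across clusters and a cluster is flagged `selected` when `q < 0.05`
#' (the associated-gene-count filter is applied downstream by
#' [select_clusters()]).
#'
#' @param fit An `episig_fit` (or list of `epi_cluster`).
#' @param dmers Tibble from [call_dmers()] over the same region universe
#'   (`region_index` matching the fit's tensor).
#' @param dmer_q_strict Stringent DMER q threshold (default 0.01).
#' @return Tibble per cluster: `cluster`, `n_regions_in_cluster`,
#'   `n_dmers_in_cluster`, `p`, `q`, `selected`.
#' @export
hypergeom_enrichment <- function(fit, dmers, dmer_q_strict = 0.01) {
  clusters <- if (inherits(fit, "episig_fit")) fit$clusters else fit
  stopifnot(length(clusters) > 0)
  universe <- sort(unique(unlist(lapply(clusters,
                                        function(cl) cl$members$region_index))))
  # stringent threshold applies to the signal marks; METH keeps its own
  # (already stricter) differential-methylation call
  strict <- dmers$region_index[
    (dmers$mark != "METH" & dmers$q < dmer_q_strict) |
      (dmers$mark == "METH" & dmers$is_dmer)]
  hits <- intersect(unique(strict), universe)
  N <- length(universe); K <- length(hits)
  res <- purrr::map_dfr(clusters, function(cl) {
    idx <- cl$members$region_index
    n <- length(idx); k <- length(intersect(idx, hits))
    if (k > n || K > N) stop("consistency error: k > n or K > N")
    tibble::tibble(cluster = cl$id, n_regions_in_cluster = n,
                   n_dmers_in_cluster = k,
                   p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$q <- bh_adjust(res$p)
  res$selected <- res$q < 0.05
  res
}

#' Final cluster selection for pathway prioritization
#'
#' Retains clusters with significant DMER enrichment (`q < q_max`) and
#' more than `min_genes` associated genes.
#'
#' @param results Tibble from [hypergeom_enrichment()].
#' @param genes_per_cluster Named vector or tibble (`cluster`, `n_genes`)
#'   of associated-gene counts per cluster.
#' @param q_max Enrichment FDR threshold (default 0.05).
#' @param min_genes Genes must exceed this count (default 200).
#' @return Vector of retained cluster ids.
#' @export
select_clusters <- function(results, genes_per_cluster, q_max = 0.05,
                            min_genes = 200) {
  if (is.data.frame(genes_per_cluster)) {
    gn <- stats::setNames(genes_per_cluster$n_genes,
                          genes_per_cluster$cluster)
  } else gn <- genes_per_cluster
  g <- gn[as.character(results$cluster)]
  g[is.na(g)] <- 0
  results$cluster[results$q < q_max & g > min_genes]
}

#' Mark composition of a cluster's DMERs
#'
#' Percentage of a cluster's DMER calls attributable to each mark.
#'
#' @param cluster An `epi_cluster`.
#' @param dmers Tibble from [call_dmers()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
dmer_composition <- function(cluster, dmers) {
  stopifnot(inherits(cluster, "epi_cluster"))
  d <- dmers[dmers$is_dmer & dmers$region_index %in%
               cluster$members$region_index, , drop = FALSE]
  if (nrow(d) == 0) stop("cluster has no DMERs")
  tab <- table(d$mark)
  stats::setNames(100 * as.vector(tab) / sum(tab), names(tab))
}
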