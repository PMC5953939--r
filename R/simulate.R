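# Shape helpers on a B-bin window (positions in (0,1] of the window).
shape_peak <- function(B, center, width, height) {
  x <- (seq_len(B) - 0.5) / B
  height * exp(-(x - center)^2 / (2 * width^2))
}
shape_ramp <- function(B, from, to, height) {
  x <- (seq_len(B) - 0.5) / B
  h <- rep(0, B)
  inside <- x >= from & x <= to
  h[inside] <- height * (x[inside] - from) / (to - from)
  h[x > to] <- height
  h
}

#' Library of chromatin-state archetypes
#'
#' Six planted templates (marks x bins, values in \[0, 1\]) mirroring
#' canonical chromatin states: active promoter, active enhancer, bivalent
#' promoter, transcribed, Polycomb-repressed and heterochromatin. Peak
#' positions are deliberately off-center and ramps one-sided so planted
#' orientation flips are identifiable. METH rows are absolute beta
#' targets around a methylated background of 0.8, dipping at active
#' elements.
#'
#' @param bins Bins per window (default 25).
#' @return Named list of `archetype` objects: `id`, `section_label`,
#'   `profile` (matrix [mark_levels()] x bins).
#' @export
archetype_library <- function(bins = 25) {
  B <- bins
  blank <- function() {
    m <- matrix(0, nrow = length(mark_levels()), ncol = B,
                dimnames = list(mark_levels(), NULL))
    m["METH", ] <- 0.8
    m
  }
  mk <- function(id, label, rows) {
    m <- blank()
    for (nm in names(rows)) m[nm, ] <- rows[[nm]]
    structure(list(id = id, section_label = label, profile = m),
              class = "archetype")
  }
  # Archetypes are told apart by which marks carry signal, not by peak
  # position: alignment shifts cancel positional differences, and the
  # sigmoid normalization saturates tall peaks, so on/off mark contrasts
  # are what survive the pipeline.
  list(
    active_promoter = mk(1L, "active_promoter", list(
      H3K4me3 = shape_peak(B, 0.40, 0.10, 0.95),
      H3K27ac = shape_peak(B, 0.40, 0.14, 0.85),
      ATAC    = shape_peak(B, 0.40, 0.07, 0.90),
      RNA     = shape_ramp(B, 0.45, 0.90, 0.80),
      METH    = 0.8 - shape_peak(B, 0.40, 0.12, 0.70))),
    active_enhancer = mk(2L, "active_enhancer", list(
      H3K4me1 = pmin(1, shape_peak(B, 0.30, 0.08, 0.90) +
                        shape_peak(B, 0.58, 0.08, 0.75)),
      H3K27ac = shape_peak(B, 0.44, 0.10, 0.80),
      ATAC    = shape_peak(B, 0.30, 0.06, 0.65),
      METH    = 0.8 - shape_peak(B, 0.35, 0.15, 0.60))),
    bivalent = mk(3L, "bivalent", list(
      H3K4me3  = shape_peak(B, 0.45, 0.09, 0.90),
      H3K27me3 = shape_ramp(B, 0.15, 0.60, 0.80),
      ATAC     = shape_peak(B, 0.45, 0.06, 0.45),
      METH     = 0.8 - shape_peak(B, 0.45, 0.15, 0.65))),
    transcribed = mk(4L, "transcribed", list(
      # Bounded gene-body domain (sharp 5' onset, softer 3' falloff) and
      # irregular exon-like RNA bumps: edge-free monotone ramps are nearly
      # invariant under mirror + translation, so planted offsets/flips
      # would be unidentifiable.
      H3K36me3 = shape_ramp(B, 0.12, 0.20, 0.90) -
                 shape_ramp(B, 0.76, 0.92, 0.90),
      RNA      = pmin(1, shape_peak(B, 0.28, 0.05, 0.85) +
                         shape_peak(B, 0.50, 0.05, 0.50) +
                         shape_peak(B, 0.68, 0.05, 0.70)),
      METH     = 0.85 - shape_peak(B, 0.12, 0.06, 0.55))),
    polycomb = mk(5L, "polycomb", list(
      # Off-center domain with a sharp 5' nucleation spike and slow 3'
      # falloff keeps planted orientation and shift identifiable.
      H3K27me3 = pmin(0.95, shape_ramp(B, 0.10, 0.18, 0.70) -
                            shape_ramp(B, 0.62, 0.90, 0.70) +
                            shape_peak(B, 0.16, 0.04, 0.35)),
      METH     = 0.8 - shape_ramp(B, 0.10, 0.30, 0.40) +
                 shape_ramp(B, 0.64, 0.92, 0.35))),
    heterochromatin = mk(6L, "heterochromatin", list(
      H3K9me3  = pmax(0, shape_ramp(B, 0.12, 0.20, 0.90) -
                         shape_ramp(B, 0.66, 0.94, 0.90)),
      H3K36me3 = shape_peak(B, 0.30, 0.06, 0.25),
      METH     = rep(0.85, B)))
  )
}

# Reverse/shift a template row into window bins: content[j] = t_f[j - s],
# zero (or NA) outside.
place_row <- function(row, shift, flip) {
  B <- length(row)
  r <- if (flip) rev(row) else row
  out <- rep(NA_real_, B)
  j <- seq_len(B)
  src <- j - shift
  ok <- src >= 1 & src <= B
  out[j[ok]] <- r[src[ok]]
  out
}

#' Generate a synthetic multi-sample multi-mark epigenomic landscape
#'
#' Emulates the data structure of a two-group, multi-sample, multi-assay
#' study: per sample, six histone-mark tracks (each sharing one
#' baseline-only input track), ATAC, RNA coverage and a METH beta track.
#' Background bins carry lognormal read-depth noise around `baseline`;
#' planted windows add `amplitude` times an archetype template, shifted by
#' a per-region sub-window offset, orientation-flipped with probability
#' `flip_prob`, plus Normal(0, `noise_sd`) template noise per sample.
#' Differential regions multiply the template contribution by
#' `2^effect_log2` in case-group samples only, on `effect_marks`. METH
#' tracks are emitted as beta values clipped to \[0, 1\].
#'
#' @param chrom_sizes Named vector of chromosome sizes (default a 10 Mb
#'   toy genome over two chromosomes).
#' @param n_archetypes Number of planted archetypes, taken in order from
#'   [archetype_library()] (default 4).
#' @param regions_per_archetype Planted windows per archetype (default 60).
#' @param samples_per_group Samples in each of the two groups (default 11,
#'   the case/control design the method targets).
#' @param noise_sd Per-bin template noise SD on the \[0, 1\] template
#'   scale (default 0.05).
#' @param max_shift_bins Planted shifts are uniform on
#'   `[-max_shift_bins, max_shift_bins]` (default 5).
#' @param flip_prob Orientation-flip probability (default 0.5).
#' @param frac_differential Fraction of planted regions with a group
#'   effect (default 0.1).
#' @param effect_log2 Log2 amplitude effect in case samples (default 1,
#'   i.e. two-fold).
#' @param effect_marks Marks carrying the effect (default: all signal
#'   marks). The effect multiplies the template contribution, so it only
#'   materializes on marks the region's archetype actually expresses: the
#'   default makes a differential region a uniformly stronger copy of its
#'   own chromatin state in the case group.
#' @param window_bp,bin_bp Layout parameters (defaults 5000 / 200).
#' @param baseline,baseline_cv Background read depth and its lognormal
#'   sdlog (defaults 1, 0.25).
#' @param amplitude Planted signal height in background units (default 3,
#'   a typical enrichment over background).
#' @param meth_baseline Background methylation beta (default 0.8).
#' @param rng_seed Integer seed; the output is fully reproducible.
#' @param out_dir If given, writes `chrom.sizes`, per-track bedGraph /
#'   methylation BED files, `samples.tsv` and `truth.tsv` there.
#' @return List with `layout`, `tracks` (named list of raw
#'   [binned_track()]s, inputs included as mark-less `input` entries per
#'   sample), `sample_sheet`, `truth` (tibble: `chrom`, `start`,
#'   `archetype`, `section_label`, `shift`, `flip`, `is_differential`,
#'   `effect_marks`, `effect_log2`), and `archetypes`.
#' @export
make_landscape <- function(chrom_sizes = c(chr1 = 6e6, chr2 = 4e6),
                           n_archetypes = 4, regions_per_archetype = 60,
                           samples_per_group = 11, noise_sd = 0.05,
                           max_shift_bins = 5, flip_prob = 0.5,
                           frac_differential = 0.1, effect_log2 = 1,
                           effect_marks = setdiff(mark_levels(), "METH"),
                           window_bp = 5000, bin_bp = 200,
                           baseline = 1, baseline_cv = 0.25, amplitude = 3,
                           meth_baseline = 0.8, rng_seed = 0,
                           out_dir = NULL) {
  layout <- genome_layout(chrom_sizes, window_bp, bin_bp)
  B <- layout$bins_per_window
  arch <- archetype_library(B)[seq_len(n_archetypes)]
  anchors <- window_anchors(layout)
  n_plant <- n_archetypes * regions_per_archetype
  withr::with_seed(as.integer(rng_seed), {
    # greedy spaced placement: planted windows never adjacent
    cand <- sample.int(nrow(anchors))
    chosen <- integer(0)
    taken <- new.env(hash = TRUE)
    for (i in cand) {
      key <- function(k) paste0(anchors$chrom[i], ":", anchors$start[i] +
                                  k * window_bp)
      if (!is.null(taken[[key(0)]]) || !is.null(taken[[key(-1)]]) ||
          !is.null(taken[[key(1)]])) next
      chosen <- c(chosen, i)
      taken[[key(0)]] <- TRUE
      if (length(chosen) == n_plant) break
    }
    if (length(chosen) < n_plant)
      stop("placement overflow: genome too small for ", n_plant,
           " spaced windows")
    chosen <- sort(chosen)
    truth <- tibble::tibble(
      chrom = anchors$chrom[chosen],
      start = anchors$start[chosen],
      archetype = rep(seq_len(n_archetypes),
                      length.out = n_plant)[sample.int(n_plant)],
      shift = sample(seq(-max_shift_bins, max_shift_bins), n_plant,
                     replace = TRUE),
      flip = stats::runif(n_plant) < flip_prob,
      is_differential = stats::runif(n_plant) < frac_differential,
      effect_log2 = effect_log2)
    truth$section_label <- vapply(truth$archetype, function(a)
      arch[[a]]$section_label, character(1))
    truth$effect_marks <- ifelse(truth$is_differential,
                                 paste(effect_marks, collapse = ","), "")
    samples <- tibble::tibble(
      sample_id = c(sprintf("case_%02d", seq_len(samples_per_group)),
                    sprintf("ctrl_%02d", seq_len(samples_per_group))),
      group = rep(c("case", "control"), each = samples_per_group))
    signal_marks <- setdiff(mark_levels(), "METH")
    tracks <- list()
    nb <- layout$total_bins
    plant_bins <- lapply(seq_len(n_plant), function(r)
      window_bin_indices(layout, truth$chrom[r], truth$start[r]))
    for (si in seq_len(nrow(samples))) {
      sid <- samples$sample_id[si]; grp <- samples$group[si]
      for (mkn in signal_marks) {
        vals <- baseline * exp(stats::rnorm(nb, 0, baseline_cv))
        for (r in seq_len(n_plant)) {
          row <- place_row(arch[[truth$archetype[r]]]$profile[mkn, ],
                           truth$shift[r], truth$flip[r])
          row[is.na(row)] <- 0
          eff <- if (truth$is_differential[r] && grp == "case" &&
                     mkn %in% effect_marks) 2^effect_log2 else 1
          vals[plant_bins[[r]]] <- vals[plant_bins[[r]]] +
            amplitude * eff * pmax(0, row + stats::rnorm(B, 0, noise_sd))
        }
        tracks[[paste(sid, mkn, sep = ":")]] <-
          binned_track(track_key(sid, mkn, grp), vals, layout)
      }
      # METH betas
      vals <- pmin(1, pmax(0, meth_baseline + stats::rnorm(nb, 0, noise_sd)))
      for (r in seq_len(n_plant)) {
        row <- place_row(arch[[truth$archetype[r]]]$profile["METH", ],
                         truth$shift[r], truth$flip[r])
        row[is.na(row)] <- meth_baseline
        if (truth$is_differential[r] && grp == "case" &&
            "METH" %in% effect_marks) row <- row - 0.2
        vals[plant_bins[[r]]] <- pmin(1, pmax(0,
          row + stats::rnorm(B, 0, noise_sd)))
      }
      tracks[[paste(sid, "METH", sep = ":")]] <-
        binned_track(track_key(sid, "METH", grp), vals, layout)
      # shared baseline-only input for the histone marks
      vals <- baseline * exp(stats::rnorm(nb, 0, baseline_cv))
      tracks[[paste(sid, "input", sep = ":")]] <-
        binned_track(track_key(sid, "H3K4me1", grp), vals, layout)
    }
  })
  sheet <- purrr::map_dfr(seq_len(nrow(samples)), function(si)
    tibble::tibble(sample_id = samples$sample_id[si],
                   group = samples$group[si],
                   mark = mark_levels()))
  out <- list(layout = layout, tracks = tracks, truth = truth,
              sample_sheet = sheet, archetypes = arch)
  if (!is.null(out_dir)) out$files <- write_landscape(out, out_dir)
  out
}

# Write a generated landscape to disk (bedGraph / BED / TSV).
write_landscape <- function(landscape, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- landscape$layout
  bt <- bin_table(layout)
  bt$end <- pmin(bt$start + layout$bin_bp,
                 layout$chrom_sizes[bt$chrom])
  sizes_path <- file.path(out_dir, "chrom.sizes")
  data.table::fwrite(data.table::data.table(
    chrom = names(layout$chrom_sizes),
    size = as.integer(layout$chrom_sizes)),
    sizes_path, sep = "\t", col.names = FALSE)
  paths <- character(0)
  for (nm in names(landscape$tracks)) {
    tr <- landscape$tracks[[nm]]
    fn <- file.path(out_dir, paste0(gsub(":", ".", nm), ifelse(
      grepl(":METH$", nm), ".meth.bed", ".bedGraph")))
    # %.17g guarantees the doubles survive the text round trip exactly
    data.table::fwrite(data.table::data.table(
      chrom = bt$chrom, start = as.integer(bt$start),
      end = as.integer(bt$end), value = sprintf("%.17g", tr$values)),
      fn, sep = "\t", col.names = FALSE, quote = FALSE)
    paths[nm] <- fn
  }
  sheet <- landscape$sample_sheet
  sheet$path <- paths[paste(sheet$sample_id, sheet$mark, sep = ":")]
  sheet$input_path <- ifelse(
    sheet$mark %in% histone_marks(),
    paths[paste(sheet$sample_id, "input", sep = ":")], "")
  sheet_path <- file.path(out_dir, "samples.tsv")
  data.table::fwrite(sheet, sheet_path, sep = "\t")
  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(landscape$truth, truth_path, sep = "\t")
  list(chrom_sizes = sizes_path, sample_sheet = sheet_path,
       truth = truth_path, tracks = paths)
}

#' Generate synthetic RNA-seq counts with planted differential genes
#'
#' Negative-binomial counts with lognormal baseline means; a fraction of
#' genes get a fold-change `fc` applied to the case-group mean
#' (alternating over- and under-expressed).
#'
#' @param n_genes Number of genes (default 2000).
#' @param samples_per_group Samples per group (default 10).
#' @param frac_de Fraction of differential genes (default 0.1).
#' @param fc Fold change on differential genes (default 4).
#' @param dispersion NB dispersion (default 0.1).
#' @param rng_seed Integer seed.
#' @return List with `counts` (gene x sample matrix), `groups`, `truth`
#'   (tibble `gene`, `is_de`, `direction`, `log2_fc`).
#' @export
make_counts <- function(n_genes = 2000, samples_per_group = 10,
                        frac_de = 0.1, fc = 4, dispersion = 0.1,
                        rng_seed = 0) {
  stopifnot(n_genes > 0, samples_per_group > 0, fc > 0, dispersion > 0)
  withr::with_seed(as.integer(rng_seed), {
    mu <- exp(stats::rnorm(n_genes, log(100), 1))
    n_de <- round(frac_de * n_genes)
    de <- sample.int(n_genes, n_de)
    dir <- rep(c(1, -1), length.out = n_de)
    groups <- rep(c("case", "control"), each = samples_per_group)
    mu_mat <- matrix(mu, n_genes, 2 * samples_per_group)
    if (n_de > 0)
      mu_mat[de, groups == "case"] <- mu[de] * fc^dir
    counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                    size = 1 / dispersion),
                     n_genes, 2 * samples_per_group)
  })
  rownames(counts) <- sprintf("gene_%04d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("case_%02d", seq_len(samples_per_group)),
                        sprintf("ctrl_%02d", seq_len(samples_per_group)))
  truth <- tibble::tibble(gene = rownames(counts), is_de = FALSE,
                          direction = NA_character_, log2_fc = 0)
  if (n_de > 0) {
    truth$is_de[de] <- TRUE
    truth$direction[de] <- ifelse(dir > 0, "over", "under")
    truth$log2_fc[de] <- dir * log2(fc)
  }
  list(counts = counts, groups = groups, truth = truth)
}

#' Run the full pipeline on in-memory tracks
#'
#' Convenience chain: sigmoid-normalize every track, scan for enriched
#' windows and assemble the region tensor.
#'
#' @param tracks Named list of raw [binned_track()]s (input-subtracted
#'   where applicable; entries named `*:input` are dropped).
#' @param layout A [genome_layout()].
#' @param z_min,min_tracks Passed to [scan_enriched_windows()].
#' @return List with `tracks` (normalized), `windows`, `tensor`.
#' @export
prepare_tensor <- function(tracks, layout, z_min = 2, min_tracks = 1) {
  tracks <- tracks[!grepl(":input$", names(tracks))]
  norm <- lapply(tracks, sigmoid_normalize)
  windows <- scan_enriched_windows(norm, layout, z_min, min_tracks)
  tensor <- build_region_tensor(windows, norm, layout)
  list(tracks = norm, windows = windows, tensor = tensor)
}

#' Exact recovery of planted alignments
#'
#' Compares a fit's member offsets/flips to the generator's truth. A
#' cluster defines its own alignment frame (the seed's orientation and
#' registration), so per cluster the modal frame is estimated first: for
#' each member matched to a planted region, the frame flip is
#' `flip_found XOR flip_true` and the frame registration is
#' `offset + shift_true` when flipped in-frame else `offset - shift_true`.
#' A member is recovered exactly when it agrees with its cluster's modal
#' frame.
#'
#' @param fit An `episig_fit`.
#' @param truth Truth tibble from [make_landscape()].
#' @return List with `fraction_recovered` (over all planted regions;
#'   unassigned planted regions count as misses) and `n_planted`.
#' @export
alignment_recovery <- function(fit, truth) {
  asg <- tidy.episig_fit(fit)
  m <- dplyr::inner_join(truth, asg, by = c("chrom", "start"))
  m <- m[!is.na(m$cluster), , drop = FALSE]
  ok <- 0L
  for (cl in unique(m$cluster)) {
    d <- m[m$cluster == cl, , drop = FALSE]
    fframe <- xor(d$flip.y, d$flip.x)  # found XOR true
    reg <- ifelse(d$flip.y, d$offset + d$shift, d$offset - d$shift)
    key <- paste(fframe, reg)
    modal <- names(which.max(table(key)))
    ok <- ok + sum(key == modal)
  }
  list(fraction_recovered = ok / nrow(truth), n_planted = nrow(truth))
}
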