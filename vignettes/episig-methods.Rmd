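---
title: "EpiSig-style integrative epigenome clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EpiSig-style integrative epigenome clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

episigr clusters fixed-width genomic windows by their joint multi-assay
epigenomic profiles — histone ChIP-seq, ATAC-seq, RNA-seq coverage and
whole-genome bisulfite methylation across many samples — while aligning
windows to each other by sub-window shifts and orientation flips. This
vignette documents the statistical model, the non-obvious design
decisions, and the synthetic-landscape generator used to validate every
stage against planted ground truth.

## 1. Data model

The genome is tiled into non-overlapping windows of `window_bp` (default
5 kb), each subdivided into bins of `bin_bp` (default 200 bp), so a
window is a track × 25-bin matrix. A *track* is one (sample, mark) pair.
After normalization, the windows that carry enriched signal in at least
one track are stacked into a **region tensor**: regions × tracks × bins,
all values in [0, 1]. All downstream stages consume this tensor, which
is the "concatenated data window" idea: all assays and samples are one
wide observation per region, so clustering groups regions by their
joint, cross-assay signature rather than by any single mark.

## 2. Normalization

Read-depth tracks are mapped through a logistic curve

$$y = \frac{1}{1 + e^{-(x - m)/s}}$$

with $m$ the median and $s = 1.4826 \cdot \mathrm{MAD}$ of the unmasked
non-zero bins. Typical background maps near 0.5 and enriched signal
saturates toward 1, which makes tracks of very different sequencing
depths comparable without quantile gymnastics. Methylation beta values
are already bounded in [0, 1] and comparable across samples, so METH
tracks pass through unchanged. Histone tracks are input-subtracted
first: the input is depth-scaled to the treatment's total unmasked
signal, subtracted per bin, and floored at zero.

A consequence worth knowing: the sigmoid *compresses* strong signal.
A two-fold raw difference between groups in an already-enriched window
shrinks to a small difference on the [0, 1] scale, which bounds the
power of downstream differential tests (Section 7).

## 3. Enrichment scan

A window is enriched when, in at least `min_tracks` tracks (default 1),
its mean normalized signal exceeds that track's genome-wide window-mean
median by `z_min` (default 2) robust z-units. The defaults are
deliberately permissive — with hundreds of tracks, one track exceeding
2 robust z-units happens for a large fraction of background windows.
The scan's job is recall (never lose a genuinely co-modified region);
rejecting background is the clustering engine's job, which it does via
its acceptance threshold (Section 5).

## 4. Alignment

Functionally equivalent regions need not have their pattern at the same
sub-window position or orientation. The engine therefore scores a
region slice against a cluster profile over all offsets in
`[-max_shift, max_shift]` bins crossed with both orientations, in C++.

Two different scores are used for two different questions.

**Admission** ("does this region belong?") uses the plain overlap score:
the negative mean squared difference over the columns where profile and
shifted slice overlap (`align_score()`, `best_alignment()`). This score
has the widest margin between genuine members and regions of other
clusters, which is what a threshold test needs.

**Registration** ("at which offset/flip does it belong?") uses a
background-extended variant. The plain overlap mean is biased toward
large offsets: shifting a noisy column out of the overlap removes a
positive contribution from the mean, so the argmax drifts outward from
the true registration. In the extended score, both the profile and the
member are embedded in an infinite background at per-track fill values
(each track's median over all tensor cells). Profile columns left
uncovered by the offset are charged against background, the member's
own overhanging columns are likewise charged, and the sum is divided by
`T * (B + |offset|)`. Every candidate offset is then averaged over the
same effective support, removing the outward bias without introducing a
tunable penalty. A flat per-cell penalty was tried first and rejected:
any fixed quantum either under- or over-corrects and drags truncated
members toward offset zero.

## 5. The clustering engine

Iteratively: select a seed, grow a cluster, remove its members, repeat.

**Seeding.** The seed head is the unassigned region with maximal
intra-region entropy (signal spread over many track × bin cells, i.e.
information-rich). Its `seed_k - 1` nearest partners by
alignment-minimized symmetrized KL divergence complete the seed set.
Partners are best-aligned to the head before the first profile is
averaged — planted shifts would otherwise blur the seed profile and
destroy the cluster's alignment frame at birth.

**Acceptance threshold.** For each seed, background regions sampled
from the whole tensor are aligned to the profile, giving a null score
distribution. The threshold is
$\theta = \max(\text{midpoint of member and background means},\
\text{background mean} + 2\,\mathrm{sd})$, re-estimated against the
current profile whenever it is used — a threshold frozen against the
seed profile drifts away from what it calibrates as members reshape the
profile. Candidates are admitted stochastically with probability
$\sigma((\text{score} - \theta)/T)$ at temperature `5e-4`, small enough
that background admission is rare while genuine members pass with
probability near 1.

**Sweeps and eviction.** Each sweep scores all candidates against the
sweep-start profile (synchronous, batched in C++), admits
stochastically, then realigns all members and evicts any falling below
$\theta$ — without eviction, occasional background admissions
permanently dilute the profile. Member offsets are recentered (the
rounded median offset is subtracted) after every pass: a profile
translation adds a constant to all member offsets, and without
recentering the frame slowly consumes the `max_shift` budget.

**Registration refinement.** A grown cluster's profile can sit at a
stable fixed point in which it mixes two adjacent registrations and
every member ties in expectation. The final refinement therefore (1)
re-anchors all members to the head slice under the extended score, then
(2) alternates batch realignment to its fixed point (stable; settles
orientations) with a sequential leave-one-out pass in which each member
is realigned against the profile minus its own contribution,
constrained to ±1-bin moves with orientation frozen. Unconstrained
sequential refinement is a mistake: frame translation is a near-neutral
direction, so free refinement drifts about one bin per pass and, once
offsets clamp at `max_shift`, scrambles orientations for templates that
resemble their own mirror image.

Clusters smaller than `min_cluster_size` are abandoned and their seed
plus members blacklisted — at the permissive scan defaults most seed
heads are background, and rejecting them one at a time would dominate
the run time.

## 6. Sections: a batch self-organizing map

Each cluster is summarized by one mean profile value per mark, and the
short mark-level vectors are mapped onto a small rectangular grid
(default 3 × 3 = nine sections). The SOM is a *batch* variant: per
epoch, every feature row is assigned to its best-matching unit, and
each node is re-estimated as the Gaussian-neighborhood-weighted mean,
blended with the previous codebook under a linearly decaying learning
rate; the neighborhood radius decays to zero so late epochs are plain
k-means refinement. The batch form was chosen over per-observation
online updates because it is deterministic given the seed and its
quantization error is monotone in the refinement phase — both
properties the test suite asserts. The map is trained from several
seeded restarts and the lowest final quantization error wins: with few
feature rows on a small grid, a single start occasionally lets two
distinct rows collapse onto one node, and a collapsed map always has a
strictly higher quantization error than one that separates them, so
restart selection removes the failure mode without a tunable threshold.

## 7. Differential calls and enrichment

Differentially modified regions (DMERs) are called per region × mark by
a Welch t-test on per-sample mean normalized window signal, BH-adjusted
across regions within each mark. Defaults encode the working
thresholds: non-METH marks `q < 0.05`; METH `|Δβ| > 0.05` and
`q < 0.0015`; differentially expressed genes two-fold and BH `p < 0.05`
on median-of-ratios-normalized counts; stringent DMERs `q < 0.01` for
cluster enrichment; cluster selection `q < 0.05` with more than 200
associated genes. Cluster enrichment is an exact hypergeometric upper
tail: universe = clustered regions, hits = regions carrying at least
one stringent DMER. A worked example: with a universe of 10 regions, 5
of them DMER regions, a cluster of 4 containing all 4 of its regions
as hits gives $P(X \ge 4) = \binom{5}{4}\binom{5}{0}/\binom{10}{4}
= 5/210$.

Gene assignment is by basal-plus-extension regulatory domains (5 kb
upstream / 1 kb downstream basal, extended up to 1 Mb toward the
neighboring gene's basal domain).

## 8. The synthetic generator and its limits

`make_landscape()` plants archetype templates — six canonical chromatin
states distinguished by which marks carry signal — into a 10 Mb toy
genome at spaced windows, with per-region sub-window shifts (uniform in
±5 bins), orientation flips (Bernoulli 0.5), per-sample template noise
(sd 0.05), lognormal background read depth, and a shared baseline-only
input per sample. Differential regions multiply the template
contribution two-fold in case samples, by default on *all* signal
marks, so a differential region is a uniformly stronger copy of its own
chromatin state — an effect restricted to marks the archetype does not
express would be no effect at all.

Two design points are easy to get wrong:

* **Distinguishability.** Alignment cancels peak-position differences
  and the sigmoid saturates peak heights, so archetypes must differ in
  which marks are on, not where peaks sit.
* **Registration identifiability.** A template that nearly equals its
  own mirror image, or its own one-bin translate, plants shifts and
  flips that no algorithm can recover. Monotone one-sided ramps are the
  canonical offender (nearly invariant under mirror + translation
  within a clipped window); the library therefore uses bounded,
  off-center domains with unequal edge widths plus asymmetric secondary
  features (exon-like RNA bumps, a 5' hypomethylated dip, a nucleation
  spike). Every template's mirror mismatch and one-bin translation gap
  exceed a third of the planting noise floor $2\sigma^2$, which the
  test suite asserts.

What the generator does **not** model: read-level sampling, fragment
lengths, GC bias, copy-number variation, mappability gaps, or
correlated replicate structure. It emulates the data *shape* of a
two-group multi-assay study well enough to give every pipeline stage a
ground truth, nothing more.

## 9. A worked run

```{r, eval = FALSE}
library(episigr)

ls <- make_landscape(samples_per_group = 4, rng_seed = 11)
prep <- prepare_tensor(ls$tracks, ls$layout)
fit <- run_episig(prep$tensor, episig_config(rng_seed = 11))
fit
#> <episig_fit> 4 clusters over 1215 regions (240 assigned, 975 unassigned)

alignment_recovery(fit, ls$truth)$fraction_recovered
#> [1] 1

map <- section_clusters(fit, prep$tensor$track_index)
dm  <- call_dmers(prep$tensor)
enr <- hypergeom_enrichment(fit, dm)
```

Every number above is reproducible: all stochastic steps derive from
the `rng_seed` arguments, and the acceptance script
(`scripts/acceptance.R`) re-computes the headline quantities from a
single command-line seed.
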