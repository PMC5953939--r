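#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Copy region i (0-based) of a regions x tracks x bins array into a dense
// tracks x bins (column-major) buffer; the strided gathers happen once so
// the alignment loops below run over contiguous memory.
static void fill_slice(const double *a, int R, int T, int B, int i,
                       std::vector<double> &buf) {
  for (int b = 0; b < B; ++b) {
    const double *col = a + ((size_t)b * T) * R + i;
    double *dst = &buf[(size_t)b * T];
    for (int t = 0; t < T; ++t) dst[t] = col[(size_t)t * R];
  }
}

// Alignment scores of a region slice against a profile for every
// (offset, flip) combination. Matrices are tracks x bins. A flip reverses
// bin order jointly across all tracks; an offset of k compares profile
// column j with slice column j + k. Overhanging columns are excluded from
// the mean. Score = -(mean squared difference); 0 is a perfect match.
// Returns a 2 x (2*max_shift + 1) matrix: row 0 = no flip, row 1 = flip;
// column s corresponds to offset s - max_shift. Overlap-free offsets get
// -Inf.
// [[Rcpp::export]]
NumericMatrix cpp_align_scores(NumericMatrix slice, NumericMatrix profile,
                               int max_shift) {
  const int T = slice.nrow(), B = slice.ncol();
  if (profile.nrow() != T || profile.ncol() != B)
    stop("dimension error: slice and profile shapes differ");
  NumericMatrix out(2, 2 * max_shift + 1);
  for (int f = 0; f < 2; ++f) {
    for (int s = -max_shift; s <= max_shift; ++s) {
      int j0 = std::max(0, -s);        // profile column range [j0, j1)
      int j1 = std::min(B, B - s);
      if (j1 <= j0) {
        out(f, s + max_shift) = R_NegInf;
        continue;
      }
      double ss = 0.0;
      long n = 0;
      for (int j = j0; j < j1; ++j) {
        int sj = j + s;                 // slice column before flip
        int col = f ? (B - 1 - sj) : sj;
        for (int t = 0; t < T; ++t) {
          double d = profile(t, j) - slice(t, col);
          ss += d * d;
          ++n;
        }
      }
      out(f, s + max_shift) = -ss / (double)n;
    }
  }
  return out;
}

// Batched best alignments: for each region index (1-based, into the
// first dimension of a regions x tracks x bins array) find the
// (offset, flip) maximizing the alignment score against the profile,
// with ties broken toward smaller |offset|, then no flip, then the
// smaller signed offset. Returns an n x 3 matrix (offset, flip, score).
//
// With `fill` empty: score = -(mean squared difference over the overlap),
// the plain contract of align_score(). With `fill` = a per-track vector of
// expected background values: both windows are notionally embedded in an
// infinite background at the fill values, so profile columns left
// uncovered by an offset are compared against background, the region's
// own overhanging columns are likewise compared against background, and
// the mean runs over the union of both windows (T * (B + |offset|)
// cells). The plain overlap-mean is biased toward large offsets (clipping
// noisy columns out of the overlap lowers the mean even when it
// misregisters the pattern); charging only the profile side leaves a
// residual outward force (an overlap cell always costs at least the
// noise level, while an excluded background-level profile edge column is
// nearly free). The symmetric embedding removes both biases while still
// charging the true content of every excluded column (excluding a
// template-rich column is expensive).
// [[Rcpp::export]]
NumericMatrix cpp_best_alignments(NumericVector arr, IntegerVector idx,
                                  NumericMatrix profile, int max_shift,
                                  NumericVector fill =
                                      NumericVector::create()) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("arr must be a 3-d array");
  const int R = dims[0], T = dims[1], B = dims[2];
  if (profile.nrow() != T || profile.ncol() != B)
    stop("dimension error: profile shape does not match the tensor");
  const bool use_fill = fill.size() > 0;
  if (use_fill && fill.size() != T)
    stop("dimension error: fill must have one value per track");
  // exclusion cost of each profile column against background, with a
  // prefix-sum so any column range sums in O(1)
  std::vector<double> excum(B + 1, 0.0);
  if (use_fill) {
    for (int j = 0; j < B; ++j) {
      double e = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = profile(t, j) - fill[t];
        e += d * d;
      }
      excum[j + 1] = excum[j] + e;
    }
  }
  const double *a = arr.begin();
  const double *pr = profile.begin();
  std::vector<double> sl((size_t)T * B);
  NumericMatrix out(idx.size(), 3);
  std::vector<double> mcum(B + 1, 0.0);  // region-vs-fill column prefix sums
  for (int r = 0; r < idx.size(); ++r) {
    const int i = idx[r] - 1;
    if (i < 0 || i >= R) stop("region index out of range");
    fill_slice(a, R, T, B, i, sl);
    if (use_fill) {
      for (int c = 0; c < B; ++c) {
        double e = 0.0;
        const double *sc = &sl[(size_t)c * T];
        for (int t = 0; t < T; ++t) {
          double d = sc[t] - fill[t];
          e += d * d;
        }
        mcum[c + 1] = mcum[c] + e;
      }
    }
    double best_sc = R_NegInf;
    int best_off = 0, best_flip = 0;
    for (int f = 0; f < 2; ++f) {
      for (int s = -max_shift; s <= max_shift; ++s) {
        int j0 = std::max(0, -s);
        int j1 = std::min(B, B - s);
        if (j1 <= j0) continue;
        double ss = 0.0;
        long n = 0;
        for (int j = j0; j < j1; ++j) {
          int sj = j + s;
          int col = f ? (B - 1 - sj) : sj;
          const double *pc = pr + (size_t)j * T;
          const double *sc = &sl[(size_t)col * T];
          for (int t = 0; t < T; ++t) {
            double d = pc[t] - sc[t];
            ss += d * d;
            ++n;
          }
        }
        double scv;
        if (!use_fill) scv = -ss / (double)n;
        else {
          double ex = excum[j0] + (excum[B] - excum[j1]);
          // region columns visited by the overlap: sj in [j0+s, j1+s)
          // before the flip, i.e. a contiguous run in either orientation
          int c0 = f ? (B - (j1 + s)) : (j0 + s);
          int c1 = f ? (B - (j0 + s)) : (j1 + s);
          double me = mcum[B] - (mcum[c1] - mcum[c0]);
          int k = s >= 0 ? s : -s;
          scv = -(ss + ex + me) / ((double)T * (B + k));
        }
        bool better = scv > best_sc;
        if (!better && scv == best_sc) {
          if (std::abs(s) < std::abs(best_off)) better = true;
          else if (std::abs(s) == std::abs(best_off)) {
            if (f < best_flip) better = true;
            else if (f == best_flip && s < best_off) better = true;
          }
        }
        if (better) { best_sc = scv; best_off = s; best_flip = f; }
      }
    }
    out(r, 0) = best_off;
    out(r, 1) = best_flip;
    out(r, 2) = best_sc;
  }
  return out;
}

// Shannon entropy (bits) of each indexed region slice viewed as a
// probability distribution over its cells. Errors on negative or all-zero
// slices.
// [[Rcpp::export]]
NumericVector cpp_intra_entropies(NumericVector arr, IntegerVector idx) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("arr must be a 3-d array");
  const int R = dims[0], T = dims[1], B = dims[2];
  const double *a = arr.begin();
  const double log2e = 1.0 / std::log(2.0);
  std::vector<double> sl((size_t)T * B);
  NumericVector out(idx.size());
  for (int r = 0; r < idx.size(); ++r) {
    const int i = idx[r] - 1;
    if (i < 0 || i >= R) stop("region index out of range");
    fill_slice(a, R, T, B, i, sl);
    double tot = 0.0;
    for (size_t k = 0; k < sl.size(); ++k) {
      if (sl[k] < 0) stop("negative signal in region slice");
      tot += sl[k];
    }
    if (tot <= 0) stop("no signal: all-zero slice");
    double h = 0.0;
    for (size_t k = 0; k < sl.size(); ++k)
      if (sl[k] > 0) {
        double p = sl[k] / tot;
        h -= p * std::log(p);
      }
    out[r] = h * log2e;
  }
  return out;
}

// Symmetric Kullback-Leibler divergence (in bits) between two slices,
// minimized over offsets in [-max_shift, max_shift] and flips. For each
// alignment the overlapping columns of both matrices are taken, a
// pseudocount eps is added per cell and each is normalized to sum 1;
// D = 0.5 * [KL(p||q) + KL(q||p)].
// [[Rcpp::export]]
double cpp_min_inter_entropy(NumericMatrix a, NumericMatrix b,
                             int max_shift, double eps) {
  const int T = a.nrow(), B = a.ncol();
  if (b.nrow() != T || b.ncol() != B)
    stop("dimension error: slices have different shapes");
  const double log2e = 1.0 / std::log(2.0);
  double best = R_PosInf;
  std::vector<double> p(T * (size_t)B), q(T * (size_t)B);
  for (int f = 0; f < 2; ++f) {
    for (int s = -max_shift; s <= max_shift; ++s) {
      int j0 = std::max(0, -s);
      int j1 = std::min(B, B - s);
      if (j1 <= j0) continue;
      size_t n = 0;
      double sp = 0.0, sq = 0.0;
      for (int j = j0; j < j1; ++j) {
        int sj = j + s;
        int col = f ? (B - 1 - sj) : sj;
        for (int t = 0; t < T; ++t) {
          double pv = a(t, j) + eps;
          double qv = b(t, col) + eps;
          p[n] = pv; q[n] = qv;
          sp += pv; sq += qv;
          ++n;
        }
      }
      double d = 0.0;
      for (size_t i = 0; i < n; ++i) {
        double pi = p[i] / sp, qi = q[i] / sq;
        d += 0.5 * (pi * std::log(pi / qi) + qi * std::log(qi / pi));
      }
      d *= log2e;
      if (d < best) best = d;
    }
  }
  return best;
}

// Batched alignment-minimized symmetric KL divergences of one head region
// against many candidate regions of a regions x tracks x bins array.
// Identical in value to cpp_min_inter_entropy(head_slice, cand_slice, ...)
// but computed with per-region log tables so the per-alignment inner loop
// is log-free:
//   KL(p||q) = (1/Sa) * sum a_i (log2 a_i - log2 b_i) - log2 Sa + log2 Sb
// where a_i, b_i include the pseudocount and Sa, Sb are their sums over
// the overlapping cells.
// [[Rcpp::export]]
NumericVector cpp_partner_divergences(NumericVector arr, int head,
                                      IntegerVector cand, int max_shift,
                                      double eps) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("arr must be a 3-d array");
  const int R = dims[0], T = dims[1], B = dims[2];
  if (head < 1 || head > R) stop("region index out of range");
  const double *a = arr.begin();
  const double log2e = 1.0 / std::log(2.0);
  const size_t NC = (size_t)T * B;
  std::vector<double> ha(NC), hla(NC), ca(NC), cla(NC);
  std::vector<double> hcol(B), ccol(B);  // per-column sums of value+eps
  fill_slice(a, R, T, B, head - 1, ha);
  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      double v = ha[(size_t)b * T + t] + eps;
      ha[(size_t)b * T + t] = v;
      hla[(size_t)b * T + t] = std::log(v);
      s += v;
    }
    hcol[b] = s;
  }
  NumericVector out(cand.size());
  for (int r = 0; r < cand.size(); ++r) {
    const int i = cand[r] - 1;
    if (i < 0 || i >= R) stop("region index out of range");
    fill_slice(a, R, T, B, i, ca);
    for (int b = 0; b < B; ++b) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) {
        double v = ca[(size_t)b * T + t] + eps;
        ca[(size_t)b * T + t] = v;
        cla[(size_t)b * T + t] = std::log(v);
        s += v;
      }
      ccol[b] = s;
    }
    double best = R_PosInf;
    for (int f = 0; f < 2; ++f) {
      for (int s = -max_shift; s <= max_shift; ++s) {
        int j0 = std::max(0, -s);
        int j1 = std::min(B, B - s);
        if (j1 <= j0) continue;
        double sa = 0.0, sb = 0.0, xab = 0.0, xba = 0.0;
        for (int j = j0; j < j1; ++j) {
          int sj = j + s;
          int col = f ? (B - 1 - sj) : sj;
          const double *pa = &ha[(size_t)j * T];
          const double *pla = &hla[(size_t)j * T];
          const double *pb = &ca[(size_t)col * T];
          const double *plb = &cla[(size_t)col * T];
          sa += hcol[j];
          sb += ccol[col];
          for (int t = 0; t < T; ++t) {
            double dl = pla[t] - plb[t];
            xab += pa[t] * dl;
            xba -= pb[t] * dl;
          }
        }
        double lsa = std::log(sa), lsb = std::log(sb);
        double d = 0.5 * ((xab / sa - lsa + lsb) +
                          (xba / sb - lsb + lsa)) * log2e;
        if (d < best) best = d;
      }
    }
    out[r] = best;
  }
  return out;
}
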