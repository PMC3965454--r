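#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Per-window opposite-homozygote counts for one query and one filter.
//
// H:   n x m logical matrix of homozygote set membership (column = marker).
// sel: 0-based indices into H's columns of the query-selected markers,
//      ordered by (chromosome, cM).
// lab: Jaccard run label per selected marker (same order as sel); when
//      prune is true, only the first in-window member of each label run
//      contributes (labels are contiguous runs along the chromosome, so a
//      label change between consecutive selected markers opens a new run).
// win_lo / win_hi: per window, 0-based inclusive range into sel (lo > hi
//      means the window selects nothing).
// maf: per selected marker MAF; f_fixed per window is the min (use_min) or
//      max over the contributing markers.
//
// Returns counts (n x W), the contributing-marker count c per window and
// f_fixed per window (NA when empty).
// [[Rcpp::export]]
List cpp_window_counts(LogicalMatrix H, IntegerVector sel, IntegerVector lab,
                       IntegerVector win_lo, IntegerVector win_hi,
                       NumericVector maf, bool use_min, bool prune) {
  const int n = H.nrow();
  const int W = win_lo.size();
  IntegerMatrix counts(n, W);
  IntegerVector cvec(W);
  NumericVector ffix(W, NA_REAL);
  for (int w = 0; w < W; ++w) {
    const int lo = win_lo[w], hi = win_hi[w];
    int c = 0;
    double fb = use_min ? 2.0 : -1.0;
    int prev_lab = INT_MIN;
    int* col = &counts(0, w);
    for (int p = lo; p <= hi; ++p) {
      const bool is_rep = !prune || p == lo || lab[p] != prev_lab;
      prev_lab = lab[p];
      if (!is_rep) continue;
      ++c;
      const double f = maf[p];
      if (use_min ? (f < fb) : (f > fb)) fb = f;
      const int mcol = sel[p];
      for (int i = 0; i < n; ++i) {
        if (H(i, mcol)) ++col[i];
      }
    }
    cvec[w] = c;
    if (c > 0) ffix[w] = fb;
  }
  return List::create(_["counts"] = counts, _["c"] = cvec, _["f_fixed"] = ffix);
}

// Survivor windows -> merged candidate segments.
//
// counts_major / counts_minor: n x W opposite-homozygote counts (either may
//   be a 0 x 0 matrix when the corresponding filter is disabled).
// k_major / k_minor: per-window tolerances.
// ext_start / ext_end: extended (flanked, clamped) window bounds in cM.
// chrom_id: integer chromosome code per window; merging never crosses it.
// focal: -1 = no interval collection, -2 = collect intervals for every
//   individual, >= 0 = collect only that (0-based) individual's intervals.
//
// Windows are ordered by (chromosome, start), so a single left-to-right pass
// per individual merges overlapping or touching extended intervals.
// Returns per-individual total candidate length (cM) and the collected
// merged intervals.
// [[Rcpp::export]]
List cpp_candidate_segments(IntegerMatrix counts_major, IntegerMatrix counts_minor,
                            IntegerVector k_major, IntegerVector k_minor,
                            bool use_major, bool use_minor,
                            NumericVector ext_start, NumericVector ext_end,
                            IntegerVector chrom_id, int focal) {
  const int W = ext_start.size();
  const int n = use_major ? counts_major.nrow() : counts_minor.nrow();
  NumericVector len(n);
  std::vector<int> out_ind, out_chrom;
  std::vector<double> out_start, out_end;
  for (int i = 0; i < n; ++i) {
    const bool collect = (focal == -2) || (focal == i);
    bool open = false;
    double cs = 0.0, ce = 0.0, tot = 0.0;
    int cc = -1;
    for (int w = 0; w < W; ++w) {
      if (use_major && counts_major(i, w) > k_major[w]) continue;
      if (use_minor && counts_minor(i, w) > k_minor[w]) continue;
      if (open && chrom_id[w] == cc && ext_start[w] <= ce) {
        if (ext_end[w] > ce) ce = ext_end[w];
      } else {
        if (open) {
          tot += ce - cs;
          if (collect) {
            out_ind.push_back(i + 1);
            out_chrom.push_back(cc);
            out_start.push_back(cs);
            out_end.push_back(ce);
          }
        }
        cs = ext_start[w];
        ce = ext_end[w];
        cc = chrom_id[w];
        open = true;
      }
    }
    if (open) {
      tot += ce - cs;
      if (collect) {
        out_ind.push_back(i + 1);
        out_chrom.push_back(cc);
        out_start.push_back(cs);
        out_end.push_back(ce);
      }
    }
    len[i] = tot;
  }
  return List::create(
    _["cand_cm"] = len,
    _["ind"] = wrap(out_ind),
    _["chrom_id"] = wrap(out_chrom),
    _["start_cm"] = wrap(out_start),
    _["end_cm"] = wrap(out_end));
}
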