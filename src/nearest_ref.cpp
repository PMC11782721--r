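#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact nearest-reference search for lookup-table inversion.
//
// For each query pair (uni, dsr) finds the reference row minimizing
//   d2 = (weight * (uni - uni_ref[j]))^2 + (dsr - dsr_ref[j])^2
// with ties resolved to the lowest row index. References are pre-sorted by
// uni so the scan can expand outward from the bisection point and stop as
// soon as the UNI term alone exceeds the incumbent distance; the arithmetic
// matches a brute-force argmin written the same way term for term, so the
// result is bit-identical to exhaustive search. Queries with NA in either
// coordinate return NA.
//
// [[Rcpp::export]]
List nearest_ref_cpp(NumericVector uni_q, NumericVector dsr_q,
                     NumericVector uni_ref, NumericVector dsr_ref,
                     double weight) {
  const R_xlen_t nq = uni_q.size();
  const R_xlen_t nr = uni_ref.size();
  if (dsr_q.size() != nq)
    stop("uni and dsr query vectors must have equal length");
  if (dsr_ref.size() != nr || nr == 0)
    stop("reference table is empty or has mismatched columns");

  // sort reference rows by uni, stable so equal values keep ascending index
  std::vector<R_xlen_t> ord(nr);
  for (R_xlen_t i = 0; i < nr; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    return uni_ref[a] < uni_ref[b];
  });
  std::vector<double> us(nr), ds(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    us[i] = uni_ref[ord[i]];
    ds[i] = dsr_ref[ord[i]];
  }

  IntegerVector idx(nq);
  NumericVector dist(nq);

  for (R_xlen_t q = 0; q < nq; ++q) {
    const double uq = uni_q[q], dq = dsr_q[q];
    if (!R_finite(uq) || !R_finite(dq)) {
      idx[q] = NA_INTEGER;
      dist[q] = NA_REAL;
      continue;
    }
    // first sorted position with us >= uq
    R_xlen_t hi = std::lower_bound(us.begin(), us.end(), uq) - us.begin();
    R_xlen_t lo = hi - 1;
    double best = R_PosInf;
    R_xlen_t best_idx = -1;

    auto consider = [&](R_xlen_t j) -> bool {
      // returns false when this side can be abandoned
      const double du = weight * (uq - us[j]);
      const double du2 = du * du;
      if (du2 > best) return false;  // strictly worse even before dsr term
      const double dv = dq - ds[j];
      const double d2 = du2 + dv * dv;
      const R_xlen_t oi = ord[j];
      if (d2 < best || (d2 == best && oi < best_idx)) {
        best = d2;
        best_idx = oi;
      }
      return true;
    };

    while (lo >= 0 || hi < nr) {
      bool lo_alive = lo >= 0;
      bool hi_alive = hi < nr;
      if (lo_alive) {
        if (consider(lo)) --lo; else lo = -1;
      }
      if (hi_alive) {
        if (consider(hi)) ++hi; else hi = nr;
      }
      if (!lo_alive && !hi_alive) break;
    }
    idx[q] = static_cast<int>(best_idx + 1);  // 1-based
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
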