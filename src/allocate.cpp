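#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Competitive radius-expanding greedy allocation.
//
// Pixels are indexed row-major, 0-based, row 0 at the northern edge.
// Pixel (i, j) has centre (x0 + (j + 0.5) * cell, y0top - (i + 0.5) * cell).
// A pixel is claimed by at most one (settlement, group) over the whole run.
// Within a ring (cumulative disk of radius k * r), settlements take turns in
// ascending input order, each claiming its single best unclaimed pixel
// (highest energy, then nearest, then smallest row-major index); the ring
// index advances when no participating settlement can claim.

struct Cand {
  double energy;
  double d2;
  int idx;
};

struct CandWorse {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.energy != b.energy) return a.energy < b.energy;
    if (a.d2 != b.d2) return a.d2 > b.d2;
    return a.idx > b.idx;
  }
};

typedef std::priority_queue<Cand, std::vector<Cand>, CandWorse> CandHeap;

// Push all unexcluded, positive-energy pixels with r_prev < dist <= r_new
// into the settlement's heap.
static void load_annulus(CandHeap &heap, const NumericVector &energy,
                         int nrow, int ncol, double cell, double x0,
                         double y0top, double sx, double sy, double r_prev,
                         double r_new) {
  if (r_new <= r_prev) return;
  double r2_new = r_new * r_new;
  // first load is the full disk including distance zero
  double r2_prev = (r_prev <= 0) ? -1.0 : r_prev * r_prev;
  int i_lo = (int)std::floor((y0top - sy - r_new) / cell - 0.5);
  int i_hi = (int)std::ceil((y0top - sy + r_new) / cell - 0.5);
  if (i_lo < 0) i_lo = 0;
  if (i_hi > nrow - 1) i_hi = nrow - 1;
  for (int i = i_lo; i <= i_hi; ++i) {
    double cy = y0top - (i + 0.5) * cell;
    double dy = cy - sy;
    double rem = r2_new - dy * dy;
    if (rem < 0) continue;
    double half = std::sqrt(rem);
    int j_lo = (int)std::ceil((sx - half - x0) / cell - 0.5);
    int j_hi = (int)std::floor((sx + half - x0) / cell - 0.5);
    if (j_lo < 0) j_lo = 0;
    if (j_hi > ncol - 1) j_hi = ncol - 1;
    for (int j = j_lo; j <= j_hi; ++j) {
      int idx = i * ncol + j;
      double e = energy[idx];
      if (e <= 0) continue;
      double cx = x0 + (j + 0.5) * cell;
      double dx = cx - sx;
      double d2 = dx * dx + dy * dy;
      if (d2 > r2_new || d2 <= r2_prev) continue;
      Cand c;
      c.energy = e;
      c.d2 = d2;
      c.idx = idx;
      heap.push(c);
    }
  }
}

// [[Rcpp::export]]
List cpp_allocate(NumericVector energy, int nrow, int ncol, double cell,
                  double x0, double y0top, NumericVector sx, NumericVector sy,
                  NumericMatrix demand, NumericVector radius_m,
                  NumericVector offtake, IntegerVector claim_init,
                  IntegerVector group_init, NumericVector consumed_init,
                  int group_offset) {
  int ns = sx.size();
  int ng = radius_m.size();
  int npix = energy.size();
  if (npix != nrow * ncol) stop("energy length does not match grid");

  IntegerVector claim = clone(claim_init);
  IntegerVector group = clone(group_init);
  NumericVector consumed = clone(consumed_init);

  IntegerMatrix n_pixels(ns, ng);
  NumericMatrix max_d2(ns, ng);
  IntegerMatrix final_ring(ns, ng);
  LogicalMatrix met(ns, ng);
  NumericMatrix consumed_sg(ns, ng);

  // farthest possible pixel-centre distance per settlement (grid corners)
  std::vector<double> maxfeas(ns);
  double xmin = x0 + 0.5 * cell, xmax = x0 + (ncol - 0.5) * cell;
  double ymax = y0top - 0.5 * cell, ymin = y0top - (nrow - 0.5) * cell;
  for (int s = 0; s < ns; ++s) {
    double dx = std::max(std::fabs(sx[s] - xmin), std::fabs(sx[s] - xmax));
    double dy = std::max(std::fabs(sy[s] - ymin), std::fabs(sy[s] - ymax));
    maxfeas[s] = std::sqrt(dx * dx + dy * dy);
  }

  for (int g = 0; g < ng; ++g) {
    double r = radius_m[g];
    std::vector<CandHeap> heaps(ns);
    std::vector<double> loaded(ns, 0.0);
    std::vector<double> rem(ns);
    std::vector<bool> active(ns);
    std::vector<bool> fully_loaded(ns, false);
    int n_active = 0;
    for (int s = 0; s < ns; ++s) {
      rem[s] = demand(s, g);
      if (rem[s] < 0) stop("negative demand");
      active[s] = rem[s] > 0;
      met(s, g) = !active[s];
      if (active[s]) ++n_active;
    }
    int k = 0;
    while (n_active > 0) {
      ++k;
      double R = k * r;
      for (int s = 0; s < ns; ++s) {
        if (!active[s] || fully_loaded[s]) continue;
        double cap = std::min(R, maxfeas[s] + cell);
        load_annulus(heaps[s], energy, nrow, ncol, cell, x0, y0top, sx[s],
                     sy[s], loaded[s], cap);
        loaded[s] = cap;
        if (cap >= maxfeas[s]) fully_loaded[s] = true;
      }
      bool any_claim = true;
      while (any_claim) {
        any_claim = false;
        for (int s = 0; s < ns; ++s) {
          if (!active[s]) continue;
          CandHeap &h = heaps[s];
          while (!h.empty() && claim[h.top().idx] != 0) h.pop();
          if (h.empty()) {
            if (fully_loaded[s]) {  // landscape exhausted for this settlement
              active[s] = false;
              --n_active;
            }
            continue;
          }
          Cand c = h.top();
          h.pop();
          claim[c.idx] = s + 1;
          group[c.idx] = group_offset + g + 1;
          double take = offtake[s] * energy[c.idx];
          if (take > rem[s]) take = rem[s];  // partial final pixel
          consumed[c.idx] = take;
          rem[s] -= take;
          consumed_sg(s, g) += take;
          n_pixels(s, g) += 1;
          if (c.d2 > max_d2(s, g)) max_d2(s, g) = c.d2;
          final_ring(s, g) = k;
          any_claim = true;
          if (rem[s] <= 0) {
            active[s] = false;
            met(s, g) = true;
            --n_active;
          }
        }
      }
    }
  }

  return List::create(
      _["claim"] = claim, _["group"] = group, _["consumed"] = consumed,
      _["n_pixels"] = n_pixels, _["max_d2"] = max_d2,
      _["final_ring"] = final_ring, _["met"] = met,
      _["consumed_sg"] = consumed_sg);
}

// Minimum distance (m) from each pixel centre to any settlement.
// [[Rcpp::export]]
NumericVector cpp_nearest_settlement(int nrow, int ncol, double cell,
                                     double x0, double y0top,
                                     NumericVector sx, NumericVector sy) {
  int ns = sx.size();
  NumericVector out(nrow * ncol);
  for (int i = 0; i < nrow; ++i) {
    double cy = y0top - (i + 0.5) * cell;
    for (int j = 0; j < ncol; ++j) {
      double cx = x0 + (j + 0.5) * cell;
      double best = R_PosInf;
      for (int s = 0; s < ns; ++s) {
        double dx = cx - sx[s];
        double dy = cy - sy[s];
        double d2 = dx * dx + dy * dy;
        if (d2 < best) best = d2;
      }
      out[i * ncol + j] = std::sqrt(best);
    }
  }
  return out;
}
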