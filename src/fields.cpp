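#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-Euler substeps of one reaction-diffusion equation
//   dF/dt = D lap(F) + prod - decay*F - cons*min(F, cap)
// on the sub-box [i0..i1] x [j0..j1] (1-based, inclusive) with no-flux
// boundaries at the box edges (the box always contains every non-zero
// source and the support of F up to a margin; at the domain boundary the
// box edge coincides with the physical no-flux boundary). Negative values
// produced by the reaction terms are clamped to zero. `decay` is spatially
// uniform; `cons` may be an empty matrix meaning zero consumption.
// [[Rcpp::export]]
NumericMatrix cpp_rd_step(NumericMatrix F0, NumericMatrix prod,
                          double decay, NumericMatrix cons,
                          double cap, double D, double dx, double dt,
                          int nsub, IntegerVector box) {
  NumericMatrix F = clone(F0);
  const int nr = F.nrow();
  const int i0 = box[0] - 1, i1 = box[1] - 1, j0 = box[2] - 1,
            j1 = box[3] - 1;
  const double idx2 = D / (dx * dx);
  const int bw = i1 - i0 + 1, bh = j1 - j0 + 1;
  const bool has_cons = cons.nrow() == nr;
  // ping-pong buffers over the box
  std::vector<double> A((size_t)bw * bh), B((size_t)bw * bh);
  double *Fp = REAL(F), *Pp = REAL(prod),
         *Cp = has_cons ? REAL(cons) : nullptr;
  for (int j = 0; j < bh; ++j)
    for (int i = 0; i < bw; ++i)
      A[(size_t)j * bw + i] = Fp[(size_t)(j + j0) * nr + (i + i0)];
  double *cur = A.data(), *nxt = B.data();
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < bh; ++j) {
      const double *col = cur + (size_t)j * bw;
      const double *colL = (j > 0) ? col - bw : col;
      const double *colR = (j < bh - 1) ? col + bw : col;
      const double *pp = Pp + (size_t)(j + j0) * nr + i0;
      const double *cc = has_cons ? Cp + (size_t)(j + j0) * nr + i0
                                  : nullptr;
      double *out = nxt + (size_t)j * bw;
      if (cc) {
        for (int i = 0; i < bw; ++i) {
          double c = col[i];
          double up = (i > 0) ? col[i - 1] : c;
          double dn = (i < bw - 1) ? col[i + 1] : c;
          double lap = idx2 * (up + dn + colL[i] + colR[i] - 4.0 * c);
          double react = pp[i] - decay * c - cc[i] * std::min(c, cap);
          double v = c + dt * (lap + react);
          out[i] = (v < 0.0) ? 0.0 : v;
        }
      } else {
        for (int i = 0; i < bw; ++i) {
          double c = col[i];
          double up = (i > 0) ? col[i - 1] : c;
          double dn = (i < bw - 1) ? col[i + 1] : c;
          double lap = idx2 * (up + dn + colL[i] + colR[i] - 4.0 * c);
          double v = c + dt * (lap + pp[i] - decay * c);
          out[i] = (v < 0.0) ? 0.0 : v;
        }
      }
    }
    std::swap(cur, nxt);
  }
  for (int j = 0; j < bh; ++j)
    for (int i = 0; i < bw; ++i)
      Fp[(size_t)(j + j0) * nr + (i + i0)] = cur[(size_t)j * bw + i];
  return F;
}

// Quasi-steady oxygen: red-black SOR solve of
//   D lap(O) + gw*(Ov - O) - k*O = 0
// with no-flux boundaries. Convergence: max absolute update below tol.
// [[Rcpp::export]]
List cpp_steady_oxygen(NumericMatrix O0, NumericMatrix gw, NumericMatrix k,
                       double D, double dx, double Ov, double tol,
                       int max_iter, double omega) {
  NumericMatrix O = clone(O0);
  int nr = O.nrow(), nc = O.ncol();
  const double idx2 = D / (dx * dx);
  double maxres = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxres = 0.0;
    for (int rb = 0; rb < 2; ++rb) {
      for (int j = 0; j < nc; ++j) {
        for (int i = (j + rb) % 2; i < nr; i += 2) {
          int nnb = 0; double snb = 0.0;
          if (i > 0)      { snb += O(i - 1, j); ++nnb; }
          if (i < nr - 1) { snb += O(i + 1, j); ++nnb; }
          if (j > 0)      { snb += O(i, j - 1); ++nnb; }
          if (j < nc - 1) { snb += O(i, j + 1); ++nnb; }
          double diag = idx2 * nnb + gw(i, j) + k(i, j);
          double rhs = idx2 * snb + gw(i, j) * Ov;
          double newO = (1.0 - omega) * O(i, j) + omega * rhs / diag;
          if (newO < 0.0) newO = 0.0;
          double res = std::fabs(newO - O(i, j));
          if (res > maxres) maxres = res;
          O(i, j) = newO;
        }
      }
    }
    if (maxres < tol) { ++it; break; }
  }
  return List::create(_["O"] = O, _["iterations"] = it,
                      _["max_update"] = maxres);
}

// In-place scatter assignment into grid state matrices. The simulation
// grid is a mutable environment by design; R's copy-on-write would
// otherwise duplicate whole matrices on every per-cell update once their
// reference counts saturate. Snapshots deep-copy explicitly.
// [[Rcpp::export]]
void cpp_set_num(NumericMatrix M, IntegerVector idx, NumericVector v) {
  const bool one = v.size() == 1;
  for (int k = 0; k < idx.size(); ++k)
    M[idx[k] - 1] = one ? v[0] : v[k];
}

// [[Rcpp::export]]
void cpp_set_int(IntegerMatrix M, IntegerVector idx, IntegerVector v) {
  const bool one = v.size() == 1;
  for (int k = 0; k < idx.size(); ++k)
    M[idx[k] - 1] = one ? v[0] : v[k];
}

// [[Rcpp::export]]
void cpp_set_lgl(LogicalMatrix M, IntegerVector idx, LogicalVector v) {
  const bool one = v.size() == 1;
  for (int k = 0; k < idx.size(); ++k)
    M[idx[k] - 1] = one ? v[0] : v[k];
}
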