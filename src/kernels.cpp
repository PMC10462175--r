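#include <Rcpp.h>
using namespace Rcpp;

// Segmented accumulation used by the hash-encoding and warping backward
// passes: out[idx[k], j] += values[k, j]. idx is 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_sum(IntegerVector idx, NumericMatrix values, int nrow) {
  int n = idx.size(), nc = values.ncol();
  if (values.nrow() != n) stop("idx/values length mismatch");
  NumericMatrix out(nrow, nc);
  for (int j = 0; j < nc; ++j) {
    double *o = &out(0, j);
    const double *v = &values(0, j);
    for (int k = 0; k < n; ++k) {
      int i = idx[k] - 1;
      if (i < 0 || i >= nrow) stop("index out of range in scatter");
      o[i] += v[k];
    }
  }
  return out;
}

// Trilinear warp forward pass. vol is a complex 3D array (column-major,
// dims d), pos an n x 3 matrix of float 1-based voxel indices. Returns the
// sampled values plus the integer base corner and fractional offsets needed
// by the backward passes. Out-of-grid corners contribute zero.
// [[Rcpp::export]]
List cpp_warp_forward(ComplexVector vol, IntegerVector d, NumericMatrix pos) {
  int n = pos.nrow();
  int d1 = d[0], d2 = d[1], d3 = d[2];
  ComplexVector vals(n);
  IntegerMatrix i0(n, 3);
  NumericMatrix tf(n, 3);
  for (int s = 0; s < n; ++s) {
    double f1 = pos(s, 0), f2 = pos(s, 1), f3 = pos(s, 2);
    int a1 = (int)std::floor(f1), a2 = (int)std::floor(f2), a3 = (int)std::floor(f3);
    double t1 = f1 - a1, t2 = f2 - a2, t3 = f3 - a3;
    i0(s, 0) = a1; i0(s, 1) = a2; i0(s, 2) = a3;
    tf(s, 0) = t1; tf(s, 1) = t2; tf(s, 2) = t3;
    double vr = 0.0, vi = 0.0;
    for (int c = 0; c < 8; ++c) {
      int b1 = c & 1, b2 = (c >> 1) & 1, b3 = (c >> 2) & 1;
      int j1 = a1 + b1, j2 = a2 + b2, j3 = a3 + b3;
      if (j1 < 1 || j1 > d1 || j2 < 1 || j2 > d2 || j3 < 1 || j3 > d3) continue;
      double w = (b1 ? t1 : 1 - t1) * (b2 ? t2 : 1 - t2) * (b3 ? t3 : 1 - t3);
      if (w == 0.0) continue;
      Rcomplex v = vol[(j1 - 1) + d1 * ((j2 - 1) + d2 * (j3 - 1))];
      vr += w * v.r; vi += w * v.i;
    }
    vals[s].r = vr; vals[s].i = vi;
  }
  return List::create(_["values"] = vals, _["i0"] = i0, _["tf"] = tf);
}

// Gradient w.r.t. the image values: scatter of interpolation weights.
// g is dL/d(out) packed complex; returns a complex array of dims d.
// [[Rcpp::export]]
ComplexVector cpp_warp_backward_vol(IntegerVector d, IntegerMatrix i0,
                                    NumericMatrix tf, ComplexVector g) {
  int n = i0.nrow();
  int d1 = d[0], d2 = d[1], d3 = d[2];
  ComplexVector out(d1 * d2 * d3);
  for (int s = 0; s < n; ++s) {
    double t1 = tf(s, 0), t2 = tf(s, 1), t3 = tf(s, 2);
    int a1 = i0(s, 0), a2 = i0(s, 1), a3 = i0(s, 2);
    double gr = g[s].r, gi = g[s].i;
    for (int c = 0; c < 8; ++c) {
      int b1 = c & 1, b2 = (c >> 1) & 1, b3 = (c >> 2) & 1;
      int j1 = a1 + b1, j2 = a2 + b2, j3 = a3 + b3;
      if (j1 < 1 || j1 > d1 || j2 < 1 || j2 > d2 || j3 < 1 || j3 > d3) continue;
      double w = (b1 ? t1 : 1 - t1) * (b2 ? t2 : 1 - t2) * (b3 ? t3 : 1 - t3);
      if (w == 0.0) continue;
      int lin = (j1 - 1) + d1 * ((j2 - 1) + d2 * (j3 - 1));
      out[lin].r += w * gr;
      out[lin].i += w * gi;
    }
  }
  return out;
}

// Gradient w.r.t. the sampling positions (per axis, voxel units):
// dL/d pos_a = Re(Conj(g) * d out / d pos_a).
// [[Rcpp::export]]
NumericMatrix cpp_warp_backward_pos(ComplexVector vol, IntegerVector d,
                                    IntegerMatrix i0, NumericMatrix tf,
                                    ComplexVector g) {
  int n = i0.nrow();
  int d1 = d[0], d2 = d[1], d3 = d[2];
  NumericMatrix gp(n, 3);
  for (int s = 0; s < n; ++s) {
    double t1 = tf(s, 0), t2 = tf(s, 1), t3 = tf(s, 2);
    int a1 = i0(s, 0), a2 = i0(s, 1), a3 = i0(s, 2);
    double gr = g[s].r, gi = g[s].i;
    double g1 = 0.0, g2 = 0.0, g3 = 0.0;
    for (int c = 0; c < 8; ++c) {
      int b1 = c & 1, b2 = (c >> 1) & 1, b3 = (c >> 2) & 1;
      int j1 = a1 + b1, j2 = a2 + b2, j3 = a3 + b3;
      if (j1 < 1 || j1 > d1 || j2 < 1 || j2 > d2 || j3 < 1 || j3 > d3) continue;
      Rcomplex v = vol[(j1 - 1) + d1 * ((j2 - 1) + d2 * (j3 - 1))];
      double gv = gr * v.r + gi * v.i;
      double w1 = b1 ? t1 : 1 - t1, w2 = b2 ? t2 : 1 - t2, w3 = b3 ? t3 : 1 - t3;
      g1 += (b1 ? 1.0 : -1.0) * w2 * w3 * gv;
      g2 += (b2 ? 1.0 : -1.0) * w1 * w3 * gv;
      g3 += (b3 ? 1.0 : -1.0) * w1 * w2 * gv;
    }
    gp(s, 0) = g1; gp(s, 1) = g2; gp(s, 2) = g3;
  }
  return gp;
}

// Weighted gather for one hash-encoding level: out[s, ] = sum_c w(s, c) *
// table[idx(s, c) - 1, ].
// [[Rcpp::export]]
NumericMatrix cpp_hash_gather(IntegerMatrix idx, NumericMatrix w,
                              NumericMatrix table) {
  int n = idx.nrow(), nc = idx.ncol(), F = table.ncol(), T = table.nrow();
  NumericMatrix out(n, F);
  for (int f = 0; f < F; ++f) {
    const double *tc = &table(0, f);
    double *oc = &out(0, f);
    for (int c = 0; c < nc; ++c) {
      const int *ic = &idx(0, c);
      const double *wc = &w(0, c);
      for (int s = 0; s < n; ++s) {
        int i = ic[s] - 1;
        if (i < 0 || i >= T) stop("hash index out of range");
        oc[s] += wc[s] * tc[i];
      }
    }
  }
  return out;
}

// Transpose of cpp_hash_gather: accumulate dY back into the table.
// [[Rcpp::export]]
NumericMatrix cpp_hash_scatter(IntegerMatrix idx, NumericMatrix w,
                               NumericMatrix dY, int n_entries) {
  int n = idx.nrow(), nc = idx.ncol(), F = dY.ncol();
  NumericMatrix out(n_entries, F);
  for (int f = 0; f < F; ++f) {
    double *oc = &out(0, f);
    const double *dc = &dY(0, f);
    for (int c = 0; c < nc; ++c) {
      const int *ic = &idx(0, c);
      const double *wc = &w(0, c);
      for (int s = 0; s < n; ++s) {
        int i = ic[s] - 1;
        if (i < 0 || i >= n_entries) stop("hash index out of range");
        oc[i] += wc[s] * dc[s];
      }
    }
  }
  return out;
}

// Vector flavour of the same.
// [[Rcpp::export]]
NumericVector cpp_scatter_sum_vec(IntegerVector idx, NumericVector values, int n) {
  int m = idx.size();
  if (values.size() != m) stop("idx/values length mismatch");
  NumericVector out(n);
  for (int k = 0; k < m; ++k) {
    int i = idx[k] - 1;
    if (i < 0 || i >= n) stop("index out of range in scatter");
    out[i] += values[k];
  }
  return out;
}
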