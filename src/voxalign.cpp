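#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// R arrays are column-major: element (i,j,k), 0-based, lives at
// i + n1*(j + n2*k). Axis order throughout is (depth, row, column).

static inline double get3(const double *v, int n1, int n2,
                          int i, int j, int k) {
  return v[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
}

// Trilinear / nearest sampling of a 3D array at continuous 0-based voxel
// coordinates. mode 0 = trilinear, 1 = nearest. clamp=true extends the
// edge value outside the grid, otherwise out-of-domain points get `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts, int mode,
                                bool clamp, double fill) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *v = REAL(vol);
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x1 = pts(p, 0), x2 = pts(p, 1), x3 = pts(p, 2);
    if (clamp) {
      x1 = std::min(std::max(x1, 0.0), (double)(n1 - 1));
      x2 = std::min(std::max(x2, 0.0), (double)(n2 - 1));
      x3 = std::min(std::max(x3, 0.0), (double)(n3 - 1));
    } else if (x1 < 0 || x1 > n1 - 1 || x2 < 0 || x2 > n2 - 1 ||
               x3 < 0 || x3 > n3 - 1 ||
               !std::isfinite(x1) || !std::isfinite(x2) ||
               !std::isfinite(x3)) {
      out[p] = fill;
      continue;
    }
    if (mode == 1) {
      int i = (int)std::lround(x1), j = (int)std::lround(x2),
          k = (int)std::lround(x3);
      out[p] = get3(v, n1, n2, i, j, k);
    } else {
      int i0 = (int)std::floor(x1), j0 = (int)std::floor(x2),
          k0 = (int)std::floor(x3);
      if (i0 >= n1 - 1) i0 = n1 - 2;
      if (j0 >= n2 - 1) j0 = n2 - 2;
      if (k0 >= n3 - 1) k0 = n3 - 2;
      if (i0 < 0) i0 = 0;
      if (j0 < 0) j0 = 0;
      if (k0 < 0) k0 = 0;
      double f1 = x1 - i0, f2 = x2 - j0, f3 = x3 - k0;
      // degenerate single-voxel axes: weight collapses to the only voxel
      if (n1 == 1) { i0 = 0; f1 = 0.0; }
      if (n2 == 1) { j0 = 0; f2 = 0.0; }
      if (n3 == 1) { k0 = 0; f3 = 0.0; }
      int i1 = (n1 == 1) ? 0 : i0 + 1;
      int j1 = (n2 == 1) ? 0 : j0 + 1;
      int k1 = (n3 == 1) ? 0 : k0 + 1;
      double c000 = get3(v, n1, n2, i0, j0, k0);
      double c100 = get3(v, n1, n2, i1, j0, k0);
      double c010 = get3(v, n1, n2, i0, j1, k0);
      double c110 = get3(v, n1, n2, i1, j1, k0);
      double c001 = get3(v, n1, n2, i0, j0, k1);
      double c101 = get3(v, n1, n2, i1, j0, k1);
      double c011 = get3(v, n1, n2, i0, j1, k1);
      double c111 = get3(v, n1, n2, i1, j1, k1);
      double c00 = c000 * (1 - f1) + c100 * f1;
      double c10 = c010 * (1 - f1) + c110 * f1;
      double c01 = c001 * (1 - f1) + c101 * f1;
      double c11 = c011 * (1 - f1) + c111 * f1;
      double c0 = c00 * (1 - f2) + c10 * f2;
      double c1 = c01 * (1 - f2) + c11 * f2;
      out[p] = c0 * (1 - f3) + c1 * f3;
    }
  }
  return out;
}

// Population variance of every block on the search lattice.
// [[Rcpp::export]]
NumericVector cpp_block_variances(NumericVector vol, IntegerVector dims,
                                  int block, int stride) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *v = REAL(vol);
  std::vector<double> vars;
  const double N = (double)block * block * block;
  for (int s3 = 0; s3 + block <= n3; s3 += stride)
    for (int s2 = 0; s2 + block <= n2; s2 += stride)
      for (int s1 = 0; s1 + block <= n1; s1 += stride) {
        double S = 0.0, SS = 0.0;
        for (int k = s3; k < s3 + block; ++k)
          for (int j = s2; j < s2 + block; ++j)
            for (int i = s1; i < s1 + block; ++i) {
              double x = get3(v, n1, n2, i, j, k);
              S += x; SS += x * x;
            }
        double m = S / N;
        vars.push_back(SS / N - m * m);
      }
  return wrap(vars);
}

// Exhaustive integer-displacement NCC block matching.
// For each eligible fixed block (variance >= var_floor), every integer
// displacement within `radius` is scored by normalized cross-correlation
// against the moving volume; the argmax is returned. Ties are broken by
// smallest displacement norm, then lexicographically on (d1, d2, d3).
// Windows with (near-)zero moving variance score -2 (NCC undefined).
// Returns one row per eligible block:
//   s1 s2 s3 (block start, 0-based) d1 d2 d3 (voxels) score
// [[Rcpp::export]]
NumericMatrix cpp_match_blocks(NumericVector fixed_, NumericVector moving,
                               IntegerVector dims, int block, int stride,
                               int radius, double var_floor) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *fv = REAL(fixed_);
  const double *mv = REAL(moving);
  const double N = (double)block * block * block;
  std::vector<double> rows;
  for (int s3 = 0; s3 + block <= n3; s3 += stride)
    for (int s2 = 0; s2 + block <= n2; s2 += stride)
      for (int s1 = 0; s1 + block <= n1; s1 += stride) {
        double Sf = 0.0, Sff = 0.0;
        for (int k = s3; k < s3 + block; ++k)
          for (int j = s2; j < s2 + block; ++j)
            for (int i = s1; i < s1 + block; ++i) {
              double x = get3(fv, n1, n2, i, j, k);
              Sf += x; Sff += x * x;
            }
        double mf = Sf / N;
        double vf = Sff / N - mf * mf;
        // ineligible: below the floor, or (near-)constant so NCC undefined
        if (!(vf >= var_floor) || vf <= 1e-12) continue;
        double best = R_NegInf;
        int bd1 = 0, bd2 = 0, bd3 = 0;
        long bnorm = 0;
        bool have = false;
        for (int d1 = -radius; d1 <= radius; ++d1) {
          int t1 = s1 + d1;
          if (t1 < 0 || t1 + block > n1) continue;
          for (int d2 = -radius; d2 <= radius; ++d2) {
            int t2 = s2 + d2;
            if (t2 < 0 || t2 + block > n2) continue;
            for (int d3 = -radius; d3 <= radius; ++d3) {
              int t3 = s3 + d3;
              if (t3 < 0 || t3 + block > n3) continue;
              double Sm = 0.0, Smm = 0.0, Sfm = 0.0;
              for (int k = 0; k < block; ++k)
                for (int j = 0; j < block; ++j)
                  for (int i = 0; i < block; ++i) {
                    double a = get3(fv, n1, n2, s1 + i, s2 + j, s3 + k);
                    double b = get3(mv, n1, n2, t1 + i, t2 + j, t3 + k);
                    Sm += b; Smm += b * b; Sfm += a * b;
                  }
              double mm = Sm / N;
              double vm = Smm / N - mm * mm;
              double score;
              if (vm <= 1e-12) {
                score = -2.0;
              } else {
                score = (Sfm / N - mf * mm) / std::sqrt(vf * vm);
              }
              long norm = (long)d1 * d1 + (long)d2 * d2 + (long)d3 * d3;
              bool take = false;
              if (!have || score > best) {
                take = true;
              } else if (score == best) {
                if (norm < bnorm) {
                  take = true;
                } else if (norm == bnorm) {
                  if (d1 < bd1 || (d1 == bd1 && (d2 < bd2 ||
                      (d2 == bd2 && d3 < bd3)))) {
                    take = true;
                  }
                }
              }
              if (take) {
                best = score; bd1 = d1; bd2 = d2; bd3 = d3;
                bnorm = norm; have = true;
              }
            }
          }
        }
        if (have) {
          rows.push_back(s1); rows.push_back(s2); rows.push_back(s3);
          rows.push_back(bd1); rows.push_back(bd2); rows.push_back(bd3);
          rows.push_back(best);
        }
      }
  const int nr = rows.size() / 7;
  NumericMatrix out(nr, 7);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 7; ++c)
      out(r, c) = rows[r * 7 + c];
  colnames(out) = CharacterVector::create("s1", "s2", "s3",
                                          "d1", "d2", "d3", "score");
  return out;
}
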