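#include <Rcpp.h>
using namespace Rcpp;

// coords is an (n_frames, n_atoms, 3) array in R's column-major layout:
// element (f, a, k) sits at f + nf * (a + na * k).
static inline double coord(const double* c, int nf, int na, int f, int a, int k) {
  return c[f + (R_xlen_t)nf * (a + (R_xlen_t)na * k)];
}

// Shrake-Rupley solvent-accessible surface area, summed per residue.
// sphere: n_points x 3 unit vectors (quasi-uniform). Burial uses <= so two
// coincident identical atoms fully occlude each other.
// [[Rcpp::export]]
NumericMatrix sasa_frames_cpp(NumericVector coords, NumericVector radii,
                              double probe, NumericMatrix sphere,
                              IntegerVector residue_index, int n_res,
                              IntegerVector frames) {
  IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  int np = sphere.nrow();
  const double* cc = coords.begin();
  NumericMatrix out(frames.size(), n_res);
  std::vector<double> rx(na), ry(na), rz(na), rexp(na);
  std::vector<int> nbr;
  nbr.reserve(na);
  for (int fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    for (int a = 0; a < na; ++a) {
      rx[a] = coord(cc, nf, na, f, a, 0);
      ry[a] = coord(cc, nf, na, f, a, 1);
      rz[a] = coord(cc, nf, na, f, a, 2);
      rexp[a] = radii[a] + probe;
    }
    for (int i = 0; i < na; ++i) {
      double ri = rexp[i];
      nbr.clear();
      for (int j = 0; j < na; ++j) {
        if (j == i) continue;
        double dx = rx[j] - rx[i], dy = ry[j] - ry[i], dz = rz[j] - rz[i];
        double cut = ri + rexp[j];
        if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
      }
      int acc = 0;
      for (int s = 0; s < np; ++s) {
        double px = rx[i] + ri * sphere(s, 0);
        double py = ry[i] + ri * sphere(s, 1);
        double pz = rz[i] + ri * sphere(s, 2);
        bool buried = false;
        for (size_t jn = 0; jn < nbr.size(); ++jn) {
          int j = nbr[jn];
          double dx = px - rx[j], dy = py - ry[j], dz = pz - rz[j];
          // <= with a tiny slack: tangent points (e.g. coincident identical
          // atoms) count as buried despite floating-point rounding
          if (dx * dx + dy * dy + dz * dz <= rexp[j] * rexp[j] * (1.0 + 1e-12) + 1e-12) {
            buried = true;
            break;
          }
        }
        if (!buried) ++acc;
      }
      double area = 4.0 * M_PI * ri * ri * (double)acc / (double)np;
      out(fi, residue_index[i] - 1) += area;
    }
  }
  return out;
}

// Minimum interatomic distance per residue pair over the selected frames.
// [[Rcpp::export]]
NumericMatrix min_distance_map_cpp(NumericVector coords,
                                   IntegerVector residue_index, int n_res,
                                   IntegerVector frames) {
  IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  const double* cc = coords.begin();
  NumericMatrix out(n_res, n_res);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    for (int i = 0; i < na; ++i) {
      double xi = coord(cc, nf, na, f, i, 0);
      double yi = coord(cc, nf, na, f, i, 1);
      double zi = coord(cc, nf, na, f, i, 2);
      int ri = residue_index[i] - 1;
      for (int j = i + 1; j < na; ++j) {
        int rj = residue_index[j] - 1;
        double dx = coord(cc, nf, na, f, j, 0) - xi;
        double dy = coord(cc, nf, na, f, j, 1) - yi;
        double dz = coord(cc, nf, na, f, j, 2) - zi;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < out(ri, rj)) {
          out(ri, rj) = d2;
          out(rj, ri) = d2;
        }
      }
    }
  }
  for (int i = 0; i < n_res; ++i)
    for (int j = 0; j < n_res; ++j)
      out(i, j) = (i == j) ? 0.0 : std::sqrt(out(i, j));
  return out;
}

// Per-frame minimum distance between two atom sets (1-based indices).
// [[Rcpp::export]]
NumericVector pair_min_frames_cpp(NumericVector coords, IntegerVector atoms_i,
                                  IntegerVector atoms_j, IntegerVector frames) {
  IntegerVector dims = coords.attr("dim");
  int nf = dims[0], na = dims[1];
  const double* cc = coords.begin();
  NumericVector out(frames.size());
  for (int fi = 0; fi < frames.size(); ++fi) {
    int f = frames[fi] - 1;
    double best = R_PosInf;
    for (int ii = 0; ii < atoms_i.size(); ++ii) {
      int a = atoms_i[ii] - 1;
      double xa = coord(cc, nf, na, f, a, 0);
      double ya = coord(cc, nf, na, f, a, 1);
      double za = coord(cc, nf, na, f, a, 2);
      for (int jj = 0; jj < atoms_j.size(); ++jj) {
        int b = atoms_j[jj] - 1;
        double dx = coord(cc, nf, na, f, b, 0) - xa;
        double dy = coord(cc, nf, na, f, b, 1) - ya;
        double dz = coord(cc, nf, na, f, b, 2) - za;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[fi] = std::sqrt(best);
  }
  return out;
}
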