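// Gaussian one- and two-electron integrals over contracted cartesian
// Gaussians, McMurchie-Davidson scheme.  Only the integral classes the
// package needs are implemented: S, T, V, multipole moments up to
// quadrupole, and the 2-/3-center ERIs of the density-fitting scheme.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
// Series for small T, asymptotic + downward recursion otherwise.
void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T < 35.0) {
    // series at m = mmax: F_m(T) = e^-T sum_k (2T)^k / [(2m+1)(2m+3)...(2m+2k+1)]
    double acc = 0.0;
    double termk = 1.0 / (2.0 * mmax + 1.0);
    acc = termk;
    for (int kk = 1; kk < 200000; ++kk) {
      termk *= 2.0 * T / (2.0 * mmax + 2.0 * kk + 1.0);
      acc += termk;
      if (termk < 1e-17 * acc) break;
    }
    F[mmax] = std::exp(-T) * acc;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * T * F[m + 1] + std::exp(-T)) / (2.0 * m + 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(PI / T);
    double expT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int m = 1; m <= mmax; ++m)
      F[m] = ((2.0 * m - 1.0) * F[m - 1] - expT) / (2.0 * T);
  }
}

// ------------------------------------------------- Hermite E coefficients
// E[t][i][j] for one dimension; i <= imax, j <= jmax, t <= i+j.
struct Etab {
  int imax, jmax;
  std::vector<double> v; // (imax+1)*(jmax+1)*(imax+jmax+1)
  double& at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

Etab build_E(int imax, int jmax, double a, double b, double AB) {
  Etab E;
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -b / p * AB; // P - A where AB = A - B => P = (aA+bB)/p; P-A = -b/p (A-B)
  double XPB = a / p * AB;  // P - B =  a/p (A-B)
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          val = (t > 0 ? E.get(i - 1, j, t - 1) / (2.0 * p) : 0.0)
              + XPA * E.get(i - 1, j, t)
              + (t + 1.0) * E.get(i - 1, j, t + 1);
        } else {
          val = (t > 0 ? E.get(i, j - 1, t - 1) / (2.0 * p) : 0.0)
              + XPB * E.get(i, j - 1, t)
              + (t + 1.0) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
  return E;
}

// --------------------------------------------------- Hermite Coulomb R_tuv
struct Rtab {
  int tmax, umax, vmax;
  std::vector<double> v;
  double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (umax + 1) + u) * (vmax + 1) + w];
  }
  double& at(int t, int u, int w) { return v[(t * (umax + 1) + u) * (vmax + 1) + w]; }
};

Rtab build_R(int tmax, int umax, int vmax, double alpha, double X, double Y, double Z) {
  int nmax = tmax + umax + vmax;
  double T = alpha * (X * X + Y * Y + Z * Z);
  std::vector<double> F(nmax + 1);
  boys(nmax, T, F.data());
  // R^n_{000} = (-2 alpha)^n F_n
  // recursion downward in n
  std::vector<std::vector<double>> Rn(nmax + 1);
  int sz = (tmax + 1) * (umax + 1) * (vmax + 1);
  auto idx = [&](int t, int u, int w) { return (t * (umax + 1) + u) * (vmax + 1) + w; };
  for (int n = 0; n <= nmax; ++n) Rn[n].assign(sz, 0.0);
  double pw = 1.0;
  for (int n = 0; n <= nmax; ++n) { Rn[n][idx(0, 0, 0)] = pw * F[n]; pw *= -2.0 * alpha; }
  for (int total = 1; total <= nmax; ++total) {
    for (int t = 0; t <= std::min(total, tmax); ++t)
      for (int u = 0; u <= std::min(total - t, umax); ++u) {
        int w = total - t - u;
        if (w < 0 || w > vmax) continue;
        for (int n = 0; n + total <= nmax; ++n) {
          double val = 0.0;
          if (t > 0) {
            val = (t > 1 ? (t - 1) * Rn[n + 1][idx(t - 2, u, w)] : 0.0)
                + X * Rn[n + 1][idx(t - 1, u, w)];
          } else if (u > 0) {
            val = (u > 1 ? (u - 1) * Rn[n + 1][idx(t, u - 2, w)] : 0.0)
                + Y * Rn[n + 1][idx(t, u - 1, w)];
          } else {
            val = (w > 1 ? (w - 1) * Rn[n + 1][idx(t, u, w - 2)] : 0.0)
                + Z * Rn[n + 1][idx(t, u, w - 1)];
          }
          Rn[n][idx(t, u, w)] = val;
        }
      }
  }
  Rtab R;
  R.tmax = tmax; R.umax = umax; R.vmax = vmax;
  R.v = Rn[0];
  return R;
}

// ------------------------------------------------------------- shell data
struct Shell {
  int l;
  int atom;
  arma::vec exps;
  arma::vec coefs; // contraction coefficients (raw, normalized later)
  double x, y, z;
  int offset;      // first basis-function index
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

// cartesian components in canonical order
void cart_comps(int l, std::vector<std::array<int, 3>>& comps) {
  comps.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comps.push_back({lx, ly, l - lx - ly});
}

double dfact(int n) { // (2n-1)!!
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

// primitive norm for cartesian gaussian (i,j,k), exponent a
double prim_norm(double a, int i, int j, int k) {
  int L = i + j + k;
  double num = std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * L);
  double den = std::sqrt(dfact(i) * dfact(j) * dfact(k));
  return num / den;
}

std::vector<Shell> parse_shells(const List& basis) {
  IntegerVector l = basis["l"];
  IntegerVector atom = basis["atom"];
  NumericMatrix centers = basis["centers"];
  List exps = basis["exps"];
  List coefs = basis["coefs"];
  int ns = l.size();
  std::vector<Shell> sh(ns);
  int off = 0;
  for (int s = 0; s < ns; ++s) {
    sh[s].l = l[s];
    sh[s].atom = atom[s];
    sh[s].exps = as<arma::vec>(exps[s]);
    sh[s].coefs = as<arma::vec>(coefs[s]);
    sh[s].x = centers(s, 0); sh[s].y = centers(s, 1); sh[s].z = centers(s, 2);
    sh[s].offset = off;
    off += sh[s].ncart();
  }
  return sh;
}

int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (auto& s : sh) n += s.ncart();
  return n;
}

// contracted self-overlap of component (i,j,k) of a shell (for normalization)
double contracted_selfoverlap(const Shell& s, int i, int j, int k) {
  double tot = 0.0;
  for (arma::uword a = 0; a < s.exps.n_elem; ++a)
    for (arma::uword b = 0; b < s.exps.n_elem; ++b) {
      double p = s.exps[a] + s.exps[b];
      double na = prim_norm(s.exps[a], i, j, k), nb = prim_norm(s.exps[b], i, j, k);
      // 1D overlaps of primitives at same center:
      // S_ii = (pi/p)^{1/2} * (2i-1)!! / (2p)^i
      double Sx = std::sqrt(PI / p) * dfact(i) / std::pow(2.0 * p, i);
      double Sy = std::sqrt(PI / p) * dfact(j) / std::pow(2.0 * p, j);
      double Sz = std::sqrt(PI / p) * dfact(k) / std::pow(2.0 * p, k);
      tot += s.coefs[a] * s.coefs[b] * na * nb * Sx * Sy * Sz;
    }
  return tot;
}

// per-component normalization factors for a shell
std::vector<double> comp_norms(const Shell& s) {
  std::vector<std::array<int, 3>> comps;
  cart_comps(s.l, comps);
  std::vector<double> nrm(comps.size());
  for (size_t c = 0; c < comps.size(); ++c)
    nrm[c] = 1.0 / std::sqrt(contracted_selfoverlap(s, comps[c][0], comps[c][1], comps[c][2]));
  return nrm;
}

} // namespace

// ------------------------------------------------------------------ overlap
// [[Rcpp::export]]
arma::mat cpp_overlap(List basis) {
  auto sh = parse_shells(basis);
  int n = nbf_total(sh);
  arma::mat S(n, n, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    for (size_t B = 0; B <= A; ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
      for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
        for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
          double a = sh[A].exps[pa], b = sh[B].exps[pb], p = a + b;
          Etab Ex = build_E(sh[A].l, sh[B].l, a, b, sh[A].x - sh[B].x);
          Etab Ey = build_E(sh[A].l, sh[B].l, a, b, sh[A].y - sh[B].y);
          Etab Ez = build_E(sh[A].l, sh[B].l, a, b, sh[A].z - sh[B].z);
          double pref = std::pow(PI / p, 1.5);
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              double val = Ex.get(ca[ia][0], cb[ib][0], 0)
                         * Ey.get(ca[ia][1], cb[ib][1], 0)
                         * Ez.get(ca[ia][2], cb[ib][2], 0) * pref;
              blk(ia, ib) += sh[A].coefs[pa] * sh[B].coefs[pb]
                           * prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2])
                           * prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]) * val;
            }
        }
      for (size_t ia = 0; ia < ca.size(); ++ia)
        for (size_t ib = 0; ib < cb.size(); ++ib) {
          double v = blk(ia, ib) * na[ia] * nb[ib];
          S(sh[A].offset + ia, sh[B].offset + ib) = v;
          S(sh[B].offset + ib, sh[A].offset + ia) = v;
        }
    }
  }
  return S;
}

namespace {
// 1D primitive overlap table S_ij for i<=imax+2, j<=jmax+2 from E coefficients
// S1d(i,j) = E_0^{ij} sqrt(pi/p)
struct S1d {
  int imax, jmax;
  std::vector<double> v;
  double get(int i, int j) const {
    if (i < 0 || j < 0) return 0.0;
    return v[i * (jmax + 1) + j];
  }
};
S1d build_S1d(int imax, int jmax, double a, double b, double AB) {
  Etab E = build_E(imax, jmax, a, b, AB);
  S1d s; s.imax = imax; s.jmax = jmax;
  s.v.assign((imax + 1) * (jmax + 1), 0.0);
  double p = a + b;
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      s.v[i * (jmax + 1) + j] = E.get(i, j, 0) * std::sqrt(PI / p);
  return s;
}
}

// ------------------------------------------------------------------ kinetic
// [[Rcpp::export]]
arma::mat cpp_kinetic(List basis) {
  auto sh = parse_shells(basis);
  int n = nbf_total(sh);
  arma::mat T(n, n, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    for (size_t B = 0; B <= A; ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
      for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
        for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
          double a = sh[A].exps[pa], b = sh[B].exps[pb];
          S1d Sx = build_S1d(sh[A].l, sh[B].l + 2, a, b, sh[A].x - sh[B].x);
          S1d Sy = build_S1d(sh[A].l, sh[B].l + 2, a, b, sh[A].y - sh[B].y);
          S1d Sz = build_S1d(sh[A].l, sh[B].l + 2, a, b, sh[A].z - sh[B].z);
          auto t1d = [&](const S1d& S1, int i, int j) {
            double v = -2.0 * b * b * S1.get(i, j + 2)
                     + b * (2.0 * j + 1.0) * S1.get(i, j)
                     - 0.5 * j * (j - 1.0) * S1.get(i, j - 2);
            return v;
          };
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              int i1 = ca[ia][0], i2 = ca[ia][1], i3 = ca[ia][2];
              int j1 = cb[ib][0], j2 = cb[ib][1], j3 = cb[ib][2];
              double val = t1d(Sx, i1, j1) * Sy.get(i2, j2) * Sz.get(i3, j3)
                         + Sx.get(i1, j1) * t1d(Sy, i2, j2) * Sz.get(i3, j3)
                         + Sx.get(i1, j1) * Sy.get(i2, j2) * t1d(Sz, i3, j3);
              blk(ia, ib) += sh[A].coefs[pa] * sh[B].coefs[pb]
                           * prim_norm(a, i1, i2, i3) * prim_norm(b, j1, j2, j3) * val;
            }
        }
      for (size_t ia = 0; ia < ca.size(); ++ia)
        for (size_t ib = 0; ib < cb.size(); ++ib) {
          double v = blk(ia, ib) * na[ia] * nb[ib];
          T(sh[A].offset + ia, sh[B].offset + ib) = v;
          T(sh[B].offset + ib, sh[A].offset + ia) = v;
        }
    }
  }
  return T;
}

// ---------------------------------------------------------- nuclear attract.
// [[Rcpp::export]]
arma::mat cpp_nuclear(List basis, arma::vec charges, arma::mat coords) {
  auto sh = parse_shells(basis);
  int n = nbf_total(sh);
  arma::mat V(n, n, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    for (size_t B = 0; B <= A; ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
      int lsum = sh[A].l + sh[B].l;
      for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
        for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
          double a = sh[A].exps[pa], b = sh[B].exps[pb], p = a + b;
          double Px = (a * sh[A].x + b * sh[B].x) / p;
          double Py = (a * sh[A].y + b * sh[B].y) / p;
          double Pz = (a * sh[A].z + b * sh[B].z) / p;
          Etab Ex = build_E(sh[A].l, sh[B].l, a, b, sh[A].x - sh[B].x);
          Etab Ey = build_E(sh[A].l, sh[B].l, a, b, sh[A].y - sh[B].y);
          Etab Ez = build_E(sh[A].l, sh[B].l, a, b, sh[A].z - sh[B].z);
          for (arma::uword c = 0; c < charges.n_elem; ++c) {
            Rtab R = build_R(lsum, lsum, lsum, p,
                             Px - coords(c, 0), Py - coords(c, 1), Pz - coords(c, 2));
            double pref = -charges[c] * 2.0 * PI / p;
            for (size_t ia = 0; ia < ca.size(); ++ia)
              for (size_t ib = 0; ib < cb.size(); ++ib) {
                double val = 0.0;
                for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
                  for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
                    for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w)
                      val += Ex.get(ca[ia][0], cb[ib][0], t)
                           * Ey.get(ca[ia][1], cb[ib][1], u)
                           * Ez.get(ca[ia][2], cb[ib][2], w) * R.get(t, u, w);
                blk(ia, ib) += sh[A].coefs[pa] * sh[B].coefs[pb]
                             * prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2])
                             * prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2])
                             * pref * val;
              }
          }
        }
      for (size_t ia = 0; ia < ca.size(); ++ia)
        for (size_t ib = 0; ib < cb.size(); ++ib) {
          double v = blk(ia, ib) * na[ia] * nb[ib];
          V(sh[A].offset + ia, sh[B].offset + ib) = v;
          V(sh[B].offset + ib, sh[A].offset + ia) = v;
        }
    }
  }
  return V;
}

// ------------------------------------------------------- multipole moments
// Returns list with x,y,z, xx,yy,zz,xy,xz,yz, and the ten third moments
// xxx,yyy,zzz,xxy,xxz,xyy,yyz,xzz,yzz,xyz about origin O.
// [[Rcpp::export]]
List cpp_multipole(List basis, arma::vec origin) {
  auto sh = parse_shells(basis);
  int n = nbf_total(sh);
  std::vector<arma::mat> M(19, arma::mat(n, n, arma::fill::zeros));
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    double AOx = sh[A].x - origin[0], AOy = sh[A].y - origin[1], AOz = sh[A].z - origin[2];
    for (size_t B = 0; B < sh.size(); ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      std::vector<arma::mat> blk(19, arma::mat(ca.size(), cb.size(), arma::fill::zeros));
      for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
        for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
          double a = sh[A].exps[pa], b = sh[B].exps[pb];
          S1d Sx = build_S1d(sh[A].l + 3, sh[B].l, a, b, sh[A].x - sh[B].x);
          S1d Sy = build_S1d(sh[A].l + 3, sh[B].l, a, b, sh[A].y - sh[B].y);
          S1d Sz = build_S1d(sh[A].l + 3, sh[B].l, a, b, sh[A].z - sh[B].z);
          auto m1 = [&](const S1d& S1, double AO, int i, int j) {
            return S1.get(i + 1, j) + AO * S1.get(i, j);
          };
          auto m2 = [&](const S1d& S1, double AO, int i, int j) {
            return S1.get(i + 2, j) + 2.0 * AO * S1.get(i + 1, j) + AO * AO * S1.get(i, j);
          };
          auto m3 = [&](const S1d& S1, double AO, int i, int j) {
            return S1.get(i + 3, j) + 3.0 * AO * S1.get(i + 2, j)
                 + 3.0 * AO * AO * S1.get(i + 1, j) + AO * AO * AO * S1.get(i, j);
          };
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              int i1 = ca[ia][0], i2 = ca[ia][1], i3 = ca[ia][2];
              int j1 = cb[ib][0], j2 = cb[ib][1], j3 = cb[ib][2];
              double cc = sh[A].coefs[pa] * sh[B].coefs[pb]
                        * prim_norm(a, i1, i2, i3) * prim_norm(b, j1, j2, j3);
              double sx = Sx.get(i1, j1), sy = Sy.get(i2, j2), sz = Sz.get(i3, j3);
              double mx = m1(Sx, AOx, i1, j1), my = m1(Sy, AOy, i2, j2), mz = m1(Sz, AOz, i3, j3);
              double qx = m2(Sx, AOx, i1, j1), qy = m2(Sy, AOy, i2, j2), qz = m2(Sz, AOz, i3, j3);
              double ox = m3(Sx, AOx, i1, j1), oy = m3(Sy, AOy, i2, j2), oz = m3(Sz, AOz, i3, j3);
              blk[0](ia, ib) += cc * mx * sy * sz;                  // x
              blk[1](ia, ib) += cc * sx * my * sz;                  // y
              blk[2](ia, ib) += cc * sx * sy * mz;                  // z
              blk[3](ia, ib) += cc * qx * sy * sz;                  // xx
              blk[4](ia, ib) += cc * sx * qy * sz;                  // yy
              blk[5](ia, ib) += cc * sx * sy * qz;                  // zz
              blk[6](ia, ib) += cc * mx * my * sz;                  // xy
              blk[7](ia, ib) += cc * mx * sy * mz;                  // xz
              blk[8](ia, ib) += cc * sx * my * mz;                  // yz
              blk[9](ia, ib) += cc * ox * sy * sz;                  // xxx
              blk[10](ia, ib) += cc * sx * oy * sz;                 // yyy
              blk[11](ia, ib) += cc * sx * sy * oz;                 // zzz
              blk[12](ia, ib) += cc * qx * my * sz;                 // xxy
              blk[13](ia, ib) += cc * qx * sy * mz;                 // xxz
              blk[14](ia, ib) += cc * mx * qy * sz;                 // xyy
              blk[15](ia, ib) += cc * sx * qy * mz;                 // yyz
              blk[16](ia, ib) += cc * mx * sy * qz;                 // xzz
              blk[17](ia, ib) += cc * sx * my * qz;                 // yzz
              blk[18](ia, ib) += cc * mx * my * mz;                 // xyz
            }
        }
      for (int m = 0; m < 19; ++m)
        for (size_t ia = 0; ia < ca.size(); ++ia)
          for (size_t ib = 0; ib < cb.size(); ++ib)
            M[m](sh[A].offset + ia, sh[B].offset + ib) = blk[m](ia, ib) * na[ia] * nb[ib];
    }
  }
  return List::create(_["x"] = M[0], _["y"] = M[1], _["z"] = M[2],
                      _["xx"] = M[3], _["yy"] = M[4], _["zz"] = M[5],
                      _["xy"] = M[6], _["xz"] = M[7], _["yz"] = M[8],
                      _["xxx"] = M[9], _["yyy"] = M[10], _["zzz"] = M[11],
                      _["xxy"] = M[12], _["xxz"] = M[13], _["xyy"] = M[14],
                      _["yyz"] = M[15], _["xzz"] = M[16], _["yzz"] = M[17],
                      _["xyz"] = M[18]);
}

// ------------------------------------------------------------ 2-center ERI
// [[Rcpp::export]]
arma::mat cpp_eri2c(List basis) {
  auto sh = parse_shells(basis);
  int n = nbf_total(sh);
  arma::mat V(n, n, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    for (size_t B = 0; B <= A; ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
      int la = sh[A].l, lb = sh[B].l;
      for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
        for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
          double a = sh[A].exps[pa], b = sh[B].exps[pb];
          // single-center "pairs": E for (la,0) with AB=0 at each center
          Etab Ea = build_E(la, 0, a, 0.0, 0.0); // exponent b=0 gives plain Hermite expansion
          Etab Eb = build_E(lb, 0, b, 0.0, 0.0);
          double alpha = a * b / (a + b);
          Rtab Rfull = build_R(la + lb, la + lb, la + lb, alpha,
                               sh[A].x - sh[B].x, sh[A].y - sh[B].y, sh[A].z - sh[B].z);
          double pref = 2.0 * std::pow(PI, 2.5) / (a * b * std::sqrt(a + b));
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              double val = 0.0;
              for (int t = 0; t <= ca[ia][0]; ++t)
                for (int u = 0; u <= ca[ia][1]; ++u)
                  for (int w = 0; w <= ca[ia][2]; ++w) {
                    double Eabc = Ea.get(ca[ia][0], 0, t) * Ea.get(ca[ia][1], 0, u) * Ea.get(ca[ia][2], 0, w);
                    if (Eabc == 0.0) continue;
                    for (int tt = 0; tt <= cb[ib][0]; ++tt)
                      for (int uu = 0; uu <= cb[ib][1]; ++uu)
                        for (int ww = 0; ww <= cb[ib][2]; ++ww) {
                          double Ecd = Eb.get(cb[ib][0], 0, tt) * Eb.get(cb[ib][1], 0, uu) * Eb.get(cb[ib][2], 0, ww);
                          if (Ecd == 0.0) continue;
                          double sgn = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
                          val += Eabc * Ecd * sgn * Rfull.get(t + tt, u + uu, w + ww);
                        }
                  }
              blk(ia, ib) += sh[A].coefs[pa] * sh[B].coefs[pb]
                           * prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2])
                           * prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2])
                           * pref * val;
            }
        }
      for (size_t ia = 0; ia < ca.size(); ++ia)
        for (size_t ib = 0; ib < cb.size(); ++ib) {
          double v = blk(ia, ib) * na[ia] * nb[ib];
          V(sh[A].offset + ia, sh[B].offset + ib) = v;
          V(sh[B].offset + ib, sh[A].offset + ia) = v;
        }
    }
  }
  return V;
}

// ------------------------------------------------------------ 3-center ERI
// (mu nu | X): orbital basis pair (mu,nu) with auxiliary function X.
// Returns a cube n x n x naux.
// [[Rcpp::export]]
arma::cube cpp_eri3c(List basis, List auxbasis) {
  auto sh = parse_shells(basis);
  auto ax = parse_shells(auxbasis);
  int n = nbf_total(sh), nx = nbf_total(ax);
  arma::cube out(n, n, nx, arma::fill::zeros);
  for (size_t A = 0; A < sh.size(); ++A) {
    std::vector<std::array<int, 3>> ca; cart_comps(sh[A].l, ca);
    auto na = comp_norms(sh[A]);
    for (size_t B = 0; B <= A; ++B) {
      std::vector<std::array<int, 3>> cb; cart_comps(sh[B].l, cb);
      auto nb = comp_norms(sh[B]);
      int lab = sh[A].l + sh[B].l;
      for (size_t X = 0; X < ax.size(); ++X) {
        std::vector<std::array<int, 3>> cx; cart_comps(ax[X].l, cx);
        auto nxn = comp_norms(ax[X]);
        arma::cube blk(ca.size(), cb.size(), cx.size(), arma::fill::zeros);
        int lx = ax[X].l;
        for (arma::uword pa = 0; pa < sh[A].exps.n_elem; ++pa)
          for (arma::uword pb = 0; pb < sh[B].exps.n_elem; ++pb) {
            double a = sh[A].exps[pa], b = sh[B].exps[pb], p = a + b;
            double Px = (a * sh[A].x + b * sh[B].x) / p;
            double Py = (a * sh[A].y + b * sh[B].y) / p;
            double Pz = (a * sh[A].z + b * sh[B].z) / p;
            Etab Ex = build_E(sh[A].l, sh[B].l, a, b, sh[A].x - sh[B].x);
            Etab Ey = build_E(sh[A].l, sh[B].l, a, b, sh[A].y - sh[B].y);
            Etab Ez = build_E(sh[A].l, sh[B].l, a, b, sh[A].z - sh[B].z);
            for (arma::uword px = 0; px < ax[X].exps.n_elem; ++px) {
              double c = ax[X].exps[px];
              double alpha = p * c / (p + c);
              Etab Exx = build_E(lx, 0, c, 0.0, 0.0);
              Rtab R = build_R(lab + lx, lab + lx, lab + lx, alpha,
                               Px - ax[X].x, Py - ax[X].y, Pz - ax[X].z);
              double pref = 2.0 * std::pow(PI, 2.5) / (p * c * std::sqrt(p + c));
              for (size_t ia = 0; ia < ca.size(); ++ia)
                for (size_t ib = 0; ib < cb.size(); ++ib) {
                  for (size_t ix = 0; ix < cx.size(); ++ix) {
                    double val = 0.0;
                    for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
                      for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
                        for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w) {
                          double Eab = Ex.get(ca[ia][0], cb[ib][0], t)
                                     * Ey.get(ca[ia][1], cb[ib][1], u)
                                     * Ez.get(ca[ia][2], cb[ib][2], w);
                          if (Eab == 0.0) continue;
                          for (int tt = 0; tt <= cx[ix][0]; ++tt)
                            for (int uu = 0; uu <= cx[ix][1]; ++uu)
                              for (int ww = 0; ww <= cx[ix][2]; ++ww) {
                                double Exv = Exx.get(cx[ix][0], 0, tt)
                                           * Exx.get(cx[ix][1], 0, uu)
                                           * Exx.get(cx[ix][2], 0, ww);
                                if (Exv == 0.0) continue;
                                double sgn = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
                                val += Eab * Exv * sgn * R.get(t + tt, u + uu, w + ww);
                              }
                        }
                    blk(ia, ib, ix) += sh[A].coefs[pa] * sh[B].coefs[pb] * ax[X].coefs[px]
                                     * prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2])
                                     * prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2])
                                     * prim_norm(c, cx[ix][0], cx[ix][1], cx[ix][2])
                                     * pref * val;
                  }
                }
            }
          }
        for (size_t ia = 0; ia < ca.size(); ++ia)
          for (size_t ib = 0; ib < cb.size(); ++ib)
            for (size_t ix = 0; ix < cx.size(); ++ix) {
              double v = blk(ia, ib, ix) * na[ia] * nb[ib] * nxn[ix];
              out(sh[A].offset + ia, sh[B].offset + ib, ax[X].offset + ix) = v;
              out(sh[B].offset + ib, sh[A].offset + ia, ax[X].offset + ix) = v;
            }
      }
    }
  }
  return out;
}
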