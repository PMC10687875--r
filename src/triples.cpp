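// Perturbative triples in a spin-orbital basis.
//
// cpp_triples_explicit: full (T) with explicit energy denominators
//   (the brute-force oracle), including the off-diagonal-Fock
//   disconnected term of semicanonical open-shell references.
//
// cpp_triples_central: Laplace-transform (T) contribution of one
//   central LMO; the energy denominators are factorized into
//   quadrature-dressed intermediates so triples amplitudes are formed
//   only for the central occupied index.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// flat index helpers for R column-major 4d arrays
inline int ix4(int i, int j, int k, int l, int d1, int d2, int d3) {
  return i + d1 * (j + d2 * (k + d3 * l));
}

// apply P(a/bc) to cube B(a,b,c) stored flat (v^3): W = B - B(b,a,c) - B(c,b,a)
void p_abc(const std::vector<double>& B, std::vector<double>& W, int v) {
  for (int c = 0; c < v; ++c)
    for (int b = 0; b < v; ++b)
      for (int a = 0; a < v; ++a) {
        W[a + v * (b + v * c)] = B[a + v * (b + v * c)]
          - B[b + v * (a + v * c)]
          - B[c + v * (b + v * a)];
      }
}

} // namespace

// [[Rcpp::export]]
double cpp_triples_explicit(arma::vec eps_o, arma::vec eps_v,
                            NumericMatrix f_ov, NumericMatrix t1,
                            NumericVector t2, NumericVector Voovv,
                            NumericVector Vvovv, NumericVector Vovoo) {
  const int no = eps_o.n_elem, nv = eps_v.n_elem;
  if (no < 3) return 0.0;
  const double* T2 = t2.begin();
  const double* OV = Voovv.begin();
  const double* VO = Vvovv.begin();
  const double* OO = Vovoo.begin();
  // per-i copies: Vv_i(e,(b,c)) and t2_i(m,(b,c))
  std::vector<arma::mat> Vvi(no), t2i(no);
  for (int i = 0; i < no; ++i) {
    Vvi[i].set_size(nv, nv * nv);
    for (int c = 0; c < nv; ++c)
      for (int b = 0; b < nv; ++b)
        for (int e = 0; e < nv; ++e)
          Vvi[i](e, b + nv * c) = VO[ix4(e, i, b, c, nv, no, nv)];
    t2i[i].set_size(no, nv * nv);
    for (int c = 0; c < nv; ++c)
      for (int b = 0; b < nv; ++b)
        for (int m = 0; m < no; ++m)
          t2i[i](m, b + nv * c) = T2[ix4(i, m, b, c, no, no, nv)];
  }
  auto t2slice = [&](int j, int k) {
    arma::mat M(nv, nv);
    for (int e = 0; e < nv; ++e)
      for (int a = 0; a < nv; ++a)
        M(a, e) = T2[ix4(j, k, a, e, no, no, nv)];
    return M;
  };
  auto vooo = [&](int j, int k) {
    arma::mat M(no, nv);
    for (int a = 0; a < nv; ++a)
      for (int m = 0; m < no; ++m)
        M(m, a) = OO[ix4(m, a, j, k, no, nv, no)];
    return M;
  };
  std::vector<double> base(nv * nv * nv), W(nv * nv * nv), D0(nv * nv * nv), Wd(nv * nv * nv);
  double E = 0.0;
  for (int i = 0; i < no; ++i)
    for (int j = i + 1; j < no; ++j)
      for (int k = j + 1; k < no; ++k) {
        std::fill(base.begin(), base.end(), 0.0);
        std::fill(D0.begin(), D0.end(), 0.0);
        int occ[3][3] = {{i, j, k}, {j, i, k}, {k, j, i}};
        double sg[3] = {1.0, -1.0, -1.0};
        for (int p = 0; p < 3; ++p) {
          int i0 = occ[p][0], j0 = occ[p][1], k0 = occ[p][2];
          double s = sg[p];
          arma::mat X1 = t2slice(j0, k0) * Vvi[i0];     // (a, (b,c))
          arma::mat X2 = vooo(j0, k0).t() * t2i[i0];    // (a, (b,c))
          for (int bc = 0; bc < nv * nv; ++bc)
            for (int a = 0; a < nv; ++a)
              base[a + nv * bc] += s * (X1(a, bc) - X2(a, bc));
          // disconnected: t1(i0,a) <j0 k0||bc> + f(i0,a) t2(j0,k0,b,c)
          for (int c = 0; c < nv; ++c)
            for (int b = 0; b < nv; ++b) {
              double vjk = OV[ix4(j0, k0, b, c, no, no, nv)];
              double tjk = T2[ix4(j0, k0, b, c, no, no, nv)];
              for (int a = 0; a < nv; ++a)
                D0[a + nv * (b + nv * c)] += s * (t1(i0, a) * vjk + f_ov(i0, a) * tjk);
            }
        }
        p_abc(base, W, nv);
        p_abc(D0, Wd, nv);
        double eo = eps_o[i] + eps_o[j] + eps_o[k];
        double contrib = 0.0;
        for (int c = 0; c < nv; ++c)
          for (int b = 0; b < nv; ++b)
            for (int a = 0; a < nv; ++a) {
              double D = eo - eps_v[a] - eps_v[b] - eps_v[c];
              double w = W[a + nv * (b + nv * c)];
              contrib += w * (w + Wd[a + nv * (b + nv * c)]) / D;
            }
        E += contrib / 6.0;
      }
  return E;
}

// [[Rcpp::export]]
double cpp_triples_central(arma::vec eps_o, arma::vec eps_v,
                           NumericMatrix f_ov, NumericMatrix t1,
                           NumericVector t2, NumericVector Voovv,
                           NumericVector Vvovv, NumericVector Vovoo,
                           arma::vec u, arma::vec tq, arma::vec wq,
                           double mu) {
  const int no = eps_o.n_elem, nv = eps_v.n_elem;
  if (no < 2) return 0.0;
  const double* T2 = t2.begin();
  const double* OV = Voovv.begin();
  const double* VO = Vvovv.begin();
  const double* OO = Vovoo.begin();
  double E = 0.0;
  std::vector<double> base(nv * nv * nv), W(nv * nv * nv), D0(nv * nv * nv), Wd(nv * nv * nv);
  for (arma::uword q = 0; q < tq.n_elem; ++q) {
    double t = tq[q];
    arma::vec ho(no), hv(nv);
    for (int m = 0; m < no; ++m) ho[m] = std::exp((eps_o[m] - mu) * t / 2.0);
    for (int a = 0; a < nv; ++a) hv[a] = std::exp(-(eps_v[a] - mu) * t / 2.0);
    arma::vec uo = u % ho;                       // u-contraction includes the dressing
    // I1(e,(b,c)) = sum_i u_i ho_i VO(e,i,b,c) * hv_b hv_c
    arma::mat I1(nv, nv * nv, arma::fill::zeros);
    for (int c = 0; c < nv; ++c)
      for (int b = 0; b < nv; ++b) {
        double hbc = hv[b] * hv[c];
        for (int e = 0; e < nv; ++e) {
          double acc = 0.0;
          for (int i = 0; i < no; ++i)
            acc += uo[i] * VO[ix4(e, i, b, c, nv, no, nv)];
          I1(e, b + nv * c) = acc * hbc;
        }
      }
    // Vvd_j(e,(b,c)) per j (dressed: ho_j hv_b hv_c, e free of dressing)
    std::vector<arma::mat> Vvd(no);
    for (int j = 0; j < no; ++j) {
      Vvd[j].set_size(nv, nv * nv);
      for (int c = 0; c < nv; ++c)
        for (int b = 0; b < nv; ++b) {
          double f = ho[j] * hv[b] * hv[c];
          for (int e = 0; e < nv; ++e)
            Vvd[j](e, b + nv * c) = VO[ix4(e, j, b, c, nv, no, nv)] * f;
        }
    }
    // T3u(k): mat(a,e) = sum_i uo_i t2(i,k,a,e) * ho_k hv_a  (e undressed)
    std::vector<arma::mat> T3u(no);
    for (int k = 0; k < no; ++k) {
      T3u[k].set_size(nv, nv);
      for (int e = 0; e < nv; ++e)
        for (int a = 0; a < nv; ++a) {
          double acc = 0.0;
          for (int i = 0; i < no; ++i)
            acc += uo[i] * T2[ix4(i, k, a, e, no, no, nv)];
          T3u[k](a, e) = acc * ho[k] * hv[a];
        }
    }
    // t2_3d slice (j,k): mat(a,e) = t2(j,k,a,e) ho_j ho_k hv_a
    auto t2slice3 = [&](int j, int k) {
      arma::mat M(nv, nv);
      double f = ho[j] * ho[k];
      for (int e = 0; e < nv; ++e)
        for (int a = 0; a < nv; ++a)
          M(a, e) = T2[ix4(j, k, a, e, no, no, nv)] * f * hv[a];
      return M;
    };
    // T1u(m,(b,c)) = sum_i uo_i t2(i,m,b,c) hv_b hv_c  (m undressed)
    arma::mat T1u(no, nv * nv);
    for (int c = 0; c < nv; ++c)
      for (int b = 0; b < nv; ++b) {
        double hbc = hv[b] * hv[c];
        for (int m = 0; m < no; ++m) {
          double acc = 0.0;
          for (int i = 0; i < no; ++i)
            acc += uo[i] * T2[ix4(i, m, b, c, no, no, nv)];
          T1u(m, b + nv * c) = acc * hbc;
        }
      }
    // t2_1d per i: mat(m,(b,c)) = t2(i,m,b,c) ho_i hv_b hv_c
    std::vector<arma::mat> t21d(no);
    for (int i = 0; i < no; ++i) {
      t21d[i].set_size(no, nv * nv);
      for (int c = 0; c < nv; ++c)
        for (int b = 0; b < nv; ++b) {
          double f = ho[i] * hv[b] * hv[c];
          for (int m = 0; m < no; ++m)
            t21d[i](m, b + nv * c) = T2[ix4(i, m, b, c, no, no, nv)] * f;
        }
    }
    // Vovoo dressed (m,a,j,k): hv_a ho_j ho_k (m undressed); plus its
    // u-contraction over the third index: VOu(m,a,k)
    auto voooD = [&](int j, int k) {
      arma::mat M(no, nv);
      double f = ho[j] * ho[k];
      for (int a = 0; a < nv; ++a)
        for (int m = 0; m < no; ++m)
          M(m, a) = OO[ix4(m, a, j, k, no, nv, no)] * f * hv[a];
      return M;
    };
    std::vector<arma::mat> VOu(no);                // per k: (m,a)
    for (int k = 0; k < no; ++k) {
      VOu[k].set_size(no, nv);
      for (int a = 0; a < nv; ++a)
        for (int m = 0; m < no; ++m) {
          double acc = 0.0;
          for (int j = 0; j < no; ++j)
            acc += uo[j] * OO[ix4(m, a, j, k, no, nv, no)];
          VOu[k](m, a) = acc * hv[a] * ho[k];
        }
    }
    // dressed singles-type pieces
    arma::vec t1u(nv), fovu(nv);
    for (int a = 0; a < nv; ++a) {
      double a1 = 0.0, a2 = 0.0;
      for (int i = 0; i < no; ++i) {
        a1 += uo[i] * t1(i, a);
        a2 += uo[i] * f_ov(i, a);
      }
      t1u[a] = a1 * hv[a]; fovu[a] = a2 * hv[a];
    }
    // oovvu(k,(b,c)) = sum_j uo_j OV(j,k,b,c) ho_k hv_b hv_c  (all dressed)
    arma::mat oovvu(no, nv * nv);
    arma::mat t2u4(no, nv * nv);
    for (int c = 0; c < nv; ++c)
      for (int b = 0; b < nv; ++b) {
        double hbc = hv[b] * hv[c];
        for (int k = 0; k < no; ++k) {
          double acc = 0.0, acc2 = 0.0;
          for (int j = 0; j < no; ++j) {
            acc += uo[j] * OV[ix4(j, k, b, c, no, no, nv)];
            acc2 += uo[j] * T2[ix4(j, k, b, c, no, no, nv)];
          }
          oovvu(k, b + nv * c) = acc * ho[k] * hbc;
          t2u4(k, b + nv * c) = acc2 * ho[k] * hbc;
        }
      }
    // the (j,k) summand is symmetric under j<->k exchange (W and the
    // disconnected part are both antisymmetric in the occupied pair),
    // so the strict ordering is doubled
    double eq = 0.0;
    for (int j = 0; j < no; ++j)
      for (int k = j + 1; k < no; ++k) {
        std::fill(base.begin(), base.end(), 0.0);
        std::fill(D0.begin(), D0.end(), 0.0);
        // perm (c, j, k): +
        arma::mat X = t2slice3(j, k) * I1;                 // (a,(b,c))
        // perm (j, c, k): -  term1 = sum_e T3u[k](a,e) Vvd[j](e,bc)
        X -= T3u[k] * Vvd[j];
        // perm (k, j, c): -  term1 = -sum_e T3u[j](a,e) Vvd[k](e,bc)  (sign folded)
        X += T3u[j] * Vvd[k];
        // hole terms
        // perm (c,j,k): - sum_m T1u(m,bc) voooD(j,k)(m,a)
        X -= voooD(j, k).t() * T1u;
        // perm (j,c,k): + sum_m t21d[j](m,bc) VOu[k](m,a)
        X += VOu[k].t() * t21d[j];
        // perm (k,j,c): - sum_m t21d[k](m,bc) * (-VOu[j](m,a))
        X -= VOu[j].t() * t21d[k];
        for (int bc = 0; bc < nv * nv; ++bc)
          for (int a = 0; a < nv; ++a)
            base[a + nv * bc] = X(a, bc);
        // disconnected
        for (int c = 0; c < nv; ++c)
          for (int b = 0; b < nv; ++b) {
            int bc = b + nv * c;
            double vd = OV[ix4(j, k, b, c, no, no, nv)] * ho[j] * ho[k] * hv[b] * hv[c];
            double td = T2[ix4(j, k, b, c, no, no, nv)] * ho[j] * ho[k] * hv[b] * hv[c];
            for (int a = 0; a < nv; ++a) {
              double val = t1u[a] * vd + fovu[a] * td
                - t1(j, a) * ho[j] * hv[a] * oovvu(k, bc)
                - f_ov(j, a) * ho[j] * hv[a] * t2u4(k, bc)
                + t1(k, a) * ho[k] * hv[a] * oovvu(j, bc)
                + f_ov(k, a) * ho[k] * hv[a] * t2u4(j, bc);
              D0[a + nv * bc] += val;
            }
          }
        p_abc(base, W, nv);
        p_abc(D0, Wd, nv);
        for (int x = 0; x < nv * nv * nv; ++x)
          eq += 2.0 * W[x] * (W[x] + Wd[x]);
      }
    E -= wq[q] * eq / 36.0;
  }
  return E;
}
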