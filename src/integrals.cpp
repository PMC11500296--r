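// Gaussian AO integrals over contracted Cartesian shells:
// overlap, kinetic, nuclear attraction, dipole moment and two-electron
// repulsion integrals via the McMurchie-Davidson scheme (Hermite expansion
// of Gaussian products + Boys function / Hermite Coulomb recursions).
//
// Contraction coefficients are expected pre-scaled on the R side (primitive
// and shell normalization); this file works with raw primitives only.
// Cartesian components within a shell are ordered lx descending, then ly
// descending (l=1: x,y,z; l=2: xx,xy,xz,yy,yz,zz).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.141592653589793238462643383279;

// ---------------------------------------------------------------------------
// Boys function F_m(T), m = 0..mmax, by downward recursion from a Taylor-type
// series at moderate T and the asymptotic/erf form at large T.
static void boys(int mmax, double T, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (T < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T < 35.0) {
    // series for F_mmax: sum_k (2T)^k (2m-1)!! / (2m+2k+1)!! * exp(-T)
    double expT = std::exp(-T);
    double sum = 0.0, term = 1.0 / (2.0 * mmax + 1.0);
    int k = 0;
    while (true) {
      sum += term;
      ++k;
      term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
      if (term < 1e-17 * sum || k > 500) break;
    }
    F[mmax] = sum * expT;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2.0 * T * F[m] + expT) / (2.0 * m - 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(PI / T) * std::erf(std::sqrt(T));
    double expT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for one dimension.
// Stored flat: E[(i*(jmax+1) + j)*(imax+jmax+1) + t].
struct ETable {
  int imax, jmax, tdim;
  std::vector<double> v;
  inline double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
  }
  inline double &ref(int i, int j, int t) {
    return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
  }
};

static void build_E(ETable &E, int imax, int jmax, double a, double b,
                    double AB) {
  E.imax = imax;
  E.jmax = jmax;
  E.tdim = imax + jmax + 1;
  E.v.assign((size_t)(imax + 1) * (jmax + 1) * E.tdim, 0.0);
  double p = a + b;
  double mu = a * b / p;
  double XPA = -b * AB / p;  // P - A with AB = A - B
  double XPB = a * AB / p;   // P - B
  // Note: with AB = Ax - Bx, P = (aA + bB)/p, P - A = -(b/p) AB, P - B = (a/p) AB.
  E.ref(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      if (j == 0) {
        for (int t = 0; t <= i; ++t)
          E.ref(i, 0, t) = (1.0 / (2.0 * p)) * E.at(i - 1, 0, t - 1) +
                           XPA * E.at(i - 1, 0, t) +
                           (t + 1) * E.at(i - 1, 0, t + 1);
      } else {
        for (int t = 0; t <= i + j; ++t)
          E.ref(i, j, t) = (1.0 / (2.0 * p)) * E.at(i, j - 1, t - 1) +
                           XPB * E.at(i, j - 1, t) +
                           (t + 1) * E.at(i, j - 1, t + 1);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R^0_{tuv}(p, PC) built from Boys values.
// R stored as flat [n][t][u][v] with n-levels collapsed during the build.
struct RTable {
  int L;
  std::vector<double> v;  // [t][u][v] at n = 0
  inline double at(int t, int u, int vv) const {
    if (t < 0 || u < 0 || vv < 0) return 0.0;
    if (t + u + vv > L) return 0.0;
    return v[(size_t)(t * (L + 1) + u) * (L + 1) + vv];
  }
};

static void build_R(RTable &R, int L, double p, const double PC[3]) {
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  std::vector<double> F;
  boys(L, T, F);
  int d = L + 1;
  // full table over n: r[n][t][u][v]
  std::vector<double> r((size_t)d * d * d * d, 0.0);
  auto idx = [d](int n, int t, int u, int v) {
    return (((size_t)n * d + t) * d + u) * d + v;
  };
  double mp = 1.0;
  for (int n = 0; n <= L; ++n) {
    r[idx(n, 0, 0, 0)] = mp * F[n];
    mp *= -2.0 * p;
  }
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t) {
      for (int u = 0; u <= tot - t; ++u) {
        int v = tot - t - u;
        for (int n = 0; n <= L - tot; ++n) {
          double val;
          if (t > 0) {
            val = PC[0] * r[idx(n + 1, t - 1, u, v)];
            if (t > 1) val += (t - 1) * r[idx(n + 1, t - 2, u, v)];
          } else if (u > 0) {
            val = PC[1] * r[idx(n + 1, t, u - 1, v)];
            if (u > 1) val += (u - 1) * r[idx(n + 1, t, u - 2, v)];
          } else {
            val = PC[2] * r[idx(n + 1, t, u, v - 1)];
            if (v > 1) val += (v - 1) * r[idx(n + 1, t, u, v - 2)];
          }
          r[idx(n, t, u, v)] = val;
        }
      }
    }
  }
  R.L = L;
  R.v.assign((size_t)d * d * d, 0.0);
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int v = 0; v <= L - t - u; ++v)
        R.v[(size_t)(t * d + u) * d + v] = r[idx(0, t, u, v)];
}

// ---------------------------------------------------------------------------
// Shell bookkeeping
struct Shell {
  int l;
  double A[3];
  std::vector<double> alpha, coef;
  int ncart;
  std::vector<int> lx, ly, lz;  // cartesian component exponents
};

static std::vector<Shell> unpack_shells(const List &shells) {
  int ns = shells.size();
  std::vector<Shell> sh(ns);
  for (int s = 0; s < ns; ++s) {
    List one = shells[s];
    Shell &S = sh[s];
    S.l = as<int>(one["l"]);
    NumericVector A = one["center"];
    S.A[0] = A[0]; S.A[1] = A[1]; S.A[2] = A[2];
    NumericVector al = one["alpha"], co = one["coef"];
    S.alpha.assign(al.begin(), al.end());
    S.coef.assign(co.begin(), co.end());
    S.ncart = (S.l + 1) * (S.l + 2) / 2;
    for (int ax = S.l; ax >= 0; --ax)
      for (int ay = S.l - ax; ay >= 0; --ay) {
        S.lx.push_back(ax);
        S.ly.push_back(ay);
        S.lz.push_back(S.l - ax - ay);
      }
  }
  return sh;
}

// Primitive-pair data for a shell pair, E tables per dimension.
struct PrimPair {
  double p, cc;
  double P[3];
  ETable E[3];
};

static void shell_pair(const Shell &A, const Shell &B, int extraj,
                       std::vector<PrimPair> &pairs) {
  pairs.clear();
  for (size_t ia = 0; ia < A.alpha.size(); ++ia) {
    for (size_t ib = 0; ib < B.alpha.size(); ++ib) {
      double a = A.alpha[ia], b = B.alpha[ib];
      double p = a + b;
      // screen on the Gaussian product prefactor
      double r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double ab = A.A[d] - B.A[d];
        r2 += ab * ab;
      }
      double K = std::exp(-a * b / p * r2);
      double cc = A.coef[ia] * B.coef[ib];
      if (std::fabs(cc) * K < 1e-16) continue;
      PrimPair pp;
      pp.p = p;
      pp.cc = cc;
      for (int d = 0; d < 3; ++d) {
        pp.P[d] = (a * A.A[d] + b * B.A[d]) / p;
        build_E(pp.E[d], A.l, B.l + extraj, a, b, A.A[d] - B.A[d]);
      }
      pairs.push_back(std::move(pp));
    }
  }
}

// ---------------------------------------------------------------------------
// One-electron integrals: overlap, kinetic, nuclear attraction, dipole.
// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List shells, NumericMatrix coords,
                      NumericVector charges) {
  std::vector<Shell> sh = unpack_shells(shells);
  int ns = sh.size();
  std::vector<int> off(ns, 0);
  int nb = 0;
  for (int s = 0; s < ns; ++s) {
    off[s] = nb;
    nb += sh[s].ncart;
  }
  NumericMatrix S(nb, nb), T(nb, nb), V(nb, nb);
  NumericMatrix DX(nb, nb), DY(nb, nb), DZ(nb, nb);
  int nat = coords.nrow();

  for (int sa = 0; sa < ns; ++sa) {
    for (int sb = 0; sb <= sa; ++sb) {
      const Shell &A = sh[sa], &B = sh[sb];
      for (size_t ia = 0; ia < A.alpha.size(); ++ia) {
        for (size_t ib = 0; ib < B.alpha.size(); ++ib) {
          double a = A.alpha[ia], bb = B.alpha[ib];
          double p = a + bb;
          double cc = A.coef[ia] * B.coef[ib];
          double r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            double ab = A.A[d] - B.A[d];
            r2 += ab * ab;
          }
          if (std::fabs(cc) * std::exp(-a * bb / p * r2) < 1e-16) continue;
          ETable E[3];
          double P[3], PC[3];
          for (int d = 0; d < 3; ++d) {
            build_E(E[d], A.l, B.l + 2, a, bb, A.A[d] - B.A[d]);
            P[d] = (a * A.A[d] + bb * B.A[d]) / p;
          }
          double sq = std::sqrt(PI / p);
          RTable R;
          for (int ca = 0; ca < A.ncart; ++ca) {
            int ii[3] = {A.lx[ca], A.ly[ca], A.lz[ca]};
            for (int cb = 0; cb < B.ncart; ++cb) {
              int jj[3] = {B.lx[cb], B.ly[cb], B.lz[cb]};
              double s1[3], sp1[3], t1[3];
              for (int d = 0; d < 3; ++d) {
                int i = ii[d], j = jj[d];
                s1[d] = E[d].at(i, j, 0) * sq;
                sp1[d] = E[d].at(i, j + 1, 0) * sq;  // moment +1 on ket
                double sjp2 = E[d].at(i, j + 2, 0) * sq;
                double sjm2 = (j >= 2) ? E[d].at(i, j - 2, 0) * sq : 0.0;
                t1[d] = -2.0 * bb * bb * sjp2 +
                        bb * (2.0 * j + 1.0) * s1[d] -
                        0.5 * j * (j - 1.0) * sjm2;
              }
              double sv = s1[0] * s1[1] * s1[2];
              double tv = t1[0] * s1[1] * s1[2] + s1[0] * t1[1] * s1[2] +
                          s1[0] * s1[1] * t1[2];
              // dipole about the origin: <a| r_d |b> = S(a, b+1_d) + B_d S
              double dx = (sp1[0] + B.A[0] * s1[0]) * s1[1] * s1[2];
              double dy = s1[0] * (sp1[1] + B.A[1] * s1[1]) * s1[2];
              double dz = s1[0] * s1[1] * (sp1[2] + B.A[2] * s1[2]);
              int I = off[sa] + ca, J = off[sb] + cb;
              S(I, J) += cc * sv;
              T(I, J) += cc * tv;
              DX(I, J) += cc * dx;
              DY(I, J) += cc * dy;
              DZ(I, J) += cc * dz;
            }
          }
          // nuclear attraction
          int Lp = A.l + B.l;
          for (int n = 0; n < nat; ++n) {
            for (int d = 0; d < 3; ++d) PC[d] = P[d] - coords(n, d);
            build_R(R, Lp, p, PC);
            double pref = -charges[n] * 2.0 * PI / p;
            for (int ca = 0; ca < A.ncart; ++ca) {
              int ii[3] = {A.lx[ca], A.ly[ca], A.lz[ca]};
              for (int cb = 0; cb < B.ncart; ++cb) {
                int jj[3] = {B.lx[cb], B.ly[cb], B.lz[cb]};
                double acc = 0.0;
                for (int t = 0; t <= ii[0] + jj[0]; ++t) {
                  double ex = E[0].at(ii[0], jj[0], t);
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= ii[1] + jj[1]; ++u) {
                    double ey = E[1].at(ii[1], jj[1], u);
                    if (ey == 0.0) continue;
                    for (int v = 0; v <= ii[2] + jj[2]; ++v) {
                      double ez = E[2].at(ii[2], jj[2], v);
                      if (ez == 0.0) continue;
                      acc += ex * ey * ez * R.at(t, u, v);
                    }
                  }
                }
                V(off[sa] + ca, off[sb] + cb) += cc * pref * acc;
              }
            }
          }
        }
      }
    }
  }
  // symmetrize (only lower triangle filled for sa > sb; diagonal blocks were
  // fully accumulated when sa == sb since ca/cb loops cover all pairs)
  for (int sa = 0; sa < ns; ++sa)
    for (int sb = 0; sb < sa; ++sb)
      for (int ca = 0; ca < sh[sa].ncart; ++ca)
        for (int cb = 0; cb < sh[sb].ncart; ++cb) {
          int I = off[sa] + ca, J = off[sb] + cb;
          S(J, I) = S(I, J);
          T(J, I) = T(I, J);
          V(J, I) = V(I, J);
          DX(J, I) = DX(I, J);
          DY(J, I) = DY(I, J);
          DZ(J, I) = DZ(I, J);
        }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V, _["dx"] = DX,
                      _["dy"] = DY, _["dz"] = DZ);
}

// ---------------------------------------------------------------------------
// Two-electron repulsion integrals, chemists' notation (ab|cd), full
// N^4 cartesian tensor (8-fold symmetry exploited over shell quartets).
// [[Rcpp::export(name = ".cpp_eri")]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = unpack_shells(shells);
  int ns = sh.size();
  std::vector<int> off(ns, 0);
  int nb = 0;
  for (int s = 0; s < ns; ++s) {
    off[s] = nb;
    nb += sh[s].ncart;
  }
  NumericVector out((R_xlen_t)nb * nb * nb * nb);
  double *g = out.begin();
  size_t N = nb;
  auto put = [&](int i, int j, int k, int l, double val) {
    g[((size_t)l * N * N * N) + ((size_t)k * N * N) + ((size_t)j * N) + i] =
        val;
  };

  // precompute shell-pair primitive data
  int npair = ns * (ns + 1) / 2;
  std::vector<std::vector<PrimPair>> pair_data(npair);
  std::vector<std::pair<int, int>> pair_sh(npair);
  int pc = 0;
  for (int sa = 0; sa < ns; ++sa)
    for (int sb = 0; sb <= sa; ++sb) {
      shell_pair(sh[sa], sh[sb], 0, pair_data[pc]);
      pair_sh[pc] = {sa, sb};
      ++pc;
    }

  RTable R;
  std::vector<double> block;
  for (int pAB = 0; pAB < npair; ++pAB) {
    int sa = pair_sh[pAB].first, sb = pair_sh[pAB].second;
    const Shell &A = sh[sa], &B = sh[sb];
    for (int pCD = 0; pCD <= pAB; ++pCD) {
      int sc = pair_sh[pCD].first, sd = pair_sh[pCD].second;
      const Shell &C = sh[sc], &D = sh[sd];
      int na = A.ncart, nbc = B.ncart, ncc = C.ncart, nd = D.ncart;
      block.assign((size_t)na * nbc * ncc * nd, 0.0);
      int L = A.l + B.l + C.l + D.l;
      for (const PrimPair &pp : pair_data[pAB]) {
        for (const PrimPair &qq : pair_data[pCD]) {
          double p = pp.p, q = qq.p;
          double alpha = p * q / (p + q);
          double pref =
              2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q)) * pp.cc *
              qq.cc;
          if (std::fabs(pref) * pp.E[0].at(0, 0, 0) * pp.E[1].at(0, 0, 0) *
                  pp.E[2].at(0, 0, 0) * qq.E[0].at(0, 0, 0) *
                  qq.E[1].at(0, 0, 0) * qq.E[2].at(0, 0, 0) <
              1e-15)
            continue;
          double PQ[3] = {pp.P[0] - qq.P[0], pp.P[1] - qq.P[1],
                          pp.P[2] - qq.P[2]};
          build_R(R, L, alpha, PQ);
          size_t bi = 0;
          for (int ca = 0; ca < na; ++ca) {
            int ia[3] = {A.lx[ca], A.ly[ca], A.lz[ca]};
            for (int cb = 0; cb < nbc; ++cb) {
              int ib[3] = {B.lx[cb], B.ly[cb], B.lz[cb]};
              // collect bra hermite coefficients
              for (int cx = 0; cx < ncc; ++cx) {
                int icc[3] = {C.lx[cx], C.ly[cx], C.lz[cx]};
                for (int cd = 0; cd < nd; ++cd, ++bi) {
                  int id[3] = {D.lx[cd], D.ly[cd], D.lz[cd]};
                  double acc = 0.0;
                  for (int t = 0; t <= ia[0] + ib[0]; ++t) {
                    double e1x = pp.E[0].at(ia[0], ib[0], t);
                    if (e1x == 0.0) continue;
                    for (int u = 0; u <= ia[1] + ib[1]; ++u) {
                      double e1y = pp.E[1].at(ia[1], ib[1], u);
                      if (e1y == 0.0) continue;
                      for (int v = 0; v <= ia[2] + ib[2]; ++v) {
                        double e1z = pp.E[2].at(ia[2], ib[2], v);
                        if (e1z == 0.0) continue;
                        double e1 = e1x * e1y * e1z;
                        for (int tau = 0; tau <= icc[0] + id[0]; ++tau) {
                          double e2x = qq.E[0].at(icc[0], id[0], tau);
                          if (e2x == 0.0) continue;
                          for (int nu = 0; nu <= icc[1] + id[1]; ++nu) {
                            double e2y = qq.E[1].at(icc[1], id[1], nu);
                            if (e2y == 0.0) continue;
                            for (int ph = 0; ph <= icc[2] + id[2]; ++ph) {
                              double e2z = qq.E[2].at(icc[2], id[2], ph);
                              if (e2z == 0.0) continue;
                              double sgn =
                                  ((tau + nu + ph) % 2 == 0) ? 1.0 : -1.0;
                              acc += e1 * e2x * e2y * e2z * sgn *
                                     R.at(t + tau, u + nu, v + ph);
                            }
                          }
                        }
                      }
                    }
                  }
                  block[bi] += pref * acc;
                }
              }
            }
          }
        }
      }
      // scatter with 8-fold symmetry
      size_t bi = 0;
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nbc; ++cb)
          for (int cx = 0; cx < ncc; ++cx)
            for (int cd = 0; cd < nd; ++cd, ++bi) {
              double val = block[bi];
              int i = off[sa] + ca, j = off[sb] + cb;
              int k = off[sc] + cx, l = off[sd] + cd;
              put(i, j, k, l, val);
              put(j, i, k, l, val);
              put(i, j, l, k, val);
              put(j, i, l, k, val);
              put(k, l, i, j, val);
              put(l, k, i, j, val);
              put(k, l, j, i, val);
              put(l, k, j, i, val);
            }
    }
  }
  out.attr("dim") = IntegerVector::create(nb, nb, nb, nb);
  return out;
}
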