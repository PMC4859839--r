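// Gaussian integrals over contracted Cartesian shells (McMurchie-Davidson).
// Shells arrive from R already primitive- and contraction-normalized, with
// centers in bohr.  Supported angular momenta: s and p (all shipped bases).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> ex, cf;
  int off, ncart;
};

static std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  int off = 0;
  for (int i = 0; i < shells.size(); ++i) {
    List s = shells[i];
    Shell sh;
    sh.l = as<int>(s["l"]);
    NumericVector c = s["center"];
    sh.cx = c[0]; sh.cy = c[1]; sh.cz = c[2];
    sh.ex = as<std::vector<double> >(s["exponents"]);
    sh.cf = as<std::vector<double> >(s["coefficients"]);
    sh.ncart = (sh.l + 1) * (sh.l + 2) / 2;
    sh.off = off;
    off += sh.ncart;
    if (sh.l > 2) stop("angular momentum above d is not supported");
    out.push_back(sh);
  }
  return out;
}

static int nbf_total(const std::vector<Shell>& sh) {
  return sh.empty() ? 0 : sh.back().off + sh.back().ncart;
}

// Cartesian components in canonical order.
static void components(int l, std::vector<int>& lx, std::vector<int>& ly,
                       std::vector<int>& lz) {
  lx.clear(); ly.clear(); lz.clear();
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j) {
      lx.push_back(i); ly.push_back(j); lz.push_back(l - i - j);
    }
}

// Boys function F_0..F_m at x.
static void boys(int m, double x, double* F) {
  const double SQRTPIO2 = 0.886226925452758014;  // sqrt(pi)/2
  if (x < 1e-13) {
    for (int n = 0; n <= m; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x > 35.0) {
    F[0] = SQRTPIO2 / std::sqrt(x);
    for (int n = 1; n <= m; ++n) F[n] = F[n - 1] * (2.0 * n - 1.0) / (2.0 * x);
    return;
  }
  double s = 0.0, term = 1.0 / (2.0 * m + 1.0);
  for (int k = 0; k < 300; ++k) {
    s += term;
    term *= x / (m + k + 1.5);
    if (term < 1e-17 * s) break;
  }
  double ex = std::exp(-x);
  F[m] = s * ex;
  for (int n = m; n > 0; --n) F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
}

// Hermite expansion table E[i][j][t] for one dimension; AB = A - B.
struct ETab {
  int imax, jmax, tdim;
  std::vector<double> v;
  void build(int i_max, int j_max, double a, double b, double AB) {
    imax = i_max; jmax = j_max; tdim = i_max + j_max + 1;
    v.assign((i_max + 1) * (j_max + 1) * tdim, 0.0);
    double p = a + b, mu = a * b / p;
    at(0, 0, 0) = std::exp(-mu * AB * AB);
    double PA = -b * AB / p, PB = a * AB / p;
    for (int i = 0; i <= i_max; ++i)
      for (int j = 0; j <= j_max; ++j) {
        if (i == 0 && j == 0) continue;
        for (int t = 0; t <= i + j; ++t) {
          double val = 0.0;
          if (i > 0) {
            if (t > 0) val += at(i - 1, j, t - 1) / (2.0 * p);
            val += PA * at(i - 1, j, t);
            if (t + 1 < tdim) val += (t + 1) * at(i - 1, j, t + 1);
          } else {
            if (t > 0) val += at(i, j - 1, t - 1) / (2.0 * p);
            val += PB * at(i, j - 1, t);
            if (t + 1 < tdim) val += (t + 1) * at(i, j - 1, t + 1);
          }
          at(i, j, t) = val;
        }
      }
  }
  double& at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * tdim + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * tdim + t];
  }
};

// Hermite Coulomb integrals R_{t,u,v} for all t+u+v <= L, given Boys values.
// R^n recursion folded into a flat table.
static void hermite_R(int L, double p, double X, double Y, double Z,
                      double R2, std::vector<double>& R, int& dim) {
  dim = L + 1;
  std::vector<double> F(L + 1);
  boys(L, p * R2, F.data());
  // work[n][t][u][v]; build down in n
  auto idx = [dim](int t, int u, int v) { return (t * dim + u) * dim + v; };
  std::vector<std::vector<double> > work(L + 1,
      std::vector<double>(dim * dim * dim, 0.0));
  for (int n = 0; n <= L; ++n) {
    double m = 1.0;
    for (int k = 0; k < n; ++k) m *= -2.0 * p;
    work[n][idx(0, 0, 0)] = m * F[n];
  }
  for (int total = 1; total <= L; ++total) {
    for (int n = 0; n <= L - total; ++n) {
      for (int t = 0; t <= total; ++t)
        for (int u = 0; u <= total - t; ++u) {
          int v = total - t - u;
          double val = 0.0;
          if (t > 0) {
            if (t > 1) val += (t - 1) * work[n + 1][idx(t - 2, u, v)];
            val += X * work[n + 1][idx(t - 1, u, v)];
          } else if (u > 0) {
            if (u > 1) val += (u - 1) * work[n + 1][idx(t, u - 2, v)];
            val += Y * work[n + 1][idx(t, u - 1, v)];
          } else {
            if (v > 1) val += (v - 1) * work[n + 1][idx(t, u, v - 2)];
            val += Z * work[n + 1][idx(t, u, v - 1)];
          }
          work[n][idx(t, u, v)] = val;
        }
    }
  }
  R = work[0];
}

// [[Rcpp::export]]
List cpp_overlap_kinetic(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  NumericMatrix S(n, n), T(n, n);
  std::vector<int> ax, ay, az, bx, by, bz;
  for (size_t A = 0; A < sh.size(); ++A) {
    for (size_t B = 0; B <= A; ++B) {
      const Shell& sa = sh[A];
      const Shell& sb = sh[B];
      components(sa.l, ax, ay, az);
      components(sb.l, bx, by, bz);
      double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
      std::vector<std::vector<double> > Sblk(sa.ncart,
          std::vector<double>(sb.ncart, 0.0)), Tblk = Sblk;
      for (size_t ia = 0; ia < sa.ex.size(); ++ia)
        for (size_t ib = 0; ib < sb.ex.size(); ++ib) {
          double a = sa.ex[ia], b = sb.ex[ib];
          double p = a + b;
          double cc = sa.cf[ia] * sb.cf[ib];
          double s1 = std::sqrt(M_PI / p);
          ETab Ex, Ey, Ez;
          Ex.build(sa.l, sb.l + 2, a, b, ABx);
          Ey.build(sa.l, sb.l + 2, a, b, ABy);
          Ez.build(sa.l, sb.l + 2, a, b, ABz);
          for (int ca = 0; ca < sa.ncart; ++ca)
            for (int cb = 0; cb < sb.ncart; ++cb) {
              int i1 = ax[ca], j1 = ay[ca], k1 = az[ca];
              int i2 = bx[cb], j2 = by[cb], k2 = bz[cb];
              double Sx = Ex.get(i1, i2, 0) * s1;
              double Sy = Ey.get(j1, j2, 0) * s1;
              double Sz = Ez.get(k1, k2, 0) * s1;
              // 1D kinetic on the ket
              double Tx = -2.0 * b * b * Ex.get(i1, i2 + 2, 0) * s1
                  + b * (2.0 * i2 + 1.0) * Sx
                  - 0.5 * i2 * (i2 - 1.0) * Ex.get(i1, i2 - 2, 0) * s1;
              double Ty = -2.0 * b * b * Ey.get(j1, j2 + 2, 0) * s1
                  + b * (2.0 * j2 + 1.0) * Sy
                  - 0.5 * j2 * (j2 - 1.0) * Ey.get(j1, j2 - 2, 0) * s1;
              double Tz = -2.0 * b * b * Ez.get(k1, k2 + 2, 0) * s1
                  + b * (2.0 * k2 + 1.0) * Sz
                  - 0.5 * k2 * (k2 - 1.0) * Ez.get(k1, k2 - 2, 0) * s1;
              Sblk[ca][cb] += cc * Sx * Sy * Sz;
              Tblk[ca][cb] += cc * (Tx * Sy * Sz + Sx * Ty * Sz + Sx * Sy * Tz);
            }
        }
      for (int ca = 0; ca < sa.ncart; ++ca)
        for (int cb = 0; cb < sb.ncart; ++cb) {
          S(sa.off + ca, sb.off + cb) = Sblk[ca][cb];
          S(sb.off + cb, sa.off + ca) = Sblk[ca][cb];
          T(sa.off + ca, sb.off + cb) = Tblk[ca][cb];
          T(sb.off + cb, sa.off + ca) = Tblk[ca][cb];
        }
    }
  }
  return List::create(Named("S") = S, Named("T") = T);
}

// Attraction integrals -sum_C q_C <mu| 1/|r-C| |nu>; charges: rows (x,y,z,q), bohr.
// [[Rcpp::export]]
NumericMatrix cpp_nuclear_attraction(List shells, NumericMatrix charges) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  NumericMatrix V(n, n);
  std::vector<int> ax, ay, az, bx, by, bz;
  for (size_t A = 0; A < sh.size(); ++A) {
    for (size_t B = 0; B <= A; ++B) {
      const Shell& sa = sh[A];
      const Shell& sb = sh[B];
      components(sa.l, ax, ay, az);
      components(sb.l, bx, by, bz);
      double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
      int L = sa.l + sb.l;
      std::vector<std::vector<double> > blk(sa.ncart,
          std::vector<double>(sb.ncart, 0.0));
      for (size_t ia = 0; ia < sa.ex.size(); ++ia)
        for (size_t ib = 0; ib < sb.ex.size(); ++ib) {
          double a = sa.ex[ia], b = sb.ex[ib];
          double p = a + b;
          double cc = sa.cf[ia] * sb.cf[ib];
          double Px = (a * sa.cx + b * sb.cx) / p;
          double Py = (a * sa.cy + b * sb.cy) / p;
          double Pz = (a * sa.cz + b * sb.cz) / p;
          ETab Ex, Ey, Ez;
          Ex.build(sa.l, sb.l, a, b, ABx);
          Ey.build(sa.l, sb.l, a, b, ABy);
          Ez.build(sa.l, sb.l, a, b, ABz);
          double pref = cc * 2.0 * M_PI / p;
          for (int ic = 0; ic < charges.nrow(); ++ic) {
            double X = Px - charges(ic, 0), Y = Py - charges(ic, 1),
                   Z = Pz - charges(ic, 2);
            double q = charges(ic, 3);
            double R2 = X * X + Y * Y + Z * Z;
            std::vector<double> R; int dim;
            hermite_R(L, p, X, Y, Z, R2, R, dim);
            auto ridx = [dim](int t, int u, int v) {
              return (t * dim + u) * dim + v;
            };
            for (int ca = 0; ca < sa.ncart; ++ca)
              for (int cb = 0; cb < sb.ncart; ++cb) {
                int i1 = ax[ca], j1 = ay[ca], k1 = az[ca];
                int i2 = bx[cb], j2 = by[cb], k2 = bz[cb];
                double sum = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int u = 0; u <= j1 + j2; ++u)
                    for (int v = 0; v <= k1 + k2; ++v)
                      sum += Ex.get(i1, i2, t) * Ey.get(j1, j2, u)
                           * Ez.get(k1, k2, v) * R[ridx(t, u, v)];
                blk[ca][cb] += -q * pref * sum;
              }
          }
        }
      for (int ca = 0; ca < sa.ncart; ++ca)
        for (int cb = 0; cb < sb.ncart; ++cb) {
          V(sa.off + ca, sb.off + cb) = blk[ca][cb];
          V(sb.off + cb, sa.off + ca) = blk[ca][cb];
        }
    }
  }
  return V;
}

struct PrimPair {
  double p, Px, Py, Pz, cc;
  ETab Ex, Ey, Ez;
};
struct ShellPair {
  int s1, s2;
  std::vector<PrimPair> prims;
};

static std::vector<ShellPair> build_pairs(const std::vector<Shell>& sh) {
  std::vector<ShellPair> pairs;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      ShellPair sp;
      sp.s1 = (int)A; sp.s2 = (int)B;
      const Shell& sa = sh[A];
      const Shell& sb = sh[B];
      double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
      for (size_t ia = 0; ia < sa.ex.size(); ++ia)
        for (size_t ib = 0; ib < sb.ex.size(); ++ib) {
          PrimPair pp;
          double a = sa.ex[ia], b = sb.ex[ib];
          pp.p = a + b;
          pp.cc = sa.cf[ia] * sb.cf[ib];
          pp.Px = (a * sa.cx + b * sb.cx) / pp.p;
          pp.Py = (a * sa.cy + b * sb.cy) / pp.p;
          pp.Pz = (a * sa.cz + b * sb.cz) / pp.p;
          pp.Ex.build(sa.l, sb.l, a, b, ABx);
          pp.Ey.build(sa.l, sb.l, a, b, ABy);
          pp.Ez.build(sa.l, sb.l, a, b, ABz);
          sp.prims.push_back(pp);
        }
      pairs.push_back(sp);
    }
  return pairs;
}

// Full two-electron integral array (mu nu | la si), chemist notation.
// [[Rcpp::export]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  size_t n1 = n, n2 = n1 * n, n3 = n2 * n;
  NumericVector eri(n3 * n);
  eri.attr("dim") = IntegerVector::create(n, n, n, n);
  double* E = eri.begin();
  std::vector<ShellPair> pairs = build_pairs(sh);
  std::vector<int> ax, ay, az, bx, by, bz, cx, cy, cz, dx, dy, dz;
  const double TWO_PI_POW = 2.0 * std::pow(M_PI, 2.5);
  for (size_t P = 0; P < pairs.size(); ++P) {
    for (size_t Q = 0; Q <= P; ++Q) {
      const ShellPair& bra = pairs[P];
      const ShellPair& ket = pairs[Q];
      const Shell& sa = sh[bra.s1];
      const Shell& sb = sh[bra.s2];
      const Shell& sc = sh[ket.s1];
      const Shell& sd = sh[ket.s2];
      components(sa.l, ax, ay, az); components(sb.l, bx, by, bz);
      components(sc.l, cx, cy, cz); components(sd.l, dx, dy, dz);
      int L = sa.l + sb.l + sc.l + sd.l;
      std::vector<double> blk((size_t)sa.ncart * sb.ncart * sc.ncart * sd.ncart,
                              0.0);
      for (size_t ip = 0; ip < bra.prims.size(); ++ip)
        for (size_t iq = 0; iq < ket.prims.size(); ++iq) {
          const PrimPair& pp = bra.prims[ip];
          const PrimPair& qq = ket.prims[iq];
          double alpha = pp.p * qq.p / (pp.p + qq.p);
          double X = pp.Px - qq.Px, Y = pp.Py - qq.Py, Z = pp.Pz - qq.Pz;
          double R2 = X * X + Y * Y + Z * Z;
          std::vector<double> R; int dim;
          hermite_R(L, alpha, X, Y, Z, R2, R, dim);
          auto ridx = [dim](int t, int u, int v) {
            return (t * dim + u) * dim + v;
          };
          double fac = pp.cc * qq.cc * TWO_PI_POW
              / (pp.p * qq.p * std::sqrt(pp.p + qq.p));
          size_t bi = 0;
          for (int ca = 0; ca < sa.ncart; ++ca)
            for (int cb = 0; cb < sb.ncart; ++cb)
              for (int cc2 = 0; cc2 < sc.ncart; ++cc2)
                for (int cd = 0; cd < sd.ncart; ++cd, ++bi) {
                  int i1 = ax[ca] + bx[cb], j1 = ay[ca] + by[cb],
                      k1 = az[ca] + bz[cb];
                  int i2 = cx[cc2] + dx[cd], j2 = cy[cc2] + dy[cd],
                      k2 = cz[cc2] + dz[cd];
                  double sum = 0.0;
                  for (int t = 0; t <= i1; ++t) {
                    double e1 = pp.Ex.get(ax[ca], bx[cb], t);
                    if (e1 == 0.0) continue;
                    for (int u = 0; u <= j1; ++u) {
                      double e2 = e1 * pp.Ey.get(ay[ca], by[cb], u);
                      if (e2 == 0.0) continue;
                      for (int v = 0; v <= k1; ++v) {
                        double e3 = e2 * pp.Ez.get(az[ca], bz[cb], v);
                        if (e3 == 0.0) continue;
                        for (int tt = 0; tt <= i2; ++tt) {
                          double f1 = qq.Ex.get(cx[cc2], dx[cd], tt);
                          if (f1 == 0.0) continue;
                          for (int uu = 0; uu <= j2; ++uu) {
                            double f2 = f1 * qq.Ey.get(cy[cc2], dy[cd], uu);
                            if (f2 == 0.0) continue;
                            for (int vv = 0; vv <= k2; ++vv) {
                              double f3 = f2 * qq.Ez.get(cz[cc2], dz[cd], vv);
                              if (f3 == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                              sum += e3 * f3 * sgn
                                   * R[ridx(t + tt, u + uu, v + vv)];
                            }
                          }
                        }
                      }
                    }
                  }
                  blk[bi] += fac * sum;
                }
        }
      // scatter with 8-fold symmetry
      size_t bi = 0;
      for (int ca = 0; ca < sa.ncart; ++ca)
        for (int cb = 0; cb < sb.ncart; ++cb)
          for (int cc2 = 0; cc2 < sc.ncart; ++cc2)
            for (int cd = 0; cd < sd.ncart; ++cd, ++bi) {
              double val = blk[bi];
              size_t a = sa.off + ca, b = sb.off + cb,
                     c = sc.off + cc2, d = sd.off + cd;
              E[a + n1 * b + n2 * c + n3 * d] = val;
              E[b + n1 * a + n2 * c + n3 * d] = val;
              E[a + n1 * b + n2 * d + n3 * c] = val;
              E[b + n1 * a + n2 * d + n3 * c] = val;
              E[c + n1 * d + n2 * a + n3 * b] = val;
              E[d + n1 * c + n2 * a + n3 * b] = val;
              E[c + n1 * d + n2 * b + n3 * a] = val;
              E[d + n1 * c + n2 * b + n3 * a] = val;
            }
    }
  }
  return eri;
}

// Electron-repulsion potential of density D at arbitrary points:
// phi(r_g) = sum_{mu nu} D[mu,nu] <mu| 1/|r - r_g| |nu>   (positive kernel).
// [[Rcpp::export]]
NumericVector cpp_esp_at_points(List shells, NumericMatrix D,
                                NumericMatrix points) {
  std::vector<Shell> sh = parse_shells(shells);
  int npts = points.nrow();
  NumericVector phi(npts);
  std::vector<int> ax, ay, az, bx, by, bz;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
      const Shell& sa = sh[A];
      const Shell& sb = sh[B];
      components(sa.l, ax, ay, az);
      components(sb.l, bx, by, bz);
      double ABx = sa.cx - sb.cx, ABy = sa.cy - sb.cy, ABz = sa.cz - sb.cz;
      int L = sa.l + sb.l;
      for (size_t ia = 0; ia < sa.ex.size(); ++ia)
        for (size_t ib = 0; ib < sb.ex.size(); ++ib) {
          double a = sa.ex[ia], b = sb.ex[ib];
          double p = a + b;
          double cc = sa.cf[ia] * sb.cf[ib];
          double Px = (a * sa.cx + b * sb.cx) / p;
          double Py = (a * sa.cy + b * sb.cy) / p;
          double Pz = (a * sa.cz + b * sb.cz) / p;
          ETab Ex, Ey, Ez;
          Ex.build(sa.l, sb.l, a, b, ABx);
          Ey.build(sa.l, sb.l, a, b, ABy);
          Ez.build(sa.l, sb.l, a, b, ABz);
          double pref = cc * 2.0 * M_PI / p;
          for (int g = 0; g < npts; ++g) {
            double X = Px - points(g, 0), Y = Py - points(g, 1),
                   Z = Pz - points(g, 2);
            double R2 = X * X + Y * Y + Z * Z;
            std::vector<double> R; int dim;
            hermite_R(L, p, X, Y, Z, R2, R, dim);
            auto ridx = [dim](int t, int u, int v) {
              return (t * dim + u) * dim + v;
            };
            double acc = 0.0;
            for (int ca = 0; ca < sa.ncart; ++ca)
              for (int cb = 0; cb < sb.ncart; ++cb) {
                int i1 = ax[ca], j1 = ay[ca], k1 = az[ca];
                int i2 = bx[cb], j2 = by[cb], k2 = bz[cb];
                double sum = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int u = 0; u <= j1 + j2; ++u)
                    for (int v = 0; v <= k1 + k2; ++v)
                      sum += Ex.get(i1, i2, t) * Ey.get(j1, j2, u)
                           * Ez.get(k1, k2, v) * R[ridx(t, u, v)];
                // A == B blocks visit both component orders; A > B visits one
                double dmat = D(sa.off + ca, sb.off + cb);
                if (A != B) dmat += D(sb.off + cb, sa.off + ca);
                acc += dmat * sum;
              }
            phi[g] += pref * acc;
          }
        }
    }
  return phi;
}

// Electron density of D evaluated at points.
// [[Rcpp::export]]
NumericVector cpp_density_at_points(List shells, NumericMatrix D,
                                    NumericMatrix points) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  int npts = points.nrow();
  NumericVector rho(npts);
  std::vector<int> lx, ly, lz;
  std::vector<double> ao(n);
  for (int g = 0; g < npts; ++g) {
    double x = points(g, 0), y = points(g, 1), z = points(g, 2);
    for (size_t A = 0; A < sh.size(); ++A) {
      const Shell& sa = sh[A];
      components(sa.l, lx, ly, lz);
      double dxp = x - sa.cx, dyp = y - sa.cy, dzp = z - sa.cz;
      double r2 = dxp * dxp + dyp * dyp + dzp * dzp;
      double rad = 0.0;
      for (size_t ip = 0; ip < sa.ex.size(); ++ip)
        rad += sa.cf[ip] * std::exp(-sa.ex[ip] * r2);
      for (int c = 0; c < sa.ncart; ++c) {
        double ang = 1.0;
        for (int k = 0; k < lx[c]; ++k) ang *= dxp;
        for (int k = 0; k < ly[c]; ++k) ang *= dyp;
        for (int k = 0; k < lz[c]; ++k) ang *= dzp;
        ao[sa.off + c] = ang * rad;
      }
    }
    double val = 0.0;
    for (int i = 0; i < n; ++i) {
      double t = 0.0;
      for (int j = 0; j < n; ++j) t += D(i, j) * ao[j];
      val += ao[i] * t;
    }
    rho[g] = val;
  }
  return rho;
}
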