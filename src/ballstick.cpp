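// Ball-and-stick model fitting with residual-bootstrap orientation sampling.
//
// Signal model per voxel:
//   S(b, g) = S0 [ (1 - sum f_j) exp(-b d) + sum_j f_j exp(-b d (g.v_j)^2) ]
// Nonlinear parameters (shared diffusivity d in log space, stick angles) are
// optimized by Nelder-Mead with the compartment amplitudes profiled out by a
// small non-negative least squares (variable projection).  Orientation
// uncertainty comes from refitting on residual-bootstrap resamples.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BSProblem {
  int nvol;
  int nf;                      // number of stick compartments (1 or 2)
  const double* b;
  std::vector<double> g;       // nvol x 3, row-major
  std::vector<double> y;       // current data vector
  // scratch
  std::vector<double> cols;    // nvol x (nf + 1)
  double yss;

  void set_data(const double* yy) {
    y.assign(yy, yy + nvol);
    yss = 0.0;
    for (int k = 0; k < nvol; ++k) yss += y[k] * y[k];
  }
};

inline void angles_to_vec(double th, double ph, double* v) {
  double st = std::sin(th);
  v[0] = st * std::cos(ph);
  v[1] = st * std::sin(ph);
  v[2] = std::cos(th);
}

inline void vec_to_angles(const double* v, double& th, double& ph) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  double z = (n > 0) ? v[2] / n : 1.0;
  z = std::max(-1.0, std::min(1.0, z));
  th = std::acos(z);
  ph = std::atan2(v[1], v[0]);
}

// solve the m x m system G a = c by Gaussian elimination with partial
// pivoting; returns false when singular
bool solve_small(int m, double* G, double* c) {
  for (int i = 0; i < m; ++i) {
    int piv = i;
    for (int r = i + 1; r < m; ++r)
      if (std::fabs(G[r * m + i]) > std::fabs(G[piv * m + i])) piv = r;
    if (std::fabs(G[piv * m + i]) < 1e-300) return false;
    if (piv != i) {
      for (int cc = 0; cc < m; ++cc) std::swap(G[i * m + cc], G[piv * m + cc]);
      std::swap(c[i], c[piv]);
    }
    for (int r = i + 1; r < m; ++r) {
      double f = G[r * m + i] / G[i * m + i];
      for (int cc = i; cc < m; ++cc) G[r * m + cc] -= f * G[i * m + cc];
      c[r] -= f * c[i];
    }
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = c[i];
    for (int cc = i + 1; cc < m; ++cc) s -= G[i * m + cc] * c[cc];
    c[i] = s / G[i * m + i];
  }
  return true;
}

// non-negative least squares for m <= 3 columns by subset enumeration.
// Returns rss; amplitudes in a (length m).
double nnls_small(const BSProblem& pb, int m, double* a) {
  const std::vector<double>& X = pb.cols;
  int nvol = pb.nvol;
  double G0[9], c0[3];
  for (int i = 0; i < m; ++i) {
    c0[i] = 0.0;
    for (int k = 0; k < nvol; ++k) c0[i] += X[k * m + i] * pb.y[k];
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < nvol; ++k) s += X[k * m + i] * X[k * m + j];
      G0[i * m + j] = s;
      G0[j * m + i] = s;
    }
  }
  double best_rss = pb.yss;   // empty subset: a = 0
  double best_a[3] = {0, 0, 0};
  int nsub = (1 << m);
  for (int sub = 1; sub < nsub; ++sub) {
    int idx[3], ms = 0;
    for (int i = 0; i < m; ++i) if (sub & (1 << i)) idx[ms++] = i;
    double G[9], c[3];
    for (int i = 0; i < ms; ++i) {
      c[i] = c0[idx[i]];
      for (int j = 0; j < ms; ++j) G[i * ms + j] = G0[idx[i] * m + idx[j]];
    }
    if (!solve_small(ms, G, c)) continue;
    bool ok = true;
    for (int i = 0; i < ms; ++i) if (c[i] < 0.0) { ok = false; break; }
    if (!ok) continue;
    // rss = y'y - 2 a'c0_s + a' G_ss a ; recompute the quadratic form
    double rss = pb.yss;
    for (int i = 0; i < ms; ++i) {
      rss -= 2.0 * c[i] * c0[idx[i]];
      for (int j = 0; j < ms; ++j)
        rss += c[i] * c[j] * G0[idx[i] * m + idx[j]];
    }
    if (rss < best_rss) {
      best_rss = rss;
      best_a[0] = best_a[1] = best_a[2] = 0.0;
      for (int i = 0; i < ms; ++i) best_a[idx[i]] = c[i];
    }
  }
  for (int i = 0; i < m; ++i) a[i] = best_a[i];
  return best_rss;
}

// build basis columns for parameters p and return nnls rss; optionally
// return amplitudes
double objective(BSProblem& pb, const double* p, double* a_out = nullptr) {
  double logd = std::max(std::log(1e-6), std::min(std::log(5e-2), p[0]));
  double d = std::exp(logd);
  int m = pb.nf + 1;
  double v[2][3];
  for (int j = 0; j < pb.nf; ++j) angles_to_vec(p[1 + 2 * j], p[2 + 2 * j], v[j]);
  pb.cols.resize((size_t)pb.nvol * m);
  double last_bd = -1.0, last_e = 1.0;   // single-shell: one distinct b > 0
  for (int k = 0; k < pb.nvol; ++k) {
    double bd = pb.b[k] * d;
    const double* g = &pb.g[3 * k];
    if (bd != last_bd) { last_e = std::exp(-bd); last_bd = bd; }
    pb.cols[k * m + 0] = last_e;
    for (int j = 0; j < pb.nf; ++j) {
      double dot = g[0] * v[j][0] + g[1] * v[j][1] + g[2] * v[j][2];
      pb.cols[k * m + 1 + j] = std::exp(-bd * dot * dot);
    }
  }
  double a[3];
  double rss = nnls_small(pb, m, a);
  if (a_out) for (int i = 0; i < m; ++i) a_out[i] = a[i];
  return rss;
}

// standard Nelder-Mead on n parameters with f-spread and simplex-diameter
// stopping; step0 sets the initial simplex size (radians / log-units)
double nelder_mead(BSProblem& pb, int n, double* p, int maxit, double tol,
                   double step0) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  int np = n + 1;
  std::vector<double> simplex((size_t)np * n), fv(np);
  std::vector<double> xc(n), xr(n), xe(n), xk(n);
  for (int j = 0; j < n; ++j) simplex[j] = p[j];
  fv[0] = objective(pb, p);
  for (int i = 1; i < np; ++i) {
    for (int j = 0; j < n; ++j) simplex[i * n + j] = p[j];
    simplex[i * n + (i - 1)] += step0;
    fv[i] = objective(pb, &simplex[i * n]);
  }
  std::vector<int> ord(np);
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < np; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return fv[a] < fv[b]; });
    double fbest = fv[ord[0]], fworst = fv[ord[np - 1]];
    if (fworst - fbest <= tol * (std::fabs(fbest) + 1e-30)) break;
    double diam = 0.0;
    for (int i = 1; i < np; ++i)
      for (int j = 0; j < n; ++j)
        diam = std::max(diam, std::fabs(simplex[ord[i] * n + j] -
                                        simplex[ord[0] * n + j]));
    if (diam < 1e-5) break;
    int iw = ord[np - 1], is2 = ord[np - 2], ib = ord[0];
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < np; ++i) if (i != iw) s += simplex[i * n + j];
      xc[j] = s / n;
    }
    for (int j = 0; j < n; ++j) xr[j] = xc[j] + alpha * (xc[j] - simplex[iw * n + j]);
    double fr = objective(pb, xr.data());
    if (fr < fv[ib]) {
      for (int j = 0; j < n; ++j) xe[j] = xc[j] + gamma * (xr[j] - xc[j]);
      double fe = objective(pb, xe.data());
      if (fe < fr) { std::copy(xe.begin(), xe.end(), &simplex[iw * n]); fv[iw] = fe; }
      else { std::copy(xr.begin(), xr.end(), &simplex[iw * n]); fv[iw] = fr; }
    } else if (fr < fv[is2]) {
      std::copy(xr.begin(), xr.end(), &simplex[iw * n]); fv[iw] = fr;
    } else {
      for (int j = 0; j < n; ++j) xk[j] = xc[j] + rho * (simplex[iw * n + j] - xc[j]);
      double fk = objective(pb, xk.data());
      if (fk < fv[iw]) { std::copy(xk.begin(), xk.end(), &simplex[iw * n]); fv[iw] = fk; }
      else {
        for (int i = 0; i < np; ++i) {
          if (i == ib) continue;
          for (int j = 0; j < n; ++j)
            simplex[i * n + j] = simplex[ib * n + j] +
              sigma * (simplex[i * n + j] - simplex[ib * n + j]);
          fv[i] = objective(pb, &simplex[i * n]);
        }
      }
    }
  }
  int ibest = 0;
  for (int i = 1; i < np; ++i) if (fv[i] < fv[ibest]) ibest = i;
  for (int j = 0; j < n; ++j) p[j] = simplex[ibest * n + j];
  return fv[ibest];
}


// objective returning the residual vector r = y - X a (amplitudes profiled)
double objective_resid(BSProblem& pb, const double* p, double* r,
                       double* a_out = nullptr) {
  double a[3];
  double rss = objective(pb, p, a);
  int m = pb.nf + 1;
  for (int k = 0; k < pb.nvol; ++k) {
    double fit = 0.0;
    for (int i = 0; i < m; ++i) fit += pb.cols[k * m + i] * a[i];
    r[k] = pb.y[k] - fit;
  }
  if (a_out) for (int i = 0; i < m; ++i) a_out[i] = a[i];
  return rss;
}

// Levenberg-Marquardt refinement with forward-difference Jacobian on the
// variable-projection objective; converges in a handful of iterations from
// a warm start, which Nelder-Mead does not
double lm_refine(BSProblem& pb, int n, double* p, int maxit) {
  const int nvol = pb.nvol;
  std::vector<double> r0(nvol), rh(nvol), J((size_t)nvol * n);
  double rss = objective_resid(pb, p, r0.data());
  double lambda = 1e-3;
  const double h = 1e-5;
  for (int it = 0; it < maxit; ++it) {
    for (int j = 0; j < n; ++j) {
      double save = p[j];
      p[j] = save + h;
      objective_resid(pb, p, rh.data());
      p[j] = save;
      for (int k = 0; k < nvol; ++k) J[(size_t)k * n + j] = (rh[k] - r0[k]) / h;
    }
    double JtJ[25], Jtr[5];
    for (int i = 0; i < n; ++i) {
      Jtr[i] = 0.0;
      for (int k = 0; k < nvol; ++k) Jtr[i] += J[(size_t)k * n + i] * r0[k];
      for (int j = 0; j <= i; ++j) {
        double sum = 0.0;
        for (int k = 0; k < nvol; ++k)
          sum += J[(size_t)k * n + i] * J[(size_t)k * n + j];
        JtJ[i * n + j] = sum;
        JtJ[j * n + i] = sum;
      }
    }
    bool accepted = false;
    for (int tryi = 0; tryi < 6; ++tryi) {
      double A[25], b[5], pnew[5];
      for (int i = 0; i < n * n; ++i) A[i] = JtJ[i];
      for (int i = 0; i < n; ++i) {
        A[i * n + i] += lambda * (JtJ[i * n + i] + 1e-12);
        b[i] = Jtr[i];                 // delta = (JtJ + lam D)^-1 J'r
      }
      if (!solve_small(n, A, b)) { lambda *= 5.0; continue; }
      double dnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        pnew[i] = p[i] - b[i];          // r = y - f(p): step is -(J'J)^-1 J'r
        dnorm = std::max(dnorm, std::fabs(b[i]));
      }
      double rss_new = objective_resid(pb, pnew, rh.data());
      if (rss_new <= rss) {
        double drop = rss - rss_new;
        std::copy(pnew, pnew + n, p);
        std::swap(r0, rh);
        rss = rss_new;
        lambda = std::max(lambda / 3.0, 1e-10);
        accepted = true;
        if (drop <= 1e-10 * (rss + 1e-30) || dnorm < 1e-8) return rss;
        break;
      }
      lambda *= 5.0;
    }
    if (!accepted) break;
  }
  return rss;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_ball_stick(NumericMatrix S, NumericVector bvals,
                        NumericMatrix bvecs, NumericMatrix init_v1,
                        NumericMatrix init_v2, NumericVector init_d,
                        int n_fibers, int n_boot, int seed,
                        int maxit_point, int maxit_boot) {
  const int nmask = S.nrow();
  const int nvol = S.ncol();
  const int nf = n_fibers;
  const int npar = 1 + 2 * nf;

  BSProblem pb;
  pb.nvol = nvol;
  pb.nf = nf;
  pb.b = REAL(bvals);
  pb.g.resize((size_t)nvol * 3);
  for (int k = 0; k < nvol; ++k)
    for (int c = 0; c < 3; ++c) pb.g[3 * k + c] = bvecs(c, k);

  NumericVector d_out(nmask), s0_out(nmask), f1_out(nmask), f2_out(nmask);
  NumericMatrix v1_out(nmask, 3), v2_out(nmask, 3);
  LogicalVector conv(nmask);
  NumericVector bv1(Dimension(nmask, n_boot, 3));
  NumericVector bv2(Dimension(nmask, n_boot, 3));
  NumericMatrix bf1(nmask, n_boot), bf2(nmask, n_boot);

  std::vector<double> yrow(nvol), yhat(nvol), resid(nvol), yboot(nvol);
  double p[5], pbest[5], ptry[5], a[3];

  for (int vx = 0; vx < nmask; ++vx) {
    for (int k = 0; k < nvol; ++k) yrow[k] = S(vx, k);
    pb.set_data(yrow.data());

    double v1i[3] = { init_v1(vx, 0), init_v1(vx, 1), init_v1(vx, 2) };
    double v2i[3] = { init_v2(vx, 0), init_v2(vx, 1), init_v2(vx, 2) };
    double d0 = std::max(1e-5, std::min(1e-2, init_d[vx]));

    // multi-start: tensor axes, and (for 2 fibers) their bisectors, which
    // are where the sticks of a symmetric crossing actually lie
    double fbest = R_PosInf;
    int nstart = (nf == 2) ? 2 : 1;
    for (int st = 0; st < nstart; ++st) {
      ptry[0] = std::log(d0);
      double a1[3], a2[3];
      if (st == 0) {
        std::copy(v1i, v1i + 3, a1);
        std::copy(v2i, v2i + 3, a2);
      } else {
        for (int c = 0; c < 3; ++c) {
          a1[c] = v1i[c] + v2i[c];
          a2[c] = v1i[c] - v2i[c];
        }
      }
      vec_to_angles(a1, ptry[1], ptry[2]);
      if (nf == 2) vec_to_angles(a2, ptry[3], ptry[4]);
      double f = nelder_mead(pb, npar, ptry, maxit_point, 1e-9, 0.3);
      f = lm_refine(pb, npar, ptry, 20);
      if (f < fbest) { fbest = f; std::copy(ptry, ptry + npar, pbest); }
    }
    std::copy(pbest, pbest + npar, p);
    double rss = objective(pb, p, a);

    double s0 = a[0];
    for (int j = 0; j < nf; ++j) s0 += a[1 + j];
    bool ok = R_finite(rss) && s0 > 1e-12;
    conv[vx] = ok;
    double vp[2][3];
    double logd = std::max(std::log(1e-6), std::min(std::log(5e-2), p[0]));
    for (int j = 0; j < nf; ++j) angles_to_vec(p[1 + 2 * j], p[2 + 2 * j], vp[j]);
    double f1 = ok ? a[1] / s0 : 0.0;
    double f2 = (ok && nf == 2) ? a[2] / s0 : 0.0;
    if (!ok) {
      // fall back to the tensor-derived direction, flagged via conv = FALSE
      std::copy(v1i, v1i + 3, vp[0]);
      std::copy(v2i, v2i + 3, vp[1]);
      s0 = 0.0;
    }
    if (nf == 2 && f2 > f1) {  // dominant fiber first
      std::swap(f1, f2);
      for (int c = 0; c < 3; ++c) std::swap(vp[0][c], vp[1][c]);
      std::swap(p[1], p[3]);
      std::swap(p[2], p[4]);
    }
    d_out[vx] = std::exp(logd);
    s0_out[vx] = s0;
    f1_out[vx] = f1;
    f2_out[vx] = f2;
    for (int c = 0; c < 3; ++c) {
      v1_out(vx, c) = vp[0][c];
      v2_out(vx, c) = vp[1][c];
    }

    // fitted signal for residual bootstrap
    {
      double aa[3];
      objective(pb, p, aa);
      int m = nf + 1;
      for (int k = 0; k < nvol; ++k) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) s += pb.cols[k * m + i] * aa[i];
        yhat[k] = s;
        resid[k] = yrow[k] - s;
      }
    }

    std::mt19937 rng((uint32_t)seed * 2654435761u + (uint32_t)vx + 1u);
    std::uniform_int_distribution<int> pick(0, nvol - 1);
    double pb_par[5], ab[3];
    for (int bi = 0; bi < n_boot; ++bi) {
      for (int k = 0; k < nvol; ++k) {
        double ys = yhat[k] + resid[pick(rng)];
        yboot[k] = (ys > 1e-12) ? ys : 1e-12;
      }
      pb.set_data(yboot.data());
      std::copy(p, p + npar, pb_par);
      lm_refine(pb, npar, pb_par, maxit_boot);
      double rssb = objective(pb, pb_par, ab);
      (void)rssb;
      double s0b = ab[0];
      for (int j = 0; j < nf; ++j) s0b += ab[1 + j];
      double vb[2][3];
      for (int j = 0; j < nf; ++j)
        angles_to_vec(pb_par[1 + 2 * j], pb_par[2 + 2 * j], vb[j]);
      double f1b = (s0b > 1e-12) ? ab[1] / s0b : 0.0;
      double f2b = (nf == 2 && s0b > 1e-12) ? ab[2] / s0b : 0.0;
      if (nf == 2) {
        // keep bootstrap fibers matched to the point-estimate fibers
        double d11 = std::fabs(vb[0][0] * vp[0][0] + vb[0][1] * vp[0][1] + vb[0][2] * vp[0][2]);
        double d12 = std::fabs(vb[0][0] * vp[1][0] + vb[0][1] * vp[1][1] + vb[0][2] * vp[1][2]);
        double d21 = std::fabs(vb[1][0] * vp[0][0] + vb[1][1] * vp[0][1] + vb[1][2] * vp[0][2]);
        double d22 = std::fabs(vb[1][0] * vp[1][0] + vb[1][1] * vp[1][1] + vb[1][2] * vp[1][2]);
        if (d12 + d21 > d11 + d22) {
          std::swap(f1b, f2b);
          for (int c = 0; c < 3; ++c) std::swap(vb[0][c], vb[1][c]);
        }
      }
      for (int j = 0; j < nf; ++j) {
        // canonical sign: align with the point estimate
        double dp = vb[j][0] * vp[j][0] + vb[j][1] * vp[j][1] + vb[j][2] * vp[j][2];
        if (dp < 0) for (int c = 0; c < 3; ++c) vb[j][c] = -vb[j][c];
      }
      for (int c = 0; c < 3; ++c) {
        bv1[vx + (size_t)nmask * (bi + (size_t)n_boot * c)] = vb[0][c];
        if (nf == 2)
          bv2[vx + (size_t)nmask * (bi + (size_t)n_boot * c)] = vb[1][c];
      }
      bf1(vx, bi) = f1b;
      bf2(vx, bi) = f2b;
      pb.set_data(yrow.data());   // restore for next voxel/boot baseline
    }
    if (vx % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["d"] = d_out, _["s0"] = s0_out, _["f1"] = f1_out, _["f2"] = f2_out,
    _["v1"] = v1_out, _["v2"] = v2_out, _["converged"] = conv,
    _["boot_v1"] = bv1, _["boot_v2"] = bv2,
    _["boot_f1"] = bf1, _["boot_f2"] = bf2);
}
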