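// Binomial logit-normal mixed model fitted per SNP:
//   alt_j ~ Binomial(R_j, p_j), logit(p_j) = b0 + b1 x_j + u_j,
//   u_j ~ N(0, sigma^2),
// one observation (and one random intercept) per population, so the
// marginal likelihood factorises over populations into one-dimensional
// integrals. Each integral is evaluated by adaptive Gauss-Hermite
// quadrature (recentred at the conditional mode of u_j and rescaled by
// the conditional curvature, which stays accurate when the random-effect
// variance is large relative to the binomial noise). Gradients are exact
// posterior expectations over the same nodes; optimisation is BFGS on
// (b0 [, b1], log sigma). The likelihood-ratio statistic compares the
// full model to the reduced model without the regime fixed effect.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double LOG2PI = 1.8378770664093453;

struct Data {
  const double *y;   // alt counts
  const double *n;   // depths
  const double *x;   // regime covariate (0/1)
  int J;             // populations with n > 0
  const double *z;   // GH nodes
  const double *lw;  // log GH weights
  int K;
  double *ustar;     // warm-started conditional modes, length J
};

inline double log1pexp(double e) {
  if (e > 35.0) return e;
  if (e < -35.0) return 0.0;
  return std::log1p(std::exp(e));
}

// marginal log-likelihood (binomial coefficient omitted) and gradient.
// Parameterisation: npar == 2 -> common intercept th[0]; npar == 3 ->
// independent group intercepts th[0] (x = 0) and th[1] (x = 1). Group
// intercepts decouple the flat direction that appears when one regime is
// fixed for an allele. th[npar-1] is log sigma.
double loglik(const Data &d, const double *th, int npar, double *grad,
              double *hess = NULL) {
  const double sig = std::exp(th[npar - 1]);
  const double isig2 = 1.0 / (sig * sig);
  if (grad) for (int a = 0; a < npar; ++a) grad[a] = 0.0;
  if (hess) for (int a = 0; a < npar * npar; ++a) hess[a] = 0.0;
  double ll = 0.0;
  double gi[64], ui[64];
  for (int j = 0; j < d.J; ++j) {
    const double yj = d.y[j], nj = d.n[j], xj = d.x[j];
    const int ia = (npar == 3 && xj > 0.5) ? 1 : 0;
    const double c = th[ia];
    // conditional mode of g(u) = y*eta - n*log1pexp(eta) - u^2/(2 sig^2)
    double u = d.ustar[j], g2 = -1.0;
    for (int it = 0; it < 60; ++it) {
      const double p = 1.0 / (1.0 + std::exp(-(c + u)));
      const double g1 = yj - nj * p - u * isig2;
      g2 = -nj * p * (1.0 - p) - isig2;
      double du = -g1 / g2;
      if (du > 4.0) du = 4.0; else if (du < -4.0) du = -4.0;
      u += du;
      if (std::fabs(du) < 1e-11) break;
    }
    d.ustar[j] = u;
    const double s = 1.0 / std::sqrt(-g2);
    const double sq2s = std::sqrt(2.0) * s;
    // adaptive nodes and integrand values
    double gmax = -1e300;
    for (int k = 0; k < d.K; ++k) {
      const double uk = u + sq2s * d.z[k];
      const double eta = c + uk;
      const double g = yj * eta - nj * log1pexp(eta) - 0.5 * uk * uk * isig2;
      ui[k] = uk;
      gi[k] = d.lw[k] + d.z[k] * d.z[k] + g;
      if (gi[k] > gmax) gmax = gi[k];
    }
    double L = 0.0;
    for (int k = 0; k < d.K; ++k) { gi[k] = std::exp(gi[k] - gmax); L += gi[k]; }
    ll += gmax + std::log(L) + std::log(sq2s) - std::log(sig) - 0.5 * LOG2PI;
    if (!grad) continue;
    // posterior expectations: scores and information terms
    double eA = 0.0, eB = 0.0, eT = 0.0, eT2 = 0.0, eU2 = 0.0, eAT = 0.0;
    for (int k = 0; k < d.K; ++k) {
      const double r = gi[k] / L;
      const double p = 1.0 / (1.0 + std::exp(-(c + ui[k])));
      const double g1 = yj - nj * p;
      const double u2 = ui[k] * ui[k];
      const double t = u2 * isig2 - 1.0;
      eA += r * g1;
      eT += r * t;
      eU2 += r * u2;
      if (hess) {
        eB += r * (g1 * g1 - nj * p * (1.0 - p));
        eT2 += r * t * t;
        eAT += r * g1 * t;
      }
    }
    const int ls = npar - 1;
    grad[ia] += eA;
    grad[ls] += eT;
    if (hess) {
      hess[ia * npar + ia] += eB - eA * eA;
      hess[ls * npar + ls] += eT2 - eT * eT - 2.0 * eU2 * isig2;
      const double cross = eAT - eA * eT;
      hess[ia * npar + ls] += cross;
      hess[ls * npar + ia] += cross;
    }
  }
  return ll;
}

inline void clamp_theta(double *th, int npar) {
  for (int a = 0; a < npar - 1; ++a) {
    if (th[a] > 30.0) th[a] = 30.0;
    if (th[a] < -30.0) th[a] = -30.0;
  }
  if (th[npar - 1] < -6.0) th[npar - 1] = -6.0;  // sigma >= exp(-6)
  if (th[npar - 1] > 3.0) th[npar - 1] = 3.0;
}

// BFGS maximisation with backtracking line search; a quasi-Newton scheme
// is preferred over full Newton here because the quadrature nodes move
// with the parameters, which makes expectation-based Hessians unreliable
// in the flat sigma directions of boundary-heavy SNPs
double fit_model(const Data &d, double *th, int npar, int maxit, double tol,
                 bool &conv) {
  double grad[3], gnew[3], step[3], thn[3], Hinv[9];
  clamp_theta(th, npar);
  for (int j = 0; j < d.J; ++j) d.ustar[j] = 0.0;
  double ll = loglik(d, th, npar, grad);
  for (int a = 0; a < npar * npar; ++a) Hinv[a] = 0.0;
  for (int a = 0; a < npar; ++a) Hinv[a * npar + a] = 1.0;
  conv = false;
  for (int it = 0; it < maxit; ++it) {
    double gmax = 0.0;
    for (int a = 0; a < npar; ++a) gmax = std::max(gmax, std::fabs(grad[a]));
    if (gmax < tol) { conv = true; break; }
    for (int a = 0; a < npar; ++a) {
      step[a] = 0.0;
      for (int b = 0; b < npar; ++b) step[a] += Hinv[a * npar + b] * grad[b];
    }
    double dot = 0.0;
    for (int a = 0; a < npar; ++a) dot += step[a] * grad[a];
    if (dot <= 0.0) { // reset to steepest ascent
      for (int a = 0; a < npar * npar; ++a) Hinv[a] = 0.0;
      for (int a = 0; a < npar; ++a) {
        Hinv[a * npar + a] = 1.0;
        step[a] = grad[a];
      }
    }
    // cap the step length
    double smax = 0.0;
    for (int a = 0; a < npar; ++a) smax = std::max(smax, std::fabs(step[a]));
    if (smax > 5.0) for (int a = 0; a < npar; ++a) step[a] *= 5.0 / smax;
    double alpha = 1.0, lln = ll;
    bool improved = false;
    for (int lsit = 0; lsit < 40; ++lsit) {
      for (int a = 0; a < npar; ++a) thn[a] = th[a] + alpha * step[a];
      clamp_theta(thn, npar);
      lln = loglik(d, thn, npar, NULL);
      if (lln > ll + 1e-13) { improved = true; break; }
      alpha *= 0.5;
    }
    if (!improved) { conv = true; break; } // numerically stationary
    loglik(d, thn, npar, gnew);
    // BFGS inverse update
    double sv[3], yv[3];
    double sy = 0.0;
    for (int a = 0; a < npar; ++a) {
      sv[a] = thn[a] - th[a];
      yv[a] = -(gnew[a] - grad[a]);  // minimise -ll convention
      sy += sv[a] * yv[a];
    }
    if (sy > 1e-12) {
      double Hy[3];
      double yHy = 0.0;
      for (int a = 0; a < npar; ++a) {
        Hy[a] = 0.0;
        for (int b = 0; b < npar; ++b) Hy[a] += Hinv[a * npar + b] * yv[b];
      }
      for (int a = 0; a < npar; ++a) yHy += yv[a] * Hy[a];
      for (int a = 0; a < npar; ++a)
        for (int b = 0; b < npar; ++b)
          Hinv[a * npar + b] += ((sy + yHy) * sv[a] * sv[b]) / (sy * sy)
            - (Hy[a] * sv[b] + sv[a] * Hy[b]) / sy;
    }
    double move = 0.0;
    for (int a = 0; a < npar; ++a) {
      move = std::max(move, std::fabs(thn[a] - th[a]));
      th[a] = thn[a];
      grad[a] = gnew[a];
    }
    ll = lln;
    if (move < 1e-11) { conv = true; break; }
  }
  return ll;
}

} // namespace

// [[Rcpp::export(name = ".glmm_lrt_cpp")]]
List glmm_lrt_cpp(NumericMatrix alt, NumericMatrix depth, NumericVector x,
                  NumericVector gh_nodes, NumericVector gh_weights,
                  int maxit = 200, double tol = 1e-6) {
  const int nsnp = alt.nrow(), npop = alt.ncol();
  if (depth.nrow() != nsnp || depth.ncol() != npop || x.size() != npop)
    stop("dimension mismatch");
  const int K = gh_nodes.size();
  if (K > 64) stop("at most 64 quadrature nodes supported");
  std::vector<double> z(K), lw(K);
  for (int k = 0; k < K; ++k) {
    z[k] = gh_nodes[k];
    lw[k] = std::log(gh_weights[k]);
  }
  NumericVector lrt(nsnp), sigma_full(nsnp), beta_regime(nsnp);
  LogicalVector converged(nsnp);
  std::vector<double> yv(npop), nv(npop), xv(npop), us(npop);
  for (int i = 0; i < nsnp; ++i) {
    int J = 0;
    double ysum = 0.0, nsum = 0.0;
    double l_sel = 0.0, l_ctl = 0.0; int c_sel = 0, c_ctl = 0;
    for (int j = 0; j < npop; ++j) {
      const double nj = depth(i, j);
      if (nj <= 0) continue;
      yv[J] = alt(i, j); nv[J] = nj; xv[J] = x[j];
      ysum += yv[J]; nsum += nj;
      const double pj = (yv[J] + 0.5) / (nj + 1.0);
      const double lg = std::log(pj / (1.0 - pj));
      if (x[j] > 0.5) { l_sel += lg; ++c_sel; } else { l_ctl += lg; ++c_ctl; }
      ++J;
    }
    if (J < 2 || ysum == 0.0 || ysum == nsum || c_sel == 0 || c_ctl == 0) {
      lrt[i] = 0.0; sigma_full[i] = 0.0; beta_regime[i] = 0.0;
      converged[i] = true;
      continue;
    }
    Data d; d.y = yv.data(); d.n = nv.data(); d.x = xv.data(); d.J = J;
    d.z = z.data(); d.lw = lw.data(); d.K = K; d.ustar = us.data();
    l_sel /= c_sel; l_ctl /= c_ctl;
    double mlog = 0.0, vlog = 0.0;
    for (int j = 0; j < J; ++j) {
      const double pj = (yv[j] + 0.5) / (nv[j] + 1.0);
      mlog += std::log(pj / (1.0 - pj));
    }
    mlog /= J;
    for (int j = 0; j < J; ++j) {
      const double pj = (yv[j] + 0.5) / (nv[j] + 1.0);
      const double lg = std::log(pj / (1.0 - pj));
      vlog += (lg - mlog) * (lg - mlog);
    }
    vlog = std::sqrt(vlog / std::max(1, J - 1));
    const double lsig0 = std::log(std::max(0.1, 0.8 * vlog));
    bool conv_r, conv_f = true;
    double th_r[3] = {mlog, lsig0, 0.0};
    const double ll_r = fit_model(d, th_r, 2, maxit, tol, conv_r);
    // group intercepts diverge when a group is fixed for one allele; the
    // marginal likelihood of such a group tends to 1, so its populations
    // drop out of the full model
    double ysum_sel = 0.0, nsum_sel = 0.0, ysum_ctl = 0.0, nsum_ctl = 0.0;
    for (int j = 0; j < J; ++j) {
      if (xv[j] > 0.5) { ysum_sel += yv[j]; nsum_sel += nv[j]; }
      else             { ysum_ctl += yv[j]; nsum_ctl += nv[j]; }
    }
    const bool deg_sel = (ysum_sel == 0.0 || ysum_sel == nsum_sel);
    const bool deg_ctl = (ysum_ctl == 0.0 || ysum_ctl == nsum_ctl);
    double ll_f, th_f[3] = {l_ctl, l_sel, lsig0};
    if (deg_sel && deg_ctl) {
      ll_f = 0.0;
      th_f[0] = (ysum_ctl == 0.0) ? -30.0 : 30.0;
      th_f[1] = (ysum_sel == 0.0) ? -30.0 : 30.0;
      th_f[2] = -6.0;
    } else if (deg_sel || deg_ctl) {
      // fit the non-degenerate group alone (intercept + sigma)
      std::vector<double> y2, n2, x2, u2;
      for (int j = 0; j < J; ++j) {
        const bool is_sel = xv[j] > 0.5;
        if ((is_sel && deg_sel) || (!is_sel && deg_ctl)) continue;
        y2.push_back(yv[j]); n2.push_back(nv[j]); x2.push_back(0.0);
      }
      u2.resize(y2.size());
      Data d2 = d;
      d2.y = y2.data(); d2.n = n2.data(); d2.x = x2.data();
      d2.J = (int)y2.size(); d2.ustar = u2.data();
      double th2[3] = {deg_sel ? l_ctl : l_sel, lsig0, 0.0};
      ll_f = fit_model(d2, th2, 2, maxit, tol, conv_f);
      if (deg_sel) {
        th_f[0] = th2[0];
        th_f[1] = (ysum_sel == 0.0) ? -30.0 : 30.0;
      } else {
        th_f[0] = (ysum_ctl == 0.0) ? -30.0 : 30.0;
        th_f[1] = th2[0];
      }
      th_f[2] = th2[1];
    } else {
      ll_f = fit_model(d, th_f, 3, maxit, tol, conv_f);
      // the full model nests the reduced one: refit from the reduced
      // optimum if the first pass fell short
      if (ll_f < ll_r) {
        double th_f2[3] = {th_r[0], th_r[0], th_r[1]};
        bool conv2;
        const double ll2 = fit_model(d, th_f2, 3, maxit, tol, conv2);
        if (ll2 > ll_f) {
          ll_f = ll2; conv_f = conv2;
          th_f[0] = th_f2[0]; th_f[1] = th_f2[1]; th_f[2] = th_f2[2];
        }
      }
    }
    lrt[i] = std::max(0.0, 2.0 * (ll_f - ll_r));
    sigma_full[i] = std::exp(th_f[2]);
    beta_regime[i] = th_f[1] - th_f[0];
    converged[i] = conv_r && conv_f;
  }
  return List::create(_["lrt"] = lrt, _["sigma"] = sigma_full,
                      _["beta_regime"] = beta_regime,
                      _["converged"] = converged);
}
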