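// Fixed-step classical RK4 integrators on a uniform grid, shared by the
// forward state passes and the backward costate passes of the
// forward-backward sweep. Paths (controls, states driving a backward pass)
// are known at the grid nodes; half-step values are obtained by 4-point
// cubic interpolation in the interior (quadratic at the two edge intervals),
// which keeps the scheme high-order for smooth paths while remaining
// bit-reproducible for identical inputs.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Half-step values: out[j] ~ x(t_j + dt/2), j = 0..n-2.
std::vector<double> half_steps(const NumericVector& x) {
  const int n = x.size();
  std::vector<double> h(n - 1);
  if (n == 2) {
    h[0] = 0.5 * (x[0] + x[1]);
    return h;
  }
  h[0] = (3.0 * x[0] + 6.0 * x[1] - x[2]) / 8.0;
  for (int j = 1; j <= n - 3; ++j)
    h[j] = (-x[j - 1] + 9.0 * x[j] + 9.0 * x[j + 1] - x[j + 2]) / 16.0;
  h[n - 2] = (3.0 * x[n - 1] + 6.0 * x[n - 2] - x[n - 3]) / 8.0;
  return h;
}

struct CostFun {
  double a0, a1, ihc, sigma;
  bool constant;
  double value(double i) const {
    if (constant) return a0;
    return a0 + 0.5 * (a1 - a0) * (std::tanh((i - ihc) * sigma) + 1.0);
  }
  double deriv(double i) const {
    if (constant) return 0.0;
    const double c = std::cosh((i - ihc) * sigma);
    return 0.5 * (a1 - a0) * sigma / (c * c);
  }
};

CostFun cost_from_list(const List& p) {
  CostFun a;
  a.a0 = as<double>(p["alpha0"]);
  a.a1 = as<double>(p["alpha1"]);
  a.ihc = as<double>(p["i_hc"]);
  a.sigma = as<double>(p["sigma"]);
  a.constant = as<bool>(p["constant"]);
  return a;
}

} // namespace

// Forward SIR: s' = -k s i, i' = k s i - i, k(t) tabulated on the grid.
// [[Rcpp::export]]
List cpp_sir_rk4(double s0, double i0, NumericVector k, double dt) {
  const int n = k.size();
  NumericVector s(n), ii(n);
  std::vector<double> kh = half_steps(k);
  s[0] = s0; ii[0] = i0;
  int nclamp = 0;
  double worst = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    const double k1 = k[j], k2 = kh[j], k4 = k[j + 1];
    double sv = s[j], iv = ii[j];
    // stage derivatives
    double ds1 = -k1 * sv * iv,             di1 = k1 * sv * iv - iv;
    double s2 = sv + 0.5 * dt * ds1,        i2 = iv + 0.5 * dt * di1;
    double ds2 = -k2 * s2 * i2,             di2 = k2 * s2 * i2 - i2;
    double s3 = sv + 0.5 * dt * ds2,        i3 = iv + 0.5 * dt * di2;
    double ds3 = -k2 * s3 * i3,             di3 = k2 * s3 * i3 - i3;
    double s4 = sv + dt * ds3,              i4 = iv + dt * di3;
    double ds4 = -k4 * s4 * i4,             di4 = k4 * s4 * i4 - i4;
    double sn = sv + dt / 6.0 * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
    double in = iv + dt / 6.0 * (di1 + 2.0 * di2 + 2.0 * di3 + di4);
    if (sn < 0.0) { worst = std::min(worst, sn); sn = 0.0; ++nclamp; }
    if (in < 0.0) { worst = std::min(worst, in); in = 0.0; ++nclamp; }
    s[j + 1] = sn; ii[j + 1] = in;
  }
  return List::create(_["s"] = s, _["i"] = ii,
                      _["nclamp"] = nclamp, _["worst"] = worst);
}

// Individual compartment probabilities against an exogenous population
// infection path: psi_s' = -kappa psi_s i, psi_i' = kappa psi_s i - psi_i.
// [[Rcpp::export]]
List cpp_psi_rk4(double ps0, double pi0, NumericVector kappa,
                 NumericVector ipop, double dt) {
  const int n = kappa.size();
  NumericVector ps(n), pi(n);
  std::vector<double> kh = half_steps(kappa), ih = half_steps(ipop);
  ps[0] = ps0; pi[0] = pi0;
  int nclamp = 0;
  double worst = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    const double k1 = kappa[j], k2 = kh[j], k4 = kappa[j + 1];
    const double i1 = ipop[j],  i2 = ih[j], i4 = ipop[j + 1];
    double sv = ps[j], iv = pi[j];
    double ds1 = -k1 * sv * i1,            di1 = k1 * sv * i1 - iv;
    double s2 = sv + 0.5 * dt * ds1,       v2 = iv + 0.5 * dt * di1;
    double ds2 = -k2 * s2 * i2,            di2 = k2 * s2 * i2 - v2;
    double s3 = sv + 0.5 * dt * ds2,       v3 = iv + 0.5 * dt * di2;
    double ds3 = -k2 * s3 * i2,            di3 = k2 * s3 * i2 - v3;
    double s4 = sv + dt * ds3,             v4 = iv + dt * di3;
    double ds4 = -k4 * s4 * i4,            di4 = k4 * s4 * i4 - v4;
    double sn = sv + dt / 6.0 * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
    double in = iv + dt / 6.0 * (di1 + 2.0 * di2 + 2.0 * di3 + di4);
    if (sn < 0.0) { worst = std::min(worst, sn); sn = 0.0; ++nclamp; }
    if (in < 0.0) { worst = std::min(worst, in); in = 0.0; ++nclamp; }
    ps[j + 1] = sn; pi[j + 1] = in;
  }
  return List::create(_["s"] = ps, _["i"] = pi,
                      _["nclamp"] = nclamp, _["worst"] = worst);
}

// Backward costates for the individual problem:
//   v_s' = (v_s - v_i) kappa i
//   v_i' = f^{-t} alpha(i) + v_i
// integrated from t_f down to t_0; kappa and i are tabulated paths
// (at equilibrium kappa = k and i is the population path).
// [[Rcpp::export]]
List cpp_costates_individual(NumericVector ipath, NumericVector kappa,
                             double dt, double t0, double lnf, List cost,
                             double vs_tf, double vi_tf) {
  const int n = ipath.size();
  const CostFun a = cost_from_list(cost);
  NumericVector vs(n), vi(n);
  std::vector<double> ih = half_steps(ipath), kh = half_steps(kappa);
  vs[n - 1] = vs_tf; vi[n - 1] = vi_tf;
  const double h = -dt;
  for (int j = n - 1; j > 0; --j) {
    const double t1 = t0 + j * dt, t2 = t1 - 0.5 * dt, t4 = t1 - dt;
    const double i1 = ipath[j], i2 = ih[j - 1], i4 = ipath[j - 1];
    const double k1 = kappa[j], k2 = kh[j - 1], k4 = kappa[j - 1];
    double s1 = vs[j], w1 = vi[j];
    double dvs1 = (s1 - w1) * k1 * i1;
    double dvi1 = std::exp(-t1 * lnf) * a.value(i1) + w1;
    double s2 = s1 + 0.5 * h * dvs1, w2 = w1 + 0.5 * h * dvi1;
    double dvs2 = (s2 - w2) * k2 * i2;
    double dvi2 = std::exp(-t2 * lnf) * a.value(i2) + w2;
    double s3 = s1 + 0.5 * h * dvs2, w3 = w1 + 0.5 * h * dvi2;
    double dvs3 = (s3 - w3) * k2 * i2;
    double dvi3 = std::exp(-t2 * lnf) * a.value(i2) + w3;
    double s4 = s1 + h * dvs3, w4 = w1 + h * dvi3;
    double dvs4 = (s4 - w4) * k4 * i4;
    double dvi4 = std::exp(-t4 * lnf) * a.value(i4) + w4;
    vs[j - 1] = s1 + h / 6.0 * (dvs1 + 2.0 * dvs2 + 2.0 * dvs3 + dvs4);
    vi[j - 1] = w1 + h / 6.0 * (dvi1 + 2.0 * dvi2 + 2.0 * dvi3 + dvi4);
  }
  return List::create(_["v_s"] = vs, _["v_i"] = vi);
}

// Backward costates for the utilitarian (population) problem:
//   v_s' = (v_s - v_i) k i
//   v_i' = f^{-t} [alpha(i) + alpha'(i) i] + (v_s - v_i) k s + v_i
// [[Rcpp::export]]
List cpp_costates_population(NumericVector spath, NumericVector ipath,
                             NumericVector k, double dt, double t0,
                             double lnf, List cost,
                             double vs_tf, double vi_tf) {
  const int n = ipath.size();
  const CostFun a = cost_from_list(cost);
  NumericVector vs(n), vi(n);
  std::vector<double> sh = half_steps(spath), ih = half_steps(ipath),
                      kh = half_steps(k);
  vs[n - 1] = vs_tf; vi[n - 1] = vi_tf;
  const double h = -dt;
  for (int j = n - 1; j > 0; --j) {
    const double t1 = t0 + j * dt, t2 = t1 - 0.5 * dt, t4 = t1 - dt;
    const double i1 = ipath[j], i2 = ih[j - 1], i4 = ipath[j - 1];
    const double s1p = spath[j], s2p = sh[j - 1], s4p = spath[j - 1];
    const double k1 = k[j], k2 = kh[j - 1], k4 = k[j - 1];
    double s1 = vs[j], w1 = vi[j];
    auto rhs = [&](double vsv, double viv, double t, double sp, double ip,
                   double kp, double* dvs, double* dvi) {
      const double d = vsv - viv;
      *dvs = d * kp * ip;
      *dvi = std::exp(-t * lnf) * (a.value(ip) + a.deriv(ip) * ip) +
             d * kp * sp + viv;
    };
    double dvs1, dvi1, dvs2, dvi2, dvs3, dvi3, dvs4, dvi4;
    rhs(s1, w1, t1, s1p, i1, k1, &dvs1, &dvi1);
    rhs(s1 + 0.5 * h * dvs1, w1 + 0.5 * h * dvi1, t2, s2p, i2, k2,
        &dvs2, &dvi2);
    rhs(s1 + 0.5 * h * dvs2, w1 + 0.5 * h * dvi2, t2, s2p, i2, k2,
        &dvs3, &dvi3);
    rhs(s1 + h * dvs3, w1 + h * dvi3, t4, s4p, i4, k4, &dvs4, &dvi4);
    vs[j - 1] = s1 + h / 6.0 * (dvs1 + 2.0 * dvs2 + 2.0 * dvs3 + dvs4);
    vi[j - 1] = w1 + h / 6.0 * (dvi1 + 2.0 * dvi2 + 2.0 * dvi3 + dvi4);
  }
  return List::create(_["v_s"] = vs, _["v_i"] = vi);
}

// Backward costates for the government (outer Stackelberg) problem:
//   lambda_s' = i Lambda
//   lambda_i' = s Lambda + f_g^{-t} [alpha_g(i) + alpha_g'(i) i] + lambda_i
// with the auxiliary integrand
//   Lambda = -(l_i - l_s)(kappa* + eps/2)
//          + f_g^{-t} f^t / 2 (v_i - v_s)
//            ( i s [beta_g f^t (v_i - v_s) - 2 f_g^t (l_i - l_s)]
//              + eps (gamma_g + beta_g) ).
// s, i, eps and the inner costates v_s, v_i are tabulated paths.
// [[Rcpp::export]]
List cpp_costates_government(NumericVector spath, NumericVector ipath,
                             NumericVector eps, NumericVector vs,
                             NumericVector vi, double dt, double t0,
                             double lnf, double lnfg, double kappa_star,
                             double beta_g, double gamma_g, List cost_g,
                             double ls_tf, double li_tf) {
  const int n = ipath.size();
  const CostFun a = cost_from_list(cost_g);
  NumericVector ls(n), li(n), Lam(n);
  std::vector<double> sh = half_steps(spath), ih = half_steps(ipath),
                      eh = half_steps(eps), vsh = half_steps(vs),
                      vih = half_steps(vi);
  ls[n - 1] = ls_tf; li[n - 1] = li_tf;
  auto lambda_fun = [&](double lsv, double liv, double t, double sp,
                        double ip, double ep, double vsp, double vip) {
    const double dl = liv - lsv, dv = vip - vsp;
    const double ft = std::exp(t * lnf), fgt = std::exp(t * lnfg);
    return -dl * (kappa_star + 0.5 * ep) +
           (1.0 / fgt) * ft * 0.5 * dv *
             (ip * sp * (beta_g * ft * dv - 2.0 * fgt * dl) +
              ep * (gamma_g + beta_g));
  };
  const double h = -dt;
  for (int j = n - 1; j > 0; --j) {
    const double t1 = t0 + j * dt, t2 = t1 - 0.5 * dt, t4 = t1 - dt;
    const double i1 = ipath[j], i2 = ih[j - 1], i4 = ipath[j - 1];
    const double s1p = spath[j], s2p = sh[j - 1], s4p = spath[j - 1];
    const double e1 = eps[j], e2 = eh[j - 1], e4 = eps[j - 1];
    const double vs1 = vs[j], vs2 = vsh[j - 1], vs4 = vs[j - 1];
    const double vi1 = vi[j], vi2 = vih[j - 1], vi4 = vi[j - 1];
    double l1 = ls[j], m1 = li[j];
    auto rhs = [&](double lsv, double liv, double t, double sp, double ip,
                   double ep, double vsp, double vip,
                   double* dls, double* dli) {
      const double L = lambda_fun(lsv, liv, t, sp, ip, ep, vsp, vip);
      *dls = ip * L;
      *dli = sp * L +
             std::exp(-t * lnfg) * (a.value(ip) + a.deriv(ip) * ip) + liv;
    };
    double a1, b1, a2, b2, a3, b3, a4, b4;
    rhs(l1, m1, t1, s1p, i1, e1, vs1, vi1, &a1, &b1);
    rhs(l1 + 0.5 * h * a1, m1 + 0.5 * h * b1, t2, s2p, i2, e2, vs2, vi2,
        &a2, &b2);
    rhs(l1 + 0.5 * h * a2, m1 + 0.5 * h * b2, t2, s2p, i2, e2, vs2, vi2,
        &a3, &b3);
    rhs(l1 + h * a3, m1 + h * b3, t4, s4p, i4, e4, vs4, vi4, &a4, &b4);
    ls[j - 1] = l1 + h / 6.0 * (a1 + 2.0 * a2 + 2.0 * a3 + a4);
    li[j - 1] = m1 + h / 6.0 * (b1 + 2.0 * b2 + 2.0 * b3 + b4);
  }
  for (int j = 0; j < n; ++j)
    Lam[j] = lambda_fun(ls[j], li[j], t0 + j * dt, spath[j], ipath[j],
                        eps[j], vs[j], vi[j]);
  return List::create(_["lambda_s"] = ls, _["lambda_i"] = li,
                      _["Lambda"] = Lam);
}
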