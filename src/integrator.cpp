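// Fixed-step RK4 integrator for the coupled canonical-microcircuit network.
//
// State per source: four populations (ss, sp, ii, dp), each with
// depolarization v (mV) and current i (mV/ms), second-order (alpha kernel)
// convolution kinetics:  v' = i,  i' = kappa*u - 2*kappa*i - kappa^2*v.
//
// All synaptic drives are expressed in firing-rate deviations sigma(v) - sigma0
// so that the all-zero state is an exact fixed point. The superficial-pyramidal
// self-inhibition is state-dependent: exp(gamma_eff) with
//   gamma_eff = gamma_base - modc * M * (sigma(v_dp_afferent) - sigma0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& v, const rowvec& slope, const rowvec& thresh) {
  mat out(4, v.n_cols);
  for (uword s = 0; s < v.n_cols; ++s)
    out.col(s) = 1.0 / (1.0 + exp(-slope(s) * (v.col(s) - thresh(s))));
  return out;
}

struct Deriv {
  mat dv, di;
  vec gam;
};

// one evaluation of the vector field; ut = exogenous input value at this time
static Deriv vfield(const mat& v, const mat& cur, double ut,
                    const cube& C, const mat& kap, const vec& gamma_base,
                    const mat& Afwd, const mat& Abwd, const mat& M,
                    double bwd_ii, double modc,
                    const rowvec& slope, const rowvec& thresh,
                    const rowvec& sig0, const vec& stimgain) {
  const uword ns = v.n_cols;
  mat r = sigm(v, slope, thresh);
  r.each_row() -= sig0;                       // rate deviations from baseline

  vec sp_r = r.row(1).t();
  vec dp_r = r.row(3).t();
  vec gam  = gamma_base - modc * (M * dp_r);  // state-dependent log self-inhibition
  vec bdrv = Abwd * dp_r;                     // backward driving afference

  mat inp(4, ns);
  for (uword s = 0; s < ns; ++s) inp.col(s) = C.slice(s) * r.col(s);
  inp.row(0) += (Afwd * sp_r).t() + (stimgain * ut).t();
  inp.row(1) += bdrv.t() - (exp(gam) % r.row(1).t()).t();
  inp.row(2) += bwd_ii * bdrv.t();

  Deriv d;
  d.dv  = cur;
  d.di  = kap % inp - 2.0 * (kap % cur) - (kap % kap) % v;
  d.gam = gam;
  return d;
}

// [[Rcpp::export]]
Rcpp::List cmc_integrate(const arma::cube& C, const arma::mat& kap,
                         const arma::vec& gamma_base,
                         const arma::mat& Afwd, const arma::mat& Abwd,
                         const arma::mat& M, double bwd_ii, double modc,
                         const arma::rowvec& slope, const arma::rowvec& thresh,
                         const arma::vec& stimgain,
                         double stim_peak, double stim_width,
                         double t0, double dt, int n_steps) {
  const uword ns = kap.n_cols;
  rowvec sig0(ns);
  for (uword s = 0; s < ns; ++s)
    sig0(s) = 1.0 / (1.0 + exp(slope(s) * thresh(s)));

  mat v(4, ns, fill::zeros), cur(4, ns, fill::zeros);
  cube V(4, ns, n_steps);
  mat  G(ns, n_steps);

  auto input = [&](double t) {
    double z = (t - stim_peak) / stim_width;
    return std::exp(-0.5 * z * z);
  };

  for (int k = 0; k < n_steps; ++k) {
    double t = t0 + k * dt;
    Deriv k1 = vfield(v, cur, input(t), C, kap, gamma_base, Afwd, Abwd, M,
                      bwd_ii, modc, slope, thresh, sig0, stimgain);
    V.slice(k) = v;
    G.col(k)   = k1.gam;
    if (!v.is_finite()) {
      uword bad = 0;
      for (uword s = 0; s < ns; ++s)
        if (!v.col(s).is_finite()) { bad = s; break; }
      Rcpp::stop("network integration diverged (non-finite state) at source %d, t = %.1f ms",
                 (int)bad + 1, t);
    }
    double um = input(t + dt / 2.0), u1 = input(t + dt);
    Deriv k2 = vfield(v + 0.5 * dt * k1.dv, cur + 0.5 * dt * k1.di, um,
                      C, kap, gamma_base, Afwd, Abwd, M, bwd_ii, modc,
                      slope, thresh, sig0, stimgain);
    Deriv k3 = vfield(v + 0.5 * dt * k2.dv, cur + 0.5 * dt * k2.di, um,
                      C, kap, gamma_base, Afwd, Abwd, M, bwd_ii, modc,
                      slope, thresh, sig0, stimgain);
    Deriv k4 = vfield(v + dt * k3.dv, cur + dt * k3.di, u1,
                      C, kap, gamma_base, Afwd, Abwd, M, bwd_ii, modc,
                      slope, thresh, sig0, stimgain);
    v   += dt / 6.0 * (k1.dv + 2.0 * k2.dv + 2.0 * k3.dv + k4.dv);
    cur += dt / 6.0 * (k1.di + 2.0 * k2.di + 2.0 * k3.di + k4.di);
  }

  return Rcpp::List::create(Rcpp::Named("v") = V, Rcpp::Named("gamma") = G);
}
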