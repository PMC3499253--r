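// Compiled trial integrator: steps the full five-component architecture
// through one trial's stimulus timeline. Mirrors the R reference
// implementation in step_model() exactly (synchronous update, same input
// composition, same Euler scheme); a test asserts trajectory equivalence.
// Convolutions are evaluated as dense kernel-matrix products (BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// dense circulant matrix of a kernel sampled at wrapped offsets 0, dx, ...
static arma::mat circulant(const arma::vec& k) {
  int n = k.n_elem;
  arma::mat K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int d = std::abs(i - j);
      if (d > n - d) d = n - d;
      K(i, j) = k[d];
    }
  return K;
}

// banded symmetric matrix of a bounded-dimension kernel (zero padding)
static arma::mat banded(const arma::vec& k) {
  int n = k.n_elem;
  arma::mat K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K(i, j) = k[std::abs(i - j)];
  return K;
}

// [[Rcpp::export]]
List sim_trial_cpp(List state, List pre, List par,
                   NumericMatrix bump_mat, NumericMatrix bump_win,
                   NumericMatrix ctx_stim, int go_t0,
                   int n_steps, double dt,
                   int snap_t0, int snap_t1, int trace_stride,
                   unsigned int seed) {
  arma::vec u_spt = as<arma::vec>(state["u_spt"]);
  arma::vec u_ctx = as<arma::vec>(state["u_ctx"]);
  arma::mat u_asc = as<arma::mat>(state["u_asc"]);
  arma::vec u_prp = as<arma::vec>(state["u_prp"]);
  arma::vec u_mot = as<arma::vec>(state["u_mot"]);
  arma::mat W_ca = as<arma::mat>(state["W_ca"]);     // n_ctx x nxy
  arma::mat W_ap_t = as<arma::mat>(state["W_ap_t"]); // n_x x nxy

  arma::mat K_spt = circulant(as<arma::vec>(pre["k_spt"]));
  arma::mat K_prp = circulant(as<arma::vec>(pre["k_prp"]));
  arma::mat K_mot = circulant(as<arma::vec>(pre["k_mot"]));
  arma::mat Kx = circulant(as<arma::vec>(pre["asc_px"]));
  arma::mat Ky = banded(as<arma::vec>(pre["asc_py"]));
  arma::mat P_spt_prp = circulant(as<arma::vec>(pre["p_spt_prp"]));
  arma::mat P_spt_asc = circulant(as<arma::vec>(pre["p_spt_asc"]));
  arma::mat P_prp_mot = circulant(as<arma::vec>(pre["p_prp_mot"]));
  arma::mat P_mot_prp = circulant(as<arma::vec>(pre["p_mot_prp"]));
  double area = as<double>(pre["area"]);

  NumericVector tau = par["tau"], h = par["h"], q = par["q"], beta = par["beta"];
  // parameter vectors ordered: spt, ctx, asc, prp, mot
  double w_self = par["w_self"], w_mut = par["w_mut"];
  double g_ctx_asc = par["g_ctx_asc"], g_asc_prp = par["g_asc_prp"];
  double g_mot_prp_inh = par["g_mot_prp_inh"], g_go = par["g_go"];
  double a_exc2 = par["asc_a_exc"], g_inh2 = par["asc_g_inh"];

  int n_x = u_spt.n_elem, n_ctx = u_ctx.n_elem, n_y = u_asc.n_cols;
  int nxy = n_x * n_y;

  (void)seed;  // noise draws use R's RNG (set.seed governs reproducibility)

  arma::vec f_spt(n_x), f_ctx(n_ctx), f_prp(n_x), f_mot(n_x);
  arma::mat f_asc(n_x, n_y);
  arma::vec in_spt(n_x), in_prp(n_x), in_mot(n_x), tmp(n_x);
  arma::mat in_asc(n_x, n_y);

  arma::vec snap_ctx(n_ctx, arma::fill::zeros);
  arma::mat snap_asc(n_x, n_y, arma::fill::zeros);
  arma::vec snap_prp(n_x, arma::fill::zeros), snap_mot(n_x, arma::fill::zeros);
  int snap_n = 0;

  int n_rec = trace_stride > 0 ? (n_steps + trace_stride - 1) / trace_stride : 0;
  arma::mat trace_prp(n_x, n_rec > 0 ? n_rec : 1, arma::fill::zeros);
  int rec_i = 0;

  double sq = std::sqrt(dt);
  arma::vec fav(f_asc.memptr(), nxy, false, true);
  arma::vec uav(u_asc.memptr(), nxy, false, true);
  arma::vec iav(in_asc.memptr(), nxy, false, true);

  for (int t = 0; t < n_steps; ++t) {
    f_spt = 1.0 / (1.0 + arma::exp(-beta[0] * u_spt));
    f_ctx = 1.0 / (1.0 + arma::exp(-beta[1] * u_ctx));
    fav = 1.0 / (1.0 + arma::exp(-beta[2] * uav));
    f_prp = 1.0 / (1.0 + arma::exp(-beta[3] * u_prp));
    f_mot = 1.0 / (1.0 + arma::exp(-beta[4] * u_mot));

    // external inputs
    in_spt.zeros();
    for (int b = 0; b < bump_win.nrow(); ++b)
      if (t >= bump_win(b, 0) && t < bump_win(b, 1))
        for (int i = 0; i < n_x; ++i) in_spt[i] += bump_mat(i, b);
    arma::vec in_ctx(n_ctx, arma::fill::zeros);
    for (int b = 0; b < ctx_stim.nrow(); ++b)
      if (t >= ctx_stim(b, 2) && t < ctx_stim(b, 3))
        in_ctx[(int)ctx_stim(b, 0)] += ctx_stim(b, 1);
    bool go = (go_t0 >= 0 && t >= go_t0);

    // projection inputs from previous step's outputs
    tmp = P_spt_asc * f_spt;                     // ridge along x
    iav = g_ctx_asc * (W_ca.t() * f_ctx);
    in_asc.each_col() += tmp;

    in_prp = P_spt_prp * f_spt
      + g_asc_prp * area * (W_ap_t * fav)
      + P_mot_prp * f_mot - g_mot_prp_inh * arma::mean(f_mot);
    in_mot = P_prp_mot * f_prp;
    if (go) in_mot += g_go;

    // Euler updates with lateral interactions
    u_spt += (dt / tau[0]) * (-u_spt + h[0] + in_spt + K_spt * f_spt);
    if (q[0] > 0) u_spt += q[0] * sq * arma::randn<arma::vec>(n_x);

    double fsum = arma::accu(f_ctx);
    arma::vec lat_ctx = w_self * f_ctx - w_mut * (fsum - f_ctx);
    u_ctx += (dt / tau[1]) * (-u_ctx + h[1] + in_ctx + lat_ctx);
    if (q[1] > 0) u_ctx += q[1] * sq * arma::randn<arma::vec>(n_ctx);

    arma::mat lat_asc = a_exc2 * (Kx * f_asc * Ky)
      - g_inh2 * (arma::accu(f_asc) / nxy);
    u_asc += (dt / tau[2]) * (-u_asc + h[2] + in_asc + lat_asc);
    if (q[2] > 0) u_asc += q[2] * sq * arma::randn<arma::mat>(n_x, n_y);

    u_prp += (dt / tau[3]) * (-u_prp + h[3] + in_prp + K_prp * f_prp);
    if (q[3] > 0) u_prp += q[3] * sq * arma::randn<arma::vec>(n_x);

    u_mot += (dt / tau[4]) * (-u_mot + h[4] + in_mot + K_mot * f_mot);
    if (q[4] > 0) u_mot += q[4] * sq * arma::randn<arma::vec>(n_x);

    // snapshots and traces (post-update outputs)
    if (t >= snap_t0 && t < snap_t1) {
      snap_ctx += 1.0 / (1.0 + arma::exp(-beta[1] * u_ctx));
      snap_asc += 1.0 / (1.0 + arma::exp(-beta[2] * u_asc));
      snap_prp += 1.0 / (1.0 + arma::exp(-beta[3] * u_prp));
      snap_mot += 1.0 / (1.0 + arma::exp(-beta[4] * u_mot));
      ++snap_n;
    }
    if (trace_stride > 0 && t % trace_stride == 0)
      trace_prp.col(rec_i++) = 1.0 / (1.0 + arma::exp(-beta[3] * u_prp));
  }
  if (snap_n > 0) {
    snap_ctx /= snap_n; snap_asc /= snap_n;
    snap_prp /= snap_n; snap_mot /= snap_n;
  }
  return List::create(
    _["u_spt"] = u_spt, _["u_ctx"] = u_ctx, _["u_asc"] = u_asc,
    _["u_prp"] = u_prp, _["u_mot"] = u_mot,
    _["f_ctx"] = snap_ctx, _["f_asc"] = snap_asc,
    _["f_prp"] = snap_prp, _["f_mot"] = snap_mot,
    _["trace_prp"] = trace_prp, _["n_rec"] = rec_i);
}
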