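// Time-stepping core for the three-population BCPNN network.
//
// The R level owns all state as plain matrices/vectors collected in an
// environment; this file advances one pattern presentation at a time.
// Per-timestep order (synchronous update, one-step propagation delay):
//   1. membranes + softmax + spike sampling, population order
//      INP -> HID -> INPRC, using z-traces from the previous step;
//   2. z-trace updates of all projections from this step's spikes;
//   3. if learning is gated on, p-trace updates.
// Spike draws use R's RNG with one uniform per unit in ascending unit
// order, so results are reproducible from set.seed() and match the
// R-level sample_spikes() call for call order.

#include <Rcpp.h>
using namespace Rcpp;

static inline void softmax_blocks(const std::vector<double>& v,
                                  std::vector<double>& pi, int H, int M) {
  for (int h = 0; h < H; ++h) {
    int o = h * M;
    double mx = v[o];
    for (int m = 1; m < M; ++m) if (v[o + m] > mx) mx = v[o + m];
    double s = 0.0;
    for (int m = 0; m < M; ++m) { pi[o + m] = std::exp(v[o + m] - mx); s += pi[o + m]; }
    for (int m = 0; m < M; ++m) pi[o + m] /= s;
  }
}

static inline void sample_pop(const std::vector<double>& pi,
                              std::vector<double>& s, double mu, bool spiking) {
  int n = (int)pi.size();
  if (!spiking) { for (int j = 0; j < n; ++j) s[j] = pi[j]; return; }
  for (int j = 0; j < n; ++j) s[j] = (unif_rand() < pi[j] * mu) ? 1.0 : 0.0;
}

// current_j = sum_i z_i W(i,j) over active patches only
static void patch_current(const NumericMatrix& W, const NumericMatrix& mask,
                          int Mpre, int Mpost,
                          const std::vector<double>& z, std::vector<double>& out) {
  int Hpre = mask.nrow(), Hpost = mask.ncol();
  int n_pre = Hpre * Mpre;
  const double* w = REAL(W);
  const double* mk = REAL(mask);
  std::fill(out.begin(), out.end(), 0.0);
  for (int jh = 0; jh < Hpost; ++jh) {
    for (int ih = 0; ih < Hpre; ++ih) {
      if (mk[jh * Hpre + ih] == 0.0) continue;
      int base = ih * Mpre;
      for (int jm = 0; jm < Mpost; ++jm) {
        int j = jh * Mpost + jm;
        const double* wcol = w + (R_xlen_t)j * n_pre;
        double acc = 0.0;
        for (int im = 0; im < Mpre; ++im) acc += z[base + im] * wcol[base + im];
        out[j] += acc;
      }
    }
  }
}

static inline void z_update(std::vector<double>& z, const std::vector<double>& s,
                            double a, double inv_mu) {
  int n = (int)z.size();
  for (int i = 0; i < n; ++i) z[i] += a * (s[i] * inv_mu - z[i]);
}

static void p_update(NumericVector p_pre, NumericVector p_post, NumericMatrix P,
                     const std::vector<double>& z_pre,
                     const std::vector<double>& z_post, double a) {
  int n_pre = (int)z_pre.size(), n_post = (int)z_post.size();
  for (int i = 0; i < n_pre; ++i) p_pre[i] += a * (z_pre[i] - p_pre[i]);
  for (int j = 0; j < n_post; ++j) p_post[j] += a * (z_post[j] - p_post[j]);
  double* p = REAL(P);
  for (int j = 0; j < n_post; ++j) {
    double zj = z_post[j];
    double* col = p + (R_xlen_t)j * n_pre;
    for (int i = 0; i < n_pre; ++i) col[i] += a * (z_pre[i] * zj - col[i]);
  }
}

static void bias_weight(const NumericVector& p_pre, const NumericVector& p_post,
                        const NumericMatrix& P, NumericVector b, NumericMatrix W,
                        double eps) {
  int n_pre = p_pre.size(), n_post = p_post.size();
  double eps2 = eps * eps;
  const double* pm = REAL(P);
  double* wm = REAL(W);
  std::vector<double> lpi(n_pre);
  for (int i = 0; i < n_pre; ++i) lpi[i] = std::log(std::max(p_pre[i], eps));
  for (int j = 0; j < n_post; ++j) {
    double pj = std::max(p_post[j], eps);
    double lpj = std::log(pj);
    b[j] = lpj;
    const double* pcol = pm + (R_xlen_t)j * n_pre;
    double* wcol = wm + (R_xlen_t)j * n_pre;
    // subtracting the sum keeps a recurrent projection's weight matrix
    // exactly symmetric (commutative add, unlike chained subtraction)
    for (int i = 0; i < n_pre; ++i)
      wcol[i] = std::log(std::max(pcol[i], eps2)) - (lpi[i] + lpj);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_spike_counts(NumericVector prob, int n_steps) {
  int n = prob.size();
  IntegerVector counts(n);
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t)
    for (int j = 0; j < n; ++j)
      if (unif_rand() < prob[j]) counts[j]++;
  return counts;
}

// Advance the full network by one pattern presentation.
// e: environment holding all state; see build_network() on the R side.
// mode: 0 train, 1 eval.  record_steps: 1-based step indices counted
// from the start of the ffwd phase at which HID/INPRC z-traces (and pi)
// are captured.
// [[Rcpp::export]]
List cpp_run_pattern(Environment e, NumericVector I_inp, NumericVector I_inprc,
                     int mode, IntegerVector phase_steps, bool spiking,
                     bool has_recurrent, IntegerVector record_steps,
                     bool record_spikes, bool update_weights) {
  RNGScope scope;

  const int Hinp = e["H_inp"], Minp = e["M_inp"];
  const int Hhid = e["H_hid"], Mhid = e["M_hid"];
  const int Ninp = Hinp * Minp, Nhid = Hhid * Mhid;

  const double dt = e["dt"], tau_p = e["tau_p"], eps = e["eps"];
  const double tau_m = e["tau_m"], mu_spk = e["mu_spk"];
  const double tau_zi = e["tau_zi"], tau_zj = e["tau_zj"];
  const double a_m = dt / tau_m, a_p = dt / tau_p;
  const double a_zi = dt / tau_zi, a_zj = dt / tau_zj;
  const double inv_mu = 1.0 / mu_spk;

  NumericMatrix Wff = e["W_ff"], Wrec = e["W_rec"], Wfb = e["W_fb"];
  NumericVector bff = e["b_ff"], brec = e["b_rec"], bfb = e["b_fb"];
  NumericMatrix mff = e["patch_ff"], mrec = e["patch_rec"], mfb = e["patch_fb"];
  NumericVector zff_pre = e["z_ff_pre"], zff_post = e["z_ff_post"];
  NumericVector zrec_pre = e["z_rec_pre"], zrec_post = e["z_rec_post"];
  NumericVector zfb_pre = e["z_fb_pre"], zfb_post = e["z_fb_post"];
  NumericVector pff_pre = e["p_ff_pre"], pff_post = e["p_ff_post"];
  NumericVector prec_pre = e["p_rec_pre"], prec_post = e["p_rec_post"];
  NumericVector pfb_pre = e["p_fb_pre"], pfb_post = e["p_fb_post"];
  NumericMatrix Pff = e["P_ff"], Prec = e["P_rec"], Pfb = e["P_fb"];
  NumericVector v_inp_r = e["v_inp"], v_hid_r = e["v_hid"], v_inprc_r = e["v_inprc"];

  // working copies of the fast state (vectors are cheap)
  std::vector<double> v_inp(v_inp_r.begin(), v_inp_r.end());
  std::vector<double> v_hid(v_hid_r.begin(), v_hid_r.end());
  std::vector<double> v_inprc(v_inprc_r.begin(), v_inprc_r.end());
  std::vector<double> zffi(zff_pre.begin(), zff_pre.end());
  std::vector<double> zffj(zff_post.begin(), zff_post.end());
  std::vector<double> zri(zrec_pre.begin(), zrec_pre.end());
  std::vector<double> zrj(zrec_post.begin(), zrec_post.end());
  std::vector<double> zbi(zfb_pre.begin(), zfb_pre.end());
  std::vector<double> zbj(zfb_post.begin(), zfb_post.end());

  std::vector<double> pi_inp(Ninp), pi_hid(Nhid), pi_inprc(Ninp);
  std::vector<double> s_inp(Ninp), s_hid(Nhid), s_inprc(Ninp);
  std::vector<double> u(std::max(Ninp, Nhid)), cur(std::max(Ninp, Nhid));

  const int n_rec = record_steps.size();
  NumericMatrix rec_hid_z(n_rec, Nhid), rec_inprc_z(n_rec, Ninp);
  NumericMatrix rec_hid_pi(n_rec, Nhid);

  int total_steps = 0;
  for (int p = 0; p < 4; ++p) total_steps += phase_steps[p];
  NumericMatrix sp_inp, sp_hid, sp_inprc;
  if (record_spikes) {
    sp_inp = NumericMatrix(total_steps, Ninp);
    sp_hid = NumericMatrix(total_steps, Nhid);
    sp_inprc = NumericMatrix(total_steps, Ninp);
  }

  int onset_step = 0;   // counts steps after the no-input phase
  int global_step = 0;

  for (int phase = 0; phase < 4; ++phase) {
    int n_steps = phase_steps[phase];
    if (n_steps == 0) continue;
    // gate table; phases: 0 no-input, 1 ffwd, 2 overlap, 3 recr
    bool in_inp = (phase == 1 || phase == 2);
    bool in_inprc = (mode == 0) && (phase == 1);   // clamp during training
    bool g_ff = (phase == 1 || phase == 2);
    bool g_rec = has_recurrent && mode == 1 && (phase == 2 || phase == 3);
    bool g_fb = (mode == 1) && (phase >= 1);
    bool learn = (mode == 0) && (phase == 1);

    for (int t = 0; t < n_steps; ++t) {
      // -- INP membrane
      for (int j = 0; j < Ninp; ++j) {
        double uj = in_inp ? I_inp[j] : 0.0;
        v_inp[j] += a_m * (uj - v_inp[j]);
      }
      softmax_blocks(v_inp, pi_inp, Hinp, Minp);
      sample_pop(pi_inp, s_inp, mu_spk, spiking);

      // -- HID membrane
      std::fill(u.begin(), u.begin() + Nhid, 0.0);
      if (g_ff) {
        patch_current(Wff, mff, Minp, Mhid, zffi, cur);
        for (int j = 0; j < Nhid; ++j) u[j] += bff[j] + cur[j];
      }
      if (g_rec) {
        patch_current(Wrec, mrec, Mhid, Mhid, zri, cur);
        for (int j = 0; j < Nhid; ++j) u[j] += brec[j] + cur[j];
      }
      for (int j = 0; j < Nhid; ++j) v_hid[j] += a_m * (u[j] - v_hid[j]);
      softmax_blocks(v_hid, pi_hid, Hhid, Mhid);
      sample_pop(pi_hid, s_hid, mu_spk, spiking);

      // -- INPRC membrane
      std::fill(u.begin(), u.begin() + Ninp, 0.0);
      if (in_inprc) for (int j = 0; j < Ninp; ++j) u[j] += I_inprc[j];
      if (g_fb) {
        patch_current(Wfb, mfb, Mhid, Minp, zbi, cur);
        for (int j = 0; j < Ninp; ++j) u[j] += bfb[j] + cur[j];
      }
      for (int j = 0; j < Ninp; ++j) v_inprc[j] += a_m * (u[j] - v_inprc[j]);
      softmax_blocks(v_inprc, pi_inprc, Hinp, Minp);
      sample_pop(pi_inprc, s_inprc, mu_spk, spiking);

      // -- z-traces
      z_update(zffi, s_inp, a_zi, inv_mu);
      z_update(zffj, s_hid, a_zj, inv_mu);
      z_update(zri, s_hid, a_zi, inv_mu);
      z_update(zrj, s_hid, a_zj, inv_mu);
      z_update(zbi, s_hid, a_zi, inv_mu);
      z_update(zbj, s_inprc, a_zj, inv_mu);

      // -- p-traces
      if (learn) {
        p_update(pff_pre, pff_post, Pff, zffi, zffj, a_p);
        if (has_recurrent) p_update(prec_pre, prec_post, Prec, zri, zrj, a_p);
        p_update(pfb_pre, pfb_post, Pfb, zbi, zbj, a_p);
      }

      if (record_spikes) {
        for (int j = 0; j < Ninp; ++j) sp_inp(global_step, j) = s_inp[j];
        for (int j = 0; j < Nhid; ++j) sp_hid(global_step, j) = s_hid[j];
        for (int j = 0; j < Ninp; ++j) sp_inprc(global_step, j) = s_inprc[j];
      }
      global_step++;

      if (phase >= 1) {
        onset_step++;
        for (int r = 0; r < n_rec; ++r) {
          if (record_steps[r] == onset_step) {
            for (int j = 0; j < Nhid; ++j) {
              rec_hid_z(r, j) = zffj[j];
              rec_hid_pi(r, j) = pi_hid[j];
            }
            for (int j = 0; j < Ninp; ++j) rec_inprc_z(r, j) = zbj[j];
          }
        }
      }
    }
  }

  if (update_weights) {
    bias_weight(pff_pre, pff_post, Pff, bff, Wff, eps);
    if (has_recurrent) bias_weight(prec_pre, prec_post, Prec, brec, Wrec, eps);
    bias_weight(pfb_pre, pfb_post, Pfb, bfb, Wfb, eps);
  }

  // write fast state back
  std::copy(v_inp.begin(), v_inp.end(), v_inp_r.begin());
  std::copy(v_hid.begin(), v_hid.end(), v_hid_r.begin());
  std::copy(v_inprc.begin(), v_inprc.end(), v_inprc_r.begin());
  std::copy(zffi.begin(), zffi.end(), zff_pre.begin());
  std::copy(zffj.begin(), zffj.end(), zff_post.begin());
  std::copy(zri.begin(), zri.end(), zrec_pre.begin());
  std::copy(zrj.begin(), zrj.end(), zrec_post.begin());
  std::copy(zbi.begin(), zbi.end(), zfb_pre.begin());
  std::copy(zbj.begin(), zbj.end(), zfb_post.begin());

  List out = List::create(_["hid_z"] = rec_hid_z, _["inprc_z"] = rec_inprc_z,
                          _["hid_pi"] = rec_hid_pi);
  if (record_spikes) {
    out["spikes_inp"] = sp_inp;
    out["spikes_hid"] = sp_hid;
    out["spikes_inprc"] = sp_inprc;
  }
  return out;
}
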