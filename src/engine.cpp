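// Fixed-step integrator for the reduced two-layer column.
//
// State layout is flat: one entry per compartment (voltage, HH gates,
// calcium pool) and one entry per merged conductance state (a pair of
// rise/decay exponentials shared by all synapses with identical target
// compartment, receptor kinetics and reversal).  Voltages advance with a
// semi-implicit update (membrane and synaptic conductances implicit,
// axial neighbour voltages explicit); gates use exponential Euler with
// tabulated rate functions.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SynEvent {
  double t;
  int state;
  double amp;
  bool operator<(const SynEvent& other) const { return t > other.t; }  // min-heap
};

inline double table_lookup(const double* col, double v, double vmin,
                           double inv_dv, int n) {
  double x = (v - vmin) * inv_dv;
  if (x <= 0.0) return col[0];
  if (x >= n - 1) return col[n - 1];
  int i = static_cast<int>(x);
  double f = x - i;
  return col[i] * (1.0 - f) + col[i + 1] * f;
}

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List syn, List drv, List lcl, List inj, List ctrl) {
  // --- unpack network -------------------------------------------------
  NumericVector C = net["C"], gL = net["gL"], EL = net["EL"];
  NumericVector gNa = net["gNa"], gK = net["gK"];
  NumericVector gCa = net["gCa"], gKCa = net["gKCa"];
  NumericVector ca_tau = net["ca_tau"], ca_f = net["ca_f"];
  IntegerVector comp_cell = net["cell"];
  IntegerVector soma_comp = net["soma_comp"];    // per cell
  NumericVector v0 = net["v0"];
  IntegerVector conn_i = net["conn_i"], conn_j = net["conn_j"];
  NumericVector conn_g = net["conn_g"];
  LogicalVector conn_rec = net["conn_rec"];      // record axial current?
  const double ca0 = as<double>(net["ca0"]);
  const double kca_kd = as<double>(net["kca_kd"]);

  const int ncomp = C.size();
  const int ncell = soma_comp.size();
  const int nconn = conn_i.size();

  // --- rate tables ----------------------------------------------------
  NumericMatrix tab = net["tables"];  // minf mtau hinf htau ninf ntau pinf ptau nmda qinf qtau
  const double vmin = as<double>(net["tab_vmin"]);
  const double inv_dv = 1.0 / as<double>(net["tab_dv"]);
  const int ntab = tab.nrow();
  const double* T_minf = &tab(0, 0);
  const double* T_mtau = &tab(0, 1);
  const double* T_hinf = &tab(0, 2);
  const double* T_htau = &tab(0, 3);
  const double* T_ninf = &tab(0, 4);
  const double* T_ntau = &tab(0, 5);
  const double* T_pinf = &tab(0, 6);
  const double* T_ptau = &tab(0, 7);
  const double* T_nmda = &tab(0, 8);
  const double* T_qinf = &tab(0, 9);
  const double* T_qtau = &tab(0, 10);

  // --- synaptic conductance states ------------------------------------
  IntegerVector st_comp = syn["comp"];
  NumericVector st_E = syn["E"];
  NumericVector st_taur = syn["tau_r"], st_taud = syn["tau_d"];
  LogicalVector st_nmda = syn["nmda"];
  const int nstate = st_comp.size();

  // --- control --------------------------------------------------------
  const double dt = as<double>(ctrl["dt"]);
  const int nstep = as<int>(ctrl["nstep"]);
  const int rec_every = as<int>(ctrl["rec_every"]);
  const double thresh = as<double>(ctrl["thresh"]);
  const double refract = as<double>(ctrl["refract"]);
  const bool record_v = as<bool>(ctrl["record_v"]);
  const bool record_state = as<bool>(ctrl["record_state"]);
  const double ENa = as<double>(ctrl["ENa"]);
  const double EK = as<double>(ctrl["EK"]);
  const double ECa = as<double>(ctrl["ECa"]);

  // per-state decay multipliers and event normalization
  std::vector<double> st_cr(nstate), st_cd(nstate), st_amp(nstate);
  for (int s = 0; s < nstate; ++s) {
    st_cr[s] = std::exp(-dt / st_taur[s]);
    st_cd[s] = std::exp(-dt / st_taud[s]);
    double tr = st_taur[s], td = st_taud[s];
    double tp = tr * td / (td - tr) * std::log(td / tr);
    double peak = std::exp(-tp / td) - std::exp(-tp / tr);
    st_amp[s] = 1.0 / peak;  // single unit-weight event peaks at 1 uS
  }

  // --- event heap (drive events + spike-triggered local events) -------
  std::priority_queue<SynEvent> heap;
  {
    NumericVector ev_t = drv["t"];
    IntegerVector ev_st = drv["state"];
    NumericVector ev_w = drv["w"];
    for (int k = 0; k < ev_t.size(); ++k)
      heap.push(SynEvent{ev_t[k], ev_st[k], ev_w[k] * st_amp[ev_st[k]]});
  }

  // local connectivity, CSR by source cell
  IntegerVector lc_src = lcl["src"], lc_st = lcl["state"];
  NumericVector lc_w = lcl["w"], lc_delay = lcl["delay"];
  const int nlc = lc_src.size();
  std::vector<int> lc_start(ncell + 1, 0);
  std::vector<int> lc_order(nlc);
  {
    for (int k = 0; k < nlc; ++k) lc_start[lc_src[k] + 1]++;
    for (int c = 0; c < ncell; ++c) lc_start[c + 1] += lc_start[c];
    std::vector<int> cur(lc_start.begin(), lc_start.end() - 1);
    for (int k = 0; k < nlc; ++k) lc_order[cur[lc_src[k]]++] = k;
  }

  // --- injections -----------------------------------------------------
  IntegerVector in_comp = inj["comp"], in_type = inj["type"];
  NumericVector in_amp = inj["amp"], in_E = inj["E"];
  NumericVector in_t0 = inj["t0"], in_t1 = inj["t1"];
  const int ninj = in_comp.size();

  // --- state ----------------------------------------------------------
  std::vector<double> V(v0.begin(), v0.end()), Vn(ncomp);
  std::vector<double> gm(ncomp), gh(ncomp), gn(ncomp), gp(ncomp), gq(ncomp), ca(ncomp);
  std::vector<double> ica_prev(ncomp, 0.0);
  for (int i = 0; i < ncomp; ++i) {
    double v = V[i];
    gm[i] = table_lookup(T_minf, v, vmin, inv_dv, ntab);
    gh[i] = table_lookup(T_hinf, v, vmin, inv_dv, ntab);
    gn[i] = table_lookup(T_ninf, v, vmin, inv_dv, ntab);
    gp[i] = table_lookup(T_pinf, v, vmin, inv_dv, ntab);
    gq[i] = table_lookup(T_qinf, v, vmin, inv_dv, ntab);
    ca[i] = ca0;
  }
  std::vector<double> A(nstate, 0.0), B(nstate, 0.0);
  std::vector<double> last_spike(ncell, -1e9);

  // scratch accumulators
  std::vector<double> Gsyn(ncomp), GEsyn(ncomp), Gax(ncomp), GEax(ncomp);
  std::vector<double> Ginj(ncomp), GEinj(ncomp), Iinj(ncomp);
  std::vector<double> Gion(ncomp), GEion(ncomp);

  // --- recording ------------------------------------------------------
  const int nrec = nstep / rec_every + 1;
  std::vector<int> rec_conn;
  for (int k = 0; k < nconn; ++k) if (conn_rec[k]) rec_conn.push_back(k);
  NumericMatrix rec_iax(rec_conn.size(), nrec);
  NumericMatrix rec_im(ncomp, nrec);
  NumericMatrix rec_V = record_v ? NumericMatrix(ncomp, nrec) : NumericMatrix(0, 0);
  std::vector<int> ca_comps;
  for (int i = 0; i < ncomp; ++i) if (ca_tau[i] > 0) ca_comps.push_back(i);
  NumericMatrix rec_ca(ca_comps.size(), nrec);
  NumericVector rec_t(nrec);
  std::vector<double> sp_cell, sp_time;

  NumericMatrix bk_icap, bk_iion, bk_isyn, bk_iax, bk_iinj;
  if (record_state) {
    bk_icap = NumericMatrix(ncomp, nstep);
    bk_iion = NumericMatrix(ncomp, nstep);
    bk_isyn = NumericMatrix(ncomp, nstep);
    bk_iax = NumericMatrix(ncomp, nstep);
    bk_iinj = NumericMatrix(ncomp, nstep);
  }

  int rec_idx = 0;
  auto record_frame = [&](double t) {
    rec_t[rec_idx] = t;
    for (size_t r = 0; r < rec_conn.size(); ++r) {
      int k = rec_conn[r];
      rec_iax(r, rec_idx) = conn_g[k] * (V[conn_i[k]] - V[conn_j[k]]);
    }
    // transmembrane (outward) = net axial in + injected current
    for (int i = 0; i < ncomp; ++i) rec_im(i, rec_idx) = 0.0;
    for (int k = 0; k < nconn; ++k) {
      double iaxk = conn_g[k] * (V[conn_i[k]] - V[conn_j[k]]);
      rec_im(conn_i[k], rec_idx) -= iaxk;
      rec_im(conn_j[k], rec_idx) += iaxk;
    }
    for (int k = 0; k < ninj; ++k) {
      if (t >= in_t0[k] && t < in_t1[k]) {
        if (in_type[k] == 0) rec_im(in_comp[k], rec_idx) += in_amp[k];
        else rec_im(in_comp[k], rec_idx) += in_amp[k] * (in_E[k] - V[in_comp[k]]);
      }
    }
    if (record_v) for (int i = 0; i < ncomp; ++i) rec_V(i, rec_idx) = V[i];
    for (size_t r = 0; r < ca_comps.size(); ++r) rec_ca(r, rec_idx) = ca[ca_comps[r]];
    ++rec_idx;
  };
  record_frame(0.0);

  // --- main loop ------------------------------------------------------
  for (int n = 0; n < nstep; ++n) {
    const double t = n * dt, tn = (n + 1) * dt;

    // 1. synaptic state decay + events arriving during this step
    for (int s = 0; s < nstate; ++s) { A[s] *= st_cr[s]; B[s] *= st_cd[s]; }
    while (!heap.empty() && heap.top().t <= tn) {
      const SynEvent ev = heap.top(); heap.pop();
      A[ev.state] += ev.amp;
      B[ev.state] += ev.amp;
    }

    // 2. accumulate synaptic conductances (NMDA block at current V)
    std::fill(Gsyn.begin(), Gsyn.end(), 0.0);
    std::fill(GEsyn.begin(), GEsyn.end(), 0.0);
    for (int s = 0; s < nstate; ++s) {
      double g = B[s] - A[s];
      if (g <= 0) continue;
      int c = st_comp[s];
      if (st_nmda[s]) g *= table_lookup(T_nmda, V[c], vmin, inv_dv, ntab);
      Gsyn[c] += g;
      GEsyn[c] += g * st_E[s];
    }

    // 3. gates (exponential Euler), ionic conductances, calcium pool
    for (int i = 0; i < ncomp; ++i) {
      double v = V[i];
      double gion = 0.0, geion = 0.0;
      if (gNa[i] > 0) {
        double minf = table_lookup(T_minf, v, vmin, inv_dv, ntab);
        double mtau = table_lookup(T_mtau, v, vmin, inv_dv, ntab);
        double hinf = table_lookup(T_hinf, v, vmin, inv_dv, ntab);
        double htau = table_lookup(T_htau, v, vmin, inv_dv, ntab);
        gm[i] += (minf - gm[i]) * (1.0 - std::exp(-dt / mtau));
        gh[i] += (hinf - gh[i]) * (1.0 - std::exp(-dt / htau));
        double g = gNa[i] * gm[i] * gm[i] * gm[i] * gh[i];
        gion += g; geion += g * ENa;
      }
      if (gK[i] > 0) {
        double ninf = table_lookup(T_ninf, v, vmin, inv_dv, ntab);
        double ntau = table_lookup(T_ntau, v, vmin, inv_dv, ntab);
        gn[i] += (ninf - gn[i]) * (1.0 - std::exp(-dt / ntau));
        double g = gK[i] * gn[i] * gn[i] * gn[i] * gn[i];
        gion += g; geion += g * EK;
      }
      if (gCa[i] > 0) {
        double pinf = table_lookup(T_pinf, v, vmin, inv_dv, ntab);
        double ptau = table_lookup(T_ptau, v, vmin, inv_dv, ntab);
        double qinf = table_lookup(T_qinf, v, vmin, inv_dv, ntab);
        double qtau = table_lookup(T_qtau, v, vmin, inv_dv, ntab);
        gp[i] += (pinf - gp[i]) * (1.0 - std::exp(-dt / ptau));
        gq[i] += (qinf - gq[i]) * (1.0 - std::exp(-dt / qtau));
        double g = gCa[i] * gp[i] * gp[i] * gq[i];
        gion += g; geion += g * ECa;
        ica_prev[i] = g * (v - ECa);  // inward negative
        double influx = ica_prev[i] < 0 ? -ica_prev[i] : 0.0;
        ca[i] += dt * (-(ca[i] - ca0) / ca_tau[i] + ca_f[i] * influx);
      }
      if (gKCa[i] > 0) {
        double c2 = ca[i] * ca[i];
        double g = gKCa[i] * c2 / (c2 + kca_kd * kca_kd);
        gion += g; geion += g * EK;
      }
      Gion[i] = gion; GEion[i] = geion;
    }

    // 4. axial coupling (explicit neighbour voltages)
    std::fill(Gax.begin(), Gax.end(), 0.0);
    std::fill(GEax.begin(), GEax.end(), 0.0);
    for (int k = 0; k < nconn; ++k) {
      int i = conn_i[k], j = conn_j[k];
      double g = conn_g[k];
      Gax[i] += g; GEax[i] += g * V[j];
      Gax[j] += g; GEax[j] += g * V[i];
    }

    // 5. injections
    std::fill(Ginj.begin(), Ginj.end(), 0.0);
    std::fill(GEinj.begin(), GEinj.end(), 0.0);
    std::fill(Iinj.begin(), Iinj.end(), 0.0);
    for (int k = 0; k < ninj; ++k) {
      if (t >= in_t0[k] && t < in_t1[k]) {
        if (in_type[k] == 0) Iinj[in_comp[k]] += in_amp[k];
        else { Ginj[in_comp[k]] += in_amp[k]; GEinj[in_comp[k]] += in_amp[k] * in_E[k]; }
      }
    }

    // 6. semi-implicit voltage update
    bool blown = false;
    for (int i = 0; i < ncomp; ++i) {
      double cd = C[i] / dt;
      double num = cd * V[i] + gL[i] * EL[i] + GEion[i] + GEsyn[i] + GEax[i] +
                   GEinj[i] + Iinj[i];
      double den = cd + gL[i] + Gion[i] + Gsyn[i] + Gax[i] + Ginj[i];
      Vn[i] = num / den;
      if (!std::isfinite(Vn[i]) || std::fabs(Vn[i]) > 200.0) blown = true;
    }
    if (blown)
      stop("numerical blow-up: |V| exceeded 200 mV at t = %f ms", tn);

    if (record_state) {
      for (int i = 0; i < ncomp; ++i) {
        bk_icap(i, n) = C[i] * (Vn[i] - V[i]) / dt;
        bk_iion(i, n) = gL[i] * (Vn[i] - EL[i]) + Gion[i] * Vn[i] - GEion[i];
        bk_isyn(i, n) = Gsyn[i] * Vn[i] - GEsyn[i];
        bk_iax(i, n) = GEax[i] - Gax[i] * Vn[i];
        bk_iinj(i, n) = GEinj[i] - Ginj[i] * Vn[i] + Iinj[i];
      }
    }

    // 7. spike detection at somata, schedule local synaptic events
    for (int c = 0; c < ncell; ++c) {
      int sc = soma_comp[c];
      if (V[sc] < thresh && Vn[sc] >= thresh && tn - last_spike[c] > refract) {
        last_spike[c] = tn;
        sp_cell.push_back(c + 1);  // 1-based for R
        sp_time.push_back(tn);
        for (int q = lc_start[c]; q < lc_start[c + 1]; ++q) {
          int k = lc_order[q];
          heap.push(SynEvent{tn + lc_delay[k], lc_st[k], lc_w[k] * st_amp[lc_st[k]]});
        }
      }
    }

    std::swap(V, Vn);
    if ((n + 1) % rec_every == 0) record_frame(tn);
  }

  List out = List::create(
      _["spike_cell"] = NumericVector(sp_cell.begin(), sp_cell.end()),
      _["spike_time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["rec_t"] = rec_t, _["i_axial"] = rec_iax, _["i_membrane"] = rec_im,
      _["ca"] = rec_ca,
      _["ca_comp"] = IntegerVector(ca_comps.begin(), ca_comps.end()),
      _["conn_recorded"] = IntegerVector(rec_conn.begin(), rec_conn.end()));
  if (record_v) out["v"] = rec_V;
  if (record_state)
    out["bookkeeping"] = List::create(
        _["i_cap"] = bk_icap, _["i_ion"] = bk_iion, _["i_syn"] = bk_isyn,
        _["i_axial_in"] = bk_iax, _["i_inj"] = bk_iinj);
  return out;
}
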