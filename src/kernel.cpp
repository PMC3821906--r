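#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time simulation kernel for the seven-compartment tumor model.
//
// State layout: np, nq (sensitive cycling/quiescent), nrp, nrq (resistant
// cycling/quiescent), nd1..nd3 (three dying stages).  One call steps the
// state from step index 0 (day t0) to index n_steps (day t0 + n_steps*dt),
// applying treatment fractions instantaneously at their step indices and
// recording the total cell count immediately BEFORE any fraction delivered
// at a sampling index (observations are pre-fraction CT scans).
//
// Growth update (per step, effective step length dtp):
//   np'  = np + theta*2*u*np*dtp - u*np*dtp + g*nq*dtp
//   nq'  = nq + (1-theta)*2*u*np*dtp - (g + mu_q)*nq*dtp
// with g the quiescent re-entry rate for that day (gamma, or gamma_rec
// inside the recruitment window).  Resistant compartments follow the same
// equations.  Dying stages advance with per-day rate D; stage-III exits are
// definitively lost.  Fractions kill a fraction kp of cycling and kq of
// quiescent sensitive cells (resistant cells are never hit); killed cells
// enter nd1; a fraction rind of the survivors becomes resistant.
//
// When the quiescent outflow (g + mu_q)*dtp would exceed the pool within a
// single step (possible under extreme recruitment rates), both outflows are
// rescaled so the compartment is exactly emptied; this keeps the bookkeeping
// conservative and the state nonnegative.
// [[Rcpp::export(name = ".sim_kernel")]]
List sim_kernel(NumericVector state0,
                double t0, double dt, int n_steps,
                IntegerVector sample_idx,
                IntegerVector fx_idx,
                double theta, double u, double mu_q,
                double gamma_base, double gamma_rec,
                double rec_start, double rec_end,
                double dtp, double D,
                double kp, double kq, double rind,
                bool keep_daily) {
  if (state0.size() != 7) stop("state0 must have 7 compartments");
  double np = state0[0], nq = state0[1];
  double nrp = state0[2], nrq = state0[3];
  double nd1 = state0[4], nd2 = state0[5], nd3 = state0[6];

  const int nsamp = sample_idx.size();
  const int nfx = fx_idx.size();
  NumericVector out(nsamp);
  double killed = 0.0, lost = 0.0;
  int si = 0, fi = 0;
  bool ok = true;

  NumericMatrix daily(keep_daily ? (n_steps + 1) : 0, 7);

  for (int k = 0; k <= n_steps; ++k) {
    if (keep_daily) {
      daily(k, 0) = np; daily(k, 1) = nq; daily(k, 2) = nrp;
      daily(k, 3) = nrq; daily(k, 4) = nd1; daily(k, 5) = nd2;
      daily(k, 6) = nd3;
    }
    while (si < nsamp && sample_idx[si] == k) {
      out[si] = np + nq + nrp + nrq + nd1 + nd2 + nd3;
      ++si;
    }
    if (fi < nfx && fx_idx[fi] == k) {
      double knp = kp * np, knq = kq * nq;
      np -= knp; nq -= knq;
      if (rind > 0.0) {
        nrp += np * rind; nrq += nq * rind;
        np *= (1.0 - rind); nq *= (1.0 - rind);
      }
      nd1 += knp + knq;
      killed += knp + knq;
      ++fi;
    }
    if (k == n_steps) break;

    double day = t0 + k * dt;
    double g = (day >= rec_start - 1e-9 && day <= rec_end + 1e-9)
                 ? gamma_rec : gamma_base;

    double rec_s = g * nq * dtp, die_s = mu_q * nq * dtp;
    double outq = (g + mu_q) * dtp;
    if (outq > 1.0) { rec_s = nq * g / (g + mu_q); die_s = nq * mu_q / (g + mu_q); }
    double rec_r = g * nrq * dtp, die_r = mu_q * nrq * dtp;
    if (outq > 1.0) { rec_r = nrq * g / (g + mu_q); die_r = nrq * mu_q / (g + mu_q); }

    double growp = (2.0 * theta - 1.0) * u * dtp;
    double np1 = np + growp * np + rec_s;
    double nq1 = nq + (1.0 - theta) * 2.0 * u * np * dtp - rec_s - die_s;
    double nrp1 = nrp + growp * nrp + rec_r;
    double nrq1 = nrq + (1.0 - theta) * 2.0 * u * nrp * dtp - rec_r - die_r;

    double nd1n = (1.0 - D) * nd1;
    double nd2n = (1.0 - D) * nd2 + D * nd1;
    double nd3n = (1.0 - D) * nd3 + D * nd2;
    lost += D * nd3;

    np = np1; nq = nq1; nrp = nrp1; nrq = nrq1;
    nd1 = nd1n; nd2 = nd2n; nd3 = nd3n;

    if (np < 0 || nq < 0 || nrp < 0 || nrq < 0) {
      if (np > -1e-9) np = std::max(np, 0.0); else ok = false;
      if (nq > -1e-9) nq = std::max(nq, 0.0); else ok = false;
      if (nrp > -1e-9) nrp = std::max(nrp, 0.0); else ok = false;
      if (nrq > -1e-9) nrq = std::max(nrq, 0.0); else ok = false;
      if (!ok) break;
    }
  }

  NumericVector final_state = NumericVector::create(np, nq, nrp, nrq, nd1, nd2, nd3);
  return List::create(_["volumes"] = out,
                      _["state"] = final_state,
                      _["killed"] = killed,
                      _["lost"] = lost,
                      _["ok"] = ok,
                      _["daily"] = daily);
}
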