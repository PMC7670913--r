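#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the voltage-based plasticity rule.
//
// Per step of size dt, in this fixed order:
//   1. x_bar decays by (1 - dt/tau_x) and gains the step's spike count;
//   2. u_bar_plus / u_bar_minus relax toward the step's voltage sample;
//   3. LTP/LTD rates are evaluated with the just-updated traces (the veto
//      threshold theta_var from the previous step);
//   4. w_ltp / w_ltd accumulate;
//   5. theta_var decays by (1 - dt/tau_theta) and gains
//      b_theta * (dt/tau_theta) * r_plus.
// The arithmetic mirrors plasticity_step() in R exactly (bit-identical).

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericVector u, NumericVector spikes, double dt,
                  NumericVector par, double w_init, bool clip_zero,
                  bool trajectory) {
  const int n = u.size();
  const double tau_x = par[0], tau_plus = par[1], tau_minus = par[2],
               theta_plus = par[3], theta_0 = par[4],
               A_LTP = par[5], A_LTD = par[6],
               b_theta = par[7], tau_theta = par[8];
  const double ax = 1.0 - dt / tau_x;
  const double kp = dt / tau_plus, km = dt / tau_minus, kt = dt / tau_theta;
  if (ax <= 0.0 || kp >= 1.0 || km >= 1.0 || kt >= 1.0)
    stop("dt must be smaller than every time constant (explicit Euler)");

  double x = 0.0, up = 0.0, um = 0.0, th = 0.0, wltp = 0.0, wltd = 0.0;

  NumericVector tx, tup, tum, tth, twp, twd;
  if (trajectory) {
    tx = NumericVector(n); tup = NumericVector(n); tum = NumericVector(n);
    tth = NumericVector(n); twp = NumericVector(n); twd = NumericVector(n);
  }

  for (int i = 0; i < n; ++i) {
    x = x * ax + spikes[i];
    const double ui = u[i];
    up = up * (1.0 - kp) + kp * ui;
    um = um * (1.0 - km) + km * ui;
    const double gp = up - theta_plus;
    const double gm = um - (theta_0 + th);
    const double rp = A_LTP * x * (gp > 0.0 ? gp : 0.0);
    const double rm = A_LTD * x * (gm > 0.0 ? gm : 0.0);
    wltp += rp * dt;
    wltd += rm * dt;
    th = th * (1.0 - kt) + b_theta * kt * rp;
    if (trajectory) {
      tx[i] = x; tup[i] = up; tum[i] = um; tth[i] = th;
      twp[i] = wltp; twd[i] = wltd;
    }
  }

  double w_final = w_init + wltp - wltd;
  if (clip_zero && w_final < 0.0) w_final = 0.0;

  List out = List::create(_["w_ltp"] = wltp, _["w_ltd"] = wltd,
                          _["w_final"] = w_final);
  if (trajectory)
    out["traj"] = List::create(_["x_bar"] = tx, _["u_bar_plus"] = tup,
                               _["u_bar_minus"] = tum, _["theta_var"] = tth,
                               _["w_ltp"] = twp, _["w_ltd"] = twd);
  return out;
}
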