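#include <Rcpp.h>
using namespace Rcpp;

// Within-trial race of the STN-GPe-thalamus circuit.
//
// Per iteration (explicit Euler, the 1/tau constants acting as step
// coefficients):
//   x_stn <- x_stn + inv_tau_s * (-x_stn + W_stn %*% y_stn - x_gpe)
//   y_stn <- tanh(lambda_stn * x_stn)
//   x_gpe <- x_gpe + inv_tau_g * (-x_gpe + W_gpe %*% x_gpe + y_stn - x_ip)
//   x_thal_i = x_dp_i - w_stn_gpi * y_stn_i        (sign-inverted GPi)
//   y_thal <- y_thal + dt_thal * (-leak * y_thal + x_thal)
// with W_stn = eps_s everywhere + identity, W_gpe = eps_g everywhere
// (eps_g = -eps_s).  Stops at the first threshold crossing of y_thal; ties
// broken by maximum y_thal then lowest index.
// [[Rcpp::export(name = ".race_cpp")]]
List race_cpp(NumericVector x_dp, NumericVector x_ip,
              NumericVector x_stn0, NumericVector x_gpe0,
              double eps_s, double inv_tau_s, double inv_tau_g,
              double lambda_stn, double w_stn_gpi,
              double threshold, double dt_thal, double leak, int max_iters,
              bool record = false) {
  const int n = x_dp.size();
  if (x_ip.size() != n || x_stn0.size() != n || x_gpe0.size() != n)
    stop("dimension mismatch between pathway drives and circuit state");
  if (max_iters <= 0) stop("max_iters must be positive");

  std::vector<double> x_stn(x_stn0.begin(), x_stn0.end());
  std::vector<double> x_gpe(x_gpe0.begin(), x_gpe0.end());
  std::vector<double> y_stn(n), y_thal(n, 0.0), x_thal(n);
  for (int i = 0; i < n; ++i) y_stn[i] = std::tanh(lambda_stn * x_stn[i]);

  NumericMatrix traj;
  if (record) traj = NumericMatrix(max_iters, n);

  int action = -1, rt = max_iters;
  bool crossed = false;
  const double eps_g = -eps_s;

  for (int it = 1; it <= max_iters; ++it) {
    double sum_y = 0.0, sum_gpe = 0.0;
    for (int i = 0; i < n; ++i) { sum_y += y_stn[i]; sum_gpe += x_gpe[i]; }
    // STN: lateral weight eps_s everywhere plus a unit self-connection
    for (int i = 0; i < n; ++i) {
      double drive = eps_s * sum_y + y_stn[i];  // (W_stn %*% y_stn)_i
      x_stn[i] += inv_tau_s * (-x_stn[i] + drive - x_gpe[i]);
    }
    for (int i = 0; i < n; ++i) y_stn[i] = std::tanh(lambda_stn * x_stn[i]);
    // GPe: uniform lateral inhibition eps_g, one-to-one STN input,
    // striatal indirect-pathway input is inhibitory
    for (int i = 0; i < n; ++i)
      x_gpe[i] += inv_tau_g * (-x_gpe[i] + eps_g * sum_gpe + y_stn[i] - x_ip[i]);
    // thalamus integrates the sign-inverted GPi signal
    for (int i = 0; i < n; ++i) {
      x_thal[i] = x_dp[i] - w_stn_gpi * y_stn[i];
      y_thal[i] += dt_thal * (-leak * y_thal[i] + x_thal[i]);
      if (record) traj(it - 1, i) = y_thal[i];
    }
    int best = -1;
    double best_y = R_NegInf;
    for (int i = 0; i < n; ++i)
      if (y_thal[i] >= threshold && y_thal[i] > best_y) {
        best = i; best_y = y_thal[i];
      }
    if (best >= 0) { action = best; rt = it; crossed = true; break; }
  }
  if (!crossed) {
    double best_y = R_NegInf;
    for (int i = 0; i < n; ++i)
      if (y_thal[i] > best_y) { best_y = y_thal[i]; action = i; }
  }

  List out = List::create(
    _["action"] = action + 1, _["rt_iters"] = rt, _["crossed"] = crossed,
    _["y_thal"] = NumericVector(y_thal.begin(), y_thal.end()),
    _["x_stn"] = NumericVector(x_stn.begin(), x_stn.end()),
    _["x_gpe"] = NumericVector(x_gpe.begin(), x_gpe.end()));
  if (record) {
    if (rt < max_iters) traj = traj(Range(0, rt - 1), _);
    out["trajectories"] = traj;
  }
  return out;
}
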