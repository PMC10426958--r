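#include <Rcpp.h>
using namespace Rcpp;

// Jansen-Rit sigmoid: voltage -> firing rate (ms^-1)
static inline double sigm(double v, double vmax, double r, double v0) {
  return 2.0 * vmax / (1.0 + std::exp(r * (v0 - v)));
}

// Right-hand side of the six JR state equations for one node.
// input is the total perturbation entering the excitatory-interneuron PSP
// equation (mean drive + noise + delayed network input), in ms^-1.
static inline void jr_rhs(const double* y, double input, double A, double B,
                          double a, double b, double C1, double C2, double C3,
                          double C4, double vmax, double r, double v0,
                          double* dy) {
  double S_py = sigm(y[1] - y[2], vmax, r, v0);
  double S_e  = sigm(C1 * y[0], vmax, r, v0);
  double S_i  = sigm(C3 * y[0], vmax, r, v0);
  dy[0] = y[3];
  dy[1] = y[4];
  dy[2] = y[5];
  dy[3] = A * a * S_py - 2.0 * a * y[3] - a * a * y[0];
  dy[4] = A * a * (input + C2 * S_e) - 2.0 * a * y[4] - a * a * y[1];
  dy[5] = B * b * C4 * S_i - 2.0 * b * y[5] - b * b * y[2];
}

// Delayed stochastic Heun integration of a Jansen-Rit network.
//
// weights:     n x n coupling matrix (already max-normalised in R), w[j,i]
//              scales the firing rate arriving at i from j.
// delay_steps: n x n integer matrix of conduction delays in integration steps.
// p, eta:      per-node drive mean and noise std (ms^-1).
// Noise is drawn once per step per node from N(0, eta^2) via the R RNG and
// held constant across both Heun stages, as is the delayed coupling term.
// Returns the pyramidal membrane potential y1 - y2 at every step (including
// t = 0) plus the final full state.
// [[Rcpp::export]]
List jr_simulate_cpp(NumericMatrix weights, IntegerMatrix delay_steps,
                     NumericVector p, NumericVector eta, double g,
                     double A, double B, double a, double b,
                     double C1, double C2, double C3, double C4,
                     double vmax, double r, double v0,
                     double dt, int n_steps,
                     NumericMatrix init_state) {
  const int n = weights.nrow();
  if (weights.ncol() != n || delay_steps.nrow() != n || delay_steps.ncol() != n)
    stop("weights and delay_steps must be square matrices of the same size");
  if (p.size() != n || eta.size() != n)
    stop("p and eta must have one entry per node");
  if (init_state.nrow() != 6 || init_state.ncol() != n)
    stop("init_state must be 6 x n");

  int max_delay = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
  const int L = max_delay + 1;

  // state: 6 variables per node
  std::vector<double> y(6 * n), dy1(6), dy2(6), yp(6);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k)
      y[6 * i + k] = init_state(k, i);

  // circular history of the firing rate S[y1 - y2] (computed once per node
  // and step at write time), pre-filled from the initial output so early
  // delayed reads fall back on the initial history
  std::vector<double> hist(static_cast<size_t>(n) * L);
  for (int i = 0; i < n; ++i) {
    double s0 = sigm(y[6 * i + 1] - y[6 * i + 2], vmax, r, v0);
    for (int s = 0; s < L; ++s) hist[static_cast<size_t>(s) * n + i] = s0;
  }

  NumericMatrix signals(n, n_steps + 1);
  for (int i = 0; i < n; ++i) signals(i, 0) = y[6 * i + 1] - y[6 * i + 2];

  std::vector<double> input(n), coup(n);
  RNGScope rngScope;

  for (int t = 0; t < n_steps; ++t) {
    // write current firing rate S[v(t)] into the history ring
    const int slot = t % L;
    for (int i = 0; i < n; ++i)
      hist[static_cast<size_t>(slot) * n + i] =
        sigm(y[6 * i + 1] - y[6 * i + 2], vmax, r, v0);

    // network input: p_i + noise + g * sum_j w_ji S[v_j(t - d_ji)]
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) {
        double w = weights(j, i);
        if (w == 0.0) continue;
        int s = t - delay_steps(j, i);
        int rs = ((s % L) + L) % L;  // pre-filled slots serve t < d
        acc += w * hist[static_cast<size_t>(rs) * n + j];
      }
      coup[i] = g * acc;
    }
    for (int i = 0; i < n; ++i) {
      double xi = (eta[i] > 0.0) ? eta[i] * norm_rand() : 0.0;
      input[i] = p[i] + xi + coup[i];
    }

    // Heun predictor-corrector; input held constant across both stages
    for (int i = 0; i < n; ++i) {
      double* yi = &y[6 * i];
      jr_rhs(yi, input[i], A, B, a, b, C1, C2, C3, C4, vmax, r, v0, dy1.data());
      for (int k = 0; k < 6; ++k) yp[k] = yi[k] + dt * dy1[k];
      jr_rhs(yp.data(), input[i], A, B, a, b, C1, C2, C3, C4, vmax, r, v0,
             dy2.data());
      for (int k = 0; k < 6; ++k) yi[k] += 0.5 * dt * (dy1[k] + dy2[k]);
      signals(i, t + 1) = yi[1] - yi[2];
    }

    if ((t & 0x3FF) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(y[6 * i])) stop("simulation diverged at step %d", t);
      Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k)
      if (!std::isfinite(y[6 * i + k]))
        stop("simulation diverged (non-finite final state)");

  NumericMatrix final_state(6, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k) final_state(k, i) = y[6 * i + k];

  return List::create(_["signals"] = signals, _["final_state"] = final_state);
}
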