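#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop mountain-car episode under the 60-5-3 LIF policy network.
// Replicates, step for step, the composition of bin_index(),
// simulate_network() and winner_take_all() with mc_step() in R, but
// without per-interval R round trips; the two paths are asserted equal
// in the test suite. Fully deterministic given the start state (the
// policy network has no noise sources).

// [[Rcpp::export]]
List mc_episode_cpp(NumericVector w, double pos0, double vel0, int max_steps,
                    double interval_ms, double dt, double input_dc,
                    double tau_m, double v_rest, double v_reset, double v_thr,
                    double t_ref, double r_m, double vmin, double vmax) {
  if (w.size() != 315) stop("expected 315 weights");
  const int n = 68;
  const int n_sub = (int)std::lround(interval_ms / dt);
  const int ref_steps = (int)std::lround(t_ref / dt);
  const double leak = dt / tau_m;

  std::vector<double> v(n, v_rest);
  std::vector<int> ref_left(n, 0);
  std::vector<double> buf(2 * n, 0.0);  // delay-1 ring buffer
  int buf_pos = 0;

  double pos = pos0, vel = vel0;
  NumericVector positions(max_steps);
  IntegerVector actions(max_steps);
  int steps_done = 0, steps_to_goal = NA_INTEGER;

  for (int stp = 0; stp < max_steps; ++stp) {
    int p_bin = (int)std::floor((pos + 1.2) / (1.8 / 30.0));
    if (p_bin < 0) p_bin = 0; if (p_bin > 29) p_bin = 29;
    int v_bin = (int)std::floor((vel - vmin) / ((vmax - vmin) / 30.0));
    if (v_bin < 0) v_bin = 0; if (v_bin > 29) v_bin = 29;
    const int a1 = p_bin, a2 = 30 + v_bin;

    int out_counts[3] = {0, 0, 0};
    for (int s = 0; s < n_sub; ++s) {
      double *row = &buf[buf_pos * n];
      for (int i = 0; i < n; ++i) {
        if (ref_left[i] > 0) {
          --ref_left[i];
          v[i] = v_reset;
          row[i] = 0.0;
          continue;
        }
        double vi = v[i] + row[i];
        row[i] = 0.0;
        double drive = (i == a1 || i == a2) ? input_dc : 0.0;
        vi += leak * ((v_rest - vi) + r_m * drive);
        if (vi >= v_thr) {
          vi = v_reset;
          ref_left[i] = ref_steps;
          double *nxt = &buf[(1 - buf_pos) * n];
          if (i < 60) {
            for (int h = 0; h < 5; ++h) nxt[60 + h] += w[i * 5 + h];
          } else if (i < 65) {
            for (int o = 0; o < 3; ++o) nxt[65 + o] += w[300 + (i - 60) * 3 + o];
          } else {
            out_counts[i - 65]++;
          }
        }
        v[i] = vi;
      }
      buf_pos = 1 - buf_pos;
    }

    int action = 1;  // do nothing when no output spiked
    if (out_counts[0] + out_counts[1] + out_counts[2] > 0) {
      action = 0;
      if (out_counts[1] > out_counts[action]) action = 1;
      if (out_counts[2] > out_counts[action]) action = 2;
    }
    // association matches the reference R implementation bit for bit
    vel = (vel + 0.001 * (action - 1)) - 0.0025 * std::cos(3.0 * pos);
    if (vel < -0.07) vel = -0.07;
    if (vel > 0.07) vel = 0.07;
    pos += vel;
    if (pos < -1.2) pos = -1.2;
    if (pos > 0.6) pos = 0.6;
    if (pos <= -1.2 && vel < 0) vel = 0.0;
    positions[stp] = pos;
    actions[stp] = action;
    steps_done = stp + 1;
    if (pos >= 0.5) { steps_to_goal = steps_done; break; }
  }
  return List::create(
      _["positions"] = positions[Range(0, steps_done - 1)],
      _["actions"] = actions[Range(0, steps_done - 1)],
      _["steps_to_goal"] = steps_to_goal);
}
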