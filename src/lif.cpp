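#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-Euler leaky integrate-and-fire network with delta-current
// synapses, integer-step delay queues, piecewise-constant external drive,
// optional Poisson background impulses, and rate-coded Poisson source
// neurons. Membrane state can be carried across calls (closed-loop use),
// so a simulation may be advanced in chunks without losing pending
// delayed currents.
//
// Units: time ms, potentials mV, drive amplitude in current units scaled
// by the membrane resistance r_m (for source neurons the drive amplitude
// is a firing rate in Hz). Delays are integer steps >= 1.

// [[Rcpp::export]]
List lif_run_cpp(int n, double tau_m, double v_rest, double v_reset,
                 double v_thr, double t_ref, double r_m,
                 LogicalVector is_source,
                 IntegerVector syn_pre, IntegerVector syn_post,
                 NumericVector syn_w, IntegerVector syn_d,
                 IntegerVector drv_neuron, NumericVector drv_start,
                 NumericVector drv_end, NumericVector drv_amp,
                 double duration, double dt,
                 double bg_rate, double bg_weight,
                 Nullable<List> state_in, bool record_times) {
  if (dt <= 0 || duration <= 0)
    stop("duration and dt must be positive");
  const int n_steps = (int)std::lround(duration / dt);
  const int n_syn = syn_pre.size();
  const int ref_steps = (int)std::lround(t_ref / dt);

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s) {
    if (syn_d[s] < 1) stop("synaptic delays must be >= 1 step");
    if (syn_d[s] > max_delay) max_delay = syn_d[s];
  }
  const int n_rows = max_delay + 1;

  // CSR adjacency over presynaptic index (1-based input)
  std::vector<int> offset(n + 1, 0);
  for (int s = 0; s < n_syn; ++s) offset[syn_pre[s]]++;
  for (int i = 0; i < n; ++i) offset[i + 1] += offset[i];
  std::vector<int> adj(n_syn);
  {
    std::vector<int> cursor(n, 0);
    for (int i = n - 1; i >= 0; --i) cursor[i] = offset[i];
    for (int s = 0; s < n_syn; ++s) adj[cursor[syn_pre[s] - 1]++] = s;
  }

  // membrane state, possibly carried over
  std::vector<double> v(n, v_rest);
  std::vector<int> ref_left(n, 0);
  std::vector<double> buffer((size_t)n_rows * n, 0.0);
  int buf_pos = 0;
  if (state_in.isNotNull()) {
    List st(state_in);
    NumericVector sv = st["v"];
    IntegerVector sr = st["ref_left"];
    NumericMatrix sb = st["buffer"];
    if (sv.size() != n || sb.ncol() != n || sb.nrow() != n_rows)
      stop("carried state does not match this network");
    for (int i = 0; i < n; ++i) { v[i] = sv[i]; ref_left[i] = sr[i]; }
    for (int r = 0; r < n_rows; ++r)
      for (int i = 0; i < n; ++i)
        buffer[(size_t)r * n + i] = sb(r, i);
    buf_pos = as<int>(st["buf_pos"]);
  }

  // piecewise-constant drive as sorted step events
  const int n_drv = drv_neuron.size();
  std::vector<double> drive(n, 0.0);
  struct Ev { int step; int neuron; double delta; };
  std::vector<Ev> events;
  events.reserve(2 * n_drv);
  for (int k = 0; k < n_drv; ++k) {
    int s0 = (int)std::lround(drv_start[k] / dt);
    int s1 = (int)std::lround(drv_end[k] / dt);
    if (s0 < 0) s0 = 0;
    if (s1 > n_steps) s1 = n_steps;
    if (s1 <= s0) continue;
    events.push_back({s0, drv_neuron[k] - 1, drv_amp[k]});
    events.push_back({s1, drv_neuron[k] - 1, -drv_amp[k]});
  }
  std::sort(events.begin(), events.end(),
            [](const Ev &a, const Ev &b) { return a.step < b.step; });
  size_t ev_i = 0;

  std::vector<int> counts(n, 0);
  std::vector<std::vector<double>> times;
  if (record_times) times.resize(n);

  const double p_bg = bg_rate * dt / 1000.0;
  const double leak = dt / tau_m;

  // Bernoulli(p) per neuron-step is realized by geometric gap sampling
  // over the flattened (step, neuron) slot sequence, so the RNG is only
  // touched once per actual impulse instead of once per slot.
  const double log_q_bg = (p_bg > 0 && p_bg < 1) ? std::log1p(-p_bg) : 0.0;
  long long bg_slot = -1;
  std::vector<char> bg_hit(n, 0);
  if (p_bg > 0) {
    bg_slot += (p_bg >= 1) ? 1
             : 1 + (long long)std::floor(std::log(unif_rand()) / log_q_bg);
  }
  // per-source-neuron geometric countdown (in steps) to the next spike;
  // re-drawn whenever the neuron's rate changes
  std::vector<long long> src_next(n, -1);
  auto draw_src = [&](int i, int from_step) {
    double p = drive[i] * dt / 1000.0;
    if (p <= 0) { src_next[i] = -1; return; }
    if (p >= 1) { src_next[i] = from_step; return; }
    src_next[i] = from_step +
        (long long)std::floor(std::log(unif_rand()) / std::log1p(-p));
  };

  for (int stp = 0; stp < n_steps; ++stp) {
    bool drive_changed = false;
    while (ev_i < events.size() && events[ev_i].step == stp) {
      drive[events[ev_i].neuron] += events[ev_i].delta;
      if (is_source[events[ev_i].neuron]) draw_src(events[ev_i].neuron, stp);
      ++ev_i;
    }
    (void)drive_changed;
    if (p_bg > 0) {
      const long long lo = (long long)stp * n, hi = lo + n;
      while (bg_slot >= lo && bg_slot < hi) {
        bg_hit[(int)(bg_slot - lo)] = 1;
        bg_slot += (p_bg >= 1) ? 1
                 : 1 + (long long)std::floor(std::log(unif_rand()) / log_q_bg);
      }
    }
    double *row = &buffer[(size_t)buf_pos * n];
    const double t_now = (stp + 1) * dt;
    for (int i = 0; i < n; ++i) {
      bool spiked = false;
      if (is_source[i]) {
        if (src_next[i] == stp) {
          spiked = true;
          draw_src(i, stp + 1);
        } else if (src_next[i] >= 0 && src_next[i] < stp) {
          draw_src(i, stp + 1);
        }
        bg_hit[i] = 0;
        row[i] = 0.0;
      } else if (ref_left[i] > 0) {
        --ref_left[i];
        v[i] = v_reset;
        bg_hit[i] = 0;
        row[i] = 0.0;
      } else {
        double vi = v[i] + row[i];
        row[i] = 0.0;
        if (bg_hit[i]) { vi += bg_weight; bg_hit[i] = 0; }
        vi += leak * ((v_rest - vi) + r_m * drive[i]);
        if (!R_finite(vi))
          stop("membrane potential diverged (neuron %d at t = %.3f ms)",
               i + 1, t_now);
        if (vi >= v_thr) {
          spiked = true;
          vi = v_reset;
          ref_left[i] = ref_steps;
        }
        v[i] = vi;
      }
      if (spiked) {
        counts[i]++;
        if (record_times) times[i].push_back(t_now);
        for (int a = offset[i]; a < offset[i + 1]; ++a) {
          int s = adj[a];
          int r = (buf_pos + syn_d[s]) % n_rows;
          buffer[(size_t)r * n + syn_post[s] - 1] += syn_w[s];
        }
      }
    }
    buf_pos = (buf_pos + 1) % n_rows;
  }

  NumericMatrix sb(n_rows, n);
  for (int r = 0; r < n_rows; ++r)
    for (int i = 0; i < n; ++i)
      sb(r, i) = buffer[(size_t)r * n + i];
  List state_out = List::create(
      _["v"] = NumericVector(v.begin(), v.end()),
      _["ref_left"] = IntegerVector(ref_left.begin(), ref_left.end()),
      _["buffer"] = sb, _["buf_pos"] = buf_pos);

  List out = List::create(
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["state"] = state_out);
  if (record_times) {
    List tl(n);
    for (int i = 0; i < n; ++i)
      tl[i] = NumericVector(times[i].begin(), times[i].end());
    out["times"] = tl;
  }
  return out;
}
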