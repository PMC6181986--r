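// Compiled simulation core for the recurrent two-compartment network.
//
// The dynamics here mirror the pure-R reference stepper (step_network)
// operation for operation; the R test suite checks the two paths against
// each other on small networks.  The core additionally generates the
// exogenous inputs (EC currents, external noise, distractor/burst sources)
// and the per-weight spontaneous fluctuations internally, from a
// self-contained random stream (xoshiro256++ with a ziggurat normal
// sampler) so that long simulations are cheap and reproducible from a
// single integer seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Random stream: splitmix64 seeding -> xoshiro256++, ziggurat normals
// (Doornik-style layering, 128 layers).
// ---------------------------------------------------------------------------

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

const int    kZigC = 128;
const double kZigR = 3.442619855899;
const double kZigV = 9.91256303526217e-3;
static double zig_x[kZigC + 1];
static double zig_ratio[kZigC];
static bool   zig_ready = false;

static void zig_init() {
  double f = std::exp(-0.5 * kZigR * kZigR);
  zig_x[0] = kZigV / f;  // virtual base-layer width
  zig_x[1] = kZigR;
  zig_x[kZigC] = 0.0;
  for (int i = 2; i < kZigC; ++i) {
    zig_x[i] = std::sqrt(-2.0 * std::log(kZigV / zig_x[i - 1] + f));
    f = std::exp(-0.5 * zig_x[i] * zig_x[i]);
  }
  for (int i = 0; i < kZigC; ++i) zig_ratio[i] = zig_x[i + 1] / zig_x[i];
  zig_ready = true;
}

struct NormalRng {
  Xoshiro rng;
  explicit NormalRng(uint64_t seed) : rng(seed) {
    if (!zig_ready) zig_init();
  }
  double tail(bool negative) {
    double x, y;
    do {
      x = std::log(rng.unif()) / kZigR;
      y = std::log(rng.unif());
    } while (-2.0 * y < x * x);
    return negative ? x - kZigR : kZigR - x;
  }
  inline double norm() {
    for (;;) {
      double u = 2.0 * rng.unif() - 1.0;
      int i = static_cast<int>(rng.next() & 0x7F);
      if (std::fabs(u) < zig_ratio[i]) return u * zig_x[i];
      if (i == 0) return tail(u < 0);
      double x = u * zig_x[i];
      double f0 = std::exp(-0.5 * (zig_x[i] * zig_x[i] - x * x));
      double f1 = std::exp(-0.5 * (zig_x[i + 1] * zig_x[i + 1] - x * x));
      if (f1 + rng.unif() * (f0 - f1) < 1.0) return x;
    }
  }
};

inline double sigmoidf(double I, double theta_f) {
  return 1.0 / (1.0 + std::exp(-(I - theta_f)));
}

}  // namespace

// Exposed for statistical testing of the normal sampler.
// [[Rcpp::export]]
NumericVector zig_rnorm_cpp(int n, double seed) {
  NormalRng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// Compiled mirror of the R single-cell simulator (simulate_cells); the R
// loop is the readable reference and the two are cross-checked in tests.
// [[Rcpp::export]]
List simulate_cells_cpp(List inp, List par, List ctrl) {
  const int n_src = as<int>(inp["n_src"]);
  const double tau_s = as<double>(inp["tau_s"]);
  const double sigma_s = as<double>(inp["sigma_s"]);
  const double sigma_n = as<double>(inp["sigma_n"]);
  arma::vec boundaries = as<arma::vec>(inp["boundaries"]);
  List M_som_l = inp["M_som"], M_dnd_l = inp["M_dnd"];
  std::vector<arma::mat> M_som, M_dnd;
  for (int i = 0; i < M_som_l.size(); ++i)
    M_som.push_back(as<arma::mat>(M_som_l[i]));
  for (int i = 0; i < M_dnd_l.size(); ++i)
    M_dnd.push_back(as<arma::mat>(M_dnd_l[i]));
  arma::vec s = as<arma::vec>(inp["s0"]);

  const double dt = as<double>(par["dt"]);
  const int n_steps = as<int>(par["n_steps"]);
  const double phi = as<double>(par["phi"]);
  const double phi_input = as<double>(par["phi_input"]);
  const double theta_f = as<double>(par["theta_f"]);
  const double beta = as<double>(par["beta"]);
  const double gamma = as<double>(par["gamma"]);
  const double tau_L = as<double>(par["tau_L"]);
  const double alpha = as<double>(par["alpha"]);
  const double eta = as<double>(par["eta"]);
  const double eta_inh = as<double>(par["eta_inh"]);
  const double c0 = as<double>(par["c0"]);
  const double theta_inh = as<double>(par["theta_inh"]);
  const double tau_w = as<double>(par["tau_w"]);
  const double eta_decay = as<double>(par["eta_decay"]);
  const double sigma_w = as<double>(par["sigma_w"]);
  const double tau_mean = as<double>(par["tau_mean"]);
  const int rule = as<int>(par["rule"]);  // 0 combined, 1 calcium-BCM
  const double alpha_som = as<double>(par["alpha_som"]);
  const double alpha_dnd = as<double>(par["alpha_dnd"]);
  const bool use_inh = as<int>(par["use_inh"]) != 0;
  const double v_som = as<double>(par["v_som"]);

  arma::mat w_som = as<arma::mat>(ctrl["w_som_init"]);
  arma::mat w_dnd = as<arma::mat>(ctrl["w_dnd_init"]);
  const int K = w_som.n_rows;
  const int n_som = w_som.n_cols;
  const int n_dnd = w_dnd.n_cols;
  const int record_every = as<int>(ctrl["record_every"]);
  const int snapshot_every = as<int>(ctrl["snapshot_every"]);
  const bool record_inputs = as<int>(ctrl["record_inputs"]) != 0;
  NormalRng rng(static_cast<uint64_t>(as<double>(ctrl["seed"])));

  arma::mat th_som_pool, th_dnd_pool, v_dnd, dv_dnd;
  arma::vec I_pyr;
  int n_inh = 0;
  if (use_inh) {
    th_som_pool = as<arma::mat>(par["theta_som_pool"]);
    th_dnd_pool = as<arma::mat>(par["theta_dnd_pool"]);
    n_inh = th_som_pool.n_rows;
    v_dnd.zeros(K, n_inh);
    dv_dnd.zeros(K, n_inh);
    I_pyr.zeros(K);
  }

  arma::mat dw_som(K, n_som, arma::fill::zeros);
  arma::mat dw_dnd(K, n_dnd, arma::fill::zeros);
  arma::vec I_input_som(n_som, arma::fill::zeros);
  arma::vec I_input_dnd(n_dnd, arma::fill::zeros);
  arma::vec I_som(n_som, arma::fill::zeros);
  arma::vec I_dnd(n_dnd, arma::fill::zeros);
  const double f0 = sigmoidf(0.0, theta_f);
  arma::vec x(K, arma::fill::value(f0)), y(K, arma::fill::value(f0));
  arma::vec z = (1.0 + gamma * f0) * phi * x;
  arma::vec E_som(K, arma::fill::zeros), E_dnd(K, arma::fill::zeros);

  const double dec_s = std::exp(-dt / tau_s);
  const double sd_s = sigma_s * std::sqrt(tau_s / 2.0 *
                                          (1.0 - dec_s * dec_s));
  const double sd_n = sigma_n * std::sqrt(dt);
  const double sw = sigma_w * std::sqrt(dt);
  const double rw = dt / tau_w;

  const int n_rec = n_steps / record_every;
  arma::mat rec_x(K, n_rec), rec_y(K, n_rec), rec_z(K, n_rec);
  arma::vec rec_t(n_rec);
  arma::mat rec_Isom, rec_Idnd;
  if (record_inputs) {
    rec_Isom.set_size(n_som, n_rec);
    rec_Idnd.set_size(n_dnd, n_rec);
  }
  const int n_snap = n_steps / snapshot_every;
  arma::cube snap_w_som(K, n_som, n_snap), snap_w_dnd(K, n_dnd, n_snap);
  arma::cube snap_v_dnd;
  if (use_inh) snap_v_dnd.set_size(K, n_inh, n_snap);
  arma::vec snap_t(n_snap);
  int ri = 0, si = 0;

  for (int k = 1; k <= n_steps; ++k) {
    const double t_now = (k - 1) * dt;
    size_t ph = 0;
    for (arma::uword b = 0; b < boundaries.n_elem; ++b)
      if (t_now >= boundaries[b]) ++ph;

    // sources and input currents
    for (int i = 0; i < n_src; ++i)
      s[i] = s[i] * dec_s + sd_s * rng.norm();
    arma::vec dr_som = M_som[ph] * s;
    arma::vec dr_dnd = M_dnd[ph] * s;
    for (int j = 0; j < n_som; ++j)
      I_input_som[j] += dt * (-I_input_som[j] / tau_L + dr_som[j]) +
        sd_n * rng.norm();
    for (int j = 0; j < n_dnd; ++j)
      I_input_dnd[j] += dt * (-I_input_dnd[j] / tau_L + dr_dnd[j]) +
        sd_n * rng.norm();

    // input rates and postsynaptic traces
    for (int j = 0; j < n_som; ++j)
      I_som[j] += dt * (-I_som[j] / tau_L +
                        phi_input * sigmoidf(I_input_som[j], theta_f));
    for (int j = 0; j < n_dnd; ++j)
      I_dnd[j] += dt * (-I_dnd[j] / tau_L +
                        phi_input * sigmoidf(I_input_dnd[j], theta_f));

    // inhibitory feedback from previous-step rates
    double inh_som = 0.0;
    arma::vec I_dndinh, inh_dnd(K, arma::fill::zeros);
    if (use_inh) {
      for (int i = 0; i < K; ++i)
        I_pyr[i] += dt * (-I_pyr[i] / tau_L + z[i]);
      arma::vec I_sominh = th_som_pool * I_pyr;
      I_dndinh = th_dnd_pool * I_pyr;
      inh_som = v_som * arma::accu(I_sominh);
      inh_dnd = v_dnd * I_dndinh;
    }

    // activations and output rates
    arma::vec exc_som = w_som * I_som;
    arma::vec exc_dnd = w_dnd * I_dnd;
    arma::vec x_new(K), y_new(K);
    for (int i = 0; i < K; ++i) {
      x_new[i] = sigmoidf(exc_som[i] - inh_som + beta * y[i], theta_f);
      y_new[i] = sigmoidf(exc_dnd[i] - inh_dnd[i] + beta * x[i], theta_f);
    }
    z = (1.0 + gamma * y_new) % (phi * x_new);

    // plasticity
    arma::vec g_som(K), g_dnd(K);
    if (rule == 0) {
      for (int i = 0; i < K; ++i) {
        E_som[i] += dt * (x_new[i] - E_som[i]) / tau_mean;
        E_dnd[i] += dt * (y_new[i] - E_dnd[i]) / tau_mean;
        const double th_s = c0 * E_som[i] * E_som[i];
        const double th_d = c0 * E_dnd[i] * E_dnd[i];
        const double xy = x_new[i] * y_new[i];
        g_som[i] = eta * ((1.0 - alpha) * x_new[i] * (x_new[i] - th_s) +
                          alpha * xy) * (1.0 - x_new[i]);
        g_dnd[i] = eta * ((1.0 - alpha) * y_new[i] * (y_new[i] - th_d) +
                          alpha * xy) * (1.0 - y_new[i]);
      }
    } else {
      for (int i = 0; i < K; ++i) {
        const double xy = x_new[i] * y_new[i];
        const double zs = (1.0 - alpha_som) * x_new[i] + alpha_som * xy;
        const double zd = (1.0 - alpha_dnd) * y_new[i] + alpha_dnd * xy;
        E_som[i] += dt * (zs - E_som[i]) / tau_mean;
        E_dnd[i] += dt * (zd - E_dnd[i]) / tau_mean;
        const double th_s = c0 * E_som[i] * E_som[i];
        const double th_d = c0 * E_dnd[i] * E_dnd[i];
        g_som[i] = eta * zs * (zs - th_s) * (1.0 - x_new[i]);
        g_dnd[i] = eta * zd * (zd - th_d) * (1.0 - y_new[i]);
      }
    }
    for (int j = 0; j < n_som; ++j) {
      const double Ij = I_som[j];
      for (int i = 0; i < K; ++i) {
        dw_som(i, j) += rw * (g_som[i] * Ij - dw_som(i, j));
        double w = w_som(i, j) + dt * (dw_som(i, j) -
                                       eta_decay * w_som(i, j));
        if (sigma_w > 0) w += sw * rng.norm();
        w_som(i, j) = w > 0.0 ? w : 0.0;
      }
    }
    for (int j = 0; j < n_dnd; ++j) {
      const double Ij = I_dnd[j];
      for (int i = 0; i < K; ++i) {
        dw_dnd(i, j) += rw * (g_dnd[i] * Ij - dw_dnd(i, j));
        double w = w_dnd(i, j) + dt * (dw_dnd(i, j) -
                                       eta_decay * w_dnd(i, j));
        if (sigma_w > 0) w += sw * rng.norm();
        w_dnd(i, j) = w > 0.0 ? w : 0.0;
      }
    }
    if (use_inh) {
      arma::vec g_v(K);
      for (int i = 0; i < K; ++i)
        g_v[i] = eta_inh *
          ((1.0 - alpha) * y_new[i] * (y_new[i] - theta_inh) +
           alpha * x_new[i] * y_new[i]) * (1.0 - y_new[i]);
      for (int j = 0; j < n_inh; ++j) {
        const double Ij = I_dndinh[j];
        for (int i = 0; i < K; ++i) {
          dv_dnd(i, j) += rw * (g_v[i] * Ij - dv_dnd(i, j));
          double v = v_dnd(i, j) + dt * (dv_dnd(i, j) -
                                         eta_decay * v_dnd(i, j));
          v_dnd(i, j) = v > 0.0 ? v : 0.0;
        }
      }
    }
    x = x_new; y = y_new;

    if (k % record_every == 0 && ri < n_rec) {
      rec_x.col(ri) = x; rec_y.col(ri) = y; rec_z.col(ri) = z;
      rec_t[ri] = k * dt;
      if (record_inputs) {
        rec_Isom.col(ri) = I_som;
        rec_Idnd.col(ri) = I_dnd;
      }
      ++ri;
    }
    if (k % snapshot_every == 0 && si < n_snap) {
      snap_w_som.slice(si) = w_som;
      snap_w_dnd.slice(si) = w_dnd;
      if (use_inh) snap_v_dnd.slice(si) = v_dnd;
      snap_t[si] = k * dt;
      ++si;
    }
  }

  List out = List::create(
    _["time"] = rec_t, _["x"] = rec_x, _["y"] = rec_y, _["z"] = rec_z,
    _["w_som"] = w_som, _["w_dnd"] = w_dnd,
    _["snap_t"] = snap_t, _["snap_w_som"] = snap_w_som,
    _["snap_w_dnd"] = snap_w_dnd);
  if (use_inh) {
    out["v_dnd"] = v_dnd;
    out["snap_v_dnd"] = snap_v_dnd;
  }
  if (record_inputs) {
    out["I_som"] = rec_Isom;
    out["I_dnd"] = rec_Idnd;
  }
  return out;
}

// [[Rcpp::export]]
List simulate_network_cpp(List net, List init, List sched, List ec,
                          List par, List ctrl) {
  arma::mat w_som = as<arma::mat>(net["w_som"]);
  arma::mat w_dnd = as<arma::mat>(net["w_dnd"]);
  arma::mat v_dnd = as<arma::mat>(net["v_dnd"]);
  const double v_som = as<double>(net["v_som"]);
  arma::mat th_som_pool = as<arma::mat>(net["theta_som_pool"]);
  arma::mat th_dnd_pool = as<arma::mat>(net["theta_dnd_pool"]);

  const int n = w_som.n_rows;
  const int n_ec = w_dnd.n_cols;
  const int n_inh = v_dnd.n_cols;

  arma::vec x = as<arma::vec>(init["x"]), y = as<arma::vec>(init["y"]);
  arma::vec z = as<arma::vec>(init["z"]);
  arma::vec I_som = as<arma::vec>(init["I_som"]);
  arma::vec I_dnd = as<arma::vec>(init["I_dnd"]);
  arma::vec I_pyr = as<arma::vec>(init["I_pyr"]);
  arma::vec D_som = as<arma::vec>(init["D_som"]);
  arma::vec F_som = as<arma::vec>(init["F_som"]);
  arma::vec D_dnd = as<arma::vec>(init["D_dnd"]);
  arma::vec F_dnd = as<arma::vec>(init["F_dnd"]);
  arma::mat dw_som = as<arma::mat>(init["dw_som"]);
  arma::mat dw_dnd = as<arma::mat>(init["dw_dnd"]);
  arma::mat dv_dnd = as<arma::mat>(init["dv_dnd"]);
  arma::vec E_som = as<arma::vec>(init["E_som"]);
  arma::vec E_dnd = as<arma::vec>(init["E_dnd"]);

  IntegerVector moving = sched["moving"];
  NumericVector pos = sched["pos"];
  IntegerVector arm = sched["arm"];
  NumericVector theta_in = sched["theta"];
  NumericVector trig = sched["trig"];
  IntegerVector burst = sched["burst"];
  IntegerVector plast_on = sched["plast_on"];
  arma::vec trig_pattern = as<arma::vec>(sched["trig_pattern"]);
  const int T = moving.size();

  IntegerVector ec_mode = ec["mode"];  // 0 place, 1 grid, 2 distractor
  NumericVector ec_center = ec["center"];
  IntegerVector ec_arm = ec["center_arm"];
  const double A_F = as<double>(ec["A_F"]);
  const double sigma_F = as<double>(ec["sigma_F"]);
  const double A_grid = as<double>(ec["A_grid"]);
  const double c_grid = as<double>(ec["c_grid"]);
  NumericVector grid_phase = ec["grid_phase"];
  NumericVector grid_period = ec["grid_period"];
  const double sigma_n_in = as<double>(ec["sigma_n"]);
  const double tau_dist = as<double>(ec["tau_dist"]);
  const double sigma_dist = as<double>(ec["sigma_dist"]);
  const double tau_burst = as<double>(ec["tau_burst"]);
  const double sigma_burst = as<double>(ec["sigma_burst"]);

  const double phi = as<double>(par["phi"]);
  const double phi_input = as<double>(par["phi_input"]);
  const double theta_f = as<double>(par["theta_f"]);
  const double beta = as<double>(par["beta"]);
  const double gamma = as<double>(par["gamma"]);
  const double tau_L = as<double>(par["tau_L"]);
  const double alpha = as<double>(par["alpha"]);
  const double eta = as<double>(par["eta"]);
  const double eta_inh = as<double>(par["eta_inh"]);
  const double c0 = as<double>(par["c0"]);
  const double theta_inh = as<double>(par["theta_inh"]);
  const double tau_w = as<double>(par["tau_w"]);
  const double eta_decay = as<double>(par["eta_decay"]);
  const double sigma_w = as<double>(par["sigma_w"]);
  const double tau_mean = as<double>(par["tau_mean"]);
  const double tau_STD = as<double>(par["tau_STD"]);
  const double tau_STF = as<double>(par["tau_STF"]);
  const double U_immobile = as<double>(par["U_immobile"]);
  const double U_run_rec = as<double>(par["U_run_rec"]);
  const double sigma_n_ext = as<double>(par["sigma_n_ext"]);
  const double dt = as<double>(par["dt"]);

  const bool single_comp = as<int>(ctrl["single_compartment"]) != 0;
  const bool inh_plast = as<int>(ctrl["inh_plasticity_on"]) != 0;
  const bool stp_pool = as<int>(ctrl["stp_pyr_pool"]) != 0;
  const bool plast_master = as<int>(ctrl["plasticity_master"]) != 0;
  const int record_every = as<int>(ctrl["record_every"]);
  IntegerVector rec_w_at = ctrl["record_weights_at"];
  const bool record_xy = as<int>(ctrl["record_xy"]) != 0;
  NormalRng rng(static_cast<uint64_t>(as<double>(ctrl["seed"])));

  // exact-OU decay/increment constants
  const double dec_in = std::exp(-dt / tau_L);
  const double sd_in = sigma_n_in *
    std::sqrt(tau_L / 2.0 * (1.0 - dec_in * dec_in));
  const double dec_ext = dec_in;
  const double sd_ext = sigma_n_ext *
    std::sqrt(tau_L / 2.0 * (1.0 - dec_ext * dec_ext));
  const double dec_dist = std::exp(-dt / tau_dist);
  const double sd_dist = sigma_dist *
    std::sqrt(tau_dist / 2.0 * (1.0 - dec_dist * dec_dist));
  const double dec_burst = std::exp(-dt / tau_burst);
  const double sd_burst = sigma_burst *
    std::sqrt(tau_burst / 2.0 * (1.0 - dec_burst * dec_burst));

  bool use_burst = false;
  for (int k = 0; k < T; ++k) if (burst[k]) { use_burst = true; break; }
  std::vector<int> dist_idx;
  for (int j = 0; j < n_ec; ++j) if (ec_mode[j] == 2) dist_idx.push_back(j);

  arma::vec n_input(n_ec, arma::fill::zeros);
  arma::vec n_ext(n, arma::fill::zeros);
  arma::vec s_dist(n_ec, arma::fill::zeros);
  arma::vec n_burst(n_ec, arma::fill::zeros);
  arma::vec u_ec(n_ec), ext(n), g_som(n), g_dnd(n), g_v(n);
  arma::vec I_sominh(n_inh), I_dndinh(n_inh), inh_dnd_drive(n);

  const int n_rec = T / record_every;
  arma::mat rec_z(n, n_rec);
  arma::mat rec_x, rec_y, rec_inh;
  if (record_xy) {
    rec_x.set_size(n, n_rec);
    rec_y.set_size(n, n_rec);
    rec_inh.set_size(n, n_rec);
  }
  IntegerVector rec_steps(n_rec);
  List w_snaps;
  std::vector<int> snap_at(rec_w_at.begin(), rec_w_at.end());
  std::sort(snap_at.begin(), snap_at.end());
  size_t snap_ptr = 0;

  bool prev_moving = moving[0] != 0;  // no onset switch before the start
  int rec_i = 0;
  const double sw_step = sigma_w * std::sqrt(dt);

  for (int k = 0; k < T; ++k) {
    const bool mv = moving[k] != 0;
    const double th = theta_in[k];
    const double ps = pos[k];
    const int ar = arm[k];

    // exogenous noise processes (fixed draw order)
    for (int j = 0; j < n_ec; ++j)
      n_input[j] = n_input[j] * dec_in + sd_in * rng.norm();
    for (size_t d = 0; d < dist_idx.size(); ++d) {
      int j = dist_idx[d];
      s_dist[j] = s_dist[j] * dec_dist + sd_dist * rng.norm();
    }
    if (use_burst)
      for (int j = 0; j < n_ec; ++j)
        n_burst[j] = n_burst[j] * dec_burst + sd_burst * rng.norm();
    for (int i = 0; i < n; ++i)
      n_ext[i] = n_ext[i] * dec_ext + sd_ext * rng.norm();

    // EC firing rates
    for (int j = 0; j < n_ec; ++j) {
      double cur;
      if (mv) {
        double tuned;
        if (ec_mode[j] == 0) {
          if (ar > 0 && ec_arm[j] != 0 && ec_arm[j] != ar) {
            tuned = 0.0;
          } else {
            double d = (ps - ec_center[j]) / sigma_F;
            tuned = A_F * std::exp(-0.5 * d * d);
          }
        } else if (ec_mode[j] == 1) {
          tuned = A_grid * std::exp(c_grid *
            std::cos(2.0 * M_PI * ps / grid_period[j] - grid_phase[j]));
        } else {
          tuned = s_dist[j];
        }
        cur = tuned + 0.5 * th - 0.5 + n_input[j];
      } else {
        cur = n_input[j] + (burst[k] ? n_burst[j] : 0.0);
      }
      u_ec[j] = phi_input * sigmoidf(cur, theta_f);
    }

    // external somatic input
    for (int i = 0; i < n; ++i)
      ext[i] = th + trig[k] * trig_pattern[i] + n_ext[i];

    // release-probability switching (recurrent synapses only)
    const double U_rec = mv ? U_run_rec : U_immobile;
    if (mv && !prev_moving) F_som.fill(U_run_rec);
    prev_moving = mv;

    // (1) inhibitory pool from previous-step rates.  With stp_pyr_pool the
    // pyramidal outputs reaching the interneurons are the recurrent traces
    // themselves (same presynaptic resource, including D*F); the readouts
    // are then computed after the trace update below.
    if (!stp_pool) {
      for (int i = 0; i < n; ++i)
        I_pyr[i] += dt * (-I_pyr[i] / tau_L + z[i]);
      I_sominh = th_som_pool * I_pyr;
      I_dndinh = th_dnd_pool * I_pyr;
    }

    // (2) short-term plasticity and traces
    for (int i = 0; i < n; ++i) {
      double fac = D_som[i] * F_som[i];
      I_som[i] += dt * (-I_som[i] / tau_L + z[i] * fac);
      double Dn = D_som[i] + dt * ((1.0 - D_som[i]) / tau_STD -
                                   z[i] * D_som[i] * F_som[i]);
      double Fn = F_som[i] + dt * ((U_rec - F_som[i]) / tau_STF +
                                   U_rec * (1.0 - F_som[i]) * z[i]);
      D_som[i] = Dn; F_som[i] = Fn;
    }
    for (int j = 0; j < n_ec; ++j) {
      double fac = D_dnd[j] * F_dnd[j];
      I_dnd[j] += dt * (-I_dnd[j] / tau_L + u_ec[j] * fac);
      double Dn = D_dnd[j] + dt * ((1.0 - D_dnd[j]) / tau_STD -
                                   u_ec[j] * D_dnd[j] * F_dnd[j]);
      double Fn = F_dnd[j] + dt * ((U_immobile - F_dnd[j]) / tau_STF +
                                   U_immobile * (1.0 - F_dnd[j]) * u_ec[j]);
      D_dnd[j] = Dn; F_dnd[j] = Fn;
    }

    if (stp_pool) {
      I_pyr = I_som;
      I_sominh = th_som_pool * I_som;
      I_dndinh = th_dnd_pool * I_som;
    }

    // (3, 4) activations and output rates
    arma::vec exc_som = w_som * I_som;
    arma::vec exc_dnd = w_dnd * I_dnd;
    const double inh_som = v_som * arma::accu(I_sominh);
    arma::vec x_new(n), y_new(n);
    if (single_comp) {
      for (int i = 0; i < n; ++i)
        x_new[i] = sigmoidf(exc_som[i] + exc_dnd[i] - inh_som + ext[i],
                            theta_f);
      y_new = x_new;
      z = phi * x_new;
      inh_dnd_drive.zeros();
    } else {
      inh_dnd_drive = v_dnd * I_dndinh;
      for (int i = 0; i < n; ++i) {
        x_new[i] = sigmoidf(exc_som[i] - inh_som + beta * y[i] + ext[i],
                            theta_f);
        y_new[i] = sigmoidf(exc_dnd[i] - inh_dnd_drive[i] + beta * x[i],
                            theta_f);
      }
      z = (1.0 + gamma * y_new) % (phi * x_new);
    }
    if (!x_new.is_finite() || !z.is_finite())
      stop("simulate_network_cpp: non-finite state at step %d", k + 1);

    // (5) plasticity
    if (plast_master && plast_on[k]) {
      for (int i = 0; i < n; ++i) {
        E_som[i] += dt * (x_new[i] - E_som[i]) / tau_mean;
        E_dnd[i] += dt * (y_new[i] - E_dnd[i]) / tau_mean;
      }
      if (single_comp) {
        for (int i = 0; i < n; ++i) {
          double thr = c0 * E_som[i] * E_som[i];
          g_som[i] = eta * x_new[i] * (x_new[i] - thr) * (1.0 - x_new[i]);
          g_dnd[i] = g_som[i];
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double thr_s = c0 * E_som[i] * E_som[i];
          double thr_d = c0 * E_dnd[i] * E_dnd[i];
          double xy = x_new[i] * y_new[i];
          g_som[i] = eta * ((1.0 - alpha) * x_new[i] * (x_new[i] - thr_s) +
                            alpha * xy) * (1.0 - x_new[i]);
          g_dnd[i] = eta * ((1.0 - alpha) * y_new[i] * (y_new[i] - thr_d) +
                            alpha * xy) * (1.0 - y_new[i]);
        }
      }
      const double rw = dt / tau_w;
      for (int j = 0; j < n; ++j) {
        const double Ij = I_som[j];
        double* dwc = dw_som.colptr(j);
        double* wc = w_som.colptr(j);
        for (int i = 0; i < n; ++i) {
          dwc[i] += rw * (g_som[i] * Ij - dwc[i]);
          double w = wc[i] + dt * (dwc[i] - eta_decay * wc[i]);
          if (sigma_w > 0) w += sw_step * rng.norm();
          wc[i] = w > 0.0 ? w : 0.0;
        }
        wc[j] = 0.0;  // no self-connections
      }
      for (int j = 0; j < n_ec; ++j) {
        const double Ij = I_dnd[j];
        double* dwc = dw_dnd.colptr(j);
        double* wc = w_dnd.colptr(j);
        for (int i = 0; i < n; ++i) {
          dwc[i] += rw * (g_dnd[i] * Ij - dwc[i]);
          double w = wc[i] + dt * (dwc[i] - eta_decay * wc[i]);
          if (sigma_w > 0) w += sw_step * rng.norm();
          wc[i] = w > 0.0 ? w : 0.0;
        }
      }
      if (!single_comp && inh_plast) {
        for (int i = 0; i < n; ++i) {
          double xy = x_new[i] * y_new[i];
          g_v[i] = eta_inh *
            ((1.0 - alpha) * y_new[i] * (y_new[i] - theta_inh) +
             alpha * xy) * (1.0 - y_new[i]);
        }
        for (int j = 0; j < n_inh; ++j) {
          const double Ij = I_dndinh[j];
          double* dvc = dv_dnd.colptr(j);
          double* vc = v_dnd.colptr(j);
          for (int i = 0; i < n; ++i) {
            dvc[i] += rw * (g_v[i] * Ij - dvc[i]);
            double v = vc[i] + dt * (dvc[i] - eta_decay * vc[i]);
            vc[i] = v > 0.0 ? v : 0.0;
          }
        }
      }
    }

    x = x_new; y = y_new;

    // recording
    if ((k + 1) % record_every == 0 && rec_i < n_rec) {
      rec_z.col(rec_i) = z;
      if (record_xy) {
        rec_x.col(rec_i) = x;
        rec_y.col(rec_i) = y;
        rec_inh.col(rec_i) = inh_dnd_drive;
      }
      rec_steps[rec_i] = k + 1;
      ++rec_i;
    }
    while (snap_ptr < snap_at.size() && snap_at[snap_ptr] == k + 1) {
      w_snaps.push_back(List::create(_["step"] = k + 1,
                                     _["w_som"] = w_som,
                                     _["w_dnd"] = w_dnd,
                                     _["v_dnd"] = v_dnd));
      ++snap_ptr;
    }
  }

  arma::vec th_som_out = c0 * arma::square(E_som);
  arma::vec th_dnd_out = c0 * arma::square(E_dnd);
  List state = List::create(
    _["x"] = x, _["y"] = y, _["z"] = z,
    _["I_som"] = I_som, _["I_dnd"] = I_dnd, _["I_pyr"] = I_pyr,
    _["D_som"] = D_som, _["F_som"] = F_som,
    _["D_dnd"] = D_dnd, _["F_dnd"] = F_dnd,
    _["w_som"] = w_som, _["w_dnd"] = w_dnd, _["v_dnd"] = v_dnd,
    _["dw_som"] = dw_som, _["dw_dnd"] = dw_dnd, _["dv_dnd"] = dv_dnd,
    _["E_som"] = E_som, _["E_dnd"] = E_dnd,
    _["theta_som"] = th_som_out, _["theta_dnd"] = th_dnd_out);

  List out = List::create(
    _["z"] = rec_z, _["rec_steps"] = rec_steps,
    _["state"] = state, _["w_snapshots"] = w_snaps);
  if (record_xy) {
    out["x"] = rec_x;
    out["y"] = rec_y;
    out["inh_dnd"] = rec_inh;
  }
  return out;
}
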