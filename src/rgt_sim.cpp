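#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of one simulated RGT (or reversal) session.
//
// Options are indexed 0..K-1 in canonical order (A,B,C,D); hole_of_option
// maps each option's contingency to a physical hole (1-based, from R).
// Q-values and penalty statistics are indexed by HOLE, so after a spatial
// reversal the agent's learned values meet new contingencies.
//
// RNG contract: two draws from R's uniform stream per trial, in fixed
// order — one for action selection, one for the penalty transition — so a
// seeded run is bit-identical to the pure-R reference implementation.

static inline int pick_cumulative(const double *p, int k, double u) {
  double acc = 0.0;
  for (int i = 0; i < k; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return k - 1;
}

// [[Rcpp::export]]
List cpp_run_session(NumericVector reward_pellets,
                     NumericVector penalty_pellets,
                     NumericVector penalty_prob,
                     NumericVector timeout_seconds,
                     IntegerVector hole_of_option,
                     LogicalVector advantageous,
                     double episode_seconds,
                     double session_seconds,
                     double pellet_cap,
                     double forced_seconds,
                     double bin_seconds,
                     bool timeout_in_clock,
                     double t_offset,
                     double alpha0, double tau0, double omega, double rho,
                     double epsilon,
                     NumericVector q_init,
                     NumericVector pen_n_init,
                     NumericVector pen_mean_init,
                     NumericVector pen_m2_init,
                     bool keep_log,
                     int max_trials) {
  const int K = reward_pellets.size();
  if (K > 16) stop("at most 16 options supported");
  std::vector<int> option_of_hole(K, -1);
  for (int o = 0; o < K; ++o) {
    int h = hole_of_option[o] - 1;
    if (h < 0 || h >= K) stop("hole_of_option out of range");
    option_of_hole[h] = o;
  }
  for (int h = 0; h < K; ++h)
    if (option_of_hole[h] < 0) stop("location map is not a bijection");

  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> pn(pen_n_init.begin(), pen_n_init.end());
  std::vector<double> pmean(pen_mean_init.begin(), pen_mean_init.end());
  std::vector<double> pm2(pen_m2_init.begin(), pen_m2_init.end());

  const int n_bins = (int)std::ceil(session_seconds / bin_seconds);
  IntegerVector bin_adv(n_bins), bin_tot(n_bins);

  std::vector<double> log_t, log_penval, log_dur;
  std::vector<int> log_hole, log_opt, log_pellets, log_penflag;

  double elapsed = 0.0;
  int pellets_total = 0, trial = 0;
  double probs[16];

  while (elapsed < session_seconds && pellets_total < pellet_cap &&
         trial < max_trials) {
    const double t0 = elapsed;
    const double t_decay = t0 + t_offset;   // decay/forced clock may carry
    const bool forced = t_decay < forced_seconds;
    const double u = unif_rand();
    int hole;
    if (forced) {
      hole = (int)(u * K);
      if (hole >= K) hole = K - 1;
    } else {
      double m = q[0];
      for (int i = 1; i < K; ++i) if (q[i] > m) m = q[i];
      double z = 0.0;
      for (int i = 0; i < K; ++i) {
        probs[i] = std::exp((q[i] - m) / epsilon);
        z += probs[i];
      }
      for (int i = 0; i < K; ++i) probs[i] /= z;
      hole = pick_cumulative(probs, K, u);
    }
    const int o = option_of_hole[hole];
    const double u2 = unif_rand();
    const bool pen = u2 < penalty_prob[o];
    const int pellets = (int)reward_pellets[o];
    const double penval = pen ? penalty_pellets[o] : 0.0;
    const double dur = episode_seconds * pellets +
        ((pen && timeout_in_clock) ? timeout_seconds[o] : 0.0);

    // penalty statistics updated before the value update, so the current
    // trial's penalty informs the current risk bonus (Welford recursion)
    pn[hole] += 1.0;
    const double d = penval - pmean[hole];
    pmean[hole] += d / pn[hole];
    pm2[hole] += d * (penval - pmean[hole]);
    const double risk =
        pn[hole] > 1.0 ? std::sqrt(pm2[hole] / pn[hole]) : 0.0;

    const double signal = omega * pellets + penval + rho * risk;
    const double alpha =
        alpha0 * ((tau0 == R_PosInf) ? 1.0 : std::exp(-t_decay / tau0));
    q[hole] += alpha * (signal - q[hole]);

    int b = (int)(t0 / bin_seconds);
    if (b >= n_bins) b = n_bins - 1;
    bin_tot[b] += 1;
    if (advantageous[o]) bin_adv[b] += 1;

    if (keep_log) {
      log_t.push_back(t0);
      log_hole.push_back(hole + 1);
      log_opt.push_back(o + 1);
      log_pellets.push_back(pellets);
      log_penflag.push_back(pen ? 1 : 0);
      log_penval.push_back(penval);
      log_dur.push_back(dur);
    }

    elapsed += dur;
    pellets_total += pellets;
    ++trial;
  }

  List out = List::create(
      _["q"] = NumericVector(q.begin(), q.end()),
      _["pen_n"] = NumericVector(pn.begin(), pn.end()),
      _["pen_mean"] = NumericVector(pmean.begin(), pmean.end()),
      _["pen_m2"] = NumericVector(pm2.begin(), pm2.end()),
      _["elapsed_seconds"] = elapsed,
      _["pellets_earned"] = pellets_total,
      _["n_trials"] = trial,
      _["bin_adv"] = bin_adv,
      _["bin_tot"] = bin_tot);
  if (keep_log) {
    out["log_t_start"] = NumericVector(log_t.begin(), log_t.end());
    out["log_hole"] = IntegerVector(log_hole.begin(), log_hole.end());
    out["log_option"] = IntegerVector(log_opt.begin(), log_opt.end());
    out["log_pellets"] =
        IntegerVector(log_pellets.begin(), log_pellets.end());
    out["log_penalty_applied"] =
        IntegerVector(log_penflag.begin(), log_penflag.end());
    out["log_penalty_pellets"] =
        NumericVector(log_penval.begin(), log_penval.end());
    out["log_elapsed"] = NumericVector(log_dur.begin(), log_dur.end());
  }
  return out;
}
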