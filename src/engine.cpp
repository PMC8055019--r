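#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Round loop for the hawk-dove simulation.
//
// RNG consumption order (must stay in lockstep with the R reference
// engine): per round, (1) one uniform per agent 1..N for the visit target,
// (2) one uniform per agent 1..N for the visitor action, (3) one uniform
// per incoming visit, grouped by host index ascending and visitor index
// ascending within a host. All draws come from R's RNG via unif_rand().
//
// All weight updates are simultaneous: probabilities and payoffs are
// computed from the pre-round weights, and the new weights are written
// only after every interaction of the round is resolved.
//
// The network is stored row-major (visitor rows contiguous) since every
// hot loop scans one agent's outgoing row. Floating-point expressions are
// kept in the exact shape used by the R reference so results match bit
// for bit.

static inline double hawk_prob(double wh, double wd, double eps) {
  double tw = wh + wd;
  if (tw > 0) return (1.0 - eps) * (wh / tw) + eps * 0.5;
  return 0.5;
}

// [[Rcpp::export]]
List engine_run_cpp(int N, int rounds, int variant,
                    double f, double hd, double dd, double dh, double hh,
                    double delta, double epsilon, double v,
                    NumericMatrix strategy0, NumericMatrix network0,
                    IntegerVector ranks0,
                    int rank_interval, int snapshot_every,
                    double rank_discount,
                    bool record_interactions) {
  // variant: 0 = random_interaction, 1 = partner_choice, 2 = dynamic_ranks
  std::vector<double> S(4 * N);            // [agent*4 + k]: w_H w_D w_h w_d
  std::vector<double> W((size_t)N * N);    // row-major: [i*N + j]
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 4; ++k) S[(size_t)i * 4 + k] = strategy0(i, k);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) W[(size_t)i * N + j] = network0(i, j);
  std::vector<int> rank(ranks0.begin(), ranks0.end());
  std::vector<double> rank_acc(N, 0.0), raw_cum(N, 0.0);

  int n_snap = rounds / snapshot_every + (rounds % snapshot_every ? 1 : 0);
  NumericMatrix outcome_counts(n_snap, 4); // hh, host_guest, ownership, dd
  NumericVector centralization(n_snap), snapshot_rounds(n_snap);

  int n_rank_rows = (variant == 2) ? rounds / rank_interval + 1 : 1;
  IntegerMatrix rank_history(n_rank_rows, N);
  NumericVector rank_history_rounds(n_rank_rows);
  for (int i = 0; i < N; ++i) rank_history(0, i) = rank[i];
  rank_history_rounds[0] = 0;
  int rank_row = 1;

  std::vector<int> log_round, log_vis, log_host, log_va, log_ha, log_rel;
  std::vector<double> log_vp, log_hp;
  if (record_interactions) {
    size_t cap = (size_t)rounds * N;
    log_round.reserve(cap); log_vis.reserve(cap); log_host.reserve(cap);
    log_va.reserve(cap); log_ha.reserve(cap); log_rel.reserve(cap);
    log_vp.reserve(cap); log_hp.reserve(cap);
  }

  std::vector<int> target(N), vis_hawk(N);
  std::vector<double> vis_pay(N), host_pi_hawk(N), host_pi_dove(N),
      round_total(N), p_hawk_host(N);
  double block[4] = {0, 0, 0, 0};
  int snap_row = 0;
  const double uniform_p = 1.0 / (N - 1);
  const double tremble_add = epsilon * uniform_p;
  const double one_minus_delta = 1.0 - delta;

  for (int r = 1; r <= rounds; ++r) {
    // (1) visit targets
    for (int i = 0; i < N; ++i) {
      double u = unif_rand();
      int chosen = -1;
      if (variant == 0) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          acc += uniform_p;
          if (u <= acc) { chosen = j; break; }
        }
      } else {
        const double *row = &W[(size_t)i * N];
        double total = 0.0;
        for (int j = 0; j < N; ++j) total += row[j];
        double acc = 0.0;
        if (total > 0) {
          double scale = (1.0 - epsilon) / total;
          for (int j = 0; j < N; ++j) {
            if (j == i) continue;
            acc += scale * row[j] + tremble_add;
            if (u <= acc) { chosen = j; break; }
          }
        } else {
          for (int j = 0; j < N; ++j) {
            if (j == i) continue;
            acc += uniform_p;
            if (u <= acc) { chosen = j; break; }
          }
        }
      }
      if (chosen < 0) chosen = (i == N - 1) ? N - 2 : N - 1;
      target[i] = chosen;
    }
    // (2) visitor actions
    for (int i = 0; i < N; ++i) {
      double pH = hawk_prob(S[(size_t)i * 4 + 2], S[(size_t)i * 4 + 3],
                            epsilon);
      vis_hawk[i] = (unif_rand() <= pH) ? 1 : 0;
    }
    // (3) host actions + resolution, host index ascending
    for (int i = 0; i < N; ++i) {
      p_hawk_host[i] = hawk_prob(S[(size_t)i * 4], S[(size_t)i * 4 + 1],
                                 epsilon);
      host_pi_hawk[i] = 0.0; host_pi_dove[i] = 0.0; round_total[i] = 0.0;
    }
    for (int h = 0; h < N; ++h) {
      for (int i = 0; i < N; ++i) {
        if (target[i] != h) continue;
        int host_hawk = (unif_rand() <= p_hawk_host[h]) ? 1 : 0;
        double pv, ph_;
        int rel; // 0 host_outranks, 1 visitor_outranks, 2 tied
        bool tied = (variant == 2) && (rank_acc[i] == rank_acc[h]);
        if (vis_hawk[i] && host_hawk) {
          if (tied) { pv = f / 3.0; ph_ = f / 3.0; rel = 2; }
          else if (rank[i] < rank[h]) { pv = f; ph_ = hh; rel = 1; }
          else { pv = hh; ph_ = f; rel = 0; }
        } else {
          rel = tied ? 2 : (rank[i] < rank[h] ? 1 : 0);
          if (vis_hawk[i]) { pv = hd; ph_ = dh; }
          else if (host_hawk) { pv = dh; ph_ = hd; }
          else { pv = dd; ph_ = dd; }
        }
        vis_pay[i] = pv;
        if (host_hawk) host_pi_hawk[h] += ph_; else host_pi_dove[h] += ph_;
        round_total[i] += pv;
        round_total[h] += ph_;
        if (vis_hawk[i] && host_hawk) block[0] += 1;
        else if (vis_hawk[i]) block[1] += 1;
        else if (host_hawk) block[2] += 1;
        else block[3] += 1;
        if (record_interactions) {
          log_round.push_back(r); log_vis.push_back(i + 1);
          log_host.push_back(h + 1); log_va.push_back(vis_hawk[i]);
          log_ha.push_back(host_hawk); log_rel.push_back(rel);
          log_vp.push_back(pv); log_hp.push_back(ph_);
        }
      }
    }
    // (4) simultaneous updates from pre-round weights
    for (int i = 0; i < N; ++i) {
      double *si = &S[(size_t)i * 4];
      si[0] = one_minus_delta * si[0] + host_pi_hawk[i];
      si[1] = one_minus_delta * si[1] + host_pi_dove[i];
      si[2] = one_minus_delta * si[2] + (vis_hawk[i] ? vis_pay[i] : 0.0);
      si[3] = one_minus_delta * si[3] + (vis_hawk[i] ? 0.0 : vis_pay[i]);
    }
    if (variant != 0) {
      size_t nn = (size_t)N * N;
      for (size_t k = 0; k < nn; ++k) W[k] = one_minus_delta * W[k];
      for (int i = 0; i < N; ++i)
        W[(size_t)i * N + target[i]] += v * vis_pay[i];
    }
    for (int i = 0; i < N; ++i) {
      raw_cum[i] += round_total[i];
      rank_acc[i] = (1.0 - rank_discount) * rank_acc[i] + round_total[i];
    }
    // (5) rank update (dynamic variant): stable sort by accumulator
    // descending, previous rank order breaking ties
    if (variant == 2 && r % rank_interval == 0) {
      std::vector<int> idx(N);
      for (int i = 0; i < N; ++i) idx[rank[i] - 1] = i;
      std::stable_sort(idx.begin(), idx.end(),
                       [&](int a, int b) { return rank_acc[a] > rank_acc[b]; });
      for (int k = 0; k < N; ++k) rank[idx[k]] = k + 1;
      if (rank_row < n_rank_rows) {
        for (int i = 0; i < N; ++i) rank_history(rank_row, i) = rank[i];
        rank_history_rounds[rank_row] = r;
        ++rank_row;
      }
    }
    // (6) snapshot
    if (r % snapshot_every == 0 || r == rounds) {
      for (int k = 0; k < 4; ++k) {
        outcome_counts(snap_row, k) = block[k];
        block[k] = 0;
      }
      // centralization: sample variance of in-sums of the row-normalized
      // (tremble-free) visit matrix
      std::vector<double> insum(N, 0.0);
      for (int i = 0; i < N; ++i) {
        const double *row = &W[(size_t)i * N];
        double tot = 0.0;
        for (int j = 0; j < N; ++j) tot += row[j];
        if (tot > 0) {
          for (int j = 0; j < N; ++j) insum[j] += row[j] / tot;
        } else {
          for (int j = 0; j < N; ++j) if (j != i) insum[j] += uniform_p;
        }
      }
      double mean = 0.0;
      for (int j = 0; j < N; ++j) mean += insum[j];
      mean /= N;
      double ss = 0.0;
      for (int j = 0; j < N; ++j) ss += (insum[j] - mean) * (insum[j] - mean);
      centralization[snap_row] = ss / (N - 1);
      snapshot_rounds[snap_row] = r;
      ++snap_row;
      if (r % snapshot_every != 0 && r == rounds) break;
    }
  }

  NumericMatrix S_out(N, 4), W_out(N, N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 4; ++k) S_out(i, k) = S[(size_t)i * 4 + k];
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) W_out(i, j) = W[(size_t)i * N + j];

  List out = List::create(
      _["final_strategy"] = S_out,
      _["final_network"] = W_out,
      _["final_ranks"] = IntegerVector(rank.begin(), rank.end()),
      _["rank_accumulator"] = NumericVector(rank_acc.begin(), rank_acc.end()),
      _["cumulative_payoff"] = NumericVector(raw_cum.begin(), raw_cum.end()),
      _["outcome_counts"] = outcome_counts,
      _["centralization"] = centralization,
      _["snapshot_rounds"] = snapshot_rounds,
      _["rank_history"] = rank_history,
      _["rank_history_rounds"] = rank_history_rounds);
  if (record_interactions) {
    out["log_round"] = IntegerVector(log_round.begin(), log_round.end());
    out["log_visitor"] = IntegerVector(log_vis.begin(), log_vis.end());
    out["log_host"] = IntegerVector(log_host.begin(), log_host.end());
    out["log_visitor_action"] = IntegerVector(log_va.begin(), log_va.end());
    out["log_host_action"] = IntegerVector(log_ha.begin(), log_ha.end());
    out["log_relation"] = IntegerVector(log_rel.begin(), log_rel.end());
    out["log_visitor_payoff"] = NumericVector(log_vp.begin(), log_vp.end());
    out["log_host_payoff"] = NumericVector(log_hp.begin(), log_hp.end());
  }
  return out;
}
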