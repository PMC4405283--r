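#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Continuous-time simulation of one triad's contact process.
//
// Ties onset at piecewise-constant competing-exponential rates
// lambda_d = exp(beta0 + theta . s_d(t)), where s_d is the same
// five-statistic vector the fitting side computes (unfamiliarity indicator
// and counts of the dyad's prior pair / group onsets over the past hour and
// the current day, windows truncated at the day start). Active ties
// dissolve at a covariate-free hazard. From a two-tie configuration the
// closing (triangle) onset occurs at rate exp(beta0_group); it is generated
// but never modelled. Rates are constant between breakpoints (events,
// hour-window expiries of counted onsets, day boundaries), so sampling uses
// competing exponentials with re-sampling at each breakpoint.
//
// Event times are recorded on an integer-second grid with the constraints
// the ingestion pipeline expects of clean logger data: strictly increasing
// times within the triad, contacts at least 2 s long, and no onsets in the
// final 2 s of the horizon, so that re-ingestion is an exact no-op.

// dyad codes 0..2 internally: 0=(1,2), 1=(1,3), 2=(2,3); unfamiliar pairs 1,2

static inline int count_recent(const std::vector<int> &v, double cutoff) {
  // #{t_e in v : t_e > cutoff}; v ascending
  int n = 0;
  for (int i = (int)v.size() - 1; i >= 0; --i) {
    if ((double)v[i] > cutoff) ++n; else break;
  }
  return n;
}

// [[Rcpp::export]]
IntegerMatrix sim_triad_core(double beta0_pair, double beta0_group,
                             NumericVector theta_pair, NumericVector theta_group,
                             double offset_hazard, NumericVector day_starts,
                             double horizon, double hour_window,
                             int max_events) {
  if (theta_pair.size() != 5 || theta_group.size() != 5)
    stop("theta vectors must have length 5");
  if (offset_hazard <= 0) stop("offset_hazard must be positive");

  bool active[3] = {false, false, false};
  int onset_at[3] = {0, 0, 0};
  std::vector<int> pairT[3], creditT[3], recentT;
  size_t ex_i = 0;                       // first not-yet-expired counted onset

  int day_idx = 0;                       // index into day_starts
  double day_start = day_starts[0];
  int n_days = day_starts.size();
  double now = 0.0;
  int last_rec = -1;

  std::vector<int> out_t, out_dyad, out_kind, out_etype, out_base;
  out_t.reserve(4096);

  auto record = [&](int t, int dyad, int kind, int etype, int base) {
    out_t.push_back(t); out_dyad.push_back(dyad + 1);
    out_kind.push_back(kind); out_etype.push_back(etype);
    out_base.push_back(base < 0 ? NA_INTEGER : base + 1);
  };

  auto advance_day_to = [&](double t) {
    while (day_idx + 1 < n_days && t >= day_starts[day_idx + 1]) {
      ++day_idx;
      day_start = day_starts[day_idx];
      for (int d = 0; d < 3; ++d) { pairT[d].clear(); creditT[d].clear(); }
      recentT.clear(); ex_i = 0;
    }
  };

  while (now < horizon) {
    // next rate breakpoint
    double bp = horizon;
    if (day_idx + 1 < n_days && day_starts[day_idx + 1] < bp)
      bp = day_starts[day_idx + 1];
    while (ex_i < recentT.size() && (double)recentT[ex_i] + hour_window <= now)
      ++ex_i;
    if (ex_i < recentT.size()) {
      double e = (double)recentT[ex_i] + hour_window;
      if (e < bp) bp = e;
    }

    // candidate onset rates given the configuration
    int nact = (int)active[0] + (int)active[1] + (int)active[2];
    int cand[3]; double crate[3]; int ncand = 0;
    int base_tie = -1;
    for (int d = 0; d < 3; ++d) if (active[d]) base_tie = d;
    if (nact < 3) {
      for (int d = 0; d < 3; ++d) {
        if (active[d]) continue;
        double lp;
        if (nact == 2) {
          lp = beta0_group;               // forced triangle closure rate
        } else {
          double s[5];
          s[0] = (d >= 1) ? 1.0 : 0.0;
          double cut = now - hour_window;
          s[1] = count_recent(pairT[d], cut);
          s[2] = (double)pairT[d].size();
          s[3] = count_recent(creditT[d], cut);
          s[4] = (double)creditT[d].size();
          const NumericVector &th = (nact == 0) ? theta_pair : theta_group;
          lp = (nact == 0) ? beta0_pair : beta0_group;
          for (int h = 0; h < 5; ++h) lp += th[h] * s[h];
        }
        if (lp > 30.0 || lp < -30.0)
          stop("onset log-rate %.1f outside [-30, 30]; use smaller parameters", lp);
        cand[ncand] = d; crate[ncand] = std::exp(lp); ++ncand;
      }
    }
    double R = nact * offset_hazard;
    for (int i = 0; i < ncand; ++i) R += crate[i];

    double E = ::exp_rand() / R;           // waiting time to the next event
    if (now + E >= bp) {
      now = bp;
      if (bp >= horizon) break;
      advance_day_to(now);
      continue;
    }
    double tcont = now + E;

    // which event fired?
    double u = ::unif_rand() * R;
    int pick_dyad = -1; bool is_offset = false;
    for (int i = 0; i < ncand; ++i) {
      if (u < crate[i]) { pick_dyad = cand[i]; break; }
      u -= crate[i];
    }
    if (pick_dyad < 0) {
      for (int d = 0; d < 3; ++d) {
        if (!active[d]) continue;
        if (u < offset_hazard) { pick_dyad = d; is_offset = true; break; }
        u -= offset_hazard;
      }
      if (pick_dyad < 0) { pick_dyad = base_tie; is_offset = true; }
    }

    if (!is_offset) {
      int tr = std::max((int)std::ceil(tcont), last_rec + 1);
      if ((double)tr > horizon - 2.0) { now = tcont; continue; }
      advance_day_to((double)tr);
      int etype, base = -1;
      if (nact == 0) {
        etype = 1;                                  // pair
        pairT[pick_dyad].push_back(tr); recentT.push_back(tr);
      } else if (nact == 1) {
        etype = 2; base = base_tie;                 // group
        creditT[pick_dyad].push_back(tr); creditT[base].push_back(tr);
        recentT.push_back(tr);
      } else {
        etype = 3;                                  // triangle (never modelled)
      }
      record(tr, pick_dyad, 0, etype, base);
      active[pick_dyad] = true; onset_at[pick_dyad] = tr;
      last_rec = tr; now = (double)tr;
    } else {
      int tr = std::max(std::max((int)std::ceil(tcont), last_rec + 1),
                        onset_at[pick_dyad] + 2);
      if ((double)tr >= horizon) { now = tcont; continue; } // closes at horizon
      advance_day_to((double)tr);
      record(tr, pick_dyad, 1, 3 + nact, -1);       // 4/5/6 = dissolution types
      active[pick_dyad] = false;
      last_rec = tr; now = (double)tr;
    }
    if ((int)out_t.size() > max_events)
      stop("simulation exceeded max_events (%d); parameters may be self-exciting",
           max_events);
  }

  // close remaining ties at the horizon, ascending dyad code
  int nact = (int)active[0] + (int)active[1] + (int)active[2];
  for (int d = 0; d < 3; ++d) {
    if (!active[d]) continue;
    record((int)horizon, d, 1, 3 + nact, -1);
    --nact; active[d] = false;
  }

  int n = (int)out_t.size();
  IntegerMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = out_t[i]; out(i, 1) = out_dyad[i]; out(i, 2) = out_kind[i];
    out(i, 3) = out_etype[i]; out(i, 4) = out_base[i];
  }
  colnames(out) = CharacterVector::create("t", "dyad", "kind", "etype", "base_dyad");
  return out;
}
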