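#include <Rcpp.h>
using namespace Rcpp;

// Daily-loop anthesis-date simulation for one parameter set over a
// precomputed site environment (tmax/tmin/daylength indexed by day after
// sowing, element 0 = first day after sowing).
//
// Phase accounting: a phase-ending day's thermal time counts toward the
// phase it completes; the next phase starts accumulating the following day.
// Returns the anthesis day after sowing (1-based) or -1 if the horizon is
// exhausted before flowering.
static int simulate_one(const double* tmax, const double* tmin,
                        const double* daylength, int H,
                        double p1, double p2, double p2o, double phint,
                        double tbase, double topt,
                        double emergence_gdd, bool stage2_fixed,
                        bool sumdtt_from_endjuv) {
  double cum = 0.0;           // thermal time since sowing
  double cum_emerg = 0.0, cum_endjuv = 0.0, cum_ti = 0.0;
  double s2 = 0.0;            // stage-2 development fraction
  int phase = 0;              // 0 pre-emergence, 1 juvenile, 2 photoperiod, 3 leaf
  int ti_target = -1;         // stage2_fixed: day index of tassel initiation
  double thresh = 0.0;        // stage-3 thermal-time requirement

  for (int t = 0; t < H; ++t) {
    double tmean = 0.5 * (tmax[t] + tmin[t]);
    double g = (tmean < topt ? tmean : topt) - tbase;
    if (g < 0.0) g = 0.0;
    cum += g;

    if (phase == 0) {
      if (cum >= emergence_gdd) {
        cum_emerg = cum;
        phase = 1;
      }
    } else if (phase == 1) {
      if (cum - cum_emerg >= p1) {
        cum_endjuv = cum;
        phase = 2;
        if (stage2_fixed) {
          double excess = daylength[t] - p2o;
          if (excess < 0.0) excess = 0.0;
          double dur = 4.0 + p2 * excess;
          ti_target = t + (int)std::ceil(dur);
        }
      }
    } else if (phase == 2) {
      bool initiated = false;
      if (stage2_fixed) {
        initiated = (t == ti_target);
      } else {
        double excess = daylength[t] - p2o;
        if (excess < 0.0) excess = 0.0;
        s2 += 1.0 / (4.0 + p2 * excess);
        initiated = (s2 >= 1.0 - 1e-12);
      }
      if (initiated) {
        cum_ti = cum;
        double sumdtt = sumdtt_from_endjuv ? (cum_ti - cum_endjuv)
                                           : (cum_ti - cum_emerg);
        double toln = sumdtt / (phint * 0.5) + 5.0;
        thresh = (toln + 0.5) * phint - sumdtt;
        phase = 3;
      }
    } else { // phase == 3
      if (cum - cum_ti >= thresh) return t + 1;
    }
  }
  return -1;
}

// Simulate anthesis dates for many parameter sets against one site
// environment. `params` columns: p1, p2, p2o, phint, tbase, topt.
// [[Rcpp::export]]
IntegerVector cpp_simulate_batch(NumericVector tmax, NumericVector tmin,
                                 NumericVector daylength,
                                 NumericMatrix params,
                                 double emergence_gdd,
                                 bool stage2_fixed,
                                 bool sumdtt_from_endjuv) {
  int H = tmax.size();
  if (tmin.size() != H || daylength.size() != H)
    stop("environment vectors must have equal length");
  if (params.ncol() != 6)
    stop("params must have 6 columns: p1, p2, p2o, phint, tbase, topt");
  int n = params.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = simulate_one(&tmax[0], &tmin[0], &daylength[0], H,
                          params(i, 0), params(i, 1), params(i, 2),
                          params(i, 3), params(i, 4), params(i, 5),
                          emergence_gdd, stage2_fixed, sumdtt_from_endjuv);
  }
  return out;
}

// First-best-found scan of a simulated-anthesis database for many lines.
//
// sim:  n_sets x n_siteyears integer matrix, -1 = simulation failure.
// obs:  n_lines x n_siteyears integer matrix, NA = missing observation.
// cols: 1-based site-year column indices defining the scored subset.
//
// For each line, rows are scanned in database generation order; the running
// best is replaced only on a strictly smaller integer SSE; ties with the
// final minimum are counted. Rows failing (-1) on any scored, observed
// site-year are ineligible. All tie logic is exact integer comparison.
// [[Rcpp::export]]
List cpp_scan_lines(IntegerMatrix sim, IntegerMatrix obs, IntegerVector cols) {
  int n = sim.nrow();
  int L = obs.nrow();
  int k = cols.size();
  if (obs.ncol() != sim.ncol())
    stop("obs and sim must have the same site-year columns");
  for (int j = 0; j < k; ++j)
    if (cols[j] < 1 || cols[j] > sim.ncol())
      stop("subset column index out of range");

  IntegerVector best_row(L), n_ties(L), n_obs(L);
  NumericVector sse_out(L);
  std::vector<int> use(k);

  for (int l = 0; l < L; ++l) {
    int m = 0;
    for (int j = 0; j < k; ++j) {
      int c = cols[j] - 1;
      if (obs(l, c) != NA_INTEGER) use[m++] = c;
    }
    n_obs[l] = m;
    if (m == 0) {
      best_row[l] = NA_INTEGER; sse_out[l] = NA_REAL; n_ties[l] = NA_INTEGER;
      continue;
    }
    long long best = -1;
    int idx = -1, ties = 0;
    for (int i = 0; i < n; ++i) {
      long long sse = 0;
      bool ok = true;
      for (int j = 0; j < m; ++j) {
        int s = sim(i, use[j]);
        if (s < 0) { ok = false; break; }
        long long d = (long long)s - (long long)obs(l, use[j]);
        sse += d * d;
      }
      if (!ok) continue;
      if (idx < 0 || sse < best) {
        best = sse; idx = i; ties = 0;
      } else if (sse == best) {
        ++ties;
      }
    }
    if (idx < 0) {
      best_row[l] = NA_INTEGER; sse_out[l] = NA_REAL; n_ties[l] = NA_INTEGER;
    } else {
      best_row[l] = idx + 1;
      sse_out[l] = (double)best;
      n_ties[l] = ties;
    }
  }
  return List::create(_["best_row"] = best_row, _["sse"] = sse_out,
                      _["n_ties"] = n_ties, _["n_obs"] = n_obs);
}
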