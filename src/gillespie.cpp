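#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Individual-based birth process on copy-number classes.
//
// State: counts of cells per ecDNA copy number k, split into two neutral
// lineage-marker groups (no-scar / scar) so chromosomal-scar frequency can be
// tracked alongside ecDNA. Cells with k = 0 divide at rate 1, cells with
// k >= 1 at rate s. A division doubles the mother's copies to 2k and splits
// them Binomial(2k, 1/2) between the daughters; the marker passes to both.
// Counts are doubles (populations can exceed .Machine$integer.max in
// principle) but are only ever incremented/decremented by 1.

static void record_state(List &records, int &ridx, double t,
                         const std::vector<double> &ns,
                         const std::vector<double> &sc) {
  size_t K = ns.size();
  while (K > 1 && ns[K - 1] == 0.0 && sc[K - 1] == 0.0) --K;
  NumericVector vns(K), vsc(K);
  for (size_t j = 0; j < K; ++j) { vns[j] = ns[j]; vsc[j] = sc[j]; }
  records[ridx++] = List::create(_["t"] = t,
                                 _["counts_noscar"] = vns,
                                 _["counts_scar"] = vsc);
}

// [[Rcpp::export]]
List cpp_gillespie(NumericVector init_noscar, NumericVector init_scar,
                   double s, double t_start, double t_end, double n_cap,
                   NumericVector record_times, NumericVector snapshot_sizes,
                   double max_events) {
  if (s <= 0) stop("selection coefficient s must be > 0");
  size_t K0 = std::max(init_noscar.size(), init_scar.size());
  if (K0 == 0) stop("empty initial state");
  std::vector<double> ns(K0, 0.0), sc(K0, 0.0);
  for (R_xlen_t j = 0; j < init_noscar.size(); ++j) ns[j] = init_noscar[j];
  for (R_xlen_t j = 0; j < init_scar.size(); ++j) sc[j] = init_scar[j];

  double N = 0.0;
  for (size_t j = 0; j < K0; ++j) {
    if (ns[j] < 0 || sc[j] < 0) stop("negative cell count in initial state");
    N += ns[j] + sc[j];
  }
  if (N < 1) stop("initial population is empty");

  double zero = ns[0] + sc[0];   // cells with no ecDNA
  double t = t_start;
  int nrt = record_times.size(), nss = snapshot_sizes.size();
  int rt = 0, st = 0, ridx = 0;
  List records(nrt + nss);
  double events = 0.0;
  std::string reason = "time";

  RNGScope scope;

  // snapshots already at/below the starting size
  while (st < nss && snapshot_sizes[st] <= N) {
    if (snapshot_sizes[st] == N) record_state(records, ridx, t, ns, sc);
    ++st;
  }
  while (rt < nrt && record_times[rt] <= t) {
    record_state(records, ridx, record_times[rt], ns, sc);
    ++rt;
  }

  for (;;) {
    if (N >= n_cap) { reason = "size"; break; }
    double npos = N - zero;
    double wtot = zero + s * npos;
    double dt = R::exp_rand() / wtot;
    double tnext = t + dt;

    // state is constant on (t, tnext): flush crossed recording times
    while (rt < nrt && record_times[rt] < tnext && record_times[rt] <= t_end) {
      record_state(records, ridx, record_times[rt], ns, sc);
      ++rt;
    }
    if (tnext > t_end) { t = t_end; reason = "time"; break; }
    t = tnext;
    if (++events > max_events) stop("event budget exceeded (max_events)");

    // pick the dividing cell proportional to rate
    size_t k = 0; bool scar_grp = false;
    double u = unif_rand() * wtot;
    if (u < zero) {
      k = 0;
      scar_grp = (unif_rand() * zero < sc[0]);
    } else {
      double target = unif_rand() * npos, acc = 0.0;
      bool found = false;
      for (size_t j = 1; j < ns.size() && !found; ++j) {
        acc += ns[j];
        if (acc > target) { k = j; scar_grp = false; found = true; }
      }
      for (size_t j = 1; j < sc.size() && !found; ++j) {
        acc += sc[j];
        if (acc > target) { k = j; scar_grp = true; found = true; }
      }
      if (!found) { // float roundoff fallback: last nonempty positive class
        for (size_t j = ns.size(); j-- > 1;) {
          if (sc[j] > 0) { k = j; scar_grp = true; break; }
          if (ns[j] > 0) { k = j; scar_grp = false; break; }
        }
        if (k == 0) stop("internal error: no ecDNA+ cell found");
      }
    }

    int n1 = (k > 0) ? (int) R::rbinom(2.0 * (double) k, 0.5) : 0;
    size_t n2 = 2 * k - (size_t) n1;
    size_t need = std::max((size_t) n1, n2);
    if (need >= ns.size()) { ns.resize(need + 1, 0.0); sc.resize(need + 1, 0.0); }
    std::vector<double> &v = scar_grp ? sc : ns;
    v[k] -= 1.0;
    v[(size_t) n1] += 1.0;
    v[n2] += 1.0;
    N += 1.0;
    if (k == 0) zero += 1.0;
    else zero += (n1 == 0 ? 1.0 : 0.0) + (n2 == 0 ? 1.0 : 0.0);

    while (st < nss && snapshot_sizes[st] <= N) {
      if (snapshot_sizes[st] == N) record_state(records, ridx, t, ns, sc);
      ++st;
    }
  }

  // flush remaining recording times only when the run ended by reaching t_end
  if (reason == "time") {
    while (rt < nrt && record_times[rt] <= t_end) {
      record_state(records, ridx, record_times[rt], ns, sc);
      ++rt;
    }
  }

  size_t K = ns.size();
  while (K > 1 && ns[K - 1] == 0.0 && sc[K - 1] == 0.0) --K;
  NumericVector out_ns(K), out_sc(K);
  for (size_t j = 0; j < K; ++j) { out_ns[j] = ns[j]; out_sc[j] = sc[j]; }

  List recs(ridx);
  for (int j = 0; j < ridx; ++j) recs[j] = records[j];

  return List::create(_["counts_noscar"] = out_ns,
                      _["counts_scar"] = out_sc,
                      _["t"] = t,
                      _["n"] = N,
                      _["n_events"] = events,
                      _["reason"] = reason,
                      _["records"] = recs);
}
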