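// Backward-in-time structured coalescent without migration: isolated demes
// whose lineages coalesce at rate k(k-1)/2 / scale_d, piecewise-constant
// per-deme scales (bottlenecks), and timed merge events (colonizations read
// backward). Scales are pair-coalescence timescales: 2N for a diploid deme of
// effective size N, N/2 for the haploid plastid genome of the same deme.
// All randomness goes through R's RNG so set.seed() on the R side gives
// bit-reproducible output.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Event {
  double time;
  int type;  // 0 = scale change, 1 = merge
  int deme;  // deme affected (scale change) or source deme (merge)
  double value;  // new scale (scale change) or target deme (merge)
};

struct Branch {
  std::vector<int> leaves;
  double length;
};

struct Genealogy {
  std::vector<Branch> branches;
  double tmrca;
  double total_length;
};

// One realized genealogy of all lineages. deme0: deme index per lineage.
Genealogy simulate_genealogy(const IntegerVector& deme0,
                             std::vector<double> scale,
                             const std::vector<Event>& events) {
  const int n = deme0.size();
  const int ndeme = scale.size();
  // active lineages: leaf sets and birth times
  std::vector<std::vector<int>> leafset(n);
  std::vector<double> birth(n, 0.0);
  std::vector<int> deme(n);
  for (int i = 0; i < n; ++i) {
    leafset[i].push_back(i);
    deme[i] = deme0[i];
  }
  std::vector<int> alive(n);
  for (int i = 0; i < n; ++i) alive[i] = i;

  Genealogy g;
  g.total_length = 0.0;
  double t = 0.0;
  size_t ev = 0;
  int guard = 0;

  while ((int)alive.size() > 1) {
    if (++guard > 100000000) stop("coalescent simulation failed to terminate");
    // per-deme pair counts
    std::vector<int> k(ndeme, 0);
    for (int id : alive) k[deme[id]]++;
    double total_rate = 0.0;
    std::vector<double> rate(ndeme, 0.0);
    for (int d = 0; d < ndeme; ++d) {
      if (k[d] > 1) {
        rate[d] = 0.5 * k[d] * (k[d] - 1) / scale[d];
        total_rate += rate[d];
      }
    }
    double next_ev = (ev < events.size()) ? events[ev].time : R_PosInf;
    if (total_rate <= 0.0) {
      if (!R_finite(next_ev))
        stop("zero-length genealogy: lineages remain in demes that never merge");
      t = next_ev;
    } else {
      double dt = R::rexp(1.0 / total_rate);
      if (t + dt >= next_ev) {
        t = next_ev;
      } else {
        t += dt;
        // choose deme proportional to rate
        double u = R::runif(0.0, total_rate);
        int d = 0;
        double acc = 0.0;
        for (; d < ndeme; ++d) {
          acc += rate[d];
          if (u <= acc) break;
        }
        if (d == ndeme) d = ndeme - 1;
        // choose an unordered pair uniformly within deme d
        std::vector<int> members;
        for (int id : alive) if (deme[id] == d) members.push_back(id);
        int kd = members.size();
        int i = (int)std::floor(R::runif(0.0, kd));
        if (i >= kd) i = kd - 1;
        int j = (int)std::floor(R::runif(0.0, kd - 1));
        if (j >= kd - 1) j = kd - 2;
        if (j >= i) ++j;
        int a = members[i], b = members[j];
        // record the two child branches
        Branch ba; ba.leaves = leafset[a]; ba.length = t - birth[a];
        Branch bb; bb.leaves = leafset[b]; bb.length = t - birth[b];
        g.total_length += ba.length + bb.length;
        g.branches.push_back(std::move(ba));
        g.branches.push_back(std::move(bb));
        // parent lineage replaces a; remove b
        std::vector<int> merged;
        merged.reserve(leafset[a].size() + leafset[b].size());
        merged.insert(merged.end(), leafset[a].begin(), leafset[a].end());
        merged.insert(merged.end(), leafset[b].begin(), leafset[b].end());
        leafset[a] = std::move(merged);
        birth[a] = t;
        alive.erase(std::find(alive.begin(), alive.end(), b));
        continue;
      }
    }
    // apply event at time t
    if (ev < events.size() && events[ev].time <= t) {
      const Event& e = events[ev];
      if (e.type == 0) {
        scale[e.deme] = e.value;
      } else {
        int target = (int)e.value;
        for (int id : alive) if (deme[id] == e.deme) deme[id] = target;
      }
      ++ev;
    }
  }
  g.tmrca = t;
  return g;
}

std::vector<Event> parse_events(const NumericMatrix& ev_mat) {
  std::vector<Event> events;
  for (int r = 0; r < ev_mat.nrow(); ++r) {
    Event e;
    e.time = ev_mat(r, 0);
    e.type = (int)ev_mat(r, 1);
    e.deme = (int)ev_mat(r, 2);
    e.value = ev_mat(r, 3);
    events.push_back(e);
  }
  std::stable_sort(events.begin(), events.end(),
                   [](const Event& a, const Event& b) { return a.time < b.time; });
  return events;
}

}  // namespace

// Simulate n_loci unlinked SNP loci: one mutation per locus placed on a
// branch with probability proportional to its length (SNP-mode convention).
// Returns a 0/1 matrix lineages x loci of derived-allele indicators.
// [[Rcpp::export(name = ".sim_snp_loci")]]
IntegerMatrix sim_snp_loci(IntegerVector deme0, NumericVector scales,
                           NumericMatrix ev_mat, int n_loci) {
  const int n = deme0.size();
  std::vector<double> sc(scales.begin(), scales.end());
  std::vector<Event> events = parse_events(ev_mat);
  IntegerMatrix out(n, n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = simulate_genealogy(deme0, sc, events);
    double u = R::runif(0.0, g.total_length);
    double acc = 0.0;
    size_t chosen = g.branches.size() - 1;
    for (size_t b = 0; b < g.branches.size(); ++b) {
      acc += g.branches[b].length;
      if (u <= acc) { chosen = b; break; }
    }
    for (int leaf : g.branches[chosen].leaves) out(leaf, l) = 1;
  }
  return out;
}

// One genealogy with its full branch decomposition, for mutation models that
// drop a variable number of mutations (plastid sequences).
// [[Rcpp::export(name = ".sim_genealogy_branches")]]
List sim_genealogy_branches(IntegerVector deme0, NumericVector scales,
                            NumericMatrix ev_mat) {
  std::vector<double> sc(scales.begin(), scales.end());
  Genealogy g = simulate_genealogy(deme0, sc, parse_events(ev_mat));
  int nb = g.branches.size();
  List leaves(nb);
  NumericVector lengths(nb);
  for (int b = 0; b < nb; ++b) {
    leaves[b] = IntegerVector(g.branches[b].leaves.begin(), g.branches[b].leaves.end());
    lengths[b] = g.branches[b].length;
  }
  return List::create(_["leaves"] = leaves, _["lengths"] = lengths,
                      _["tmrca"] = g.tmrca, _["total_length"] = g.total_length);
}

// TMRCA and total branch length over independent replicate genealogies.
// [[Rcpp::export(name = ".sim_genealogy_stats")]]
NumericMatrix sim_genealogy_stats(IntegerVector deme0, NumericVector scales,
                                  NumericMatrix ev_mat, int n_reps) {
  std::vector<double> sc(scales.begin(), scales.end());
  std::vector<Event> events = parse_events(ev_mat);
  NumericMatrix out(n_reps, 2);
  for (int r = 0; r < n_reps; ++r) {
    Genealogy g = simulate_genealogy(deme0, sc, events);
    out(r, 0) = g.tmrca;
    out(r, 1) = g.total_length;
  }
  colnames(out) = CharacterVector::create("tmrca", "total_length");
  return out;
}
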