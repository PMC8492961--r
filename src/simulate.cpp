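#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Discrete-time exclusion-process simulation of RNAPII transcription on a
// population of identical synthetic genes.  Positions are 1-based active-site
// coordinates; states: 0 = MOVING, 1 = STALLED, 2 = BACKTRACKED.
//
// Per step (dt minutes), downstream-first sweep:
//   MOVING:      stall with prob stall_rate*dt, else hop n ~ Pois(v*1000*dt),
//                truncated to stay >= footprint behind the nearest engaged
//                downstream polymerase (truncation == collision).
//   STALLED:     backtrack with prob backtrack_rate*dt, else resume with
//                prob resume_stall*dt.
//   BACKTRACKED: resume with prob resume_backtrack*dt.
// Collision resolution: upstream (always MOVING) becomes STALLED; a STALLED
// downstream partner is removed (collision termination); MOVING or
// BACKTRACKED downstream partners are unchanged.
// Initiation: prob min(initiation_rate*dt, 1) per gene per step, blocked
// while any engaged active site lies within footprint nt of position 1.
// Rate*dt uses R's RNG so runs are reproducible via set.seed() in R.

struct Pol {
  int pos;
  int state;
  int et;  // early-termination site, 0 = none
};

struct Params {
  double init_p;
  double hop_mean;
  int window1_end;
  double p_stall[2], p_bt[2], p_res_st[2], p_res_bt[2];
  double et_prob, et_mean;
  int L, fp;
};

struct Tally {
  int initiated = 0, completed = 0, early = 0, coll = 0;
};

static Params unpack_params(const List& par) {
  Params P;
  double dt = as<double>(par["dt"]);
  P.init_p = std::min(as<double>(par["initiation_rate"]) * dt, 1.0);
  P.hop_mean = as<double>(par["elongation_rate"]) * 1000.0 * dt;
  P.window1_end = as<int>(par["window1_end"]);
  P.p_stall[0] = as<double>(par["stall_rate_w1"]) * dt;
  P.p_stall[1] = as<double>(par["stall_rate_w2"]) * dt;
  P.p_bt[0] = as<double>(par["backtrack_rate_w1"]) * dt;
  P.p_bt[1] = as<double>(par["backtrack_rate_w2"]) * dt;
  P.p_res_st[0] = as<double>(par["resume_stall_w1"]) * dt;
  P.p_res_st[1] = as<double>(par["resume_stall_w2"]) * dt;
  P.p_res_bt[0] = as<double>(par["resume_backtrack_w1"]) * dt;
  P.p_res_bt[1] = as<double>(par["resume_backtrack_w2"]) * dt;
  P.et_prob = as<double>(par["early_term_prob"]);
  P.et_mean = as<double>(par["early_term_mean"]);
  P.L = as<int>(par["gene_length"]);
  P.fp = as<int>(par["footprint"]);
  for (int w = 0; w < 2; ++w) {
    if (P.p_stall[w] > 1.0 || P.p_res_bt[w] > 1.0 ||
        P.p_bt[w] + P.p_res_st[w] > 1.0)
      stop("per-step transition probability exceeds 1 after dt scaling; "
           "reduce dt or the stalling/backtracking/resumption rates");
  }
  return P;
}

static inline int draw_et_site(const Params& P) {
  int s;
  do {
    s = (int) R::rpois(P.et_mean);
  } while (s <= 0 || s > P.L);
  return s;
}

// One advance-and-transition sweep over a single gene, most downstream first.
static void advance_gene(std::vector<Pol>& g, const Params& P, Tally& t) {
  int n = (int) g.size();
  if (n == 0) return;
  std::vector<char> dead(n, 0);
  for (int i = 0; i < n; ++i) {
    if (dead[i]) continue;
    Pol& p = g[i];
    int w = (p.pos <= P.window1_end) ? 0 : 1;
    if (p.state == 0) {                       // MOVING
      double u = unif_rand();
      if (u < P.p_stall[w]) {
        p.state = 1;
      } else {
        int hop = (int) R::rpois(P.hop_mean);
        if (hop > 0) {
          int j = i - 1;
          while (j >= 0 && dead[j]) --j;
          long limit = (j >= 0) ? (long) g[j].pos - P.fp : LONG_MAX;
          long newpos = (long) p.pos + hop;
          bool coll = false;
          if (newpos > limit) { newpos = limit; coll = true; }
          if (p.et > 0 && newpos >= p.et) {
            dead[i] = 1; t.early++;
          } else if (newpos >= P.L) {
            dead[i] = 1; t.completed++;
          } else {
            p.pos = (int) newpos;
            if (coll) {
              p.state = 1;                    // upstream stalls
              if (j >= 0 && g[j].state == 1) { dead[j] = 1; t.coll++; }
            }
          }
        }
      }
    } else if (p.state == 1) {                // STALLED
      double u = unif_rand();
      if (u < P.p_bt[w]) p.state = 2;
      else if (u < P.p_bt[w] + P.p_res_st[w]) p.state = 0;
    } else {                                  // BACKTRACKED
      if (unif_rand() < P.p_res_bt[w]) p.state = 0;
    }
  }
  // compact out removed polymerases, preserving descending order
  int k = 0;
  for (int i = 0; i < n; ++i) if (!dead[i]) g[k++] = g[i];
  g.resize(k);
}

static void initiate_gene(std::vector<Pol>& g, const Params& P, Tally& t) {
  if (unif_rand() >= P.init_p) return;
  if (!g.empty() && g.back().pos - 1 < P.fp) return;  // position 1 occluded
  Pol p;
  p.pos = 1; p.state = 0; p.et = 0;
  if (P.et_prob > 0 && unif_rand() < P.et_prob) p.et = draw_et_site(P);
  g.push_back(p);
  t.initiated++;
}

static void check_gene_invariants(const std::vector<Pol>& g, const Tally& t,
                                  const Params& P, int step) {
  for (size_t i = 0; i + 1 < g.size(); ++i) {
    if (g[i].pos - g[i + 1].pos < P.fp)
      stop("footprint exclusion violated at step %d", step);
  }
  for (size_t i = 0; i < g.size(); ++i) {
    if (g[i].pos < 1 || g[i].pos > P.L || g[i].state < 0 || g[i].state > 2)
      stop("invalid polymerase position/state at step %d", step);
  }
  int engaged = (int) g.size();
  if (t.initiated != engaged + t.completed + t.early + t.coll)
    stop("polymerase conservation violated at step %d", step);
}

static List ensemble_to_list(const std::vector<std::vector<Pol> >& genes,
                             const std::vector<Tally>& tallies) {
  int total = 0;
  for (size_t g = 0; g < genes.size(); ++g) total += (int) genes[g].size();
  IntegerVector gi(total), pos(total), state(total), et(total);
  int k = 0;
  for (size_t g = 0; g < genes.size(); ++g)
    for (size_t i = 0; i < genes[g].size(); ++i) {
      gi[k] = (int) g + 1;
      pos[k] = genes[g][i].pos;
      state[k] = genes[g][i].state;
      et[k] = genes[g][i].et;
      ++k;
    }
  int n = (int) genes.size();
  IntegerVector initiated(n), completed(n), early(n), coll(n);
  for (int g = 0; g < n; ++g) {
    initiated[g] = tallies[g].initiated;
    completed[g] = tallies[g].completed;
    early[g] = tallies[g].early;
    coll[g] = tallies[g].coll;
  }
  return List::create(
    _["gene"] = gi, _["position"] = pos, _["state"] = state,
    _["early_term_site"] = et,
    _["initiated"] = initiated, _["completed"] = completed,
    _["early_terminated"] = early, _["collision_terminated"] = coll);
}

static List run_core(std::vector<std::vector<Pol> >& genes,
                     std::vector<Tally>& tallies,
                     const Params& P, int n_steps,
                     bool do_advance, bool do_init,
                     bool check_invariants, int avg_from) {
  int n_genes = (int) genes.size();
  double mov_w1 = 0, rest_w1 = 0, mov_w2 = 0, rest_w2 = 0;
  int avg_steps = 0;
  std::vector<double> avg_occ(P.L, 0.0);
  for (int s = 1; s <= n_steps; ++s) {
    for (int g = 0; g < n_genes; ++g) {
      if (do_advance) advance_gene(genes[g], P, tallies[g]);
      if (do_init) initiate_gene(genes[g], P, tallies[g]);
      if (check_invariants) check_gene_invariants(genes[g], tallies[g], P, s);
    }
    if (avg_from > 0 && s >= avg_from) {
      ++avg_steps;
      for (int g = 0; g < n_genes; ++g)
        for (size_t i = 0; i < genes[g].size(); ++i) {
          avg_occ[genes[g][i].pos - 1] += 1.0;
          bool w1 = genes[g][i].pos <= P.window1_end;
          bool mov = genes[g][i].state == 0;
          if (w1) { if (mov) mov_w1++; else rest_w1++; }
          else    { if (mov) mov_w2++; else rest_w2++; }
        }
    }
    if (s % 500 == 0) checkUserInterrupt();
  }
  NumericVector avg_occupancy(P.L);
  if (avg_steps > 0)
    for (int i = 0; i < P.L; ++i) avg_occupancy[i] = avg_occ[i] / avg_steps;
  // final-snapshot occupancy and window state counts
  IntegerVector occupancy(P.L);
  int f_mov_w1 = 0, f_rest_w1 = 0, f_mov_w2 = 0, f_rest_w2 = 0;
  for (int g = 0; g < n_genes; ++g)
    for (size_t i = 0; i < genes[g].size(); ++i) {
      occupancy[genes[g][i].pos - 1]++;
      bool w1 = genes[g][i].pos <= P.window1_end;
      bool mov = genes[g][i].state == 0;
      if (w1) { if (mov) f_mov_w1++; else f_rest_w1++; }
      else    { if (mov) f_mov_w2++; else f_rest_w2++; }
    }
  return List::create(
    _["occupancy"] = occupancy,
    _["avg_occupancy"] = avg_occupancy,
    _["ensemble"] = ensemble_to_list(genes, tallies),
    _["snapshot_counts"] = IntegerVector::create(
      _["moving_w1"] = f_mov_w1, _["other_w1"] = f_rest_w1,
      _["moving_w2"] = f_mov_w2, _["other_w2"] = f_rest_w2),
    _["averaged_counts"] = NumericVector::create(
      _["moving_w1"] = mov_w1, _["other_w1"] = rest_w1,
      _["moving_w2"] = mov_w2, _["other_w2"] = rest_w2,
      _["n_steps"] = (double) avg_steps));
}

// [[Rcpp::export]]
List cpp_simulate(List params, int population, int n_steps,
                  bool check_invariants, int avg_from) {
  Params P = unpack_params(params);
  std::vector<std::vector<Pol> > genes(population);
  std::vector<Tally> tallies(population);
  return run_core(genes, tallies, P, n_steps, true, true,
                  check_invariants, avg_from);
}

// [[Rcpp::export]]
List cpp_step_ensemble(IntegerVector gene, IntegerVector pos,
                       IntegerVector state, IntegerVector et,
                       IntegerVector initiated, IntegerVector completed,
                       IntegerVector early, IntegerVector coll,
                       List params, int n_genes, int n_steps,
                       bool do_advance, bool do_init, bool check_invariants) {
  Params P = unpack_params(params);
  std::vector<std::vector<Pol> > genes(n_genes);
  std::vector<Tally> tallies(n_genes);
  for (int g = 0; g < n_genes; ++g) {
    tallies[g].initiated = initiated[g];
    tallies[g].completed = completed[g];
    tallies[g].early = early[g];
    tallies[g].coll = coll[g];
  }
  for (int i = 0; i < gene.size(); ++i) {
    if (gene[i] < 1 || gene[i] > n_genes) stop("gene index out of range");
    Pol p;
    p.pos = pos[i]; p.state = state[i]; p.et = et[i];
    genes[gene[i] - 1].push_back(p);
  }
  // sort each gene most-downstream-first
  for (int g = 0; g < n_genes; ++g)
    std::sort(genes[g].begin(), genes[g].end(),
              [](const Pol& a, const Pol& b) { return a.pos > b.pos; });
  return run_core(genes, tallies, P, n_steps, do_advance, do_init,
                  check_invariants, 0);
}
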