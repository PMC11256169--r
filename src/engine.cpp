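// Lattice engine for the skin community agent-based model.
//
// The update loop follows fixed per-timestep semantics:
//   1. every nutrient field gains its replenish rate on every patch, then is
//      smoothed (each patch keeps (1-D) and spreads D equally over its 8
//      toroidal neighbours); the antibiotic field decays geometrically;
//   2. agents act in a freshly shuffled order: consume from their usable
//      carbon sources (total intake capped at uptake/(1+defect)), pay
//      maintenance, die on energy <= 0, die with probability p_kill when the
//      local antibiotic is at or above their MIC, divide when energy reaches
//      the division threshold and capacity allows, and random-walk to a
//      neighbour patch when local usable nutrient is below the forage
//      threshold.
//
// All randomness is drawn from a xoshiro256++ stream whose seed is taken from
// R's RNG at entry, so set.seed() at the R level fixes the whole trajectory.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// ---- fast deterministic RNG (seeded from R's stream) ----------------------

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_R() {
    // 53 random bits per draw are plenty to seed splitmix
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    x ^= ((uint64_t)(unif_rand() * 9007199254740992.0)) << 7;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int rint(int n) { return (int)(runif() * n); }  // uniform on 0..n-1
};

// ---- parameter bundles ----------------------------------------------------

struct SpeciesPar {
  double uptake, yield, maintenance, divthr, mic, defect;
  std::vector<int> sources;  // 0-based indices into the nutrient field list
};

std::vector<SpeciesPar> unpack_species(const List& species) {
  std::vector<SpeciesPar> out(species.size());
  for (int k = 0; k < species.size(); ++k) {
    List s = species[k];
    SpeciesPar p;
    p.uptake      = as<double>(s["uptake_rate"]);
    p.yield       = as<double>(s["yield"]);
    p.maintenance = as<double>(s["maintenance"]);
    p.divthr      = as<double>(s["division_threshold"]);
    p.mic         = as<double>(s["mic"]);
    p.defect      = as<double>(s["growth_defect"]);
    IntegerVector src = s["source_idx"];
    p.sources.assign(src.begin(), src.end());
    out[k] = p;
  }
  return out;
}

// small absolute tolerance on the division threshold guards against
// accumulated floating-point error in the energy ledger
const double DIV_TOL = 1e-9;

struct Engine {
  int rows, cols, capacity;
  double p_kill, ab_decay, forage_frac;
  std::vector<SpeciesPar> sp;
  std::vector<NumericMatrix> fields;
  NumericMatrix antibiotic;
  NumericVector replenish, diffusivity;
  NumericMatrix buf;

  std::vector<int> a_sp, a_row, a_col;
  std::vector<double> a_en;
  std::vector<char> a_dead;
  std::vector<int> occ;          // per-patch live-agent count
  std::vector<long> n_by_sp;
  std::vector<double> consumed;  // per-nutrient intake this step
  Xoshiro rng;

  int wrap_r(int r) const { return (r % rows + rows) % rows; }
  int wrap_c(int c) const { return (c % cols + cols) % cols; }
  int cell(int r, int c) const { return r + rows * c; }

  void fields_step() {
    for (size_t k = 0; k < fields.size(); ++k) {
      NumericMatrix& f = fields[k];
      double rep = replenish[k], D = diffusivity[k];
      int n = rows * cols;
      double* fv = REAL(f);
      if (rep > 0) for (int i = 0; i < n; ++i) fv[i] += rep;
      if (D > 0) {
        double* bv = REAL(buf);
        std::fill(bv, bv + n, 0.0);
        double share = D / 8.0;
        for (int c = 0; c < cols; ++c) {
          int cm = wrap_c(c - 1), cp = wrap_c(c + 1);
          for (int r = 0; r < rows; ++r) {
            double v = fv[cell(r, c)];
            if (v == 0.0) continue;
            int rm = wrap_r(r - 1), rp = wrap_r(r + 1);
            bv[cell(r, c)] += (1.0 - D) * v;
            double sv = share * v;
            bv[cell(rm, cm)] += sv; bv[cell(rm, c)] += sv; bv[cell(rm, cp)] += sv;
            bv[cell(r,  cm)] += sv;                        bv[cell(r,  cp)] += sv;
            bv[cell(rp, cm)] += sv; bv[cell(rp, c)] += sv; bv[cell(rp, cp)] += sv;
          }
        }
        std::copy(bv, bv + n, fv);
      }
    }
    if (ab_decay < 1.0) {
      double* av = REAL(antibiotic);
      int n = rows * cols;
      for (int i = 0; i < n; ++i) av[i] *= ab_decay;
    }
  }

  // one agent's turn; may append offspring and mutate fields/occupancy
  void agent_turn(size_t i) {
    const SpeciesPar& p = sp[a_sp[i]];
    int r = a_row[i], c = a_col[i];
    int here = cell(r, c);

    // 1. consume, total intake capped at the defect-scaled uptake
    double cap = p.uptake / (1.0 + p.defect);
    double rem = cap, got = 0.0;
    for (int f : p.sources) {
      if (rem <= 0) break;
      double* fv = REAL(fields[f]);
      double take = std::min(rem, fv[here]);
      if (take > 0) {
        fv[here] -= take;
        rem -= take;
        got += take;
        consumed[f] += take;
      }
    }
    // 2. energy ledger
    a_en[i] += p.yield * got - p.maintenance;
    // 3. starvation
    if (a_en[i] <= 0) { kill(i, here); return; }
    // 4. antibiotic kill rule (threshold on local concentration)
    if (REAL(antibiotic)[here] >= p.mic && p_kill > 0 && rng.runif() < p_kill) {
      kill(i, here);
      return;
    }
    // 5. division
    if (a_en[i] >= p.divthr - DIV_TOL) {
      int tr = -1, tc = -1;
      if (occ[here] < capacity) { tr = r; tc = c; }
      else {
        int opts_r[8], opts_c[8], nopt = 0;
        for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int nr = wrap_r(r + dr), nc = wrap_c(c + dc);
          if (occ[cell(nr, nc)] < capacity) { opts_r[nopt] = nr; opts_c[nopt] = nc; ++nopt; }
        }
        if (nopt > 0) { int j = rng.rint(nopt); tr = opts_r[j]; tc = opts_c[j]; }
      }
      if (tr >= 0) {  // else: division deferred, energy retained
        a_en[i] *= 0.5;
        a_sp.push_back(a_sp[i]); a_row.push_back(tr); a_col.push_back(tc);
        a_en.push_back(a_en[i]); a_dead.push_back(0);
        occ[cell(tr, tc)]++;
        n_by_sp[a_sp[i]]++;
      }
    }
    // 6. forage movement when the patch has run low on usable nutrient
    double usable = 0.0;
    for (int f : p.sources) usable += REAL(fields[f])[here];
    if (usable < forage_frac * p.uptake) {
      int dr = rng.rint(3) - 1, dc = rng.rint(3) - 1;
      if (dr != 0 || dc != 0) {
        int nr = wrap_r(r + dr), nc = wrap_c(c + dc);
        int there = cell(nr, nc);
        if (occ[there] < capacity) {
          occ[here]--; occ[there]++;
          a_row[i] = nr; a_col[i] = nc;
        }
      }
    }
  }

  void kill(size_t i, int here) {
    a_dead[i] = 1;
    occ[here]--;
    n_by_sp[a_sp[i]]--;
  }

  void compact() {
    size_t j = 0, n = a_sp.size();
    for (size_t i = 0; i < n; ++i) {
      if (!a_dead[i]) {
        if (j != i) {
          a_sp[j] = a_sp[i]; a_row[j] = a_row[i];
          a_col[j] = a_col[i]; a_en[j] = a_en[i];
        }
        ++j;
      }
    }
    a_sp.resize(j); a_row.resize(j); a_col.resize(j);
    a_en.resize(j); a_dead.assign(j, 0);
  }
};

Engine make_engine(List nutrient_fields, NumericMatrix antibiotic,
                   NumericVector replenish, NumericVector diffusivity,
                   List species,
                   IntegerVector agent_species, IntegerVector agent_row,
                   IntegerVector agent_col, NumericVector agent_energy,
                   int capacity, double p_kill, double ab_decay,
                   double forage_frac) {
  Engine e;
  e.antibiotic = clone(antibiotic);
  e.rows = e.antibiotic.nrow(); e.cols = e.antibiotic.ncol();
  e.capacity = capacity; e.p_kill = p_kill;
  e.ab_decay = ab_decay; e.forage_frac = forage_frac;
  e.replenish = replenish; e.diffusivity = diffusivity;
  for (int k = 0; k < nutrient_fields.size(); ++k)
    e.fields.push_back(clone(as<NumericMatrix>(nutrient_fields[k])));
  e.buf = NumericMatrix(e.rows, e.cols);
  e.sp = unpack_species(species);

  int n = agent_species.size();
  e.a_sp.resize(n); e.a_row.resize(n); e.a_col.resize(n);
  e.a_en.resize(n); e.a_dead.assign(n, 0);
  e.occ.assign(e.rows * e.cols, 0);
  e.n_by_sp.assign(e.sp.size(), 0);
  e.consumed.assign(e.fields.size(), 0.0);
  for (int i = 0; i < n; ++i) {
    e.a_sp[i] = agent_species[i] - 1;        // R side is 1-based
    e.a_row[i] = agent_row[i] - 1;
    e.a_col[i] = agent_col[i] - 1;
    e.a_en[i] = agent_energy[i];
    e.occ[e.cell(e.a_row[i], e.a_col[i])]++;
    e.n_by_sp[e.a_sp[i]]++;
  }
  e.rng.seed_from_R();
  return e;
}

List engine_result(Engine& e, IntegerMatrix counts, NumericMatrix consumed,
                   int steps_done) {
  int n = e.a_sp.size();
  IntegerVector osp(n), orow(n), ocol(n);
  NumericVector oen(n);
  for (int i = 0; i < n; ++i) {
    osp[i] = e.a_sp[i] + 1; orow[i] = e.a_row[i] + 1;
    ocol[i] = e.a_col[i] + 1; oen[i] = e.a_en[i];
  }
  List flds(e.fields.size());
  for (size_t k = 0; k < e.fields.size(); ++k) flds[k] = e.fields[k];
  return List::create(
    _["fields"] = flds, _["antibiotic"] = e.antibiotic,
    _["species"] = osp, _["row"] = orow, _["col"] = ocol, _["energy"] = oen,
    _["counts"] = counts, _["consumed"] = consumed,
    _["steps_done"] = steps_done);
}

}  // namespace

// Run n_steps full timesteps.  If watch_species > 0 (1-based), stop after the
// first step at which that species' live count is zero.
// [[Rcpp::export]]
List cpp_run(List nutrient_fields, NumericMatrix antibiotic,
             NumericVector replenish, NumericVector diffusivity,
             List species,
             IntegerVector agent_species, IntegerVector agent_row,
             IntegerVector agent_col, NumericVector agent_energy,
             int capacity, double p_kill, double ab_decay, double forage_frac,
             int n_steps, int watch_species) {
  Engine e = make_engine(nutrient_fields, antibiotic, replenish, diffusivity,
                         species, agent_species, agent_row, agent_col,
                         agent_energy, capacity, p_kill, ab_decay, forage_frac);
  int nsp = e.sp.size(), nnut = e.fields.size();
  IntegerMatrix counts(n_steps, nsp);
  NumericMatrix consumed(n_steps, nnut);
  std::vector<size_t> order;
  int steps_done = 0;

  for (int t = 0; t < n_steps; ++t) {
    e.fields_step();
    std::fill(e.consumed.begin(), e.consumed.end(), 0.0);
    size_t n = e.a_sp.size();
    order.resize(n);
    for (size_t i = 0; i < n; ++i) order[i] = i;
    for (size_t i = n; i > 1; --i) {        // Fisher-Yates
      size_t j = e.rng.rint((int)i);
      std::swap(order[i - 1], order[j]);
    }
    for (size_t i = 0; i < n; ++i) e.agent_turn(order[i]);
    e.compact();
    for (int k = 0; k < nsp; ++k) counts(t, k) = (int)e.n_by_sp[k];
    for (int k = 0; k < nnut; ++k) consumed(t, k) = e.consumed[k];
    ++steps_done;
    if (watch_species > 0 && e.n_by_sp[watch_species - 1] == 0) break;
  }
  if (steps_done < n_steps) {
    counts = counts(Range(0, steps_done - 1), Range(0, nsp - 1));
    consumed = consumed(Range(0, steps_done - 1), Range(0, nnut - 1));
  }
  return engine_result(e, counts, consumed, steps_done);
}

// Field update only (replenish + diffusion + antibiotic decay); no agents,
// no clock advance.  Shares the exact code path used inside cpp_run.
// [[Rcpp::export]]
List cpp_fields_update(List nutrient_fields, NumericMatrix antibiotic,
                       NumericVector replenish, NumericVector diffusivity,
                       double ab_decay) {
  Engine e = make_engine(nutrient_fields, antibiotic, replenish, diffusivity,
                         List::create(), IntegerVector(), IntegerVector(),
                         IntegerVector(), NumericVector(),
                         1, 0.0, ab_decay, 0.0);
  e.fields_step();
  List flds(e.fields.size());
  for (size_t k = 0; k < e.fields.size(); ++k) flds[k] = e.fields[k];
  return List::create(_["fields"] = flds, _["antibiotic"] = e.antibiotic);
}

// Run the per-agent rule for a single agent (1-based index); fields are NOT
// replenished and the clock does not advance.  Used by agent_step() so unit
// tests exercise the identical rule implementation the full loop uses.
// [[Rcpp::export]]
List cpp_agent_step(List nutrient_fields, NumericMatrix antibiotic,
                    NumericVector replenish, NumericVector diffusivity,
                    List species,
                    IntegerVector agent_species, IntegerVector agent_row,
                    IntegerVector agent_col, NumericVector agent_energy,
                    int capacity, double p_kill, double ab_decay,
                    double forage_frac, int index) {
  Engine e = make_engine(nutrient_fields, antibiotic, replenish, diffusivity,
                         species, agent_species, agent_row, agent_col,
                         agent_energy, capacity, p_kill, ab_decay, forage_frac);
  std::fill(e.consumed.begin(), e.consumed.end(), 0.0);
  size_t n_before = e.a_sp.size();
  e.agent_turn((size_t)(index - 1));
  bool survives = !e.a_dead[index - 1];
  bool divided = e.a_sp.size() > n_before;
  e.compact();
  int nsp = e.sp.size(), nnut = e.fields.size();
  IntegerMatrix counts(1, nsp);
  NumericMatrix consumed(1, nnut);
  for (int k = 0; k < nsp; ++k) counts(0, k) = (int)e.n_by_sp[k];
  for (int k = 0; k < nnut; ++k) consumed(0, k) = e.consumed[k];
  List out = engine_result(e, counts, consumed, 0);
  out["survives"] = survives;
  out["divided"] = divided;
  return out;
}
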