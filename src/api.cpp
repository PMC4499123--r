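// Rcpp interface: parameter loading, structure/energy utilities, move
// enumeration, flux tree handles, the Gillespie engine, the naive
// lockstep oracle and exhaustive enumeration.
#include <Rcpp.h>

#include <fstream>
#include <sstream>

#include "rnakin.h"

using namespace Rcpp;
using namespace rnakin;

// ---------------------------------------------------------------------
// parameters
// ---------------------------------------------------------------------

namespace {

int parse_int(const std::string& tok) {
  int sign = 1;
  size_t k = 0;
  if (!tok.empty() && (tok[0] == '-' || tok[0] == '+')) {
    sign = tok[0] == '-' ? -1 : 1;
    k = 1;
  }
  long v = 0;
  for (; k < tok.size(); ++k) {
    if (tok[k] < '0' || tok[k] > '9')
      throw std::runtime_error("bad integer token '" + tok + "'");
    v = v * 10 + (tok[k] - '0');
  }
  return (int)(sign * v);
}

std::vector<int> need_ints(std::istream& in, size_t n, const std::string& w) {
  std::vector<int> out;
  out.reserve(n);
  std::string tok;
  while (out.size() < n && in >> tok) {
    if (tok[0] == '#') {
      std::string rest;
      std::getline(in, rest);
      continue;
    }
    out.push_back(parse_int(tok));
  }
  if (out.size() != n)
    throw std::runtime_error("parameter section '" + w + "' truncated");
  return out;
}

void parse_param_file(const std::string& path, EnergyParams* p) {
  std::ifstream in(path);
  if (!in) throw std::runtime_error("cannot open parameter file " + path);
  std::string line;
  while (std::getline(in, line)) {
    if (line.empty() || line[0] == '#') continue;
    if (line[0] != '@') continue;
    std::istringstream hd(line.substr(1));
    std::string name;
    hd >> name;
    std::vector<int> dims;
    int d;
    size_t total = 1;
    while (hd >> d) { dims.push_back(d); total *= (size_t)d; }
    if (name == "tetraloops" || name == "triloops" || name == "hexaloops") {
      int nrow = dims.empty() ? 0 : dims[0];
      std::vector<std::pair<std::string, int>> rows;
      for (int k = 0; k < nrow; ++k) {
        std::string sq;
        int en;
        in >> sq >> en;
        rows.push_back({sq, en});
      }
      if (name == "tetraloops") p->tetraloops = rows;
      else if (name == "triloops") p->triloops = rows;
      else p->hexaloops = rows;
      continue;
    }
    std::vector<int> v = need_ints(in, total, name);
    if (name == "stack") p->stack = v;
    else if (name == "mismatch_hairpin") p->mm_hairpin = v;
    else if (name == "mismatch_internal") p->mm_interior = v;
    else if (name == "mismatch_internal_1n") p->mm_int_1n = v;
    else if (name == "mismatch_internal_23") p->mm_int_23 = v;
    else if (name == "mismatch_multi") p->mm_multi = v;
    else if (name == "mismatch_exterior") p->mm_ext = v;
    else if (name == "dangle5") p->dangle5 = v;
    else if (name == "dangle3") p->dangle3 = v;
    else if (name == "int11") p->int11 = v;
    else if (name == "int21") p->int21 = v;
    else if (name == "int22") p->int22 = v;
    else if (name == "hairpin") p->hairpin_len = v;
    else if (name == "bulge") p->bulge_len = v;
    else if (name == "internal") p->interior_len = v;
    else if (name == "ninio") { p->ninio_m = v[0]; p->ninio_max = v[1]; }
    else if (name == "multiloop") {
      p->ml_unpaired = v[0];
      p->ml_offset = v[1];
      p->ml_branch = v[2];
    } else if (name == "misc") p->terminal_au = v[0];
    else if (name == "lxc_times_1000") p->lxc = v[0] / 1000.0;
    // unknown sections are ignored
  }
}

RateParams rates_from_list(List rp) {
  RateParams out;
  out.k0 = as<double>(rp["k0"]);
  out.k0n = as<double>(rp["k0_nuc"]);
  out.alpha = as<double>(rp["alpha"]);
  return out;
}

Move move_from_list(List mv) {
  Move m;
  m.kind = as<int>(mv["kind"]);
  m.ri = as<int>(mv["ri"]);
  m.rj = as<int>(mv["rj"]);
  m.ai = as<int>(mv["ai"]);
  m.aj = as<int>(mv["aj"]);
  if (mv.containsElementNamed("nucn")) m.nucn = as<int>(mv["nucn"]);
  return m;
}

DataFrame moves_to_df(const std::vector<Move>& mv,
                      const std::vector<std::pair<int, int>>* owners) {
  int n = (int)mv.size();
  IntegerVector kind(n), ri(n), rj(n), ai(n), aj(n), nucn(n);
  NumericVector dG(n), rate(n);
  IntegerVector oi(n), oj(n);
  for (int k = 0; k < n; ++k) {
    kind[k] = mv[k].kind;
    ri[k] = mv[k].ri; rj[k] = mv[k].rj;
    ai[k] = mv[k].ai; aj[k] = mv[k].aj;
    nucn[k] = mv[k].nucn;
    dG[k] = mv[k].dG / 100.0;  // kcal/mol
    rate[k] = mv[k].rate;
    if (owners) { oi[k] = (*owners)[k].first; oj[k] = (*owners)[k].second; }
  }
  if (owners)
    return DataFrame::create(_["kind"] = kind, _["ri"] = ri, _["rj"] = rj,
                             _["ai"] = ai, _["aj"] = aj, _["nucn"] = nucn,
                             _["dG"] = dG, _["rate"] = rate,
                             _["owner_i"] = oi, _["owner_j"] = oj);
  return DataFrame::create(_["kind"] = kind, _["ri"] = ri, _["rj"] = rj,
                           _["ai"] = ai, _["aj"] = aj, _["nucn"] = nucn,
                           _["dG"] = dG, _["rate"] = rate);
}

}  // namespace

// [[Rcpp::export]]
SEXP rk_params_load(std::string loops_path, std::string int22_path,
                    double temperature, bool ml_log) {
  XPtr<EnergyParams> p(new EnergyParams(), true);
  parse_param_file(loops_path, p);
  parse_param_file(int22_path, p);
  p->ml_log = ml_log;
  p->set_temperature(temperature);
  p->index_special_loops();
  if (p->stack.size() != 49 || p->int22.size() != 9216)
    stop("parameter tables incomplete");
  return p;
}

// [[Rcpp::export]]
List rk_params_info(SEXP pp) {
  XPtr<EnergyParams> p(pp);
  return List::create(_["temperature"] = p->temperature,
                      _["rt"] = p->rt_dc / 100.0,
                      _["ml_log"] = p->ml_log,
                      _["terminal_au"] = p->terminal_au / 100.0,
                      _["n_tetraloops"] = (int)p->tetraloops.size());
}

// ---------------------------------------------------------------------
// structures
// ---------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector rk_parse_db(std::string seq, std::string db) {
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  return IntegerVector(pt.begin() + 1, pt.end());
}

// [[Rcpp::export]]
std::string rk_write_db(IntegerVector pairs) {
  PairTable pt(pairs.size() + 1, 0);
  for (int k = 0; k < pairs.size(); ++k) pt[k + 1] = pairs[k];
  return write_dot_bracket(pt);
}

// [[Rcpp::export]]
std::string rk_canonical_seq(std::string seq) {
  return decode_seq(encode_seq(seq));
}

// [[Rcpp::export]]
List rk_decompose(std::string seq, std::string db) {
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  auto elems = decompose_all(s, pt);
  List out(elems.size());
  for (size_t k = 0; k < elems.size(); ++k) {
    const Element& e = elems[k];
    IntegerMatrix br(e.branches.size(), 2);
    for (size_t b = 0; b < e.branches.size(); ++b) {
      br(b, 0) = e.branches[b].first;
      br(b, 1) = e.branches[b].second;
    }
    out[k] = List::create(
        _["i"] = e.ext ? (int)s.size() - 1 : e.i,
        _["j"] = e.ext ? 1 : e.j, _["external"] = e.ext,
        _["degree"] = e.degree,
        _["members"] = IntegerVector(e.ss.begin(), e.ss.end()),
        _["branches"] = br, _["helix_outer_i"] = e.hp,
        _["helix_outer_j"] = e.hq, _["helix_length"] = e.hlen);
  }
  return out;
}

// [[Rcpp::export]]
double rk_structure_energy(std::string seq, std::string db, SEXP pp) {
  XPtr<EnergyParams> p(pp);
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  return structure_energy_dc(s, pt, *p) / 100.0;
}

// [[Rcpp::export]]
NumericVector rk_structure_energies(std::string seq,
                                    std::vector<std::string> dbs, SEXP pp) {
  XPtr<EnergyParams> p(pp);
  Seq s = encode_seq(seq);
  NumericVector out(dbs.size());
  for (size_t k = 0; k < dbs.size(); ++k) {
    PairTable pt = parse_dot_bracket(s, dbs[k]);
    out[k] = structure_energy_dc(s, pt, *p) / 100.0;
  }
  return out;
}

// [[Rcpp::export]]
List rk_loop_energies(std::string seq, std::string db, SEXP pp) {
  // per loop element: face energy of the labelled face plus the stacks of
  // the closing helix; these sum to the structure energy
  XPtr<EnergyParams> p(pp);
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  auto elems = decompose_all(s, pt);
  int n = (int)elems.size();
  IntegerVector li(n), lj(n), deg(n);
  LogicalVector ext(n);
  NumericVector en(n);
  for (int k = 0; k < n; ++k) {
    const Element& e = elems[k];
    double v = face_energy(s, pt, e.ext ? 0 : e.i, e.ext ? 0 : e.j, *p);
    // stacks of the closing helix belong to this element
    for (int t = 0; t < e.hlen - 1; ++t)
      v += face_energy(s, pt, e.hp + t, e.hq - t, *p);
    li[k] = e.ext ? (int)s.size() - 1 : e.i;
    lj[k] = e.ext ? 1 : e.j;
    deg[k] = e.degree;
    ext[k] = e.ext;
    en[k] = v / 100.0;
  }
  return List::create(_["i"] = li, _["j"] = lj, _["external"] = ext,
                      _["degree"] = deg, _["energy"] = en);
}

// ---------------------------------------------------------------------
// moves
// ---------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame rk_loop_moves(std::string seq, std::string db, SEXP pp, List rates) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  auto elems = decompose_all(s, pt);
  std::vector<Move> all;
  std::vector<std::pair<int, int>> owners;
  for (auto& e : elems) {
    enumerate_element_moves(s, pt, e, *p, rp);
    for (auto& m : e.moves) {
      all.push_back(m);
      owners.push_back({e.ext ? (int)s.size() - 1 : e.i, e.ext ? 1 : e.j});
    }
  }
  return moves_to_df(all, &owners);
}

// [[Rcpp::export]]
DataFrame rk_bruteforce_moves(std::string seq, std::string db, SEXP pp,
                              List rates) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  auto mv = bruteforce_moves(s, pt, *p, rp);
  return moves_to_df(mv, nullptr);
}

// [[Rcpp::export]]
double rk_move_dG(std::string seq, std::string db, List mv, SEXP pp) {
  XPtr<EnergyParams> p(pp);
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  Move m = move_from_list(mv);
  return move_dG_local(s, pt, m, *p) / 100.0;
}

// [[Rcpp::export]]
List rk_apply_move(std::string seq, std::string db, List mv) {
  Seq s = encode_seq(seq);
  PairTable pt = parse_dot_bracket(s, db);
  Move m = move_from_list(mv);
  if (m.ri) {
    if (pt[m.ri] != m.rj) stop("move removes a pair absent from the state");
    pt[m.ri] = 0;
    pt[m.rj] = 0;
  }
  if (m.ai) {
    if (pt[m.ai] != 0 || pt[m.aj] != 0)
      stop("move adds a pair onto occupied positions");
    pt[m.ai] = m.aj;
    pt[m.aj] = m.ai;
  }
  validate_structure(s, pt);
  return List::create(_["db"] = write_dot_bracket(pt));
}

// [[Rcpp::export]]
double rk_kawasaki_rate(double dG_kcal, double k0, double beta) {
  RateParams rp;
  rp.k0 = k0;
  return kawasaki_rate(dG_kcal * 100.0, rp, beta / 100.0);
}

// ---------------------------------------------------------------------
// flux tree handle
// ---------------------------------------------------------------------

namespace {
struct TreeHandle {
  FluxTree t;
  int n;
  TreeHandle(int n_) : t(std::max(1, n_)), n(n_) {}
};
}  // namespace

// [[Rcpp::export]]
SEXP rk_ftree_build(NumericVector values) {
  XPtr<TreeHandle> h(new TreeHandle((int)values.size()), true);
  for (int k = 0; k < values.size(); ++k) {
    if (values[k] < 0) stop("negative flux in slot %d", k + 1);
    h->t.update(k, values[k]);
  }
  return h;
}

// [[Rcpp::export]]
List rk_ftree_update(SEXP hp, int slot, double value) {
  XPtr<TreeHandle> h(hp);
  if (slot < 1 || slot > h->n) stop("dead or invalid slot %d", slot);
  int nodes = h->t.update(slot - 1, value);
  return List::create(_["nodes_touched"] = nodes, _["root"] = h->t.root());
}

// [[Rcpp::export]]
double rk_ftree_root(SEXP hp) {
  XPtr<TreeHandle> h(hp);
  return h->t.root();
}

// [[Rcpp::export]]
NumericVector rk_ftree_leaves(SEXP hp) {
  XPtr<TreeHandle> h(hp);
  NumericVector out(h->n);
  for (int k = 0; k < h->n; ++k) out[k] = h->t.leaf(k);
  return out;
}

// [[Rcpp::export]]
List rk_ftree_select(SEXP hp, double target) {
  XPtr<TreeHandle> h(hp);
  int nodes = 0;
  double rem = 0;
  int slot = h->t.select(target, &rem, &nodes);
  return List::create(_["slot"] = slot + 1, _["remainder"] = rem,
                      _["nodes_touched"] = nodes);
}

// [[Rcpp::export]]
int rk_ftree_capacity(SEXP hp) {
  XPtr<TreeHandle> h(hp);
  return h->t.capacity();
}

// ---------------------------------------------------------------------
// engine
// ---------------------------------------------------------------------

namespace {

List stats_to_list(const StepStats& st) {
  return List::create(
      _["steps"] = (double)st.steps,
      _["max_rebuilt_preexisting"] = st.max_rebuilt_preexisting,
      _["total_rebuilt"] = (double)st.total_rebuilt,
      _["total_refresh_ops"] = (double)st.total_refresh_ops,
      _["max_tree_nodes_update"] = st.max_tree_nodes_update,
      _["max_tree_nodes_select"] = st.max_tree_nodes_select,
      _["max_affected_total"] = st.max_affected_total);
}

}  // namespace

// [[Rcpp::export]]
List rk_simulate(std::string seq, std::string init_db, SEXP pp, List rates,
                 double t_max, std::string target_db, double seed,
                 double max_steps, bool record_events, bool collect_tau) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable init = parse_dot_bracket(s, init_db);
  PairTable target;
  bool has_target = !target_db.empty();
  if (has_target) target = parse_dot_bracket(s, target_db);

  Engine eng(s, init, *p, rp, (std::uint64_t)seed);
  std::vector<double> times, energies, tauphi;
  std::vector<std::string> dbs;
  auto record = [&]() {
    times.push_back(eng.time());
    dbs.push_back(write_dot_bracket(eng.pair_table()));
    energies.push_back(eng.energy_dc() / 100.0);
  };
  record();
  std::string reason = "max_time";
  double fpt = NA_REAL;
  if (has_target && eng.pair_table() == target) {
    reason = "target_reached";
    fpt = 0.0;
  } else {
    long long nstep = 0;
    std::string at_tmax;
    double e_at_tmax = 0.0;
    while (eng.time() < t_max) {
      double phi = eng.total_flux();
      double tau;
      at_tmax = write_dot_bracket(eng.pair_table());
      e_at_tmax = eng.energy_dc();
      if (!eng.step(&tau, nullptr)) { reason = "no_moves"; break; }
      if (collect_tau) tauphi.push_back(tau * phi);
      if (eng.time() >= t_max) {
        // the state at t_max is the one whose holding interval covers it
        times.push_back(t_max);
        dbs.push_back(at_tmax);
        energies.push_back(e_at_tmax / 100.0);
        return List::create(
            _["time"] = times, _["db"] = dbs, _["energy"] = energies,
            _["final_db"] = at_tmax, _["t_final"] = t_max,
            _["reason"] = reason, _["fpt"] = fpt, _["tau_phi"] = tauphi,
            _["stats"] = stats_to_list(eng.stats()),
            _["final_energy"] = e_at_tmax / 100.0,
            _["n_loops"] = eng.n_elements());
      }
      if (record_events) record();
      if (has_target && eng.pair_table() == target) {
        reason = "target_reached";
        fpt = eng.time();
        break;
      }
      if (++nstep >= (long long)max_steps) { reason = "max_steps"; break; }
      if ((nstep & 0xffff) == 0) Rcpp::checkUserInterrupt();
    }
  }
  if (!record_events) record();
  return List::create(
      _["time"] = times, _["db"] = dbs, _["energy"] = energies,
      _["final_db"] = write_dot_bracket(eng.pair_table()),
      _["t_final"] = eng.time(), _["reason"] = reason, _["fpt"] = fpt,
      _["tau_phi"] = tauphi, _["stats"] = stats_to_list(eng.stats()),
      _["final_energy"] = eng.energy_dc() / 100.0,
      _["n_loops"] = eng.n_elements());
}

// [[Rcpp::export]]
List rk_ensemble_final(std::string seq, std::vector<std::string> init_dbs,
                       SEXP pp, List rates, double t_max, int n_traj,
                       double seed, double max_steps) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  std::vector<PairTable> inits;
  for (auto& d : init_dbs) inits.push_back(parse_dot_bracket(s, d));
  if (inits.empty()) stop("no initial structures");
  std::vector<std::string> finals(n_traj);
  std::mt19937_64 seeder((std::uint64_t)seed);
  for (int k = 0; k < n_traj; ++k) {
    Engine eng(s, inits[k % inits.size()], *p, rp, seeder());
    double tau;
    long long nstep = 0;
    std::string holding = write_dot_bracket(eng.pair_table());
    while (eng.time() < t_max && nstep < (long long)max_steps) {
      holding = write_dot_bracket(eng.pair_table());
      if (!eng.step(&tau, nullptr)) { holding = write_dot_bracket(eng.pair_table()); break; }
      ++nstep;
    }
    // the state occupied at t_max is the one whose holding interval
    // covers it (the pre-crossing structure), not the post-jump state
    finals[k] = eng.time() >= t_max ? holding
                                    : write_dot_bracket(eng.pair_table());
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["final_db"] = finals);
}

// [[Rcpp::export]]
List rk_first_passage(std::string seq, std::string target_db, SEXP pp,
                      List rates, double t_cap, int n_traj, double seed,
                      double max_steps) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable init(s.size(), 0);  // open chain
  PairTable target = parse_dot_bracket(s, target_db);
  NumericVector t_out(n_traj);
  LogicalVector censored(n_traj);
  std::mt19937_64 seeder((std::uint64_t)seed);
  for (int k = 0; k < n_traj; ++k) {
    Engine eng(s, init, *p, rp, seeder());
    double tau;
    long long nstep = 0;
    bool hit = (init == target);
    while (!hit && eng.time() < t_cap && nstep < (long long)max_steps) {
      if (!eng.step(&tau, nullptr)) break;
      ++nstep;
      if (eng.pair_table() == target) hit = true;
    }
    t_out[k] = hit ? eng.time() : NA_REAL;
    censored[k] = !hit;
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = t_out, _["censored"] = censored);
}

// population occupancy of tracked structures on a time grid, computed
// trajectory-by-trajectory in C++ to keep memory flat
// [[Rcpp::export]]
NumericMatrix rk_population_counts(std::string seq, std::string init_db,
                                   SEXP pp, List rates, NumericVector grid,
                                   std::vector<std::string> tracked,
                                   int n_traj, double seed,
                                   double max_steps) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable init = parse_dot_bracket(s, init_db);
  std::vector<PairTable> tr;
  for (auto& d : tracked) tr.push_back(parse_dot_bracket(s, d));
  int G = grid.size(), T = (int)tr.size();
  NumericMatrix counts(G, T + 1);  // last column: "other"
  std::mt19937_64 seeder((std::uint64_t)seed);
  double tmax = grid[G - 1];
  for (int k = 0; k < n_traj; ++k) {
    Engine eng(s, init, *p, rp, seeder());
    int g = 0;
    double tau;
    long long nstep = 0;
    while (g < G) {
      double t_now = eng.time();
      // current state holds until the next event
      PairTable cur = eng.pair_table();
      bool more = eng.step(&tau, nullptr);
      double t_next = more ? eng.time() : std::numeric_limits<double>::max();
      while (g < G && grid[g] >= t_now && grid[g] < t_next) {
        int which = T;
        for (int q = 0; q < T; ++q)
          if (cur == tr[q]) { which = q; break; }
        counts(g, which) += 1.0;
        ++g;
      }
      if (!more || ++nstep >= (long long)max_steps || t_now > tmax) {
        // absorb remaining grid points with the final state
        PairTable fin = eng.pair_table();
        while (g < G) {
          int which = T;
          for (int q = 0; q < T; ++q)
            if (fin == tr[q]) { which = q; break; }
          counts(g, which) += 1.0;
          ++g;
        }
        break;
      }
    }
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// ---------------------------------------------------------------------
// lockstep: fast engine vs naive full-recompute engine on one RNG stream
// ---------------------------------------------------------------------

namespace {

// naive engine: rebuilds everything from scratch each step; moves come
// from the brute-force generator, owners are derived per move, slots are
// allocated by the same deterministic rule as the fast engine
struct NaiveEngine {
  Seq s;
  int N;
  PairTable pt;
  const EnergyParams& p;
  RateParams rp;
  std::mt19937_64 rng;
  double t = 0.0;
  std::unordered_map<std::int64_t, int> slot_of;
  std::vector<int> free_slots;
  int next_slot = 0;

  NaiveEngine(const Seq& s_, const PairTable& init, const EnergyParams& p_,
              const RateParams& rp_, std::uint64_t seed)
      : s(s_), N((int)s_.size() - 1), pt(init), p(p_), rp(rp_), rng(seed) {
    auto elems = decompose_all(s, pt);
    for (auto& e : elems) slot_of[lkey(e)] = next_slot++;
  }
  std::int64_t lkey(const Element& e) const {
    return e.ext ? 0 : (std::int64_t)e.i * (N + 2) + e.j;
  }
  std::int64_t key(int i, int j) const {
    return i == 0 ? 0 : (std::int64_t)i * (N + 2) + j;
  }
  double unif01() { return (rng() >> 11) * (1.0 / 9007199254740992.0); }
  double unif01_open0() {
    return ((rng() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }

  std::pair<int, int> owner_of(const Move& m) const {
    if (m.ri && m.ai) {  // shift: owner holds the consumed unpaired nt
      int mpos = (m.ai == m.ri || m.ai == m.rj) ? m.aj : m.ai;
      auto f = enclosing_face(pt, mpos);
      return element_label_of_face(pt, f.first, f.second);
    }
    if (m.ai) {  // addition: owner holds the consumed nucleotides
      auto f = enclosing_face(pt, m.ai);
      return element_label_of_face(pt, f.first, f.second);
    }
    // removal
    bool so = (m.ri - 1 >= 1 && pt[m.ri - 1] == m.rj + 1);
    bool si = (pt[m.ri + 1] == m.rj - 1);
    if (si && !so) {  // outer terminal pair: owned by the outer loop
      auto f = enclosing_face(pt, m.ri);
      return element_label_of_face(pt, f.first, f.second);
    }
    return element_label_of_face(pt, m.ri, m.rj);
  }

  // one step; returns chosen move (ri,rj,ai,aj) and flux, or ok=false
  bool step(Move* chosen, double* flux, double* tau) {
    // fresh decomposition and slot maintenance (same allocator rule)
    auto elems = decompose_all(s, pt);
    std::vector<std::pair<std::int64_t, const Element*>> now;
    for (auto& e : elems) now.push_back({lkey(e), &e});
    std::sort(now.begin(), now.end(),
              [](auto& a, auto& b) { return a.first < b.first; });
    // frees: labels in slot_of not present any more, in label order
    std::vector<std::pair<std::int64_t, int>> gone;
    for (auto& kv : slot_of) {
      bool found = false;
      for (auto& nv : now)
        if (nv.first == kv.first) { found = true; break; }
      if (!found) gone.push_back(kv);
    }
    std::sort(gone.begin(), gone.end());
    for (auto& kv : gone) {
      slot_of.erase(kv.first);
      free_slots.push_back(kv.second);
    }
    for (auto& nv : now) {
      if (!slot_of.count(nv.first)) {
        int sl;
        if (!free_slots.empty()) { sl = free_slots.back(); free_slots.pop_back(); }
        else sl = next_slot++;
        slot_of[nv.first] = sl;
      }
    }
    // group brute-force moves by owner slot
    auto mv = bruteforce_moves(s, pt, p, rp);
    int maxslot = next_slot;
    std::vector<std::vector<Move>> per(maxslot);
    for (auto& m : mv) {
      auto lab = owner_of(m);
      auto it = slot_of.find(key(lab.first, lab.second));
      if (it == slot_of.end()) throw std::runtime_error("naive: owner miss");
      per[it->second].push_back(m);
    }
    // per-slot flux; fresh partial-sum tree (same pairwise summation)
    FluxTree tree(std::max(1, maxslot));
    while (tree.capacity() < maxslot) tree.resize_capacity(2 * tree.capacity());
    for (int sl = 0; sl < maxslot; ++sl) {
      double f = 0;
      for (auto& m : per[sl]) f += m.rate;
      tree.update(sl, f);
    }
    double Phi = tree.root();
    *flux = Phi;
    if (!(Phi > 0)) return false;
    double r1 = unif01();
    double r2 = unif01_open0();
    *tau = -std::log(r2) / Phi;
    double rem;
    int sl = tree.select(r1 * Phi, &rem, nullptr);
    const Move* pick = nullptr;
    double cum = 0;
    for (auto& m : per[sl]) {
      cum += m.rate;
      if (cum > rem) { pick = &m; break; }
    }
    if (!pick) {
      for (auto it = per[sl].rbegin(); it != per[sl].rend(); ++it)
        if (it->rate > 0) { pick = &*it; break; }
      if (!pick) throw std::runtime_error("naive: empty slot selected");
    }
    *chosen = *pick;
    if (pick->ri) { pt[pick->ri] = 0; pt[pick->rj] = 0; }
    Move fired = *pick;
    if (fired.ai) { pt[fired.ai] = fired.aj; pt[fired.aj] = fired.ai; }
    t += *tau;
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List rk_lockstep(std::string seq, std::string init_db, SEXP pp, List rates,
                 double n_steps, double seed, bool verify_cache,
                 int verify_every) {
  XPtr<EnergyParams> p(pp);
  RateParams rp = rates_from_list(rates);
  Seq s = encode_seq(seq);
  PairTable init = parse_dot_bracket(s, init_db);
  Engine fast(s, init, *p, rp, (std::uint64_t)seed);
  NaiveEngine naive(s, init, *p, rp, (std::uint64_t)seed);
  long long n = (long long)n_steps;
  long long done = 0;
  std::string mismatch = "";
  double max_flux_rel = 0.0;
  for (long long k = 0; k < n; ++k) {
    if (verify_cache && (k % verify_every) == 0) {
      std::string msg = fast.verify_against_bruteforce(1e-9);
      if (!msg.empty()) {
        mismatch = "cache check failed at step " + std::to_string(k) + ": " +
                   msg;
        break;
      }
    }
    double flux_fast = fast.total_flux();
    Move mf, mn;
    double tau_f, flux_naive, tau_n;
    bool okn = naive.step(&mn, &flux_naive, &tau_n);
    bool okf = fast.step(&tau_f, &mf);
    if (okf != okn) {
      mismatch = "termination mismatch at step " + std::to_string(k);
      break;
    }
    if (!okf) break;
    double rel = std::abs(flux_fast - flux_naive) /
                 std::max(1e-300, std::abs(flux_naive));
    max_flux_rel = std::max(max_flux_rel, rel);
    if (mf.ri != mn.ri || mf.rj != mn.rj || mf.ai != mn.ai ||
        mf.aj != mn.aj) {
      mismatch = "event mismatch at step " + std::to_string(k);
      break;
    }
    if (fast.pair_table() != naive.pt) {
      mismatch = "state mismatch at step " + std::to_string(k);
      break;
    }
    if (tau_f != tau_n) {
      mismatch = "waiting-time mismatch at step " + std::to_string(k);
      break;
    }
    ++done;
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ok"] = mismatch.empty(), _["steps"] = (double)done,
                      _["mismatch"] = mismatch,
                      _["max_flux_reldiff"] = max_flux_rel,
                      _["stats"] = stats_to_list(fast.stats()));
}

// ---------------------------------------------------------------------
// enumeration
// ---------------------------------------------------------------------

// [[Rcpp::export]]
std::vector<std::string> rk_enumerate(std::string seq, int max_n) {
  Seq s = encode_seq(seq);
  auto pts = enumerate_structures(s, max_n);
  std::vector<std::string> out;
  out.reserve(pts.size());
  for (auto& pt : pts) out.push_back(write_dot_bracket(pt));
  return out;
}

// [[Rcpp::export]]
double rk_count_structures(std::string seq) {
  Seq s = encode_seq(seq);
  return count_structures(s);
}
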