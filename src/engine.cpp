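// Gillespie engine.  Each step: read the total flux from the partial-sum
// tree, draw r1 and r2, advance time by tau = -ln(r2)/Phi, select the
// loop element by tree descent on r1*Phi and the move within it by a
// cumulative scan of its cached rates, fire the move, then rebuild only
// the affected loop elements and refresh the O(1) set of lone-pair rates
// that couple neighbouring faces.
#include "rnakin.h"

namespace rnakin {

namespace {
inline int pg(const PairTable& pt, int x) {
  return (x >= 1 && x < (int)pt.size()) ? pt[x] : 0;
}
}  // namespace

Engine::Engine(const Seq& s, const PairTable& init, const EnergyParams& p,
               const RateParams& rp, std::uint64_t seed)
    : seq_(s),
      N_((int)s.size() - 1),
      pt_(init),
      par_(p),
      rp_(rp),
      rng_(seed),
      tree_(8) {
  validate_structure(seq_, pt_);
  energy_dc_ = structure_energy_dc(seq_, pt_, par_);
  auto elems = decompose_all(seq_, pt_);
  for (auto& e : elems) {
    int slot = alloc_slot();
    e.slot = slot;
    enumerate_element_moves(seq_, pt_, e, par_, rp_);
    elems_[slot] = std::move(e);
    live_[slot] = 1;
    ++n_live_;
    slot_of_[elems_[slot].ext ? 0 : key(elems_[slot].i, elems_[slot].j)] =
        slot;
    tree_.update(slot, elems_[slot].flux);
  }
}

int Engine::alloc_slot() {
  if (!free_slots_.empty()) {
    int s = free_slots_.back();
    free_slots_.pop_back();
    return s;
  }
  int s = (int)elems_.size();
  elems_.emplace_back();
  live_.push_back(0);
  if (s >= tree_.capacity()) tree_.resize_capacity(2 * tree_.capacity());
  return s;
}

void Engine::remove_element(int slot) {
  live_[slot] = 0;
  --n_live_;
  slot_of_.erase(elems_[slot].ext ? 0 : key(elems_[slot].i, elems_[slot].j));
  elems_[slot].moves.clear();
  elems_[slot].flux = 0.0;
  tree_.update(slot, 0.0);
  free_slots_.push_back(slot);
}

void Engine::install_element(int i, int j, bool ext,
                             std::vector<int>* touched) {
  std::int64_t k = ext ? 0 : key(i, j);
  auto it = slot_of_.find(k);
  int slot;
  if (it != slot_of_.end()) {
    slot = it->second;
  } else {
    slot = alloc_slot();
    live_[slot] = 1;
    ++n_live_;
    slot_of_[k] = slot;
  }
  Element e = build_element(seq_, pt_, ext ? 0 : i, ext ? 0 : j);
  e.slot = slot;
  enumerate_element_moves(seq_, pt_, e, par_, rp_);
  elems_[slot] = std::move(e);
  int nt = tree_.update(slot, elems_[slot].flux);
  stats_.max_tree_nodes_update = std::max(stats_.max_tree_nodes_update, nt);
  touched->push_back(slot);
}

// labels of elements whose cached data may change, evaluated on the
// current pair table; before = true means pt_ is in the pre-move state
void Engine::collect_labels(const Move& mv, bool before,
                            std::vector<std::pair<int, int>>* out) {
  auto add_face_elem = [&](std::pair<int, int> f) {
    out->push_back(element_label_of_face(pt_, f.first, f.second));
  };
  auto add_enclosing = [&](int x) { add_face_elem(enclosing_face(pt_, x)); };
  int a = mv.ri, b = mv.rj, c = mv.ai, d = mv.aj;
  if (before) {
    if (a) {
      out->push_back(element_label_of_face(pt_, a, b));
      add_enclosing(a);
      if (pg(pt_, a - 1) == b + 1 && pg(pt_, a - 2) != b + 2)
        add_enclosing(a - 1);  // remnant helix above becomes lone
    }
    if (c) {
      add_enclosing(c);
      if (pg(pt_, c + 1) == d - 1)
        out->push_back(element_label_of_face(pt_, c + 1, d - 1));
      if (pg(pt_, c - 1) == d + 1) {
        out->push_back(element_label_of_face(pt_, c - 1, d + 1));
        if (pg(pt_, c - 2) != d + 2) add_enclosing(c - 1);  // lone -> helix
      }
    }
  } else {
    if (c) {
      out->push_back(element_label_of_face(pt_, c, d));
      add_enclosing(c);
      if (pg(pt_, c - 1) == d + 1 && pg(pt_, c - 2) != d + 2)
        add_enclosing(c - 1);
    }
    if (a) {
      if (pt_[a] == 0) add_enclosing(a);
      if (pt_[b] == 0) add_enclosing(b);
      if (pg(pt_, a + 1) == b - 1)
        out->push_back(element_label_of_face(pt_, a + 1, b - 1));
      if (pg(pt_, a - 1) == b + 1 && pg(pt_, a - 2) != b + 2)
        add_enclosing(a - 1);
    }
  }
}

void Engine::refresh_coupled(int slot_changed, const std::vector<int>& fresh) {
  Element& x = elems_[slot_changed];
  auto is_fresh = [&](int s) {
    for (int f : fresh)
      if (f == s) return true;
    return false;
  };
  auto refresh_pair_moves = [&](int slot, int pi, int pj) {
    Element& e = elems_[slot];
    bool changed = false;
    for (auto& m : e.moves) {
      if (m.ri == pi && m.rj == pj) {
        double old = m.rate;
        m.dG = move_dG_local(seq_, pt_, m, par_);
        double beta = par_.beta_dc();
        if (m.kind == RETRACTION && m.nucn > 0)
          m.rate = rp_.k0n * std::pow((double)m.nucn, -rp_.alpha) *
                   std::exp(-beta * m.dG);
        else
          m.rate = kawasaki_rate(m.dG, rp_, beta);
        if (m.rate != old) changed = true;
        ++stats_.total_refresh_ops;
      }
    }
    if (changed) {
      e.flux = 0.0;
      for (auto& m : e.moves) e.flux += m.rate;
      int nt = tree_.update(slot, e.flux);
      stats_.max_tree_nodes_update =
          std::max(stats_.max_tree_nodes_update, nt);
    }
  };
  // partner across this element's lone closing pair
  if (!x.ext && x.hlen == 1) {
    auto f = enclosing_face(pt_, x.i);
    auto lab = element_label_of_face(pt_, f.first, f.second);
    auto it = slot_of_.find(lab.first == 0 ? 0 : key(lab.first, lab.second));
    if (it != slot_of_.end() && !is_fresh(it->second))
      refresh_pair_moves(it->second, x.i, x.j);
  }
  // children across lone branch helices of this face
  for (auto& br : x.branches) {
    if (pg(pt_, br.first + 1) != br.second - 1) {  // lone branch pair
      auto it = slot_of_.find(key(br.first, br.second));
      if (it != slot_of_.end() && !is_fresh(it->second))
        refresh_pair_moves(it->second, br.first, br.second);
    }
  }
}

void Engine::apply_and_update(const Move& mv) {
  std::vector<std::pair<int, int>> labs_before, labs_after;
  collect_labels(mv, true, &labs_before);
  // fire
  if (mv.ri) { pt_[mv.ri] = 0; pt_[mv.rj] = 0; }
  if (mv.ai) { pt_[mv.ai] = mv.aj; pt_[mv.aj] = mv.ai; }
  collect_labels(mv, false, &labs_after);

  // union of candidate labels, deduplicated, sorted for determinism
  std::vector<std::pair<int, int>> all = labs_before;
  all.insert(all.end(), labs_after.begin(), labs_after.end());
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());

  auto exists_now = [&](std::pair<int, int> L) {
    if (L.first == 0) return true;  // external loop always present
    if (pt_[L.first] != L.second) return false;
    return !(pg(pt_, L.first + 1) == L.second - 1);  // stack faces: no label
  };

  int destroyed = 0, created = 0, rebuilt_pre = 0;
  std::vector<int> fresh;
  // frees first (sorted label order), then installs
  for (auto& L : all) {
    if (!exists_now(L)) {
      auto it = slot_of_.find(L.first == 0 ? 0 : key(L.first, L.second));
      if (it != slot_of_.end()) {
        remove_element(it->second);
        ++destroyed;
      }
    }
  }
  for (auto& L : all) {
    if (exists_now(L)) {
      bool pre = slot_of_.count(L.first == 0 ? 0 : key(L.first, L.second));
      install_element(L.first, L.second, L.first == 0, &fresh);
      if (pre) ++rebuilt_pre;
      else ++created;
    }
  }
  for (int s : fresh) refresh_coupled(s, fresh);

  stats_.max_rebuilt_preexisting =
      std::max(stats_.max_rebuilt_preexisting, rebuilt_pre);
  stats_.total_rebuilt += rebuilt_pre + created;
  stats_.max_affected_total =
      std::max(stats_.max_affected_total, destroyed + created + rebuilt_pre);
}

bool Engine::step(double* tau, Move* fired) {
  double Phi = tree_.root();
  if (!(Phi > 0.0)) return false;
  double r1 = unif01();
  double r2 = unif01_open0();
  *tau = -std::log(r2) / Phi;
  double rem;
  int nodes;
  int slot = tree_.select(r1 * Phi, &rem, &nodes);
  stats_.max_tree_nodes_select = std::max(stats_.max_tree_nodes_select, nodes);
  Element& e = elems_[slot];
  const Move* chosen = nullptr;
  double cum = 0.0;
  for (auto& m : e.moves) {
    cum += m.rate;
    if (cum > rem) { chosen = &m; break; }
  }
  if (!chosen) {  // guard against terminal rounding at the boundary
    for (auto it = e.moves.rbegin(); it != e.moves.rend(); ++it)
      if (it->rate > 0) { chosen = &*it; break; }
    if (!chosen) throw std::runtime_error("selected element has no moves");
  }
  Move mv = *chosen;
  if (fired) *fired = mv;
  t_ += *tau;
  energy_dc_ += mv.dG;
  apply_and_update(mv);
  ++stats_.steps;
  return true;
}

std::string Engine::verify_against_bruteforce(double tol) {
  // 1. slot map must equal a fresh decomposition
  auto ref = decompose_all(seq_, pt_);
  if ((int)ref.size() != n_live_)
    return "element count mismatch: " + std::to_string(n_live_) + " vs " +
           std::to_string(ref.size());
  for (auto& e : ref) {
    auto it = slot_of_.find(e.ext ? 0 : key(e.i, e.j));
    if (it == slot_of_.end())
      return "missing element (" + std::to_string(e.i) + "," +
             std::to_string(e.j) + ")";
    const Element& c = elems_[it->second];
    if (c.ss != e.ss || c.branches != e.branches || c.hlen != e.hlen ||
        c.hp != e.hp || c.hq != e.hq)
      return "stale element record (" + std::to_string(e.i) + "," +
             std::to_string(e.j) + ")";
  }
  // 2. cached move multiset must equal the brute-force neighbourhood
  std::vector<Move> cached;
  for (size_t s = 0; s < elems_.size(); ++s)
    if (live_[s])
      cached.insert(cached.end(), elems_[s].moves.begin(),
                    elems_[s].moves.end());
  auto keyless = [](const Move& a, const Move& b) {
    if (a.ri != b.ri) return a.ri < b.ri;
    if (a.rj != b.rj) return a.rj < b.rj;
    if (a.ai != b.ai) return a.ai < b.ai;
    return a.aj < b.aj;
  };
  std::sort(cached.begin(), cached.end(), keyless);
  std::vector<Move> brute = bruteforce_moves(seq_, pt_, par_, rp_);
  std::sort(brute.begin(), brute.end(), keyless);
  if (cached.size() != brute.size())
    return "move count mismatch: cached " + std::to_string(cached.size()) +
           " vs brute " + std::to_string(brute.size());
  double flux_c = 0, flux_b = 0;
  for (size_t k = 0; k < cached.size(); ++k) {
    const Move &a = cached[k], &b = brute[k];
    if (a.ri != b.ri || a.rj != b.rj || a.ai != b.ai || a.aj != b.aj)
      return "move key mismatch at index " + std::to_string(k);
    if (a.kind != b.kind)
      return "move kind mismatch at index " + std::to_string(k);
    if (a.nucn != b.nucn)
      return "nucleation distance mismatch at index " + std::to_string(k);
    if (std::abs(a.rate - b.rate) >
        tol * std::max(1.0, std::abs(b.rate)))
      return "stale rate at index " + std::to_string(k);
    if (std::abs(a.dG - b.dG) > 1e-6)
      return "stale dG at index " + std::to_string(k);
    flux_c += a.rate;
    flux_b += b.rate;
  }
  if (std::abs(tree_.root() - flux_b) >
      1e-9 * std::max(1.0, std::abs(flux_b)))
    return "tree root disagrees with total flux";
  (void)flux_c;
  return "";
}

}  // namespace rnakin
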