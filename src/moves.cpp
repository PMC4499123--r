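// Elementary move set, transition rates and local free-energy differences.
//
// Six move kinds connect neighbouring structures: helix nucleation,
// extension, retraction (including removal of a lone pair, which is the
// inverse of nucleation), opening of a pair inside a helix, helix
// morphing and single-nucleotide defect diffusion (the last two are
// shift moves: one pair removed, one added, sharing an endpoint).
//
// Rates: Kawasaki k = k0 exp(-beta dG / 2) for all moves except
// nucleation, whose forward rate k0n * n^(-alpha) comes from polymer
// loop-closure scaling over the ring distance n; the lone-pair removal
// takes the detailed-balance partner rate k0n * n^(-alpha) exp(-beta dG).
#include "rnakin.h"

namespace rnakin {

double kawasaki_rate(double dG_dc, const RateParams& rp, double beta_dc) {
  return rp.k0 * std::exp(-beta_dc * dG_dc / 2.0);
}

double nucleation_fwd_rate(int n, const RateParams& rp) {
  return rp.k0n * std::pow((double)n, -rp.alpha);
}

namespace {

inline int pg(const PairTable& pt, int x) {
  return (x >= 1 && x < (int)pt.size()) ? pt[x] : 0;
}

struct FaceSet {
  // anchors of affected faces; (0,0) = exterior
  std::pair<int, int> f[8];
  int n = 0;
  void add(std::pair<int, int> a) {
    for (int k = 0; k < n; ++k)
      if (f[k] == a) return;
    f[n++] = a;
  }
};

void faces_around(const Seq& s, const PairTable& pt, const Move& mv,
                  bool after, FaceSet* out) {
  if (mv.ri) {
    if (!after) {
      out->add({mv.ri, mv.rj});          // face closed by the removed pair
      out->add(enclosing_face(pt, mv.ri));
    } else {
      if (pt[mv.ri] == 0) out->add(enclosing_face(pt, mv.ri));
      if (pt[mv.rj] == 0) out->add(enclosing_face(pt, mv.rj));
    }
  }
  if (mv.ai) {
    if (!after) {
      out->add(enclosing_face(pt, mv.ai));
      out->add(enclosing_face(pt, mv.aj));
    } else {
      out->add({mv.ai, mv.aj});
      out->add(enclosing_face(pt, mv.ai));
    }
  }
}

}  // namespace

double move_dG_local(const Seq& s, PairTable& pt, const Move& mv,
                     const EnergyParams& p, FaceCache* cache) {
  FaceSet before, after;
  faces_around(s, pt, mv, false, &before);
  double e0 = 0.0;
  for (int k = 0; k < before.n; ++k) {
    int a = before.f[k].first;
    if (cache) {
      bool hit = false;
      for (int c = 0; c < cache->n; ++c)
        if (cache->anchor[c] == a) { e0 += cache->e[c]; hit = true; break; }
      if (hit) continue;
      double v = face_energy(s, pt, a, before.f[k].second, p);
      if (cache->n < 24) {
        cache->anchor[cache->n] = a;
        cache->e[cache->n] = v;
        ++cache->n;
      }
      e0 += v;
      continue;
    }
    e0 += face_energy(s, pt, before.f[k].first, before.f[k].second, p);
  }
  // apply
  if (mv.ri) { pt[mv.ri] = 0; pt[mv.rj] = 0; }
  if (mv.ai) { pt[mv.ai] = mv.aj; pt[mv.aj] = mv.ai; }
  faces_around(s, pt, mv, true, &after);
  double e1 = 0.0;
  for (int k = 0; k < after.n; ++k)
    e1 += face_energy(s, pt, after.f[k].first, after.f[k].second, p);
  // revert
  if (mv.ai) { pt[mv.ai] = 0; pt[mv.aj] = 0; }
  if (mv.ri) { pt[mv.ri] = mv.rj; pt[mv.rj] = mv.ri; }
  return e1 - e0;
}

namespace {

inline void rate_move(const Seq& s, PairTable& pt, Move& m,
                      const EnergyParams& p, const RateParams& rp,
                      FaceCache* cache = nullptr) {
  m.dG = move_dG_local(s, pt, m, p, cache);
  double beta = p.beta_dc();
  if (m.kind == NUCLEATION) {
    m.rate = nucleation_fwd_rate(m.nucn, rp);
  } else if (m.kind == RETRACTION && m.nucn > 0) {
    // lone-pair removal: detailed-balance partner of nucleation
    m.rate = rp.k0n * std::pow((double)m.nucn, -rp.alpha) *
             std::exp(-beta * m.dG);
  } else {
    m.rate = kawasaki_rate(m.dG, rp, beta);
  }
}

inline bool move_less(const Move& a, const Move& b) {
  if (a.kind != b.kind) return a.kind < b.kind;
  if (a.ri != b.ri) return a.ri < b.ri;
  if (a.rj != b.rj) return a.rj < b.rj;
  if (a.ai != b.ai) return a.ai < b.ai;
  return a.aj < b.aj;
}

// ring items of the face of e strictly between a and b (enclosed side)
int ring_between(const Element& e, int a, int b) {
  int n = 0;
  for (int x : e.ss)
    if (x > a && x < b) ++n;
  for (auto& br : e.branches)
    if (br.first > a && br.first < b) ++n;
  return n;
}

int helix_len_inward(const PairTable& pt, int p, int q) {
  int len = 1;
  while (pt[p + len] == q - len && q - len > p + len) ++len;
  return len;
}

}  // namespace

void enumerate_element_moves(const Seq& s, PairTable& pt, Element& e,
                             const EnergyParams& p, const RateParams& rp) {
  e.moves.clear();
  int N = (int)s.size() - 1;
  FaceCache cache;
  auto push = [&](int kind, int ri, int rj, int ai, int aj, int nucn) {
    Move m;
    m.kind = kind; m.ri = ri; m.rj = rj; m.ai = ai; m.aj = aj; m.nucn = nucn;
    rate_move(s, pt, m, p, rp, &cache);
    e.moves.push_back(m);
  };

  // extension candidates (added pair stacks onto an existing helix end)
  int exc_i = 0, exc_j = 0;  // closing-helix inward extension
  if (!e.ext && pt[e.i + 1] == 0 && pt[e.j - 1] == 0 &&
      pair_type(s[e.i + 1], s[e.j - 1]) && (e.j - 1) - (e.i + 1) >= 4) {
    exc_i = e.i + 1; exc_j = e.j - 1;
    push(EXTENSION, 0, 0, exc_i, exc_j, 0);
  }
  for (auto& br : e.branches) {
    int a = br.first - 1, b = br.second + 1;
    if (a == exc_i && b == exc_j) continue;  // 1x1 face: same candidate
    if (a >= 1 && b <= N && pt[a] == 0 && pt[b] == 0 &&
        pair_type(s[a], s[b]))
      push(EXTENSION, 0, 0, a, b, 0);
  }

  // nucleation: all other valid pairings of two unpaired members
  for (size_t x = 0; x < e.ss.size(); ++x) {
    for (size_t y = x + 1; y < e.ss.size(); ++y) {
      int a = e.ss[x], b = e.ss[y];
      if (b - a < 4 || !pair_type(s[a], s[b])) continue;
      bool is_ext = (pg(pt, a - 1) == b + 1) || (pg(pt, a + 1) == b - 1);
      if (is_ext) continue;  // classified as extension above
      push(NUCLEATION, 0, 0, a, b, ring_between(e, a, b));
    }
  }

  // removals of the pairs bordering this face from its side
  if (!e.ext) {
    if (e.hlen == 1)
      push(RETRACTION, e.i, e.j, 0, 0,
           (int)e.ss.size() + (int)e.branches.size());
    else
      push(RETRACTION, e.i, e.j, 0, 0, 0);
    // opening a pair strictly inside the closing helix
    for (int t = 1; t <= e.hlen - 2; ++t)
      push(INTERIOR_OPEN, e.hp + t, e.hq - t, 0, 0, 0);
  }
  for (auto& br : e.branches) {
    if (helix_len_inward(pt, br.first, br.second) >= 2)
      push(RETRACTION, br.first, br.second, 0, 0, 0);
  }

  // shift moves: a bordering pair re-pairs with an unpaired member
  auto shifts_for = [&](int a, int b) {
    for (int m : e.ss) {
      if (m != b && std::abs(m - a) >= 4 && pair_type(s[std::min(a, m)],
                                                      s[std::max(a, m)])) {
        int kind = (std::abs(m - b) == 1) ? DEFECT_DIFFUSION : MORPH;
        push(kind, a, b, std::min(a, m), std::max(a, m), 0);
      }
      if (m != a && std::abs(m - b) >= 4 && pair_type(s[std::min(b, m)],
                                                      s[std::max(b, m)])) {
        int kind = (std::abs(m - a) == 1) ? DEFECT_DIFFUSION : MORPH;
        push(kind, a, b, std::min(b, m), std::max(b, m), 0);
      }
    }
  };
  if (!e.ext) shifts_for(e.i, e.j);
  for (auto& br : e.branches) shifts_for(br.first, br.second);

  std::sort(e.moves.begin(), e.moves.end(), move_less);
  e.flux = 0.0;
  for (auto& m : e.moves) e.flux += m.rate;
}

// ---------------------------------------------------------------------
// Brute-force global neighbourhood: independent generation by scanning
// all candidate pairings/removals with a crossing test, used as oracle.
// ---------------------------------------------------------------------

namespace {

// are unpaired positions a < b on the same face? walk with helix jumps
bool same_face(const PairTable& pt, int a, int b) {
  int p = a + 1;
  while (p < b) {
    int q = pt[p];
    if (q == 0) { ++p; continue; }
    if (q > p && q < b) { p = q + 1; continue; }
    return false;  // q > b (crossing) or q < p (face closes before b)
  }
  return true;
}

int ring_distance(const PairTable& pt, int a, int b) {
  int p = a + 1, n = 0;
  while (p < b) {
    int q = pt[p];
    if (q == 0) { ++n; ++p; }
    else { ++n; p = q + 1; }
  }
  return n;
}

}  // namespace

std::vector<Move> bruteforce_moves(const Seq& s, PairTable& pt,
                                   const EnergyParams& p,
                                   const RateParams& rp) {
  int N = (int)s.size() - 1;
  std::vector<Move> out;
  auto push = [&](int kind, int ri, int rj, int ai, int aj, int nucn) {
    Move m;
    m.kind = kind; m.ri = ri; m.rj = rj; m.ai = ai; m.aj = aj; m.nucn = nucn;
    rate_move(s, pt, m, p, rp);
    out.push_back(m);
  };

  // additions
  for (int a = 1; a <= N - 4; ++a) {
    if (pt[a] != 0) continue;
    for (int b = a + 4; b <= N; ++b) {
      if (pt[b] != 0 || !pair_type(s[a], s[b])) continue;
      if (!same_face(pt, a, b)) continue;
      bool ext_move = (pg(pt, a - 1) == b + 1) || (pg(pt, a + 1) == b - 1);
      if (ext_move) push(EXTENSION, 0, 0, a, b, 0);
      else push(NUCLEATION, 0, 0, a, b, ring_distance(pt, a, b));
    }
  }
  // removals
  for (int a = 1; a <= N; ++a) {
    int b = pt[a];
    if (b <= a) continue;
    bool so = (pg(pt, a - 1) == b + 1), si = (pg(pt, a + 1) == b - 1);
    if (so && si) push(INTERIOR_OPEN, a, b, 0, 0, 0);
    else if (so || si) push(RETRACTION, a, b, 0, 0, 0);
    else push(RETRACTION, a, b, 0, 0, ring_distance(pt, a, b));
  }
  // shifts
  for (int a = 1; a <= N; ++a) {
    int b = pt[a];
    if (b <= a) continue;
    pt[a] = 0; pt[b] = 0;
    for (int m = 1; m <= N; ++m) {
      if (pt[m] != 0 || m == a || m == b) continue;
      // keep a
      if (std::abs(m - a) >= 4 && pair_type(s[std::min(a, m)],
                                            s[std::max(a, m)]) &&
          same_face(pt, std::min(a, m), std::max(a, m))) {
        int kind = (std::abs(m - b) == 1) ? DEFECT_DIFFUSION : MORPH;
        Move mv;
        mv.kind = kind; mv.ri = a; mv.rj = b;
        mv.ai = std::min(a, m); mv.aj = std::max(a, m);
        pt[a] = b; pt[b] = a;
        rate_move(s, pt, mv, p, rp);
        pt[a] = 0; pt[b] = 0;
        out.push_back(mv);
      }
      // keep b
      if (std::abs(m - b) >= 4 && pair_type(s[std::min(b, m)],
                                            s[std::max(b, m)]) &&
          same_face(pt, std::min(b, m), std::max(b, m))) {
        int kind = (std::abs(m - a) == 1) ? DEFECT_DIFFUSION : MORPH;
        Move mv;
        mv.kind = kind; mv.ri = a; mv.rj = b;
        mv.ai = std::min(b, m); mv.aj = std::max(b, m);
        pt[a] = b; pt[b] = a;
        rate_move(s, pt, mv, p, rp);
        pt[a] = 0; pt[b] = 0;
        out.push_back(mv);
      }
    }
    pt[a] = b; pt[b] = a;
  }
  std::sort(out.begin(), out.end(), move_less);
  return out;
}

}  // namespace rnakin
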