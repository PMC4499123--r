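// Nearest-neighbour free-energy evaluation per face (hairpin, stack,
// bulge, interior, multiloop, exterior) under the bundled Turner-99
// tables.  Dangling ends follow the per-unpaired-base convention: a base
// adjacent to a single helix end contributes its dangle energy; a base
// shared between two helix ends contributes the more favourable of the
// two options.  Multiloops are linear in the branch count with an
// optional logarithmic growth term in the unpaired length.
#include "rnakin.h"

namespace rnakin {

namespace {

// dangle contributions of the unpaired face member x (exterior/multiloop)
inline double dangle_contrib(const Seq& s, const PairTable& pt, int x,
                             const EnergyParams& p) {
  int N = (int)s.size() - 1;
  double left = 1e18, right = 1e18;
  if (x - 1 >= 1 && pt[x - 1] != 0) {
    int t = pair_type(s[pt[x - 1]], s[x - 1]);  // stem exits 3' onto x
    if (t) left = p.d3(t, s[x]);
  }
  if (x + 1 <= N && pt[x + 1] != 0) {
    int t = pair_type(s[x + 1], s[pt[x + 1]]);  // stem entered 5' from x
    if (t) right = p.d5(t, s[x]);
  }
  if (left > 1e17 && right > 1e17) return 0.0;
  if (left > 1e17) return right;
  if (right > 1e17) return left;
  return std::min(left, right);
}

double hairpin_energy(const Seq& s, int i, int j, const EnergyParams& p) {
  int u = j - i - 1;
  int t = pair_type(s[i], s[j]);
  const char* L = "NACGU";
  if (u == 3 && !p.triloops.empty()) {
    std::string key;
    for (int k = i; k <= j; ++k) key.push_back(L[s[k]]);
    for (auto& tl : p.triloops)
      if (tl.first == key) return tl.second + p.tau(t);
  }
  if (u == 4 && !p.tetra_idx.empty()) {
    std::uint32_t key = 0;
    for (int k = i; k <= j; ++k) key = key * 5u + (std::uint32_t)s[k];
    auto it = std::lower_bound(
        p.tetra_idx.begin(), p.tetra_idx.end(), key,
        [](const std::pair<std::uint32_t, int>& a, std::uint32_t b) {
          return a.first < b;
        });
    if (it != p.tetra_idx.end() && it->first == key) return it->second;
  }
  if (u == 6 && !p.hexaloops.empty()) {
    std::string key;
    for (int k = i; k <= j; ++k) key.push_back(L[s[k]]);
    for (auto& tl : p.hexaloops)
      if (tl.first == key) return tl.second;
  }
  double e = (u <= 30) ? p.hairpin_len[u]
                       : p.hairpin_len[30] +
                             std::trunc(p.lxc * std::log(u / 30.0));
  if (u == 3) e += p.tau(t);
  else e += p.mm(p.mm_hairpin, t, s[i + 1], s[j - 1]);
  return e;
}

double two_loop_energy(const Seq& s, int i, int j, int pp, int qq,
                       const EnergyParams& p) {
  // face closed by (i,j) with single branch (pp,qq): stack/bulge/interior
  int n1 = pp - i - 1, n2 = j - qq - 1;
  int t1 = pair_type(s[i], s[j]);
  int t2 = pair_type(s[qq], s[pp]);
  if (n1 == 0 && n2 == 0) return p.st(t1, t2);
  int ns = std::min(n1, n2), nl = std::max(n1, n2);
  if (ns == 0) {  // bulge
    if (nl == 1) return p.bulge_len[1] + p.st(t1, t2);
    double e = (nl <= 30) ? p.bulge_len[nl]
                          : p.bulge_len[30] +
                                std::trunc(p.lxc * std::log(nl / 30.0));
    return e + p.tau(t1) + p.tau(t2);
  }
  int si1 = s[i + 1], sj1 = s[j - 1], sp1 = s[pp - 1], sq1 = s[qq + 1];
  if (ns == 1 && nl == 1) return p.i11(t1, t2, si1, sj1);
  if (ns == 1 && nl == 2) {
    if (n1 == 1) return p.i21(t1, t2, si1, sq1, sj1);
    return p.i21(t2, t1, sq1, si1, sp1);
  }
  if (ns == 1) {  // 1 x n, n >= 3
    double e = p.interior_len[std::min(1 + nl, 30)];
    if (1 + nl > 30) e += std::trunc(p.lxc * std::log((1 + nl) / 30.0));
    e += std::min<double>(p.ninio_max, (nl - ns) * (double)p.ninio_m);
    e += p.mm(p.mm_int_1n, t1, si1, sj1) + p.mm(p.mm_int_1n, t2, sq1, sp1);
    return e;
  }
  if (ns == 2 && nl == 2) return p.i22(t1, t2, si1, sp1, sq1, sj1);
  if (ns == 2 && nl == 3) {
    return p.interior_len[5] + std::min(p.ninio_max, p.ninio_m) +
           p.mm(p.mm_int_23, t1, si1, sj1) + p.mm(p.mm_int_23, t2, sq1, sp1);
  }
  int u = n1 + n2;
  double e = (u <= 30) ? p.interior_len[u]
                       : p.interior_len[30] +
                             std::trunc(p.lxc * std::log(u / 30.0));
  e += std::min<double>(p.ninio_max, (nl - ns) * (double)p.ninio_m);
  e += p.mm(p.mm_interior, t1, si1, sj1) + p.mm(p.mm_interior, t2, sq1, sp1);
  return e;
}

}  // namespace

void EnergyParams::index_special_loops() {
  tetra_idx.clear();
  for (auto& tl : tetraloops) {
    std::uint32_t key = 0;
    for (char c : tl.first) {
      int b = c == 'A' ? 1 : c == 'C' ? 2 : c == 'G' ? 3 : c == 'U' ? 4 : 0;
      key = key * 5u + (std::uint32_t)b;
    }
    tetra_idx.push_back({key, tl.second});
  }
  std::sort(tetra_idx.begin(), tetra_idx.end());
}

double face_energy(const Seq& s, const PairTable& pt, int i, int j,
                   const EnergyParams& p) {
  int N = (int)s.size() - 1;
  double e = 0.0;
  if (i == 0) {  // exterior loop
    int k = 1;
    while (k <= N) {
      if (pt[k] == 0) {
        e += dangle_contrib(s, pt, k, p);
        ++k;
      } else {
        e += p.tau(pair_type(s[k], s[pt[k]]));
        k = pt[k] + 1;
      }
    }
    return e;
  }
  // collect branches / unpaired of the face closed by (i,j)
  int nb = 0, nu = 0;
  int first_b = 0, first_q = 0;
  double dang = 0.0, tausum = 0.0;
  int k = i + 1;
  while (k < j) {
    if (pt[k] == 0) {
      ++nu;
      dang += dangle_contrib(s, pt, k, p);
      ++k;
    } else {
      if (!nb) { first_b = k; first_q = pt[k]; }
      ++nb;
      tausum += p.tau(pair_type(s[k], s[pt[k]]));
      k = pt[k] + 1;
    }
  }
  if (nb == 0) return hairpin_energy(s, i, j, p);
  if (nb == 1) return two_loop_energy(s, i, j, first_b, first_q, p);
  // multiloop: closing stem + branches, linear in branch count,
  // optionally logarithmic in the unpaired length
  e = p.ml_offset + (double)p.ml_branch * (nb + 1);
  if (p.ml_log && nu > 6)
    e += (double)p.ml_unpaired * 6 + 1.75 * p.rt_dc * std::log(nu / 6.0);
  else
    e += (double)p.ml_unpaired * nu;
  e += tausum + p.tau(pair_type(s[i], s[j]));
  e += dang;
  return e;
}

double structure_energy_dc(const Seq& s, const PairTable& pt,
                           const EnergyParams& p) {
  int N = (int)s.size() - 1;
  double e = face_energy(s, pt, 0, 0, p);
  for (int k = 1; k <= N; ++k)
    if (pt[k] > k) e += face_energy(s, pt, k, pt[k], p);
  return e;
}

}  // namespace rnakin
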