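// Exhaustive enumeration of pseudoknot-free secondary structures with
// canonical pairs (G-C, A-U, G-U), a minimum hairpin of 3 unpaired
// nucleotides and lonely pairs allowed.  Generation uses an interval
// recursion on the last position; the independent count oracle uses a
// first-position recursion with memoisation.
#include <functional>
#include <map>

#include "rnakin.h"

namespace rnakin {

namespace {

struct Gen {
  const Seq& s;
  int N;
  std::map<int, std::vector<std::vector<std::pair<int, int>>>> memo;
  explicit Gen(const Seq& seq) : s(seq), N((int)seq.size() - 1) {}

  // all pairings of the interval [i, j] as lists of (a,b)
  const std::vector<std::vector<std::pair<int, int>>>& interval(int i, int j) {
    int kk = i * (N + 2) + j;
    auto it = memo.find(kk);
    if (it != memo.end()) return it->second;
    std::vector<std::vector<std::pair<int, int>>> out;
    if (j - i < 4) {
      out.emplace_back();  // only the empty pairing
    } else {
      // j unpaired
      for (auto& v : interval(i, j - 1)) out.push_back(v);
      // j paired to k
      for (int k = i; k <= j - 4; ++k) {
        if (!pair_type(s[k], s[j])) continue;
        auto& inner = interval(k + 1, j - 1);
        auto& outer = interval(i, k - 1);
        for (auto& o : outer) {
          for (auto& in : inner) {
            std::vector<std::pair<int, int>> v = o;
            v.push_back({k, j});
            v.insert(v.end(), in.begin(), in.end());
            out.push_back(v);
          }
        }
      }
    }
    return memo.emplace(kk, std::move(out)).first->second;
  }
};

}  // namespace

std::vector<PairTable> enumerate_structures(const Seq& s, int max_n) {
  int N = (int)s.size() - 1;
  if (N > max_n)
    throw std::runtime_error(
        "sequence too long for exhaustive enumeration (N = " +
        std::to_string(N) + ", guard " + std::to_string(max_n) + ")");
  Gen g(s);
  auto lists = g.interval(1, N);
  std::vector<PairTable> out;
  out.reserve(lists.size());
  for (auto& v : lists) {
    PairTable pt(N + 1, 0);
    for (auto& pr : v) { pt[pr.first] = pr.second; pt[pr.second] = pr.first; }
    out.push_back(std::move(pt));
  }
  return out;
}

double count_structures(const Seq& s) {
  int N = (int)s.size() - 1;
  // c[i][j]: structures of [i..j]; recursion on the FIRST position:
  // i unpaired, or i paired to m
  std::vector<std::vector<double>> c(N + 2, std::vector<double>(N + 2, -1));
  std::function<double(int, int)> rec = [&](int i, int j) -> double {
    if (j - i < 4) return 1.0;
    double& v = c[i][j];
    if (v >= 0) return v;
    double tot = rec(i + 1, j);
    for (int m = i + 4; m <= j; ++m)
      if (pair_type(s[i], s[m])) tot += rec(i + 1, m - 1) * rec(m + 1, j);
    v = tot;
    return v;
  };
  return rec(1, N);
}

}  // namespace rnakin
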