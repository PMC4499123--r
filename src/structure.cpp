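// Sequence encoding, dot-bracket I/O, structure validation, face walking
// and decomposition into loop elements.
#include "rnakin.h"

namespace rnakin {

Seq encode_seq(const std::string& s) {
  Seq out(s.size() + 1, 0);
  for (size_t k = 0; k < s.size(); ++k) {
    char c = std::toupper(s[k]);
    int b;
    switch (c) {
      case 'A': b = 1; break;
      case 'C': b = 2; break;
      case 'G': b = 3; break;
      case 'U': b = 4; break;
      case 'T': b = 4; break;  // silently converted
      default:
        throw std::runtime_error("invalid RNA letter '" + std::string(1, s[k]) +
                                 "' at position " + std::to_string(k + 1));
    }
    out[k + 1] = b;
  }
  if (s.empty()) throw std::runtime_error("empty sequence");
  return out;
}

std::string decode_seq(const Seq& s) {
  const char* L = "NACGU";
  std::string out;
  for (size_t k = 1; k < s.size(); ++k) out.push_back(L[s[k]]);
  return out;
}

PairTable parse_dot_bracket(const Seq& s, const std::string& db) {
  int N = (int)s.size() - 1;
  if ((int)db.size() != N)
    throw std::runtime_error("structure length " + std::to_string(db.size()) +
                             " does not match sequence length " +
                             std::to_string(N));
  PairTable pt(N + 1, 0);
  std::vector<int> stk;
  for (int k = 1; k <= N; ++k) {
    char c = db[k - 1];
    if (c == '(') {
      stk.push_back(k);
    } else if (c == ')') {
      if (stk.empty())
        throw std::runtime_error("unbalanced ')' at position " +
                                 std::to_string(k));
      int i = stk.back();
      stk.pop_back();
      pt[i] = k;
      pt[k] = i;
    } else if (c != '.') {
      throw std::runtime_error("invalid character '" + std::string(1, c) +
                               "' at position " + std::to_string(k));
    }
  }
  if (!stk.empty())
    throw std::runtime_error("unbalanced '(' at position " +
                             std::to_string(stk.back()));
  validate_structure(s, pt);
  return pt;
}

std::string write_dot_bracket(const PairTable& pt) {
  int N = (int)pt.size() - 1;
  std::string db(N, '.');
  for (int k = 1; k <= N; ++k) {
    if (pt[k] > k) db[k - 1] = '(';
    else if (pt[k] != 0) db[k - 1] = ')';
  }
  return db;
}

void validate_structure(const Seq& s, const PairTable& pt) {
  int N = (int)s.size() - 1;
  if ((int)pt.size() != N + 1)
    throw std::runtime_error("pair table length mismatch");
  for (int k = 1; k <= N; ++k) {
    int q = pt[k];
    if (q == 0) continue;
    if (q < 1 || q > N || pt[q] != k || q == k)
      throw std::runtime_error("pair table not symmetric at position " +
                               std::to_string(k));
    if (q > k) {
      if (pair_type(s[k], s[q]) == 0)
        throw std::runtime_error(
            "non-canonical pair " + std::to_string(k) + "-" +
            std::to_string(q));
      if (q - k < 4)
        throw std::runtime_error("hairpin loop closed by " + std::to_string(k) +
                                 "-" + std::to_string(q) +
                                 " has fewer than 3 unpaired nucleotides");
    }
  }
  // nestedness via a stack scan
  std::vector<int> stk;
  for (int k = 1; k <= N; ++k) {
    if (pt[k] > k) stk.push_back(k);
    else if (pt[k] != 0) {
      if (stk.empty() || stk.back() != pt[k])
        throw std::runtime_error("pseudoknot: crossing pair at position " +
                                 std::to_string(k));
      stk.pop_back();
    }
  }
}

std::pair<int, int> enclosing_face(const PairTable& pt, int x) {
  // face containing position x (or containing the pair (pt[x], x) as a
  // branch when x is paired); works for paired and unpaired x
  int k = x - 1;
  while (k >= 1) {
    int q = pt[k];
    if (q == 0) { --k; continue; }
    if (q > x) return {k, q};
    k = std::min(k, q) - 1;  // skip the closed group to the left
  }
  return {0, 0};
}

std::pair<int, int> element_label_of_face(const PairTable& pt, int i, int j) {
  if (i == 0) return {0, 0};
  while (pt[i + 1] == j - 1 && j - 1 > i + 1) { ++i; --j; }
  return {i, j};
}

Element build_element(const Seq& s, const PairTable& pt, int i, int j) {
  int N = (int)s.size() - 1;
  Element e;
  if (i == 0) {
    e.ext = true;
    e.i = N;
    e.j = 1;
    e.hlen = 0;
    int p = 1;
    while (p <= N) {
      if (pt[p] == 0) { e.ss.push_back(p); ++p; }
      else { e.branches.emplace_back(p, pt[p]); p = pt[p] + 1; }
    }
    e.degree = (int)e.branches.size();
    return e;
  }
  e.ext = false;
  e.i = i;
  e.j = j;
  // closing helix: extend outward while stacked
  int p = i, q = j;
  while (p - 1 >= 1 && q + 1 <= N && pt[p - 1] == q + 1) { --p; ++q; }
  e.hp = p;
  e.hq = q;
  e.hlen = i - p + 1;
  int k = i + 1;
  while (k < j) {
    if (pt[k] == 0) { e.ss.push_back(k); ++k; }
    else { e.branches.emplace_back(k, pt[k]); k = pt[k] + 1; }
  }
  e.degree = 1 + (int)e.branches.size();
  return e;
}

std::vector<Element> decompose_all(const Seq& s, const PairTable& pt) {
  int N = (int)s.size() - 1;
  std::vector<Element> out;
  out.push_back(build_element(s, pt, 0, 0));  // external, always present
  for (int k = 1; k <= N; ++k) {
    int q = pt[k];
    if (q <= k) continue;
    // (k,q) labels an element iff the face it closes is not a stack face
    bool stackface = (pt[k + 1] == q - 1 && q - 1 > k + 1);
    if (!stackface) out.push_back(build_element(s, pt, k, q));
  }
  return out;
}

}  // namespace rnakin
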