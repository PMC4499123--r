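// Core types for RNA secondary-structure folding kinetics.
// Positions are 1-based throughout; pair tables use 0 for "unpaired".
// Energies are handled internally in units of 0.01 kcal/mol ("decacal")
// as doubles, so that table lookups stay exact while logarithmic terms
// (long loops, multiloop growth) remain representable.
#pragma once

#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <stdexcept>
#include <string>
#include <unordered_map>
#include <utility>
#include <vector>

namespace rnakin {

// bases: 0=N, 1=A, 2=C, 3=G, 4=U
using Seq = std::vector<int>;        // index 0 unused
using PairTable = std::vector<int>;  // index 0 unused, 0 = unpaired

inline int pair_type(int a, int b) {
  // CG=1 GC=2 GU=3 UG=4 AU=5 UA=6, 0 otherwise
  if (a == 2 && b == 3) return 1;
  if (a == 3 && b == 2) return 2;
  if (a == 3 && b == 4) return 3;
  if (a == 4 && b == 3) return 4;
  if (a == 1 && b == 4) return 5;
  if (a == 4 && b == 1) return 6;
  return 0;
}

Seq encode_seq(const std::string& s);          // throws on invalid letters
std::string decode_seq(const Seq& s);

struct EnergyParams {
  std::vector<int> stack;                      // [7][7]
  std::vector<int> mm_hairpin, mm_interior, mm_int_1n, mm_int_23, mm_multi,
      mm_ext;                                  // [7][5][5]
  std::vector<int> dangle5, dangle3;           // [7][5]
  std::vector<int> int11;                      // [7][7][5][5]
  std::vector<int> int21;                      // [7][7][5][5][5]
  std::vector<int> int22;                      // [6][6][4][4][4][4]
  std::vector<int> hairpin_len, bulge_len, interior_len;  // [31], idx = size
  int ninio_m = 50, ninio_max = 300;
  int ml_unpaired = 0, ml_offset = 340, ml_branch = 40;
  int terminal_au = 50;
  double lxc = 107.856;
  bool ml_log = true;       // logarithmic multiloop growth beyond 6 unpaired
  double temperature = 310.15;  // K
  double rt_dc = 0.0019872 * 310.15 * 100.0;  // RT in 0.01 kcal/mol units
  std::vector<std::pair<std::string, int>> tetraloops, triloops, hexaloops;
  std::vector<std::pair<std::uint32_t, int>> tetra_idx;  // numeric keys
  void index_special_loops();

  void set_temperature(double tk) {
    temperature = tk;
    rt_dc = 0.0019872 * tk * 100.0;
  }
  double beta_dc() const { return 1.0 / rt_dc; }

  int st(int t1, int t2) const { return stack[(t1 - 1) * 7 + (t2 - 1)]; }
  int mm(const std::vector<int>& tab, int t, int b5, int b3) const {
    return tab[(t - 1) * 25 + b5 * 5 + b3];
  }
  int d5(int t, int b) const { return dangle5[(t - 1) * 5 + b]; }
  int d3(int t, int b) const { return dangle3[(t - 1) * 5 + b]; }
  int i11(int t1, int t2, int a, int b) const {
    return int11[((t1 - 1) * 7 + (t2 - 1)) * 25 + a * 5 + b];
  }
  int i21(int t1, int t2, int a, int b, int c) const {
    return int21[((((t1 - 1) * 7 + (t2 - 1)) * 5 + a) * 5 + b) * 5 + c];
  }
  int i22(int t1, int t2, int a, int b, int c, int d) const {
    return int22[(((((t1 - 1) * 6 + (t2 - 1)) * 4 + (a - 1)) * 4 + (b - 1)) *
                      4 + (c - 1)) * 4 + (d - 1)];
  }
  int tau(int t) const { return t >= 3 ? terminal_au : 0; }
};

// --- structure utilities -------------------------------------------------

PairTable parse_dot_bracket(const Seq& s, const std::string& db);
std::string write_dot_bracket(const PairTable& pt);
// throws std::runtime_error with a position report on invalid structures
void validate_structure(const Seq& s, const PairTable& pt);

// face = the nearest-neighbour loop enclosed by pair (i,j), or the
// exterior loop when i == 0.  Returns energy in 0.01 kcal/mol.
double face_energy(const Seq& s, const PairTable& pt, int i, int j,
                   const EnergyParams& p);

// small memo of face energies of the *current* state, used while
// enumerating the many candidate moves of one loop element
struct FaceCache {
  int anchor[24];
  double e[24];
  int n = 0;
  void reset() { n = 0; }
};
double structure_energy_dc(const Seq& s, const PairTable& pt,
                           const EnergyParams& p);

// enclosing face of position x: closing pair (i,j), or (0,0) for exterior
std::pair<int, int> enclosing_face(const PairTable& pt, int x);
// label of the loop element owning the face closed by (i,j):
// descends through stacked pairs to the innermost pair of the helix
std::pair<int, int> element_label_of_face(const PairTable& pt, int i, int j);

// --- loop elements and moves ---------------------------------------------

enum MoveKind : int {
  NUCLEATION = 0,
  EXTENSION = 1,
  RETRACTION = 2,
  INTERIOR_OPEN = 3,
  MORPH = 4,
  DEFECT_DIFFUSION = 5
};

struct Move {
  int kind = 0;
  int ri = 0, rj = 0;  // pair removed (0,0 if none)
  int ai = 0, aj = 0;  // pair added (0,0 if none)
  int nucn = 0;        // loop-closure distance for nucleation / lone removal
  double dG = 0.0;     // decacal
  double rate = 0.0;
};

struct RateParams {
  double k0 = 1.0;
  double k0n = 1.0;
  double alpha = 1.5;
};

struct Element {
  bool ext = false;
  int i = 0, j = 0;           // label (i<j); external loop labelled (N,1)
  int hp = 0, hq = 0;         // outer terminal pair of the closing helix
  int hlen = 0;               // closing-helix length (0 for external)
  int degree = 0;             // base pairs bordering the face
  std::vector<int> ss;                        // unpaired members, ascending
  std::vector<std::pair<int, int>> branches;  // branch outer pairs, in order
  std::vector<Move> moves;
  double flux = 0.0;
  int slot = -1;
};

// build the element whose face is closed by (i,j) (or external if i==0)
Element build_element(const Seq& s, const PairTable& pt, int i, int j);
std::vector<Element> decompose_all(const Seq& s, const PairTable& pt);

// generic local free-energy difference of a move, evaluated by comparing
// the affected faces before/after on a scratch pair table
double move_dG_local(const Seq& s, PairTable& pt, const Move& mv,
                     const EnergyParams& p, FaceCache* cache = nullptr);

double kawasaki_rate(double dG_dc, const RateParams& rp, double beta_dc);
double nucleation_fwd_rate(int n, const RateParams& rp);

// enumerate (and rate) all moves owned by element e; requires e built
// against the current pt.  dG computed with move_dG_local.
void enumerate_element_moves(const Seq& s, PairTable& pt, Element& e,
                             const EnergyParams& p, const RateParams& rp);

// global brute-force neighbourhood (no loop partition); independent of the
// per-element enumeration except for the shared rate formulas
std::vector<Move> bruteforce_moves(const Seq& s, PairTable& pt,
                                   const EnergyParams& p,
                                   const RateParams& rp);

// --- partial-sum tree -----------------------------------------------------

class FluxTree {
 public:
  explicit FluxTree(int capacity = 4);
  void resize_capacity(int cap);           // rebuild preserving leaves
  int capacity() const { return cap_; }
  double root() const { return node_[1]; }
  double leaf(int slot) const { return node_[cap_ + slot]; }
  int update(int slot, double v);          // returns nodes touched
  // first slot with cumulative sum strictly greater than target;
  // remainder = target minus cumulative sum before that slot
  int select(double target, double* remainder, int* nodes) const;
  void rebuild_from_leaves();
  long long updates_since_rebuild = 0;

 private:
  int cap_;
  std::vector<double> node_;  // node_[1] root; leaves at cap_..2cap_-1
};

// --- engine ---------------------------------------------------------------

struct StepStats {
  long long steps = 0;
  int max_rebuilt_preexisting = 0;
  long long total_rebuilt = 0;
  long long total_refresh_ops = 0;
  int max_tree_nodes_update = 0;
  int max_tree_nodes_select = 0;
  int max_affected_total = 0;  // rebuilt + created + destroyed
};

class Engine {
 public:
  Engine(const Seq& s, const PairTable& init, const EnergyParams& p,
         const RateParams& rp, std::uint64_t seed);

  // performs one Gillespie step; returns false when no moves remain.
  // tau receives the waiting time; fired (optional) the move taken.
  bool step(double* tau, Move* fired = nullptr);
  double total_flux() const { return tree_.root(); }
  const PairTable& pair_table() const { return pt_; }
  double time() const { return t_; }
  double energy_dc() const { return energy_dc_; }
  const StepStats& stats() const { return stats_; }
  int n_elements() const { return n_live_; }

  // full verification against the brute-force oracle (used by tests):
  // checks move multiset and rate agreement of the cached partition
  std::string verify_against_bruteforce(double tol);

  std::uint64_t rng_next() { return rng_(); }
  double unif01() { return (rng_() >> 11) * (1.0 / 9007199254740992.0); }
  double unif01_open0() {
    return ((rng_() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }

 private:
  Seq seq_;
  int N_;
  PairTable pt_;
  const EnergyParams& par_;
  RateParams rp_;
  double t_ = 0.0;
  double energy_dc_ = 0.0;
  std::mt19937_64 rng_;
  FluxTree tree_;
  std::vector<Element> elems_;   // by slot
  std::vector<char> live_;
  std::vector<int> free_slots_;  // stack, reused smallest-last
  std::unordered_map<std::int64_t, int> slot_of_;  // label key -> slot
  int n_live_ = 0;
  StepStats stats_;

  std::int64_t key(int i, int j) const {
    return (std::int64_t)i * (N_ + 2) + j;
  }
  int alloc_slot();
  void install_element(int i, int j, bool ext, std::vector<int>* rebuilt_pre);
  void remove_element(int slot);
  void collect_labels(const Move& mv, bool before,
                      std::vector<std::pair<int, int>>* out);
  void apply_and_update(const Move& mv);
  void refresh_coupled(int slot_changed, const std::vector<int>& touched);
  friend class EngineTester;
};

// --- enumeration oracle ---------------------------------------------------

// all pseudoknot-free structures with canonical pairs, min hairpin 3,
// lonely pairs allowed; guard: N <= max_n
std::vector<PairTable> enumerate_structures(const Seq& s, int max_n = 30);
// independent count by a first-position recursion (different decomposition)
double count_structures(const Seq& s);

}  // namespace rnakin
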