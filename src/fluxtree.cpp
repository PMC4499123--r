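// Partial-sum tree over per-loop fluxes: logarithmic total, update and
// weighted selection.  Leaves live at node_[cap .. 2 cap - 1]; every
// internal node holds the sum of its two children, recomputed exactly on
// each update, so the root always equals the pairwise sum of the leaves.
#include "rnakin.h"

namespace rnakin {

FluxTree::FluxTree(int capacity) {
  int c = 1;
  while (c < capacity) c <<= 1;
  cap_ = c;
  node_.assign(2 * cap_, 0.0);
}

void FluxTree::resize_capacity(int cap) {
  int c = 1;
  while (c < cap) c <<= 1;
  if (c <= cap_) return;
  std::vector<double> leaves(node_.begin() + cap_, node_.end());
  cap_ = c;
  node_.assign(2 * cap_, 0.0);
  std::copy(leaves.begin(), leaves.end(), node_.begin() + cap_);
  rebuild_from_leaves();
}

int FluxTree::update(int slot, double v) {
  if (slot < 0 || slot >= cap_)
    throw std::runtime_error("flux tree: slot out of range");
  if (v < 0)
    throw std::runtime_error("flux tree: negative flux");
  int k = cap_ + slot;
  node_[k] = v;
  int touched = 1;
  for (k >>= 1; k >= 1; k >>= 1) {
    node_[k] = node_[2 * k] + node_[2 * k + 1];
    ++touched;
  }
  if (++updates_since_rebuild >= 1000000) {
    rebuild_from_leaves();
    updates_since_rebuild = 0;
  }
  return touched;
}

int FluxTree::select(double target, double* remainder, int* nodes) const {
  if (!(target >= 0.0) || target >= node_[1])
    throw std::runtime_error("flux tree: selection target outside [0, root)");
  int k = 1, touched = 1;
  while (k < cap_) {
    double ls = node_[2 * k];
    if (target < ls) {
      k = 2 * k;
    } else {
      target -= ls;
      k = 2 * k + 1;
    }
    ++touched;
  }
  if (remainder) *remainder = target;
  if (nodes) *nodes = touched;
  return k - cap_;
}

void FluxTree::rebuild_from_leaves() {
  for (int k = cap_ - 1; k >= 1; --k)
    node_[k] = node_[2 * k] + node_[2 * k + 1];
}

}  // namespace rnakin
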