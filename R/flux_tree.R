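#' Partial-sum tree over per-loop fluxes
#'
#' Binary tree in which every internal node stores the sum of its
#' children: the root is the total flux, point updates touch only the
#' leaf-to-root path, and weighted selection descends from the root —
#' all in O(log2 capacity).
#'
#' @param values non-negative per-slot fluxes.
#' @return a `flux_tree` handle.
#' @examples
#' t <- flux_tree(c(1, 2, 3, 4))
#' flux_tree_root(t)   # 10
#' @export
flux_tree <- function(values = numeric()) {
  h <- rk_ftree_build(as.numeric(values))
  structure(list(ptr = h, n = length(values)), class = "flux_tree")
}

#' @export
print.flux_tree <- function(x, ...) {
  cat(sprintf("flux tree: %d live slots, capacity %d, root = %g\n",
              x$n, rk_ftree_capacity(x$ptr), rk_ftree_root(x$ptr)))
  invisible(x)
}

#' Update one slot of a flux tree
#' @param tree a `flux_tree`.
#' @param slot 1-based live slot index.
#' @param value new non-negative flux.
#' @return invisibly, the number of tree nodes touched.
#' @export
flux_tree_update <- function(tree, slot, value) {
  res <- rk_ftree_update(tree$ptr, as.integer(slot), as.numeric(value))
  invisible(res$nodes_touched)
}

#' Total flux (tree root)
#' @param tree a `flux_tree`.
#' @export
flux_tree_root <- function(tree) rk_ftree_root(tree$ptr)

#' Leaf values of a flux tree
#' @param tree a `flux_tree`.
#' @export
flux_tree_leaves <- function(tree) rk_ftree_leaves(tree$ptr)

#' Weighted selection from a flux tree
#'
#' Returns the first slot (in slot order) whose cumulative flux exceeds
#' `target`, together with the remainder `target - (cumulative sum before
#' the slot)`, which lies in `[0, flux_slot)`.
#'
#' @param tree a `flux_tree`.
#' @param target number in `[0, root)`.
#' @return list with `slot`, `remainder` and `nodes_touched`.
#' @export
flux_tree_select <- function(tree, target) {
  rk_ftree_select(tree$ptr, as.numeric(target))
}
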