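# Robinson-Foulds distances from explicit bipartition / clade sets.
# Splits are compared as canonical label strings so two trees never need a
# shared tip numbering.

# Non-trivial splits of a tree as canonical strings. Unrooted mode: each
# internal edge's bipartition, represented by the side NOT containing the
# alphabetically first leaf. Rooted mode: each non-root internal node's clade.
tree_splits <- function(tree, rooted = FALSE) {
  n <- length(tree$tip.label)
  work <- if (rooted) tree else ape::unroot(tree)
  parts <- ape::prop.part(work)
  labs <- attr(parts, "labels")
  ref <- sort(labs)[1]
  out <- character(0)
  for (i in seq_along(parts)) {
    if (i == 1L) next  # first entry is the full leaf set (the root)
    side <- labs[parts[[i]]]
    k <- length(side)
    if (rooted) {
      if (k < 2L || k > n - 1L) next
    } else {
      if (k < 2L || k > n - 2L) next
      if (ref %in% side) side <- setdiff(labs, side)
    }
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

check_same_leaves <- function(t1, t2) {
  d12 <- setdiff(t1$tip.label, t2$tip.label)
  d21 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d12) || length(d21))
    stop("leaf sets differ; only in tree 1: {",
         paste(sort(d12), collapse = ","), "}; only in tree 2: {",
         paste(sort(d21), collapse = ","), "}")
  invisible(TRUE)
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference between the two trees' sets of
#' non-trivial bipartitions (default, unrooted comparison: trees are
#' unrooted first) or between their clade sets (`rooted = TRUE`). The
#' caller prunes to a common leaf set first (see
#' [prune_to_common_leaves()]); mismatched leaf sets are an error.
#'
#' @param t1,t2 `"phylo"` trees on identical leaf sets.
#' @param rooted Compare rooted clades instead of unrooted bipartitions.
#' @return Non-negative integer.
#' @examples
#' rf_distance(parse_newick("((A,B),(C,D));"), parse_newick("((A,C),(B,D));"))
#' @export
rf_distance <- function(t1, t2, rooted = FALSE) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1, rooted = rooted)
  s2 <- tree_splits(t2, rooted = rooted)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Normalized Robinson-Foulds distance
#'
#' [rf_distance()] divided by the maximum possible distance, taken as the
#' total number of non-trivial internal edges (clades, in rooted mode) of
#' the two trees: `2(n - 3)` for two binary unrooted trees on `n` leaves.
#' When both trees are stars the denominator is 0 and the distance is
#' defined as 0.
#'
#' @inheritParams rf_distance
#' @return A real in `[0, 1]`.
#' @export
nrfd <- function(t1, t2, rooted = FALSE) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1, rooted = rooted)
  s2 <- tree_splits(t2, rooted = rooted)
  denom <- length(s1) + length(s2)
  if (denom == 0L) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / denom
}
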