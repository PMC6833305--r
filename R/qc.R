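# Tree-distance standardization against a bootstrap calibration, average
# bootstrap support, and the 5X long-terminal-branch filter.

#' Bootstrap quantile of ML-vs-bootstrap tree distances
#'
#' Computes the normalized Robinson-Foulds distance between an ML gene tree
#' and each of its bootstrap trees (pruning each pair to the shared leaf
#' set) and returns the empirical `q`-quantile: the smallest observed value
#' with at least `q * 100` percent of the sample less than or equal to it
#' (order statistic at rank `ceiling(q * n)`, no interpolation).
#'
#' @param ml The ML `"phylo"` gene tree.
#' @param boots List of bootstrap `"phylo"` trees (at least 1; typically 100).
#' @param q Quantile level in (0, 1]; default 0.99.
#' @return The quantile, a real in `[0, 1]`, with the full distance sample
#'   attached as attribute `"distances"`.
#' @export
distance_quantile <- function(ml, boots, q = 0.99) {
  if (inherits(boots, "phylo")) boots <- list(boots)
  if (length(boots) < 1L) stop("empty bootstrap tree list")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  d <- vapply(boots, function(b) {
    pr <- prune_to_common_leaves(ml, b, min_shared = 4)
    nrfd(pr$t1, pr$t2)
  }, numeric(1))
  s <- sort(d)
  val <- s[max(1L, ceiling(q * length(s)))]
  attr(val, "distances") <- d
  val
}

#' Standardize a tree distance by its bootstrap calibration quantile
#'
#' Divides a raw distance `D` (usually an NRFD between two ML gene trees of
#' the same locus) by the bootstrap quantile `q` from
#' [distance_quantile()]. A standardized value strictly greater than 1
#' flags the two trees as significantly incongruent: `D` falls outside the
#' bootstrap confidence region of tree distances. With `q = 0` the
#' calibration is degenerate; the value is reported as `Inf` and the flag
#' is `D > 0`.
#'
#' @param D Raw distance, `>= 0`.
#' @param q Calibration quantile, `>= 0`.
#' @return List with `raw`, `quantile`, `value` (`D/q`), `significant`.
#' @export
standardize_distance <- function(D, q) {
  if (!is.numeric(D) || D < 0) stop("D must be a non-negative real")
  if (!is.numeric(q) || q < 0) stop("q must be a non-negative real")
  if (q == 0) {
    return(list(raw = D, quantile = 0, value = if (D > 0) Inf else 0,
                significant = D > 0))
  }
  v <- D / q
  list(raw = D, quantile = q, value = v, significant = v > 1)
}

#' Average bootstrap support of a gene tree
#'
#' Arithmetic mean of the numeric internal-node support values; the root's
#' label and the leaves are excluded. Errors when no support value is
#' present.
#'
#' @param tree A `"phylo"` tree with supports in `node.label`.
#' @return Mean support (same scale as the labels, e.g. 0-100).
#' @export
mean_bootstrap_support <- function(tree) {
  sup <- node_supports(tree)
  if (ape::is.rooted(tree) && length(sup)) sup <- sup[-1L]  # node.label[1] is the root
  sup <- sup[!is.na(sup)]
  if (!length(sup)) stop("tree carries no internal support values")
  mean(sup)
}

#' Flag leaves with unusually long terminal branches
#'
#' The sequence filter applied after per-locus tree estimation: the
#' reference tree (typically the concatenation tree) is pruned to the gene
#' tree's leaf set (merged edges summed), and a leaf is flagged when its
#' terminal branch in the gene tree is at least `factor` times the terminal
#' branch of the same leaf in the pruned reference ("5X or longer"). A leaf
#' whose pruned-reference terminal branch is 0 is flagged iff its
#' gene-tree terminal branch is positive. Gene-tree leaves absent from the
#' reference are skipped and recorded in the `"skipped"` attribute with a
#' warning.
#'
#' @param gene_tree Gene `"phylo"` tree with branch lengths.
#' @param reference Reference `"phylo"` tree with branch lengths.
#' @param factor Length-ratio threshold, default 5.
#' @return Character vector of flagged leaf labels; attributes `"ratios"`
#'   (named ratio per tested leaf) and `"skipped"`.
#' @export
long_branch_flags <- function(gene_tree, reference, factor = 5) {
  if (is.null(gene_tree$edge.length))
    stop("gene tree lacks branch lengths (first edge ",
         paste(gene_tree$edge[1, ], collapse = "->"), ")")
  if (is.null(reference$edge.length))
    stop("reference tree lacks branch lengths (first edge ",
         paste(reference$edge[1, ], collapse = "->"), ")")
  skipped <- setdiff(gene_tree$tip.label, reference$tip.label)
  shared <- intersect(gene_tree$tip.label, reference$tip.label)
  if (length(shared) < 4L)
    stop("gene tree and reference share only ", length(shared),
         " leaves (need >= 4)")
  if (length(skipped))
    warning("leaves absent from reference, skipped: ",
            paste(skipped, collapse = ", "))
  ref_p <- ape::keep.tip(reference, shared)
  g_len <- terminal_lengths(gene_tree)[shared]
  r_len <- terminal_lengths(ref_p)[shared]
  flagged <- ifelse(r_len == 0, g_len > 0, g_len >= factor * r_len)
  ratios <- ifelse(r_len == 0, ifelse(g_len > 0, Inf, 0), g_len / r_len)
  names(ratios) <- shared
  out <- shared[flagged]
  attr(out, "ratios") <- ratios
  attr(out, "skipped") <- skipped
  out
}

terminal_lengths <- function(tree) {
  n <- length(tree$tip.label)
  idx <- match(seq_len(n), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}
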