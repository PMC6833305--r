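#' Parse a newick string into a phylo tree
#'
#' Trees throughout the package are [ape::read.tree()] `"phylo"` objects:
#' leaf labels in `tip.label`, optional branch lengths in `edge.length`,
#' and internal node labels (read as bootstrap/posterior supports when
#' numeric) in `node.label`. On top of ape's parser this wrapper enforces
#' the package's tree invariants: a single statement, unique leaf labels,
#' and non-negative branch lengths.
#'
#' @param text A single newick statement ending in `";"`.
#' @return An object of class `"phylo"`. The tree is rooted (in the
#'   [ape::is.rooted()] sense) iff the basal node has exactly two children.
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.95:0.5,C:2);")
#' node_supports(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("parse error: input must be a single non-empty newick string")
  text <- trimws(text)
  if (!endsWith(text, ";"))
    stop("parse error: newick statement must end in ';' (got '",
         substr(text, nchar(text), nchar(text)), "')")
  if (sum(gregexpr(";", text, fixed = TRUE)[[1]] > 0) > 1L)
    stop("parse error: more than one newick statement supplied")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("parse error: not a valid newick statement")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length(s) present")
  invisible(tree)
}

#' Serialize a tree to newick
#'
#' Round-trip stable with [parse_newick()] up to child order; branch lengths
#' are written with `digits` significant digits.
#'
#' @param tree A `"phylo"` tree.
#' @param digits Significant digits for branch lengths (default 6).
#' @return A newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 6) {
  if (!inherits(tree, "phylo")) stop("write_newick: not a 'phylo' tree")
  if (length(tree$tip.label) == 0L) stop("write_newick: empty tree")
  ape::write.tree(tree, digits = digits)
}

#' Read / write multi-tree newick files (one statement per line)
#'
#' The RAxML bootstrap-file convention: each line holds one newick tree.
#'
#' @param path File path.
#' @return `read_trees()` returns a list of `"phylo"` trees (class
#'   `"multiPhylo"`); `write_trees()` returns `path` invisibly.
#' @export
read_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  for (t in trees) validate_tree(t)
  trees
}

#' @rdname read_trees
#' @param trees A `"phylo"` or list of them.
#' @param digits Significant digits for branch lengths.
#' @export
write_trees <- function(trees, path, digits = 6) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1), digits = digits), path)
  invisible(path)
}

#' Numeric internal-node support values of a tree
#'
#' @param tree A `"phylo"` tree whose `node.label` holds supports.
#' @return Numeric vector, one entry per internal node (`NA` where the label
#'   is absent or non-numeric), in `node.label` order (root first).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Root a tree with an outgroup
#'
#' Places the root on the branch separating `outgroup` from the remaining
#' leaves. Errors if the outgroup is not present or not monophyletic in the
#' unrooted tree.
#'
#' @param tree A `"phylo"` tree (rooted or unrooted).
#' @param outgroup Character vector of one or more leaf labels.
#' @param drop If `TRUE`, remove the outgroup leaves after rooting.
#' @return A rooted `"phylo"` tree.
#' @export
root_by_outgroup <- function(tree, outgroup, drop = FALSE) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup label(s) absent from tree: ", paste(missing, collapse = ", "))
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(utree, outgroup)) {
    stop("outgroup is not monophyletic in the unrooted tree; conflicting split: {",
         paste(sort(outgroup), collapse = ","), "} vs {",
         paste(sort(setdiff(tree$tip.label, outgroup)), collapse = ","), "}")
  }
  rooted <- ape::root(utree, outgroup = outgroup, resolve.root = TRUE)
  if (drop) rooted <- ape::drop.tip(rooted, outgroup)
  rooted
}

#' Prune two trees to their shared leaf set
#'
#' Both trees are restricted to the leaves they have in common; degree-2
#' nodes created by pruning are suppressed and their incident branch lengths
#' summed (via [ape::keep.tip()]).
#'
#' @param t1,t2 `"phylo"` trees.
#' @param min_shared Minimum shared leaf count (default 3; use 4 when the
#'   result feeds an unrooted distance).
#' @return A list with elements `t1`, `t2` and `shared` (the common labels).
#' @export
prune_to_common_leaves <- function(t1, t2, min_shared = 3) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < min_shared)
    stop("trees share only ", length(shared), " leaves (need >= ",
         min_shared, ")")
  list(t1 = ape::keep.tip(t1, shared),
       t2 = ape::keep.tip(t2, shared),
       shared = sort(shared))
}
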