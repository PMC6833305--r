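# Shared fixtures and independent oracles.

nwk <- function(s) parse_newick(s)

# All 15 unrooted binary 5-taxon topologies with their non-trivial splits
# known BY CONSTRUCTION: such a tree is exactly a pair of disjoint cherries
# {x,y} and {z,w} plus a fifth tip at the central node, and its two
# non-trivial bipartitions are those cherries. This enumeration never touches
# the package's split machinery.
five_taxon_topologies <- function(taxa = c("a", "b", "c", "d", "e")) {
  out <- list()
  pairs <- utils::combn(taxa, 2, simplify = FALSE)
  for (c1 in pairs) {
    rest <- setdiff(taxa, c1)
    for (c2 in utils::combn(rest, 2, simplify = FALSE)) {
      key <- paste(sort(c(paste(sort(c1), collapse = ""),
                          paste(sort(c2), collapse = ""))), collapse = "/")
      if (!is.null(out[[key]])) next
      v <- setdiff(rest, c2)
      out[[key]] <- list(
        newick = sprintf("((%s,%s),(%s,%s),%s);", c1[1], c1[2],
                         c2[1], c2[2], v),
        splits = c(paste(sort(c1), collapse = ""),
                   paste(sort(c2), collapse = "")))
    }
  }
  out
}

oracle_rf <- function(splits1, splits2) {
  length(setdiff(splits1, splits2)) + length(setdiff(splits2, splits1))
}

# One rooted NNI neighbor of a rooted binary tree: at internal non-root node
# v with parent u, swap one child subtree of v with v's sibling. Pure edge
# surgery on the phylo edge matrix.
rooted_nni <- function(tree, which_node = 1L, which_child = 1L) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  internals <- setdiff((nt + 1L):(nt + tree$Nnode), root)
  v <- internals[which_node]
  u <- tree$edge[match(v, tree$edge[, 2]), 1]
  ch_v <- tree$edge[tree$edge[, 1] == v, 2]
  sib <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  b <- ch_v[which_child]
  e_vb <- which(tree$edge[, 1] == v & tree$edge[, 2] == b)
  e_us <- which(tree$edge[, 1] == u & tree$edge[, 2] == sib)
  tree$edge[e_vb, 1] <- u
  tree$edge[e_us, 1] <- v
  # normalize through newick so downstream code sees a clean phylo
  parse_newick(ape::write.tree(tree))
}

# Balanced 5-taxon species tree with all internal branch lengths tau.
balanced_sp5 <- function(tau) {
  tr <- parse_newick("(((A:0,B:0):1,C:0):1,(D:0,E:0):1):0;")
  tr$edge.length[tr$edge.length == 1] <- tau
  species_tree_cu(tr)
}

withr_like_tempdir <- function() {
  d <- tempfile("clitest")
  dir.create(d)
  d
}

# Columns are AAAA, AATT, ATCG, A-A-: only column 2 is informative.
toy_alignment <- function() {
  rbind(s1 = c("A", "A", "A", "A"),
        s2 = c("A", "A", "T", "-"),
        s3 = c("A", "T", "C", "A"),
        s4 = c("A", "T", "G", "-"))
}
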