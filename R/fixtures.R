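# Synthetic-data generators: random species trees, Jukes-Cantor alignments,
# and a long-branch fixture helper. Everything is a pure function of its seed
# and parameters so fixtures can be rebuilt in tests rather than stored.

# Run expr with R's RNG temporarily seeded; global RNG state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random species tree in coalescent units
#'
#' Builds a rooted binary topology by random sequential joining (repeatedly
#' fusing two uniformly chosen subtrees) and draws each internal branch
#' length uniformly from `tau_range`. Terminal branch lengths are set to 0
#' (they carry no information under the one-allele pseudo-likelihood).
#'
#' @param n_taxa Number of species (`>= 3`).
#' @param tau_range Length-2 vector `(lo, hi)` of coalescent units, `0 <=
#'   lo <= hi`.
#' @param seed Integer seed.
#' @param labels Tip labels (default `t1..tn`).
#' @return A [species_tree_cu()] tree.
#' @examples
#' random_species_tree(5, c(2, 2), seed = 1)  # all internal edges exactly 2
#' @export
random_species_tree <- function(n_taxa, tau_range = c(0.5, 2), seed = 1,
                                labels = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (length(tau_range) != 2 || tau_range[1] < 0 || tau_range[1] > tau_range[2])
    stop("tau_range must be (lo, hi) with 0 <= lo <= hi")
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n_taxa))
  if (length(labels) != n_taxa) stop("need one label per taxon")
  with_seed(seed, {
    sub <- as.list(labels)
    while (length(sub) > 1L) {
      ij <- sample.int(length(sub), 2L)
      sub[[ij[1]]] <- paste0("(", sub[[ij[1]]], ",", sub[[ij[2]]], ")")
      sub[[ij[2]]] <- NULL
    }
    tree <- parse_newick(paste0(sub[[1]], ";"))
    k <- length(param_nodes(tree))
    tau <- stats::runif(k, tau_range[1], tau_range[2])
    species_tree_cu(set_internal_edge_lengths(tree, tau))
  })
}

#' Simulate an alignment under the Jukes-Cantor model
#'
#' I.i.d. sites: the root state is uniform over A/C/G/T and along an edge
#' of length `b` (expected substitutions per site) each site changes to a
#' specific other state with probability `(1/4)(1 - exp(-4 b / 3))`.
#'
#' @param tree A `"phylo"` tree with branch lengths on all edges.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return Character-matrix alignment (rows = tips).
#' @export
jc_simulate_alignment <- function(tree, n_sites, seed = 1) {
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (n_sites < 1) stop("n_sites must be >= 1")
  bases <- c("A", "C", "G", "T")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  with_seed(seed, {
    states <- matrix(0L, nn, n_sites)
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
    # edges in cladewise order: parents are assigned before children
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; b <- tree$edge.length[e]
      p_change <- 0.75 * (1 - exp(-4 * b / 3))
      s <- states[p, ]
      mut <- stats::runif(n_sites) < p_change
      if (any(mut)) {
        shift <- sample.int(3L, sum(mut), replace = TRUE)
        s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
      }
      states[ch, ] <- s
    }
    aln <- matrix(bases[states[seq_len(nt), , drop = FALSE]], nt, n_sites)
    rownames(aln) <- tree$tip.label
    aln
  })
}

#' Multiply one leaf's terminal branch by a factor
#'
#' Deterministic fixture for exercising [long_branch_flags()]: returns the
#' tree with the terminal branch of `leaf` scaled by `factor`.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param leaf Leaf label.
#' @param factor Multiplier (`5` reproduces the filter's threshold case).
#' @export
stretch_terminal_branch <- function(tree, leaf, factor) {
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop("leaf not in tree: ", leaf)
  e <- match(i, tree$edge[, 2])
  tree$edge.length[e] <- tree$edge.length[e] * factor
  tree
}
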