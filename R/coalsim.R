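# R-facing wrappers around the C++ censored-coalescent simulator.

# Flatten a species tree into the arrays the C++ core expects (0-based).
# Heights are decorative (they give gene trees sensible node times) and are
# computed bottom-up with terminal branch lengths taken as given.
sp_encode <- function(sp) {
  sp <- species_tree_cu(sp)
  nt <- length(sp$tip.label)
  nn <- nt + sp$Nnode
  root <- nt + 1L
  parent <- integer(nn)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  blen <- numeric(nn)
  blen[sp$edge[, 2]] <- sp$edge.length
  child <- matrix(-1L, nn, 2)
  slot <- integer(nn)
  for (e in seq_len(nrow(sp$edge))) {
    p <- sp$edge[e, 1]
    slot[p] <- slot[p] + 1L
    child[p, slot[p]] <- sp$edge[e, 2] - 1L
  }
  depth <- integer(nn)
  for (v in seq_len(nn)) {
    x <- v
    while (x != root) { depth[v] <- depth[v] + 1L; x <- parent[x] }
  }
  internals <- root:nn
  postorder <- internals[order(depth[internals], decreasing = TRUE)]
  dur <- rep(Inf, nn)
  nonroot_int <- setdiff(internals, root)
  dur[nonroot_int] <- blen[nonroot_int]
  height <- numeric(nn)
  for (v in postorder) {
    ch <- child[v, ] + 1L
    ch <- ch[ch > 0L]
    height[v] <- max(height[ch] + blen[ch])
  }
  list(S = nt, child = child, dur = dur, height = height,
       postorder = as.integer(postorder - 1L), labels = sp$tip.label)
}

occupancy_index <- function(occupancy, labels) {
  lapply(occupancy, function(taxa) {
    idx <- match(taxa, labels)
    if (anyNA(idx))
      stop("taxa not in species tree: ",
           paste(taxa[is.na(idx)], collapse = ", "))
    if (!length(idx)) stop("empty taxon set in occupancy")
    as.integer(idx - 1L)
  })
}

# Fast path used by the bootstrap: simulate genes and return only their
# aggregated rooted-triple counts.
sim_triple_counts <- function(sp, occupancy, seed, offset = 0) {
  enc <- sp_encode(sp)
  species <- sort(enc$labels)
  triples <- species_triples(species)
  tri_idx <- matrix(match(triples, enc$labels) - 1L, ncol = 3)
  occ <- occupancy_index(occupancy, enc$labels)
  cnt <- sim_triple_counts_cpp(enc$S, enc$child, enc$dur, enc$height,
                               enc$postorder, occ, tri_idx,
                               as.numeric(seed), as.numeric(offset))
  dimnames(cnt) <- list(triple_names(triples), c("ab", "ac", "bc"))
  structure(cnt, class = "triple_table", species = species)
}

#' Simulate one rooted gene tree under the censored coalescent
#'
#' One lineage enters at each requested leaf; within each internal
#' population of duration `tau` (coalescent units), while `k >= 2` lineages
#' remain the next coalescence is exponential with rate `k(k-1)/2` and is
#' applied only if it falls within the remaining duration, merging a
#' uniformly random pair; the root population runs until a single lineage
#' remains. Node heights (coalescent units) are attached as branch lengths.
#'
#' @param sp A [species_tree_cu()] tree with internal branch lengths.
#' @param taxa Leaf subset to sample (default: all species).
#' @param seed Integer seed; the same seed and inputs give the identical
#'   tree.
#' @return A rooted `"phylo"` gene tree.
#' @export
simulate_gene_tree <- function(sp, taxa = NULL, seed = 1) {
  sp <- species_tree_cu(sp)
  if (is.null(taxa)) taxa <- sp$tip.label
  if (!length(taxa)) stop("empty taxon set")
  simulate_gene_tree_set(sp, occupancy = list(taxa), seed = seed)[[1L]]
}

#' Simulate a set of rooted gene trees
#'
#' Independent gene trees from the censored multispecies coalescent, gene
#' `i` restricted to `occupancy[[i]]`. Gene `i` draws from its own RNG
#' stream derived from `(seed, i)`, so the set is reproducible and
#' per-gene order-independent.
#'
#' @param sp A [species_tree_cu()] tree with internal branch lengths.
#' @param n Number of complete genes (all species present); ignored when
#'   `occupancy` is given.
#' @param occupancy List of taxon subsets, one per gene.
#' @param seed Integer seed.
#' @return A `"multiPhylo"` list of rooted gene trees.
#' @examples
#' sp <- species_tree_cu("((A:0,B:0):1,C:0):0;")
#' genes <- simulate_gene_tree_set(sp, n = 50, seed = 42)
#' triple_counts(genes)
#' @export
simulate_gene_tree_set <- function(sp, n = NULL, occupancy = NULL, seed = 1) {
  sp <- species_tree_cu(sp)
  if (is.null(occupancy)) {
    if (is.null(n)) stop("give either n or occupancy")
    occupancy <- rep(list(sp$tip.label), n)
  }
  enc <- sp_encode(sp)
  occ <- occupancy_index(occupancy, enc$labels)
  raw <- sim_gene_trees_cpp(enc$S, enc$child, enc$dur, enc$height,
                            enc$postorder, occ, as.numeric(seed), 0)
  trees <- lapply(raw, function(x) {
    tr <- list(edge = x$edge, edge.length = as.numeric(x$edge.length),
               Nnode = as.integer(x$Nnode),
               tip.label = enc$labels[x$tip + 1L])
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

# TMRCA heights of simulated complete genes (calibration helper).
sim_root_times <- function(sp, n, seed, taxa = NULL) {
  sp <- species_tree_cu(sp)
  if (is.null(taxa)) taxa <- sp$tip.label
  enc <- sp_encode(sp)
  occ <- occupancy_index(rep(list(taxa), n), enc$labels)
  sim_root_times_cpp(enc$S, enc$child, enc$dur, enc$height, enc$postorder,
                     occ, as.numeric(seed), 0)
}
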