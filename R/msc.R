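# Multispecies-coalescent pseudo-likelihood of a species tree from rooted
# triples, with branch-length optimization on a fixed topology.
#
# The sufficient statistic is the per-triple multinomial of rooted
# resolutions across gene trees: for species a < b < c (alphabetical), the
# probability that a gene tree shows the species-tree-concordant pair is
# 1 - (2/3) exp(-tau) and each discordant resolution has probability
# (1/3) exp(-tau), where tau is the total internal branch length (coalescent
# units) separating the concordant pair's MRCA from the triple's MRCA.

#' Species tree in coalescent units
#'
#' Validates a rooted binary `"phylo"` tree as a species tree whose
#' *internal* branch lengths are in coalescent units. Terminal branch
#' lengths carry no information under the one-allele-per-species
#' pseudo-likelihood and are ignored (and set to 0 when absent).
#'
#' @param tree A rooted binary `"phylo"` tree (or newick string).
#' @param require_lengths Demand internal branch lengths (needed for
#'   simulation and likelihood evaluation, not for a topology to be fitted).
#' @return The tree with class `c("species_tree_cu", "phylo")`.
#' @export
species_tree_cu <- function(tree, require_lengths = TRUE) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (!inherits(tree, "phylo")) stop("species tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  validate_tree(tree)
  if (is.null(tree$edge.length)) {
    if (require_lengths) stop("species tree lacks branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("species-tree branch lengths must be finite and >= 0")
  class(tree) <- unique(c("species_tree_cu", class(tree)))
  tree
}

# Canonical sorted triples of a species set, as a 3-column label matrix.
species_triples <- function(species) {
  species <- sort(unique(species))
  if (length(species) < 3L) {
    return(matrix(character(0), 0, 3))
  }
  t(utils::combn(species, 3))
}

triple_names <- function(triples) {
  apply(triples, 1L, paste, collapse = "|")
}

#' Rooted-triple counts of a gene-tree set
#'
#' For every unordered species triple `{a, b, c}` (labels sorted), counts
#' how many gene trees resolve it as `ab|c`, `ac|b`, and `bc|a` (which pair
#' coalesces below the triple's MRCA). Genes missing any of the three taxa,
#' or leaving the triple unresolved at a polytomy, contribute nothing to
#' that triple.
#'
#' @param genes List of **rooted** `"phylo"` gene trees (a `"multiPhylo"`
#'   works).
#' @param species Species label set; defaults to the union of gene-tree
#'   leaf labels.
#' @return Integer matrix of class `"triple_table"`: one row per triple
#'   (rowname `"a|b|c"`), columns `ab`, `ac`, `bc`.
#' @examples
#' genes <- lapply(c("((A,B),C);", "((A,B),C);", "((A,C),B);"), parse_newick)
#' triple_counts(genes)
#' @export
triple_counts <- function(genes, species = NULL) {
  if (inherits(genes, "phylo")) genes <- list(genes)
  genes <- unclass(genes)
  if (!length(genes)) stop("empty gene-tree set")
  if (is.null(species)) species <- unique(unlist(lapply(genes, `[[`, "tip.label")))
  triples <- species_triples(species)
  counts <- matrix(0L, nrow(triples), 3L,
                   dimnames = list(triple_names(triples), c("ab", "ac", "bc")))
  for (g in genes) {
    # the 3-leaf star is a rooted-but-unresolved triple, not an unrooted tree
    if (!ape::is.rooted(g) &&
        !(length(g$tip.label) == 3L && g$Nnode == 1L))
      stop("gene tree is unrooted; root it first (see root_by_outgroup)")
    tl <- g$tip.label
    if (length(tl) < 3L) next
    keep <- which(triples[, 1] %in% tl & triples[, 2] %in% tl &
                    triples[, 3] %in% tl)
    if (!length(keep)) next
    m <- ape::mrca(g)
    for (r in keep) {
      a <- triples[r, 1]; b <- triples[r, 2]; cc <- triples[r, 3]
      mab <- m[a, b]; mac <- m[a, cc]; mbc <- m[b, cc]
      if (mab == mac && mac == mbc) next  # polytomy: unresolved triple
      col <- if (mac == mbc) 1L else if (mab == mbc) 2L else 3L
      counts[r, col] <- counts[r, col] + 1L
    }
  }
  structure(counts, class = "triple_table", species = sort(unique(species)))
}

#' Rooted-triple probabilities under the coalescent
#'
#' For a species triple whose concordant pair is separated from the triple
#' MRCA by internal length `tau` (coalescent units), the gene-tree
#' resolution is concordant with probability `1 - (2/3) exp(-tau)` and each
#' discordant resolution has probability `(1/3) exp(-tau)`.
#'
#' @param tau Internal branch length, `>= 0` (vectorized).
#' @return Matrix with columns `concordant`, `discordant1`, `discordant2`
#'   (rows sum to 1).
#' @examples
#' triple_probs(0)  # star tree: 1/3 each
#' triple_probs(1)[, "concordant"]  # 0.7547470
#' @export
triple_probs <- function(tau) {
  if (any(is.na(tau)) || any(tau < 0)) stop("tau must be >= 0")
  e <- exp(-tau)
  cbind(concordant = 1 - (2 / 3) * e,
        discordant1 = (1 / 3) * e,
        discordant2 = (1 / 3) * e)
}

#' Internal branch length governing a species triple
#'
#' The sum of internal branch lengths on the path from the MRCA of the
#' species-tree-concordant pair up to the MRCA of all three species.
#'
#' @param sp A [species_tree_cu()] tree.
#' @param triple Character vector of 3 species labels.
#' @return Non-negative real (coalescent units).
#' @export
triple_tau <- function(sp, triple) {
  sp <- species_tree_cu(sp)
  if (length(triple) != 3L) stop("triple must name exactly 3 species")
  missing <- setdiff(triple, sp$tip.label)
  if (length(missing)) stop("species missing from tree: ",
                            paste(missing, collapse = ", "))
  mod <- triple_model(sp, matrix(sort(triple), 1L, 3L))
  sum(mod$P[1L, ] * internal_edge_lengths(sp))
}

# --- internal machinery -----------------------------------------------------

# Parameter edges of a rooted binary species tree: edges whose child is a
# non-root internal node (n - 2 of them for n tips). Returns node ids.
param_nodes <- function(sp) {
  nt <- length(sp$tip.label)
  setdiff((nt + 1L):(nt + sp$Nnode), nt + 1L)
}

internal_edge_lengths <- function(sp) {
  pn <- param_nodes(sp)
  if (!length(pn)) return(numeric(0))
  sp$edge.length[match(pn, sp$edge[, 2])]
}

set_internal_edge_lengths <- function(sp, tau) {
  pn <- param_nodes(sp)
  sp$edge.length <- rep(0, nrow(sp$edge))
  sp$edge.length[match(pn, sp$edge[, 2])] <- tau
  sp
}

# For each triple (rows of a sorted 3-column label matrix): which count
# column (ab/ac/bc) is concordant with `sp`, and the 0/1 incidence of
# parameter edges on the path MRCA(pair) -> MRCA(triple).
triple_model <- function(sp, triples) {
  nt <- length(sp$tip.label)
  nn <- nt + sp$Nnode
  parent <- integer(nn)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  pn <- param_nodes(sp)
  pid <- integer(nn)
  pid[pn] <- seq_along(pn)
  m <- ape::mrca(sp)
  k <- nrow(triples)
  P <- matrix(0, k, length(pn))
  conc <- integer(k)
  for (i in seq_len(k)) {
    a <- triples[i, 1]; b <- triples[i, 2]; cc <- triples[i, 3]
    mab <- m[a, b]; mac <- m[a, cc]; mbc <- m[b, cc]
    if (mac == mbc) { conc[i] <- 1L; top <- mac; bot <- mab }
    else if (mab == mbc) { conc[i] <- 2L; top <- mab; bot <- mac }
    else { conc[i] <- 3L; top <- mab; bot <- mbc }
    x <- bot
    while (x != top) {
      P[i, pid[x]] <- 1
      x <- parent[x]
    }
  }
  list(P = P, concordant = conc)
}

# Align a triple_table to a species tree: rows restricted to triples whose
# species all occur in sp, with columns reordered to (concordant, disc, disc).
align_counts <- function(sp, counts) {
  if (!inherits(counts, "triple_table")) stop("counts must be a triple_table")
  triples <- do.call(rbind, strsplit(rownames(counts), "|", fixed = TRUE))
  extra <- setdiff(attr(counts, "species"), sp$tip.label)
  if (length(extra))
    stop("triple counts mention species absent from the tree: ",
         paste(extra, collapse = ", "))
  keep <- triples[, 1] %in% sp$tip.label & triples[, 2] %in% sp$tip.label &
    triples[, 3] %in% sp$tip.label
  triples <- triples[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  mod <- triple_model(sp, triples)
  n_conc <- counts[cbind(seq_len(nrow(counts)), mod$concordant)]
  n_disc <- rowSums(counts) - n_conc
  list(P = mod$P, n_conc = as.numeric(n_conc), n_disc = as.numeric(n_disc))
}

PROB_FLOOR <- 1e-300

msc_loglik_tau <- function(tau, al) {
  T <- drop(al$P %*% tau)
  p <- 1 - (2 / 3) * exp(-T)
  sum(al$n_conc * log(pmax(p, PROB_FLOOR))) +
    sum(al$n_disc * (log(1 / 3) - T))
}

msc_grad_tau <- function(tau, al) {
  T <- drop(al$P %*% tau)
  e <- exp(-T)
  p <- pmax(1 - (2 / 3) * e, PROB_FLOOR)
  dT <- al$n_conc * ((2 / 3) * e / p) - al$n_disc
  drop(crossprod(al$P, dT))
}

#' Pseudo-loglikelihood of a species tree given triple counts
#'
#' Sum over species triples of the multinomial loglikelihood of the
#' observed rooted resolutions under [triple_probs()] evaluated at
#' [triple_tau()]. Triples with zero total count contribute 0;
#' probabilities are floored at `1e-300`.
#'
#' @param sp A [species_tree_cu()] tree with internal branch lengths.
#' @param counts A `"triple_table"` from [triple_counts()], on a species
#'   set contained in `sp`'s.
#' @return The pseudo-loglikelihood (a real, `<= 0`).
#' @export
pseudo_loglik <- function(sp, counts) {
  sp <- species_tree_cu(sp)
  al <- align_counts(sp, counts)
  msc_loglik_tau(internal_edge_lengths(sp), al)
}

#' Fit coalescent-unit branch lengths on a fixed topology
#'
#' Maximizes the pseudo-loglikelihood over the internal branch lengths of a
#' rooted binary topology, within box bounds. The objective is concave in
#' the natural branch-length scale, so bounded L-BFGS-B from a small fixed
#' set of starting vectors is deterministic and finds the global optimum;
#' `start` overrides the default multi-start (used internally for
#' warm-started bootstrap refits).
#'
#' @param topology Rooted binary `"phylo"` tree (lengths, if any, ignored).
#' @param counts A `"triple_table"`.
#' @param tau_min,tau_max Box bounds on each internal length (defaults
#'   `1e-6`, `10`).
#' @param start Optional numeric start vector (one value recycled, or one
#'   per internal edge).
#' @return List of class `"msc_fit"`: `tree` (a [species_tree_cu()] with
#'   fitted internal lengths, terminal lengths 0), `loglik`, `tau`.
#' @examples
#' cnt <- triple_counts(lapply(rep(c("((A,B),C);", "((A,C),B);"), c(3, 1)),
#'                             parse_newick))
#' fit_branch_lengths(parse_newick("((A,B),C);"), cnt)$tau  # -log(3 * 0.25 / 2)
#' @export
fit_branch_lengths <- function(topology, counts, tau_min = 1e-6, tau_max = 10,
                               start = NULL) {
  sp <- species_tree_cu(topology, require_lengths = FALSE)
  al <- align_counts(sp, counts)
  k <- ncol(al$P)
  if (k == 0L) {
    fitted <- set_internal_edge_lengths(sp, numeric(0))
    return(structure(list(tree = fitted, loglik = msc_loglik_tau(numeric(0), al),
                          tau = numeric(0)), class = "msc_fit"))
  }
  starts <- if (is.null(start)) list(rep(0.1, k), rep(1, k), rep(3, k))
  else list(pmin(pmax(rep(start, length.out = k), tau_min), tau_max))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, fn = function(x) -msc_loglik_tau(x, al),
                        gr = function(x) -msc_grad_tau(x, al),
                        method = "L-BFGS-B", lower = tau_min, upper = tau_max,
                        control = list(maxit = 200L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  tau <- best$par
  fitted <- set_internal_edge_lengths(sp, tau)
  structure(list(tree = species_tree_cu(fitted), loglik = -best$value,
                 tau = tau), class = "msc_fit")
}

#' @export
print.msc_fit <- function(x, ...) {
  cat("MSC pseudo-likelihood fit\n")
  cat("  internal edges:", length(x$tau), "\n")
  cat("  tau:", paste(signif(x$tau, 5), collapse = ", "), "\n")
  cat("  loglik:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}
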