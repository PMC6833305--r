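---
title: "Comparing species trees against gene trees under the multispecies coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing species trees against gene trees under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaltest)
```

## The problem

Phylogenomic pipelines routinely produce several competing species trees for
the same data: a concatenation tree, and gene-tree summary trees from methods
such as ASTRAL, STAR or NJst. Bootstrap support values measure each tree's
internal stability but do not compare one tree *against another*. `coaltest`
implements a direct comparison: given a collection of rooted gene trees, any
two candidate species-tree topologies can be scored under the multispecies
coalescent (MSC) and tested against each other with a parametric-bootstrap
likelihood ratio test (the *coalescent bootstrap LRT*, cbLRT). Around that
core the package provides the supporting statistics such comparisons need in
practice: Robinson–Foulds distances standardized by bootstrap calibration,
alignment informativeness summaries, a long-terminal-branch sequence filter,
and standardized divergence-time comparison.

## The model

Under the MSC with one sampled allele per species, the probability that a
gene tree resolves a species triple $\{a, b, c\}$ concordantly with the
species tree is

$$P(\text{concordant}) = 1 - \tfrac{2}{3}e^{-\tau},$$

and each discordant resolution has probability $\tfrac13 e^{-\tau}$, where
$\tau$ is the total *internal* branch length, in coalescent units, on the
path from the MRCA of the concordant pair to the MRCA of the triple. A
coalescent unit is time divided by $2N$ generations; $\tau = 0$ is a hard
polytomy (all three resolutions equally likely), $\tau \gtrsim 5$ makes
discordance negligible.

The pseudo-loglikelihood of a species tree $S$ given gene trees is the sum
over species triples of the multinomial loglikelihood of the observed
rooted-triple counts $(n_{ab|c}, n_{ac|b}, n_{bc|a})$ under these
probabilities. It is a *composite* likelihood — triples overlap and are not
independent — but its maximizer is consistent for the species tree and its
branch lengths, and it is the quantity maximized by MP-EST-style methods.
Terminal branches carry no information (a single lineage cannot coalesce
with itself), so the package fits and reports only internal lengths.

### Branch-length optimization

`fit_branch_lengths()` maximizes the pseudo-loglikelihood over the $n-2$
internal branch lengths of a fixed rooted binary topology, within box
bounds $[\tau_{\min}, \tau_{\max}] = [10^{-6}, 10]$. Each triple term is
concave in the path length $T$, and $T$ is a nonnegative linear map of the
edge lengths, so the objective is concave on the natural scale. We
therefore use bounded L-BFGS-B with the analytic gradient, from a fixed
three-vector multi-start ($\tau = 0.1, 1, 3$ on all edges) — deterministic,
and the multi-start is insurance rather than necessity. We deliberately do
*not* optimize on the log scale: log-reparameterization destroys the
concavity that makes the natural-scale problem easy. Bootstrap refits
inside the cbLRT warm-start from the observed fit (a single start), which
is both faster and deterministic. Probabilities are floored at $10^{-300}$
so boundary fits never produce $-\infty$.

The bounds matter only at the extremes: a triple whose concordant fraction
$\hat p \le 1/3$ drives its path to $\tau_{\min}$, and perfectly concordant
triples drive it to $\tau_{\max}$; both are reported as-is.

## The cbLRT

Given null tree $T_0$ and alternative $T_1$, both with branch lengths
freshly fitted, the statistic is $t^\* = 2(\log L_1 - \log L_0)$. Its null
distribution is approximated by simulating `n_boot` gene-tree sets from
$T_0$ with its fitted branch lengths, re-fitting *both* topologies on each
replicate, and recomputing $t_i$. The p-value is the exact count ratio
$\#\{t_i \ge t^\*\}/n$, ties counting toward the null, and the null is
rejected when $p \le \alpha$.

Design choices worth knowing:

* **Occupancy is replicated.** Each bootstrap gene inherits the taxon set
  of the corresponding observed gene, because triple coverage shapes the
  null distribution.
* **Branch lengths are re-optimized on every bootstrap replicate.**
  Without re-optimization the null distribution ignores estimation noise.
* **Roles are kept as given by default.** The test simulates from the tree
  you designate as the null, and $t^\*$ is negative when the null fits
  better. An optional `swap_roles = TRUE` relabels the lower-scoring tree
  as the null after fitting, which makes the call symmetric in input order
  — the convention used when candidates are first sorted by likelihood —
  but a swapped test is no longer a calibrated test of the tree you passed
  in: if the data actually come from your null, the swap would make the
  bootstrap simulate from the *wrong* tree and reject almost surely. This
  is the one place the package departs from the design sketch it was built
  against, and it is a deliberate correctness fix.
* **Conservativeness.** Even with roles fixed, the parametric bootstrap for
  this non-nested, non-pivotal statistic is conservative: the fitted null
  absorbs the same sampling noise that drives $t^\*$, so under the null the
  bootstrap distribution recenters near the observed statistic and
  p-values concentrate around 0.5 rather than being uniform. The test
  essentially never rejects a true null (good), at the cost of some power
  near the boundary. Rejections should therefore be read as strong
  evidence.

`sequential_lrt()` reproduces the ranked procedure: candidates are sorted
by fitted pseudo-loglikelihood (ascending, stable ties) and each
consecutive pair is tested with the lower tree as the null. The reported
best tree is found by climbing from the bottom while each test rejects;
the climb stops at the first non-rejection, a conservative step-up reading
of "the last tree not rejected in favor of a higher-ranked one".

The test assumes the gene trees are known without error; gene-tree
estimation noise is not propagated, which can inflate rejections of trees
that disagree with systematically biased gene trees. Generating bootstrap
gene trees from sequence-level resampling would address this and is out of
scope here.

## The simulator

`simulate_gene_tree_set()` draws gene trees from the censored MSC: one
lineage per sampled species enters at its leaf; in the population above
each internal node (duration = that node's parent branch length, in
coalescent units) lineages coalesce at rate $k(k-1)/2$, uniformly chosen
pairs, censored at the population boundary; the root population runs to a
single lineage. Per-gene RNG streams are derived by mixing
(SplitMix64) the user seed with the gene index, so gene $i$'s tree does not
depend on how many genes precede it and the same seed always reproduces the
same set, whichever entry point (full trees, triple counts, root times)
consumes the stream.

## What the synthetic data do and do not establish

The generators state a simple world: species trees with 3–8 taxa, internal
branches of 0.5–2 coalescent units (the regime where discordance is
substantial but resolvable), a few hundred to a few thousand loci, complete
or explicitly subset taxon occupancy, and — for alignment-level tests —
Jukes–Cantor sequences with identical rates across sites and branches.
Green tests establish that the closed forms, the simulator, the optimizer
and the test logic agree with each other and with independent oracles at
those scales. They do not establish robustness to gene-tree estimation
error, alignment error, rate heterogeneity, missing-data pathologies, or
the 90-taxon, 5162-locus scale of real mammal data sets; the headline
numbers of such analyses (average RF distances between method trees,
percent of significant genes, and so on) require the external data and
cluster-scale runs and are deliberately not asserted anywhere in this
package.

Defaults chosen once, where no value was prescribed: `random_species_tree`
draws internal lengths from $U(0.5, 2)$; recovery tests use 2000 genes
(enough for $\pm 0.1$ on each internal $\tau$); calibration tests use
30{,}000 three-taxon genes with $3\sigma$ binomial bands.

## Numerical conventions

* RF distances compare canonical label-set bipartitions (unrooted, the
  default) or clades (`rooted = TRUE`); NRFD divides by the total
  non-trivial internal edge count of both trees, which equals $2(n-3)$ for
  two binary unrooted trees and extends to partially resolved inputs; two
  stars have NRFD 0 by convention.
* The bootstrap distance quantile is the order statistic at rank
  $\lceil qn \rceil$ — no interpolation, so the 99% quantile of 100
  distances is the 99th sorted value.
* `standardize_distance()` flags strictly greater than 1; a zero
  calibration quantile yields an `Inf` sentinel and flags any positive
  distance.
* The long-branch filter compares terminal branches after pruning the
  reference to the gene's leaf set (merged edges summed), uses
  "$\ge$ factor" as the threshold, treats a zero reference terminal as
  flagged only when the gene terminal is positive, and skips (with a
  warning) gene leaves absent from the reference.
* `standardize_times()` uses the half-width of the reported 95% interval;
  real posterior intervals are asymmetric, and the half-width reading is
  the documented convention. The flag is strictly $|y^\*| > 1$. Degenerate
  (zero-width) reference intervals drop the row with a warning rather than
  dividing by zero.
* Parsimony-informative site: at least two states, each in at least two
  sequences; gaps, `N` and `?` never count as states. The per-gene
  chi-squared compares (informative, non-informative) site counts between
  two alignment stages as a 2x2 Pearson test, 1 df, no continuity
  correction; a zero margin reports $p = 1$ with a `degenerate` flag.
* Unresolved triples (polytomies) contribute no count rather than
  fractional counts; the three-leaf star is accepted as a rooted but
  unresolved gene tree, while any larger non-binary root is treated as an
  unrooted tree and rejected with instructions to root first.

## Known limitations

One allele per species; no migration or hybridization; no topology search
(candidates come from other programs); composite likelihood, so likelihood
differences are not chi-squared distributed (hence the bootstrap); the
cbLRT's conservativeness noted above; JC-only sequence simulation intended
for exercising alignment QC, not for realism.
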