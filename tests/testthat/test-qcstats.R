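test_that("alignment_summary counts informative sites and composition", {
  s <- alignment_summary(toy_alignment())
  expect_equal(s$prop_informative, 1 / 4)
  expect_equal(sum(s$base_freqs), 1, tolerance = 1e-12)
  expect_equal(s$n_sites, 4)
  expect_equal(s$n_seqs, 4)

  same <- matrix("A", 3, 5, dimnames = list(paste0("s", 1:3), NULL))
  expect_equal(alignment_summary(same)$prop_informative, 0)

  gcaln <- matrix(c("G", "C", "C", "G"), 2, 2,
                  dimnames = list(c("x", "y"), NULL))
  expect_equal(alignment_summary(gcaln)$gc_content, 1)

  expect_error(alignment_summary(matrix(character(0), 2, 0,
                                        dimnames = list(c("a", "b"), NULL))),
               "0 sites")
})

test_that("alignment_summary is invariant to row and column permutation", {
  aln <- jc_simulate_alignment(balanced_sp5(1) |> (\(t) {
    t$edge.length <- rep(0.15, nrow(t$edge)); t })(), 200, seed = 4)
  s0 <- alignment_summary(aln)
  s1 <- alignment_summary(aln[sample(nrow(aln)), sample(ncol(aln))])
  expect_equal(s1$prop_informative, s0$prop_informative)
  expect_equal(s1$base_freqs, s0$base_freqs)
})

test_that("informative_chi2 matches the 2x2 Pearson formula and oracle", {
  expect_equal(informative_chi2(c(40, 60), c(40, 60))$chi2, 0)
  expect_equal(informative_chi2(c(40, 60), c(40, 60))$pvalue, 1)
  expect_equal(informative_chi2(c(40, 60), c(60, 40))$chi2, 8)

  deg <- informative_chi2(c(0, 100), c(0, 100))
  expect_true(deg$degenerate)
  expect_equal(deg$pvalue, 1)

  set.seed(42)
  for (i in 1:50) {
    a <- rpois(2, 50) + 1
    b <- rpois(2, 50) + 1
    got <- informative_chi2(a, b)
    ref <- suppressWarnings(chisq.test(rbind(a, b), correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$pvalue, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("distance_quantile uses the ceil-rank order statistic", {
  ml <- nwk("((A,B),(C,D),E);")
  # bootstrap trees identical to ml: all distances 0
  expect_equal(as.numeric(distance_quantile(ml, rep(list(ml), 10))), 0)

  # monotone non-decreasing in q
  boots <- lapply(1:30, function(s) random_species_tree(5, c(1, 1), seed = s,
                                                        labels = LETTERS[1:5]))
  ml2 <- random_species_tree(5, c(1, 1), seed = 999, labels = LETTERS[1:5])
  qs <- vapply(c(0.5, 0.8, 0.9, 0.99, 1),
               function(q) as.numeric(distance_quantile(ml2, boots, q)),
               numeric(1))
  expect_true(all(diff(qs) >= 0))
  expect_error(distance_quantile(ml, list()), "empty")
})

test_that("standardize_distance applies the strict >1 flag", {
  expect_false(standardize_distance(0.2, 0.2)$significant)
  expect_equal(standardize_distance(0.2, 0.2)$value, 1)
  expect_equal(standardize_distance(0, 0.2)$value, 0)
  s <- standardize_distance(0.24, 0.2)
  expect_equal(s$value, 1.2)
  expect_true(s$significant)
  # degenerate calibration
  expect_true(standardize_distance(0.1, 0)$significant)
  expect_equal(standardize_distance(0.1, 0)$value, Inf)
  expect_false(standardize_distance(0, 0)$significant)
})

test_that("mean_bootstrap_support averages internal supports, root excluded", {
  expect_equal(mean_bootstrap_support(nwk("(((A,B)90,C)100,(D,E)80);")), 90)
  expect_equal(mean_bootstrap_support(nwk("(((A,B)55,C),D);")), 55)
  expect_error(mean_bootstrap_support(nwk("((A,B),C);")), "no internal support")
})

test_that("long_branch_flags implements the 5X terminal-branch rule", {
  ref <- nwk("(((A:0.05,B:0.05):0.1,C:0.05):0.1,(D:0.05,E:0.05):0.1);")
  gene <- ref
  # A: ratio 10 -> flagged; B: ratio 4.8 -> not
  gene$edge.length[match(match("A", gene$tip.label), gene$edge[, 2])] <- 0.50
  gene$edge.length[match(match("B", gene$tip.label), gene$edge[, 2])] <- 0.24
  flags <- long_branch_flags(gene, ref)
  expect_equal(as.character(flags), "A")
  expect_equal(unname(attr(flags, "ratios")["B"]), 4.8)

  # identical trees: empty set for any factor > 1
  for (f in c(1.01, 2, 5, 100))
    expect_length(as.character(long_branch_flags(ref, ref, factor = f)), 0)

  # leaf absent from the reference is skipped with a warning
  gene2 <- nwk("(((A:0.05,B:0.05):0.1,Z:0.05):0.1,(D:0.05,E:0.05):0.1);")
  expect_warning(flags2 <- long_branch_flags(gene2, ref), "skipped")
  expect_equal(attr(flags2, "skipped"), "Z")

  noel <- nwk("(((A,B),C),(D,E));")
  expect_error(long_branch_flags(noel, ref), "lacks branch lengths")
})

test_that("reference pruning sums merged edges before the 5X comparison", {
  # full reference: A's terminal is 0.05, but pruning X merges 0.1 onto the
  # path, leaving A's terminal at 0.05 (terminal edges unaffected) while the
  # internal structure changes; use a case where the TERMINAL itself merges:
  ref <- nwk("(((A:0.05,X:0.05):0.2,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  gene <- nwk("((A:0.9,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  # after pruning X from ref, A's terminal = 0.05 + 0.2 = 0.25; 0.9 < 5*0.25
  expect_length(as.character(long_branch_flags(gene, ref)), 0)
  gene2 <- gene
  gene2$edge.length[match(match("A", gene2$tip.label), gene2$edge[, 2])] <- 1.3
  expect_equal(as.character(long_branch_flags(gene2, ref)), "A")
})
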