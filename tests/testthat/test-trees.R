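test_that("parse_newick reads structure, lengths and supports", {
  tr <- nwk("((A,B),C);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(ape::is.rooted(tr))

  tr2 <- nwk("((A:1,B:1)0.95:0.5,C:2);")
  expect_equal(node_supports(tr2), c(NA, 0.95))
  expect_equal(tr2$edge.length[match(match("C", tr2$tip.label),
                                     tr2$edge[, 2])], 2)

  expect_error(nwk("((A,B),(A,C));"), "duplicate leaf label")
  expect_error(nwk(""), "parse error")
  expect_error(nwk("((A,B),C;"), "parenthes")
  expect_error(nwk("((A,B),C)"), "must end in ';'")
})

test_that("write_newick round-trips trees", {
  for (s in c("((A,B),C);", "((A:1,B:1)0.95:0.5,C:2);",
              "(((a,b),(c,d)),e);")) {
    tr <- nwk(s)
    back <- nwk(write_newick(tr))
    expect_equal(rf_distance(tr, back, rooted = TRUE), 0)
    expect_setequal(back$tip.label, tr$tip.label)
    if (!is.null(tr$edge.length))
      expect_equal(sort(back$edge.length), sort(tr$edge.length))
  }
  expect_error(write_newick(structure(list(tip.label = character(0)),
                                      class = "phylo")), "empty")
})

test_that("root_by_outgroup places and validates the root", {
  utr <- ape::unroot(nwk("((A,B),(C,D));"))
  r <- root_by_outgroup(utr, "D")
  expect_true(ape::is.rooted(r))
  # D is sister to everything else: the root splits D | {A,B,C}
  expect_true(ape::is.monophyletic(r, c("A", "B", "C")))

  r2 <- root_by_outgroup(nwk("(A,(B,(C,D)));"), c("C", "D"))
  expect_true(ape::is.monophyletic(r2, c("A", "B")))

  expect_error(root_by_outgroup(utr, "X"), "absent")
  expect_error(root_by_outgroup(ape::unroot(nwk("((A,C),(B,D));")),
                                c("A", "B")), "not monophyletic")

  dropped <- root_by_outgroup(utr, "D", drop = TRUE)
  expect_setequal(dropped$tip.label, c("A", "B", "C"))
})

test_that("prune_to_common_leaves restricts, merges lengths, errors", {
  t1 <- nwk("(((A:1,B:1):1,C:2):1,D:3);")
  t2 <- nwk("(((A:1,B:1):1,C:2):1,E:3);")
  pr <- prune_to_common_leaves(t1, t2)
  expect_equal(pr$shared, c("A", "B", "C"))
  expect_setequal(pr$t1$tip.label, c("A", "B", "C"))

  # pruning D removes its cherry partner's parent: 0.1 + 0.2 merge to 0.3
  t3 <- nwk("(((A:1,B:1):0.1,X:1):0.2,(C:1,D:1):1);")
  pr2 <- prune_to_common_leaves(t3, nwk("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_true(any(abs(pr2$t1$edge.length - 0.3) < 1e-12))

  expect_error(prune_to_common_leaves(nwk("((A,B),C);"), nwk("((X,Y),Z);")),
               "share only 0")
})

test_that("path lengths between surviving leaves are preserved by pruning", {
  set.seed(1)
  for (rep in 1:5) {
    sp <- random_species_tree(8, c(0.2, 1.5), seed = rep)
    tr <- sp
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    keep <- sample(tr$tip.label, 5)
    pruned <- ape::keep.tip(tr, keep)
    d_full <- ape::cophenetic.phylo(tr)[keep, keep]
    d_sub <- ape::cophenetic.phylo(pruned)[keep, keep]
    expect_equal(d_sub, d_full, tolerance = 1e-10)
  }
})

test_that("rf_distance matches the spec examples and errors on mismatch", {
  expect_equal(rf_distance(nwk("((A,B),(C,D));"), nwk("((A,C),(B,D));")), 2)
  expect_equal(rf_distance(nwk("((A,B),(C,(D,E)));"),
                           nwk("((A,C),(B,(D,E)));")), 2)
  t <- nwk("((A,B),(C,D));")
  expect_equal(rf_distance(t, t), 0)
  expect_error(rf_distance(t, nwk("((A,B),(C,E));")), "leaf sets differ")
})

test_that("rf oracle equivalence over all 15 unrooted 5-taxon topologies", {
  topos <- five_taxon_topologies()
  trees <- lapply(topos, function(x) nwk(x$newick))
  for (i in seq_along(topos)) {
    for (j in seq_along(topos)) {
      expected <- oracle_rf(topos[[i]]$splits, topos[[j]]$splits)
      expect_equal(rf_distance(trees[[i]], trees[[j]]), expected,
                   info = paste(names(topos)[i], "vs", names(topos)[j]))
    }
  }
  # cross-check against an independent mature implementation
  skip_if_not_installed("phangorn")
  for (i in c(1, 7, 15)) for (j in c(3, 9)) {
    expect_equal(rf_distance(trees[[i]], trees[[j]]),
                 as.numeric(phangorn::RF.dist(trees[[i]], trees[[j]])))
  }
})

test_that("rf_distance is a symmetric premetric on random trees", {
  for (s in 1:8) {
    t1 <- random_species_tree(7, c(1, 1), seed = s)
    t2 <- random_species_tree(7, c(1, 1), seed = s + 100)
    expect_equal(rf_distance(t1, t1), 0)
    expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
    expect_gte(nrfd(t1, t2), 0)
    expect_lte(nrfd(t1, t2), 1)
  }
})

test_that("nrfd normalizes by total internal edges", {
  expect_equal(nrfd(nwk("((A,B),(C,D));"), nwk("((A,C),(B,D));")), 1)
  expect_equal(nrfd(nwk("((A,B),(C,(D,E)));"), nwk("((A,C),(B,(D,E)));")),
               0.5)
  t <- nwk("((A,B),(C,D));")
  expect_equal(nrfd(t, t), 0)
  # two stars: denominator 0, defined as 0
  expect_equal(nrfd(nwk("(A,B,C,D);"), nwk("(A,B,C,D);")), 0)
})
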