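test_that("triple_counts reads rooted resolutions from gene trees", {
  genes <- lapply(c("((A,B),C);", "((A,B),C);", "((A,C),B);"), nwk)
  cnt <- triple_counts(genes)
  expect_equal(unname(cnt["A|B|C", ]), c(2L, 1L, 0L))

  cnt2 <- triple_counts(list(nwk("((A,B),(C,D));")))
  expect_equal(unname(cnt2["A|B|C", ]), c(1L, 0L, 0L))  # AB|C
  expect_equal(unname(cnt2["A|C|D", ]), c(0L, 0L, 1L))  # CD|A
  expect_equal(sum(cnt2), 4L)  # every 3-subset resolved once

  # root polytomy leaves the triple uncounted
  expect_equal(sum(triple_counts(list(nwk("(A,B,C);")),
                                 species = c("A", "B", "C"))), 0L)
  expect_error(triple_counts(list(ape::unroot(nwk("((A,B),(C,D));")))),
               "unrooted")
})

test_that("triple_probs follows the coalescent closed form", {
  expect_equal(unname(triple_probs(0)[1, ]), rep(1 / 3, 3))
  p1 <- triple_probs(1)
  expect_equal(unname(p1[1, 1]), 0.7547470, tolerance = 1e-6)
  expect_equal(unname(p1[1, 2]), (1 / 3) * exp(-1), tolerance = 1e-12)
  expect_equal(unname(triple_probs(50)[1, 1]), 1, tolerance = 1e-20)

  taus <- seq(0, 8, by = 0.25)
  P <- triple_probs(taus)
  expect_equal(rowSums(P), rep(1, length(taus)))
  expect_true(all(P[, 1] >= 1 / 3))
  expect_true(all(diff(P[, 1]) > 0))
  expect_error(triple_probs(-0.1), "tau")
})

test_that("triple_tau sums internal edges between the two MRCAs", {
  sp <- species_tree_cu("((A:0,B:0):0.7,(C:0,D:0):1.3):0;")
  expect_equal(triple_tau(sp, c("A", "B", "C")), 0.7)
  expect_equal(triple_tau(sp, c("A", "C", "D")), 1.3)

  cat4 <- species_tree_cu("(((A:0,B:0):0.4,C:0):0.9,D:0):0;")
  expect_equal(triple_tau(cat4, c("A", "B", "D")), 0.4 + 0.9)
  expect_equal(triple_tau(cat4, c("A", "B", "C")), 0.4)
  expect_equal(triple_tau(cat4, c("A", "C", "D")), 0.9)
  expect_error(triple_tau(sp, c("A", "B", "X")), "missing")
})

test_that("pseudo_loglik evaluates the triple multinomial", {
  tt <- function(counts) {
    structure(matrix(as.integer(counts), 1, 3,
                     dimnames = list("A|B|C", c("ab", "ac", "bc"))),
              class = "triple_table", species = c("A", "B", "C"))
  }
  sp0 <- species_tree_cu("((A:0,B:0):1e-12,C:0):0;")
  expect_equal(pseudo_loglik(sp0, tt(c(1, 1, 1))), 3 * log(1 / 3),
               tolerance = 1e-6)

  sp50 <- species_tree_cu("((A:0,B:0):50,C:0):0;")
  expect_equal(pseudo_loglik(sp50, tt(c(10, 0, 0))), 0, tolerance = 1e-8)

  spm <- species_tree_cu(sprintf("((A:0,B:0):%.6f,C:0):0;", log(8 / 3)))
  expect_equal(pseudo_loglik(spm, tt(c(75, 13, 12))),
               75 * log(0.75) + 25 * log(0.125), tolerance = 1e-4)

  # invariant to the order of triples (row shuffling)
  sp5 <- balanced_sp5(1)
  genes <- simulate_gene_tree_set(sp5, n = 100, seed = 3)
  cnt <- triple_counts(genes)
  shuffled <- cnt[sample(nrow(cnt)), , drop = FALSE]
  attr(shuffled, "species") <- attr(cnt, "species")
  class(shuffled) <- "triple_table"
  expect_equal(pseudo_loglik(sp5, shuffled), pseudo_loglik(sp5, cnt))

  # invariant to gene order
  cnt_rev <- triple_counts(rev(unclass(genes)))
  expect_equal(pseudo_loglik(sp5, cnt_rev), pseudo_loglik(sp5, cnt))
})

test_that("fitted tau matches the analytic single-triple MLE", {
  topo <- nwk("((A,B),C);")
  for (p_hat in seq(0.4, 0.95, by = 0.05)) {
    n <- 200L
    n_conc <- as.integer(round(p_hat * n))
    rest <- n - n_conc
    cnt <- structure(matrix(c(n_conc, rest %/% 2L, rest - rest %/% 2L), 1, 3,
                            dimnames = list("A|B|C", c("ab", "ac", "bc"))),
                     class = "triple_table", species = c("A", "B", "C"))
    fit <- fit_branch_lengths(topo, cnt)
    expect_equal(fit$tau, -log(3 * (1 - p_hat) / 2), tolerance = 1e-4,
                 info = paste("p_hat =", p_hat))
  }
})

test_that("concordant fraction at or below 1/3 pins tau at the lower bound", {
  cnt <- structure(matrix(c(30L, 35L, 35L), 1, 3,
                          dimnames = list("A|B|C", c("ab", "ac", "bc"))),
                   class = "triple_table", species = c("A", "B", "C"))
  fit <- fit_branch_lengths(nwk("((A,B),C);"), cnt, tau_min = 1e-6)
  expect_equal(fit$tau, 1e-6, tolerance = 1e-6)
})

test_that("the generating topology outranks its NNI neighbours", {
  sp <- balanced_sp5(2)
  cnt <- coaltest:::sim_triple_counts(sp, rep(list(sp$tip.label), 2000),
                                      seed = 77)
  ll_true <- fit_branch_lengths(sp, cnt)$loglik
  for (k in 1:2) for (ch in 1:2) {
    alt <- rooted_nni(sp, k, ch)
    expect_gt(ll_true, fit_branch_lengths(alt, cnt)$loglik)
  }
})
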