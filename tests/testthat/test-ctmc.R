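# Rate model, transition probabilities, regime painting and the pruning
# likelihood.

test_that("transition matrices match the closed form and its limits", {
  m <- rate_model(1, 1)
  expect_equal(transition_matrix(m, 0), diag(2), ignore_attr = TRUE)
  expect_equal(unname(transition_matrix(m, 100)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  # asymmetric case against the truncated-series matrix exponential
  m2 <- rate_model(1, 3)
  P <- transition_matrix(m2, 0.5)
  expect_lt(max(abs(P - series_P(1, 3, 0.5))), 1e-10)
  expect_equal(unname(P[1, 1]), 0.78383, tolerance = 1e-5)
  expect_equal(unname(P[2, 1]), 0.64850, tolerance = 1e-5)
  # zero-rate model: identity for all t
  expect_equal(transition_matrix(rate_model(0, 0), 3), diag(2),
               ignore_attr = TRUE)
  expect_error(transition_matrix(m, -1), "non-negative")
})

test_that("Chapman-Kolmogorov and monotone mixing hold", {
  for (s in 1:10) {
    m <- random_model(s)
    set.seed(s + 100)
    t1 <- runif(1, 0, 2)
    t2 <- runif(1, 0, 2)
    lhs <- transition_matrix(m, t1) %*% transition_matrix(m, t2)
    expect_lt(max(abs(lhs - transition_matrix(m, t1 + t2))), 1e-10)
    # |P_MM(t) - pi_M| strictly decreasing in t
    pi_m <- stationary(m)[["marine"]]
    ts <- seq(0.1, 3, by = 0.1)
    dev <- vapply(ts, function(t) {
      abs(transition_matrix(m, t)[1, 1] - pi_m)
    }, 1)
    expect_true(all(diff(dev) < 0))
  }
})

test_that("normalization yields unit expected flux and reconstructs Q", {
  nz <- normalize_rates(rate_model(1, 1))
  expect_equal(nz$rate, 1)
  expect_equal(nz$model$q_mn, 1)
  nz2 <- normalize_rates(rate_model(2, 2))
  expect_equal(nz2$rate, 2)
  expect_equal(c(nz2$model$q_mn, nz2$model$q_nm), c(1, 1))
  nz3 <- normalize_rates(rate_model(1, 3))
  expect_equal(nz3$rate, 1.5)
  expect_equal(c(nz3$model$q_mn, nz3$model$q_nm), c(2 / 3, 2))
  # r * Qhat == Q, pi shared, unit flux under Qhat
  expect_equal(nz3$rate * nz3$model$q_mn, 1)
  expect_equal(stationary(nz3$model), stationary(rate_model(1, 3)))
  pi <- stationary(nz3$model)
  expect_equal(pi[["marine"]] * nz3$model$q_mn +
                 pi[["non_marine"]] * nz3$model$q_nm, 1)
  expect_error(normalize_rates(rate_model(0, 0)), "zero")
})

test_that("regime painting covers stems and resolves nesting", {
  tr <- read_tree("((a:1,b:1):1,(c:1,d:1):1);")
  one <- paint_regimes(tr, list(all = c("a", "b", "c", "d")))
  expect_true(all(one == "all"))

  reg <- paint_regimes(tr, list(cd = c("c", "d")))
  cd_tips <- match(c("c", "d"), tr$tip.label)
  mrca <- ape::getMRCA(tr, c("c", "d"))
  in_cd <- tr$edge[, 2] %in% c(cd_tips, mrca)
  expect_true(all(reg[in_cd] == "cd"))
  expect_true(all(reg[!in_cd] == "background"))

  # nested clades: most specific wins
  tr2 <- read_tree("(a:1,(b:1,(c:1,d:1):1):1);")
  reg2 <- paint_regimes(tr2, list(bcd = c("b", "c", "d"), cd = c("c", "d")))
  edge_c <- which(tr2$edge[, 2] == match("c", tr2$tip.label))
  edge_b <- which(tr2$edge[, 2] == match("b", tr2$tip.label))
  expect_equal(reg2[edge_c], "cd")
  expect_equal(reg2[edge_b], "bcd")

  expect_error(paint_regimes(tr, list(bad = c("a", "c"))),
               "not monophyletic")
})

test_that("pruning log-likelihood matches hand and enumeration values", {
  at <- annotate(read_tree("(A:1,B:1);"),
                 c(A = "marine", B = "non_marine"))
  expect_equal(tree_loglik(at, rate_model(1, 1)),
               log(0.5 * 0.56766764 * 0.43233236 * 2), tolerance = 1e-5)
  # zero-length branches: likelihood equals the root prior mass
  at0 <- annotate(read_tree("(A:0,B:0);"), c(A = "marine", B = "marine"))
  expect_equal(exp(tree_loglik(at0, rate_model(1, 1))), 0.5)
  # impossible configuration through zero branches
  at_imp <- annotate(read_tree("(A:0,B:0);"),
                     c(A = "marine", B = "non_marine"))
  expect_identical(tree_loglik(at_imp, rate_model(1, 1)), -Inf)
  # enumeration oracle on random trees and rates
  for (s in 1:12) {
    at <- random_atree(sample(3:6, 1), seed = s)
    m <- random_model(s + 50)
    expect_lt(abs(tree_loglik(at, m) - enum_loglik(at, m)), 1e-10)
  }
})

test_that("painted likelihood collapses to homogeneous when regimes agree", {
  at <- random_atree(12, seed = 77)
  m <- rate_model(0.7, 0.4)
  defs <- list(cl = sort(habtrans:::descendant_tips(at$tree,
                                                    length(at$tree$tip.label) + 2L)))
  defs$cl <- at$tree$tip.label[defs$cl]
  part <- regime_partition(list(cl = m, background = m), defs)
  expect_equal(tree_loglik(at, part), tree_loglik(at, m), tolerance = 1e-12)
  # and a genuinely different clade regime changes the likelihood
  part2 <- regime_partition(list(cl = rate_model(3, 0.1), background = m),
                            defs)
  expect_false(isTRUE(all.equal(tree_loglik(at, part2),
                                tree_loglik(at, m))))
  # painted likelihood also matches the enumeration oracle
  small <- random_atree(5, seed = 301)
  tips <- small$tree$tip.label
  cl <- tips[habtrans:::descendant_tips(
    small$tree, ape::getMRCA(small$tree, tips[1:2]) )]
  p3 <- regime_partition(list(cl = rate_model(2, 0.3),
                              background = rate_model(0.2, 1)),
                         list(cl = cl))
  expect_lt(abs(tree_loglik(small, p3) - enum_loglik(small, p3)), 1e-10)
})

test_that("stationary-root likelihood is invariant under rerooting", {
  for (s in 1:8) {
    at <- random_atree(10, seed = 400 + s)
    m <- random_model(s)
    ll0 <- tree_loglik(at, m, root = "stationary")
    og <- sample(at$tree$tip.label, 1)
    rt <- reroot_tree(at$tree, og)
    at2 <- annotated_tree(rt, at$labels)
    expect_lt(abs(tree_loglik(at2, m, root = "stationary") - ll0), 1e-8)
  }
})

test_that("likelihood is numerically stable on large trees", {
  tr <- simulate_tree(4000, seed = 12)
  sim <- simulate_history(tr, rate_model(0.3, 0.3), seed = 13)
  ll <- tree_loglik(sim$atree, rate_model(0.3, 0.3))
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})
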