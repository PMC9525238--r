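# Independent oracles and fixture builders used across the test files.
# The oracles deliberately avoid the package's pruning/DP code paths:
# likelihoods and posteriors are computed by exhaustive enumeration over all
# internal-state assignments, and transition matrices by truncated-series
# matrix exponentials.

# Series matrix exponential of the 2-state rate matrix, with scaling and
# squaring so the truncated series is evaluated at a small argument (the
# plain series suffers catastrophic cancellation for large s*t).
series_P <- function(q_mn, q_nm, t, terms = 40L) {
  k <- max(0L, ceiling(log2(max((q_mn + q_nm) * t, 1e-12)))) + 2L
  Q <- matrix(c(-q_mn, q_nm, q_mn, -q_nm), 2L, 2L)
  A <- Q * (t / 2^k)
  P <- diag(2)
  term <- diag(2)
  for (j in seq_len(terms)) {
    term <- term %*% A / j
    P <- P + term
  }
  for (j in seq_len(k)) P <- P %*% P
  P
}

# Per-edge transition matrices for a (possibly regime-painted) model.
edge_P_list <- function(atree, model) {
  tree <- atree$tree
  qq <- habtrans:::edge_rates(tree, model)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    transition_matrix(rate_model(qq[i, 1L], qq[i, 2L]), tree$edge.length[i])
  })
}

# All internal-state assignments with their joint probabilities.
enum_assignments <- function(atree, model, root = "equal", root_p = NULL) {
  tree <- atree$tree
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ts <- habtrans:::tip_states_int(atree)
  pr <- habtrans:::root_probabilities(root, model, root_p)
  Ps <- edge_P_list(atree, model)
  internals <- (nt + 1L):nn
  combos <- as.matrix(expand.grid(rep(list(1:2), length(internals))))
  probs <- numeric(nrow(combos))
  states <- matrix(0L, nrow(combos), nn)
  for (r in seq_len(nrow(combos))) {
    st <- integer(nn)
    st[seq_len(nt)] <- ts
    st[internals] <- combos[r, ]
    p <- pr[[st[nt + 1L]]]
    for (i in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[i]][st[tree$edge[i, 1L]], st[tree$edge[i, 2L]]]
    }
    probs[r] <- p
    states[r, ] <- st
  }
  list(probs = probs, states = states, internals = internals)
}

enum_loglik <- function(atree, model, root = "equal", root_p = NULL) {
  log(sum(enum_assignments(atree, model, root, root_p)$probs))
}

# Marginal posterior P(marine) per node by enumeration.
enum_marginals <- function(atree, model, root = "equal", root_p = NULL) {
  en <- enum_assignments(atree, model, root, root_p)
  tot <- sum(en$probs)
  vapply(seq_len(ncol(en$states)), function(v) {
    sum(en$probs[en$states[, v] == 1L]) / tot
  }, 1)
}

# Best joint assignment (max probability) by enumeration; returns the
# maximum log-probability.
enum_joint_max <- function(atree, model, root = "equal", root_p = NULL) {
  en <- enum_assignments(atree, model, root, root_p)
  log(max(en$probs))
}

# Random rooted tree with uniform branch lengths and random binary labels.
random_atree <- function(n, seed, min_len = 0.05, max_len = 2) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, min_len, max_len))
  labs <- sample(c("marine", "non_marine"), n, replace = TRUE)
  # guarantee both states where possible
  if (n >= 2L && length(unique(labs)) == 1L) {
    labs[1L] <- setdiff(c("marine", "non_marine"), labs[1L])
  }
  annotated_tree(tr, stats::setNames(labs, tr$tip.label))
}

random_model <- function(seed, max_rate = 5) {
  set.seed(seed)
  q <- runif(2, 0.01, max_rate)
  rate_model(q[1L], q[2L])
}
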