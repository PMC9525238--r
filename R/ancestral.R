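# Ancestral habitat reconstruction: marginal posterior state probabilities
# at every node (up-down algorithm) and exact joint maximum-likelihood
# assignment (Pupko dynamic programming), under configurable root policies.

#' Marginal posterior habitat probabilities at every node
#'
#' Standard up-down (inside-outside) algorithm: an upward pruning pass
#' computes conditional likelihoods below each node, a downward pass folds
#' in the likelihood of the rest of the tree, and the two are combined and
#' normalized per node. At the root the posterior is proportional to the
#' root-policy weights times the conditional likelihoods. Tips with certain
#' labels get probability 1 on their observed state.
#'
#' @inheritParams tree_loglik
#' @return object of class `node_posterior`: a data.frame with columns
#'   `node` (1..tips+internals, tips first, root = tips+1), `p_marine`,
#'   `p_non_marine`, with the log-likelihood in attribute `"loglik"`.
#' @examples
#' at <- annotate(read_tree("(A:1,B:1);"), c(A = "marine", B = "marine"))
#' marginal_posteriors(at, rate_model(1, 1))  # root p_marine ~ 0.6329
#' @export
marginal_posteriors <- function(atree, model, root = "equal", root_p = NULL) {
  stopifnot(inherits(atree, "annotated_tree"))
  tree <- atree$tree
  if (!ape::is.rooted(tree)) {
    stop_habtrans("tree must be rooted before ancestral reconstruction ",
                  "(see reroot_tree)")
  }
  qq <- edge_rates(tree, model)
  P <- mk2_edge_P(qq[, 1L], qq[, 2L], tree$edge.length)
  pr <- root_probabilities(root, model, root_p)
  up <- mk2_pruning(tree, tip_states_int(atree), P, pr)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  # upward messages per edge, normalized (constants cancel in the posterior)
  m1 <- P[, 1L] * up$L1[e2] + P[, 2L] * up$L2[e2]
  m2 <- P[, 3L] * up$L1[e2] + P[, 4L] * up$L2[e2]
  msum <- m1 + m2
  bad <- msum <= 0 | !is.finite(msum)
  if (any(bad)) {
    stop_habtrans("zero or non-finite message on edge ", which(bad)[1L],
                  " (impossible tip configuration)")
  }
  m1 <- m1 / msum
  m2 <- m2 / msum
  # outside probabilities, preorder
  O1 <- numeric(nn)
  O2 <- numeric(nn)
  r <- root_node(tree)
  O1[r] <- pr[[1L]]
  O2[r] <- pr[[2L]]
  edges_of_parent <- split(seq_len(nrow(tree$edge)), e1)
  for (i in preorder_edges(tree)) {
    u <- e1[i]
    v <- e2[i]
    sib <- setdiff(edges_of_parent[[as.character(u)]], i)
    ex1 <- O1[u]
    ex2 <- O2[u]
    for (j in sib) {
      ex1 <- ex1 * m1[j]
      ex2 <- ex2 * m2[j]
    }
    o1 <- P[i, 1L] * ex1 + P[i, 3L] * ex2
    o2 <- P[i, 2L] * ex1 + P[i, 4L] * ex2
    osum <- o1 + o2
    if (osum > 0) {
      O1[v] <- o1 / osum
      O2[v] <- o2 / osum
    }
  }
  p1 <- O1 * up$L1
  p2 <- O2 * up$L2
  tot <- p1 + p2
  if (any(tot <= 0 | !is.finite(tot))) {
    stop_habtrans("degenerate posterior at node ",
                  which(tot <= 0 | !is.finite(tot))[1L])
  }
  out <- data.frame(node = seq_len(nn), p_marine = p1 / tot,
                    p_non_marine = p2 / tot)
  attr(out, "loglik") <- up$loglik
  class(out) <- c("node_posterior", "data.frame")
  out
}

#' Exact joint maximum-likelihood ancestral states
#'
#' Dynamic programming over states (the Pupko algorithm): the single
#' assignment of habitats to all internal nodes that maximizes the joint
#' likelihood, not the collection of per-node marginal maxima. Ties (exactly
#' equal joint scores, as happens on symmetric configurations) are broken
#' deterministically — prefer the state with the higher marginal posterior,
#' then marine — and flagged.
#'
#' @inheritParams tree_loglik
#' @param tol log-likelihood difference below which two choices are treated
#'   as tied.
#' @return object of class `trait_history`: list with `tree`, `states`
#'   (character, one per node; tips first), `events` (data.frame of
#'   state-change edges with columns `edge`, `parent_state`, `child_state`,
#'   `direction`), `tie_nodes` (integer), `log_joint` (the joint
#'   log-likelihood of the returned assignment, including tip states).
#' @export
joint_ml_states <- function(atree, model, root = "equal", root_p = NULL,
                            tol = 1e-9) {
  stopifnot(inherits(atree, "annotated_tree"))
  tree <- atree$tree
  if (!ape::is.rooted(tree)) {
    stop_habtrans("tree must be rooted before ancestral reconstruction")
  }
  qq <- edge_rates(tree, model)
  P <- mk2_edge_P(qq[, 1L], qq[, 2L], tree$edge.length)
  logP <- log(P)
  pr <- root_probabilities(root, model, root_p)
  tip_state <- tip_states_int(atree)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  marg <- marginal_posteriors(atree, model, root, root_p)
  # S[v, b]: best log score of subtree below v given state(v) = b,
  # accumulated via child-edge contributions C[i, a] =
  #   max_b logP[a -> b] + S[child(i), b].
  S <- matrix(0, nn, 2L)
  S[seq_len(nt), ] <- -Inf
  S[cbind(seq_len(nt), tip_state)] <- 0
  C <- matrix(NA_real_, nrow(tree$edge), 2L)
  back <- matrix(NA_integer_, nrow(tree$edge), 2L)
  tie_edge <- matrix(FALSE, nrow(tree$edge), 2L)
  pick <- function(sc, node) {
    # deterministic argmax with tie handling
    if (abs(sc[1L] - sc[2L]) <= tol && is.finite(sc[1L])) {
      pm <- marg$p_marine[node]
      list(state = if (pm >= 0.5) 1L else 2L, tie = TRUE)
    } else {
      list(state = which.max(sc), tie = FALSE)
    }
  }
  for (i in postorder_edges(tree)) {
    v <- e2[i]
    for (a in 1:2) {
      sc <- c(logP[i, if (a == 1L) 1L else 3L] + S[v, 1L],
              logP[i, if (a == 1L) 2L else 4L] + S[v, 2L])
      pk <- pick(sc, v)
      C[i, a] <- sc[pk$state]
      back[i, a] <- pk$state
      tie_edge[i, a] <- pk$tie
    }
    S[e1[i], ] <- S[e1[i], ] + C[i, ]
  }
  r <- root_node(tree)
  root_sc <- log(c(pr[[1L]], pr[[2L]])) + S[r, ]
  pk <- pick(root_sc, r)
  states <- integer(nn)
  states[r] <- pk$state
  ties <- if (pk$tie) r else integer(0)
  for (i in preorder_edges(tree)) {
    a <- states[e1[i]]
    states[e2[i]] <- back[i, a]
    if (tie_edge[i, a]) ties <- c(ties, e2[i])
  }
  states[seq_len(nt)] <- tip_state  # tips are observed
  st_chr <- mk2_states()[states]
  trait_history(tree, st_chr, tie_nodes = sort(unique(ties)),
                log_joint = root_sc[pk$state])
}

#' Construct a trait history from per-node states
#'
#' A `trait_history` couples a rooted tree with one habitat state per node
#' (tips first, then internals in ape numbering) and the derived list of
#' state-change edges. Used both for reconstructed histories
#' ([joint_ml_states()]) and simulated truth ([simulate_history()]).
#'
#' @param tree rooted `phylo`.
#' @param states character vector of `"marine"`/`"non_marine"`, one per
#'   node.
#' @param tie_nodes integer node ids whose state was a flagged tie.
#' @param log_joint optional joint log-likelihood of the assignment.
#' @return object of class `trait_history`.
#' @export
trait_history <- function(tree, states, tie_nodes = integer(0),
                          log_joint = NA_real_) {
  nn <- n_tips(tree) + tree$Nnode
  stopifnot(length(states) == nn, all(states %in% mk2_states()))
  chg <- which(states[tree$edge[, 1L]] != states[tree$edge[, 2L]])
  events <- data.frame(
    edge = chg,
    parent_state = states[tree$edge[chg, 1L]],
    child_state = states[tree$edge[chg, 2L]],
    direction = ifelse(states[tree$edge[chg, 1L]] == "marine",
                       "M->NM", "NM->M"),
    stringsAsFactors = FALSE
  )
  structure(list(tree = tree, states = states, events = events,
                 tie_nodes = tie_nodes, log_joint = log_joint),
            class = "trait_history")
}

#' @export
print.trait_history <- function(x, ...) {
  cat("trait_history:", n_tips(x$tree), "tips,", nrow(x$events),
      "state-change edge(s),", length(x$tie_nodes), "tie(s)\n")
  invisible(x)
}

#' Pooled root-state posterior across trees and posterior draws
#'
#' Averages the marginal root posterior over the trees of a set and over
#' (thinned) posterior rate draws, separately for each requested rooting —
#' the machinery behind "both root alternatives converge to the same
#' ancestral habitat" style summaries.
#'
#' @param trees a [tree_set()].
#' @param draws a `posterior_sample` from [sample_posterior()] (homogeneous
#'   model), or a single [rate_model()] for a point estimate.
#' @param rootings named list of outgroup tip vectors to re-root at, or
#'   `NULL` to use the trees as rooted.
#' @param max_draws cap on the number of posterior draws used (evenly
#'   thinned).
#' @inheritParams tree_loglik
#' @return data.frame with one row per rooting: `rooting`, `p_marine`,
#'   `p_non_marine`.
#' @export
root_state_summary <- function(trees, draws, rootings = NULL,
                               max_draws = 50L, root = "equal",
                               root_p = NULL) {
  stopifnot(inherits(trees, "tree_set"))
  if (inherits(draws, "rate_model")) {
    models <- list(draws)
  } else if (inherits(draws, "posterior_sample")) {
    d <- as.data.frame(draws)
    if (nrow(d) == 0L) stop_habtrans("empty posterior draw set")
    if (!all(c("q_mn", "q_nm") %in% names(d))) {
      stop_habtrans("root_state_summary needs homogeneous-model draws")
    }
    keep <- unique(round(seq(1L, nrow(d), length.out = min(max_draws,
                                                           nrow(d)))))
    models <- lapply(keep, function(i) rate_model(d$q_mn[i], d$q_nm[i]))
  } else {
    stop_habtrans("draws must be a posterior_sample or a rate_model")
  }
  if (is.null(rootings)) rootings <- list(as_rooted = NULL)
  if (is.null(names(rootings))) {
    names(rootings) <- paste0("rooting_", seq_along(rootings))
  }
  out <- lapply(names(rootings), function(nm) {
    og <- rootings[[nm]]
    acc <- c(0, 0)
    n <- 0L
    for (at in trees) {
      at2 <- if (is.null(og)) at else {
        annotated_tree(reroot_tree(at$tree, og), at$labels, at$mode)
      }
      for (mod in models) {
        mp <- marginal_posteriors(at2, mod, root, root_p)
        rr <- root_node(at2$tree)
        acc <- acc + c(mp$p_marine[rr], mp$p_non_marine[rr])
        n <- n + 1L
      }
    }
    data.frame(rooting = nm, p_marine = acc[1L] / n,
               p_non_marine = acc[2L] / n)
  })
  do.call(rbind, out)
}
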