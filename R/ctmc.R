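# The two-state continuous-time Markov model of habitat evolution:
# rate matrix, analytic transition probabilities, pruning likelihood with
# optional branch-painted regimes, and the normalized-matrix global rate.

# state coding used throughout: 1 = marine, 2 = non_marine
mk2_states <- function() c("marine", "non_marine")

#' Two-state habitat transition rate model
#'
#' The Mk2 rate matrix for habitat evolution, parameterized by the
#' instantaneous rates `q_mn` (marine to non-marine) and `q_nm` (non-marine
#' to marine), both in transitions per unit branch length (here,
#' substitutions/site). The stationary distribution is
#' `pi = (q_nm, q_mn) / (q_mn + q_nm)`; a two-state chain is always
#' reversible (`pi_m * q_mn = pi_nm * q_nm`).
#'
#' @param q_mn rate marine -> non-marine, `>= 0`.
#' @param q_nm rate non-marine -> marine, `>= 0`.
#' @return object of class `rate_model`.
#' @examples
#' m <- rate_model(1, 3)
#' stationary(m)          # (0.75, 0.25)
#' normalize_rates(m)     # global rate r = 1.5
#' @export
rate_model <- function(q_mn, q_nm) {
  stopifnot(length(q_mn) == 1L, length(q_nm) == 1L,
            is.finite(q_mn), is.finite(q_nm))
  if (q_mn < 0 || q_nm < 0) stop_habtrans("rates must be non-negative")
  structure(list(q_mn = as.numeric(q_mn), q_nm = as.numeric(q_nm)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model: q_mn = %g, q_nm = %g\n", x$q_mn, x$q_nm))
  invisible(x)
}

#' @rdname rate_model
#' @param model a `rate_model`.
#' @return `stationary()`: named numeric `(marine, non_marine)` stationary
#'   frequencies.
#' @export
stationary <- function(model) {
  s <- model$q_mn + model$q_nm
  if (s <= 0) stop_habtrans("stationary distribution undefined for s = 0")
  stats::setNames(c(model$q_nm, model$q_mn) / s, mk2_states())
}

#' Analytic transition probability matrix
#'
#' Closed form for the two-state chain:
#' `P_ij(t) = pi_j + (delta_ij - pi_j) * exp(-(q_mn + q_nm) * t)`.
#' When both rates are zero the matrix is the identity for every `t`.
#'
#' @param model a [rate_model()].
#' @param t branch length, `>= 0`.
#' @return 2x2 row-stochastic matrix with rows/columns `marine`,
#'   `non_marine`.
#' @export
transition_matrix <- function(model, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop_habtrans("t must be a single non-negative number")
  }
  p <- mk2_edge_P(model$q_mn, model$q_nm, t)
  matrix(c(p[1, "P11"], p[1, "P21"], p[1, "P12"], p[1, "P22"]), 2L, 2L,
         dimnames = list(mk2_states(), mk2_states()))
}

# Vectorized per-edge transition probabilities; one row per edge.
mk2_edge_P <- function(q_mn, q_nm, t) {
  s <- q_mn + q_nm
  pos <- s > 0
  e <- ifelse(pos, exp(-s * t), 1)
  pi_m <- ifelse(pos, q_nm / ifelse(pos, s, 1), 1)
  P11 <- ifelse(pos, pi_m + (1 - pi_m) * e, 1)
  P21 <- ifelse(pos, pi_m * (1 - e), 0)
  cbind(P11 = P11, P12 = 1 - P11, P21 = P21, P22 = 1 - P21)
}

#' Normalized rate matrix and the global rate
#'
#' Rescales the rate matrix so that one transition is expected per unit
#' branch length at stationarity. The scalar
#' `r = pi_m * q_mn + pi_nm * q_nm` is the "global rate" — the overall speed
#' of habitat evolution regardless of direction — and the normalized matrix
#' `Q/r` preserves the stationary distribution. `r * Qhat` reconstructs `Q`
#' exactly.
#'
#' @param model a [rate_model()] with `q_mn + q_nm > 0`.
#' @return list with elements `model` (the normalized `rate_model`) and
#'   `rate` (the global rate `r`).
#' @export
normalize_rates <- function(model) {
  s <- model$q_mn + model$q_nm
  if (s <= 0) stop_habtrans("cannot normalize the zero rate matrix")
  pi <- stationary(model)
  r <- pi[["marine"]] * model$q_mn + pi[["non_marine"]] * model$q_nm
  list(model = rate_model(model$q_mn / r, model$q_nm / r), rate = r)
}

#' Clade-specific rate regimes
#'
#' A `regime_partition` assigns a separate [rate_model()] to each named,
#' monophyletic clade (tip-set-defined), with a background model for every
#' branch outside the named clades. A clade's regime covers all branches
#' inside it *and its stem branch* (so transitions into the clade are
#' governed by the clade's rates); nested clades resolve to the most
#' specific (smallest) containing clade. The painting itself is
#' tree-specific and is recomputed per tree by [paint_regimes()], so one
#' `regime_partition` applies across a [tree_set()].
#'
#' @param models named list of `rate_model`s: one per clade plus one named
#'   `background` (or the name given in `background`).
#' @param clade_defs named list of tip-name character vectors defining the
#'   clades; names must match `models`.
#' @param background name of the background regime in `models`.
#' @return object of class `regime_partition`.
#' @export
regime_partition <- function(models, clade_defs, background = "background") {
  stopifnot(is.list(models), is.list(clade_defs))
  if (!all(vapply(models, inherits, TRUE, "rate_model"))) {
    stop_habtrans("all models must be rate_model objects")
  }
  need <- c(names(clade_defs), background)
  if (!all(need %in% names(models))) {
    stop_habtrans("missing model(s) for regime(s): ",
                  paste(setdiff(need, names(models)), collapse = ", "))
  }
  structure(list(models = models, clade_defs = clade_defs,
                 background = background),
            class = "regime_partition")
}

#' @export
print.regime_partition <- function(x, ...) {
  cat("regime_partition:", length(x$clade_defs), "clade regime(s) +",
      x$background, "\n")
  invisible(x)
}

#' Paint branches with clade regimes
#'
#' Maps every branch of `tree` to a regime name: branches inside a named
#' clade (including its stem branch) take that clade's regime, nested clades
#' resolve to the smallest containing clade, and all remaining branches take
#' the background regime. Each clade's tip set must be monophyletic in
#' `tree`.
#'
#' @param tree a rooted `phylo`.
#' @param clade_defs named list of tip-name vectors.
#' @param background background regime name.
#' @return character vector of regime names, one per row of `tree$edge`.
#' @export
paint_regimes <- function(tree, clade_defs, background = "background") {
  stopifnot(inherits(tree, "phylo"))
  n_edge <- nrow(tree$edge)
  out <- rep(background, n_edge)
  sizes <- vapply(clade_defs, length, 1L)
  for (nm in names(clade_defs)[order(-sizes)]) {
    tips <- clade_defs[[nm]]
    if (!all(tips %in% tree$tip.label)) {
      stop_habtrans("clade '", nm, "' lists tips absent from tree")
    }
    idx <- match(tips, tree$tip.label)
    if (length(idx) == 1L) {
      mrca <- idx
    } else {
      mrca <- ape::getMRCA(tree, tips)
      desc <- descendant_tips(tree, mrca)
      if (!setequal(desc, idx)) {
        stop_habtrans("clade '", nm, "' is not monophyletic in tree")
      }
    }
    nodes <- c(mrca, descendant_nodes(tree, mrca))
    out[tree$edge[, 2L] %in% nodes] <- nm
  }
  out
}

# All descendant node ids (internal + tips) strictly below `node`.
descendant_nodes <- function(tree, node) {
  kids <- child_list(tree)
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

descendant_tips <- function(tree, node) {
  nt <- n_tips(tree)
  if (node <= nt) return(node)
  d <- descendant_nodes(tree, node)
  d[d <= nt]
}

# Resolve root-state prior probabilities from a policy spec.
# policy: "equal", "stationary", or "fixed" (with p_marine = root_p).
root_probabilities <- function(root = c("equal", "stationary", "fixed"),
                               model = NULL, root_p = NULL) {
  root <- match.arg(root)
  pr <- switch(root,
    equal = c(0.5, 0.5),
    stationary = {
      m <- if (inherits(model, "regime_partition")) {
        model$models[[model$background]]
      } else {
        model
      }
      unname(stationary(m))
    },
    fixed = {
      if (is.null(root_p) || root_p < 0 || root_p > 1) {
        stop_habtrans("fixed root policy needs root_p (P(marine)) in [0,1]")
      }
      c(root_p, 1 - root_p)
    }
  )
  stats::setNames(pr, mk2_states())
}

# Per-edge (q_mn, q_nm) under a homogeneous model or a regime partition.
edge_rates <- function(tree, model) {
  n_edge <- nrow(tree$edge)
  if (inherits(model, "rate_model")) {
    return(cbind(q_mn = rep(model$q_mn, n_edge),
                 q_nm = rep(model$q_nm, n_edge)))
  }
  if (!inherits(model, "regime_partition")) {
    stop_habtrans("model must be a rate_model or regime_partition")
  }
  reg <- paint_regimes(tree, model$clade_defs, model$background)
  q1 <- vapply(model$models, function(m) m$q_mn, 1)
  q2 <- vapply(model$models, function(m) m$q_nm, 1)
  cbind(q_mn = unname(q1[reg]), q_nm = unname(q2[reg]))
}

# Integer tip states (1 = marine, 2 = non_marine) in tip-index order.
tip_states_int <- function(atree) {
  if (atree$mode != "binary") {
    stop_habtrans("likelihood requires binary-mode labels ",
                  "(annotate with mode = 'binary')")
  }
  match(atree$labels[atree$tree$tip.label], mk2_states())
}

#' Pruning log-likelihood of tip habitats
#'
#' Felsenstein pruning over a post-order traversal, with per-branch
#' transition probabilities from the branch's regime and per-node scaling
#' accumulated in log space (stable on trees with tens of thousands of
#' tips). The root combines the conditional likelihoods under the chosen
#' root policy. Impossible data (only reachable through zero-length
#' branches joining tips fixed in different states) give `-Inf`.
#'
#' @param atree an [annotate()]d tree (binary mode), rooted.
#' @param model a [rate_model()] or [regime_partition()].
#' @param root root-state policy: `"equal"` (default, `(0.5, 0.5)`),
#'   `"stationary"`, or `"fixed"` (see `root_p`).
#' @param root_p `P(marine)` at the root for the `"fixed"` policy.
#' @return the log-likelihood (scalar).
#' @examples
#' at <- annotate(read_tree("(A:1,B:1);"),
#'                c(A = "marine", B = "non_marine"))
#' tree_loglik(at, rate_model(1, 1))  # about -1.40478
#' @export
tree_loglik <- function(atree, model, root = "equal", root_p = NULL) {
  stopifnot(inherits(atree, "annotated_tree"))
  tree <- atree$tree
  if (!ape::is.rooted(tree)) {
    stop_habtrans("tree must be rooted (see reroot_tree)")
  }
  qq <- edge_rates(tree, model)
  P <- mk2_edge_P(qq[, 1L], qq[, 2L], tree$edge.length)
  pr <- root_probabilities(root, model, root_p)
  mk2_pruning(tree, tip_states_int(atree), P, pr)$loglik
}

# Core pruning engine. P has one row per edge (original edge order).
# `ord` may supply a precomputed post-order edge ordering (hot loop of the
# MCMC). Returns partials (per-node rescaled) and the log-likelihood.
mk2_pruning <- function(tree, tip_state, P, root_prob, ord = NULL) {
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  L1 <- numeric(nn)
  L2 <- numeric(nn)
  L1[seq_len(nt)] <- as.numeric(tip_state == 1L)
  L2[seq_len(nt)] <- as.numeric(tip_state == 2L)
  if (nn > nt) {
    L1[(nt + 1L):nn] <- 1
    L2[(nt + 1L):nn] <- 1
  }
  logscale <- 0
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  if (is.null(ord)) ord <- postorder_edges(tree)
  p11 <- P[, 1L]
  p12 <- P[, 2L]
  p21 <- P[, 3L]
  p22 <- P[, 4L]
  for (i in ord) {
    p <- e1[i]
    v <- e2[i]
    c1 <- L1[v]
    c2 <- L2[v]
    a <- L1[p] * (p11[i] * c1 + p12[i] * c2)
    b <- L2[p] * (p21[i] * c1 + p22[i] * c2)
    m <- if (a > b) a else b
    if (is.nan(m)) {
      stop_habtrans("non-finite partial likelihood at node ", p)
    }
    if (m > 0 && m < 1e-140) {
      a <- a / m
      b <- b / m
      logscale <- logscale + log(m)
    }
    L1[p] <- a
    L2[p] <- b
  }
  r <- root_node(tree)
  lik <- root_prob[[1L]] * L1[r] + root_prob[[2L]] * L2[r]
  ll <- if (lik > 0) log(lik) + logscale else -Inf
  list(loglik = ll, L1 = L1, L2 = L2, logscale = logscale, postorder = ord)
}
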