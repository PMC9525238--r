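# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All user-facing stochastic operations take an
# explicit integer seed and route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# log(sum(exp(x))) without overflow; -Inf for empty input.
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Number of tips of a phylo object.
n_tips <- function(tree) length(tree$tip.label)

# Children of each node as a list indexed by node id (tips have none).
child_list <- function(tree) {
  n_node <- n_tips(tree) + tree$Nnode
  out <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

root_node <- function(tree) n_tips(tree) + 1L

# Depth (number of edges from the root) of every node; O(E) stack DFS.
node_depths <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  depth <- rep(NA_integer_, nn)
  r <- root_node(tree)
  depth[r] <- 0L
  kids <- child_list(tree)
  stack <- integer(nn)
  sp <- 1L
  stack[1L] <- r
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    for (k in kids[[v]]) {
      depth[k] <- depth[v] + 1L
      sp <- sp + 1L
      stack[sp] <- k
    }
  }
  depth
}

# Edge indices ordered so every edge is visited after all edges in its
# child's subtree (valid post-order for the pruning recursions); independent
# of how the edge matrix happens to be stored.
postorder_edges <- function(tree) {
  depth <- node_depths(tree)
  order(depth[tree$edge[, 2L]], decreasing = TRUE)
}

# Edge indices parent-before-child (pre-order), for downward recursions.
preorder_edges <- function(tree) {
  depth <- node_depths(tree)
  order(depth[tree$edge[, 2L]], decreasing = FALSE)
}

stop_habtrans <- function(...) stop(..., call. = FALSE)
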