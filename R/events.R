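# Transition events: persistence-filtered counting of habitat switches on a
# trait history, relative dating on mean-path-length chronograms, and
# per-direction tallies across tree sets.

#' Relative chronogram by mean path length
#'
#' Dates every internal node by the mean path length (MPL) to its descendant
#' tips — the calibration-free core of Pathd8-style smoothing — enforces
#' age monotonicity (a parent is raised to just above its oldest child when
#' the raw means invert, by `1e-9 * root age`), and rescales so the root has
#' age 1 and all tips age 0. On an ultrametric tree the relative ages equal
#' the relative node depths exactly.
#'
#' @param tree rooted `phylo` with non-negative branch lengths and at least
#'   two tips.
#' @return object of class `chronogram`: list with `tree` and `ages`
#'   (numeric, one per node; tips are 0, root is 1, ages decrease
#'   root-to-tip).
#' @examples
#' ch <- mpl_chronogram(read_tree("((A:1,B:3):2,C:6);"))
#' ch$ages  # cherry at 2/4.667 = 0.4286 of root age
#' @export
mpl_chronogram <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_habtrans("tree must be rooted")
  if (n_tips(tree) < 2L) stop_habtrans("need at least 2 tips")
  if (is.null(tree$edge.length)) stop_habtrans("tree has no branch lengths")
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  path_sum <- numeric(nn)   # sum of path lengths to descendant tips
  tip_cnt <- integer(nn)
  tip_cnt[seq_len(nt)] <- 1L
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  for (i in postorder_edges(tree)) {
    p <- e1[i]
    v <- e2[i]
    path_sum[p] <- path_sum[p] + path_sum[v] + tip_cnt[v] * tree$edge.length[i]
    tip_cnt[p] <- tip_cnt[p] + tip_cnt[v]
  }
  raw <- path_sum / tip_cnt
  root_age <- raw[root_node(tree)]
  if (root_age <= 0) stop_habtrans("tree has zero total depth")
  eps <- 1e-9 * root_age
  age <- raw
  ord <- postorder_edges(tree)
  # enforce parent age strictly above child ages
  for (i in ord) {
    p <- e1[i]
    if (age[p] <= age[e2[i]]) age[p] <- age[e2[i]] + eps
  }
  age <- age / age[root_node(tree)]
  age[seq_len(nt)] <- 0
  structure(list(tree = tree, ages = age), class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("chronogram:", n_tips(x$tree),
      "tips, relative ages (root = 1, tips = 0)\n")
  invisible(x)
}

#' Count directed habitat transitions with the persistence rule
#'
#' Every edge whose parent and child states differ is a transition event.
#' An event is *counted* only if it founds a persistent clade: the number of
#' descendant tips reachable from the child without any further state
#' change must be at least `min_clade_size` (default 2, distinguishing
#' establishing colonizers from one-off tips). Setting `min_clade_size = 1`
#' recovers the unfiltered total.
#'
#' @param history a [trait_history()].
#' @param min_clade_size minimum number of same-state tips for an event to
#'   be counted.
#' @return data.frame with one row per state-change edge: `edge`,
#'   `parent_state`, `child_state`, `direction` (`"M->NM"` or `"NM->M"`),
#'   `persistent_tip_count`, `counted`.
#' @export
count_transitions <- function(history, min_clade_size = 2L) {
  stopifnot(inherits(history, "trait_history"))
  tree <- history$tree
  st <- history$states
  nt <- n_tips(tree)
  kids <- child_list(tree)
  # persistent tips below a node along monochromatic paths (iterative DFS,
  # safe on very deep trees)
  persist <- function(v0, s) {
    if (st[v0] != s) return(0L)
    total <- 0L
    stack <- v0
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (st[v] != s) next
      if (v <= nt) total <- total + 1L else stack <- c(stack, kids[[v]])
    }
    total
  }
  ev <- history$events
  if (nrow(ev) == 0L) {
    ev$persistent_tip_count <- integer(0)
    ev$counted <- logical(0)
    return(ev)
  }
  ev$persistent_tip_count <- vapply(
    seq_len(nrow(ev)),
    function(j) persist(tree$edge[ev$edge[j], 2L], ev$child_state[j]),
    integer(1)
  )
  ev$counted <- ev$persistent_tip_count >= min_clade_size
  ev
}

#' Relative timing of transition events
#'
#' Places each event on its branch (midpoint by default; the parent-node and
#' child-node conventions are available) and converts chronogram ages
#' (1 at the root, 0 at tips) to time measured from the root, so
#' `relative_time = 0` is the root and `1` is the present.
#'
#' @param events event table from [count_transitions()].
#' @param chrono a [mpl_chronogram()] built from the same tree the history
#'   was reconstructed on.
#' @param placement where on the branch the event is assumed to sit.
#' @return `events` with a `relative_time` column added.
#' @export
event_times <- function(events, chrono,
                        placement = c("midpoint", "parent", "child")) {
  placement <- match.arg(placement)
  stopifnot(inherits(chrono, "chronogram"))
  ne <- nrow(chrono$tree$edge)
  if (nrow(events) > 0L && any(events$edge < 1L | events$edge > ne)) {
    stop_habtrans("event edge id(s) absent from chronogram")
  }
  a_par <- chrono$ages[chrono$tree$edge[events$edge, 1L]]
  a_chi <- chrono$ages[chrono$tree$edge[events$edge, 2L]]
  events$relative_time <- switch(placement,
    midpoint = 1 - (a_par + a_chi) / 2,
    parent = 1 - a_par,
    child = 1 - a_chi
  )
  if (nrow(events) == 0L) events$relative_time <- numeric(0)
  events
}

#' Histogram of event times
#'
#' Bins `relative_time` of events on `[0, 1]` for ridgeline-style timing
#' summaries. Reports both the counted-only and the all-events populations.
#'
#' @param events event table with a `relative_time` column (see
#'   [event_times()]).
#' @param bins number of equal-width bins on `[0, 1]`.
#' @return data.frame with `bin_start`, `bin_end`, `n_counted`, `n_all`.
#' @export
event_time_histogram <- function(events, bins = 20L) {
  br <- seq(0, 1, length.out = bins + 1L)
  cut_idx <- function(x) pmin(pmax(findInterval(x, br, rightmost.closed = TRUE),
                                   1L), bins)
  n_all <- tabulate(cut_idx(events$relative_time), bins)
  n_cnt <- tabulate(cut_idx(events$relative_time[events$counted]), bins)
  data.frame(bin_start = br[-(bins + 1L)], bin_end = br[-1L],
             n_counted = n_cnt, n_all = n_all)
}

#' Tally transition counts across a set of histories
#'
#' Per-tree counted-event totals by direction plus boxplot-style summaries
#' (median, quartiles, 1.5 IQR whiskers). The unfiltered per-tree totals
#' (all state-change edges) are reported alongside the persistence-filtered
#' ("counted") totals.
#'
#' @param event_list list of event tables from [count_transitions()], one
#'   per tree/history.
#' @return list with `per_tree` (data.frame: `tree`, `m_to_nm`, `nm_to_m`,
#'   `m_to_nm_all`, `nm_to_m_all`) and `summary` (data.frame per direction:
#'   median, `q1`, `q3`, whisker bounds of the counted totals).
#' @export
tally_transitions <- function(event_list) {
  stopifnot(length(event_list) >= 1L)
  per_tree <- do.call(rbind, lapply(seq_along(event_list), function(i) {
    ev <- event_list[[i]]
    data.frame(
      tree = i,
      m_to_nm = sum(ev$counted & ev$direction == "M->NM"),
      nm_to_m = sum(ev$counted & ev$direction == "NM->M"),
      m_to_nm_all = sum(ev$direction == "M->NM"),
      nm_to_m_all = sum(ev$direction == "NM->M")
    )
  }))
  summ <- do.call(rbind, lapply(
    c(m_to_nm = "m_to_nm", nm_to_m = "nm_to_m"),
    function(col) {
      x <- per_tree[[col]]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3L] - q[1L]
      lw <- min(x[x >= q[1L] - 1.5 * iqr])
      uw <- max(x[x <= q[3L] + 1.5 * iqr])
      data.frame(direction = if (col == "m_to_nm") "M->NM" else "NM->M",
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 lower_whisker = lw, upper_whisker = uw)
    }
  ))
  rownames(summ) <- NULL
  list(per_tree = per_tree, summary = summ)
}
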