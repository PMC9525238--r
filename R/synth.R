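# Synthetic data with recorded ground truth: birth-death trees, simulated
# habitat histories, jittered tree sets, and study-like clade bundles.

#' Simulate a birth-death tree conditioned on tip count
#'
#' Ultrametric tree in time units (birth-death process conditioned on `n`
#' extant tips), optionally rescaled by a multiplicative rate factor to
#' mimic a substitutions/site branch-length regime. Deterministic given
#' `seed`.
#'
#' @param n number of tips (`>= 2`).
#' @param birth,death per-lineage birth and death rates (`birth > death >=
#'   0`).
#' @param scale multiplicative branch-length factor (e.g. substitutions per
#'   site per time unit); 1 keeps time units.
#' @param seed integer seed.
#' @return a `phylo` with `n` tips.
#' @export
simulate_tree <- function(n, birth = 1, death = 0, scale = 1, seed = NULL) {
  stopifnot(n >= 2L, birth > death, death >= 0, scale > 0)
  tree <- with_seed(seed, ape::rphylo(n, birth = birth, death = death,
                                      fossils = FALSE))
  tree$edge.length <- tree$edge.length * scale
  tree
}

#' Simulate a habitat history down a tree
#'
#' Gillespie simulation of the two-state chain along every branch
#' (exponential waiting times at the branch's regime rates), recording
#' every transition event with its position on the branch. Tip labels
#' derive from the final states, so replaying the recorded events from the
#' root state reproduces them exactly.
#'
#' @param tree rooted `phylo`.
#' @param model a [rate_model()] or [regime_partition()].
#' @param root_state `"marine"`, `"non_marine"`, or `NULL` to draw from the
#'   stationary distribution (of the background regime for partitions).
#' @param seed integer seed.
#' @return list with `atree` (the [annotated_tree()] of simulated tip
#'   labels), `history` (a [trait_history()] holding the true node states)
#'   and `events` (data.frame of every simulated event: `edge`, `position`
#'   as a fraction along the branch, `direction`).
#' @export
simulate_history <- function(tree, model, root_state = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_habtrans("tree must be rooted")
  qq <- edge_rates(tree, model)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  with_seed(seed, {
    st <- integer(nn)
    r <- root_node(tree)
    if (is.null(root_state)) {
      m <- if (inherits(model, "regime_partition")) {
        model$models[[model$background]]
      } else {
        model
      }
      pi <- stationary(m)
      st[r] <- if (runif(1) < pi[["marine"]]) 1L else 2L
    } else {
      st[r] <- match(match.arg(root_state, mk2_states()), mk2_states())
    }
    ev_edge <- integer(0)
    ev_pos <- numeric(0)
    ev_dir <- character(0)
    e1 <- tree$edge[, 1L]
    e2 <- tree$edge[, 2L]
    for (i in preorder_edges(tree)) {
      cur <- st[e1[i]]
      len <- tree$edge.length[i]
      t <- 0
      repeat {
        rate <- if (cur == 1L) qq[i, 1L] else qq[i, 2L]
        if (rate <= 0) break
        t <- t + rexp(1L, rate)
        if (t >= len) break
        cur <- 3L - cur
        ev_edge <- c(ev_edge, i)
        ev_pos <- c(ev_pos, t / len)
        ev_dir <- c(ev_dir, if (cur == 2L) "M->NM" else "NM->M")
      }
      st[e2[i]] <- cur
    }
    list(
      atree = annotated_tree(
        tree, stats::setNames(mk2_states()[st[seq_len(nt)]], tree$tip.label)
      ),
      history = trait_history(tree, mk2_states()[st]),
      events = data.frame(edge = ev_edge, position = ev_pos,
                          direction = ev_dir, stringsAsFactors = FALSE)
    )
  })
}

#' Jittered tree replicates standing in for a posterior tree set
#'
#' Produces `n` copies of an annotated tree with every branch length
#' multiplied by an i.i.d. log-normal factor (topology and labels fixed) —
#' a stand-in for the "100 alternative phylogenies" that carry phylogenetic
#' uncertainty. With `mean_correct = TRUE` (default) the log-normal is
#' mean-1 (`meanlog = -sd^2/2`) so expected branch lengths match the
#' original.
#'
#' @param atree an [annotated_tree()].
#' @param n number of replicate trees.
#' @param jitter_sd log-scale standard deviation (`>= 0`; 0 gives identical
#'   copies).
#' @param seed integer seed.
#' @param mean_correct center the multiplicative factors to mean 1.
#' @return a [tree_set()].
#' @export
make_tree_set <- function(atree, n = 100L, jitter_sd = 0.1, seed = NULL,
                          mean_correct = TRUE) {
  stopifnot(inherits(atree, "annotated_tree"), jitter_sd >= 0, n >= 1L)
  mu <- if (mean_correct) -jitter_sd^2 / 2 else 0
  with_seed(seed, {
    tree_set(lapply(seq_len(n), function(i) {
      tr <- atree$tree
      if (jitter_sd > 0) {
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), meanlog = mu, sdlog = jitter_sd)
      }
      annotated_tree(tr, atree$labels, atree$mode)
    }))
  })
}

#' Emit a study-like synthetic data bundle to disk
#'
#' For each configured clade, simulates a birth-death tree, evolves a
#' habitat history under the clade's rates, writes a jittered tree set
#' (Newick, one tree per line), a habitat table (TSV), the true node states
#' and true event table (TSV), and a JSON manifest listing every emitted
#' file with its md5 checksum. The clade configurations are chosen so that
#' contrasting regimes (e.g. a fast, non-marine-biased clade versus a slow
#' symmetric one) are distinguishable by the inference module.
#'
#' @param dir output directory (created if needed).
#' @param clades named list; each element a list with `n` (tips, `>= 4`),
#'   `q_mn`, `q_nm`, and optionally `birth` (1), `death` (0), `scale` (1),
#'   `root_state` (`NULL` = stationary draw).
#' @param n_trees trees per clade set.
#' @param jitter_sd log-normal branch jitter of the tree sets.
#' @param seed integer seed (one stream drives the whole bundle).
#' @return the manifest, invisibly: per clade the file paths, true rates and
#'   event counts, plus md5 checksums.
#' @export
study_like_bundle <- function(dir, clades, n_trees = 10L, jitter_sd = 0.05,
                              seed = 1L) {
  stopifnot(is.list(clades), length(clades) > 0L,
            !is.null(names(clades)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, n_trees = n_trees, jitter_sd = jitter_sd,
                   clades = list())
  with_seed(seed, {
    for (nm in names(clades)) {
      cfg <- clades[[nm]]
      if (cfg$n < 4L) stop_habtrans("clade '", nm, "' too small (< 4 tips)")
      birth <- cfg$birth %||% 1
      death <- cfg$death %||% 0
      scale <- cfg$scale %||% 1
      tree <- simulate_tree(cfg$n, birth, death, scale, seed = NULL)
      tree$tip.label <- paste0(nm, "_t", seq_len(cfg$n))
      model <- rate_model(cfg$q_mn, cfg$q_nm)
      sim <- simulate_history(tree, model, root_state = cfg$root_state,
                              seed = NULL)
      tset <- make_tree_set(sim$atree, n_trees, jitter_sd, seed = NULL)
      tree_file <- file.path(dir, paste0(nm, "_trees.nwk"))
      writeLines(vapply(tset, function(a) write_tree(a$tree), ""), tree_file)
      hab_file <- file.path(dir, paste0(nm, "_habitat.tsv"))
      utils::write.table(
        data.frame(tip_id = names(sim$atree$labels),
                   habitat = unname(sim$atree$labels)),
        hab_file, sep = "\t", quote = FALSE, row.names = FALSE
      )
      ev_file <- file.path(dir, paste0(nm, "_true_events.tsv"))
      utils::write.table(sim$events, ev_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      st_file <- file.path(dir, paste0(nm, "_true_states.tsv"))
      utils::write.table(
        data.frame(node = seq_along(sim$history$states),
                   state = sim$history$states),
        st_file, sep = "\t", quote = FALSE, row.names = FALSE
      )
      files <- c(trees = tree_file, habitat = hab_file,
                 true_events = ev_file, true_states = st_file)
      manifest$clades[[nm]] <- list(
        n_tips = cfg$n, q_mn = cfg$q_mn, q_nm = cfg$q_nm,
        n_true_events = nrow(sim$events),
        files = as.list(files),
        md5 = as.list(unname(tools::md5sum(files)))
      )
    }
  })
  manifest_file <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
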