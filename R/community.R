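# Community-level analyses: unweighted UniFrac phylogenetic distinctness
# with Monte-Carlo significance, and sequence-similarity-network
# assortativity by habitat.

#' Unweighted UniFrac distance between two tip sets
#'
#' Fraction of branch length unique to one of the two communities among the
#' branch length on paths to at least one of them; branches leading to
#' neither community are excluded. 0 means identical communities, 1 means
#' the communities occupy phylogenetically disjoint subtrees.
#'
#' @param tree rooted or unrooted `phylo` with branch lengths.
#' @param a,b non-empty character vectors of tip names (presence/absence
#'   communities).
#' @return distance in `[0, 1]`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' unifrac_unweighted(tr, c("A", "B"), c("A", "C"))  # 3/5
#' @export
unifrac_unweighted <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  if (length(a) == 0L || length(b) == 0L) {
    stop_habtrans("communities must be non-empty")
  }
  bad <- setdiff(c(a, b), tree$tip.label)
  if (length(bad) > 0L) {
    stop_habtrans("tips not in tree: ", paste(bad, collapse = ", "))
  }
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  in_a <- logical(nn)
  in_b <- logical(nn)
  in_a[match(unique(a), tree$tip.label)] <- TRUE
  in_b[match(unique(b), tree$tip.label)] <- TRUE
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  for (i in postorder_edges(tree)) {
    in_a[e1[i]] <- in_a[e1[i]] || in_a[e2[i]]
    in_b[e1[i]] <- in_b[e1[i]] || in_b[e2[i]]
  }
  la <- in_a[e2]
  lb <- in_b[e2]
  covered <- la | lb
  unique_len <- sum(tree$edge.length[xor(la, lb)])
  total_len <- sum(tree$edge.length[covered])
  if (total_len <= 0) stop_habtrans("no branch length covered")
  unique_len / total_len
}

#' Pairwise UniFrac distances with permutation significance
#'
#' Observed unweighted UniFrac distances for every sample pair, with a
#' Monte-Carlo null obtained by shuffling tip identities across the union
#' of each compared pair (the scheme of mothur's unweighted test: sizes and
#' overlap structure are preserved, memberships are randomized).
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, Bonferroni-adjusted
#' across pairs.
#'
#' @param tree `phylo` with branch lengths.
#' @param communities named list of tip-name vectors (one per sample), or a
#'   data.frame with columns `sample` and `tip_id`.
#' @param n_perm number of randomizations (default 1000).
#' @param seed integer seed.
#' @return list with `pairs` (data.frame: `sample_a`, `sample_b`,
#'   `distance`, `p`, `p_adj`) and `dist` (the symmetric distance matrix).
#' @export
unifrac_significance <- function(tree, communities, n_perm = 1000L,
                                 seed = NULL) {
  if (is.data.frame(communities)) {
    communities <- split(as.character(communities$tip_id),
                         communities$sample)
  }
  stopifnot(is.list(communities), length(communities) >= 2L)
  if (n_perm < 1L) stop_habtrans("n_perm must be at least 1")
  nms <- names(communities)
  pairs <- utils::combn(seq_along(communities), 2L)
  with_seed(seed, {
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      ia <- pairs[1L, k]
      ib <- pairs[2L, k]
      a <- unique(communities[[ia]])
      b <- unique(communities[[ib]])
      obs <- unifrac_unweighted(tree, a, b)
      u <- union(a, b)
      null_ge <- 0L
      for (j in seq_len(n_perm)) {
        perm <- sample(u)
        pa <- perm[match(a, u)]
        pb <- perm[match(b, u)]
        if (unifrac_unweighted(tree, pa, pb) >= obs) {
          null_ge <- null_ge + 1L
        }
      }
      data.frame(sample_a = nms[ia], sample_b = nms[ib], distance = obs,
                 p = (1 + null_ge) / (1 + n_perm))
    })
    res <- do.call(rbind, rows)
    res$p_adj <- pmin(1, res$p * nrow(res))
    dmat <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
    for (k in seq_len(ncol(pairs))) {
      dmat[pairs[1L, k], pairs[2L, k]] <- res$distance[k]
      dmat[pairs[2L, k], pairs[1L, k]] <- res$distance[k]
    }
    list(pairs = res, dist = dmat)
  })
}

#' UPGMA dendrogram of habitats from a UniFrac distance matrix
#'
#' @param dmat symmetric distance matrix (e.g. `unifrac_significance()$dist`).
#' @return a `phylo` dendrogram (average-linkage clustering).
#' @export
unifrac_upgma <- function(dmat) {
  ape::as.phylo(stats::hclust(stats::as.dist(dmat), method = "average"))
}

#' Read an all-against-all hit table (12-column tabular)
#'
#' Standard BLAST tabular dialect: `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, no header. Malformed
#' rows are reported with their line number.
#'
#' @param path file path.
#' @return data.frame with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12L), cols))
    out$pident <- numeric(0)
    out$length <- integer(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12L)) {
    stop_habtrans("malformed hit row at line ", which(nfield != 12L)[1L],
                  ": expected 12 tab-separated fields, got ",
                  nfield[which(nfield != 12L)[1L]])
  }
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num_cols <- cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      stop_habtrans("malformed hit row at line ", which(is.na(v))[1L],
                    ": non-numeric '", cc, "'")
    }
    out[[cc]] <- v
  }
  out
}

#' Build a habitat-labelled sequence-similarity graph
#'
#' Filters pairwise hits by percent identity and query coverage
#' (`alignment length / query sequence length * 100`; supply `seq_lengths`)
#' and assembles an undirected graph. Self-hits are dropped; duplicate
#' pairs collapse to the maximum identity. With `reciprocal = TRUE` an edge
#' is kept only if passing hits exist in both query/subject directions.
#'
#' @param hits data.frame from [read_blast_hits()] (or equivalent).
#' @param habitats named character vector: habitat per sequence id (must
#'   cover every node that survives filtering).
#' @param identity_threshold minimum percent identity (e.g. 80-97).
#' @param coverage_threshold minimum query coverage percent (study default
#'   75); set `NULL` to skip the coverage filter.
#' @param seq_lengths named numeric vector of sequence lengths; required
#'   when `coverage_threshold` is not `NULL`.
#' @param reciprocal require hits in both directions.
#' @return an `igraph` graph with vertex attribute `habitat` and edge
#'   attributes `identity` and `coverage`.
#' @export
build_graph <- function(hits, habitats, identity_threshold,
                        coverage_threshold = 75, seq_lengths = NULL,
                        reciprocal = FALSE) {
  stopifnot(is.data.frame(hits))
  keep <- hits$qseqid != hits$sseqid & hits$pident >= identity_threshold
  if (!is.null(coverage_threshold)) {
    if (is.null(seq_lengths)) {
      stop_habtrans("coverage filtering needs seq_lengths ",
                    "(alignment length / query length)")
    }
    qlen <- seq_lengths[hits$qseqid]
    if (anyNA(qlen)) {
      stop_habtrans("seq_lengths missing for: ",
                    paste(unique(hits$qseqid[is.na(qlen)]), collapse = ", "))
    }
    cov <- 100 * hits$length / as.numeric(qlen)
    keep <- keep & cov >= coverage_threshold
  } else {
    cov <- rep(NA_real_, nrow(hits))
  }
  h <- hits[keep, , drop = FALSE]
  covk <- cov[keep]
  if (nrow(h) > 0L && reciprocal) {
    fwd <- paste(h$qseqid, h$sseqid, sep = "\r")
    rev <- paste(h$sseqid, h$qseqid, sep = "\r")
    ok <- fwd %in% rev
    h <- h[ok, , drop = FALSE]
    covk <- covk[ok]
  }
  if (nrow(h) > 0L) {
    lo <- pmin(h$qseqid, h$sseqid)
    hi <- pmax(h$qseqid, h$sseqid)
    key <- paste(lo, hi, sep = "\r")
    ord <- order(key, -h$pident)
    first <- !duplicated(key[ord])
    idx <- ord[first]
    edges <- data.frame(from = lo[idx], to = hi[idx],
                        identity = h$pident[idx], coverage = covk[idx],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        identity = numeric(0), coverage = numeric(0))
  }
  nodes <- sort(unique(c(hits$qseqid, hits$sseqid)))
  hab <- habitats[nodes]
  if (anyNA(hab)) {
    stop_habtrans("habitat missing for node(s): ",
                  paste(nodes[is.na(hab)], collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, habitat = unname(hab),
                          stringsAsFactors = FALSE)
  )
  igraph::set_graph_attr(g, "thresholds",
                         c(identity = identity_threshold,
                           coverage = coverage_threshold %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Habitat assortativity of a similarity graph
#'
#' Newman's categorical assortativity coefficient over the habitat mixing
#' matrix: `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)`. 1 when
#' edges connect only same-habitat sequences, negative when habitats
#' preferentially connect to each other.
#'
#' @param graph graph from [build_graph()].
#' @return coefficient in `[-1, 1]`.
#' @export
graph_assortativity <- function(graph) {
  if (igraph::ecount(graph) == 0L) {
    stop_habtrans("assortativity undefined on an edgeless graph")
  }
  types <- as.integer(factor(igraph::vertex_attr(graph, "habitat")))
  igraph::assortativity_nominal(graph, types = types, directed = FALSE)
}
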