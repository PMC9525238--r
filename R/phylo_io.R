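# Tree and habitat-metadata I/O: the substrate for every other module.
# Trees are ape "phylo" objects throughout; habitat annotations ride along in
# an "annotated_tree" wrapper.

#' Habitat vocabularies and the four-state to binary collapse map
#'
#' The binary vocabulary is `marine` / `non_marine`; the four-state
#' vocabulary distinguishes `soil`, `freshwater`, `marine_euphotic` and
#' `marine_aphotic`. The collapse map sends soil and freshwater to
#' `non_marine` and both marine layers to `marine`; binary labels pass
#' through unchanged, so the map is total and idempotent.
#'
#' @param mode `"binary"` or `"fourstate"`.
#' @return `habitat_states()`: character vector of valid labels.
#' @export
habitat_states <- function(mode = c("binary", "fourstate")) {
  mode <- match.arg(mode)
  if (mode == "binary") c("marine", "non_marine")
  else c("soil", "freshwater", "marine_euphotic", "marine_aphotic")
}

#' @rdname habitat_states
#' @param x character vector of habitat labels (either vocabulary).
#' @return `collapse_habitat()`: `x` mapped onto the binary vocabulary.
#' @export
collapse_habitat <- function(x) {
  map <- c(
    soil = "non_marine", freshwater = "non_marine",
    marine_euphotic = "marine", marine_aphotic = "marine",
    marine = "marine", non_marine = "non_marine"
  )
  bad <- setdiff(unique(x), names(map))
  if (length(bad) > 0L) {
    stop_habtrans("unknown habitat label(s): ", paste(bad, collapse = ", "))
  }
  unname(map[x])
}

#' Read a Newick tree with validation
#'
#' Parses a single Newick statement (from a string or a file) into an ape
#' `phylo` object. Square-bracket comments are discarded; quoted labels are
#' accepted; internal node labels are retained (they carry clade tags used by
#' regime painting). Parsing is strict: unbalanced parentheses, a missing
#' terminal `;`, duplicate tip names and negative branch lengths are errors,
#' and missing branch lengths are rejected unless `default_length` supplies
#' an explicit value.
#'
#' @param x a Newick string, or (if `file = TRUE`) a path to a file holding
#'   one Newick statement.
#' @param file logical; treat `x` as a file path.
#' @param default_length if non-`NULL`, branch lengths absent from the input
#'   are set to this value (typically `0`) instead of being an error.
#' @return an object of class `phylo`.
#' @examples
#' tr <- read_tree("((A:1,B:2):0.5,C:3);")
#' @export
read_tree <- function(x, file = FALSE, default_length = NULL) {
  txt <- if (file) paste(readLines(x, warn = FALSE), collapse = "") else x
  txt <- trimws(txt)
  parse_newick_checked(txt, default_length = default_length)
}

# Shared validation + parse of one Newick statement.
parse_newick_checked <- function(txt, default_length = NULL) {
  if (!nzchar(txt)) stop_habtrans("empty Newick input")
  # discard square-bracket comments (tolerated, never interpreted)
  txt <- gsub("\\[[^]]*\\]", "", txt)
  if (!grepl(";\\s*$", txt)) {
    stop_habtrans("Newick parse error: missing terminating ';' at position ",
                  nchar(txt))
  }
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_habtrans("Newick parse error: unbalanced ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop_habtrans("Newick parse error: ", depth,
                  " unclosed '(' by position ", nchar(txt))
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) stop_habtrans("Newick parse error: unparseable input")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_habtrans("duplicate tip name(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (is.null(default_length)) {
      stop_habtrans("tree has no branch lengths ",
                    "(set default_length = 0 to accept)")
    }
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_length)) {
      stop_habtrans(sum(is.na(tree$edge.length)),
                    " branch length(s) missing ",
                    "(set default_length = 0 to accept)")
    }
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) {
    stop_habtrans("negative branch length(s) are not allowed")
  }
  tree
}

#' Write a tree as Newick
#'
#' Round-trips with [read_tree()] up to floating-point formatting (10
#' significant digits).
#'
#' @param tree a `phylo` object.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a habitat annotation table
#'
#' Expects a TSV with header `tip_id<TAB>habitat`.
#'
#' @param path file path.
#' @return data.frame with columns `tip_id`, `habitat`.
#' @export
read_habitat_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("tip_id", "habitat") %in% names(tab))) {
    stop_habtrans("habitat table must have columns 'tip_id' and 'habitat'")
  }
  tab[, c("tip_id", "habitat")]
}

#' Attach habitat labels to a tree
#'
#' Builds an `annotated_tree`: a `phylo` plus a total tip-to-habitat map. In
#' binary mode, four-state labels are collapsed via the fixed map (soil and
#' freshwater are non-marine; both marine layers are marine). Every tip must
#' receive exactly one label; table rows for tips absent from the tree are
#' ignored with a warning; conflicting duplicate rows are an error.
#'
#' @param tree a `phylo` object.
#' @param table a data.frame with columns `tip_id` and `habitat`, or a named
#'   character vector of habitats.
#' @param mode label vocabulary of the result: `"binary"` (default) or
#'   `"fourstate"`.
#' @return an object of class `annotated_tree` with elements `tree`,
#'   `labels` (named character, one per tip) and `mode`.
#' @examples
#' tr <- read_tree("(A:1,B:1);")
#' at <- annotate(tr, c(A = "soil", B = "marine_euphotic"))
#' at$labels  # A collapses to non_marine, B to marine
#' @export
annotate <- function(tree, table, mode = c("binary", "fourstate")) {
  mode <- match.arg(mode)
  if (is.data.frame(table)) {
    tips <- as.character(table$tip_id)
    habs <- as.character(table$habitat)
  } else {
    tips <- names(table)
    habs <- as.character(table)
  }
  if (is.null(tips)) stop_habtrans("habitat table must name its tips")
  ok <- c(habitat_states("binary"), habitat_states("fourstate"))
  bad <- setdiff(unique(habs), ok)
  if (length(bad) > 0L) {
    stop_habtrans("unknown habitat label(s): ", paste(bad, collapse = ", "))
  }
  # duplicates: fine if consistent, error if conflicting
  if (anyDuplicated(tips)) {
    for (tp in unique(tips[duplicated(tips)])) {
      if (length(unique(habs[tips == tp])) > 1L) {
        stop_habtrans("conflicting habitat labels for tip: ", tp)
      }
    }
    keep <- !duplicated(tips)
    tips <- tips[keep]
    habs <- habs[keep]
  }
  extra <- setdiff(tips, tree$tip.label)
  if (length(extra) > 0L) {
    warning("ignoring ", length(extra), " table tip(s) absent from tree: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
    habs <- habs[!(tips %in% extra)]
    tips <- tips[!(tips %in% extra)]
  }
  missing <- setdiff(tree$tip.label, tips)
  if (length(missing) > 0L) {
    stop_habtrans("unlabelled tips: ", paste(missing, collapse = ", "))
  }
  labels <- stats::setNames(habs, tips)[tree$tip.label]
  if (mode == "binary") {
    labels <- stats::setNames(collapse_habitat(labels), names(labels))
  } else if (any(labels %in% habitat_states("binary"))) {
    stop_habtrans("fourstate mode requires four-state labels for all tips")
  }
  annotated_tree(tree, labels, mode)
}

#' @rdname annotate
#' @param labels named character vector, one habitat per tip.
#' @export
annotated_tree <- function(tree, labels, mode = c("binary", "fourstate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(names(labels), tree$tip.label) ||
      length(labels) != length(tree$tip.label)) {
    stop_habtrans("labels must cover every tip exactly once")
  }
  if (!all(labels %in% habitat_states(mode))) {
    stop_habtrans("labels outside the '", mode, "' vocabulary")
  }
  structure(
    list(tree = tree, labels = labels[tree$tip.label], mode = mode),
    class = "annotated_tree"
  )
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree:", n_tips(x$tree), "tips,", x$mode, "labels (",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Re-root a tree on the edge subtending an outgroup
#'
#' The outgroup may be a single tip or a set of tips; it must form a clade in
#' the unrooted sense (i.e. one side of some split). Total path lengths
#' between tips are unchanged by re-rooting.
#'
#' @param tree a `phylo` object.
#' @param outgroup tip name or character vector of tip names.
#' @return a rooted `phylo`.
#' @export
reroot_tree <- function(tree, outgroup) {
  outgroup <- as.character(outgroup)
  if (!all(outgroup %in% tree$tip.label)) {
    stop_habtrans("outgroup tip(s) not in tree: ",
                  paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
  }
  if (length(outgroup) == n_tips(tree)) {
    stop_habtrans("outgroup cannot be the whole tip set")
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  comp <- setdiff(tree$tip.label, outgroup)
  og_ok <- ape::is.monophyletic(utree, outgroup)
  comp_ok <- ape::is.monophyletic(utree, comp)
  if (!og_ok && !comp_ok) {
    stop_habtrans("outgroup {", paste(outgroup, collapse = ","),
                  "} is not monophyletic in the unrooted topology")
  }
  # the split is the same from either side; root on whichever side ape can
  # treat as a clade of the unrooted topology (the complement when the
  # outgroup is attached at a basal multifurcation)
  sides <- list(outgroup, comp)
  if (!og_ok) sides <- rev(sides)
  for (side in sides) {
    rooted <- tryCatch(
      ape::root(utree, outgroup = side, resolve.root = TRUE),
      error = function(e) NULL
    )
    if (!is.null(rooted)) return(rooted)
  }
  stop_habtrans("could not root on the edge subtending {",
                paste(outgroup, collapse = ","), "}")
}

#' Randomly remove tips of one habitat
#'
#' Removes `round(fraction * n)` uniformly-random tips carrying the target
#' habitat(s), where `n` is the number of such tips, then collapses any
#' resulting unifurcations by summing branch lengths. Used for
#' sampling-effort sensitivity analyses (removal fractions of 5-70% with
#' replicate seeds). Deterministic given `seed`.
#'
#' @param atree an `annotated_tree`.
#' @param habitat habitat label(s) to subsample (in `atree`'s vocabulary).
#' @param fraction fraction of target tips to remove, in `[0, 1]`.
#' @param seed integer seed.
#' @return the pruned `annotated_tree`.
#' @export
subsample_tips <- function(atree, habitat, fraction, seed = NULL) {
  stopifnot(inherits(atree, "annotated_tree"))
  if (fraction < 0 || fraction > 1) stop_habtrans("fraction must be in [0,1]")
  if (!all(habitat %in% habitat_states(atree$mode))) {
    stop_habtrans("habitat outside the '", atree$mode, "' vocabulary")
  }
  target <- names(atree$labels)[atree$labels %in% habitat]
  if (length(target) == 0L) {
    stop_habtrans("no tips carry habitat ", paste(habitat, collapse = "/"))
  }
  k <- round(fraction * length(target))
  if (k == 0L) return(atree)
  if (n_tips(atree$tree) - k < 2L) {
    stop_habtrans("removal would leave fewer than 2 tips")
  }
  drop <- with_seed(seed, sample(target, k))
  pruned <- ape::drop.tip(atree$tree, drop, trim.internal = TRUE,
                          collapse.singles = TRUE)
  annotated_tree(pruned, atree$labels[pruned$tip.label], atree$mode)
}

#' A set of annotated trees sharing one tip set
#'
#' Wraps an ordered list of [annotate()]d trees that share identical tip
#' names and labels — the container for the "analysis over 100 alternative
#' phylogenies" design that carries phylogenetic uncertainty through the
#' inference.
#'
#' @param atrees list of `annotated_tree` objects (or a single one).
#' @return object of class `tree_set` (a list of `annotated_tree`).
#' @export
tree_set <- function(atrees) {
  if (inherits(atrees, "annotated_tree")) atrees <- list(atrees)
  stopifnot(length(atrees) >= 1L,
            all(vapply(atrees, inherits, TRUE, "annotated_tree")))
  ref <- atrees[[1]]
  for (i in seq_along(atrees)) {
    a <- atrees[[i]]
    if (!setequal(a$tree$tip.label, ref$tree$tip.label)) {
      stop_habtrans("tree ", i, " has a different tip set")
    }
    if (!identical(a$labels[sort(names(a$labels))],
                   ref$labels[sort(names(ref$labels))])) {
      stop_habtrans("tree ", i, " has different labels")
    }
  }
  structure(atrees, class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("tree_set:", length(x), "trees,", n_tips(x[[1]]$tree), "shared tips\n")
  invisible(x)
}

#' Read a tree set from a multi-line Newick file
#'
#' One Newick statement per line; all trees are annotated from the same
#' habitat table.
#'
#' @param path Newick file, one tree per line.
#' @param table habitat table (data.frame or named vector), as in
#'   [annotate()].
#' @inheritParams annotate
#' @return a [tree_set()].
#' @export
read_tree_set <- function(path, table, mode = c("binary", "fourstate")) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_habtrans("no trees in ", path)
  tree_set(lapply(lines, function(l) {
    suppressWarnings(annotate(parse_newick_checked(trimws(l)), table, mode))
  }))
}
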