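#' Construct a dated tree from an ape phylogeny
#'
#' A `dated_tree` is a rooted ultrametric phylogeny whose branch lengths are
#' in time units (Myr), with one age (time before present) per node. Node
#' ages are derived from branch lengths: the root age is the maximum
#' root-to-leaf path length and every node's age is root age minus its
#' root-to-node path length. Leaves must sit at the present (age 0) within a
#' relative tolerance of the root age; within tolerance their ages are
#' snapped to exactly 0.
#'
#' @param phy an [ape::as.phylo] object with branch lengths on all non-root
#'   edges. Polytomies are accepted.
#' @param source_label optional identifier for the chronogram's source
#'   (conventionally `"CLOCK:CALSET"`, e.g. `"LN:C3"`).
#' @param tol relative ultrametricity tolerance: leaf ages must be within
#'   `tol * root_age` of 0.
#'
#' @return an object of class `dated_tree`: a list with elements `phy` (the
#'   phylogeny), `age` (numeric vector over all nodes, tips first, in Myr),
#'   `root_age`, and `source_label`.
#'
#' @details Leaf labels must be unique, non-empty, and must not contain the
#'   `"|"` character, which is reserved as the clade-key separator.
#'
#' @seealso [read_chronogram()], [node_age_table()]
#' @export
dated_tree <- function(phy, source_label = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a 'phylo' object")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a chronogram requires time-unit branch lengths")
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    bad <- which(!is.finite(phy$edge.length))[1L]
    stop(sprintf("missing or non-finite branch length on edge %d (%d -> %d)",
                 bad, phy$edge[bad, 1L], phy$edge[bad, 2L]))
  }
  labs <- phy$tip.label
  if (any(!nzchar(labs))) stop("empty leaf labels are not allowed")
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (any(grepl("|", labs, fixed = TRUE))) {
    stop("leaf labels must not contain '|' (reserved clade-key separator)")
  }
  ntip <- length(labs)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ntip)])
  if (root_age <= 0) stop("all branch lengths are zero; root age must be positive")
  age <- root_age - depth
  tip_age <- age[seq_len(ntip)]
  off <- abs(tip_age) / root_age
  if (any(off > tol)) {
    worst <- which.max(off)
    stop(sprintf(
      "tree is not ultrametric: leaf '%s' sits %.6g Myr from the present (relative offset %.3g > tolerance %.3g)",
      labs[worst], tip_age[worst], off[worst], tol))
  }
  age[seq_len(ntip)] <- 0
  obj <- structure(
    list(phy = phy, age = age, root_age = root_age,
         source_label = source_label),
    class = "dated_tree")
  validate_dated_tree(obj)
  obj
}

# internal: parent age strictly above each child age on every edge
validate_dated_tree <- function(x) {
  e <- x$phy$edge
  bad <- which(x$age[e[, 1L]] <= x$age[e[, 2L]])
  if (length(bad)) {
    stop(sprintf(
      "node ages not strictly decreasing towards the tips: edge %d -> %d (parent age %.6g <= child age %.6g)",
      e[bad[1L], 1L], e[bad[1L], 2L],
      x$age[e[bad[1L], 1L]], x$age[e[bad[1L], 2L]]))
  }
  invisible(x)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree%s: %d leaves, %d internal nodes, root age %.4g Myr\n",
              if (is.null(x$source_label)) "" else paste0(" [", x$source_label, "]"),
              length(x$phy$tip.label), x$phy$Nnode, x$root_age))
  invisible(x)
}

# Strip all square-bracket blocks (FigTree/BEAST [&...] annotations and plain
# comments) from a tree document. Handles nesting; errors on an unbalanced
# block, naming the character position.
strip_tree_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    c_i <- chars[i]
    if (c_i == "[") depth <- depth + 1L
    keep[i] <- depth == 0L
    if (c_i == "]") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("unbalanced ']' at character %d", i))
    }
  }
  if (depth > 0L) stop("unclosed '[' comment block at end of document")
  paste(chars[keep], collapse = "")
}

#' Read a time-calibrated tree (chronogram)
#'
#' Parses a Newick or NEXUS tree document whose branch lengths are in time
#' units (Myr) and derives node ages. Square-bracket annotation blocks (such
#' as FigTree/BEAST `[&rate=...]` comments) are stripped before parsing, so
#' the output dialects of the common dating programs are read uniformly;
#' branch lengths, never annotations, are the sole age source. NEXUS
#' translate tables are honored. The tree is taken as rooted exactly as
#' written; no re-rooting is performed.
#'
#' @param x a file path, or a character string holding the document itself.
#' @param format `"newick"` or `"nexus"`.
#' @param source_label optional source identifier stored on the result.
#' @param tol relative ultrametricity tolerance (see [dated_tree()]).
#'
#' @return a [dated_tree()] object. A NEXUS file with several trees yields
#'   the first, with a warning.
#'
#' @examples
#' tr <- read_chronogram("((A:1,B:1):2,(C:2,D:2):1);")
#' node_age_table(tr)
#' @export
read_chronogram <- function(x, format = c("newick", "nexus"),
                            source_label = NULL, tol = 1e-6) {
  format <- match.arg(format)
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (file.exists(x) && !grepl("\n|;", x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else x
  text <- strip_tree_comments(text)
  check_balance(text)
  phy <- if (format == "newick") {
    p <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
    if (is.null(p)) stop("Newick parse error: no tree found in document")
    p
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    tryCatch(ape::read.nexus(tf),
             error = function(e) stop("NEXUS parse error: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) > 1L) warning("document contains ", length(phy),
                                  " trees; using the first")
    phy <- phy[[1L]]
  }
  dated_tree(phy, source_label = source_label, tol = tol)
}

# quick structural pre-check with character positions, since downstream
# parsers report little
check_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("malformed document: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L) stop("malformed document: unmatched '(' (document truncated?)")
  invisible(TRUE)
}

# internal: list of sorted leaf-label vectors, one per internal node, in
# node-number order (ntip+1 ... ntip+nnode)
clade_leaf_sets <- function(tree) {
  phy <- tree$phy
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  lapply(pp, function(i) sort(labs[i], method = "radix"))
}

clade_key <- function(leaves) paste(leaves, collapse = "|")

# deterministic clade ordering: lexicographic smallest leaf, then clade size
order_clades <- function(leaf_sets) {
  smallest <- vapply(leaf_sets, `[`, character(1L), 1L)
  size <- lengths(leaf_sets)
  order(smallest, size, method = "radix")
}

#' Tabulate internal-node ages by clade
#'
#' Lists every internal node of a dated tree as its rooted clade (the set of
#' descendant leaf labels) together with its age in Myr. Leaves are excluded
#' (their age is identically 0). The root counts as an internal node, so a
#' binary rooted tree on L leaves yields L-1 rows.
#'
#' @param tree a [dated_tree()].
#' @return a `data.frame` with columns `clade` (leaf labels sorted and joined
#'   by `"|"`), `n_leaves`, and `age` (Myr), ordered by the lexicographically
#'   smallest leaf then clade size. The leaf-label sets themselves are
#'   attached as the `leaves` attribute (a list, same order).
#' @export
node_age_table <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  sets <- clade_leaf_sets(tree)
  ntip <- length(tree$phy$tip.label)
  ages <- tree$age[ntip + seq_along(sets)]
  ord <- order_clades(sets)
  out <- data.frame(
    clade = vapply(sets[ord], clade_key, character(1L)),
    n_leaves = lengths(sets[ord]),
    age = ages[ord],
    stringsAsFactors = FALSE)
  attr(out, "leaves") <- sets[ord]
  out
}

#' Serialize a dated tree to Newick
#'
#' Branch lengths are written as parent age minus child age, so reading the
#' output back reproduces every node age (round-trip relative error below
#' 1e-9).
#'
#' @param tree a [dated_tree()].
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when `file` is given).
#' @export
write_chronogram <- function(tree, file = NULL, digits = 15L) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phy
  phy$edge.length <- tree$age[phy$edge[, 1L]] - tree$age[phy$edge[, 2L]]
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
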