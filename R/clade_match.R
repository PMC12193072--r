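#' Internal nodes shared across a panel of chronograms
#'
#' Node identity across trees is the rooted clade: the set of descendant
#' leaf labels. A node is shared when every tree in the panel contains an
#' internal node with exactly that leaf set; trees whose topologies differ
#' therefore contribute fewer shared nodes. The root clade (all leaves)
#' counts as a node. All trees must carry the same leaf label set.
#'
#' @param trees a list of two or more [dated_tree()] objects.
#' @return a `data.frame` with columns `clade` and `n_leaves`, one row per
#'   shared internal node, deterministically ordered (lexicographically
#'   smallest leaf, then clade size); leaf-label sets in the `leaves`
#'   attribute.
#' @seealso [excluded_clades()] to see which clades were dropped and where.
#' @export
shared_clades <- function(trees) {
  check_panel(trees)
  key_sets <- lapply(trees, function(t)
    vapply(clade_leaf_sets(t), clade_key, character(1L)))
  shared <- Reduce(intersect, key_sets)
  sets1 <- clade_leaf_sets(trees[[1L]])
  keys1 <- vapply(sets1, clade_key, character(1L))
  sets <- sets1[match(shared, keys1)]
  ord <- order_clades(sets)
  out <- data.frame(
    clade = vapply(sets[ord], clade_key, character(1L)),
    n_leaves = lengths(sets[ord]),
    stringsAsFactors = FALSE)
  attr(out, "leaves") <- sets[ord]
  out
}

# common panel validation: >= 2 trees, identical leaf sets (error names the
# symmetric difference)
check_panel <- function(trees) {
  if (!is.list(trees) || length(trees) < 2L)
    stop("need at least 2 trees")
  ok <- vapply(trees, inherits, logical(1L), "dated_tree")
  if (!all(ok)) stop("all panel elements must be dated_tree objects")
  ref <- sort(trees[[1L]]$phy$tip.label, method = "radix")
  for (i in seq_along(trees)[-1L]) {
    labs <- sort(trees[[i]]$phy$tip.label, method = "radix")
    if (!identical(labs, ref)) {
      dif <- c(setdiff(ref, labs), setdiff(labs, ref))
      stop("trees have differing leaf sets; symmetric difference: ",
           paste(dif, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Clades excluded from the shared set, per source
#'
#' For each tree in a labeled panel, reports the internal clades present in
#' that tree but absent from at least one other tree, i.e. the nodes that a
#' shared-node analysis excludes.
#'
#' @param trees a named list of [dated_tree()] objects.
#' @return a `data.frame` with columns `source`, `clade`, `n_leaves`: one row
#'   per (source, non-shared clade) combination. Zero rows when all
#'   topologies agree.
#' @export
excluded_clades <- function(trees) {
  check_panel(trees)
  labels <- panel_labels(trees)
  shared <- shared_clades(trees)$clade
  rows <- lapply(seq_along(trees), function(i) {
    sets <- clade_leaf_sets(trees[[i]])
    keys <- vapply(sets, clade_key, character(1L))
    extra <- setdiff(keys, shared)
    if (!length(extra)) return(NULL)
    data.frame(source = labels[i], clade = extra,
               n_leaves = lengths(sets[match(extra, keys)]),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows, data.frame(source = character(), clade = character(),
                              n_leaves = integer(), stringsAsFactors = FALSE))
}

panel_labels <- function(trees) {
  labels <- names(trees)
  if (is.null(labels)) {
    labels <- vapply(seq_along(trees), function(i) {
      sl <- trees[[i]]$source_label
      if (is.null(sl)) sprintf("source_%d", i) else sl
    }, character(1L))
  }
  if (anyDuplicated(labels)) stop("source labels must be unique")
  if (any(!nzchar(labels))) stop("source labels must be non-empty")
  labels
}

#' Assemble the shared-clade-by-source age matrix
#'
#' Builds the dense matrix of node ages (Myr) whose rows are clades shared
#' by every tree of the panel and whose columns are the labeled sources.
#' This matrix is the common input of [deviation_from_group_mean()],
#' [pairwise_matrix()], [paired_wilcoxon()] and [mds_embed()].
#'
#' @param trees a named list of [dated_tree()] objects; names are the source
#'   labels (conventionally `"CLOCK:CALSET"`). Unnamed lists fall back to
#'   each tree's `source_label`.
#' @param clades optional restriction: a character vector of clade keys (or
#'   the `data.frame` from [shared_clades()]); must be a subset of the
#'   shared clades. Default: all shared clades.
#' @return an `age_matrix`: a numeric matrix (clades x sources, Myr) with
#'   clade keys as rownames, plus attributes `leaves` (list of leaf sets)
#'   and `n_leaves`.
#' @export
build_age_matrix <- function(trees, clades = NULL) {
  check_panel(trees)
  labels <- panel_labels(trees)
  sh <- shared_clades(trees)
  if (is.null(clades)) {
    use <- sh
  } else {
    keys <- if (is.data.frame(clades)) clades$clade else as.character(clades)
    miss <- setdiff(keys, sh$clade)
    if (length(miss)) {
      # name the first offending clade and the sources lacking it
      lack <- vapply(trees, function(t) {
        !(miss[1L] %in% vapply(clade_leaf_sets(t), clade_key, character(1L)))
      }, logical(1L))
      stop(sprintf("clade '%s' is not shared by all sources (absent from: %s)",
                   miss[1L], paste(labels[lack], collapse = ", ")))
    }
    use <- sh[match(keys, sh$clade), , drop = FALSE]
    attr(use, "leaves") <- attr(sh, "leaves")[match(keys, sh$clade)]
  }
  ages <- vapply(trees, function(t) {
    tab <- node_age_table(t)
    tab$age[match(use$clade, tab$clade)]
  }, numeric(nrow(use)))
  ages <- matrix(ages, nrow = nrow(use), ncol = length(trees),
                 dimnames = list(use$clade, labels))
  if (any(ages <= 0)) stop("all shared-clade ages must be positive")
  structure(ages, class = c("age_matrix", "matrix", "array"),
            leaves = attr(use, "leaves"), n_leaves = use$n_leaves)
}

#' @export
print.age_matrix <- function(x, ...) {
  cat(sprintf("Age matrix: %d shared clades x %d sources (Myr)\n",
              nrow(x), ncol(x)))
  cat("Sources:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Export an age matrix as TSV
#'
#' Rows are identified by the two lexicographically smallest leaf labels of
#' the clade plus its size; columns are the source labels; values in Myr at
#' full precision.
#'
#' @param matrix an `age_matrix` from [build_age_matrix()].
#' @param file output path.
#' @export
write_age_matrix <- function(matrix, file) {
  stopifnot(inherits(matrix, "age_matrix"))
  leaves <- attr(matrix, "leaves")
  id <- vapply(leaves, function(l)
    paste(c(l[seq_len(min(2L, length(l)))], sprintf("n=%d", length(l))),
          collapse = "|"),
    character(1L))
  df <- data.frame(clade = id, n_leaves = lengths(leaves),
                   format(unclass(matrix), digits = 15L, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
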