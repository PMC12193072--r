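#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Grows a pure-birth tree forward in time until `n_taxa` lineages exist and
#' cuts it at the present, via [ape::rphylo()] with zero death rate. The
#' result is ultrametric with leaf labels `t1..tn` and is deterministic
#' under `seed`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate speciation rate per Myr (> 0); expected branch
#'   durations scale as 1/birth_rate.
#' @param seed integer seed; `NULL` uses (and advances) the global RNG.
#' @return a [dated_tree()].
#' @export
simulate_yule <- function(n_taxa, birth_rate, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  phy <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  phy$tip.label <- sprintf("t%d", seq_len(n_taxa))
  dated_tree(phy)
}

#' Perturb node ages with multiplicative lognormal noise and bias
#'
#' Emulates the age distortion a relaxed-clock model imposes: every internal
#' node age x becomes `bias * x * exp(e)` with `e ~ Normal(0, sigma^2)`.
#' Under `"iid_lognormal"` the errors are drawn independently per node, as
#' uncorrelated clock models distort ages; under
#' `"autocorrelated_lognormal"` the error evolves root-to-tips as a Brownian
#' walk (root error `Normal(0, sigma^2)`, each internal child adding an
#' independent `Normal(0, sigma^2)` increment), so parent and child errors
#' are positively correlated, as under autocorrelated clocks. Ages are then
#' made monotone top-down by capping each internal node at
#' `parent_age * (1 - 1e-9)`; leaves stay at 0 and the topology is
#' unchanged.
#'
#' With `sigma = 0` the operation is a pure rescaling by `bias`, for which
#' the comparison statistics have closed forms: two sources with biases b1,
#' b2 differ by `P% = 200 (b1 - b2) / (b1 + b2)` at every node.
#'
#' @param tree a [dated_tree()].
#' @param noise_model `"iid_lognormal"` or `"autocorrelated_lognormal"`.
#' @param sigma standard deviation of the log-age error (>= 0).
#' @param bias multiplicative age bias (> 0); 1 means unbiased.
#' @param seed integer seed; `NULL` uses the global RNG.
#' @return a [dated_tree()] with the same topology and perturbed ages.
#' @export
perturb_ages <- function(tree,
                         noise_model = c("iid_lognormal", "autocorrelated_lognormal"),
                         sigma, bias = 1, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  noise_model <- match.arg(noise_model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (bias <= 0) stop("bias must be positive")
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  e <- with_seed(seed, {
    if (noise_model == "iid_lognormal") {
      setNames(rnorm(nnode, 0, sigma), ntip + seq_len(nnode))
    } else {
      err <- numeric(ntip + nnode)
      err[root] <- rnorm(1L, 0, sigma)
      edge <- reorder(phy, "cladewise")$edge  # parents precede children
      for (i in seq_len(nrow(edge))) {
        child <- edge[i, 2L]
        if (child > ntip) err[child] <- err[edge[i, 1L]] + rnorm(1L, 0, sigma)
      }
      setNames(err[ntip + seq_len(nnode)], ntip + seq_len(nnode))
    }
  })
  age <- tree$age
  idx <- ntip + seq_len(nnode)
  age[idx] <- bias * age[idx] * exp(e[as.character(idx)])
  # enforce parent > child top-down (root first in cladewise edge order)
  edge <- reorder(phy, "cladewise")$edge
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2L]
    if (child > ntip) {
      cap <- age[edge[i, 1L]] * (1 - 1e-9)
      if (age[child] > cap) age[child] <- cap
    }
  }
  phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  dated_tree(phy, source_label = tree$source_label)
}

# One interchange move. Picks an internal non-root node v (not in `avoid`)
# and a sibling subtree s: if s is internal, a child of v and a child of s
# are exchanged (the clades of both v and s change); if s is a leaf, s is
# exchanged with a child of v (only v's clade changes). `only_single = TRUE`
# restricts to leaf-sibling moves. Returns NULL when no admissible move
# exists, else list(phy, affected).
nni_move <- function(phy, ntip, avoid, only_single = FALSE) {
  root <- ntip + 1L
  internal <- setdiff(ntip + seq_len(phy$Nnode), root)
  cand <- setdiff(internal, avoid)
  cand <- cand[sample.int(length(cand))]
  for (v in cand) {
    u <- phy_parent(phy, v)
    sibs <- setdiff(phy_children(phy, u), v)
    sibs <- setdiff(sibs, avoid)
    if (only_single) sibs <- sibs[sibs <= ntip]
    if (!length(sibs)) next
    s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
    kids_v <- phy_children(phy, v)
    cv <- if (length(kids_v) == 1L) kids_v else sample(kids_v, 1L)
    i_v <- which(phy$edge[, 1L] == v & phy$edge[, 2L] == cv)
    if (s > ntip) {
      kids_s <- phy_children(phy, s)
      cs <- if (length(kids_s) == 1L) kids_s else sample(kids_s, 1L)
      i_s <- which(phy$edge[, 1L] == s & phy$edge[, 2L] == cs)
      phy$edge[i_v, 2L] <- cs
      phy$edge[i_s, 2L] <- cv
      return(list(phy = phy, affected = c(v, s)))
    } else {
      i_u <- which(phy$edge[, 1L] == u & phy$edge[, 2L] == s)
      phy$edge[i_v, 2L] <- s
      phy$edge[i_u, 2L] <- cv
      return(list(phy = phy, affected = v))
    }
  }
  NULL
}

# redraw ages for nodes whose children changed: uniform between the oldest
# child and the parent
redraw_ages <- function(phy, age, nodes) {
  for (w in nodes) {
    lo <- max(age[phy_children(phy, w)])
    hi <- age[phy_parent(phy, w)]
    age[w] <- runif(1L, lo, hi)
  }
  age
}

rebuild_dated <- function(phy, age, source_label = NULL) {
  phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  phy <- reorder(phy, "cladewise")
  dated_tree(phy, source_label = source_label)
}

# Apply interchange moves until exactly n_broken clades differ from the
# original tree; retries seeded move sets until the count is exact.
rearrange_break <- function(tree, n_broken, seed = NULL, max_attempts = 200L) {
  if (n_broken == 0L) return(tree)
  orig_keys <- vapply(clade_leaf_sets(tree), clade_key, character(1L))
  ntip <- length(tree$phy$tip.label)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      phy <- tree$phy
      age <- tree$age
      affected <- integer()
      ok <- TRUE
      while (length(affected) < n_broken) {
        remaining <- n_broken - length(affected)
        mv <- nni_move(phy, ntip, avoid = affected,
                       only_single = remaining == 1L)
        if (is.null(mv) && remaining == 1L) mv <- NULL  # no single move left
        if (is.null(mv)) { ok <- FALSE; break }
        if (length(mv$affected) > remaining) { ok <- FALSE; break }
        phy <- mv$phy
        age <- redraw_ages(phy, age, mv$affected)
        affected <- c(affected, mv$affected)
      }
      if (!ok) next
      out <- rebuild_dated(phy, age, tree$source_label)
      new_keys <- vapply(clade_leaf_sets(out), clade_key, character(1L))
      if (length(setdiff(orig_keys, new_keys)) == n_broken &&
          setequal(setdiff(orig_keys, new_keys), orig_keys[affected - ntip])) {
        return(out)
      }
    }
    stop("could not rearrange exactly ", n_broken, " clades on this tree")
  })
}

#' Topologically rearrange a dated tree by interchange moves
#'
#' Performs `k` nearest-neighbor-interchange moves at randomly chosen
#' internal edges: each move exchanges a child subtree of an internal node
#' with a subtree on the other side of the edge (a child of its internal
#' sibling, or the leaf sibling itself). Exactly the one or two internal
#' clades flanking each chosen edge cease to be shared with the original
#' tree; ages of the affected nodes are redrawn uniformly between their
#' oldest child and their parent. Used to emulate panels whose chronogram
#' topologies disagree at a few nodes.
#'
#' @param tree a [dated_tree()].
#' @param k number of moves (>= 0); the tree needs at least `k + 2` internal
#'   nodes.
#' @param seed integer seed; `NULL` uses the global RNG.
#' @return a [dated_tree()]; `k = 0` returns the input unchanged.
#' @seealso [generate_panel()], whose `broken_clades` asks for an exact
#'   count of differing clades rather than a move count.
#' @export
rearrange_clades <- function(tree, k, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"), k >= 0)
  if (k == 0L) return(tree)
  if (tree$phy$Nnode < k + 2L)
    stop("k too large: tree has ", tree$phy$Nnode,
         " internal nodes but k + 2 = ", k + 2L, " are required")
  orig_keys <- vapply(clade_leaf_sets(tree), clade_key, character(1L))
  ntip <- length(tree$phy$tip.label)
  with_seed(seed, {
    for (attempt in seq_len(200L)) {
      phy <- tree$phy
      age <- tree$age
      affected <- integer()
      ok <- TRUE
      for (move in seq_len(k)) {
        mv <- nni_move(phy, ntip, avoid = affected)
        if (is.null(mv)) { ok <- FALSE; break }
        phy <- mv$phy
        age <- redraw_ages(phy, age, mv$affected)
        affected <- c(affected, mv$affected)
      }
      if (!ok) next
      out <- rebuild_dated(phy, age, tree$source_label)
      new_keys <- vapply(clade_leaf_sets(out), clade_key, character(1L))
      lost <- setdiff(orig_keys, new_keys)
      if (setequal(lost, orig_keys[affected - ntip])) return(out)
    }
    stop("could not realize ", k, " independent interchange moves on this tree")
  })
}

#' Configuration for a synthetic chronogram panel
#'
#' Describes a panel of chronograms derived from one Yule tree: each source
#' (a clock model / calibration set combination) perturbs the base tree's
#' ages with its own noise model, noise level, and multiplicative bias, and
#' designated sources may additionally disagree topologically at a known
#' number of clades. Because the biases are known, the expected values of
#' the D, P and P% statistics on the generated panel are known too, making
#' the whole comparison pipeline testable end to end.
#'
#' @param n_taxa leaves in the base tree (>= 3).
#' @param birth_rate Yule speciation rate per Myr.
#' @param sources a `data.frame` with columns `clock`, `calibration`,
#'   `noise_model` (`"iid_lognormal"`/`"autocorrelated_lognormal"`), `sigma`
#'   (>= 0) and `bias` (> 0); one row per chronogram. Source labels are
#'   `clock:calibration` and must be unique.
#' @param root_scale optional target root age in Myr; the base tree is
#'   rescaled so its root sits there.
#' @param broken_clades number of clades to rearrange in the designated
#'   sources (0 = all topologies identical).
#' @param broken_sources character vector of source labels whose topology is
#'   rearranged; required when `broken_clades > 0`.
#' @param seed integer master seed; all per-source streams derive from it.
#' @return a `synthetic_panel_config` list.
#' @export
synthetic_panel_config <- function(n_taxa, birth_rate, sources,
                                   root_scale = NULL, broken_clades = 0L,
                                   broken_sources = NULL, seed = 1L) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  need <- c("clock", "calibration", "noise_model", "sigma", "bias")
  if (!is.data.frame(sources) || !all(need %in% names(sources)))
    stop("`sources` must have columns ", paste(need, collapse = ", "))
  if (any(sources$sigma < 0)) stop("sigma must be >= 0")
  if (any(sources$bias <= 0)) stop("bias must be > 0")
  labels <- paste(sources$clock, sources$calibration, sep = ":")
  if (anyDuplicated(labels)) stop("clock:calibration pairs must be unique")
  if (broken_clades > 0L) {
    if (is.null(broken_sources)) stop("broken_sources required when broken_clades > 0")
    miss <- setdiff(broken_sources, labels)
    if (length(miss)) stop("unknown broken_sources: ", paste(miss, collapse = ", "))
  }
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 sources = sources, labels = labels,
                 root_scale = root_scale,
                 broken_clades = as.integer(broken_clades),
                 broken_sources = broken_sources, seed = as.integer(seed)),
            class = "synthetic_panel_config")
}

#' Generate a synthetic chronogram panel
#'
#' Simulates the base Yule tree, then derives one chronogram per configured
#' source: designated sources are topologically rearranged at exactly
#' `broken_clades` clades, and every source's ages are perturbed with its
#' own noise model, sigma, and bias. Each per-source random stream is
#' derived deterministically from the master seed, so identical
#' configurations reproduce identical panels byte for byte.
#'
#' @param config a [synthetic_panel_config()].
#' @return a named list of [dated_tree()] objects (names = source labels),
#'   with the unperturbed base tree in the `base_tree` attribute.
#' @examples
#' src <- data.frame(clock = c("A", "B"), calibration = c("C1", "C1"),
#'                   noise_model = "iid_lognormal", sigma = 0,
#'                   bias = c(1, 1.5))
#' panel <- generate_panel(synthetic_panel_config(20, 0.05, src, seed = 7))
#' pairwise_percent_difference(build_age_matrix(panel), "B:C1", "A:C1")
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  base <- simulate_yule(config$n_taxa, config$birth_rate,
                        seed = derive_seed(config$seed, 0L))
  if (!is.null(config$root_scale)) {
    phy <- base$phy
    phy$edge.length <- phy$edge.length * (config$root_scale / base$root_age)
    base <- dated_tree(phy)
  }
  out <- vector("list", nrow(config$sources))
  names(out) <- config$labels
  for (i in seq_along(out)) {
    t_i <- base
    if (config$broken_clades > 0L && config$labels[i] %in% config$broken_sources) {
      t_i <- rearrange_break(t_i, config$broken_clades,
                             seed = derive_seed(config$seed, 500000L + i))
    }
    t_i <- perturb_ages(t_i,
                        noise_model = config$sources$noise_model[i],
                        sigma = config$sources$sigma[i],
                        bias = config$sources$bias[i],
                        seed = derive_seed(config$seed, 1000000L + i))
    t_i$source_label <- config$labels[i]
    out[[i]] <- t_i
  }
  attr(out, "base_tree") <- base
  attr(out, "config") <- config
  out
}

#' Write a synthetic panel to disk
#'
#' One Newick file per source plus a manifest TSV (`source`, `clock`,
#' `calibration`, `file`, `noise_model`, `sigma`, `bias`, `seed`) that
#' [run_comparison()] can consume directly.
#'
#' @param panel result of [generate_panel()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  config <- attr(panel, "config")
  if (is.null(config)) stop("`panel` must come from generate_panel()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(panel))
  for (i in seq_along(panel)) {
    files[i] <- paste0(gsub("[^A-Za-z0-9_.-]", "_", names(panel)[i]), ".nwk")
    write_chronogram(panel[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    source = names(panel),
    clock = config$sources$clock, calibration = config$sources$calibration,
    file = files, noise_model = config$sources$noise_model,
    sigma = config$sources$sigma, bias = config$sources$bias,
    seed = config$seed, stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
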