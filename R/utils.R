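# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# random state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic stream derivation: one sub-seed per (seed, index) pair,
# always in [1, 2^31 - 2] so it is a valid 32-bit R seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629) + 1L
}

# children of a node in a phylo edge matrix
phy_children <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

# rbind a list of data.frames, dropping NULLs; `empty` is returned when
# nothing remains
rbind_rows <- function(rows, empty) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

phy_parent <- function(phy, node) {
  i <- which(phy$edge[, 2L] == node)
  if (!length(i)) NA_integer_ else phy$edge[i, 1L]
}
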