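#' Construct a calibration set
#'
#' A calibration set is a list of hard min/max age bounds on named nodes,
#' the form in which fossil constraints enter Bayesian dating as
#' hard-bounded priors. Bounds are closed intervals: an age exactly at the
#' minimum or maximum satisfies the constraint.
#'
#' @param label set identifier (e.g. `"C1"`).
#' @param constraints a `data.frame` with columns `node_no` (unique
#'   integer), `node_name`, `min_ma` and `max_ma` (Myr, `0 < min <= max`).
#' @return a `calibration_set` object.
#' @export
calibration_set <- function(label, constraints) {
  need <- c("node_no", "node_name", "min_ma", "max_ma")
  if (!is.data.frame(constraints) || !all(need %in% names(constraints)))
    stop("`constraints` must have columns ", paste(need, collapse = ", "))
  constraints <- constraints[need]
  if (anyDuplicated(constraints$node_no)) stop("node_no must be unique within a set")
  if (any(constraints$min_ma <= 0)) stop("minimum ages must be positive")
  if (any(constraints$min_ma > constraints$max_ma))
    stop("each minimum age must not exceed its maximum")
  structure(list(label = label, constraints = constraints),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("Calibration set %s: %d min/max node-age constraints (Myr)\n",
              x$label, nrow(x$constraints)))
  print(x$constraints, row.names = FALSE)
  invisible(x)
}

#' Built-in calibration sets for dating plastid evolution
#'
#' Loads the three bundled fossil calibration sets (C1, C2, C3), each with
#' 17 min/max node-age constraints spanning cyanobacterial events (Great
#' Oxidation Event, earliest cyanobacteria, Nostocales, ...) and algal/plant
#' fossils (earliest Rhodophyta, Ulvophyceae, land plants, angiosperms,
#' ...). C2 and C3 raise the Ulvophyceae minimum to 948 Myr; C3 further
#' raises the earliest-Rhodophyta minimum to 1560 Myr, reflecting the oldest
#' described multicellular red-alga macrofossil. The constraints are keyed
#' by node number; the leaf sets defining each calibrated node are user
#' configuration (see `mrca_map` in [check_calibrations()]), not hard-coded
#' taxonomy.
#'
#' @param file path to a calibration TSV (columns `node_no`, `node_name`,
#'   then `min_<label>`/`max_<label>` pairs). Defaults to the bundled table.
#' @return a named list of [calibration_set()] objects.
#' @examples
#' cal <- load_builtin_calibrations()
#' cal$C3$constraints[cal$C3$constraints$node_no == 6, ]
#' @export
load_builtin_calibrations <- function(file = system.file("extdata", "calibrations.tsv",
                                                         package = "chronocompare")) {
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  mins <- grep("^min_", names(tab), value = TRUE)
  labels <- sub("^min_", "", mins)
  if (!all(paste0("max_", labels) %in% names(tab)))
    stop("calibration table must pair every min_<set> with a max_<set> column")
  out <- lapply(labels, function(l) {
    calibration_set(l, data.frame(
      node_no = tab$node_no, node_name = tab$node_name,
      min_ma = tab[[paste0("min_", l)]], max_ma = tab[[paste0("max_", l)]],
      stringsAsFactors = FALSE))
  })
  names(out) <- labels
  out
}

#' Check a chronogram against a calibration set
#'
#' For each constraint that has an entry in `mrca_map`, finds the most
#' recent common ancestor of the mapped leaves in the tree and compares its
#' age against the closed interval `[min_ma, max_ma]`. If the mapped leaves
#' are not monophyletic in this tree, the MRCA clade (possibly spanning
#' extra taxa) is still used, with a warning — the same semantics dating
#' software applies to calibration taxa. Constraints absent from `mrca_map`
#' are skipped: the map is the user's taxonomic configuration.
#'
#' @param tree a [dated_tree()].
#' @param cal a [calibration_set()].
#' @param mrca_map a named list: names are `node_no` values (as characters),
#'   elements are character vectors of at least 2 leaf labels whose MRCA is
#'   the calibrated node.
#' @return a `data.frame` of violations with columns `node_no`, `node_name`,
#'   `age`, `min_ma`, `max_ma`, `violation` (`"below_min"`/`"above_max"`) and
#'   `amount` (Myr beyond the bound). Zero rows when the tree satisfies
#'   every checked bound.
#' @export
check_calibrations <- function(tree, cal, mrca_map) {
  stopifnot(inherits(tree, "dated_tree"), inherits(cal, "calibration_set"))
  if (!is.list(mrca_map) || is.null(names(mrca_map)))
    stop("`mrca_map` must be a named list of leaf-label vectors")
  cons <- cal$constraints
  rows <- list()
  for (k in seq_len(nrow(cons))) {
    key <- as.character(cons$node_no[k])
    if (!key %in% names(mrca_map)) next
    tips <- mrca_map[[key]]
    if (length(tips) < 2L)
      stop(sprintf("constraint %s ('%s'): mrca_map needs at least 2 leaves",
                   key, cons$node_name[k]))
    miss <- setdiff(tips, tree$phy$tip.label)
    if (length(miss))
      stop(sprintf("constraint %s ('%s'): leaves missing from tree: %s",
                   key, cons$node_name[k], paste(miss, collapse = ", ")))
    node <- ape::getMRCA(tree$phy, tips)
    desc <- ape::extract.clade(tree$phy, node)$tip.label
    if (length(desc) > length(tips) && !all(desc %in% tips))
      warning(sprintf(
        "constraint %s ('%s'): mapped leaves are not monophyletic; MRCA spans %d taxa",
        key, cons$node_name[k], length(desc)))
    age <- tree$age[node]
    if (age < cons$min_ma[k]) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_no = cons$node_no[k], node_name = cons$node_name[k], age = age,
        min_ma = cons$min_ma[k], max_ma = cons$max_ma[k],
        violation = "below_min", amount = cons$min_ma[k] - age,
        stringsAsFactors = FALSE)
    } else if (age > cons$max_ma[k]) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_no = cons$node_no[k], node_name = cons$node_name[k], age = age,
        min_ma = cons$min_ma[k], max_ma = cons$max_ma[k],
        violation = "above_max", amount = age - cons$max_ma[k],
        stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows, data.frame(node_no = integer(), node_name = character(),
                              age = numeric(), min_ma = numeric(),
                              max_ma = numeric(), violation = character(),
                              amount = numeric(), stringsAsFactors = FALSE))
}
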