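#' Read a chronogram panel from a manifest
#'
#' The manifest is a TSV with columns `source` (unique label, conventionally
#' `clock:calibration`), `clock`, `calibration`, and `file` (tree path,
#' relative to the manifest's directory unless absolute); an optional
#' `format` column selects `newick` (default) or `nexus` per file.
#'
#' @param manifest path to the manifest TSV.
#' @return a named list of [dated_tree()] objects with a `sources`
#'   attribute (the manifest `data.frame`).
#' @export
read_panel <- function(manifest) {
  tab <- read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("source", "clock", "calibration", "file")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$source)) stop("manifest source labels must be unique")
  if (is.null(tab$format)) tab$format <- "newick"
  base_dir <- dirname(manifest)
  trees <- lapply(seq_len(nrow(tab)), function(i) {
    path <- tab$file[i]
    if (!file.exists(path)) path <- file.path(base_dir, tab$file[i])
    if (!file.exists(path)) stop("tree file not found: ", tab$file[i])
    read_chronogram(path, format = tab$format[i], source_label = tab$source[i])
  })
  names(trees) <- tab$source
  attr(trees, "sources") <- tab
  trees
}

#' Run the full chronogram-comparison analysis
#'
#' Orchestrates the pipeline over a labeled panel: shared-clade matching
#' (recording the excluded clades per source), age-matrix assembly, the two
#' D groupings (per clock across its calibration sets, and per calibration
#' set across clocks), the pairwise P (Myr) and P% matrices, paired
#' Wilcoxon tests over all unordered source pairs with a single
#' Benjamini-Hochberg correction across that family, classical MDS of the
#' absolute pairwise dissimilarities, and (optionally) calibration-bound
#' checking of every source tree.
#'
#' @param panel a named list of [dated_tree()] objects (e.g. from
#'   [read_panel()] or [generate_panel()]), or a manifest path. Labels must
#'   parse as `clock:calibration` unless `clocks`/`calibrations` are given.
#' @param clocks,calibrations optional character vectors (same length as
#'   the panel) overriding the clock/calibration parsed from each label.
#' @param mds_stat dissimilarity fed to MDS: absolute `"P"` (Myr, default)
#'   or absolute `"Ppct"` (%).
#' @param mds_dims embedding dimensions.
#' @param calibrations_set optional [calibration_set()] (or named list of
#'   them keyed by calibration label) to check each tree against.
#' @param mrca_map the `node_no` to leaf-set map for
#'   [check_calibrations()]; required with `calibrations_set`.
#' @return a `comparison_report`: list with `age_matrix`,
#'   `excluded_clades`, `n_nodes`, `D_by_clock` and `D_by_calibration`
#'   (clocks x calibration-set matrices of D values; the by-clock grouping
#'   sums to zero along rows, the by-calibration one along columns),
#'   `P_signed`, `P_abs`, `Ppct_signed`, `Ppct_abs` (pairwise matrices),
#'   `tests` (data.frame with raw and BH-adjusted p-values), `mds`, and
#'   `calibration_violations`.
#' @export
run_comparison <- function(panel, clocks = NULL, calibrations = NULL,
                           mds_stat = c("P", "Ppct"), mds_dims = 2L,
                           calibrations_set = NULL, mrca_map = NULL) {
  mds_stat <- match.arg(mds_stat)
  if (is.character(panel) && length(panel) == 1L) panel <- read_panel(panel)
  labels <- panel_labels(panel)
  names(panel) <- labels
  if (length(panel) < 2L) stop("need at least 2 sources")
  if (is.null(clocks) || is.null(calibrations)) {
    parts <- strsplit(labels, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("labels must be 'clock:calibration' (offending: ",
           paste(labels[bad], collapse = ", "),
           "); or supply `clocks` and `calibrations`")
    if (is.null(clocks)) clocks <- vapply(parts, `[`, character(1L), 1L)
    if (is.null(calibrations)) calibrations <- vapply(parts, `[`, character(1L), 2L)
  }
  excluded <- excluded_clades(panel)
  mat <- build_age_matrix(panel)
  message(sprintf("using %d nodes shared by all %d sources (%d clade exclusion records)",
                  nrow(mat), ncol(mat), nrow(excluded)))

  D_by_clock <- d_grouping(mat, labels, split_by = clocks, cells = calibrations,
                           what = "clock")
  D_by_cal <- d_grouping(mat, labels, split_by = calibrations, cells = clocks,
                         what = "calibration set", transpose = TRUE)

  P_signed <- pairwise_matrix(mat, "P", signed = TRUE)
  P_abs <- pairwise_matrix(mat, "P", signed = FALSE)
  Ppct_signed <- pairwise_matrix(mat, "Ppct", signed = TRUE)
  Ppct_abs <- pairwise_matrix(mat, "Ppct", signed = FALSE)

  pairs <- which(upper.tri(matrix(0, length(labels), length(labels))), arr.ind = TRUE)
  tests <- data.frame(
    source_x = labels[pairs[, 1L]], source_y = labels[pairs[, 2L]],
    statistic = NA_real_, n = NA_integer_, p_raw = NA_real_,
    degenerate = NA, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    wt <- paired_wilcoxon(mat[, pairs[k, 1L]], mat[, pairs[k, 2L]])
    tests$statistic[k] <- wt$statistic
    tests$n[k] <- wt$n
    tests$p_raw[k] <- wt$p_raw
    tests$degenerate[k] <- wt$degenerate
  }
  tests$p_adjusted <- bh_adjust(tests$p_raw)

  mds_in <- if (mds_stat == "P") P_abs else Ppct_abs
  mds <- mds_embed(mds_in, dims = mds_dims)

  violations <- NULL
  if (!is.null(calibrations_set)) {
    if (is.null(mrca_map)) stop("`mrca_map` is required with `calibrations_set`")
    violations <- lapply(seq_along(panel), function(i) {
      cs <- if (inherits(calibrations_set, "calibration_set")) calibrations_set
            else calibrations_set[[calibrations[i]]]
      if (is.null(cs)) return(NULL)
      v <- check_calibrations(panel[[i]], cs, mrca_map)
      if (nrow(v)) cbind(source = labels[i], v, stringsAsFactors = FALSE) else NULL
    })
    violations <- rbind_rows(
      violations,
      data.frame(source = character(), node_no = integer(),
                 node_name = character(), age = numeric(),
                 min_ma = numeric(), max_ma = numeric(),
                 violation = character(), amount = numeric(),
                 stringsAsFactors = FALSE))
  }

  structure(list(age_matrix = mat, excluded_clades = excluded,
                 n_nodes = nrow(mat), sources = labels,
                 clocks = clocks, calibrations = calibrations,
                 D_by_clock = D_by_clock, D_by_calibration = D_by_cal,
                 P_signed = P_signed, P_abs = P_abs,
                 Ppct_signed = Ppct_signed, Ppct_abs = Ppct_abs,
                 tests = tests, mds = mds, mds_stat = mds_stat,
                 calibration_violations = violations),
            class = "comparison_report")
}

# D grouped by one factor, laid out as a clocks x calibration-sets matrix.
# split_by = clocks: each row is one clock's D across its calibration sets
# (row sums ~ 0). split_by = calibrations (transpose = TRUE): each column is
# one calibration set's D across clocks (column sums ~ 0).
d_grouping <- function(mat, labels, split_by, cells, what, transpose = FALSE) {
  rows <- unique(if (transpose) cells else split_by)
  cols <- unique(if (transpose) split_by else cells)
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = if (transpose) list(rows, cols) else list(rows, cols))
  for (g in unique(split_by)) {
    members <- labels[split_by == g]
    if (length(members) < 2L) {
      warning("grouping by ", what, " '", g,
              "' has fewer than 2 sources; skipped")
      next
    }
    dt <- deviation_from_group_mean(mat, members)
    for (s in members) {
      i <- if (transpose) cells[labels == s] else g
      j <- if (transpose) g else cells[labels == s]
      out[i, j] <- dt$D[s]
    }
  }
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Chronogram comparison over %d shared nodes, %d sources\n",
              x$n_nodes, length(x$sources)))
  if (nrow(x$excluded_clades))
    cat(sprintf("Excluded (not shared) clade records: %d\n", nrow(x$excluded_clades)))
  cat("\nD by clock (rows sum to 0; %):\n"); print(round(x$D_by_clock, 2))
  cat("\nD by calibration set (columns sum to 0; %):\n"); print(round(x$D_by_calibration, 2))
  cat("\nLargest |P| (Myr):", round(max(abs(x$P_signed)), 1),
      " Largest |P%|:", round(max(abs(x$Ppct_signed)), 1), "\n")
  sig <- sum(x$tests$p_adjusted < 0.05 & !x$tests$degenerate)
  cat(sprintf("Paired Wilcoxon: %d of %d source pairs significant after BH at 0.05\n",
              sig, nrow(x$tests)))
  invisible(x)
}

#' Export a comparison report
#'
#' Writes the report as TSV tables plus one JSON summary: `age_matrix.tsv`,
#' `D_table.tsv` (both groupings side by side, percentages at 2 decimals),
#' `P_matrix.tsv` and `Ppct_matrix.tsv` (signed), `tests.tsv`, `mds.tsv`,
#' `violations.tsv` (header only when no check was run or nothing was
#' violated), and `summary.json`, which holds every statistic at full
#' precision so that [read_report_summary()] round-trips the numbers
#' losslessly.
#'
#' @param report a `comparison_report` from [run_comparison()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_age_matrix(report$age_matrix, file.path(dir, "age_matrix.tsv"))

  dA <- as.data.frame(round(report$D_by_clock, 2))
  dB <- as.data.frame(round(report$D_by_calibration, 2))
  names(dA) <- paste0("byclock_", names(dA))
  names(dB) <- paste0("bycal_", names(dB))
  dtab <- cbind(clock = rownames(report$D_by_clock), dA, dB)
  write.table(dtab, file.path(dir, "D_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  write_square <- function(m, file, digits = NULL) {
    v <- unclass(m)
    if (!is.null(digits)) v <- round(v, digits)
    df <- data.frame(source = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_square(report$P_signed, file.path(dir, "P_matrix.tsv"), 2)
  write_square(report$Ppct_signed, file.path(dir, "Ppct_matrix.tsv"), 2)

  write.table(report$tests, file.path(dir, "tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mds_df <- data.frame(source = report$mds$sources, report$mds$coordinates,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mds_df, file.path(dir, "mds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  viol <- report$calibration_violations
  if (is.null(viol))
    viol <- data.frame(source = character(), node_no = integer(),
                       node_name = character(), age = numeric(),
                       min_ma = numeric(), max_ma = numeric(),
                       violation = character(), amount = numeric())
  write.table(viol, file.path(dir, "violations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  summary <- list(
    n_nodes = report$n_nodes, sources = report$sources,
    clocks = report$clocks, calibrations = report$calibrations,
    excluded_clades = report$excluded_clades,
    D_by_clock = mat_to_list(report$D_by_clock),
    D_by_calibration = mat_to_list(report$D_by_calibration),
    P_signed = mat_to_list(report$P_signed),
    Ppct_signed = mat_to_list(report$Ppct_signed),
    tests = report$tests,
    mds_stat = report$mds_stat,
    mds_coordinates = mat_to_list(report$mds$coordinates),
    mds_eigenvalues = report$mds$eigenvalues,
    versions = list(chronocompare = as.character(utils::packageVersion("chronocompare")),
                    R = R.version.string))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE, na = "null")
  invisible(dir)
}

mat_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = unclass(unname(m)))
}

#' Re-read the full-precision summary of an exported report
#'
#' @param dir directory written by [export_report()].
#' @return the parsed `summary.json`, with the matrix entries restored as
#'   numeric matrices with dimnames.
#' @export
read_report_summary <- function(dir) {
  s <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  restore <- function(x) {
    m <- x$values
    if (is.null(dim(m))) m <- matrix(m, nrow = length(x$rows))
    dimnames(m) <- list(x$rows, x$cols)
    m
  }
  for (f in c("D_by_clock", "D_by_calibration", "P_signed", "Ppct_signed",
              "mds_coordinates")) {
    s[[f]] <- restore(s[[f]])
  }
  s
}
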