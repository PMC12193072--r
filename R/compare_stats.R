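#' Signed percentage deviation from the group-mean node age (D)
#'
#' For a group of sources (columns of the age matrix), computes for each
#' source s the statistic
#' \deqn{D(s) = \frac{1}{n}\sum_{i=1}^{n} 100\,\frac{x_i(s) - \bar x_i}{\bar x_i},}
#' where \eqn{x_i(s)} is the age of node i in source s, \eqn{\bar x_i} is
#' the mean age of node i across the group, and n is the number of shared
#' nodes. D is signed: positive values mean the source dates nodes older
#' than the group mean on average. Because the per-node deviations sum to
#' zero across the group, so do the D values (to floating-point accuracy) —
#' a useful internal consistency check on any reported table.
#'
#' The group is a parameter because two groupings are equally natural: the
#' calibration sets of one clock model (impact of calibrations given the
#' clock) or the clock models under one calibration set (impact of clocks
#' given the calibrations). The group mean is always recomputed over the
#' chosen group, never over the full panel.
#'
#' @param matrix an `age_matrix` from [build_age_matrix()] (or any positive
#'   numeric matrix with column names).
#' @param group character vector of at least two source labels; default all
#'   columns.
#' @return a `deviation_table`: a list with `D` (named numeric vector, %),
#'   `group`, and `n_nodes`.
#' @export
deviation_from_group_mean <- function(matrix, group = colnames(matrix)) {
  m <- as_age_mat(matrix)
  if (length(group) < 2L) stop("group must contain at least 2 sources")
  miss <- setdiff(group, colnames(m))
  if (length(miss)) stop("unknown source(s): ", paste(miss, collapse = ", "))
  sub <- m[, group, drop = FALSE]
  xbar <- rowMeans(sub)
  if (any(xbar == 0)) stop("group-mean node age of 0 encountered")
  dev <- 100 * sweep(sub, 1L, xbar, "-") / xbar
  structure(list(D = colMeans(dev), group = group, n_nodes = nrow(sub)),
            class = "deviation_table")
}

#' @export
print.deviation_table <- function(x, ...) {
  cat(sprintf("D over %d nodes (%% deviation from group-mean age):\n", x$n_nodes))
  print(round(x$D, 2))
  invisible(x)
}

as_age_mat <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || !is.numeric(m)) stop("`matrix` must be a numeric matrix")
  if (is.null(colnames(m))) stop("`matrix` must have source labels as column names")
  if (any(m <= 0)) stop("all node ages must be positive")
  m
}

pick_cols <- function(m, x, y) {
  miss <- setdiff(c(x, y), colnames(m))
  if (length(miss)) stop("unknown source(s): ", paste(miss, collapse = ", "))
  if (identical(x, y)) stop("x and y must name different sources")
  list(x = m[, x], y = m[, y])
}

#' Mean pairwise node-age difference between two sources (P, Myr)
#'
#' \deqn{P(x,y) = \frac{1}{n}\sum_{i=1}^n (x_i - y_i)} in the signed form;
#' the absolute form averages \eqn{|x_i - y_i|}. Signed P is antisymmetric
#' in its arguments and its magnitude is bounded by absolute P.
#'
#' @param matrix an age matrix.
#' @param x,y source labels (columns).
#' @param signed average signed differences (default) or absolute ones.
#' @return a single value in Myr.
#' @export
pairwise_mean_difference <- function(matrix, x, y, signed = TRUE) {
  m <- as_age_mat(matrix)
  cols <- pick_cols(m, x, y)
  d <- cols$x - cols$y
  if (!signed) d <- abs(d)
  mean(d)
}

#' Mean pairwise percentage node-age difference between two sources (P%)
#'
#' Per node, the difference is scaled by the mean of the two ages:
#' \deqn{P\%(x,y) = \frac{1}{n}\sum_{i=1}^n 100\,
#'   \frac{x_i - y_i}{0.5\,(x_i + y_i)}.}
#' This symmetric normalization bounds each per-node term in (-200, 200)
#' for positive ages; a pure scale factor b between the sources gives
#' exactly 200(b-1)/(b+1) per node.
#'
#' @inheritParams pairwise_mean_difference
#' @return a single value in percent.
#' @export
pairwise_percent_difference <- function(matrix, x, y, signed = TRUE) {
  m <- as_age_mat(matrix)
  cols <- pick_cols(m, x, y)
  d <- cols$x - cols$y
  if (!signed) d <- abs(d)
  mean(100 * d / (0.5 * (cols$x + cols$y)))
}

#' All-pairs matrix of P or P% statistics
#'
#' @param matrix an age matrix with at least two sources.
#' @param statistic `"P"` (mean age difference, Myr) or `"Ppct"` (mean
#'   percentage difference, %).
#' @param signed signed (antisymmetric) or absolute (symmetric, >= 0) form.
#' @return a `pairwise_matrix`: a square numeric matrix over the sources
#'   with zero diagonal and attributes `statistic` and `units`.
#' @export
pairwise_matrix <- function(matrix, statistic = c("P", "Ppct"), signed = TRUE) {
  statistic <- match.arg(statistic)
  m <- as_age_mat(matrix)
  src <- colnames(m)
  if (length(src) < 2L) stop("need at least 2 sources")
  f <- if (statistic == "P") pairwise_mean_difference else pairwise_percent_difference
  out <- matrix(0, length(src), length(src), dimnames = list(src, src))
  for (i in seq_along(src)) {
    for (j in seq_along(src)) {
      if (i != j) out[i, j] <- f(m, src[i], src[j], signed = signed)
    }
  }
  structure(out, class = c("pairwise_matrix", "matrix", "array"),
            statistic = paste0(statistic, if (signed) "_signed" else "_abs"),
            units = if (statistic == "P") "Myr" else "%")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("Pairwise %s matrix (%s), %d sources:\n",
              attr(x, "statistic"), attr(x, "units"), ncol(x)))
  print(round(unclass(x), 2))
  invisible(x)
}
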