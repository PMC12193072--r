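#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of a location shift between paired node-age vectors. Zero
#' differences are dropped (Wilcoxon's original prescription) and tied
#' absolute differences receive mid-ranks. With 25 or fewer non-zero
#' differences the p-value comes from the exact null distribution of the
#' positive-rank sum W — computed by dynamic programming over the observed
#' (possibly tied) rank multiset, so it remains exact under ties, which
#' [stats::wilcox.test()] does not offer. Above 25 the normal approximation
#' with tie-corrected variance and continuity correction is used. The
#' two-sided p is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param x,y numeric vectors of equal length, paired by node.
#' @return a `wilcoxon_result`: list with `statistic` (W, the positive-rank
#'   sum), `n` (non-zero differences used), `p_raw`, `exact` (logical), and
#'   `degenerate` (`TRUE` when all differences are zero, in which case
#'   `p_raw` is 1).
#' @examples
#' paired_wilcoxon(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # p = 0.0625
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, n = 0L, p_raw = 1,
                          exact = TRUE, degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of W over the 2^n equiprobable sign assignments.
    # Mid-ranks are multiples of 1/2, so work on doubled ranks (integers).
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[k+1] = #assignments with doubled sum k
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction toward the mean
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = w, n = n, p_raw = p, exact = exact,
                 degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank: W = %g, n = %d, p = %.4g%s%s\n",
              x$statistic, x$n, x$p_raw,
              if (x$exact) " (exact)" else " (normal approx.)",
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a family of p-values; a thin,
#' validating wrapper around [stats::p.adjust()] that preserves input order.
#'
#' @param p numeric vector of raw p-values, each in \[0, 1\].
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric non-negative dissimilarity matrix into `dims`
#' dimensions by double-centering the squared dissimilarities and taking the
#' top eigenpairs of the resulting Gram matrix — the metric MDS that R's
#' [stats::cmdscale()] implements, which this function uses. Negative
#' eigenvalues (non-Euclidean input) are truncated and reported in the
#' returned spectrum. Coordinates are centered on the origin.
#'
#' @param d a square symmetric matrix with zero diagonal and non-negative
#'   entries — e.g. an absolute [pairwise_matrix()] of P (Myr) or P% —
#'   with source labels as dimnames.
#' @param dims number of embedding dimensions (default 2).
#' @return an `mds_embedding`: list with `coordinates` (sources x dims
#'   matrix; columns zero-padded when fewer than `dims` positive eigenvalues
#'   exist), `eigenvalues` (full spectrum, descending), and `sources`.
#' @export
mds_embed <- function(d, dims = 2L) {
  m <- unclass(d)
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop("`d` must be a square numeric matrix")
  if (dims < 1L) stop("`dims` must be >= 1")
  if (any(m < 0)) stop("dissimilarities must be non-negative")
  if (any(abs(diag(m)) > 0)) stop("diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-8 * (1 + max(abs(m)))))
    stop("`d` must be symmetric (use an absolute, not signed, statistic)")
  m <- (m + t(m)) / 2
  src <- rownames(m)
  if (is.null(src)) src <- sprintf("source_%d", seq_len(nrow(m)))
  dims <- min(as.integer(dims), nrow(m) - 1L)
  fit <- cmdscale(m, k = dims, eig = TRUE)
  coords <- matrix(0, nrow(m), dims,
                   dimnames = list(src, sprintf("dim%d", seq_len(dims))))
  if (!is.null(fit$points) && ncol(fit$points) > 0L) {
    coords[, seq_len(ncol(fit$points))] <- fit$points
  }
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 sources = src),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  neg <- sum(x$eigenvalues < -1e-9 * max(abs(x$eigenvalues)))
  cat(sprintf("Classical MDS embedding: %d sources in %d dimensions (%d negative eigenvalue%s truncated)\n",
              length(x$sources), ncol(x$coordinates), neg, if (neg == 1) "" else "s"))
  print(round(x$coordinates, 4))
  invisible(x)
}
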