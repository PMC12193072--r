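# shared fixtures and independent oracles, built in code

quartet <- function() read_chronogram("((A:1,B:1):2,(C:2,D:2):1);")

# a small panel config: `biases` per source, one clock per source unless
# clocks/cals given
panel_config <- function(n_taxa, biases, sigma = 0, seed = 1,
                         noise_model = "iid_lognormal",
                         clocks = sprintf("CL%d", seq_along(biases)),
                         cals = rep("C1", length(biases)), ...) {
  synthetic_panel_config(
    n_taxa = n_taxa, birth_rate = 0.05,
    sources = data.frame(clock = clocks, calibration = cals,
                         noise_model = noise_model, sigma = sigma,
                         bias = biases, stringsAsFactors = FALSE),
    seed = seed, ...)
}

# independent Wilcoxon oracle: full enumeration of the 2^n sign patterns,
# mid-ranked ties, zeros dropped, two-sided p = 2 * min tail
enum_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12), mean(w_all >= w_obs - 1e-12)))
}

# orthogonal Procrustes RMSD: optimal translation + rotation/reflection of
# `b` onto `a` (closed form via SVD); independent of any package code
procrustes_rmsd <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  rot <- s$v %*% t(s$u)
  sqrt(mean((a - b %*% rot)^2))
}

# random positive age matrix with labeled sources
random_age_matrix <- function(n_nodes, sources, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_nodes * length(sources), log(500), 0.6)),
              n_nodes, length(sources),
              dimnames = list(NULL, sources))
  m
}
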