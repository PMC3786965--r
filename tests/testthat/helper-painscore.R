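# Shared fixtures and independent oracles, built in code.

# Minimal valid animal table covering the six design cells.
make_animals <- function(n_per_cell = 1, cells = design_cells()) {
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  tibble::tibble(
    animal_id = sprintf("%s_%s_%02d", cells$strain[idx], cells$group[idx],
                        rep(seq_len(n_per_cell), times = nrow(cells))),
    strain = cells$strain[idx],
    surgery = cells$surgery[idx],
    drug = cells$drug[idx]
  )
}

# Random valid ethogram (integer counts, optional coupled durations).
random_ethogram <- function(n_per_cell = 2, n_behav = 4, seed = 1,
                            durations = FALSE) {
  set.seed(seed)
  animals <- make_animals(n_per_cell)
  behaviours <- paste0("B", seq_len(n_behav))
  freq <- matrix(rpois(nrow(animals) * n_behav, 5), nrow(animals), n_behav,
                 dimnames = list(animals$animal_id, behaviours))
  dur <- NULL
  if (durations) {
    dur <- matrix(round(rgamma(length(freq), 2, 0.5), 4), nrow(freq),
                  ncol(freq), dimnames = dimnames(freq))
    dur[freq == 0] <- 0
  }
  ethogram(animals, freq, dur = dur)
}

# Independent brute-force canonical discriminant oracle: forms the
# between/within scatter matrices directly and solves eigen(W^-1 B).
# Deliberately naive (dense solve, no whitening) so it shares no code path
# with the implementation under test.
brute_cda <- function(X, g) {
  g <- factor(g)
  grand <- colMeans(X)
  levs <- levels(g)
  p <- ncol(X)
  B <- matrix(0, p, p)
  W <- matrix(0, p, p)
  for (l in levs) {
    Xi <- X[g == l, , drop = FALSE]
    mi <- colMeans(Xi)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
    W <- W + crossprod(sweep(Xi, 2, mi))
  }
  ev <- eigen(solve(W) %*% B)
  ord <- order(Re(ev$values), decreasing = TRUE)
  n_fun <- min(length(levs) - 1, p)
  lambda <- Re(ev$values)[ord][seq_len(n_fun)]
  A <- Re(ev$vectors)[, ord, drop = FALSE][, seq_len(n_fun), drop = FALSE]
  # normalise to unit pooled within-group variance of scores
  n <- nrow(X)
  k <- length(levs)
  for (j in seq_len(n_fun)) {
    s <- drop(crossprod(A[, j], (W / (n - k)) %*% A[, j]))
    A[, j] <- A[, j] / sqrt(s)
  }
  scores <- sweep(X, 2, grand) %*% A
  wilks <- vapply(seq_len(n_fun),
                  function(f) prod(1 / (1 + lambda[f:n_fun])), numeric(1))
  list(eigenvalues = lambda, scores = scores, wilks = wilks, W = W, B = B)
}

# Random well-conditioned multi-group gaussian dataset for oracle checks.
random_gaussian_groups <- function(k, p, n_per_group, seed) {
  set.seed(seed)
  X <- matrix(rnorm(k * n_per_group * p), k * n_per_group, p)
  g <- rep(paste0("g", seq_len(k)), each = n_per_group)
  # inject group mean shifts on a random subset of variables
  shifts <- matrix(rnorm(k * p, sd = 1.2), k, p)
  X <- X + shifts[match(g, unique(g)), ]
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, g = g)
}

expect_matching_scores <- function(s1, s2, tol = 1e-6) {
  stopifnot(ncol(s1) == ncol(s2))
  for (j in seq_len(ncol(s1))) {
    d_same <- max(abs(s1[, j] - s2[, j]))
    d_flip <- max(abs(s1[, j] + s2[, j]))
    testthat::expect_lt(min(d_same, d_flip), tol)
  }
}
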