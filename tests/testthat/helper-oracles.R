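# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops; deliberately share no code with the
# package internals.

oracle_membership <- function(x) {
  u <- x
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    for (i in seq_len(nrow(x))) {
      u[i, j] <- (x[i, j] - lo) / (hi - lo)
    }
  }
  u
}

oracle_weights <- function(p) {
  w <- numeric(length(p))
  for (i in seq_along(p)) w[i] <- p[i] / sum(p)
  w
}

oracle_d_unweighted <- function(u) {
  d <- numeric(nrow(u))
  for (i in seq_len(nrow(u))) d[i] <- sum(u[i, ]) / ncol(u)
  d
}

oracle_d_weighted <- function(u, w) {
  d <- numeric(nrow(u))
  for (i in seq_len(nrow(u))) {
    for (j in seq_len(ncol(u))) d[i] <- d[i] + w[j] * u[i, j]
  }
  d
}

# best split of sorted 1-D values into k contiguous groups by total
# within-group sum of squared deviations, found by exhaustive search
oracle_best_contiguous_partition <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- function(v) sum((v - mean(v))^2)
  best <- NULL; best_cost <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (c_i in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, c_i], n)
    cost <- 0
    lab <- integer(n)
    for (g in seq_len(k)) {
      idx <- (bounds[g] + 1):bounds[g + 1]
      cost <- cost + wss(xs[idx])
      lab[idx] <- g
    }
    if (cost < best_cost) {
      best_cost <- cost
      best <- integer(n)
      best[ord] <- lab
    }
  }
  best
}

# two-sided permutation p-value for the Pearson correlation
oracle_permutation_p <- function(x, y, n_perm = 200000, seed = 7) {
  set.seed(seed)
  r_obs <- abs(cor(x, y))
  hits <- 0L
  Y <- replicate(n_perm, sample(y))
  r_perm <- abs(as.vector(cor(x, Y)))
  mean(r_perm >= r_obs - 1e-12)
}

# partitions agree up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

table1_d <- function() {
  fx <- load_fixture("table1_strain_D")
  stats::setNames(fx$D, fx$strain)
}
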