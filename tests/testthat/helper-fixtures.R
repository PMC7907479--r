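# Deterministic random fixtures, built in code at test time.

# Random strictly positive contingency table with unit sum.
random_contingency <- function(n, seed, N_pairs = 100L) {
  set.seed(seed)
  M <- matrix(rexp(n * n), n, n)
  M <- M / sum(M)
  structure(M, class = c("contingency_table", "matrix"),
            N_pairs = as.integer(N_pairs), n = as.integer(n))
}

# Random column-stochastic transition matrix.
random_transition <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rexp(n * n), n, n)
  sweep(M, 2, colSums(M), "/")
}

# Pair sample drawn from a transition matrix with uniform initial states.
sample_from_transition <- function(Lambda, N, seed) {
  set.seed(seed)
  n <- ncol(Lambda)
  i <- sample.int(n, N, replace = TRUE)
  cum <- apply(Lambda, 2, cumsum)
  u <- runif(N)
  j <- vapply(seq_len(N), function(t) {
    findInterval(u[t], cum[, i[t]]) + 1L
  }, integer(1))
  j[j > n] <- n
  pair_sample(i, j, n)
}

# Relabel the categories of a pair sample by a permutation.
permute_sample <- function(sample, perm) {
  pair_sample(perm[sample$i], perm[sample$j], sample$n)
}
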