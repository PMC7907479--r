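# Direct Bayesian model reduction of an empirical transition law.
#
# The empirical law Lambda (column-stochastic, final x initial) is factorized
# as Lambda_K = lambda_K gamma_K through K latent states: gamma_K is a hard
# (0/1) affiliation of the n observed categories to the K states, and
# lambda_K holds the K outgoing (emission) distributions. For a fixed
# affiliation the optimal lambda has a closed form: the count-weighted
# average of the empirical conditional columns assigned to each state.

# Closed-form emissions for an affiliation vector g (length n, values 1..K).
# States whose member columns carry zero mass get a uniform column so the
# matrix stays stochastic; such states never contribute to the entropy.
lambda_for_affiliation <- function(C, g, K) {
  n <- ncol(C)
  mass <- colSums(C)
  lam <- matrix(0, n, K)
  for (k in seq_len(K)) {
    cols <- which(g == k)
    mk <- sum(mass[cols])
    lam[, k] <- if (mk > 0) rowSums(C[, cols, drop = FALSE]) / mk else rep(1 / n, n)
  }
  lam
}

# Cross-entropy functional S = -sum_ij C[j,i] log lambda[j, g[i]].
affiliation_entropy <- function(C, g, lam) {
  cross_entropy_sum(C, lam[, g, drop = FALSE])
}

new_reduced_model <- function(C, g, K, capped = FALSE) {
  n <- ncol(C)
  lam <- lambda_for_affiliation(C, g, K)
  gamma <- matrix(0, K, n)
  gamma[cbind(g, seq_len(n))] <- 1
  structure(
    list(
      K = as.integer(K),
      gamma = gamma,
      lambda = lam,
      S = affiliation_entropy(C, g, lam),
      V = (n - 1L) * K + n * (K - 1L),
      n = n,
      affiliation = g,
      capped = capped
    ),
    class = "reduced_model"
  )
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model> K =", x$K, "of n =", x$n,
      "| S =", format(x$S, digits = 6),
      "| V =", x$V, if (x$capped) "(capped)" else "", "\n")
  invisible(x)
}

# One alternating-reassignment descent from a starting affiliation: each
# category column in turn is moved to the latent state that minimizes the
# resulting cross-entropy (emissions re-derived per candidate move, ties ->
# lowest state index), never emptying a state, until a full sweep makes no
# move. S is nonincreasing across moves, so the descent terminates.
descend_affiliation <- function(C, g, K, max_sweeps = 100L) {
  n <- ncol(C)
  S_cur <- affiliation_entropy(C, g, lambda_for_affiliation(C, g, K))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      k0 <- g[i]
      if (sum(g == k0) == 1L) next
      for (k in seq_len(K)) {
        if (k == k0) next
        g2 <- g
        g2[i] <- k
        S2 <- affiliation_entropy(C, g2, lambda_for_affiliation(C, g2, K))
        if (S2 < S_cur - 1e-15) {
          g <- g2
          S_cur <- S2
          changed <- TRUE
        }
      }
    }
    if (!changed) {
      # escape single-move local minima: exchange the states of a column
      # pair, then resume sweeping if that helped
      for (i in seq_len(n - 1L)) {
        for (i2 in (i + 1L):n) {
          if (g[i] == g[i2]) next
          g2 <- g
          g2[c(i, i2)] <- g[c(i2, i)]
          S2 <- affiliation_entropy(C, g2, lambda_for_affiliation(C, g2, K))
          if (S2 < S_cur - 1e-15) {
            g <- g2
            S_cur <- S2
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  list(g = g, S = S_cur)
}

# Starting points: one contiguous-blocks split (categories are ordered
# intensities) plus seeded random affiliations covering all K states.
initial_affiliations <- function(n, K, restarts) {
  inits <- list(as.integer(cut(seq_len(n), K)))
  extra <- max(0L, restarts - 1L)
  if (extra > 0L) {
    rand <- with_local_seed(8191L + n * 131L + K, {
      lapply(seq_len(extra), function(r) {
        g <- c(sample.int(K), sample.int(K, n - K, replace = TRUE))
        g[sample.int(n)]
      })
    })
    inits <- c(inits, rand)
  }
  inits
}

#' Fit a reduced latent-Markov model of dimension K
#'
#' Factorizes the empirical transition law encoded by a contingency table
#' into `K` latent states by direct Bayesian model reduction: a hard
#' assignment of the `n` observed categories to `K` states, with each
#' state's emission column the count-weighted average of the empirical
#' conditional columns it absorbs. The assignment minimizing the
#' cross-entropy `S` is searched by alternating reassignment sweeps from
#' several starting points (one contiguous-blocks split plus seeded random
#' starts); the search is deterministic and does not touch the caller's
#' RNG stream.
#'
#' When `K` exceeds the number of categories observed as initial states, no
#' assignment can keep all states distinct and nonempty; the model for the
#' largest attainable dimension is returned with `capped = TRUE`.
#'
#' @param C A [contingency()] table.
#' @param K Candidate latent dimension, `1 <= K <= n`.
#' @param restarts Number of search starts (default 10).
#' @return An object of class `reduced_model` with fields `K`, `gamma`
#'   (K-by-n 0/1 affiliation matrix, columns sum to one), `lambda` (n-by-K
#'   column-stochastic emissions), `S` (cross-entropy, nats), `V`
#'   (effective parameter count `(n-1)K + n(K-1)`), and `capped`.
#' @seealso [exhaustive_reduced_model()] for the global optimum by full
#'   set-partition enumeration (small `n` only).
#' @export
fit_reduced_model <- function(C, K, restarts = 10L) {
  n <- ncol(C)
  K <- as.integer(K)
  if (K < 1L || K > n) abort("`K` must lie in 1..n.")
  K_cap <- sum(colSums(C) > 0)
  capped <- K > K_cap
  K_use <- if (capped) K_cap else K

  if (K_use == 1L) {
    g <- rep(1L, n)
  } else if (K_use == n) {
    g <- seq_len(n)
  } else {
    best <- NULL
    for (g0 in initial_affiliations(n, K_use, restarts)) {
      res <- descend_affiliation(C, g0, K_use)
      if (is.null(best) || res$S < best$S - 1e-15) best <- res
    }
    g <- best$g
  }
  new_reduced_model(C, g, K_use, capped = capped)
}

# Enumerate set partitions of 1..n into exactly K nonempty blocks
# (restricted-growth strings), calling fn(g) for each affiliation vector.
enumerate_partitions <- function(n, K, fn) {
  g <- integer(n)
  recurse <- function(i, maxk) {
    if (i > n) {
      if (maxk == K) fn(g)
      return(invisible(NULL))
    }
    # prune: remaining positions must be able to reach K blocks
    top <- min(maxk + 1L, K)
    for (k in seq_len(top)) {
      if (K - max(maxk, k) > n - i) next
      g[i] <<- k
      recurse(i + 1L, max(maxk, k))
    }
  }
  recurse(1L, 0L)
  invisible(NULL)
}

#' Globally optimal reduced model by exhaustive partition enumeration
#'
#' Enumerates every set partition of the `n` observed categories into `K`
#' nonempty latent states, evaluates the closed-form optimal emissions for
#' each, and returns the partition with minimal cross-entropy. Serves as
#' the independent optimality oracle for [fit_reduced_model()]; the
#' Stirling-number growth restricts it to `n <= 10`.
#'
#' @inheritParams fit_reduced_model
#' @return A `reduced_model`, globally optimal over hard assignments.
#' @export
exhaustive_reduced_model <- function(C, K) {
  n <- ncol(C)
  if (n > 10L) {
    abort("exhaustive enumeration is limited to n <= 10; use fit_reduced_model().")
  }
  K <- as.integer(K)
  if (K < 1L || K > n) abort("`K` must lie in 1..n.")
  K_cap <- sum(colSums(C) > 0)
  capped <- K > K_cap
  K_use <- if (capped) K_cap else K

  best_g <- NULL
  best_S <- Inf
  enumerate_partitions(n, K_use, function(g) {
    lam <- lambda_for_affiliation(C, g, K_use)
    S <- affiliation_entropy(C, g, lam)
    if (S < best_S - 1e-15) {
      best_S <<- S
      best_g <<- g
    }
  })
  new_reduced_model(C, best_g, K_use, capped = capped)
}

#' Cross-entropy of a contingency table under a reduced model
#'
#' Evaluates `S = -sum_ij C[j, i] log[(lambda gamma)[j, i]]` in nats, with
#' the convention `0 log 0 = 0`. The result is `+Inf` only if some
#' observed transition (`C[j, i] > 0`) has zero model probability.
#'
#' @param C A [contingency()] table.
#' @param model A `reduced_model` over the same alphabet.
#' @return Nonnegative entropy in nats (possibly `+Inf`).
#' @export
model_entropy <- function(C, model) {
  stopifnot(inherits(model, "reduced_model"))
  if (ncol(C) != model$n) abort("model and table alphabets differ.")
  cross_entropy_sum(unclass(C), model$lambda %*% model$gamma)
}

#' Composed transition matrix of a reduced model
#'
#' The matrix product `Lambda_K = lambda_K gamma_K`, the rank-`K`
#' transition law the model implies on the observed categories. Columns
#' sum to one.
#'
#' @param model A `reduced_model`.
#' @return An n-by-n column-stochastic matrix (final x initial).
#' @export
compose_transition <- function(model) {
  stopifnot(inherits(model, "reduced_model"))
  model$lambda %*% model$gamma
}
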