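#' Corrected Akaike information criterion for a reduced model
#'
#' `AICc = N S + V + V (V + 1) / (N - V - 1)`, combining the
#' data-cross-entropy term `N S` with a finite-sample complexity penalty.
#' When the denominator is not positive (`V + 1 >= N`, more parameters
#' than pairs) the model is excluded by returning `+Inf` rather than
#' erroring, so short series degrade gracefully toward small-K models.
#'
#' @param S Cross-entropy of the model in nats (see [model_entropy()]).
#' @param V Effective parameter count (nonnegative integer).
#' @param N_pairs Number of observed transition pairs.
#' @return The AICc score (vectorized over `S`/`V`); `+Inf` where
#'   `N_pairs - V - 1 <= 0`.
#' @export
aicc <- function(S, V, N_pairs) {
  out <- N_pairs * S + V + V * (V + 1) / (N_pairs - V - 1)
  out[N_pairs - V - 1 <= 0] <- Inf
  out
}

#' Posterior model weights from AICc scores
#'
#' `p_K` proportional to `exp(-(AICc_K - min AICc))`, normalized to sum to
#' one. Entries equal to `+Inf` (excluded models) receive zero weight.
#'
#' @param aicc_values Numeric vector of AICc scores, at least one finite.
#' @return Nonnegative weights summing to one.
#' @export
akaike_weights <- function(aicc_values) {
  finite <- is.finite(aicc_values)
  if (!any(finite)) abort("all candidate models are excluded (AICc = +Inf).")
  w <- exp(-(aicc_values - min(aicc_values[finite])))
  w[!finite] <- 0
  w / sum(w)
}

#' Latent entropy and latent dimension of a pair sample
#'
#' The central measures of the package. Every candidate latent dimension
#' `K = 1..n_effective` is fitted by direct Bayesian model reduction
#' ([fit_reduced_model()]), scored by [aicc()], and weighted by its
#' posterior probability ([akaike_weights()]); the latent entropy
#' `S_bar = sum_K p_K S_K` (nats) quantifies how unpredictable the
#' transition dynamics are, and the latent dimension
#' `K_bar = sum_K p_K K` quantifies their memory (`K_bar = 1`: the final
#' state ignores the initial one).
#'
#' Categories never observed in the sample (empty row and column of the
#' contingency table) are dropped before fitting, so `n_effective` can be
#' smaller than the alphabet size; a single-category sample returns
#' `S_bar = 0`, `K_bar = 1` exactly. Dimensions above the number of
#' categories observed as initial states would duplicate the largest
#' attainable model and receive zero weight.
#'
#' @param sample A [pair_sample()].
#' @param restarts Search restarts per fit, passed to
#'   [fit_reduced_model()].
#' @param warn Emit a warning when the sample fails
#'   [check_sample_size()] (`N_pairs <= n_effective^2`)? Default `TRUE`;
#'   pipelines record the flag in a map instead.
#' @return An object of class `latent_measures` with fields `S_bar`,
#'   `K_bar`, `p` (posterior weights), `S_per_K`, `AICc_per_K`, `V_per_K`,
#'   `n_effective`, `N_pairs`, `size_ok`, and `kept_categories` (indices
#'   of the original alphabet retained). Use [tidy()] for the per-K table
#'   and [glance()] for the one-row summary.
#' @examples
#' s <- sample_toast(0, 0.5, n_experiments = 1000, seed = 1)
#' glance(latent_measures(s))
#' @export
latent_measures <- function(sample, restarts = 10L, warn = TRUE) {
  stopifnot(inherits(sample, "pair_sample"))
  N <- sample$N_pairs
  C_full <- contingency(sample)
  keep <- which(rowSums(C_full) + colSums(C_full) > 0)
  C <- unclass(C_full)[keep, keep, drop = FALSE]
  n_eff <- length(keep)

  if (n_eff == 1L) {
    out <- list(
      S_bar = 0, K_bar = 1, p = 1, S_per_K = 0,
      AICc_per_K = aicc(0, 0L, N), V_per_K = 0L,
      n_effective = 1L, N_pairs = N, size_ok = N > 1,
      kept_categories = keep
    )
    return(structure(out, class = "latent_measures"))
  }

  size_ok <- N > n_eff^2
  if (warn && !size_ok) {
    warn_msg <- sprintf(
      "sample has N_pairs = %d <= n^2 = %d; latent measures may be inaccurate.",
      N, n_eff^2
    )
    warn(warn_msg)
  }

  K_cap <- sum(colSums(C) > 0)
  S_per_K <- numeric(n_eff)
  V_per_K <- integer(n_eff)
  AICc_per_K <- numeric(n_eff)
  for (K in seq_len(n_eff)) {
    if (K <= K_cap) {
      m <- fit_reduced_model(C, K, restarts = restarts)
      S_per_K[K] <- m$S
      V_per_K[K] <- m$V
      AICc_per_K[K] <- aicc(m$S, m$V, N)
    } else {
      # duplicate of the K_cap model: excluded from the average
      S_per_K[K] <- S_per_K[K_cap]
      V_per_K[K] <- (n_eff - 1L) * K + n_eff * (K - 1L)
      AICc_per_K[K] <- Inf
    }
  }

  p <- akaike_weights(AICc_per_K)
  structure(
    list(
      S_bar = sum(p * S_per_K),
      K_bar = sum(p * seq_len(n_eff)),
      p = p,
      S_per_K = S_per_K,
      AICc_per_K = AICc_per_K,
      V_per_K = V_per_K,
      n_effective = n_eff,
      N_pairs = N,
      size_ok = size_ok,
      kept_categories = keep
    ),
    class = "latent_measures"
  )
}

#' @export
print.latent_measures <- function(x, ...) {
  cat("<latent_measures> S_bar =", format(x$S_bar, digits = 6),
      "nats | K_bar =", format(x$K_bar, digits = 6),
      "| n_effective =", x$n_effective,
      "| N_pairs =", x$N_pairs, "\n")
  if (!x$size_ok) cat("  (N_pairs <= n^2: estimates may be inaccurate)\n")
  invisible(x)
}

#' Per-dimension summary of a latent-measures fit
#'
#' @param x A `latent_measures` object.
#' @param ... Unused.
#' @return A tibble with one row per candidate dimension `K`: entropy `S`,
#'   parameter count `V`, `AICc`, and posterior `weight`.
#' @export
tidy.latent_measures <- function(x, ...) {
  tibble(
    K = seq_len(x$n_effective),
    S = x$S_per_K,
    V = as.integer(x$V_per_K),
    AICc = x$AICc_per_K,
    weight = x$p
  )
}

#' One-row summary of a latent-measures fit
#'
#' @param x A `latent_measures` object.
#' @param ... Unused.
#' @return A one-row tibble with `S_bar`, `K_bar`, `n_effective`,
#'   `N_pairs`, `size_ok`.
#' @export
glance.latent_measures <- function(x, ...) {
  tibble(
    S_bar = x$S_bar,
    K_bar = x$K_bar,
    n_effective = x$n_effective,
    N_pairs = x$N_pairs,
    size_ok = x$size_ok
  )
}
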