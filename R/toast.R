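# The linear Markovian falling-toast toy model: a two-state transition
# matrix parameterized by deviations from the fair Bernoulli coin, used to
# illustrate how the latent entropy (predictability) and latent dimension
# (memory) decouple.

#' Falling-toast transition matrix
#'
#' Builds the two-state transition matrix
#' \deqn{\Lambda = \begin{pmatrix} 0.5 - U_s + U_h & 0.5 - U_s - U_h \\
#'                                 0.5 + U_s - U_h & 0.5 + U_s + U_h
#'                 \end{pmatrix}}
#' with state 1 = "butter up" (row/column 1) and state 2 = "butter down".
#' `u_s` models the asymmetry of the toast (buttering shifts the outcome
#' towards one side regardless of the start), `u_h` the table-height
#' effect (a low table preserves the initial side, giving the outcome
#' memory). Columns sum to one identically; only parameter combinations
#' keeping all entries in [0, 1] are admissible.
#'
#' @param u_s Asymmetry deviation.
#' @param u_h Height/memory deviation.
#' @return A 2x2 column-stochastic matrix (final x initial) with dimnames
#'   `c("up", "down")`.
#' @examples
#' toast_transition(0, 0)    # fair coin
#' toast_transition(0, 0.5)  # identity: outcome = initial side
#' toast_transition(0.5, 0)  # always butter down
#' @export
toast_transition <- function(u_s, u_h) {
  L <- matrix(
    c(0.5 - u_s + u_h, 0.5 + u_s - u_h,
      0.5 - u_s - u_h, 0.5 + u_s + u_h),
    nrow = 2, ncol = 2,
    dimnames = list(final = c("up", "down"), initial = c("up", "down"))
  )
  bad <- which(L < -1e-12 | L > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "entry [%d, %d] = %.4g of the transition matrix lies outside [0, 1]; infeasible (u_s, u_h).",
      bad[1, 1], bad[1, 2], L[bad[1, , drop = FALSE]]
    ))
  }
  pmin(pmax(L, 0), 1)
}

toast_feasible <- function(u_s, u_h) {
  abs(u_s) + abs(u_h) <= 0.5 + 1e-12
}

#' Sample independent falling-toast experiments
#'
#' Each experiment draws the initial side `X` uniformly from
#' \{up, down\} and the final side `Y` from the corresponding column of
#' [toast_transition()]. Experiments are independent repeats, not a time
#' chain; the latent measures consume the resulting [pair_sample()]
#' either way.
#'
#' @inheritParams toast_transition
#' @param n_experiments Number of experiments (default 10000).
#' @param seed Optional integer; if given, `set.seed(seed)` is called
#'   first.
#' @return A [pair_sample()] over the two sides (1 = up, 2 = down).
#' @export
sample_toast <- function(u_s, u_h, n_experiments = 10000L, seed = NULL) {
  if (n_experiments < 1L) abort("`n_experiments` must be at least 1.")
  L <- toast_transition(u_s, u_h)
  if (!is.null(seed)) set.seed(seed)
  x <- sample.int(2L, n_experiments, replace = TRUE)
  p_up <- L[1, x]
  y <- ifelse(runif(n_experiments) < p_up, 1L, 2L)
  pair_sample(x, y, 2L)
}

#' Latent measures of one falling-toast configuration
#'
#' Convenience wrapper: [sample_toast()] followed by [latent_measures()].
#'
#' @inheritParams sample_toast
#' @param ... Passed on to [latent_measures()].
#' @return A `latent_measures` object.
#' @export
latent_toast <- function(u_s, u_h, n_experiments = 10000L, seed = NULL, ...) {
  latent_measures(sample_toast(u_s, u_h, n_experiments, seed), warn = FALSE, ...)
}

#' Sweep the falling-toast parameter square
#'
#' Evaluates the latent entropy and latent dimension over a grid of
#' `(u_s, u_h)` configurations, averaging over replicate experiment sets.
#' Grid points whose transition matrix would leave [0, 1] are recorded as
#' infeasible (`NA` measures), not errors.
#'
#' @param u_s,u_h Numeric vectors of parameter values; the sweep covers
#'   their Cartesian product. Defaults: `seq(0, 0.5, by = 0.1)`.
#' @param n_experiments Experiments per replicate (default 10000).
#' @param replicates Replicates averaged per grid point (default 1).
#' @param seed Integer seed for the whole sweep (default 1).
#' @return A tibble of class `toast_sweep` with columns `u_s`, `u_h`,
#'   `feasible`, `S_bar`, `K_bar` and attributes `n_experiments`,
#'   `replicates`, `seed`.
#' @examples
#' \donttest{
#' sweep <- sweep_toast(n_experiments = 2000, seed = 1)
#' autoplot(sweep)
#' }
#' @export
sweep_toast <- function(u_s = seq(0, 0.5, by = 0.1),
                        u_h = seq(0, 0.5, by = 0.1),
                        n_experiments = 10000L,
                        replicates = 1L,
                        seed = 1L) {
  grid <- tidyr::expand_grid(u_s = u_s, u_h = u_h)
  set.seed(seed)
  res <- purrr::pmap_dfr(grid, function(u_s, u_h) {
    if (!toast_feasible(u_s, u_h)) {
      return(tibble(u_s = u_s, u_h = u_h, feasible = FALSE,
                    S_bar = NA_real_, K_bar = NA_real_))
    }
    acc <- purrr::map(seq_len(replicates), function(r) {
      latent_toast(u_s, u_h, n_experiments)
    })
    tibble(
      u_s = u_s, u_h = u_h, feasible = TRUE,
      S_bar = mean(purrr::map_dbl(acc, "S_bar")),
      K_bar = mean(purrr::map_dbl(acc, "K_bar"))
    )
  })
  structure(
    res,
    n_experiments = n_experiments, replicates = replicates, seed = seed,
    class = c("toast_sweep", class(res))
  )
}

#' Plot a falling-toast parameter sweep
#'
#' Tiles of the latent entropy and latent dimension over the `(u_s, u_h)`
#' square; infeasible points are blank.
#'
#' @param object A [sweep_toast()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.toast_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("u_s", "u_h", "S_bar", "K_bar")],
    cols = c("S_bar", "K_bar"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$u_s, y = .data$u_h,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~measure, labeller = ggplot2::labeller(
      measure = c(K_bar = "latent dimension", S_bar = "latent entropy (nats)")
    )) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(U[s]), y = expression(U[h]), fill = NULL)
}
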