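#' Category alphabet for discretized intensities
#'
#' An alphabet is the ordered set of `n` categories that a discretized pixel
#' trace can take, optionally together with the `n + 1` intensity thresholds
#' that define the bins.
#'
#' @param n Positive integer number of categories.
#' @param labels Ordered vector of `n` distinct category identifiers.
#'   Defaults to `1:n`.
#' @param bin_edges Optional strictly increasing numeric vector of length
#'   `n + 1` giving the intensity thresholds (in the units of the input
#'   image) that separate the categories.
#' @return An object of class `category_alphabet`.
#' @export
category_alphabet <- function(n, labels = seq_len(n), bin_edges = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    abort("`n` must be a single positive integer.")
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    abort("`labels` must be `n` distinct category identifiers.")
  }
  if (!is.null(bin_edges)) {
    if (length(bin_edges) != n + 1L || any(diff(bin_edges) <= 0)) {
      abort("`bin_edges` must be strictly increasing and of length `n + 1`.")
    }
  }
  structure(
    list(n = n, labels = labels, bin_edges = bin_edges),
    class = "category_alphabet"
  )
}

#' @export
print.category_alphabet <- function(x, ...) {
  cat("<category_alphabet> n =", x$n, "\n")
  invisible(x)
}

#' Discretize a continuous intensity trace into categories
#'
#' Maps a numeric series onto an ordered alphabet of intensity categories,
#' the "discretized color scale" on which all latent measures operate. By
#' default bins are uniform over the range of a reference series (pass the
#' global range of a whole image stack through `range` to give every pixel
#' the same alphabet). A series that is already integer-valued with at most
#' `n_bins` distinct values keeps its distinct values as categories, so no
#' bin is empty. A constant series collapses to a single-category alphabet
#' and is flagged, not an error.
#'
#' @param values Nonempty numeric vector of finite intensities, in temporal
#'   order.
#' @param n_bins Number of bins requested (default 8).
#' @param edges Optional explicit bin edges (length `n_bins + 1`, strictly
#'   increasing); overrides `range`.
#' @param range Optional numeric length-2 reference range covered by the
#'   uniform bins; defaults to `range(values)`. Values outside it are
#'   clamped into the first/last bin.
#' @return A list with elements `categories` (integer vector of bin
#'   indices, temporal order preserved), `alphabet`
#'   ([category_alphabet()]), and `constant` (`TRUE` when the series had a
#'   single distinct value).
#' @examples
#' discretize_series(c(0, 1, 0, 1), n_bins = 2)$categories
#' @export
discretize_series <- function(values, n_bins = 8, edges = NULL, range = NULL) {
  if (length(values) == 0L || !all(is.finite(values))) {
    abort("`values` must be a nonempty vector of finite numbers.")
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) abort("`n_bins` must be a positive integer.")

  if (!is.null(edges)) {
    n <- length(edges) - 1L
    alphabet <- category_alphabet(n, bin_edges = as.numeric(edges))
    cats <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
    return(list(categories = as.integer(cats), alphabet = alphabet, constant = FALSE))
  }

  distinct <- sort(unique(values))
  if (length(distinct) == 1L) {
    return(list(
      categories = rep(1L, length(values)),
      alphabet = category_alphabet(1L, labels = distinct),
      constant = TRUE
    ))
  }
  if (is_wholenumber(values) && length(distinct) <= n_bins) {
    cats <- match(values, distinct)
    return(list(
      categories = as.integer(cats),
      alphabet = category_alphabet(length(distinct), labels = distinct),
      constant = FALSE
    ))
  }

  rng <- if (is.null(range)) base::range(values) else as.numeric(range)
  if (length(rng) != 2L || rng[1] >= rng[2]) {
    abort("`range` must be two increasing finite numbers.")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cats <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(
    categories = as.integer(cats),
    alphabet = category_alphabet(n_bins, bin_edges = edges),
    constant = FALSE
  )
}

#' Observed transition pairs over a category alphabet
#'
#' A pair sample is the universal input of the latent measures: a set of
#' (initial category, final category) observations, either consecutive
#' frames of one pixel, pooled pixels of a patch, or independent repeats of
#' an experiment.
#'
#' @param i Integer vector of initial-category indices in `1..n`.
#' @param j Integer vector of final-category indices in `1..n`, same length
#'   as `i`.
#' @param n Number of categories of the shared alphabet (positive integer),
#'   or a [category_alphabet()].
#' @return An object of class `pair_sample` with fields `i`, `j`, `n`,
#'   `N_pairs`.
#' @export
pair_sample <- function(i, j, n) {
  if (inherits(n, "category_alphabet")) n <- n$n
  n <- as.integer(n)
  i <- as.integer(i)
  j <- as.integer(j)
  if (length(i) != length(j) || length(i) < 1L) {
    abort("`i` and `j` must be nonempty vectors of equal length.")
  }
  if (anyNA(i) || anyNA(j) || any(i < 1L | i > n) || any(j < 1L | j > n)) {
    abort("category indices must lie in 1..n.")
  }
  structure(
    list(i = i, j = j, n = n, N_pairs = length(i)),
    class = "pair_sample"
  )
}

#' @export
print.pair_sample <- function(x, ...) {
  cat("<pair_sample>", x$N_pairs, "pairs over", x$n, "categories\n")
  invisible(x)
}

#' @rdname pair_sample
#' @param x A `pair_sample`.
#' @param ... Unused.
#' @export
as_tibble.pair_sample <- function(x, ...) {
  tibble(initial = x$i, final = x$j)
}

#' Consecutive transition pairs of a categorical series
#'
#' Turns a temporally ordered category sequence of length `T` into the
#' `T - 1` transitions (X(t), X(t+1)).
#'
#' @param categories Integer vector of category indices, length at least 2.
#' @param alphabet A [category_alphabet()] or the integer number of
#'   categories.
#' @return A [pair_sample()] with `N_pairs = length(categories) - 1`.
#' @export
pairs_from_series <- function(categories, alphabet) {
  T_len <- length(categories)
  if (T_len < 2L) {
    abort("need at least two time points to form a transition pair.")
  }
  pair_sample(categories[-T_len], categories[-1L], alphabet)
}

#' Average contingency table of a pair sample
#'
#' The n-by-n matrix of joint relative frequencies
#' `C[j, i] = #\{pairs (i, j)\} / N_pairs`, with row index `j` the final
#' category and column index `i` the initial one. Its entries sum to one;
#' all latent-measure fits operate on this table.
#'
#' @param sample A [pair_sample()].
#' @return A numeric matrix of class `contingency_table` with attributes
#'   `N_pairs` (pair count) and `n`.
#' @export
contingency <- function(sample) {
  stopifnot(inherits(sample, "pair_sample"))
  n <- sample$n
  idx <- (sample$i - 1L) * n + sample$j
  C <- matrix(tabulate(idx, nbins = n * n), n, n) / sample$N_pairs
  structure(C, class = c("contingency_table", "matrix"),
            N_pairs = sample$N_pairs, n = n)
}

#' Sample-size adequacy of a pair sample
#'
#' The transition statistics of an `n`-category alphabet have of order
#' `n^2` cells, so the latent measures are reliable as long as the number
#' of observed pairs exceeds `n^2`. Pipelines flag (but still compute)
#' pixels that fail this check.
#'
#' @param sample A [pair_sample()].
#' @return `TRUE` iff `N_pairs > n^2`.
#' @export
check_sample_size <- function(sample) {
  stopifnot(inherits(sample, "pair_sample"))
  sample$N_pairs > sample$n^2
}
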