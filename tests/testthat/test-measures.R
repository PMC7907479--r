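test_that("AICc follows the corrected-penalty formula and excludes saturated models", {
  expect_equal(aicc(0, 4, 100), 4 + 20 / 95)
  expect_equal(aicc(log(2), 1, 100), 100 * log(2) + 1 + 2 / 98)
  expect_identical(aicc(0.5, 100, 100), Inf)
  expect_identical(aicc(0.5, 99, 100), Inf) # denominator exactly zero
  # vectorized over models
  expect_equal(aicc(c(0, log(2)), c(4, 1), 100),
               c(4 + 20 / 95, 100 * log(2) + 1 + 2 / 98))
})

test_that("posterior weights renormalize exponentiated AICc differences", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, Inf)), c(1, 0))
  w <- akaike_weights(c(4.21, 70.34))
  expect_lt(abs(w[1] - 1), 1e-12)
  expect_equal(w[2], exp(-(70.34 - 4.21)) / (1 + exp(-(70.34 - 4.21))))
  expect_error(akaike_weights(c(Inf, Inf)), "excluded")
})

test_that("a constant outcome gives zero latent entropy and no memory", {
  set.seed(2)
  x <- sample.int(2, 10000, replace = TRUE)
  m <- latent_measures(pair_sample(x, rep(2L, 10000), 2))
  expect_identical(m$S_bar, 0)
  expect_lt(abs(m$K_bar - 1), 0.05)
})

test_that("a deterministic copy of the initial state gives maximal latent dimension", {
  set.seed(3)
  x <- sample.int(2, 10000, replace = TRUE)
  m <- latent_measures(pair_sample(x, x, 2))
  expect_lt(abs(m$K_bar - 2), 1e-6)
  expect_identical(m$S_bar, 0)
})

test_that("an independent uniform outcome concentrates weight on small dimensions", {
  set.seed(4)
  x <- sample.int(2, 10000, replace = TRUE)
  y <- sample.int(2, 10000, replace = TRUE)
  m <- latent_measures(pair_sample(x, y, 2))
  expect_gt(m$p[1], 0.5) # the memoryless model dominates
  expect_lt(abs(m$S_bar - log(2)), 0.01)
})

test_that("single-category samples return the exact degenerate measures", {
  m <- latent_measures(pair_sample(rep(1L, 5), rep(1L, 5), 3))
  expect_identical(m$S_bar, 0)
  expect_identical(m$K_bar, 1)
  expect_equal(m$n_effective, 1L)
})

test_that("short samples trigger the adequacy warning but still compute", {
  s <- pair_sample(rep(1:3, 3), rep(c(2L, 3L, 1L), 3), 3)
  expect_warning(m <- latent_measures(s), "inaccurate")
  expect_true(is.finite(m$S_bar))
  m2 <- suppressWarnings(latent_measures(s))
  expect_true(m2$K_bar >= 1)
})

test_that("latent dimension recovers the true rank of factorizable dynamics", {
  # two latent profiles shared by three observed categories
  Lambda <- cbind(c(0.7, 0.2, 0.1), c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
  s <- sample_from_transition(Lambda, 10000, seed = 8)
  m <- latent_measures(s)
  expect_lt(abs(m$K_bar - 2), 0.1)
  expect_equal(which.max(m$p), 2L)
})

test_that("weights normalize and measures respect their bounds on random inputs", {
  for (r in 1:40) {
    n <- 2 + (r %% 4)
    s <- sample_from_transition(random_transition(n, 400 + r), 400, seed = 500 + r)
    m <- latent_measures(s, warn = FALSE)
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_true(m$K_bar >= 1 && m$K_bar <= m$n_effective)
    expect_true(m$S_bar >= 0 && m$S_bar <= log(m$n_effective) + 1e-9)
  }
})

test_that("latent measures are invariant under category relabeling", {
  for (r in 1:8) {
    n <- 3 + (r %% 3)
    s <- sample_from_transition(random_transition(n, 600 + r), 500, seed = 700 + r)
    set.seed(800 + r)
    sp <- permute_sample(s, sample.int(n))
    m <- latent_measures(s, warn = FALSE)
    mp <- latent_measures(sp, warn = FALSE)
    expect_equal(mp$S_bar, m$S_bar, tolerance = 1e-9)
    expect_equal(mp$K_bar, m$K_bar, tolerance = 1e-9)
  }
})

test_that("tidy and glance expose the per-K table and the summary row", {
  m <- latent_toast(0, 0.3, n_experiments = 2000, seed = 9)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("K", "S", "V", "AICc", "weight"))
  expect_equal(nrow(td), m$n_effective)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)

  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$S_bar, m$S_bar)
  expect_equal(gl$K_bar, m$K_bar)
})
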