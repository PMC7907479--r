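test_that("generation is bit-reproducible from spec and seed", {
  spec <- synth_preset("capillary", H = 12, W = 12, T = 50, seed = 3)
  g1 <- generate_stack(spec)
  g2 <- generate_stack(spec)
  expect_identical(g1$stack$frames, g2$stack$frames)
  expect_identical(g1$mask, g2$mask)
  g3 <- generate_stack(spec, seed = 4)
  expect_false(identical(g1$stack$frames, g3$stack$frames))
})

test_that("capillary masks are seeded, bounded and connected", {
  expect_identical(capillary_mask(10, 10, width = 0), matrix(FALSE, 10, 10))

  m1 <- capillary_mask(64, 64, n_branches = 1, width = 1, seed = 2)
  expect_gt(sum(m1), 0)
  # a single un-dilated branch is one connected 8-neighbor path
  comp <- matrix(FALSE, 64, 64)
  start <- which(m1, arr.ind = TRUE)[1, ]
  frontier <- list(start)
  comp[start[1], start[2]] <- TRUE
  while (length(frontier) > 0) {
    p <- frontier[[1]]; frontier <- frontier[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; cc <- p[2] + dc
      if (r >= 1 && r <= 64 && cc >= 1 && cc <= 64 &&
          m1[r, cc] && !comp[r, cc]) {
        comp[r, cc] <- TRUE
        frontier <- c(frontier, list(c(r, cc)))
      }
    }
  }
  expect_identical(comp, m1)

  expect_identical(capillary_mask(32, 32, seed = 5),
                   capillary_mask(32, 32, seed = 5))
  frac <- mean(capillary_mask(64, 64, seed = 6))
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.40)
})

test_that("infeasible local dynamics are rejected at spec validation", {
  expect_error(
    synthetic_spec(4, 4, 10, dynamics_out = toast_params(0.2, 0),
                   gradient_param = "u_h", gradient_range = c(0, 0.5)),
    "infeasible"
  )
})

test_that("exchangeable pixels homogenize as the record lengthens", {
  v <- vapply(c(200, 2000), function(T_len) {
    spec <- synthetic_spec(14, 14, T_len, dynamics_out = toast_params(0.25, 0),
                           noise_sd = 0.1, seed = 7)
    maps <- compute_measure_maps(generate_stack(spec)$stack, n_bins = 2)
    stats::var(as.vector(maps$S_bar))
  }, numeric(1))
  expect_lt(v[2], v[1])
})

test_that("masked dynamics lower the latent entropy inside the mask", {
  spec <- synthetic_spec(16, 16, 400,
                         dynamics_out = toast_params(0, 0),
                         dynamics_in = toast_params(0.4, 0),
                         mask = capillary_mask(16, 16, width = 3, seed = 8),
                         noise_sd = 0.1, seed = 8)
  gs <- generate_stack(spec)
  expect_gt(mean(gs$mask), 0)
  maps <- compute_measure_maps(gs$stack, n_bins = 2)
  expect_lt(mean(maps$S_bar[gs$mask]), mean(maps$S_bar[!gs$mask]) - 0.2)
})

test_that("a parameter gradient appears as a monotone entropy ramp", {
  spec <- synthetic_spec(16, 24, 500, dynamics_out = toast_params(0, 0),
                         gradient_param = "u_s", gradient_range = c(0, 0.45),
                         noise_sd = 0.1, seed = 9)
  gs <- generate_stack(spec)
  expect_equal(gs$params$u_s[1, 1], 0)
  expect_equal(gs$params$u_s[1, 24], 0.45)
  maps <- compute_measure_maps(gs$stack, n_bins = 2)
  cm <- colMeans(maps$S_bar)
  expect_lte(cor(seq_along(cm), cm, method = "spearman"), -0.95)
})

test_that("general n-state matrix dynamics are simulated from stationarity", {
  M <- matrix(c(0.8, 0.1, 0.1,
                0.1, 0.8, 0.1,
                0.1, 0.1, 0.8), 3, 3) # symmetric, stationary = uniform
  spec <- synthetic_spec(6, 6, 800, dynamics_out = M, noise_sd = 0, seed = 10)
  gs <- generate_stack(spec)
  expect_setequal(unique(as.vector(gs$stack$frames)), c(0, 1, 2))
  occ <- tabulate(as.vector(gs$stack$frames) + 1, 3) / length(gs$stack$frames)
  expect_true(all(abs(occ - 1 / 3) < 0.05))
  # sticky three-state dynamics carry memory: K_bar well above 1
  maps <- compute_measure_maps(gs$stack, n_bins = 3, patch = 6)
  expect_gt(maps$K_bar[1, 1], 1.5)
})
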