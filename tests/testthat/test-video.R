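make_uniform_stack <- function(H = 8, W = 8, T = 120, seed = 1, noise_sd = 0.1) {
  gs <- generate_stack(synthetic_spec(H, W, T, dynamics_out = toast_params(0, 0),
                                      noise_sd = noise_sd, seed = seed))
  gs$stack
}

test_that("constant stacks map to zero entropy and unit dimension", {
  frames <- array(3.7, dim = c(5, 4, 6))
  maps <- compute_measure_maps(video_stack(frames), n_bins = 8)
  expect_true(all(maps$S_bar == 0))
  expect_true(all(maps$K_bar == 1))
  expect_true(all(maps$n_effective == 1L))
})

test_that("regions with distinct dynamics separate cleanly in the entropy map", {
  H <- 16; W <- 16
  mask <- matrix(FALSE, H, W); mask[, 1:8] <- TRUE
  spec <- synthetic_spec(H, W, 500,
                         dynamics_out = toast_params(0, 0),
                         dynamics_in = toast_params(0.4, 0),
                         mask = mask, noise_sd = 0.1, seed = 11)
  gs <- generate_stack(spec)
  maps <- compute_measure_maps(gs$stack, n_bins = 2)
  expect_lt(mean(maps$S_bar[mask]), mean(maps$S_bar[!mask]))
  thr <- (mean(maps$S_bar[mask]) + mean(maps$S_bar[!mask])) / 2
  accuracy <- mean((maps$S_bar < thr) == mask)
  expect_gte(accuracy, 0.95)
})

test_that("patch pooling gives every member pixel the pooled measure", {
  stack <- make_uniform_stack(H = 6, W = 6, T = 80, seed = 2)
  maps <- compute_measure_maps(stack, n_bins = 2, patch = 6)
  expect_equal(length(unique(as.vector(maps$S_bar))), 1L)
  expect_equal(length(unique(as.vector(maps$K_bar))), 1L)

  # pooled value equals the measure of the concatenated member pairs
  d <- discretize_series(as.vector(stack$frames), n_bins = 2)
  cats <- array(d$categories, dim = dim(stack$frames))
  i <- as.vector(cats[-dim(cats)[1], , ]); j <- as.vector(cats[-1, , ])
  pooled <- latent_measures(pair_sample(i, j, 2), warn = FALSE)
  expect_equal(maps$S_bar[1, 1], pooled$S_bar)
  expect_equal(maps$K_bar[1, 1], pooled$K_bar)
})

test_that("maps are equivariant under spatial transposition", {
  stack <- make_uniform_stack(H = 5, W = 7, T = 60, seed = 3)
  maps <- compute_measure_maps(stack, n_bins = 2)
  stack_t <- video_stack(aperm(stack$frames, c(1, 3, 2)))
  maps_t <- compute_measure_maps(stack_t, n_bins = 2)
  expect_identical(maps_t$S_bar, t(maps$S_bar))
  expect_identical(maps_t$K_bar, t(maps$K_bar))
})

test_that("pixels are computed independently: sub-rectangles match the full run", {
  stack <- make_uniform_stack(H = 8, W = 8, T = 60, seed = 4)
  rng <- range(stack$frames)
  maps <- compute_measure_maps(stack, n_bins = 2, range = rng)
  sub <- video_stack(stack$frames[, 3:6, 2:5, drop = FALSE])
  maps_sub <- compute_measure_maps(sub, n_bins = 2, range = rng)
  expect_identical(maps_sub$S_bar, maps$S_bar[3:6, 2:5])
  expect_identical(maps_sub$K_bar, maps$K_bar[3:6, 2:5])
})

test_that("the marginal-entropy baseline is order-invariant with exact limits", {
  set.seed(10)
  frames <- array(0, dim = c(10, 2, 2))
  frames[, 1, 1] <- 0.3                     # constant pixel
  frames[, 2, 1] <- rep(c(0, 1), 5)         # alternating pixel
  frames[, 1, 2] <- c(rep(0, 5), rep(1, 5)) # blocked pixel
  frames[, 2, 2] <- runif(10)
  stack <- video_stack(frames)
  b <- baseline_marginal_entropy_map(stack, n_bins = 2)
  expect_equal(b[1, 1], 0)
  expect_equal(b[2, 1], log(2))
  expect_equal(b[1, 2], log(2))
})

test_that("frame shuffling changes the latent map but not the baseline", {
  spec <- synthetic_spec(12, 12, 600, dynamics_out = toast_params(0, 0.4),
                         noise_sd = 0.05, seed = 5)
  stack <- generate_stack(spec)$stack
  set.seed(6)
  perm <- sample.int(dim(stack$frames)[1])
  shuffled <- video_stack(stack$frames[perm, , ])

  rng <- range(stack$frames)
  b1 <- baseline_marginal_entropy_map(stack, n_bins = 2, range = rng)
  b2 <- baseline_marginal_entropy_map(shuffled, n_bins = 2, range = rng)
  expect_identical(b1, b2)

  m1 <- compute_measure_maps(stack, n_bins = 2, range = rng)
  m2 <- compute_measure_maps(shuffled, n_bins = 2, range = rng)
  # sticky dynamics (entropy ~ h(0.9)) look like a fair coin once shuffled
  expect_gt(mean(m2$S_bar) - mean(m1$S_bar), 0.2)
})

test_that("maps round-trip through float TIFF, CSV and manifest", {
  stack <- make_uniform_stack(H = 6, W = 5, T = 60, seed = 7)
  maps <- compute_measure_maps(stack, n_bins = 3)
  prefix <- file.path(withr::local_tempdir(), "run")
  files <- write_maps(maps, prefix, input = "synthetic", seed = 7)
  expect_true(all(file.exists(files)))

  rt <- read_maps(prefix)
  # float TIFF: exact at 32-bit precision, bit-stable thereafter
  expect_equal(rt$S_bar, maps$S_bar, tolerance = 1e-6)
  maps2 <- maps; maps2$S_bar <- rt$S_bar; maps2$K_bar <- rt$K_bar
  write_maps(maps2, paste0(prefix, "_gen2"))
  rt2 <- read_maps(paste0(prefix, "_gen2"))
  expect_identical(rt2$S_bar, rt$S_bar)
  expect_identical(rt2$K_bar, rt$K_bar)

  # CSV: full precision, H rows x W columns, 0-based headers
  csv_lines <- readLines(paste0(prefix, "_Sbar.csv"))
  expect_equal(length(csv_lines), nrow(maps$S_bar) + 1L)
  expect_equal(strsplit(csv_lines[1], ",")[[1]][1], "col_0")
  csv <- as.matrix(utils::read.csv(paste0(prefix, "_Sbar.csv"),
                                   check.names = FALSE))
  expect_identical(unname(csv), unname(maps$S_bar))

  manifest <- jsonlite::read_json(files[["manifest"]], simplifyVector = TRUE)
  expect_equal(manifest$n_bins, maps$n_bins)
  expect_equal(manifest$patch, 1L)
  expect_equal(manifest$seed, 7L)
})

test_that("stacks read back from multi-page TIFF and frame directories", {
  dir <- withr::local_tempdir()
  set.seed(8)
  frames <- lapply(1:3, function(t) matrix(runif(12), 3, 4))

  tiff::writeTIFF(frames, file.path(dir, "stack.tif"))
  st <- read_stack(file.path(dir, "stack.tif"))
  expect_equal(dim(st), c(3L, 3L, 4L))

  fdir <- file.path(dir, "frames"); dir.create(fdir)
  for (t in 1:3) {
    png::writePNG(frames[[t]], file.path(fdir, sprintf("frame_%02d.png", t)))
  }
  st2 <- read_stack(fdir)
  expect_equal(dim(st2), c(3L, 3L, 4L))
  expect_equal(st2$frames[2, , ], frames[[2]], tolerance = 1e-2)
})

test_that("measure maps convert to tidy tibbles and plots", {
  stack <- make_uniform_stack(H = 4, W = 3, T = 40, seed = 9)
  maps <- compute_measure_maps(stack, n_bins = 2)
  tb <- tibble::as_tibble(maps)
  expect_equal(nrow(tb), 12L)
  expect_named(tb, c("row", "col", "S_bar", "K_bar", "n_effective", "size_warning"))
  expect_equal(tb$S_bar[tb$row == 2 & tb$col == 3], maps$S_bar[2, 3])
  expect_s3_class(autoplot(maps), "ggplot")
})
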