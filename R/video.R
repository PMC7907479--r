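#' Time-ordered image stack
#'
#' A video stack holds `T` equally sized frames of scalar pixel
#' intensities as a `T x H x W` array, optionally with acquisition
#' metadata. Multichannel input must be reduced to a scalar per pixel
#' beforehand.
#'
#' @param frames A `T x H x W` numeric array (`T >= 2`, all finite), or a
#'   list of `T` equal-sized `H x W` matrices.
#' @param frame_interval Optional time between frames in seconds.
#' @param pixel_size Optional physical size of one pixel (length units
#'   per pixel).
#' @return An object of class `video_stack` with fields `frames`,
#'   `frame_interval`, `pixel_size`.
#' @export
video_stack <- function(frames, frame_interval = NULL, pixel_size = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L || length(dims[[1]]) != 2L) {
      abort("all frames must be matrices of identical size.")
    }
    arr <- array(0, dim = c(length(frames), dims[[1]]))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
    frames <- arr
  }
  if (length(dim(frames)) != 3L) abort("`frames` must be a T x H x W array.")
  if (dim(frames)[1] < 2L) abort("a stack needs at least two frames.")
  if (!all(is.finite(frames))) abort("all pixel intensities must be finite.")
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<video_stack>", d[1], "frames of", d[2], "x", d[3], "pixels\n")
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported frame format '%s' (use TIFF or PNG).", ext))
  )
  if (length(dim(img)) == 3L) {
    abort("multichannel frames are not supported; reduce to a scalar per pixel first.")
  }
  img
}

#' Read an image stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of equally sized
#' single-channel TIFF/PNG frames, ordered by filename.
#'
#' @param path Path to a multi-page TIFF or to a frame directory.
#' @param frame_interval,pixel_size Optional metadata stored on the
#'   stack; see [video_stack()].
#' @return A [video_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL, pixel_size = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) abort("frame directory must hold at least two frames.")
    frames <- lapply(files, read_frame_file)
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (any(vapply(frames, function(f) length(dim(f)) == 3L, logical(1)))) {
      abort("multichannel frames are not supported; reduce to a scalar per pixel first.")
    }
  }
  video_stack(frames, frame_interval = frame_interval, pixel_size = pixel_size)
}

# Shared global discretization of a whole stack: one alphabet for every
# pixel so entropies are on a comparable scale.
discretize_stack <- function(stack, n_bins, range = NULL) {
  d <- discretize_series(as.vector(stack$frames), n_bins = n_bins, range = range)
  list(
    categories = array(d$categories, dim = dim(stack$frames)),
    alphabet = d$alphabet,
    constant = d$constant
  )
}

patch_blocks <- function(extent, patch) {
  starts <- seq(1L, extent, by = patch)
  lapply(starts, function(s) s:min(s + patch - 1L, extent))
}

#' Pixel-wise latent-entropy and latent-dimension maps
#'
#' Discretizes the stack on one shared intensity alphabet (uniform bins
#' over the global range), forms each pixel's consecutive transition
#' pairs, and computes the latent measures independently per pixel. With
#' `patch > 1` the transition pairs of each `patch x patch` block are
#' pooled into a single sample (a coarser observable with
#' `patch^2 (T - 1)` pairs) and every member pixel receives the pooled
#' values; edge-partial blocks are allowed.
#'
#' Pixels whose pair count does not exceed `n_effective^2` are flagged in
#' `size_warning` but still computed. Maps are indexed `[row, column]`
#' with the origin at the top-left.
#'
#' @param stack A [video_stack()].
#' @param n_bins Number of global intensity bins (default 8).
#' @param patch Patch edge length in pixels (default 1 = per pixel).
#' @param range Optional length-2 reference intensity range for the
#'   shared bins (defaults to the global range of `stack`); pass the
#'   full-stack range when analysing a spatial sub-rectangle so the
#'   alphabet matches the full run.
#' @param restarts Search restarts per fit; see [fit_reduced_model()].
#' @param progress Print a progress line every few hundred blocks?
#' @return An object of class `measure_map`: matrices `S_bar`, `K_bar`,
#'   `n_effective`, `size_warning` (all `H x W`), plus the discretization
#'   metadata. Use [as_tibble()] for a long per-pixel tibble and
#'   [autoplot()] to display the maps.
#' @export
compute_measure_maps <- function(stack, n_bins = 8, patch = 1, range = NULL,
                                 restarts = 10L, progress = FALSE) {
  stopifnot(inherits(stack, "video_stack"))
  n_bins <- as.integer(n_bins)
  patch <- as.integer(patch)
  if (n_bins < 1L) abort("`n_bins` must be positive.")
  if (patch < 1L) abort("`patch` must be positive.")

  d <- dim(stack$frames)
  T_len <- d[1]; H <- d[2]; W <- d[3]
  disc <- discretize_stack(stack, n_bins, range = range)
  cats <- disc$categories
  n <- disc$alphabet$n

  S_map <- matrix(NA_real_, H, W)
  K_map <- matrix(NA_real_, H, W)
  n_map <- matrix(NA_integer_, H, W)
  w_map <- matrix(NA, H, W)

  row_blocks <- patch_blocks(H, patch)
  col_blocks <- patch_blocks(W, patch)
  n_blocks <- length(row_blocks) * length(col_blocks)
  done <- 0L
  for (rb in row_blocks) {
    for (cb in col_blocks) {
      block <- cats[, rb, cb, drop = FALSE]
      i <- as.vector(block[-T_len, , , drop = FALSE])
      j <- as.vector(block[-1L, , , drop = FALSE])
      lm <- latent_measures(pair_sample(i, j, n), restarts = restarts,
                            warn = FALSE)
      S_map[rb, cb] <- lm$S_bar
      K_map[rb, cb] <- lm$K_bar
      n_map[rb, cb] <- lm$n_effective
      w_map[rb, cb] <- !lm$size_ok
      done <- done + 1L
      if (progress && done %% 500L == 0L) {
        message(sprintf("latentmap: %d/%d blocks done", done, n_blocks))
      }
    }
  }

  structure(
    list(
      S_bar = S_map, K_bar = K_map, n_effective = n_map,
      size_warning = w_map,
      n_bins = n, patch = patch,
      bin_edges = disc$alphabet$bin_edges,
      T = T_len
    ),
    class = "measure_map"
  )
}

#' @export
print.measure_map <- function(x, ...) {
  cat("<measure_map>", nrow(x$S_bar), "x", ncol(x$S_bar),
      "pixels | n_bins =", x$n_bins, "| patch =", x$patch, "\n")
  cat("  S_bar in [", format(min(x$S_bar), digits = 4), ",",
      format(max(x$S_bar), digits = 4), "] nats | K_bar in [",
      format(min(x$K_bar), digits = 4), ",",
      format(max(x$K_bar), digits = 4), "]\n")
  invisible(x)
}

#' @rdname compute_measure_maps
#' @param x A `measure_map`.
#' @param ... Unused.
#' @export
as_tibble.measure_map <- function(x, ...) {
  H <- nrow(x$S_bar); W <- ncol(x$S_bar)
  tibble(
    row = rep(seq_len(H), times = W),
    col = rep(seq_len(W), each = H),
    S_bar = as.vector(x$S_bar),
    K_bar = as.vector(x$K_bar),
    n_effective = as.vector(x$n_effective),
    size_warning = as.vector(x$size_warning)
  )
}

#' Plot latent-measure maps
#'
#' Raster panels of the latent-entropy and latent-dimension maps, origin
#' at the top-left as in the input images.
#'
#' @param object A `measure_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.measure_map <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("row", "col", "S_bar", "K_bar")],
    cols = c("S_bar", "K_bar"), names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~measure, labeller = ggplot2::labeller(
      measure = c(K_bar = "latent dimension", S_bar = "latent entropy (nats)")
    )) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = NULL)
}

#' Order-invariant marginal-entropy baseline map
#'
#' Shannon entropy (nats) of each pixel's marginal category histogram
#' under the same shared discretization as [compute_measure_maps()]. The
#' baseline is invariant under any temporal permutation of the frames, so
#' contrasting it with the latent-entropy map isolates what the latent
#' measures extract from the temporal ordering.
#'
#' @inheritParams compute_measure_maps
#' @return An `H x W` numeric matrix of marginal entropies.
#' @export
baseline_marginal_entropy_map <- function(stack, n_bins = 8, range = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  disc <- discretize_stack(stack, n_bins, range = range)
  cats <- disc$categories
  d <- dim(cats)
  out <- matrix(0, d[2], d[3])
  for (r in seq_len(d[2])) {
    for (cc in seq_len(d[3])) {
      p <- tabulate(cats[, r, cc], nbins = disc$alphabet$n) / d[1]
      out[r, cc] <- cross_entropy_sum(p, p)
    }
  }
  out
}

write_map_csv <- function(m, path) {
  header <- paste(sprintf("col_%d", seq_len(ncol(m)) - 1L), collapse = ",")
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, lines), path)
}

read_map_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
}

#' Write latent-measure maps to disk
#'
#' Writes each map both as a single-page 32-bit float TIFF (IEEE-float
#' sample format, readable by `tiff::readTIFF()`, ImageJ, or tifffile)
#' and as a CSV matrix (`H` rows, `W` comma-separated columns, 0-based
#' column headers), plus a JSON run manifest. The CSV carries full double
#' precision; the TIFF is exact at 32-bit float precision.
#'
#' @param maps A `measure_map` from [compute_measure_maps()].
#' @param out_prefix Path prefix for the output files
#'   (`<prefix>_Sbar.tif`, `<prefix>_Kbar.tif`, `<prefix>_Sbar.csv`,
#'   `<prefix>_Kbar.csv`, `<prefix>_manifest.json`).
#' @param input Optional input path recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_maps <- function(maps, out_prefix, input = NULL, seed = NULL) {
  stopifnot(inherits(maps, "measure_map"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) abort(sprintf("output directory '%s' does not exist.", dir))

  files <- c(
    Sbar_tif = paste0(out_prefix, "_Sbar.tif"),
    Kbar_tif = paste0(out_prefix, "_Kbar.tif"),
    Sbar_csv = paste0(out_prefix, "_Sbar.csv"),
    Kbar_csv = paste0(out_prefix, "_Kbar.csv"),
    manifest = paste0(out_prefix, "_manifest.json")
  )
  write_float_tiff(maps$S_bar, files[["Sbar_tif"]])
  write_float_tiff(maps$K_bar, files[["Kbar_tif"]])
  write_map_csv(maps$S_bar, files[["Sbar_csv"]])
  write_map_csv(maps$K_bar, files[["Kbar_csv"]])

  manifest <- list(
    input = input,
    n_bins = maps$n_bins,
    patch = maps$patch,
    n_frames = maps$T,
    height = nrow(maps$S_bar),
    width = ncol(maps$S_bar),
    seed = seed,
    software = paste0("latentmap ", as.character(packageVersion("latentmap")))
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(files)
}

#' Read latent-measure maps written by [write_maps()]
#'
#' @param out_prefix The prefix passed to [write_maps()].
#' @return A list with `S_bar` and `K_bar` matrices (float-TIFF
#'   precision) and the parsed `manifest`.
#' @export
read_maps <- function(out_prefix) {
  manifest <- jsonlite::read_json(paste0(out_prefix, "_manifest.json"),
                                  simplifyVector = TRUE)
  S <- tiff::readTIFF(paste0(out_prefix, "_Sbar.tif"))
  K <- tiff::readTIFF(paste0(out_prefix, "_Kbar.tif"))
  list(S_bar = S, K_bar = K, manifest = manifest)
}
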