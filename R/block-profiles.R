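## Block-based unsupervised phenotype profiling: images are divided into
## sub-cellular blocks, a two-stage clustering learns stereotypical pixel
## types and block types, and each image (or sub-image) is described by its
## block-type frequency vector.

as_channel_array <- function(image, channels = NULL) {
  if (inherits(image, "image_stack")) {
    a <- image$data
    if (!is.null(channels)) a <- a[, , channels, drop = FALSE]
    return(a)
  }
  if (is.matrix(image)) return(array(image, c(dim(image), 1)))
  stopifnot(length(dim(image)) == 3)
  if (!is.null(channels)) image[, , channels, drop = FALSE] else image
}

rescale_channels <- function(a, bounds) {
  pmin(pmax((a - bounds[1]) / (bounds[2] - bounds[1]), 0), 1)
}

# Squared-distance nearest-centre assignment, deterministic tie-break to the
# lowest index.
nearest_center <- function(X, centers) {
  d <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  max.col(-d, ties.method = "first")
}

# kmeans that degrades gracefully when there are fewer distinct points than
# requested centres: the distinct points become centres, cyclically repeated
# to length k (repeated centres can never win a first-index tie-break, so
# their profile entries stay zero).
safe_kmeans <- function(X, k, seed, nstart = 5) {
  u <- unique(X)
  if (nrow(u) <= k)
    return(u[rep(seq_len(nrow(u)), length.out = k), , drop = FALSE])
  # Lloyd iterations are deterministic given the seeded starts; residual
  # non-convergence at the default tolerance does not affect assignments
  # meaningfully, so the iteration-cap warning is silenced.
  km <- with_seed(seed, suppressWarnings(
    kmeans(X, centers = k, nstart = nstart, iter.max = 500,
           algorithm = "Lloyd")))
  km$centers
}

# Per-block pixel-type composition features of one image. Returns the
# feature matrix (n_fg_blocks x n_pixel_types) of foreground blocks.
block_features <- function(a, model) {
  p <- model$params
  a <- rescale_channels(a, p$intensity_bounds)
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  bs <- p$block_size
  nbr <- h %/% bs; nbc <- w %/% bs       # partial edge blocks discarded
  if (nbr < 1 || nbc < 1) return(matrix(0, 0, nrow(model$pixel_centers)))
  a <- a[seq_len(nbr * bs), seq_len(nbc * bs), , drop = FALSE]
  px <- matrix(a, ncol = nc)
  fg <- rowSums(px > p$fg_threshold) > 0
  blk <- as.vector(outer((seq_len(nbr * bs) - 1) %/% bs + 1,
                         ((seq_len(nbc * bs) - 1) %/% bs) * nbr,
                         "+"))
  fg_frac <- as.vector(rowsum(fg * 1, blk)) / (bs * bs)
  keep_blk <- which(fg_frac >= p$block_fg_frac & fg_frac > 0)
  if (!length(keep_blk)) return(matrix(0, 0, nrow(model$pixel_centers)))
  sel <- fg & (blk %in% keep_blk)
  types <- nearest_center(px[sel, , drop = FALSE], model$pixel_centers)
  tab <- table(factor(blk[sel], levels = keep_blk),
               factor(types, levels = seq_len(nrow(model$pixel_centers))))
  feat <- unclass(tab / rowSums(tab))
  matrix(feat, nrow = length(keep_blk))
}

#' Fit a block-type model to a set of images
#'
#' Channels are rescaled by fixed intensity bounds (default 0 and 35000) and
#' clipped to \[0, 1\]. Foreground pixels (any channel above the threshold)
#' are clustered into a small set of pixel types; each foreground block
#' (`block_size`^2 tile containing at least `block_fg_frac` foreground
#' pixels) is summarized by its pixel-type composition; and block summaries
#' are clustered into `n_types` stereotypical block types. Deterministic
#' given `seed`.
#'
#' @param images list of images ([image_stack()], `h x w x c` arrays, or
#'   matrices for single-channel data).
#' @param channels channels used for profiling (default: all).
#' @param block_size block side, px.
#' @param n_types number of block types K (profile length).
#' @param n_pixel_types number of pixel types in the first stage.
#' @param intensity_bounds per-channel rescaling bounds.
#' @param fg_threshold foreground threshold on rescaled intensity.
#' @param block_fg_frac minimum foreground-pixel fraction for a block to
#'   count as foreground.
#' @param max_pixels maximum foreground pixels sampled for the pixel-type
#'   clustering.
#' @param seed fit seed.
#' @return object of class `block_model`.
#' @export
fit_block_model <- function(images, channels = NULL, block_size = 20,
                            n_types = 30, n_pixel_types = 10,
                            intensity_bounds = c(0, 35000),
                            fg_threshold = 0.2, block_fg_frac = 0.2,
                            max_pixels = 50000, seed = 1L) {
  stopifnot(n_types >= 2, block_size >= 2,
            fg_threshold > 0, fg_threshold < 1)
  if (!is.list(images)) images <- list(images)
  arrays <- lapply(images, as_channel_array, channels = channels)
  nc <- dim(arrays[[1]])[3]

  ## stage 1: pixel types from a subsample of foreground pixels
  fg_px <- do.call(rbind, lapply(arrays, function(a) {
    a <- rescale_channels(a, intensity_bounds)
    px <- matrix(a, ncol = nc)
    px <- px[rowSums(px > fg_threshold) > 0, , drop = FALSE]
    if (nrow(px) > max_pixels)
      px <- px[with_seed(derive_seed(seed, "pxsub", nrow(px)),
                         sample.int(nrow(px), max_pixels)), , drop = FALSE]
    px
  }))
  if (!nrow(fg_px)) stop("unfit model: no foreground pixels in any image")
  if (nrow(fg_px) > max_pixels)
    fg_px <- fg_px[with_seed(derive_seed(seed, "pxsub2"),
                             sample.int(nrow(fg_px), max_pixels)), ,
                   drop = FALSE]
  pixel_centers <- safe_kmeans(fg_px, n_pixel_types,
                               derive_seed(seed, "pxkm"))

  model <- structure(list(
    pixel_centers = pixel_centers, block_centers = NULL,
    params = list(block_size = block_size, n_types = n_types,
                  intensity_bounds = intensity_bounds,
                  fg_threshold = fg_threshold,
                  block_fg_frac = block_fg_frac, channels = channels),
    seed = seed), class = "block_model")

  ## stage 2: block types from per-block pixel-type compositions
  feats <- do.call(rbind, lapply(arrays, block_features, model = model))
  if (!nrow(feats)) stop("unfit model: no foreground blocks in any image")
  model$block_centers <- safe_kmeans(feats, n_types,
                                     derive_seed(seed, "blkkm"))
  model
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf(
    "block_model: %d block types, %d pixel types, block %d px, bounds [%g, %g], fg > %.2f\n",
    nrow(x$block_centers), nrow(x$pixel_centers), x$params$block_size,
    x$params$intensity_bounds[1], x$params$intensity_bounds[2],
    x$params$fg_threshold))
  invisible(x)
}

new_profile <- function(freq, weight) {
  structure(list(freq = freq, weight = weight), class = "block_profile")
}

#' Block-type frequency profile of one image
#'
#' Assigns every foreground block to its nearest block type and returns the
#' normalized frequency vector over the K block types, weighted by the
#' number of foreground blocks. An image with no foreground yields an
#' all-zero profile with weight 0.
#'
#' @param image an image (see [fit_block_model()]).
#' @param model a fitted [fit_block_model()].
#' @return object of class `block_profile`: `freq` (length K, sums to 1 when
#'   `weight > 0`) and `weight` (foreground block count).
#' @export
profile_image <- function(image, model) {
  stopifnot(inherits(model, "block_model"))
  a <- as_channel_array(image, model$params$channels)
  feats <- block_features(a, model)
  K <- nrow(model$block_centers)
  if (!nrow(feats)) return(new_profile(numeric(K), 0))
  types <- nearest_center(feats, model$block_centers)
  new_profile(as.numeric(tabulate(types, K)) / nrow(feats), nrow(feats))
}

#' @export
predict.block_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "image_stack") &&
      is.null(dim(newdata)))
    lapply(newdata, profile_image, model = object)
  else profile_image(newdata, object)
}

#' @export
print.block_profile <- function(x, ...) {
  cat(sprintf("block_profile: K = %d, weight = %g, top type = %d (%.2f)\n",
              length(x$freq), x$weight,
              if (x$weight > 0) which.max(x$freq) else NA,
              if (x$weight > 0) max(x$freq) else 0))
  invisible(x)
}

#' Grid of sub-image profiles (tissue-microarray-core emulation)
#'
#' Divides the image into `cell_px` x `cell_px` sub-images (edge cells keep
#' the truncated remainder; grid dimensions are `ceiling(dim / cell_px)`)
#' and profiles each cell. At 0.4619 um/px the default 1300 px cell spans
#' ~0.6 mm, the size of a tissue-microarray core.
#'
#' @param image an image.
#' @param model a fitted [fit_block_model()].
#' @param cell_px sub-image side, px.
#' @return object of class `profile_cube`: `profiles` (n_cells x K matrix,
#'   cells in column-major grid order), `weights`, `grid` (rows, cols) and
#'   `cells` (data.frame of grid coordinates).
#' @export
grid_subimages <- function(image, model, cell_px = 1300) {
  a <- as_channel_array(image, model$params$channels)
  h <- dim(a)[1]; w <- dim(a)[2]
  nr <- ceiling(h / cell_px); ncg <- ceiling(w / cell_px)
  K <- nrow(model$block_centers)
  cells <- expand.grid(row = seq_len(nr), col = seq_len(ncg))
  profiles <- matrix(0, nrow(cells), K)
  weights <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ys <- ((cells$row[i] - 1) * cell_px + 1):min(cells$row[i] * cell_px, h)
    xs <- ((cells$col[i] - 1) * cell_px + 1):min(cells$col[i] * cell_px, w)
    pr <- profile_image(a[ys, xs, , drop = FALSE], model)
    profiles[i, ] <- pr$freq
    weights[i] <- pr$weight
  }
  structure(list(profiles = profiles, weights = weights,
                 grid = c(rows = nr, cols = ncg), cells = cells,
                 cell_px = cell_px), class = "profile_cube")
}

#' @export
print.profile_cube <- function(x, ...) {
  cat(sprintf("profile_cube: %d x %d cells of %d px, K = %d, %d with tissue\n",
              x$grid[1], x$grid[2], x$cell_px, ncol(x$profiles),
              sum(x$weights > 0)))
  invisible(x)
}

#' Tissue-weighted aggregation of block profiles
#'
#' Weighted mean of profiles with weights proportional to the amount of
#' tissue (foreground block count), renormalized to sum to one.
#'
#' @param profiles a `profile_cube`, a list of `block_profile`s, or a
#'   numeric matrix (rows = profiles).
#' @param weights weights; defaults to the profiles' own tissue weights.
#' @return aggregated `block_profile` (weight = total weight).
#' @export
aggregate_profiles <- function(profiles, weights = NULL) {
  if (inherits(profiles, "profile_cube")) {
    if (is.null(weights)) weights <- profiles$weights
    profiles <- profiles$profiles
  } else if (is.list(profiles) && inherits(profiles[[1]], "block_profile")) {
    if (is.null(weights))
      weights <- vapply(profiles, `[[`, numeric(1), "weight")
    profiles <- do.call(rbind, lapply(profiles, `[[`, "freq"))
  }
  stopifnot(is.matrix(profiles), length(weights) == nrow(profiles))
  if (all(weights <= 0)) stop("undefined profile: all weights are zero")
  freq <- colSums(profiles * weights) / sum(weights)
  s <- sum(freq)
  new_profile(if (s > 0) freq / s else freq, sum(weights))
}
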