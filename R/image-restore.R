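## Artifact estimation and removal for IF section scans. The observation
## model is observed = (true + B) * S with a slowly varying additive
## background B and a multiplicative stripe profile S that is constant along
## y and periodic along x (default period 1560 px).

#' Additive-background / multiplicative-stripe artifact model
#'
#' @param B background field, same shape as the image (clamped at 0).
#' @param S stripe profile of length `period`, strictly positive, mean ~= 1
#'   (the overall scale is carried by B and the image).
#' @param period stripe period along x, px.
#' @return object of class `artifact_model`.
#' @export
artifact_model <- function(B, S, period = length(S)) {
  if (length(S) != period) stop("stripe profile length must equal the period")
  if (any(S <= 0)) stop("invalid artifact: stripe profile must be positive")
  if (abs(mean(S) - 1) > 0.1)
    stop("invalid artifact: stripe profile mean must be within 10% of 1")
  structure(list(B = pmax(B, 0), S = as.numeric(S),
                 period = as.integer(period)), class = "artifact_model")
}

#' @export
print.artifact_model <- function(x, ...) {
  cat(sprintf(
    "artifact_model: B %d x %d (mean %.1f), stripe period %d px (range %.3f-%.3f)\n",
    nrow(x$B), ncol(x$B), mean(x$B), x$period, min(x$S), max(x$S)))
  invisible(x)
}

# Tile a period-length stripe profile along x, truncating a fractional final
# period at the image edge.
tile_stripe <- function(S, width) {
  rep_len(S, width)
}

#' Coarse tissue mask for artifact estimation
#'
#' Otsu threshold on the channel itself followed by a generous dilation, so
#' that "non-tissue" pixels used for background/stripe estimation are safely
#' clear of tissue. Deliberately independent of the final cellular mask.
#'
#' @param x intensity matrix.
#' @param dilate_radius dilation radius (px) applied to the thresholded mask.
#' @return logical matrix, TRUE on (dilated) tissue.
#' @export
tissue_mask_otsu <- function(x, dilate_radius = 15) {
  rng <- range(x)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  xs <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  m <- xs > thr
  if (dilate_radius > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(2 * dilate_radius + 1, "disc"))
  m > 0
}

# Iterative harmonic (edge-free diffusion) infilling of NA cells in a small
# matrix: missing cells relax to the mean of their 4-neighbours while known
# cells stay fixed. This is the discrete smooth limit of Mumford-Shah style
# inpainting for a slowly varying field.
harmonic_infill <- function(M, tol = 1e-6, max_iter = 10000) {
  miss <- is.na(M)
  if (!any(miss)) return(M)
  if (all(miss)) stop("background inestimable: no tissue-free block")
  M[miss] <- mean(M[!miss])
  nr <- nrow(M); nc <- ncol(M)
  for (it in seq_len(max_iter)) {
    up <- rbind(M[1, , drop = FALSE], M[-nr, , drop = FALSE])
    dn <- rbind(M[-1, , drop = FALSE], M[nr, , drop = FALSE])
    lf <- cbind(M[, 1, drop = FALSE], M[, -nc, drop = FALSE])
    rt <- cbind(M[, -1, drop = FALSE], M[, nc, drop = FALSE])
    newv <- (up + dn + lf + rt) / 4
    delta <- max(abs(newv[miss] - M[miss]))
    M[miss] <- newv[miss]
    if (delta <= tol * max(abs(M))) break
  }
  M
}

# 1-D linear interpolation with linear (end-slope) extrapolation.
interp_extrap <- function(xs, v, xout) {
  if (length(xs) == 1) return(rep(v, length(xout)))
  lo <- v[1] - (v[2] - v[1]) / (xs[2] - xs[1]) * (xs[1] - min(xout, xs[1]))
  n <- length(xs)
  hi <- v[n] + (v[n] - v[n - 1]) / (xs[n] - xs[n - 1]) *
    (max(xout, xs[n]) - xs[n])
  approx(c(min(xout, xs[1]), xs, max(xout, xs[n]) + 1e-9),
         c(lo, v, hi), xout = xout)$y
}

# Bilinear interpolation from values on a rectangular (block-centre) grid up
# to pixel resolution, linearly extrapolated beyond the outer centres.
bilinear_upsample <- function(vals, centers_y, centers_x, h, w) {
  tmp <- if (length(centers_y) == 1)
    matrix(vals[1, ], h, length(centers_x), byrow = TRUE)
  else apply(vals, 2, function(v) interp_extrap(centers_y, v, seq_len(h)))
  if (length(centers_x) == 1) return(matrix(tmp[, 1], h, w))
  t(apply(tmp, 1, function(v) interp_extrap(centers_x, v, seq_len(w))))
}

# Block partition of 1..n into runs of `size` (final run truncated).
block_breaks <- function(n, size) {
  starts <- seq(1, n, by = size)
  ends <- pmin(starts + size - 1, n)
  list(starts = starts, ends = ends, centers = (starts + ends) / 2)
}

#' Estimate the additive background field
#'
#' Divides the image into large blocks (default 480 px tall and one stripe
#' period wide, so the mean-one stripe averages out within each block),
#' averages observed intensity in blocks containing no tissue, infills
#' tissue-covered blocks by smooth harmonic diffusion, and upsamples the
#' block grid to pixel resolution bilinearly.
#'
#' @param observed intensity matrix.
#' @param tissue_mask logical matrix, TRUE on tissue.
#' @param block_height block height (px).
#' @param block_width block width (px); default one stripe period.
#' @param period stripe period used for the default block width.
#' @return estimated background matrix `B`.
#' @export
estimate_background <- function(observed, tissue_mask, block_height = 480,
                                block_width = NULL, period = 1560) {
  stopifnot(all(dim(observed) == dim(tissue_mask)))
  if (is.null(block_width)) block_width <- period
  by <- block_breaks(nrow(observed), block_height)
  bx <- block_breaks(ncol(observed), block_width)
  nbr <- length(by$starts); nbc <- length(bx$starts)
  vals <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    ys <- by$starts[i]:by$ends[i]; xs <- bx$starts[j]:bx$ends[j]
    if (!any(tissue_mask[ys, xs]))
      vals[i, j] <- mean(observed[ys, xs])
  }
  if (all(is.na(vals)))
    stop("background inestimable: no tissue-free block")
  vals <- harmonic_infill(vals)
  bilinear_upsample(vals, by$centers, bx$centers,
                    nrow(observed), ncol(observed))
}

#' Estimate the periodic stripe profile
#'
#' For each phase in `[1, period]`, averages `observed / B` over the
#' non-tissue pixels whose column is congruent to that phase modulo the
#' period; empty phases are interpolated circularly from neighbours; the
#' profile is rescaled to mean one.
#'
#' @param observed intensity matrix.
#' @param B background field (strictly positive on used pixels).
#' @param tissue_mask logical matrix, TRUE on tissue.
#' @param period stripe period, px.
#' @return stripe profile of length `period`, mean 1.
#' @export
estimate_stripes <- function(observed, B, tissue_mask, period = 1560) {
  stopifnot(all(dim(observed) == dim(tissue_mask)),
            all(dim(observed) == dim(B)))
  keep <- !tissue_mask
  if (any(B[keep] <= 0)) stop("background must be positive on used pixels")
  ratio <- observed / B
  phase <- ((seq_len(ncol(observed)) - 1) %% period) + 1
  sums <- colSums(ratio * keep)
  cnts <- colSums(keep)
  S <- as.numeric(rowsum(sums, phase) / pmax(rowsum(cnts, phase), 1))
  have <- as.numeric(rowsum(cnts, phase)) > 0
  ph_idx <- sort(unique(phase))
  full <- rep(NA_real_, period)
  full[ph_idx] <- ifelse(have, S, NA_real_)
  if (!any(!is.na(full))) stop("stripe inestimable: all phases empty")
  if (any(is.na(full))) {             # circular interpolation of gaps
    idx <- which(!is.na(full))
    ext_x <- c(idx - period, idx, idx + period)
    ext_y <- rep(full[idx], 3)
    full[is.na(full)] <- approx(ext_x, ext_y, xout = which(is.na(full)))$y
  }
  full / mean(full)
}

#' Estimate the full artifact model of an image
#'
#' Background first (one-period-wide blocks make the mean-one stripe cancel),
#' then the stripe from `observed / B`. Optional refinement passes
#' re-estimate the background on the de-striped image with finer blocks
#' (once the stripe is divided out, block width is no longer tied to the
#' period), then re-estimate the stripe — markedly more accurate when the
#' image spans only a few stripe periods.
#'
#' @inheritParams estimate_background
#' @param refine number of refinement passes (0 = the plain two-step
#'   estimate).
#' @param refine_block_width block width (px) used in refinement passes.
#' @return an [artifact_model()].
#' @export
estimate_artifacts <- function(observed, tissue_mask = NULL,
                               block_height = 480, period = 1560,
                               refine = 6, refine_block_width = block_height) {
  if (is.null(tissue_mask)) tissue_mask <- tissue_mask_otsu(observed)
  B <- estimate_background(observed, tissue_mask, block_height,
                           period = period)
  S <- estimate_stripes(observed, B, tissue_mask, period)
  for (k in seq_len(refine)) {
    destriped <- observed / matrix(tile_stripe(S, ncol(observed)),
                                   nrow(observed), ncol(observed),
                                   byrow = TRUE)
    B <- estimate_background(destriped, tissue_mask, block_height,
                             block_width = refine_block_width)
    S <- estimate_stripes(observed, B, tissue_mask, period)
  }
  artifact_model(B = B, S = S, period = period)
}

#' Invert the artifact model
#'
#' Recovers `true = observed / S - B` elementwise, optionally clamping
#' negative intensities to zero (physical non-negativity).
#'
#' @param observed intensity matrix.
#' @param model an [artifact_model()].
#' @param clamp clamp negatives at 0 (default TRUE).
#' @return corrected intensity matrix.
#' @export
correct_image <- function(observed, model, clamp = TRUE) {
  stopifnot(inherits(model, "artifact_model"))
  if (!all(dim(model$B) == dim(observed)))
    stop("dimension mismatch between image and artifact model")
  S_row <- tile_stripe(model$S, ncol(observed))
  out <- observed / matrix(S_row, nrow(observed), ncol(observed),
                           byrow = TRUE) - model$B
  if (clamp) out <- pmax(out, 0)
  out
}

#' Rescale a DAPI image to the reference exposure time
#'
#' DAPI intensity varies linearly with exposure; each image is rescaled to an
#' effective exposure of `reference_ms` (125 ms).
#'
#' @param image intensity matrix.
#' @param exposure_ms actual exposure time, ms (> 0).
#' @param reference_ms target exposure, ms.
#' @return rescaled image.
#' @export
scale_dapi_exposure <- function(image, exposure_ms, reference_ms = 125) {
  if (is.null(exposure_ms) || is.na(exposure_ms) || exposure_ms <= 0)
    stop("missing or invalid exposure time")
  image * (reference_ms / exposure_ms)
}

#' Match intensity percentiles across replicate sections
#'
#' Each replicate section is mapped by the unique linear transform sending
#' its 25th/75th tissue-intensity percentiles to the across-section averages
#' of those percentiles, removing slide-to-slide technical variation while
#' preserving within-section contrast up to an affine map.
#'
#' @param sections list of >= 2 intensity matrices (replicate sections).
#' @param tissue_masks list of logical masks; percentiles are computed over
#'   tissue pixels only. Default: all pixels.
#' @param probs the two matched percentiles.
#' @return list with `sections` (transformed arrays), `transforms`
#'   (data.frame `gain`, `offset`, `p_low`, `p_high`) and `targets`.
#' @export
normalize_replicates <- function(sections, tissue_masks = NULL,
                                 probs = c(0.25, 0.75)) {
  if (length(sections) < 2) stop("need at least 2 replicate sections")
  if (is.null(tissue_masks))
    tissue_masks <- lapply(sections, function(s)
      matrix(TRUE, nrow(s), ncol(s)))
  pct <- t(vapply(seq_along(sections), function(i)
    quantile(sections[[i]][tissue_masks[[i]]], probs, names = FALSE),
    numeric(2)))
  if (any(pct[, 2] <= pct[, 1]))
    stop("degenerate contrast: p75 <= p25 in a section")
  targets <- colMeans(pct)
  gain <- (targets[2] - targets[1]) / (pct[, 2] - pct[, 1])
  offset <- targets[1] - gain * pct[, 1]
  out <- lapply(seq_along(sections), function(i)
    gain[i] * sections[[i]] + offset[i])
  list(sections = out,
       transforms = data.frame(gain = gain, offset = offset,
                               p_low = pct[, 1], p_high = pct[, 2]),
       targets = targets)
}
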