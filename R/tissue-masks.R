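## Cellular / stromal / tumor masks from DAPI and vimentin, and the mean
## tumor marker intensity statistic.

# Local Gaussian-weighted mean (normalized at borders, no reflection).
local_mean <- function(x, window) {
  if (window <= 1 || window %% 2 == 0) stop("window must be odd and > 1")
  gaussian_smooth(x, sigma = window / 4)
}

adaptive_threshold <- function(x, window, offset) {
  x > local_mean(x, window) * (1 + offset)
}

remove_small_objects <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Nuclear and cellular masks from the DAPI channel
#'
#' Nuclear pixels are those above a locally adaptive Gaussian-weighted mean
#' threshold of DAPI (speckle below `min_size` px removed); the cellular mask
#' is the morphological closing of the nuclear mask with a disc, filling the
#' area between nuclei.
#'
#' @param dapi DAPI intensity matrix.
#' @param window adaptive-threshold window, px (odd, > 1).
#' @param offset relative threshold offset: a pixel is nuclear when
#'   `dapi > local_mean * (1 + offset)`. Lowering `offset` never shrinks the
#'   nuclear mask.
#' @param closing_radius disc radius (px) of the closing; 0 = no closing.
#' @param min_size connected components smaller than this are dropped.
#' @return list with logical `nuclear` and `cellular` masks
#'   (`nuclear` is always a subset of `cellular`).
#' @export
cellular_mask <- function(dapi, window = 101, offset = 0.25, closing_radius = 10,
                          min_size = 20) {
  nuclear <- adaptive_threshold(dapi, window, offset)
  nuclear <- remove_small_objects(nuclear, min_size)
  cellular <- if (closing_radius > 0 && any(nuclear)) {
    cl <- EBImage::closing(nuclear * 1,
                           EBImage::makeBrush(2 * closing_radius + 1, "disc"))
    matrix(cl > 0, nrow(dapi), ncol(dapi)) | nuclear
  } else nuclear
  list(nuclear = nuclear, cellular = cellular)
}

#' Stromal mask from the vimentin channel
#'
#' Same adaptive-threshold + closing operation as [cellular_mask()], applied
#' to the stromal-specific marker.
#'
#' @param vimentin vimentin intensity matrix.
#' @inheritParams cellular_mask
#' @return logical stromal mask.
#' @export
stromal_mask <- function(vimentin, window = 101, offset = 0.25,
                         closing_radius = 10, min_size = 20) {
  cellular_mask(vimentin, window, offset, closing_radius, min_size)$cellular
}

#' Bundle tissue masks and derive the tumor mask
#'
#' The tumor mask is, by definition, the cellular region excluding stroma:
#' `tumor = cellular & !stromal`, exactly.
#'
#' @param cellular,stromal,nuclear logical masks of equal dimension.
#' @return object of class `mask_set` with `nuclear`, `cellular`, `stromal`,
#'   `tumor`.
#' @export
mask_set <- function(cellular, stromal, nuclear = cellular) {
  stopifnot(all(dim(cellular) == dim(stromal)),
            all(dim(cellular) == dim(nuclear)))
  structure(list(nuclear = nuclear, cellular = cellular, stromal = stromal,
                 tumor = cellular & !stromal), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  n <- length(x$cellular)
  cat(sprintf(
    "mask_set: %.1f%% nuclear, %.1f%% cellular, %.1f%% stromal, %.1f%% tumor\n",
    100 * mean(x$nuclear), 100 * mean(x$cellular), 100 * mean(x$stromal),
    100 * mean(x$tumor)))
  invisible(x)
}

#' Compute all masks of a section from its DAPI and vimentin channels
#'
#' @param stack an [image_stack()] containing `dapi_channel` and
#'   `stroma_channel`.
#' @param dapi_channel,stroma_channel channel names.
#' @param ... passed to [cellular_mask()] / [stromal_mask()].
#' @return a [mask_set()].
#' @export
compute_masks <- function(stack, dapi_channel = "DAPI",
                          stroma_channel = "VIM", ...) {
  stopifnot(inherits(stack, "image_stack"))
  cm <- cellular_mask(stack$data[, , dapi_channel], ...)
  st <- stromal_mask(stack$data[, , stroma_channel], ...)
  mask_set(cm$cellular, st, cm$nuclear)
}

#' Mean marker intensity over tumor pixels
#'
#' Arithmetic mean of the marker over the tumor mask; values outside the
#' tumor mask never influence the result. An empty tumor mask yields `NA`
#' (the statistic is undefined, not zero) with a warning.
#'
#' @param marker intensity matrix.
#' @param masks a [mask_set()] (or any list with a logical `tumor` element).
#' @return scalar mean intensity, or `NA_real_`.
#' @export
mean_tumor_intensity <- function(marker, masks) {
  tumor <- masks$tumor
  stopifnot(all(dim(marker) == dim(tumor)))
  if (!any(tumor)) {
    warning("empty tumor mask: mean tumor intensity undefined")
    return(NA_real_)
  }
  mean(marker[tumor])
}
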