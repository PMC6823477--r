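## Recursive multi-scale decomposition of biomarker pixel intensity across
## the nested hierarchy dataset > model > tumor > sector > image > region >
## microenvironment > cellular > subcellular, restricted to nuclear pixels.

#' Define the scale ladder of the decomposition
#'
#' Above-image levels are nested grouping columns of the cohort index;
#' within-image levels are Gaussian widths applied coarse-to-fine, with
#' `sigma = Inf` (the image mean over analyzed pixels) for the image level
#' and the residual after the finest width forming the subcellular level.
#'
#' @param levels_above ordered above-image grouping levels (coarse to fine);
#'   must be columns of the cohort index passed to [decompose_scales()].
#' @param sigmas named, strictly decreasing Gaussian widths in px. Default
#'   `c(image = Inf, region = 1000, microenvironment = 100, cellular = 10)`.
#'   May be empty to disable within-image levels.
#' @param pixel_size um/px, carried for reporting.
#' @return object of class `scale_ladder`.
#' @export
scale_ladder <- function(levels_above = c("model", "tumor", "sector"),
                         sigmas = c(image = Inf, region = 1000,
                                    microenvironment = 100, cellular = 10),
                         pixel_size = 0.4619) {
  if (length(sigmas)) {
    if (is.null(names(sigmas)) || any(!nzchar(names(sigmas))))
      stop("sigmas must be named")
    if (any(diff(sigmas) >= 0))
      stop("within-image widths must be strictly decreasing")
    if (any(sigmas <= 0)) stop("widths must be positive")
  }
  if (anyDuplicated(c(levels_above, names(sigmas))))
    stop("duplicate level names")
  structure(list(levels_above = levels_above, sigmas = sigmas,
                 pixel_size = pixel_size), class = "scale_ladder")
}

#' Decompose pixel intensity into additive per-scale contributions
#'
#' Starting from the grand mean over all analyzed pixels (the dataset
#' contribution), the residual is recursively averaged at increasingly finer
#' levels: above the image, each group's contribution is the simple
#' unweighted mean across its member images of the image-mean residual;
#' within the image, each level's contribution is the mask-normalized
#' Gaussian-weighted local mean of the residual at that level's width
#' (`sigma = Inf` reduces to the image mean over analyzed pixels). The final
#' residual is the subcellular contribution. By construction the
#' contributions sum exactly to the original intensity at every analyzed
#' pixel.
#'
#' @param images list of intensity matrices.
#' @param nuclear_masks list of logical masks of analyzed pixels, one per
#'   image.
#' @param index data.frame with one row per image holding the grouping
#'   columns named in `ladder$levels_above`.
#' @param ladder a [scale_ladder()].
#' @return object of class `scale_decomp`: per-image contribution lists
#'   (scalars for dataset/above-image levels, matrices within image), masks,
#'   originals and the scale names in order.
#' @export
decompose_scales <- function(images, nuclear_masks, index,
                             ladder = scale_ladder()) {
  stopifnot(inherits(ladder, "scale_ladder"),
            length(images) == length(nuclear_masks),
            length(images) == nrow(index))
  miss <- setdiff(ladder$levels_above, names(index))
  if (length(miss))
    stop("index lacks hierarchy columns: ", paste(miss, collapse = ", "))
  n <- length(images)
  npix <- vapply(nuclear_masks, sum, numeric(1))
  if (any(npix == 0))
    stop("image ", which(npix == 0)[1], " has no analyzed pixels")

  contribs <- replicate(n, list(), simplify = FALSE)
  resid <- lapply(seq_len(n), function(i) images[[i]])

  ## dataset: grand mean over all analyzed pixels
  tot <- sum(vapply(seq_len(n), function(i)
    sum(resid[[i]][nuclear_masks[[i]]]), numeric(1)))
  mu <- tot / sum(npix)
  for (i in seq_len(n)) {
    contribs[[i]]$dataset <- mu
    resid[[i]] <- resid[[i]] - mu
  }

  ## above-image levels: unweighted mean of member-image mean residuals
  for (li in seq_along(ladder$levels_above)) {
    lev <- ladder$levels_above[li]
    gid <- interaction(index[, ladder$levels_above[seq_len(li)], drop = FALSE],
                       drop = TRUE)
    for (gg in levels(gid)) {
      members <- which(gid == gg)
      if (!length(members))
        stop("empty group at level ", lev, ": ", gg)
      im_means <- vapply(members, function(i)
        mean(resid[[i]][nuclear_masks[[i]]]), numeric(1))
      gmean <- mean(im_means)
      for (i in members) {
        contribs[[i]][[lev]] <- gmean
        resid[[i]] <- resid[[i]] - gmean
      }
    }
  }

  ## within-image levels: masked Gaussian local means, coarse to fine
  for (si in seq_along(ladder$sigmas)) {
    lev <- names(ladder$sigmas)[si]
    sg <- ladder$sigmas[[si]]
    for (i in seq_len(n)) {
      sm <- gaussian_smooth(resid[[i]], sg, nuclear_masks[[i]])
      sm[is.na(sm)] <- 0
      contribs[[i]][[lev]] <- sm
      resid[[i]] <- resid[[i]] - sm
    }
  }

  for (i in seq_len(n)) contribs[[i]]$subcellular <- resid[[i]]
  structure(list(
    contributions = contribs, masks = nuclear_masks, images = images,
    index = index,
    scales = c("dataset", ladder$levels_above, names(ladder$sigmas),
               "subcellular"),
    ladder = ladder), class = "scale_decomp")
}

#' @export
print.scale_decomp <- function(x, ...) {
  cat(sprintf("scale_decomp: %d images, %d analyzed pixels, scales: %s\n",
              length(x$images),
              sum(vapply(x$masks, sum, numeric(1))),
              paste(x$scales, collapse = " > ")))
  invisible(x)
}

#' Variance attributed to each scale
#'
#' Population variance of each scale's contribution over all analyzed pixels
#' of the cohort, and its fraction of the total variance of the original
#' intensity. Fractions are not renormalized to sum to one (contributions
#' are not orthogonal); with zero total variance fractions are `NA`.
#'
#' @param decomp a [decompose_scales()] result.
#' @return data.frame with `scale`, `variance`, `fraction`.
#' @export
variance_table <- function(decomp) {
  stopifnot(inherits(decomp, "scale_decomp"))
  pool <- function(get) {
    unlist(lapply(seq_along(decomp$images), function(i) {
      v <- get(i)
      if (length(v) == 1) rep(v, sum(decomp$masks[[i]]))
      else v[decomp$masks[[i]]]
    }))
  }
  total <- pvar(pool(function(i) decomp$images[[i]]))
  vars <- vapply(decomp$scales, function(sc)
    pvar(pool(function(i) decomp$contributions[[i]][[sc]])), numeric(1))
  data.frame(scale = decomp$scales, variance = vars,
             fraction = if (total > 0) vars / total
                        else rep(NA_real_, length(vars)),
             row.names = NULL)
}

#' @export
summary.scale_decomp <- function(object, ...) {
  tab <- variance_table(object)
  class(tab) <- c("summary.scale_decomp", "data.frame")
  tab
}

#' Reconstruct intensity from the stored contributions of one image
#'
#' @param decomp a `scale_decomp`.
#' @param i image index.
#' @return matrix equal (at analyzed pixels) to the original intensity.
#' @export
reconstruct_image <- function(decomp, i) {
  Reduce(`+`, lapply(decomp$contributions[[i]], function(v)
    if (length(v) == 1) matrix(v, nrow(decomp$images[[i]]),
                               ncol(decomp$images[[i]])) else v))
}
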