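#' Describe a PDX cohort design
#'
#' The cohort hierarchy is model > tumor > sector > section image. A *sample*
#' is one sector of one tumor, the unit on which molecular assays run; each
#' sample contributes `sections_per_sample` replicate section images. The
#' default mirrors a 4-model x 3-tumor x 3-sector design with 3 sections,
#' imaged at 0.4619 um/px with a stripe period of 1560 px along x.
#'
#' @param n_models,tumors_per_model,sectors_per_tumor,sections_per_sample
#'   positive counts defining the hierarchy.
#' @param image_height,image_width image dimensions in pixels.
#' @param pixel_size physical pixel size, um/px.
#' @param channels ordered channel names; `"DAPI"` (nuclear) and `"VIM"`
#'   (stromal) are interpreted specially by the generator, any others are
#'   phenotype markers.
#' @param replicate_chips RNA sequencing replicate chips per sample.
#' @param stripe_period stripe artifact period along x, pixels.
#' @param seed base integer seed for all synthetic generation.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_models = 4, tumors_per_model = 3,
                          sectors_per_tumor = 3, sections_per_sample = 3,
                          image_height = 4096, image_width = 3120,
                          pixel_size = 0.4619,
                          channels = c("DAPI", "VIM", "MARKER"),
                          replicate_chips = 4, stripe_period = 1560,
                          seed = 1L) {
  counts <- c(n_models, tumors_per_model, sectors_per_tumor,
              sections_per_sample, replicate_chips)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all counts must be positive integers")
  if (image_height < 1 || image_width < 1)
    stop("invalid design: image dimensions must be positive")
  if (pixel_size <= 0) stop("invalid design: pixel_size must be > 0")
  structure(list(
    n_models = as.integer(n_models),
    tumors_per_model = as.integer(tumors_per_model),
    sectors_per_tumor = as.integer(sectors_per_tumor),
    sections_per_sample = as.integer(sections_per_sample),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_size = pixel_size, channels = channels,
    replicate_chips = as.integer(replicate_chips),
    stripe_period = as.integer(stripe_period), seed = as.integer(seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("PDX cohort design:",
      sprintf("%d models x %d tumors x %d sectors = %d samples",
              x$n_models, x$tumors_per_model, x$sectors_per_tumor,
              x$n_models * x$tumors_per_model * x$sectors_per_tumor),
      sprintf("%d sections/sample; images %d x %d px @ %.4f um/px",
              x$sections_per_sample, x$image_height, x$image_width,
              x$pixel_size),
      sprintf("channels: %s; stripe period %d px; seed %d",
              paste(x$channels, collapse = ", "), x$stripe_period, x$seed),
      sep = "\n  ")
  invisible(x)
}

#' Enumerate the sample units of a cohort design
#'
#' @param design a [cohort_design()].
#' @return data.frame with one row per sample (columns `model`, `tumor`,
#'   `sector`), lexicographically ordered; `nrow` equals the product of the
#'   three counts.
#' @examples
#' nrow(enumerate_samples(cohort_design(4, 3, 3)))  # 36 sample units
#' @export
enumerate_samples <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  g <- expand.grid(sector = seq_len(design$sectors_per_tumor),
                   tumor = seq_len(design$tumors_per_model),
                   model = seq_len(design$n_models))
  out <- g[order(g$model, g$tumor, g$sector), c("model", "tumor", "sector")]
  rownames(out) <- NULL
  out
}

#' Enumerate section images (samples x replicate sections)
#'
#' @inheritParams enumerate_samples
#' @return data.frame with columns `model`, `tumor`, `sector`, `section`.
#' @export
enumerate_sections <- function(design) {
  s <- enumerate_samples(design)
  out <- s[rep(seq_len(nrow(s)), each = design$sections_per_sample), ]
  out$section <- rep(seq_len(design$sections_per_sample), nrow(s))
  rownames(out) <- NULL
  out
}
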