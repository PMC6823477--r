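## Disk interfaces: per-channel 16-bit grayscale TIFF and the cohort index
## CSV mapping images to model/tumor/sector/section.

#' Write an image stack as per-channel 16-bit TIFFs
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_<channel>.tif`.
#' @return invisibly, the written file paths (named by channel).
#' @export
write_image_stack <- function(stack, dir, prefix = "image") {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, sprintf("%s_%s.tif", prefix,
                                           stack$channels)),
                    stack$channels)
  for (ch in stack$channels)
    tiff::writeTIFF(pmin(pmax(stack$data[, , ch], 0), 65535) / 65535,
                    paths[[ch]], bits.per.sample = 16)
  invisible(paths)
}

#' Read per-channel TIFFs into an image stack
#'
#' @param paths named character vector (names = channels) of 16-bit
#'   grayscale TIFF paths.
#' @param pixel_size um/px.
#' @param exposure_ms named per-channel exposures.
#' @return an [image_stack()] with intensities on the 0-65535 scale.
#' @export
read_image_stack <- function(paths, pixel_size = 0.4619,
                             exposure_ms = setNames(rep(125, length(paths)),
                                                    names(paths))) {
  stopifnot(!is.null(names(paths)))
  mats <- lapply(paths, function(p) tiff::readTIFF(p) * 65535)
  dat <- array(0, c(dim(mats[[1]]), length(mats)))
  for (i in seq_along(mats)) dat[, , i] <- mats[[i]]
  image_stack(dat, names(paths), pixel_size, exposure_ms)
}

#' Write a cohort index CSV
#'
#' Columns: `model, tumor, sector, section, channel, path, exposure_ms`.
#'
#' @param index section index ([enumerate_sections()]).
#' @param paths_by_section list (one element per index row) of named channel
#'   path vectors as returned by [write_image_stack()].
#' @param file output CSV path.
#' @param exposure_ms default exposure recorded per channel.
#' @return invisibly, the written data.frame.
#' @export
write_cohort_index <- function(index, paths_by_section, file,
                               exposure_ms = 125) {
  rows <- lapply(seq_len(nrow(index)), function(i) {
    p <- paths_by_section[[i]]
    data.frame(index[rep(i, length(p)),
                     c("model", "tumor", "sector", "section")],
               channel = names(p), path = unname(p),
               exposure_ms = exposure_ms)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}
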