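## Synthetic PDX cohort generator: tissue images with exact per-scale ground
## truth, molecular count/variant tables and growth curves. Every downstream
## stage of the pipeline has a parameter-recovery oracle against this module.

SCALE_NAMES <- c("dataset", "model", "tumor", "sector", "image",
                 "region", "microenvironment", "cellular", "subcellular")

#' Per-scale intensity effects for the image generator
#'
#' A phenotype channel is built additively: dataset mean + model offset +
#' tumor offset + sector offset + image (section) offset + smooth random
#' fields at the region/microenvironment/cellular characteristic lengths +
#' per-pixel (subcellular) noise. Each term is drawn with the standard
#' deviation given here, in raw intensity units of a 16-bit image.
#'
#' Default characteristic lengths (1000, 100, 10 px = 462, 46, 4.6 um at
#' 0.4619 um/px) deliberately match the Gaussian widths of the default
#' [scale_ladder()] so parameter recovery is well posed.
#'
#' @param mean dataset-level mean intensity.
#' @param sd named vector of standard deviations; names must be a subset of
#'   `model, tumor, sector, image, region, microenvironment, cellular,
#'   subcellular`. Missing names default to 0.
#' @param lengths named characteristic lengths (px) for the within-image
#'   fields `region`, `microenvironment`, `cellular`.
#' @return object of class `scale_effects`.
#' @export
scale_effects <- function(mean = 10000,
                          sd = c(model = 2000, tumor = 1000, sector = 800,
                                 image = 400, region = 800,
                                 microenvironment = 600, cellular = 500,
                                 subcellular = 400),
                          lengths = c(region = 1000, microenvironment = 100,
                                      cellular = 10)) {
  full <- setNames(numeric(8), SCALE_NAMES[-1])
  if (length(sd)) {
    bad <- setdiff(names(sd), names(full))
    if (length(bad)) stop("unknown scale names: ", paste(bad, collapse = ", "))
    full[names(sd)] <- sd
  }
  if (any(full < 0) || mean < 0) stop("effects must be non-negative")
  if (any(lengths <= 0)) stop("characteristic lengths must be positive")
  structure(list(mean = mean, sd = full,
                 lengths = lengths[c("region", "microenvironment", "cellular")]),
            class = "scale_effects")
}

#' Tissue geometry parameters for the image generator
#'
#' Nuclei are randomly placed discs with Gaussian intensity falloff inside an
#' elliptical tissue region; the stroma is a thresholded smooth random field.
#' Defaults give roughly 40% nuclear coverage of the tissue area and a ~25%
#' stromal fraction, with artifact-estimable tissue-free image corners.
#'
#' @param nucleus_radius,nucleus_radius_sd mean/SD of nucleus radius (px).
#' @param nuclear_coverage target fraction of tissue-ellipse pixels covered
#'   by nuclei.
#' @param dapi_amplitude,dapi_amplitude_sd peak DAPI intensity per nucleus.
#' @param background,noise_sd off-tissue baseline intensity and per-pixel
#'   Gaussian noise SD (all channels).
#' @param stroma_sigma smoothing length (px) of the stromal field.
#' @param stroma_frac stromal fraction of the tissue area.
#' @param vim_amplitude vimentin intensity added on stroma.
#' @param tissue_axes_frac ellipse semi-axes as a fraction of the half image
#'   dimensions.
#' @return list of class `tissue_geometry`.
#' @export
tissue_geometry <- function(nucleus_radius = 8, nucleus_radius_sd = 1.5,
                            nuclear_coverage = 0.4, dapi_amplitude = 28000,
                            dapi_amplitude_sd = 3000, background = 150,
                            noise_sd = 60, stroma_sigma = 100,
                            stroma_frac = 0.25, vim_amplitude = 22000,
                            tissue_axes_frac = 0.75) {
  structure(as.list(environment()), class = "tissue_geometry")
}

#' A multi-channel image stack
#'
#' @param data numeric array `height x width x channels`.
#' @param channels channel names.
#' @param pixel_size um/px.
#' @param exposure_ms named per-channel exposure times (ms).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, channels, pixel_size = 0.4619,
                        exposure_ms = setNames(rep(125, length(channels)),
                                               channels)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(channels))
  dimnames(data)[[3]] <- channels
  structure(list(data = data, channels = channels, pixel_size = pixel_size,
                 exposure_ms = exposure_ms), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, channels [%s], %.4f um/px\n",
              d[1], d[2], paste(x$channels, collapse = ", "), x$pixel_size))
  invisible(x)
}

# Offsets for the above-image scales of one section key, reproducible per
# group: every image of a model sees the same model offset, etc.
group_offsets <- function(key, design, effects) {
  s <- design$seed
  draw <- function(sdv, ...) {
    if (sdv == 0) return(0)
    with_seed(derive_seed(s, ...), rnorm(1, 0, sdv))
  }
  c(model  = draw(effects$sd[["model"]], "off-model", key[["model"]]),
    tumor  = draw(effects$sd[["tumor"]], "off-tumor", key[["model"]],
                  key[["tumor"]]),
    sector = draw(effects$sd[["sector"]], "off-sector", key[["model"]],
                  key[["tumor"]], key[["sector"]]),
    image  = draw(effects$sd[["image"]], "off-image", key[["model"]],
                  key[["tumor"]], key[["sector"]], key[["section"]]))
}

#' Generate one synthetic section image with ground truth
#'
#' Builds an artifact-free multi-channel image for one section of the cohort:
#' a DAPI channel of blob-like nuclei on a dark background, a vimentin
#' channel marking contiguous stromal regions, and phenotype channels
#' composed additively from per-scale contributions drawn with the standard
#' deviations in `effects`. Fully reproducible per `(design$seed, key)`.
#'
#' @param key named vector/list with `model`, `tumor`, `sector`, `section`.
#' @param design a [cohort_design()].
#' @param effects a [scale_effects()].
#' @param geometry a [tissue_geometry()].
#' @return list with `image` (an [image_stack()], intensities clipped to
#'   \[0, 65535\]) and `truth`: nuclear/stromal/tissue masks, and per
#'   phenotype channel the list of per-scale contributions (scalars for the
#'   above-image scales, matrices within image). For every channel the sum of
#'   stored contributions equals the artifact-free channel exactly (clipping
#'   is absorbed into the subcellular residual).
#' @export
generate_tissue_image <- function(key, design, effects = scale_effects(),
                                  geometry = tissue_geometry()) {
  stopifnot(inherits(design, "cohort_design"))
  key <- as.list(key)
  h <- design$image_height; w <- design$image_width
  g <- geometry
  ktag <- unlist(key[c("model", "tumor", "sector", "section")])

  with_seed(derive_seed(design$seed, "geom", ktag), {
    yc <- (h + 1) / 2; xc <- (w + 1) / 2
    ay <- g$tissue_axes_frac * h / 2; ax <- g$tissue_axes_frac * w / 2
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    tissue <- ((yy - yc) / ay)^2 + ((xx - xc) / ax)^2 <= 1

    ## nuclei: discs with Gaussian falloff, centers uniform in the ellipse
    r0 <- g$nucleus_radius
    n_nuc <- max(1L, round(g$nuclear_coverage * sum(tissue) /
                             (pi * r0^2) * 1.3))
    th <- runif(n_nuc, 0, 2 * pi); rr <- sqrt(runif(n_nuc))
    cy <- yc + rr * ay * sin(th); cx <- xc + rr * ax * cos(th)
    rad <- pmax(2, rnorm(n_nuc, r0, g$nucleus_radius_sd))
    amp <- pmax(0, rnorm(n_nuc, g$dapi_amplitude, g$dapi_amplitude_sd))
    dapi <- matrix(0, h, w); nuc <- matrix(FALSE, h, w)
    for (i in seq_len(n_nuc)) {
      ri <- rad[i]; e <- ceiling(2 * ri)
      ys <- max(1, floor(cy[i] - e)):min(h, ceiling(cy[i] + e))
      xs <- max(1, floor(cx[i] - e)):min(w, ceiling(cx[i] + e))
      d2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
      dapi[ys, xs] <- dapi[ys, xs] + amp[i] * exp(-d2 / (2 * (ri / 2)^2))
      nuc[ys, xs] <- nuc[ys, xs] | (d2 <= ri^2)
    }
    nuc <- nuc & tissue
    dapi <- dapi * tissue

    ## stroma: thresholded smooth field inside the tissue ellipse
    sfield <- smooth_field(h, w, min(g$stroma_sigma, min(h, w) / 3))
    thr <- quantile(sfield[tissue], 1 - g$stroma_frac)
    stroma <- (sfield > thr) & tissue
    vim_soft <- gaussian_smooth(stroma * 1, 3)
    vim <- g$vim_amplitude * vim_soft * tissue
  })

  nchan <- length(design$channels)
  dat <- array(0, c(h, w, nchan))
  contribs <- list()
  off <- group_offsets(key, design, effects)
  for (ci in seq_len(nchan)) {
    ch <- design$channels[ci]
    noise <- with_seed(derive_seed(design$seed, "noise", ch, ktag),
                       matrix(rnorm(h * w, 0, g$noise_sd), h, w))
    if (ch == "DAPI") {
      dat[, , ci] <- pmin(pmax(dapi + g$background + noise, 0), 65535)
    } else if (ch == "VIM") {
      dat[, , ci] <- pmin(pmax(vim + g$background + noise, 0), 65535)
    } else {
      cc <- list(dataset = effects$mean, model = off[["model"]],
                 tumor = off[["tumor"]], sector = off[["sector"]],
                 image = off[["image"]])
      for (lev in c("region", "microenvironment", "cellular")) {
        sdv <- effects$sd[[lev]]
        cc[[lev]] <- if (sdv == 0) matrix(0, h, w) else
          with_seed(derive_seed(design$seed, "field", lev, ch, ktag),
                    sdv * smooth_field(h, w, effects$lengths[[lev]]))
      }
      cc$subcellular <- with_seed(
        derive_seed(design$seed, "subcell", ch, ktag),
        matrix(rnorm(h * w, 0, effects$sd[["subcellular"]]), h, w))
      total <- Reduce(`+`, cc)
      truth_ch <- pmin(pmax(total * tissue + g$background * !tissue + noise,
                            0), 65535)
      # absorb tissue windowing/clipping/noise into the subcellular residual
      # so the stored contributions sum to the channel exactly
      cc$subcellular <- truth_ch - (total - cc$subcellular)
      contribs[[ch]] <- cc
      dat[, , ci] <- truth_ch
    }
  }
  list(image = image_stack(dat, design$channels, design$pixel_size),
       truth = list(key = key, nuclear_mask = nuc, stromal_mask = stroma,
                    tissue_mask = tissue, contributions = contribs))
}

#' Draw a random additive-background / periodic-stripe artifact model
#'
#' The background B is a positive slowly varying field (offset + plane +
#' large-scale smooth noise); the stripe S is a mean-one strictly positive
#' two-harmonic profile of length `period`.
#'
#' @param height,width image dimensions (px).
#' @param period stripe period along x (px).
#' @param b_mean,b_slope,b_smooth_amp background mean, plane amplitude and
#'   smooth-field amplitude (intensity units).
#' @param s_amp stripe modulation amplitudes (fundamental, first overtone).
#' @param seed integer seed.
#' @return an [artifact_model()].
#' @export
random_artifact_model <- function(height, width, period = 1560,
                                  b_mean = 1500, b_slope = 300,
                                  b_smooth_amp = 200, s_amp = c(0.12, 0.05),
                                  seed = 1L) {
  with_seed(derive_seed(seed, "artifact", height, width), {
    yy <- matrix(seq_len(height) / height - 0.5, height, width)
    xx <- matrix(rep(seq_len(width) / width - 0.5, each = height),
                 height, width)
    B <- b_mean + b_slope * (runif(1, -1, 1) * yy + runif(1, -1, 1) * xx) +
      b_smooth_amp * smooth_field(height, width, max(height, width) / 2)
    B <- pmax(B, 0)
    ph <- runif(2, 0, 2 * pi)
    phase <- seq_len(period) / period
    S <- 1 + s_amp[1] * sin(2 * pi * phase + ph[1]) +
      s_amp[2] * sin(4 * pi * phase + ph[2])
    S <- S / mean(S)
  })
  artifact_model(B = B, S = S, period = period)
}

#' Apply the observation artifact model to a true image
#'
#' Implements the forward model `observed = (true + B) * S`, with the stripe
#' profile constant along y and tiled periodically along x (truncated at the
#' image edge for fractional periods).
#'
#' @param truth numeric matrix (one channel) of artifact-free intensities.
#' @param model an [artifact_model()]; `model$B` must match `dim(truth)`.
#' @return observed intensity matrix.
#' @export
apply_artifacts <- function(truth, model) {
  stopifnot(inherits(model, "artifact_model"), is.matrix(truth))
  if (!all(dim(model$B) == dim(truth)))
    stop("background field dimensions do not match the image")
  S_row <- tile_stripe(model$S, ncol(truth))
  (truth + model$B) * matrix(S_row, nrow(truth), ncol(truth), byrow = TRUE)
}

#' Simulate hierarchical RNA count chips and a DNA variant table
#'
#' Counts follow a negative-binomial model whose log-mean carries gene,
#' model, tumor and sector effects; each sample is sequenced on
#' `design$replicate_chips` replicate chips. The variant table designates a
#' subset of loci as mutant in pure mouse; their allele frequencies co-vary
#' across samples through a per-sample mouse-contamination factor.
#'
#' @param design a [cohort_design()].
#' @param n_features number of genes (>= 10).
#' @param base_mean baseline expected count per gene.
#' @param sd_model,sd_tumor,sd_sector SDs of log-scale group effects.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param n_loci,mouse_frac variant loci count and mouse-mutant fraction.
#' @param contamination per-sample mouse fraction in \[0,1\]; default drawn
#'   Uniform(0.02, 0.3).
#' @param seed integer seed (default `design$seed`).
#' @return list with `counts` (features x samples x chips array), `samples`
#'   (the sample index), `variants` (long table `locus, sample, vaf,
#'   mouse_mutant`), `mouse_loci`, `contamination`, and a synthetic
#'   per-sample `qc` metrics table.
#' @export
generate_counts <- function(design, n_features = 200, base_mean = 50,
                            sd_model = 1, sd_tumor = 0.4, sd_sector = 0.2,
                            dispersion = 0.1, n_loci = 40, mouse_frac = 0.3,
                            contamination = NULL, seed = design$seed) {
  if (n_features < 10) stop("need at least 10 features")
  samples <- enumerate_samples(design)
  ns <- nrow(samples); nc <- design$replicate_chips
  with_seed(derive_seed(seed, "counts"), {
    gene <- rnorm(n_features, 0, 0.5)
    em <- matrix(rnorm(n_features * design$n_models, 0, sd_model),
                 n_features)
    et <- matrix(rnorm(n_features * design$n_models * design$tumors_per_model,
                       0, sd_tumor), n_features)
    es <- matrix(rnorm(n_features * ns, 0, sd_sector), n_features)
    counts <- array(0L, c(n_features, ns, nc))
    for (s in seq_len(ns)) {
      mi <- samples$model[s]
      ti <- (samples$model[s] - 1) * design$tumors_per_model + samples$tumor[s]
      mu <- exp(log(base_mean) + gene + em[, mi] + et[, ti] + es[, s])
      for (ch in seq_len(nc)) {
        counts[, s, ch] <- if (dispersion > 0)
          rnbinom(n_features, mu = mu, size = 1 / dispersion)
        else rpois(n_features, mu)
      }
    }
    if (is.null(contamination)) contamination <- runif(ns, 0.02, 0.3)
    stopifnot(length(contamination) == ns)
    n_mouse <- round(mouse_frac * n_loci)
    mouse_loci <- seq_len(n_mouse)
    u <- runif(n_loci, 0.6, 1)            # mouse VAF scale per locus
    hv <- runif(n_loci, 0.2, 0.6)         # human base VAF per locus
    vaf <- matrix(0, n_loci, ns)
    for (l in seq_len(n_loci)) {
      vaf[l, ] <- if (l %in% mouse_loci)
        pmin(pmax(contamination * u[l] + rnorm(ns, 0, 0.01), 0), 1)
      else pmin(pmax(hv[l] + rnorm(ns, 0, 0.03), 0), 1)
    }
    variants <- data.frame(
      locus = rep(sprintf("locus%03d", seq_len(n_loci)), ns),
      sample = rep(seq_len(ns), each = n_loci),
      vaf = as.vector(vaf),
      mouse_mutant = rep(seq_len(n_loci) %in% mouse_loci, ns))
    qc <- data.frame(
      sample = seq_len(ns),
      mapped_reads = round(exp(rnorm(ns, log(3e6), 0.6))),
      pct_on_amplicon = pmin(100, rnorm(ns, 92, 4)),
      mean_read_length = rnorm(ns, 108, 6),
      pct_genes_mapped = pmin(100, rnorm(ns, 52, 5)))
  })
  list(counts = counts, samples = samples, variants = variants,
       mouse_loci = sprintf("locus%03d", mouse_loci),
       contamination = contamination, qc = qc)
}

#' Simulate an exponential tumor growth curve
#'
#' Volumes follow `V0 * 2^(t / doubling)` with multiplicative lognormal
#' noise, measured twice weekly until the true volume reaches
#' `stop_volume` (~600 mm3 endpoint).
#'
#' @param true_doubling_days true doubling time (> 0), days.
#' @param v0 implantation volume, mm3.
#' @param noise_sd SD of the lognormal measurement noise (log scale).
#' @param interval_days measurement spacing (twice weekly = 3.5 d).
#' @param stop_volume harvest threshold on the true volume, mm3.
#' @param seed integer seed.
#' @return data.frame with `days` and `volume`.
#' @export
generate_growth_curve <- function(true_doubling_days, v0 = 100,
                                  noise_sd = 0.1, interval_days = 3.5,
                                  stop_volume = 600, seed = 1L) {
  if (true_doubling_days <= 0) stop("doubling time must be positive")
  n_max <- ceiling(true_doubling_days * log2(stop_volume / v0) /
                     interval_days) + 1
  days <- seq(0, by = interval_days, length.out = max(1, n_max))
  vol_true <- v0 * 2^(days / true_doubling_days)
  keep <- seq_len(if (any(vol_true >= stop_volume))
    which(vol_true >= stop_volume)[1] else length(days))
  days <- days[keep]; vol_true <- vol_true[keep]
  noise <- with_seed(derive_seed(seed, "growth"),
                     exp(rnorm(length(days), 0, noise_sd)))
  data.frame(days = days, volume = vol_true * noise)
}

#' Simulate all section images of a cohort
#'
#' Convenience wrapper running [generate_tissue_image()] for every row of
#' [enumerate_sections()].
#'
#' @inheritParams generate_tissue_image
#' @return list with `index` (section data.frame) and `records` (list of
#'   per-section `generate_tissue_image()` results, in index order).
#' @export
simulate_cohort_images <- function(design, effects = scale_effects(),
                                   geometry = tissue_geometry()) {
  idx <- enumerate_sections(design)
  recs <- lapply(seq_len(nrow(idx)), function(i)
    generate_tissue_image(as.list(idx[i, ]), design, effects, geometry))
  list(index = idx, records = recs)
}
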