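# Shared fixtures, built once per test run and cached. Image sizes are kept
# small (a few hundred px) with correspondingly scaled stripe periods and
# Gaussian widths so the full pipeline runs in seconds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# One 400 x 360 px section with a 120 px stripe period.
small_design <- function(seed = 7) {
  cohort_design(1, 1, 1, 1, image_height = 400, image_width = 360,
                channels = c("DAPI", "VIM", "M1"), stripe_period = 120,
                seed = seed)
}

small_geometry <- function() {
  tissue_geometry(nucleus_radius = 6, stroma_sigma = 30)
}

small_effects <- function() {
  scale_effects(mean = 8000,
                sd = c(region = 300, microenvironment = 200, cellular = 150,
                       subcellular = 100),
                lengths = c(region = 80, microenvironment = 20, cellular = 5))
}

fixture_section <- function() {
  fixture("section", function()
    generate_tissue_image(list(model = 1, tumor = 1, sector = 1, section = 1),
                          small_design(), small_effects(), small_geometry()))
}

fixture_artifact <- function() {
  fixture("artifact", function() {
    sec <- fixture_section()
    am <- random_artifact_model(400, 360, period = 120, seed = 5)
    list(truth = sec$image$data[, , "M1"], model = am,
         observed = apply_artifacts(sec$image$data[, , "M1"], am),
         tissue = sec$truth$tissue_mask)
  })
}

# Sector-heterogeneous model for sampling tests: 3 tumors x 3 sectors x 2
# sections at 240 px, sub-images of 80 px. Sector effects dominate, with a
# smaller per-section effect, so restricted strategies stay biased.
sampling_design <- function() {
  cohort_design(1, 3, 3, 2, image_height = 240, image_width = 240,
                channels = c("DAPI", "VIM", "M1"), stripe_period = 120,
                seed = 21)
}

sampling_effects <- function() {
  scale_effects(mean = 12000,
                sd = c(sector = 6000, image = 1500, microenvironment = 1500,
                       subcellular = 500),
                lengths = c(region = 60, microenvironment = 20, cellular = 4))
}

fixture_sampling_cohort <- function() {
  fixture("sampling_cohort", function() {
    sim <- simulate_cohort_images(sampling_design(), sampling_effects(),
                                  tissue_geometry(nucleus_radius = 5,
                                                  stroma_sigma = 25,
                                                  tissue_axes_frac = 0.95))
    images <- lapply(sim$records, `[[`, "image")
    bm <- fit_block_model(images, channels = c("DAPI", "M1"),
                          block_size = 8, n_types = 30, seed = 11)
    pool <- build_subimage_pool(images, sim$index, bm, cell_px = 80)
    list(sim = sim, images = images, model = bm, pool = pool)
  })
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Two-channel texture images for block-profile oracles: texture A has
# channel 1 high / channel 2 low, texture B the reverse.
texture_image <- function(h, w, which = c("A", "B"), seed = 1) {
  which <- match.arg(which)
  with_seed(seed, {
    hi <- matrix(25000 + rnorm(h * w, 0, 800), h, w)
    lo <- matrix(12000 + rnorm(h * w, 0, 800), h, w)
  })
  a <- array(0, c(h, w, 2))
  if (which == "A") { a[, , 1] <- hi; a[, , 2] <- lo }
  else { a[, , 1] <- lo; a[, , 2] <- hi }
  a
}
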