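# A reduced ladder with Gaussian widths (Inf, 64, 16, 4) px on small images
# is used throughout; the generator injects fields at matching lengths.

toy_ladder <- function() {
  scale_ladder(levels_above = c("tumor", "sector"),
               sigmas = c(image = Inf, region = 64, microenvironment = 16,
                          cellular = 4))
}

toy_cohort <- function(sd, seed = 31, n_tumors = 2, n_sectors = 3,
                       n_sections = 3, px = 192) {
  d <- cohort_design(1, n_tumors, n_sectors, n_sections,
                     image_height = px, image_width = px,
                     channels = c("DAPI", "VIM", "M1"), seed = seed)
  eff <- scale_effects(mean = 8000, sd = sd,
                       lengths = c(region = 64, microenvironment = 16,
                                   cellular = 4))
  sim <- simulate_cohort_images(d, eff,
                                tissue_geometry(nucleus_radius = 5,
                                                stroma_sigma = 20))
  list(images = lapply(sim$records, function(r) r$image$data[, , "M1"]),
       masks = lapply(sim$records, function(r) r$truth$nuclear_mask),
       index = sim$index)
}

test_that("constant input yields only a dataset contribution", {
  imgs <- list(matrix(7, 40, 40), matrix(7, 40, 40))
  msks <- list(matrix(TRUE, 40, 40), matrix(TRUE, 40, 40))
  idx <- data.frame(tumor = c(1, 2), sector = c(1, 1))
  dec <- decompose_scales(imgs, msks, idx, toy_ladder())
  expect_equal(dec$contributions[[1]]$dataset, 7)
  for (sc in setdiff(dec$scales, "dataset"))
    expect_lt(max(abs(dec$contributions[[1]][[sc]])), 1e-9)
  tab <- variance_table(dec)
  expect_equal(tab$variance, rep(0, nrow(tab)))
  expect_true(all(is.na(tab$fraction)))   # zero total variance
})

test_that("contributions reconstruct the original exactly (any input)", {
  set.seed(8)
  imgs <- lapply(1:6, function(i) matrix(rnorm(64 * 64, 100, 20), 64, 64))
  msks <- lapply(1:6, function(i) matrix(runif(64 * 64) > 0.4, 64, 64))
  idx <- expand.grid(sector = 1:3, tumor = 1:2)[, c("tumor", "sector")]
  dec <- decompose_scales(imgs, msks, idx,
                          scale_ladder(c("tumor", "sector"),
                                       c(image = Inf, region = 16,
                                         cellular = 3)))
  for (i in 1:6) {
    rec <- reconstruct_image(dec, i)
    err <- abs(rec - imgs[[i]])[msks[[i]]] / max(abs(imgs[[i]]))
    expect_lt(max(err), 1e-6)
  }
})

test_that("variance injected at the sector scale is attributed to it", {
  co <- toy_cohort(c(sector = 1500, subcellular = 150), px = 96,
                   n_sections = 3)
  dec <- decompose_scales(co$images, co$masks, co$index, toy_ladder())
  tab <- variance_table(dec)
  sector_var <- tab$variance[tab$scale == "sector"]
  expect_equal(tab$scale[which.max(tab$variance)], "sector")
  expect_gt(sector_var / sum(tab$variance), 0.4)
})

test_that("variance injected at the microenvironment scale dominates", {
  co <- toy_cohort(c(microenvironment = 1200, subcellular = 150),
                   n_tumors = 1, n_sectors = 2, n_sections = 2, px = 192)
  dec <- decompose_scales(co$images, co$masks, co$index, toy_ladder())
  tab <- variance_table(dec)
  expect_equal(tab$scale[which.max(tab$variance)], "microenvironment")
})

test_that("attributed variance grows with the injected SD", {
  vars <- vapply(c(400, 800, 1600), function(s) {
    co <- toy_cohort(c(sector = s, subcellular = 100), px = 64,
                     n_sections = 2, seed = 17)
    dec <- decompose_scales(co$images, co$masks, co$index, toy_ladder())
    tab <- variance_table(dec)
    tab$variance[tab$scale == "sector"]
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("group-mean decomposition matches nested ANOVA on a toy instance", {
  # two groups of one image each, within-image levels disabled
  set.seed(5)
  imgs <- list(matrix(rnorm(100, 10, 2), 10, 10),
               matrix(rnorm(100, 14, 2), 10, 10))
  msks <- list(matrix(TRUE, 10, 10), matrix(TRUE, 10, 10))
  idx <- data.frame(group = c(1, 2))
  dec <- decompose_scales(imgs, msks, idx,
                          scale_ladder("group", sigmas = numeric(0)))
  tab <- variance_table(dec)

  x <- c(imgs[[1]], imgs[[2]])
  g <- rep(1:2, each = 100)
  grand <- mean(x)
  gm <- tapply(x, g, mean)
  ss_between <- sum((gm[g] - grand)^2) / length(x)
  ss_within <- sum((x - gm[g])^2) / length(x)
  expect_equal(tab$variance[tab$scale == "group"], unname(ss_between),
               tolerance = 1e-10)
  expect_equal(tab$variance[tab$scale == "subcellular"], unname(ss_within),
               tolerance = 1e-10)
  expect_equal(sum(tab$variance[-1]), pvar <- mean((x - grand)^2),
               tolerance = 1e-10)   # orthogonal split in this special case
})

test_that("single image with no within-image levels puts all variance in residual", {
  set.seed(6)
  img <- matrix(rnorm(400, 50, 5), 20, 20)
  dec <- decompose_scales(list(img), list(matrix(TRUE, 20, 20)),
                          data.frame(group = 1),
                          scale_ladder("group", sigmas = numeric(0)))
  tab <- variance_table(dec)
  expect_equal(tab$variance[tab$scale == "group"], 0)
  expect_equal(tab$fraction[tab$scale == "subcellular"], 1, tolerance = 1e-10)
})

test_that("missing hierarchy columns and empty masks are rejected", {
  img <- matrix(1, 8, 8)
  expect_error(decompose_scales(list(img), list(matrix(TRUE, 8, 8)),
                                data.frame(a = 1), toy_ladder()),
               "hierarchy")
  expect_error(decompose_scales(list(img), list(matrix(FALSE, 8, 8)),
                                data.frame(tumor = 1, sector = 1),
                                toy_ladder()),
               "analyzed pixels")
  expect_error(scale_ladder(sigmas = c(a = 10, b = 20)), "decreasing")
})
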