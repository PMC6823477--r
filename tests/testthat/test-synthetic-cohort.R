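test_that("sample enumeration follows the product rule and ordering", {
  d <- cohort_design(4, 3, 3, image_height = 64, image_width = 64)
  s <- enumerate_samples(d)
  expect_equal(nrow(s), 36)
  expect_false(any(duplicated(s)))
  expect_equal(s, s[order(s$model, s$tumor, s$sector), ],
               ignore_attr = TRUE)

  expect_equal(nrow(enumerate_samples(cohort_design(1, 1, 1))), 1)
  s2 <- enumerate_samples(cohort_design(2, 3, 1))
  expect_equal(nrow(s2), 6)
  expect_equal(as.vector(table(s2$model)), c(3L, 3L))

  expect_error(cohort_design(0, 3, 3), "invalid design")
  expect_error(cohort_design(4, -1, 3), "invalid design")
})

test_that("image generation is deterministic and additively exact", {
  r1 <- fixture_section()
  r2 <- generate_tissue_image(list(model = 1, tumor = 1, sector = 1,
                                   section = 1),
                              small_design(), small_effects(),
                              small_geometry())
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$truth$nuclear_mask, r2$truth$nuclear_mask)

  cc <- r1$truth$contributions[["M1"]]
  total <- Reduce(`+`, lapply(cc, function(v)
    if (length(v) == 1) matrix(v, 400, 360) else v))
  expect_lt(max(abs(total - r1$image$data[, , "M1"])), 1e-8)

  expect_true(is.logical(r1$truth$nuclear_mask))
  expect_true(is.logical(r1$truth$stromal_mask))
  expect_true(all(r1$image$data >= 0 & r1$image$data <= 65535))
})

test_that("degenerate effects give a constant phenotype channel", {
  d <- cohort_design(1, 1, 1, 1, image_height = 80, image_width = 80,
                     channels = c("DAPI", "VIM", "M1"), seed = 3)
  eff <- scale_effects(mean = 5000, sd = c(subcellular = 0))
  g <- tissue_geometry(noise_sd = 0, nucleus_radius = 5, stroma_sigma = 15)
  r <- generate_tissue_image(list(model = 1, tumor = 1, sector = 1,
                                  section = 1), d, eff, g)
  m1 <- r$image$data[, , "M1"]
  expect_equal(unique(as.vector(m1[r$truth$tissue_mask])), 5000)
})

test_that("sector-level variance appears between, not within, sectors", {
  d <- cohort_design(1, 1, 3, 6, image_height = 48, image_width = 48,
                     channels = c("DAPI", "VIM", "M1"), seed = 13)
  eff <- scale_effects(mean = 5000, sd = c(sector = 1000, subcellular = 0))
  g <- tissue_geometry(noise_sd = 0, nucleus_radius = 4, stroma_sigma = 10)
  idx <- enumerate_sections(d)
  means <- vapply(seq_len(nrow(idx)), function(i) {
    r <- generate_tissue_image(as.list(idx[i, ]), d, eff, g)
    mean(r$image$data[, , "M1"][r$truth$tissue_mask])
  }, numeric(1))
  by_sector <- split(means, idx$sector)
  # sections within a sector share the mean; sectors differ
  expect_true(all(vapply(by_sector, function(v) diff(range(v)), 1) < 1e-9))
  expect_gt(diff(range(vapply(by_sector, mean, 1))), 100)
})

test_that("artifact application matches the elementwise forward model", {
  tr <- matrix(runif(40 * 36, 0, 1000), 40, 36)
  # identity artifacts
  id <- artifact_model(B = matrix(0, 40, 36), S = rep(1, 12))
  expect_equal(apply_artifacts(tr, id), tr)
  # pure artifact image
  am <- artifact_model(B = matrix(50, 40, 36),
                       S = 1 + 0.1 * sin(2 * pi * (1:12) / 12))
  expect_equal(apply_artifacts(matrix(0, 40, 36), am),
               (matrix(0, 40, 36) + am$B) *
                 matrix(rep_len(am$S, 36), 40, 36, byrow = TRUE))
  # brute-force elementwise oracle
  obs <- apply_artifacts(tr, am)
  oracle <- matrix(0, 40, 36)
  for (i in 1:40) for (j in 1:36)
    oracle[i, j] <- (tr[i, j] + am$B[i, j]) * am$S[((j - 1) %% 12) + 1]
  expect_equal(obs, oracle)
  # invalid stripe rejected
  expect_error(artifact_model(B = matrix(0, 4, 4), S = c(1, -1, 1, 1)),
               "positive")
})

test_that("count generation respects contamination and hierarchy", {
  d <- cohort_design(2, 1, 2, 1, image_height = 32, image_width = 32,
                     replicate_chips = 4, seed = 5)
  g0 <- generate_counts(d, n_features = 50, contamination = rep(0, 4))
  mouse_rows <- g0$variants$mouse_mutant
  expect_true(all(g0$variants$vaf[mouse_rows] <= 0.05))

  g1 <- generate_counts(d, n_features = 50,
                        contamination = c(0.1, 0.3, 0.1, 0.3))
  v <- g1$variants[g1$variants$mouse_mutant, ]
  m1 <- tapply(v$vaf, v$sample, mean)
  expect_gt(m1[["2"]], m1[["1"]])
  expect_gt(m1[["4"]], m1[["3"]])

  expect_error(generate_counts(d, n_features = 5), "10 features")

  # zero dispersion, near-equal means: chips agree up to Poisson noise
  g2 <- generate_counts(d, n_features = 1000, base_mean = 500,
                        sd_model = 0, sd_tumor = 0, sd_sector = 0,
                        dispersion = 0)
  rpm <- rpm_normalize(g2$counts)
  cv <- apply(rpm$rpm[, 1, ], 1, sd) / rowMeans(rpm$rpm[, 1, ])
  expect_lt(median(cv), 3 / sqrt(500))   # ~Poisson CV at mean 500
})

test_that("growth curves follow the exponential model and recover doubling", {
  # closed form, no noise
  gc0 <- generate_growth_curve(1, v0 = 100, noise_sd = 0, interval_days = 1)
  expect_equal(gc0$volume, 100 * 2^gc0$days)
  # stopping rule: start at the endpoint
  gc1 <- generate_growth_curve(3, v0 = 600, noise_sd = 0.05)
  expect_equal(nrow(gc1), 1)
  expect_error(generate_growth_curve(-1), "positive")

  # recovery: mean fitted doubling within 10% of truth at noise SD 0.05
  fits <- vapply(1:500, function(i) {
    gc <- generate_growth_curve(5, v0 = 100, noise_sd = 0.05, seed = i)
    fit_growth(gc$days, gc$volume)$doubling_time
  }, numeric(1))
  expect_lt(abs(mean(fits) - 5) / 5, 0.1)
})
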