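# All sampling tests share one sector-heterogeneous synthetic model
# (3 tumors x 3 sectors x 2 sections, 9 sub-images per section).

test_that("the true profile is the aggregate over all sub-images", {
  fx <- fixture_sampling_cohort()
  tp <- true_profile(fx$pool)
  direct <- aggregate_profiles(fx$pool$profiles, fx$pool$weights)
  expect_equal(tp$freq, direct$freq)
  expect_equal(sum(tp$freq), 1)
  # permutation invariance over sub-image order
  perm <- with_seed(1, sample(nrow(fx$pool$meta)))
  shuffled <- fx$pool
  shuffled$meta <- shuffled$meta[perm, ]
  shuffled$profiles <- shuffled$profiles[perm, , drop = FALSE]
  shuffled$weights <- shuffled$weights[perm]
  expect_equal(true_profile(shuffled)$freq, tp$freq)
})

test_that("goodness uses strict mean absolute deviation below tolerance", {
  k30a <- c(1, rep(0, 29)); k30b <- c(0, 1, rep(0, 28))
  expect_true(is_good(k30a, k30a))                      # deviation 0
  expect_false(is_good(k30a, k30b))                     # 2/30 ~ 0.067
  # boundary: deviation exactly tol is not good
  p <- rep(1 / 30, 30)
  q <- p + rep(c(0.01, -0.01), 15)
  expect_false(is_good(q, p, tol = 0.01))
  expect_true(is_good(q, p, tol = 0.010001))
  # zero-weight sample profile never counts
  zero <- structure(list(freq = rep(0, 30), weight = 0),
                    class = "block_profile")
  expect_false(is_good(zero, p))
})

test_that("strategy pools respect the hierarchy (provenance audit)", {
  fx <- fixture_sampling_cohort()
  m <- fx$pool$meta
  sector_spans_tumors <- FALSE
  for (r in 1:200) {
    rs <- run_strategy(fx$pool, "within_section", 6, seed = r)
    u <- unique(m[rs$drawn, c("tumor", "sector", "section")])
    expect_equal(nrow(u), 1)
    rt <- run_strategy(fx$pool, "within_tumor", 6, seed = r)
    expect_equal(length(unique(m$tumor[rt$drawn])), 1)
    rsec <- run_strategy(fx$pool, "within_sector", 6, seed = r)
    expect_equal(length(unique(m$sector[rsec$drawn])), 1)
    if (length(unique(m$tumor[rsec$drawn])) > 1) sector_spans_tumors <- TRUE
  }
  # within-sector draws may span multiple tumors
  expect_true(sector_spans_tumors)
})

test_that("exhaustive within-model sampling is always good", {
  fx <- fixture_sampling_cohort()
  n_all <- nrow(fx$pool$meta)
  rs <- run_strategy(fx$pool, "within_model", n_all, seed = 1)
  expect_equal(rs$profile$freq, true_profile(fx$pool)$freq,
               tolerance = 1e-12)
  expect_equal(confidence(fx$pool, "within_model", n_all, runs = 20), 1)
})

test_that("a homogeneous model gives confidence 1 for every strategy", {
  prof <- matrix(rep(c(0.5, 0.5, rep(0, 28)), 12), 12, 30, byrow = TRUE)
  meta <- expand.grid(section = 1:2, sector = 1:2, tumor = 1:3)
  meta$model <- 1; meta$cell <- 1
  pool <- structure(list(meta = meta, profiles = prof,
                         weights = rep(10, 12)), class = "subimage_pool")
  for (st in c("within_model", "within_tumor", "within_sector",
               "within_sample", "within_section"))
    expect_equal(confidence(pool, st, 1, runs = 50), 1)
})

test_that("restricted strategies cannot beat model-wide sampling", {
  fx <- fixture_sampling_cohort()
  tp <- true_profile(fx$pool)
  for (n in c(10, 30)) {
    c_model <- confidence(fx$pool, "within_model", n, runs = 400,
                          truth = tp, seed = 5)
    c_sector <- confidence(fx$pool, "within_sector", n, runs = 400,
                           truth = tp, seed = 5)
    c_section <- confidence(fx$pool, "within_section", n, runs = 400,
                            truth = tp, seed = 5)
    mc <- 3 * sqrt(0.25 / 400)   # generous MC margin
    expect_gte(c_model + mc, c_sector)
    expect_gte(c_sector + mc, c_section)
  }
})

test_that("confidence curves average refits and expose the saturation level", {
  fx <- fixture_sampling_cohort()
  cc <- confidence_curve(fx$pool, strategies = c("within_model",
                                                 "within_section"),
                         n_grid = c(5, 162), runs = 100, refits = 1,
                         seed = 9)
  # refits = 1 on a static pool reduces to confidence()
  expect_equal(cc$confidence[cc$strategy == "within_model" & cc$n == 5],
               confidence(fx$pool, "within_model", 5, runs = 100,
                          seed = derive_seed(9, "conf", 1)))
  # exhaustive within-model draw is always good
  expect_equal(cc$confidence[cc$strategy == "within_model" & cc$n == 162], 1)
  # saturation confidence is the maximum over the curve
  sat <- saturation_confidence(cc)
  expect_equal(sat[["within_model"]],
               max(cc$confidence[cc$strategy == "within_model"]))

  # curves averaged over refits stay in [0, 1] and non-decreasing in n for
  # within_model (up to MC error)
  wm <- cc$confidence[cc$strategy == "within_model"]
  expect_true(all(diff(wm) >= -0.05))
})

test_that("refit averaging draws a fresh pool per refit seed", {
  mk_pool <- function(p1) {
    meta <- expand.grid(section = 1:2, sector = 1:2, tumor = 1:2)
    meta$model <- 1; meta$cell <- 1
    prof <- matrix(rep(c(p1, 1 - p1, rep(0, 28)), 8), 8, 30, byrow = TRUE)
    structure(list(meta = meta, profiles = prof, weights = rep(5, 8)),
              class = "subimage_pool")
  }
  calls <- 0
  pool_fn <- function(refit_seed) { calls <<- calls + 1; mk_pool(0.4) }
  cc <- confidence_curve(pool_fn, strategies = "within_model", n_grid = 2,
                         runs = 10, refits = 3, seed = 2)
  expect_equal(calls, 3)
  # homogeneous pools: every refit reaches confidence 1
  expect_equal(cc$confidence, 1)
})
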