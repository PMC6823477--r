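## Sampling-design analysis: how confidently does a set of sub-images
## (tissue-microarray-style cores) capture a PDX model's full phenotypic
## heterogeneity, under five nested sampling strategies?

SAMPLING_STRATEGIES <- c("within_model", "within_tumor", "within_sector",
                         "within_sample", "within_section")

#' Build the sub-image pool of a model from profiled section images
#'
#' Grids every section image into sub-images, profiles each, and assembles
#' the pool used by the sampling strategies. Sub-images with zero tissue
#' weight carry no profile and are excluded.
#'
#' @param images list of images (one per section).
#' @param index data.frame with one row per image: `model`, `tumor`,
#'   `sector`, `section`.
#' @param model a fitted [fit_block_model()].
#' @param cell_px sub-image side, px.
#' @return object of class `subimage_pool`: `meta` (provenance of each
#'   sub-image), `profiles` (n x K), `weights`.
#' @export
build_subimage_pool <- function(images, index, model, cell_px = 1300) {
  stopifnot(length(images) == nrow(index))
  metas <- list(); profs <- list(); wts <- list()
  for (i in seq_len(nrow(index))) {
    cube <- grid_subimages(images[[i]], model, cell_px)
    keep <- cube$weights > 0
    if (!any(keep)) next
    m <- index[rep(i, sum(keep)), c("model", "tumor", "sector", "section")]
    m$cell <- which(keep)
    metas[[length(metas) + 1]] <- m
    profs[[length(profs) + 1]] <- cube$profiles[keep, , drop = FALSE]
    wts[[length(wts) + 1]] <- cube$weights[keep]
  }
  if (!length(metas)) stop("empty pool: no sub-image has tissue")
  meta <- do.call(rbind, metas); rownames(meta) <- NULL
  structure(list(meta = meta, profiles = do.call(rbind, profs),
                 weights = unlist(wts)), class = "subimage_pool")
}

#' @export
print.subimage_pool <- function(x, ...) {
  cat(sprintf(
    "subimage_pool: %d sub-images (%d tumors x %d sectors), K = %d\n",
    nrow(x$meta), length(unique(x$meta$tumor)),
    length(unique(x$meta$sector)), ncol(x$profiles)))
  invisible(x)
}

#' True heterogeneity profile of a model
#'
#' Tissue-weighted aggregate over every sub-image of the model (all replicate
#' tumors, sectors and sections).
#'
#' @param pool a [build_subimage_pool()].
#' @return aggregated `block_profile`.
#' @export
true_profile <- function(pool) {
  stopifnot(inherits(pool, "subimage_pool"))
  aggregate_profiles(pool$profiles, pool$weights)
}

#' Does a sample profile capture the true heterogeneity?
#'
#' A sample is "good" when the mean absolute deviation across the K block
#' types between sample and true profile is strictly below `tol`. A
#' zero-weight sample profile never counts as good.
#'
#' @param sample_profile,true_profile `block_profile`s (or numeric vectors)
#'   of equal length.
#' @param tol deviation tolerance (default 0.01).
#' @return logical.
#' @export
is_good <- function(sample_profile, true_profile, tol = 0.01) {
  wt <- 1
  if (inherits(sample_profile, "block_profile")) {
    wt <- sample_profile$weight; sample_profile <- sample_profile$freq
  }
  if (inherits(true_profile, "block_profile"))
    true_profile <- true_profile$freq
  stopifnot(length(sample_profile) == length(true_profile))
  if (wt <= 0) return(FALSE)
  mean(abs(sample_profile - true_profile)) < tol
}

strategy_pool_indices <- function(pool, strategy, seed) {
  m <- pool$meta
  pick <- function(keys) {
    u <- unique(keys)
    sel <- u[with_seed(derive_seed(seed, "unit"),
                       sample.int(length(u), 1))]
    which(keys == sel)
  }
  switch(strategy,
    within_model   = seq_len(nrow(m)),
    within_tumor   = pick(m$tumor),
    within_sector  = pick(m$sector),
    within_sample  = pick(paste(m$tumor, m$sector)),
    within_section = pick(paste(m$tumor, m$sector, m$section)),
    stop("unknown strategy: ", strategy))
}

#' One sampling run of a strategy
#'
#' Selects the strategy's sampling unit uniformly at random where the rule
#' requires (e.g. one tumor for `within_tumor`), draws `n` sub-images
#' uniformly without replacement from the permitted pool (with replacement
#' when the pool holds fewer than `n`), and aggregates them tissue-weighted.
#'
#' @param pool a [build_subimage_pool()] of one model.
#' @param strategy one of `within_model`, `within_tumor`, `within_sector`,
#'   `within_sample`, `within_section`.
#' @param n sub-images per run.
#' @param seed run seed.
#' @return list with `profile` (aggregated `block_profile`) and `drawn`
#'   (pool row indices, for provenance audits).
#' @export
run_strategy <- function(pool, strategy, n, seed = 1L) {
  stopifnot(inherits(pool, "subimage_pool"), n >= 1)
  idx <- strategy_pool_indices(pool, strategy, seed)
  if (!length(idx)) stop("empty pool for strategy ", strategy)
  drawn <- if (n == length(idx)) idx
  else if (length(idx) == 1) rep(idx, n)
  else with_seed(derive_seed(seed, "draw"),
                 sample(idx, n, replace = n > length(idx)))
  pr <- aggregate_profiles(pool$profiles[drawn, , drop = FALSE],
                           pool$weights[drawn])
  list(profile = pr, drawn = drawn)
}

#' Monte-Carlo sampling confidence
#'
#' Fraction of `runs` independent sampling runs whose aggregated profile is
#' a good match (see [is_good()]) to the model's true profile.
#'
#' @inheritParams run_strategy
#' @param runs sampling runs (default 1000).
#' @param tol deviation tolerance for [is_good()].
#' @param truth reference profile; default [true_profile()] of the pool.
#' @param seed base seed; run `r` uses the substream `(seed, n, r)`, shared
#'   across strategies so curves are paired.
#' @return confidence in \[0, 1\].
#' @export
confidence <- function(pool, strategy, n, runs = 1000, tol = 0.01,
                       truth = NULL, seed = 1L) {
  if (is.null(truth)) truth <- true_profile(pool)
  good <- vapply(seq_len(runs), function(r) {
    rs <- run_strategy(pool, strategy, n, derive_seed(seed, "run", n, r))
    is_good(rs$profile, truth, tol)
  }, logical(1))
  mean(good)
}

#' Confidence curves over n, averaged across block-model refits
#'
#' For each strategy and each `n`, computes [confidence()] and averages it
#' over `refits` independent refits of the block model (each refit seed
#' produces its own pool via `pool_fn`), absorbing clustering-seed
#' variability.
#'
#' @param pool_fn either a static [build_subimage_pool()] (used for every
#'   refit) or `function(refit_seed)` returning a pool.
#' @param strategies character vector of strategies.
#' @param n_grid values of n.
#' @param runs,tol,seed as in [confidence()].
#' @param refits number of block-model refits averaged (default 40).
#' @return object of class `confidence_curve`: data.frame `strategy`, `n`,
#'   `confidence`, `se` (binomial Monte-Carlo standard error).
#' @export
confidence_curve <- function(pool_fn, strategies = SAMPLING_STRATEGIES,
                             n_grid = c(1, 2, 5, 10, 20, 50), runs = 1000,
                             tol = 0.01, refits = 40, seed = 1L) {
  static <- inherits(pool_fn, "subimage_pool")
  rows <- list()
  for (rf in seq_len(refits)) {
    pool <- if (static) pool_fn else pool_fn(derive_seed(seed, "refit", rf))
    truth <- true_profile(pool)
    for (st in strategies) for (n in n_grid) {
      cf <- confidence(pool, st, n, runs, tol, truth,
                       seed = derive_seed(seed, "conf", rf))
      rows[[length(rows) + 1]] <- data.frame(strategy = st, n = n,
                                             refit = rf, confidence = cf)
    }
  }
  all <- do.call(rbind, rows)
  agg <- aggregate(confidence ~ strategy + n, all, mean)
  agg <- agg[order(match(agg$strategy, strategies), agg$n), ]
  agg$se <- sqrt(pmax(agg$confidence * (1 - agg$confidence), 0.25 / runs) /
                   (runs * refits))
  rownames(agg) <- NULL
  structure(agg, class = c("confidence_curve", "data.frame"),
            runs = runs, refits = refits, tol = tol)
}

#' Saturation confidence of a curve
#'
#' The saturation (highest) confidence reached by each strategy over the
#' evaluated n grid.
#'
#' @param curve a [confidence_curve()].
#' @return named numeric vector, one entry per strategy.
#' @export
saturation_confidence <- function(curve) {
  stopifnot(inherits(curve, "confidence_curve"))
  vapply(split(curve$confidence, curve$strategy), max, numeric(1))
}

#' @export
plot.confidence_curve <- function(x, ...) {
  sts <- unique(x$strategy)
  cols <- hcl.colors(length(sts), "Dark 3")
  plot.default(range(x$n), c(0, 1), type = "n", xlab = "sub-images (n)",
               ylab = "confidence", ...)
  for (i in seq_along(sts)) {
    d <- x[x$strategy == sts[i], ]
    lines(d$n, d$confidence, col = cols[i], lwd = 2, type = "b", pch = 16)
  }
  legend("bottomright", legend = sts, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
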