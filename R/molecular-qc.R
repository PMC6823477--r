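## Tabular side-pipeline: sequencing QC gates, RPM normalization with
## replicate-chip averaging, mouse-variant exclusion, spike-in flagging,
## growth-rate estimation and scale-stratified profile correlations.

#' DNA sequencing sample QC gate
#'
#' Pass requires strictly more than 1e6 mapped reads AND strictly more than
#' 85% of reads mapped to the amplicon.
#'
#' @param mapped_reads,pct_on_amplicon per-sample metrics (vectors allowed).
#' @return logical pass/fail; missing metrics fail.
#' @export
dna_qc <- function(mapped_reads, pct_on_amplicon) {
  ok <- mapped_reads > 1e6 & pct_on_amplicon > 85
  ok[is.na(ok)] <- FALSE
  ok
}

#' RNA sequencing sample QC gate
#'
#' Pass requires mean mapped read length strictly above 100 bases AND
#' strictly more than 45% of genes with mapped reads.
#'
#' @param mean_read_length,pct_genes_mapped per-sample metrics.
#' @return logical pass/fail; missing metrics fail.
#' @export
rna_qc <- function(mean_read_length, pct_genes_mapped) {
  ok <- mean_read_length > 100 & pct_genes_mapped > 45
  ok[is.na(ok)] <- FALSE
  ok
}

#' RPM-normalize replicate chips and average per sample
#'
#' Each chip's counts are scaled so its total equals one million reads
#' (reads per million); the reported expression per sample is the arithmetic
#' mean of the RPM values across replicate chips.
#'
#' @param counts features x chips matrix (one sample), or a features x
#'   samples x chips array.
#' @return for a matrix: list with `rpm` (features x chips, each column
#'   summing to 1e6) and `expression` (per-feature chip average); for an
#'   array: list with `rpm` array and `expression` features x samples
#'   matrix.
#' @examples
#' rpm_normalize(matrix(c(1, 1, 2), 3, 1))$rpm  # 250000, 250000, 500000
#' @export
rpm_normalize <- function(counts) {
  norm_mat <- function(m, label = "") {
    tot <- colSums(m)
    if (any(tot <= 0))
      stop("zero-total chip: ", paste0(label, which(tot <= 0), collapse = ", "))
    rpm <- sweep(m, 2, tot, "/") * 1e6
    list(rpm = rpm, expression = rowMeans(rpm))
  }
  if (is.matrix(counts)) return(norm_mat(counts, "chip "))
  stopifnot(length(dim(counts)) == 3)
  rpm <- counts * 0
  expr <- matrix(0, dim(counts)[1], dim(counts)[2])
  for (s in seq_len(dim(counts)[2])) {
    r <- norm_mat(counts[, s, ], sprintf("sample %d chip ", s))
    rpm[, s, ] <- r$rpm
    expr[, s] <- r$expression
  }
  list(rpm = rpm, expression = expr)
}

#' Drop variant loci called mutant in pure mouse
#'
#' Loci with pure-mouse mutation calls are candidate false positives driven
#' by residual mouse DNA (their allele frequencies co-vary with the sample's
#' mouse contamination) and are removed entirely; all other rows are
#' untouched.
#'
#' @param variants data.frame with at least `locus` and logical
#'   `mouse_mutant` columns.
#' @return filtered data.frame.
#' @export
filter_mouse_variants <- function(variants) {
  stopifnot(all(c("locus", "mouse_mutant") %in% names(variants)))
  mouse_loci <- unique(variants$locus[variants$mouse_mutant])
  out <- variants[!(variants$locus %in% mouse_loci), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag genes affected by a mouse RNA spike-in
#'
#' For each non-low expressed gene, computes the relative difference
#' statistic `2 * (x - y) / (x + y)` between expression without (`x`) and
#' with (`y`) the spike-in. A gene is flagged when the absolute statistic
#' exceeds `cutoff`; both signed exceedances are also reported.
#'
#' @param x,y expression (e.g. RPM) without / with spike-in.
#' @param cutoff flagging threshold (default 0.5).
#' @param min_expression "non-low" filter: genes with pair mean at or below
#'   this (or with `x + y = 0`) are excluded.
#' @return data.frame with `statistic`, `flagged` (|stat| > cutoff),
#'   `flagged_up` (stat > cutoff), `flagged_down` (stat < -cutoff), and
#'   `used` marking genes that passed the expression filter.
#' @export
spike_in_flag <- function(x, y, cutoff = 0.5, min_expression = 10) {
  stopifnot(length(x) == length(y))
  used <- (x + y) > 0 & (x + y) / 2 > min_expression
  stat <- rep(NA_real_, length(x))
  stat[used] <- 2 * (x[used] - y[used]) / (x[used] + y[used])
  data.frame(statistic = stat,
             flagged = !is.na(stat) & abs(stat) > cutoff,
             flagged_up = !is.na(stat) & stat > cutoff,
             flagged_down = !is.na(stat) & stat < -cutoff,
             used = used)
}

#' Fit an exponential growth model to a tumor volume curve
#'
#' Ordinary least squares of log volume on days; the doubling time is
#' `log(2) / slope` (undefined, `NA`, for non-positive slopes).
#'
#' @param days,volumes measurement times (days) and volumes (> 0).
#' @return object of class `growth_fit` with `slope` (per day),
#'   `intercept`, `doubling_time` (days) and the underlying `lm` fit.
#' @examples
#' fit_growth(0:6, 100 * 2^(0:6))  # doubling time 1 day
#' @export
fit_growth <- function(days, volumes) {
  stopifnot(length(days) == length(volumes))
  if (length(days) < 2) stop("need at least 2 time points")
  if (any(volumes <= 0)) stop("volumes must be positive")
  fit <- lm(log(volumes) ~ days)
  slope <- unname(coef(fit)[2])
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 doubling_time = if (slope > 0) log(2) / slope else NA_real_,
                 fit = fit), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: slope %.4f /day, doubling time %s days\n",
              x$slope, if (is.na(x$doubling_time)) "undefined"
              else sprintf("%.2f", x$doubling_time)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    doubling_time = object$doubling_time)
}

#' One-way ANOVA of doubling times across models
#'
#' Classical one-way ANOVA of per-tumor doubling times with the PDX model as
#' the grouping variable.
#'
#' @param doubling_times numeric vector.
#' @param model_labels grouping factor (>= 2 groups).
#' @return list with `F`, `p_value`, `df` and the `aov` fit. Zero
#'   within-group variance with distinct means is degenerate: `F = Inf`,
#'   `p_value = 0`, with a warning.
#' @export
anova_doubling <- function(doubling_times, model_labels) {
  model_labels <- factor(model_labels)
  if (nlevels(model_labels) < 2) stop("need at least 2 groups")
  if (length(doubling_times) <= nlevels(model_labels))
    stop("no residual degrees of freedom")
  fit <- aov(doubling_times ~ model_labels)
  tab <- suppressWarnings(anova(fit))   # degeneracy re-diagnosed below
  Fv <- tab[["F value"]][1]; pv <- tab[["Pr(>F)"]][1]
  ssb <- tab[["Sum Sq"]][1]; ssw <- tab[["Sum Sq"]][2]
  tot <- ssb + ssw
  if (tot <= 0 || ssb <= 1e-12 * tot) {          # no between-group signal
    Fv <- 0; pv <- 1
  } else if (ssw <= 1e-12 * tot) {               # zero within-group variance
    warning("zero within-group variance: F is degenerate (infinite)")
    Fv <- Inf; pv <- 0
  }
  list(F = Fv, p_value = pv, df = tab$Df, fit = fit)
}

#' Mean pairwise sample correlation at a hierarchy level
#'
#' Readouts (features) are z-score normalized across all samples (constant
#' readouts removed); the statistic is the mean Pearson correlation over all
#' sample pairs sharing the given level of the hierarchy (`"dataset"` = all
#' pairs, `"model"` = same model, `"tumor"` = same model and tumor).
#'
#' @param profiles features x samples numeric matrix.
#' @param hierarchy data.frame with one row per sample (`model`, `tumor`,
#'   ... columns).
#' @param level `"dataset"`, `"model"`, or `"tumor"`.
#' @return mean pairwise Pearson r (`NA` if no qualifying pair).
#' @export
correlation_by_scale <- function(profiles, hierarchy,
                                 level = c("model", "tumor", "dataset")) {
  level <- match.arg(level)
  stopifnot(ncol(profiles) == nrow(hierarchy))
  keep <- apply(profiles, 1, sd) > 0
  z <- t(scale(t(profiles[keep, , drop = FALSE])))
  if (nrow(z) < 2) stop("fewer than 2 varying readouts")
  grp <- switch(level,
    dataset = rep(1, ncol(profiles)),
    model = hierarchy$model,
    tumor = paste(hierarchy$model, hierarchy$tumor))
  cors <- c()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    cm <- cor(z[, idx, drop = FALSE])
    cors <- c(cors, cm[upper.tri(cm)])
  }
  if (!length(cors)) return(NA_real_)
  mean(cors)
}
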