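# Inference of changes in compositional noise versus diversity between two
# categories of focal adhesions. Both noise and diversity inflate the
# coefficient of variation (CV) of component densities, but they move the
# pairwise correlations in opposite directions: shared diversity raises
# r-squared while independent binding noise lowers it. The signs of
# delta-log(CV) and delta-r-squared therefore disentangle the two, with the
# SEM across datasets guarding each sign.

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values Numeric vector, n >= 2, positive mean.
#' @return CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stopf("CV undefined for non-positive mean")
  sd(values) / m
}

# Vectorized, NA-tolerant column CVs; NA where undefined.
col_cv <- function(mat) {
  m <- colMeans(mat, na.rm = TRUE)
  s <- apply(mat, 2, sd, na.rm = TRUE)
  ifelse(m > 0, s / m, NA_real_)
}

col_fano <- function(mat) {
  m <- colMeans(mat, na.rm = TRUE)
  v <- apply(mat, 2, var, na.rm = TRUE)
  ifelse(m > 0, v / m, NA_real_)
}

#' Pairwise Pearson r and r-squared between component columns
#'
#' @param x Numeric matrix (adhesions x components) or an
#'   [fa_density_table()].
#' @return List with symmetric `r` and `r2` matrices (unit diagonal).
#'   Pairs involving a zero-variance column are `NA` and flagged with a
#'   warning.
#' @export
pairwise_r2 <- function(x) {
  mat <- if (inherits(x, "fa_density_table")) fa_density_matrix(x) else as.matrix(x)
  if (nrow(mat) < 3) stopf("pairwise r2 needs >= 3 adhesions")
  sds <- apply(mat, 2, sd)
  r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  bad <- which(sds == 0 | is.na(sds))
  if (length(bad)) {
    warning(sprintf("zero-variance component(s) flagged undefined: %s",
                    paste(colnames(mat)[bad], collapse = ", ")), call. = FALSE)
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  diag(r) <- 1
  list(r = r, r2 = r * r)
}

# Shared engine for the per-dataset, per-feature delta statistics.
# stat_fun maps a matrix to a named per-feature vector; delta_fun combines
# the category-1 and category-2 vectors into per-feature deltas.
delta_engine <- function(mats1, mats2, min_n, stat_fun, delta_fun, measure) {
  if (length(mats1) != length(mats2)) {
    stopf("category lists must cover the same datasets")
  }
  n1 <- vapply(mats1, nrow, 0L)
  n2 <- vapply(mats2, nrow, 0L)
  keep <- n1 >= min_n & n2 >= min_n
  if (!any(keep)) {
    stopf("no dataset has >= %d adhesions in both categories", min_n)
  }
  vals <- lapply(which(keep), function(d) {
    delta_fun(stat_fun(mats1[[d]]), stat_fun(mats2[[d]]))
  })
  m <- do.call(rbind, vals) # datasets x features
  drop_feat <- apply(m, 2, function(v) any(!is.finite(v)))
  if (any(drop_feat)) {
    warning(sprintf("%d feature(s) with undefined values dropped from the %s average",
                    sum(drop_feat), measure), call. = FALSE)
    m <- m[, !drop_feat, drop = FALSE]
    if (ncol(m) == 0) stopf("all features undefined in %s comparison", measure)
  }
  per_component <- colMeans(m)           # mean over datasets, per feature
  per_dataset <- rowMeans(m)             # mean over features, per dataset
  nd <- nrow(m)
  structure(list(
    mean = mean(per_component),
    sem = if (nd > 1) sd(per_dataset) / sqrt(nd) else 0,
    per_component = per_component,
    per_dataset = per_dataset,
    values = m,
    n_datasets = nd,
    excluded_datasets = sum(!keep),
    measure = measure), class = "fa_delta")
}

#' Change in log coefficient of variation between two categories
#'
#' For every dataset with at least `min_n` adhesions in both categories,
#' computes per component `log(CV2 / CV1)`; datasets failing the rule are
#' dropped. Values are averaged first over qualifying datasets and then
#' over components; the SEM is taken across datasets (the per-dataset
#' component means).
#'
#' @param mats1,mats2 Lists (one element per dataset, matched order) of
#'   numeric matrices, adhesions x components, of raw densities for
#'   category 1 and category 2.
#' @param min_n Minimum adhesions per category per dataset (default 5).
#' @return An `fa_delta`: list with `mean`, `sem`, `per_component`,
#'   `per_dataset`, `n_datasets`.
#' @export
delta_log_cv <- function(mats1, mats2, min_n = 5) {
  delta_engine(mats1, mats2, min_n, col_cv,
               function(s1, s2) log(s2 / s1), "log_cv")
}

#' Change in pairwise r-squared between two categories
#'
#' Per dataset and unordered component pair, `r2(category 2) - r2(category
#' 1)` on the supplied (typically Box-Cox z-scored) values, averaged and
#' SEM'd as in [delta_log_cv()]. Pairs with zero variance are dropped with
#' a warning.
#'
#' @inheritParams delta_log_cv
#' @return An `fa_delta`.
#' @export
delta_r2 <- function(mats1, mats2, min_n = 5) {
  pair_r2 <- function(mat) {
    r <- suppressWarnings(cor(mat))
    r2 <- r * r
    r2[upper.tri(r2)]
  }
  delta_engine(mats1, mats2, min_n, pair_r2,
               function(s1, s2) s2 - s1, "r2")
}

#' Change in Fano factor between two categories
#'
#' Variance-over-mean replacing the CV of [delta_log_cv()]; the change is
#' again `log(F2 / F1)` per component. An alternative dispersion measure:
#' for most comparisons its sign agrees with the CV-based change.
#'
#' @inheritParams delta_log_cv
#' @return An `fa_delta`.
#' @export
delta_fano <- function(mats1, mats2, min_n = 5) {
  delta_engine(mats1, mats2, min_n, col_fano,
               function(s1, s2) log(s2 / s1), "fano")
}

#' Noise/diversity verdict from the two delta statistics
#'
#' Quadrant rule: a negative delta-log(CV) with a positive delta-r2 means
#' the noise is lower in category 2; the opposite signs mean noise is lower
#' in category 1. Matching signs (both up or both down) are the diversity
#' quadrants. If the absolute value of either mean is smaller than its SEM
#' the sign is insignificant and the inference inconclusive.
#'
#' @param dlogcv,dr2 `fa_delta` objects (or lists with `mean` and `sem`).
#' @return One of `"noise_lower_in_2"`, `"noise_lower_in_1"`,
#'   `"diversity_higher_in_2"`, `"diversity_higher_in_1"`,
#'   `"inconclusive"`.
#' @export
infer_change <- function(dlogcv, dr2) {
  m1 <- dlogcv$mean; s1 <- dlogcv$sem
  m2 <- dr2$mean;    s2 <- dr2$sem
  if (abs(m1) < s1 || abs(m2) < s2 || m1 == 0 || m2 == 0) {
    return("inconclusive")
  }
  if (m1 < 0 && m2 > 0) return("noise_lower_in_2")
  if (m1 > 0 && m2 < 0) return("noise_lower_in_1")
  if (m1 > 0 && m2 > 0) return("diversity_higher_in_2")
  "diversity_higher_in_1"
}

#' Full two-category comparison on a preprocessed study
#'
#' Slices a preprocessed density table (see [preprocess_study()]) into two
#' categories along a classification axis, computes [delta_log_cv()] on raw
#' densities and [delta_r2()] on Box-Cox z-scores per dataset, and applies
#' [infer_change()]. Optionally restricted to one level of a second axis
#' (the two-way sub-categorization design).
#'
#' @param study An `fa_study` from [preprocess_study()].
#' @param axis Classification column: `"area_cat"`, `"age"`, `"ecc_cat"`,
#'   `"density_cat"` or `"dynamics"`.
#' @param cat1,cat2 The two category levels to compare (1 vs 2).
#' @param fix Optional second classification column held fixed.
#' @param fix_level Level of `fix` to restrict to.
#' @param min_n Minimum adhesions per category per dataset.
#' @return An `fa_delta_stats`: list with `dlogcv`, `dr2`, `verdict`,
#'   `label`, `n_datasets`.
#' @export
compare_categories <- function(study, axis, cat1, cat2,
                               fix = NULL, fix_level = NULL, min_n = 5) {
  stopifnot(inherits(study, "fa_study"))
  tbl <- study$table
  if (!axis %in% names(tbl)) stopf("axis column '%s' not present", axis)
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(fix)) {
    if (is.null(fix_level)) stopf("fix_level required when fix is given")
    keep <- tbl[[fix]] == fix_level & !is.na(tbl[[fix]])
  }
  comps <- fa_components(study$table)
  raw <- as.matrix(tbl[, comps, drop = FALSE])
  z <- study$z
  ds_ids <- sort(unique(tbl$dataset))
  slice <- function(mat, ds, lev) {
    sel <- keep & tbl$dataset == ds & tbl[[axis]] == lev & !is.na(tbl[[axis]])
    mat[sel, , drop = FALSE]
  }
  raw1 <- lapply(ds_ids, function(d) slice(raw, d, cat1))
  raw2 <- lapply(ds_ids, function(d) slice(raw, d, cat2))
  z1 <- lapply(ds_ids, function(d) slice(z, d, cat1))
  z2 <- lapply(ds_ids, function(d) slice(z, d, cat2))
  dcv <- delta_log_cv(raw1, raw2, min_n = min_n)
  dr2 <- delta_r2(z1, z2, min_n = min_n)
  structure(list(
    label = sprintf("%s: %s vs %s%s", axis, cat1, cat2,
                    if (is.null(fix)) "" else sprintf(" | %s = %s", fix, fix_level)),
    dlogcv = dcv, dr2 = dr2,
    verdict = infer_change(dcv, dr2),
    n_datasets = min(dcv$n_datasets, dr2$n_datasets)),
    class = "fa_delta_stats")
}

#' @export
print.fa_delta_stats <- function(x, ...) {
  cat(sprintf("comparison   %s\n", x$label))
  cat(sprintf("  dlog(CV)   %+.4f +/- %.4f\n", x$dlogcv$mean, x$dlogcv$sem))
  cat(sprintf("  d(r2)      %+.4f +/- %.4f\n", x$dr2$mean, x$dr2$sem))
  cat(sprintf("  datasets   %d\n", x$n_datasets))
  cat(sprintf("  verdict    %s\n", x$verdict))
  invisible(x)
}
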