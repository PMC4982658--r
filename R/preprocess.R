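# Density-table preprocessing: two-parameter Box-Cox transformation with
# per-dataset maximum-likelihood lambda, z-scoring, single-pass Tukey
# outlier removal, and category assignment by area, eccentricity and mean
# normalized internal density via multilevel Otsu thresholding.

#' Two-parameter Box-Cox transformation
#'
#' `x = ((y + lambda2)^lambda1 - 1) / lambda1` for `lambda1 != 0`, and
#' `log(y + lambda2)` at `lambda1 = 0`.
#'
#' @param y Numeric values with `y + lambda2 > 0`.
#' @param lambda1 Power parameter.
#' @param lambda2 Shift parameter (default 0).
#' @return Transformed values.
#' @export
boxcox_transform <- function(y, lambda1, lambda2 = 0) {
  if (any(y + lambda2 <= 0, na.rm = TRUE)) {
    stopf("Box-Cox domain error: y + lambda2 must be > 0")
  }
  if (lambda1 == 0) log(y + lambda2) else ((y + lambda2)^lambda1 - 1) / lambda1
}

# Profile log-likelihood of the Box-Cox power at fixed shift (normal model,
# MLE variance), up to an additive constant.
boxcox_loglik <- function(y, lambda1, lambda2 = 0) {
  x <- boxcox_transform(y, lambda1, lambda2)
  n <- length(x)
  v <- sum((x - mean(x))^2) / n
  -n / 2 * log(v) + (lambda1 - 1) * sum(log(y + lambda2))
}

# Default shift: zero when all values are positive, otherwise just enough
# to make the support positive.
default_lambda2 <- function(y) {
  m <- min(y, na.rm = TRUE)
  if (m > 0) 0 else -m + 1e-6 * max(1, diff(range(y, na.rm = TRUE)))
}

#' Maximum-likelihood Box-Cox power for one component
#'
#' Profile log-likelihood maximized over a bounded grid.
#'
#' @param y Positive (after shifting) numeric vector, length >= 10.
#' @param lambda2 Shift; `NULL` selects [the default][boxcox_transform]
#'   rule.
#' @param grid Candidate powers (default `seq(-2, 2, by = 0.01)`).
#' @return List with `lambda1`, `lambda2` and the grid log-likelihoods.
#' @export
boxcox_lambda_ml <- function(y, lambda2 = NULL, grid = seq(-2, 2, by = 0.01)) {
  y <- y[!is.na(y)]
  if (length(y) < 10) stopf("lambda estimation needs >= 10 values")
  if (is.null(lambda2)) lambda2 <- default_lambda2(y)
  ll <- vapply(grid, function(l1) boxcox_loglik(y, l1, lambda2), 0)
  list(lambda1 = grid[which.max(ll)], lambda2 = lambda2, loglik = ll,
       grid = grid)
}

#' Per-dataset Box-Cox power of a density table
#'
#' The dataset power is the mean of the per-component maximum-likelihood
#' powers, one shared power per dataset.
#'
#' @param x An [fa_density_table()] (possibly several datasets).
#' @param grid Candidate powers.
#' @return Named list per dataset id: `lambda1` (dataset mean),
#'   `per_component` (named vector), `lambda2` (named vector).
#' @export
estimate_lambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
  stopifnot(inherits(x, "fa_density_table"))
  comps <- fa_components(x)
  lapply(fa_split_datasets(x), function(d) {
    fits <- lapply(comps, function(cc) boxcox_lambda_ml(d[[cc]], grid = grid))
    l1 <- vapply(fits, `[[`, 0, "lambda1")
    l2 <- vapply(fits, `[[`, 0, "lambda2")
    names(l1) <- names(l2) <- comps
    list(lambda1 = mean(l1), per_component = l1, lambda2 = l2)
  })
}

#' Z-score values and flag Tukey outliers
#'
#' Values are normalized by subtracting the mean and dividing by the
#' standard deviation; z-scores outside `[Q1 - 2 IQR, Q3 + 2 IQR]` are
#' flagged as outliers. Fences come from the full z vector in a single
#' pass; quartiles by linear interpolation of order statistics.
#'
#' @param values Numeric vector with positive standard deviation.
#' @param k Fence multiplier (default 2).
#' @return List with `z` (z-scores), `keep` (logical mask) and `fences`.
#' @export
zscore_and_tukey <- function(values, k = 2) {
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stopf("constant input: z-scores undefined")
  z <- (values - mean(values, na.rm = TRUE)) / s
  q <- quartiles(z[!is.na(z)])
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- !is.na(z) & z >= fences[1] & z <= fences[2]
  list(z = z, keep = keep, fences = fences)
}

#' Multilevel Otsu thresholds
#'
#' Thresholds maximizing the between-class variance over a histogram of the
#' pooled values, found by exhaustive search over all threshold
#' combinations (exact for the binned data).
#'
#' @param values Numeric vector with at least `n_classes` distinct values.
#' @param n_classes Number of classes (default 3).
#' @param n_bins Histogram bins (default 256).
#' @return Numeric vector of `n_classes - 1` thresholds (bin upper edges);
#'   class k is the interval between thresholds k-1 and k.
#' @export
otsu_multilevel <- function(values, n_classes = 3, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < n_classes) {
    stopf("fewer distinct values than classes")
  }
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(values, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)              # cumulative weight
  cm <- cumsum(w * mids)       # cumulative mass
  # Between-class variance of classes delimited at bin boundaries `cuts`
  # (cut after bin b means classes split between bins b and b+1).
  bcv <- function(cuts) {
    lo <- c(0L, cuts)
    hi <- c(cuts, n_bins)
    wk <- cw[hi] - c(0, cw[lo[-1]])
    mk <- cm[hi] - c(0, cm[lo[-1]])
    ok <- wk > 0
    sum(mk[ok]^2 / wk[ok])     # + const; maximizing this maximizes the BCV
  }
  cut_sets <- combn(n_bins - 1L, n_classes - 1L)
  scores <- apply(cut_sets, 2, bcv)
  # empty bins between well-separated modes make whole ranges of cuts tie
  # at the maximum; take the tied cut set closest to the component-wise
  # median so thresholds land mid-gap
  maxv <- max(scores)
  tied <- which(scores >= maxv - abs(maxv) * 1e-12)
  cand <- cut_sets[, tied, drop = FALSE]
  med <- apply(cand, 1, median)
  best <- cand[, which.min(colSums(abs(cand - med)))]
  edges[best + 1L]
}

# Label values by thresholds into named classes.
otsu_classify <- function(values, thresholds, labels) {
  stopifnot(length(labels) == length(thresholds) + 1)
  idx <- findInterval(values, thresholds, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

#' Mean normalized internal density score
#'
#' The eight non-phospho protein densities are z-scored per component per
#' dataset and averaged per adhesion; the phosphorylation-site channels are
#' excluded. Scores are then categorized into three classes by
#' [otsu_multilevel()] on the pooled scores from all datasets.
#'
#' @param x An [fa_density_table()].
#' @param proteins Component columns entering the score (default the eight
#'   non-phospho proteins present in `x`).
#' @return List with `score` (per adhesion), `category` (factor
#'   low/mid/high) and `thresholds`.
#' @export
mean_normalized_density <- function(x, proteins = NULL) {
  stopifnot(inherits(x, "fa_density_table"))
  comps <- fa_components(x)
  if (is.null(proteins)) proteins <- fa_protein_components(comps)
  missing <- setdiff(proteins, names(x))
  if (length(missing)) {
    stopf("missing protein columns for density score: %s",
          paste(missing, collapse = ", "))
  }
  score <- rep(NA_real_, nrow(x))
  for (ds in unique(x$dataset)) {
    sel <- x$dataset == ds
    zz <- vapply(proteins, function(cc) {
      v <- x[[cc]][sel]
      (v - mean(v)) / sd(v)
    }, numeric(sum(sel)))
    if (sum(sel) == 1L) zz <- matrix(zz, nrow = 1)
    score[sel] <- rowMeans(zz)
  }
  thr <- otsu_multilevel(score, n_classes = 3)
  list(score = score,
       category = otsu_classify(score, thr, c("low", "mid", "high")),
       thresholds = thr)
}

#' Reference classification thresholds from a REF52 CycIF dataset
#'
#' Otsu thresholds are dataset-dependent; these constants, obtained on one
#' reference REF52 focal-adhesion dataset, are kept for orientation only.
#' The package always recomputes thresholds from the data at hand.
#'
#' @return Named list of threshold pairs.
#' @export
fa_reference_thresholds <- function() {
  list(area_um2 = c(2.71, 6.17),
       eccentricity = c(0.86, 0.92),
       density_score = c(-0.42, 0.282))
}

#' Preprocess a multi-dataset density study
#'
#' Runs the full preprocessing chain: per-dataset Box-Cox power estimation
#' (dataset power = mean of per-component ML powers), transformation,
#' z-scoring per component per dataset, single-pass Tukey outlier removal
#' (an adhesion is dropped if any of its component z-scores falls outside
#' the fences), then Otsu 3-class categorization of area and eccentricity
#' on values pooled across all datasets, and the mean normalized internal
#' density score with its own pooled Otsu categorization.
#'
#' @param x An [fa_density_table()] holding all datasets, or a list of
#'   per-dataset tables.
#' @param grid Box-Cox power grid.
#' @param tukey_k Tukey fence multiplier.
#' @return An `fa_study`: list with `table` (surviving rows with
#'   `area_cat`, `ecc_cat`, `density_cat`, `density_score` columns added),
#'   `z` (matrix of Box-Cox z-scores for the surviving rows), `transform`
#'   (per-dataset lambda state), `thresholds`, `n_removed`.
#' @export
preprocess_study <- function(x, grid = seq(-2, 2, by = 0.01), tukey_k = 2) {
  if (is.list(x) && !inherits(x, "fa_density_table")) {
    comps <- fa_components(x[[1]])
    x <- fa_density_table(do.call(rbind, lapply(x, as_tibble)), comps)
  }
  stopifnot(inherits(x, "fa_density_table"))
  comps <- fa_components(x)
  transform <- estimate_lambda(x, grid = grid)

  z <- matrix(NA_real_, nrow(x), length(comps),
              dimnames = list(NULL, comps))
  keep <- rep(TRUE, nrow(x))
  for (ds in names(transform)) {
    sel <- which(x$dataset == ds)
    l1 <- transform[[ds]]$lambda1
    for (cc in comps) {
      tv <- boxcox_transform(x[[cc]][sel], l1, transform[[ds]]$lambda2[[cc]])
      zt <- zscore_and_tukey(tv, k = tukey_k)
      z[sel, cc] <- zt$z
      keep[sel] <- keep[sel] & zt$keep
    }
  }

  tbl <- x[keep, , drop = FALSE]
  z <- z[keep, , drop = FALSE]

  thresholds <- list()
  if ("area" %in% names(tbl)) {
    thresholds$area <- otsu_multilevel(x$area, n_classes = 3)
    tbl$area_cat <- otsu_classify(tbl$area, thresholds$area, c("S", "M", "L"))
  }
  if ("eccentricity" %in% names(tbl)) {
    thresholds$eccentricity <- otsu_multilevel(x$eccentricity, n_classes = 3)
    tbl$ecc_cat <- otsu_classify(tbl$eccentricity, thresholds$eccentricity,
                                 c("low", "mid", "high"))
  }
  dens <- mean_normalized_density(fa_density_table(tbl, comps))
  tbl$density_score <- dens$score
  tbl$density_cat <- dens$category
  thresholds$density <- dens$thresholds

  structure(list(table = fa_density_table(tbl, comps), z = z,
                 transform = transform, thresholds = thresholds,
                 n_removed = sum(!keep)),
            class = "fa_study")
}
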