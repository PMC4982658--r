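# Image-analysis chain: subpixel registration by single-step upsampled
# DFT cross-correlation, high-pass background subtraction, watershed
# segmentation of adhesions, per-region measurement, backward tracking
# and age / dynamics classification.

#' Subpixel translation between two images
#'
#' Single-step discrete Fourier transform registration: the integer shift
#' is located on the full cross-correlation; the peak is then refined on a
#' locally upsampled cross-correlation computed by matrix-multiply DFT,
#' giving 1/upsample px accuracy. Returns the translation `(dy, dx)` of
#' `moving` relative to `reference` (circularly shifting `reference` by
#' `(dy, dx)` reproduces `moving`).
#'
#' @param reference,moving Numeric matrices of equal size.
#' @param upsample Upsampling factor (>= 1; 1 = integer precision).
#' @return Numeric `c(dy, dx)`.
#' @export
register_translation <- function(reference, moving, upsample = 100) {
  if (!all(dim(reference) == dim(moving))) stopf("images must share a shape")
  if (upsample < 1) stopf("upsample must be >= 1")
  if (sd(reference) == 0 || sd(moving) == 0) {
    stopf("degenerate input: flat image has no registrable structure")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  F1 <- stats::fft(reference)
  F2 <- stats::fft(moving)
  R <- F2 * Conj(F1)
  cc <- Re(stats::fft(R, inverse = TRUE))
  peak <- which.max(cc)
  py <- (peak - 1) %% nr
  px <- (peak - 1) %/% nr
  if (py > nr / 2) py <- py - nr
  if (px > nc / 2) px <- px - nc
  if (upsample <= 1) return(c(dy = py, dx = px))

  # Refine within +/- 1.5 px of the integer peak at 1/upsample resolution
  # using an explicit DFT evaluated only at the candidate offsets.
  win <- ceiling(upsample * 1.5)
  offs <- (-win:win) / upsample
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  ey <- exp(2i * pi * outer(py + offs, fy / nr))   # candidates x freq
  ex <- exp(2i * pi * outer(fx / nc, px + offs))   # freq x candidates
  cc_up <- Re(ey %*% R %*% ex)
  best <- arrayInd(which.max(cc_up), dim(cc_up))
  c(dy = py + offs[best[1]], dx = px + offs[best[2]])
}

#' Apply a translation to an image
#'
#' Fourier phase-ramp shift (periodic boundary); exact for integer shifts,
#' band-limited interpolation for fractional ones.
#'
#' @param image Numeric matrix.
#' @param dy,dx Shift in pixels (positive = down / right).
#' @return Shifted matrix.
#' @export
shift_image <- function(image, dy, dx) fourier_shift(image, dy, dx)

#' High-pass background subtraction
#'
#' Subtracts a smoothed copy of the image (smoothing scale `width` px) and
#' clips at zero, removing large-scale illumination gradients while
#' preserving structures much smaller than `width`. The Gaussian smoother
#' is the classic choice; the median smoother is robust to the signal
#' itself and leaves densities of sparse bright structures unbiased.
#'
#' @param image Numeric matrix.
#' @param width Smoothing scale in px (> 0): Gaussian sigma, or median
#'   window radius.
#' @param method `"gaussian"` or `"median"`.
#' @return Filtered matrix (>= 0).
#' @export
highpass_subtract <- function(image, width = 40, method = c("gaussian",
                                                            "median")) {
  method <- match.arg(method)
  if (width <= 0) stopf("width must be > 0")
  bg <- if (method == "gaussian") {
    as.matrix(EBImage::gblur(image, sigma = width))
  } else {
    mx <- max(image)
    rng <- max(image) - min(image)
    if (rng == 0) {
      matrix(image[1], nrow(image), ncol(image))
    } else {
      as.matrix(EBImage::medianFilter((image - min(image)) / rng,
                                      size = round(width))) * rng + min(image)
    }
  }
  pmax(image - bg, 0)
}

#' Segment adhesions by watershed
#'
#' Gaussian-smooths the background-subtracted marker image, masks pixels
#' below an intensity threshold, and runs a tolerance-based watershed
#' seeded at the remaining local maxima. Regions below `min_area` px are
#' removed and labels renumbered contiguously.
#'
#' @param image Background-subtracted marker image (matrix).
#' @param smooth_sigma Smoothing sigma in px.
#' @param threshold Numeric intensity threshold, or `"otsu"` for a 2-class
#'   Otsu threshold on the smoothed image.
#' @param tolerance Watershed tolerance (minimum peak-to-saddle height
#'   separating two objects).
#' @param min_area Minimum region size in px.
#' @return Integer label matrix (`0` = background); an all-zero map if no
#'   seeds are found.
#' @export
segment_adhesions <- function(image, smooth_sigma = 1, threshold = "otsu",
                              tolerance = 1, min_area = 5) {
  sm <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(image, smooth_sigma))
        else image
  thr <- if (identical(threshold, "otsu")) {
    if (length(unique(as.vector(sm))) < 2) return(matrix(0L, nrow(image), ncol(image)))
    otsu_multilevel(as.vector(sm), n_classes = 2)
  } else as.numeric(threshold)
  masked <- sm * (sm > thr)
  if (!any(masked > 0)) return(matrix(0L, nrow(image), ncol(image)))
  labs <- EBImage::imageData(EBImage::watershed(EBImage::Image(masked),
                                                tolerance = tolerance,
                                                ext = 1))
  labs <- matrix(as.integer(labs), nrow(image), ncol(image))
  keep <- which(tabulate(labs) >= min_area)
  relab <- integer(max(labs, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(image), ncol(image))
  pos <- labs > 0
  out[pos] <- relab[labs[pos]]
  out
}

# Centroids (row, col) per label of a label map; rows ordered by label.
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(matrix(numeric(0), 0, 2))
  idx <- which(labels > 0)
  lab <- labels[idx]
  ys <- (idx - 1) %% nrow(labels) + 1
  xs <- (idx - 1) %/% nrow(labels) + 1
  cbind(tapply(ys, lab, mean)[as.character(ids)],
        tapply(xs, lab, mean)[as.character(ids)])
}

#' Measure labeled regions across channels
#'
#' Per region: pixel count, physical area, centroid, ellipse eccentricity
#' from second central moments (the inter-focal distance over the major
#' axis length), and the density of each channel (mean intensity over the
#' region's pixels).
#'
#' @param labels Integer label matrix.
#' @param channels Named list of intensity matrices registered to the
#'   label frame.
#' @param pixel_size Pixel size (micron/px) for the area column.
#' @return Tibble: `label`, `pixels`, `area`, `cy`, `cx`, `eccentricity`,
#'   one density column per channel.
#' @export
measure_regions <- function(labels, channels, pixel_size = 1) {
  for (ch in channels) {
    if (!all(dim(ch) == dim(labels))) stopf("channel shape mismatch")
  }
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    out <- tibble(label = integer(0), pixels = integer(0), area = numeric(0),
                  cy = numeric(0), cx = numeric(0), eccentricity = numeric(0))
    for (nm in names(channels)) out[[nm]] <- numeric(0)
    return(out)
  }
  idx <- which(labels > 0)
  lab <- factor(labels[idx], levels = ids)
  ys <- (idx - 1) %% nrow(labels) + 1
  xs <- (idx - 1) %/% nrow(labels) + 1
  npx <- as.integer(table(lab))
  cy <- tapply(ys, lab, mean)
  cx <- tapply(xs, lab, mean)
  ecc <- vapply(seq_along(ids), function(k) {
    sel <- lab == ids[k]
    dy <- ys[sel] - cy[k]; dx <- xs[sel] - cx[k]
    mu20 <- mean(dy^2); mu02 <- mean(dx^2); mu11 <- mean(dy * dx)
    tr <- mu20 + mu02
    det <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    if (l1 <= 0) return(0)
    sqrt(max(1 - l2 / l1, 0))
  }, 0)
  out <- tibble(label = ids, pixels = npx,
                area = npx * pixel_size^2,
                cy = as.numeric(cy), cx = as.numeric(cx),
                eccentricity = ecc)
  for (nm in names(channels)) {
    out[[nm]] <- as.numeric(tapply(channels[[nm]][idx], lab, mean))
  }
  out
}

#' Track adhesions backward through a label-map sequence
#'
#' Starting from the final (post-fixation) frame, each tracked region is
#' matched to a region in the preceding frame by maximum pixel overlap;
#' ties are broken by larger overlap fraction, then nearer centroid. A
#' region with no overlap is matched to the nearest centroid within
#' `max_dist` px. Regions absent from the final frame are excluded.
#'
#' @param label_sequence List of >= 2 integer label matrices, final frame
#'   last.
#' @param images Optional list of intensity matrices (same length) from
#'   which per-frame total intensities are recorded.
#' @param max_dist Centroid matching radius in px (default 10).
#' @param shifts Optional list of `(dy, dx)` integer translations mapping
#'   each frame into the final frame's coordinates (applied before
#'   matching).
#' @return List of `fa_trajectory`: each with `id`, `frames`, `labels`,
#'   `areas`, `centroids` (matrix), `totals` (or `NA`), `first_frame`.
#' @export
track_adhesions <- function(label_sequence, images = NULL, max_dist = 10,
                            shifts = NULL) {
  nf <- length(label_sequence)
  if (nf < 2) stopf("tracking needs >= 2 frames")
  if (!is.null(shifts)) {
    label_sequence <- lapply(seq_len(nf), function(f) {
      s <- round(shifts[[f]])
      roll_int(label_sequence[[f]], s[1], s[2])
    })
  }
  final <- label_sequence[[nf]]
  ids <- sort(unique(final[final > 0]))
  tracks <- lapply(ids, function(i) {
    list(id = i, frames = nf, labels = i,
         areas = sum(final == i),
         centroids = matrix(label_centroids(final)[match(i, ids), ], 1, 2),
         totals = if (!is.null(images)) sum(images[[nf]][final == i]) else NA_real_,
         first_frame = nf)
  })
  cur_label <- ids                      # current label per track (NA = ended)
  for (f in seq(nf - 1, 1)) {
    prev <- label_sequence[[f]]
    nxt <- label_sequence[[f + 1]]
    prev_ids <- sort(unique(prev[prev > 0]))
    if (!length(prev_ids)) { cur_label[] <- NA; next }
    cen_prev <- label_centroids(prev)
    cen_next <- label_centroids(nxt)
    next_ids <- sort(unique(nxt[nxt > 0]))
    taken <- logical(length(prev_ids))
    for (t in order(vapply(tracks, function(x) -x$areas[1], 0))) {
      lb <- cur_label[t]
      if (is.na(lb)) next
      sel <- nxt == lb
      ov <- table(prev[sel & prev > 0])
      cand <- NA_integer_
      if (length(ov)) {
        best <- max(ov)
        tied <- as.integer(names(ov)[ov == best])
        tied <- tied[!taken[match(tied, prev_ids)]]
        if (length(tied) > 1) {
          # larger overlap fraction of the candidate, then nearer centroid
          frac <- best / vapply(tied, function(s) sum(prev == s), 0)
          tied <- tied[frac == max(frac)]
          if (length(tied) > 1) {
            cn <- cen_next[match(lb, next_ids), ]
            dd <- sqrt(rowSums((cen_prev[match(tied, prev_ids), , drop = FALSE] -
                                matrix(cn, length(tied), 2, byrow = TRUE))^2))
            tied <- tied[which.min(dd)]
          }
        }
        if (length(tied)) cand <- tied[1]
      }
      if (is.na(cand)) {
        cn <- cen_next[match(lb, next_ids), ]
        free <- which(!taken)
        if (length(free)) {
          dd <- sqrt(rowSums((cen_prev[free, , drop = FALSE] -
                              matrix(cn, length(free), 2, byrow = TRUE))^2))
          if (min(dd) <= max_dist) cand <- prev_ids[free[which.min(dd)]]
        }
      }
      if (is.na(cand)) { cur_label[t] <- NA; next }
      taken[match(cand, prev_ids)] <- TRUE
      cur_label[t] <- cand
      tracks[[t]]$frames <- c(f, tracks[[t]]$frames)
      tracks[[t]]$labels <- c(cand, tracks[[t]]$labels)
      tracks[[t]]$areas <- c(sum(prev == cand), tracks[[t]]$areas)
      tracks[[t]]$centroids <- rbind(cen_prev[match(cand, prev_ids), ],
                                     tracks[[t]]$centroids)
      tracks[[t]]$totals <- c(
        if (!is.null(images)) sum(images[[f]][prev == cand]) else NA_real_,
        tracks[[t]]$totals)
      tracks[[t]]$first_frame <- f
    }
  }
  lapply(tracks, function(t) structure(t, class = "fa_trajectory"))
}

# Integer circular shift of a matrix by (dy, dx).
roll_int <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

#' Age category and dynamics class of a tracked adhesion
#'
#' Age follows the first-appearance frame at a 3-minute frame interval,
#' with the final frame of the sequence taken at fixation: appearance one
#' frame before the final is `3'`, two is `6'`, three `9'`, four `12'`;
#' adhesions present five or more frames, or already present in the first
#' frame, are `(>12')`. Only `(>12')`-old adhesions receive a dynamics
#' class, from the Pearson correlation between total marker intensity and
#' time over the last four pre-fixation frames: r > 0.7 assembling (AS),
#' r < -0.7 disassembling (DS), otherwise stationary (ST); a constant
#' trace (undefined r) is ST.
#'
#' @param trajectory An `fa_trajectory` from [track_adhesions()].
#' @param n_frames Total frames in the tracked sequence.
#' @param r_threshold Correlation threshold (default 0.7).
#' @param flat_tol Relative-variation floor below which a trace counts as
#'   constant (and hence stationary).
#' @return List with `age` and `dynamics` (`NA` unless age is `(>12')`).
#' @export
classify_dynamics <- function(trajectory, n_frames, r_threshold = 0.7,
                              flat_tol = 0.01) {
  f <- trajectory$first_frame
  k <- n_frames - f
  age <- if (f == 1L || k >= 5L) "(>12')"
         else c("3'", "6'", "9'", "12'")[k]
  dynamics <- NA_character_
  if (age == "(>12')") {
    use <- trajectory$frames >= n_frames - 4L & trajectory$frames <= n_frames - 1L
    tt <- trajectory$frames[use]
    yy <- trajectory$totals[use]
    if (length(yy) >= 3 && !any(is.na(yy))) {
      # a trace with no meaningful relative variation is stationary even if
      # its residual drift happens to be monotone
      flat <- sd(yy) == 0 || (mean(yy) > 0 && sd(yy) / mean(yy) < flat_tol)
      r <- if (flat) 0 else cor(tt, yy)
      dynamics <- if (r > r_threshold) "AS"
                  else if (r < -r_threshold) "DS" else "ST"
    } else {
      dynamics <- "ST"
    }
  }
  list(age = age, dynamics = dynamics)
}
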