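# End-to-end image analysis: registration of the multiplexed channels to
# the marker frame, background subtraction, segmentation of the marker,
# backward tracking through the pre-fixation movie, measurement and
# age / dynamics classification. Produces a density table ready for
# preprocessing.

#' Analyze a multiplexed image set into a density table
#'
#' @param iset An `fa_image_set` (see [generate_image_set()]) or a list
#'   with the same fields (`marker`, `channels`, `pixel_size`).
#' @param dataset_id Dataset label for the output table.
#' @param register_channel Channel used to register the post-fixation
#'   stack against the final marker frame (default `"paxillin"`; `NULL`
#'   disables registration).
#' @param highpass_width High-pass smoothing scale (px).
#' @param highpass_method `"gaussian"` or `"median"`, see
#'   [highpass_subtract()].
#' @param smooth_sigma,threshold,tolerance,min_area Segmentation
#'   parameters, see [segment_adhesions()].
#' @return An [fa_density_table()] with geometry, age and dynamics
#'   columns; the final-frame label map and trajectories are attached as
#'   attributes `labels` and `trajectories`.
#' @export
analyze_image_set <- function(iset, dataset_id = "cell1",
                              register_channel = "paxillin",
                              highpass_width = 40,
                              highpass_method = "gaussian",
                              smooth_sigma = 1,
                              threshold = "otsu", tolerance = 10,
                              min_area = 5) {
  marker <- iset$marker
  nf <- length(marker)
  channels <- iset$channels
  if (!is.null(register_channel) && register_channel %in% names(channels)) {
    sh <- register_translation(marker[[nf]], channels[[register_channel]])
    if (any(abs(sh) > 0.005)) {
      channels <- lapply(channels, shift_image, dy = -sh[1], dx = -sh[2])
    }
  }
  marker_hp <- lapply(marker, highpass_subtract, width = highpass_width,
                      method = highpass_method)
  channels_hp <- lapply(channels, highpass_subtract, width = highpass_width,
                        method = highpass_method)

  label_seq <- lapply(marker_hp, segment_adhesions,
                      smooth_sigma = smooth_sigma, threshold = threshold,
                      tolerance = tolerance, min_area = min_area)
  final_labels <- label_seq[[nf]]
  meas <- measure_regions(final_labels, channels_hp,
                          pixel_size = iset$pixel_size %||% 1)
  tracks <- track_adhesions(label_seq, images = marker_hp)
  cls <- lapply(tracks, classify_dynamics, n_frames = nf)
  track_ids <- vapply(tracks, function(t) t$id, 0L)
  ord <- match(meas$label, track_ids)

  tbl <- tibble(dataset = dataset_id,
                adhesion = meas$label,
                pixels = meas$pixels,
                area = meas$area,
                eccentricity = meas$eccentricity,
                cy = meas$cy, cx = meas$cx,
                age = vapply(ord, function(i)
                  if (is.na(i)) NA_character_ else cls[[i]]$age, ""),
                dynamics = vapply(ord, function(i)
                  if (is.na(i)) NA_character_ else cls[[i]]$dynamics, ""))
  for (nm in names(channels_hp)) tbl[[nm]] <- meas[[nm]]
  out <- fa_density_table(tbl, components = names(channels_hp))
  attr(out, "labels") <- final_labels
  attr(out, "trajectories") <- tracks
  out
}

#' Equal-pixel-sampling control for the noise inference
#'
#' Recomputes per-adhesion densities from a random pixel subsample so that
#' pixel-count differences between area categories cannot drive the
#' inference: either the mean number of sampled pixels is equalized across
#' categories (`mode = "equal_mean"`) or a fixed number of pixels is drawn
#' from every adhesion (`mode = "fixed"`, default 10 px). Adhesions
#' smaller than the request keep all their pixels. The subsampled
#' densities replace the measured ones and the full two-category delta
#' analysis is rerun.
#'
#' @param labels Integer label matrix.
#' @param channels Named list of intensity matrices.
#' @param categories Factor/character vector of per-label categories
#'   (ordered by label id) defining the comparison groups.
#' @param cat1,cat2 The two category levels to compare.
#' @param mode `"equal_mean"` or `"fixed"`.
#' @param n_pixels Pixels per adhesion for `mode = "fixed"`.
#' @param seed Integer seed for the subsampling.
#' @return List with `densities` (subsampled density tibble including a
#'   `category` column), `dlogcv`, `dr2`, `verdict`.
#' @export
equal_pixel_control <- function(labels, channels, categories, cat1, cat2,
                                mode = c("equal_mean", "fixed"),
                                n_pixels = 10, seed = 1) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  ids <- sort(unique(labels[labels > 0]))
  if (length(categories) != length(ids)) {
    stopf("categories must have one entry per label")
  }
  pix <- split(which(labels > 0), labels[labels > 0])
  pix <- pix[as.character(ids)]
  sizes <- lengths(pix)
  target <- if (mode == "fixed") {
    rep(n_pixels, length(ids))
  } else {
    # equalize the mean sampled count across categories at the smallest
    # category mean, by per-adhesion proportional subsampling
    mns <- tapply(sizes, categories, mean)
    frac <- min(mns) / mns[as.character(categories)]
    pmax(1, round(sizes * as.numeric(frac)))
  }
  sampled <- lapply(seq_along(ids), function(i) {
    if (sizes[i] <= target[i]) pix[[i]]
    else sample(pix[[i]], target[i])
  })
  dens <- tibble(label = ids, category = as.character(categories),
                 sampled_pixels = lengths(sampled))
  for (nm in names(channels)) {
    dens[[nm]] <- vapply(sampled, function(px) mean(channels[[nm]][px]), 0)
  }
  m1 <- as.matrix(dens[dens$category == cat1, names(channels), drop = FALSE])
  m2 <- as.matrix(dens[dens$category == cat2, names(channels), drop = FALSE])
  dcv <- delta_log_cv(list(m1), list(m2))
  dr2 <- delta_r2(list(log(m1 + 1)), list(log(m2 + 1)))
  list(densities = dens, dlogcv = dcv, dr2 = dr2,
       verdict = infer_change(dcv, dr2))
}
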