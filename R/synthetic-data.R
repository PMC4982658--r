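# Desk-scale surrogates for a six-dataset multiplexed adhesion study:
# density tables with a controllable common diversity factor and
# independent per-component noise, and small multi-channel image stacks
# with ground truth for exercising the image-analysis chain.

#' Configuration for a synthetic multiplexed study
#'
#' Defaults emulate the study design: 6 datasets from 3 repeats of 2
#' labeling orders, 10 labeled components, a shared per-adhesion diversity
#' factor with a common linear effect on all component densities, and
#' independent lognormal binding noise per component.
#'
#' @param n_datasets Number of datasets (default 6; ids `R<i>O<j>`).
#' @param n_cells Cells per dataset.
#' @param adhesions_per_cell Adhesions per cell.
#' @param components Component names (default [fa_components_default()]).
#' @param base_mean Named mean density per component (arbitrary
#'   fluorescence units); defaults span ~40-250.
#' @param diversity_sd Log-sd of the shared lognormal diversity factor.
#' @param noise_sd Per-component log-sd of independent lognormal noise
#'   (scalar or named vector).
#' @param area_meanlog,area_sdlog Lognormal area distribution (micron^2).
#' @param age_probs Named probabilities over the age categories
#'   `>12'`, `12'`, `9'`, `6'`, `3'`.
#' @param dynamics_probs Named probabilities over AS/ST/DS for `>12'`-old
#'   adhesions.
#' @param image_size Image side in pixels (square).
#' @param n_frames Marker time-lapse frames at 3-minute spacing, the last
#'   frame taken at fixation time; 6 frames resolve all five age
#'   categories including `(>12')`.
#' @param pixel_size Pixel size in micron/px.
#' @param background Constant image background level.
#' @param image_noise_sd Additive Gaussian image noise sd (0 = noise
#'   free).
#' @param shift Inter-cycle translation `(dy, dx)` in px applied to the
#'   post-fixation channels (exercises registration).
#' @param seed Integer seed.
#' @return A list of class `fa_synth_config`.
#' @export
synthetic_study_config <- function(n_datasets = 6, n_cells = 3,
                                   adhesions_per_cell = 30,
                                   components = fa_components_default(),
                                   base_mean = NULL,
                                   diversity_sd = 0.4, noise_sd = 0.25,
                                   area_meanlog = log(3), area_sdlog = 0.6,
                                   age_probs = c("(>12')" = 0.6, "12'" = 0.1,
                                                 "9'" = 0.1, "6'" = 0.1,
                                                 "3'" = 0.1),
                                   dynamics_probs = c(AS = 0.4, ST = 0.4,
                                                      DS = 0.2),
                                   image_size = 256, n_frames = 6,
                                   pixel_size = 0.16, background = 5,
                                   image_noise_sd = 0, shift = c(0, 0),
                                   seed = 1) {
  if (anyDuplicated(components)) stopf("component names must be unique")
  if (diversity_sd < 0 || any(noise_sd < 0)) stopf("sds must be >= 0")
  if (is.null(base_mean)) {
    base_mean <- setNames(
      round(seq(40, 250, length.out = length(components))), components)
  }
  if (length(noise_sd) == 1L) {
    noise_sd <- setNames(rep(noise_sd, length(components)), components)
  }
  names(age_probs) <- c("(>12')", "12'", "9'", "6'", "3'")
  structure(list(
    n_datasets = n_datasets, n_cells = n_cells,
    adhesions_per_cell = adhesions_per_cell, components = components,
    base_mean = base_mean, diversity_sd = diversity_sd, noise_sd = noise_sd,
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    age_probs = age_probs, dynamics_probs = dynamics_probs,
    image_size = image_size, n_frames = n_frames, pixel_size = pixel_size,
    background = background, image_noise_sd = image_noise_sd,
    shift = shift, seed = as.integer(seed)), class = "fa_synth_config")
}

fa_age_levels <- function() c("(>12')", "12'", "9'", "6'", "3'")

# Dataset roster: repeats x labeling orders.
dataset_roster <- function(n_datasets) {
  reps <- ceiling(n_datasets / 2)
  ids <- as.vector(t(outer(paste0("R", seq_len(reps)), c("O1", "O2"),
                           paste0)))[seq_len(n_datasets)]
  tibble(dataset = ids,
         labeling_order = sub("^R\\d+", "", ids))
}

#' Generate synthetic per-adhesion density tables
#'
#' Per adhesion a latent diversity factor `d > 0` multiplies all component
#' means; independent lognormal noise is applied per component. Area,
#' eccentricity, age category and dynamics class are attached, with area
#' positively correlated with age among assembling adhesions.
#'
#' @param config An [synthetic_study_config()].
#' @return Named list of [fa_density_table()], one per dataset, each
#'   carrying a `truth` attribute with the latent diversity factors.
#' @export
generate_density_tables <- function(config) {
  stopifnot(inherits(config, "fa_synth_config"))
  roster <- dataset_roster(config$n_datasets)
  n <- config$n_cells * config$adhesions_per_cell
  tables <- vector("list", nrow(roster))
  names(tables) <- roster$dataset
  for (k in seq_len(nrow(roster))) {
    set.seed(derive_seed(config$seed, k))
    d <- rlnorm(n, 0, config$diversity_sd)
    dens <- vapply(config$components, function(cc) {
      config$base_mean[[cc]] * d * rlnorm(n, 0, config$noise_sd[[cc]])
    }, numeric(n))
    age <- factor(sample(names(config$age_probs), n, replace = TRUE,
                         prob = config$age_probs), levels = fa_age_levels())
    dynamics <- rep(NA_character_, n)
    old <- age == "(>12')"
    dynamics[old] <- sample(names(config$dynamics_probs), sum(old),
                            replace = TRUE, prob = config$dynamics_probs)
    # Assembling adhesions grow: area scales with age rank (3' youngest).
    age_rank <- 5L - as.integer(age)      # 0 for 3' ... 4 for (>12')
    growth <- ifelse(is.na(dynamics) | dynamics == "AS",
                     1 + 0.35 * age_rank, 1 + 0.35 * 4)
    area <- rlnorm(n, config$area_meanlog, config$area_sdlog) * growth
    ecc <- sqrt(stats::rbeta(n, 8, 2))    # oval adhesions, ecc ~ 0.7-0.99
    tbl <- tibble(dataset = roster$dataset[k],
                  labeling_order = roster$labeling_order[k],
                  cell = rep(seq_len(config$n_cells),
                             each = config$adhesions_per_cell),
                  adhesion = seq_len(n),
                  pixels = pmax(1L, round(area / config$pixel_size^2)),
                  area = area, eccentricity = ecc,
                  age = as.character(age), dynamics = dynamics)
    for (cc in config$components) tbl[[cc]] <- dens[, cc]
    out <- fa_density_table(tbl, config$components)
    attr(out, "truth") <- list(diversity = d, seed = derive_seed(config$seed, k))
    tables[[k]] <- out
  }
  tables
}

# Subpixel image translation via Fourier phase shift (periodic boundary).
fourier_shift <- function(im, dy, dx) {
  nr <- nrow(im); nc <- ncol(im)
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  phase <- exp(-2i * pi * (outer(fy * dy, rep(1, nc)) +
                           outer(rep(1, nr), fx * dx)))
  Re(stats::fft(stats::fft(im) * phase, inverse = TRUE)) / (nr * nc)
}

# Filled-ellipse pixel mask at center (cy, cx), semi-axes (a, b) px,
# orientation theta (radians, major axis).
ellipse_mask <- function(size, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  dy <- yy - cy; dx <- xx - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic multiplexed image set with ground truth
#'
#' Renders elliptical adhesions (flat-top by default, Gaussian-profiled on
#' request) into a pre-fixation marker time-lapse and a post-fixation
#' multi-channel stack, using per-adhesion densities from
#' [generate_density_tables()]. Marker intensities trend up (AS), flat
#' (ST) or down (DS) across frames; adhesions younger than the movie
#' appear at their truth frame. A configured inter-cycle translation is
#' applied to the post-fixation channels.
#'
#' @param config An [synthetic_study_config()] (image fields used;
#'   `image_size >= 64`, `n_frames >= 5`).
#' @param n_adhesions Number of adhesions rendered (default
#'   `adhesions_per_cell`).
#' @param profile `"flat"` (constant density inside the ellipse; exact
#'   render/measure round trip) or `"gaussian"` (peaked; exercises
#'   watershed splitting).
#' @param max_tries Placement attempts before regenerating a colliding
#'   adhesion.
#' @return An `fa_image_set`: list with `marker` (list of `n_frames`
#'   matrices, the last at fixation time), `channels` (named list of
#'   post-fixation matrices), `labels` (truth label map), `truth` (tibble:
#'   id, center, semi-axes, appearance frame, age, dynamics, per-channel
#'   density), `pixel_size`, `shift`.
#' @export
generate_image_set <- function(config, n_adhesions = NULL,
                               profile = c("flat", "gaussian"),
                               max_tries = 200) {
  stopifnot(inherits(config, "fa_synth_config"))
  profile <- match.arg(profile)
  if (config$image_size < 64) stopf("image size must be >= 64")
  if (config$n_frames < 5) stopf("need >= 5 time-lapse frames")
  n <- n_adhesions %||% config$adhesions_per_cell
  size <- config$image_size
  full <- generate_density_tables(config)[[1]]
  comps <- fa_components(full)
  if (n > nrow(full)) stopf("n_adhesions exceeds configured adhesions per dataset")
  tab <- as_tibble(full)[seq_len(n), ]
  set.seed(derive_seed(config$seed, 999))

  # Geometry: semi-axes from area and eccentricity, non-overlapping centers.
  area_px <- tab$area / config$pixel_size^2
  ratio <- sqrt(1 - tab$eccentricity^2)          # b / a
  a <- sqrt(area_px / (pi * ratio))
  b <- a * ratio
  theta <- runif(n, 0, pi)
  cy <- numeric(n); cx <- numeric(n)
  ord <- order(-a)                      # place large adhesions first
  for (i in ord) {
    margin <- ceiling(a[i]) + 2
    placed <- FALSE
    prior <- ord[seq_len(which(ord == i) - 1)]
    for (try in seq_len(max_tries)) {
      py <- runif(1, margin, size - margin)
      px <- runif(1, margin, size - margin)
      if (!length(prior) ||
          all(sqrt((py - cy[prior])^2 + (px - cx[prior])^2) >
              a[i] + a[prior] + 3)) {
        cy[i] <- py; cx[i] <- px; placed <- TRUE; break
      }
    }
    if (!placed) stopf("could not place %d non-overlapping adhesions", n)
  }

  masks <- lapply(seq_len(n), function(i) {
    ellipse_mask(size, cy[i], cx[i], a[i], b[i], theta[i])
  })
  labels <- matrix(0L, size, size)
  for (i in seq_len(n)) labels[masks[[i]]] <- i

  render <- function(amps) {
    im <- matrix(config$background, size, size)
    for (i in seq_len(n)) {
      if (amps[i] <= 0) next
      if (profile == "flat") {
        im[masks[[i]]] <- im[masks[[i]]] + amps[i]
      } else {
        yy <- matrix(seq_len(size), size, size); xx <- t(yy)
        u <- (xx - cx[i]) * cos(theta[i]) + (yy - cy[i]) * sin(theta[i])
        v <- -(xx - cx[i]) * sin(theta[i]) + (yy - cy[i]) * cos(theta[i])
        g <- amps[i] * exp(-((u / (a[i] / 1.5))^2 + (v / (b[i] / 1.5))^2))
        im <- im + g * (g > amps[i] * 0.05)
      }
    }
    if (config$image_noise_sd > 0) {
      im <- im + matrix(rnorm(size^2, 0, config$image_noise_sd), size, size)
    }
    im
  }

  # Appearance frame from truth age: sequence frame F = n_frames is at
  # fixation; age 3' appeared at F-1, 6' at F-2, 9' at F-3, 12' at F-4,
  # (>12') before the movie (frame <= F-5, encoded 0).
  age_to_appear <- c("(>12')" = 0L, "12'" = -4L, "9'" = -3L, "6'" = -2L,
                     "3'" = -1L)
  appear <- age_to_appear[tab$age] + config$n_frames
  appear[tab$age == "(>12')"] <- 0L
  appear <- pmax(appear, 0L)

  slope <- ifelse(is.na(tab$dynamics), 0.15,     # young adhesions assemble
                  c(AS = 0.15, ST = 0, DS = -0.15)[tab$dynamics])
  marker_amp <- if ("paxillin" %in% comps) tab$paxillin else tab[[comps[1]]]
  marker <- lapply(seq_len(config$n_frames), function(f) {
    amps <- marker_amp * (1 + slope * (f - config$n_frames)) *
      (f >= pmax(appear, 1L))
    render(pmax(amps, 0))
  })

  channels <- lapply(comps, function(cc) {
    im <- render(tab[[cc]])
    if (any(config$shift != 0)) {
      im <- fourier_shift(im, config$shift[1], config$shift[2])
    }
    im
  })
  names(channels) <- comps

  truth <- tibble(id = seq_len(n), cy = cy, cx = cx, a = a, b = b,
                  theta = theta, area_px = vapply(masks, sum, 0L),
                  appear_frame = as.integer(appear), age = tab$age,
                  dynamics = tab$dynamics)
  for (cc in comps) truth[[cc]] <- tab[[cc]]

  structure(list(marker = marker, channels = channels, labels = labels,
                 truth = truth, pixel_size = config$pixel_size,
                 shift = config$shift, config = config),
            class = "fa_image_set")
}

#' Read an image set written by [fa_write_image_set()]
#'
#' @param dir Directory holding `marker.tif`, `channels.tif`, `labels.tif`,
#'   `truth.csv` and `meta.json`.
#' @return A list with `marker` (list of matrices), `channels` (named
#'   list), `labels`, `truth`, `pixel_size`, `shift`. Intensities are
#'   returned on the normalized [0, 1] TIFF scale.
#' @export
fa_read_image_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  as_mats <- function(x) if (is.list(x)) x else list(x)
  marker <- as_mats(tiff::readTIFF(file.path(dir, "marker.tif"), all = TRUE))
  channels <- as_mats(tiff::readTIFF(file.path(dir, "channels.tif"),
                                     all = TRUE))
  names(channels) <- meta$channels
  list(marker = marker, channels = channels,
       labels = tiff::readTIFF(file.path(dir, "labels.tif")),
       truth = as_tibble(read.csv(file.path(dir, "truth.csv"))),
       pixel_size = meta$pixel_size, shift = meta$shift)
}

#' Write an image set to disk as TIFF stacks plus a CSV truth table
#'
#' @param iset An `fa_image_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
fa_write_image_set <- function(iset, dir) {
  stopifnot(inherits(iset, "fa_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  norm <- function(im) im / max(im, 1)
  tiff::writeTIFF(lapply(iset$marker, norm), file.path(dir, "marker.tif"))
  tiff::writeTIFF(lapply(iset$channels, norm), file.path(dir, "channels.tif"))
  tiff::writeTIFF(iset$labels / max(iset$labels, 1),
                  file.path(dir, "labels.tif"))
  write.csv(as.data.frame(iset$truth), file.path(dir, "truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(pixel_size = iset$pixel_size,
                            shift = iset$shift,
                            channels = names(iset$channels),
                            seed = iset$config$seed),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
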