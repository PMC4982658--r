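# Stochastic simulator of adhesion-site assembly. Each adhesion offers a
# number of identical binding sites N drawn from a "diversity" distribution;
# each recruited protein binds with probability p drawn from a "noise"
# distribution around its center. Counts are then binomial (or multinomial
# for competing proteins) realizations. Widening the site distribution
# raises diversity among adhesions; widening the probability distribution
# raises compositional noise.

#' Define a stochastic assembly model
#'
#' @param topology One of `"noncompetitive"` (each protein binds its own
#'   sites independently), `"competitive"` (proteins compete for the same
#'   sites; one site hosts at most one protein) or `"multistep"` (proteins
#'   recruited in ordered layers, counts of a layer serving as sites for
#'   the next).
#' @param sites List describing the site-count distribution:
#'   `dist` in `"uniform"`, `"normal"`, `"poisson"`; `mean` (dimensionless
#'   expected site count); `range` (full width: uniform = mean +/- range/2,
#'   normal sd = range/4 truncated at 0, poisson ignores it).
#' @param proteins Named list, one entry per recruited protein, each a list
#'   with `p` (binding-probability center in (0,1)), `w` (noise width >= 0;
#'   p is drawn uniformly on p +/- w/2 per adhesion and clamped to [0,1])
#'   and optional `stoich` (relative number of binding sites, default 1;
#'   noncompetitive only). For `topology = "multistep"` give `layers`
#'   instead.
#' @param layers For multistep models: list of layers, each a named list of
#'   protein specs as in `proteins` with an additional `parent` naming the
#'   previous-layer protein whose count provides the binding sites
#'   (layer-1 proteins bind the site pool itself).
#' @param site_name Name under which the drawn site count is reported as an
#'   observed component (the recruiting protein); `NULL` to omit.
#'   Defaults to `"A"` for noncompetitive and multistep models and to
#'   `NULL` for competitive models, where the recruiter is not measured.
#' @return An object of class `fa_assembly_model`.
#' @export
assembly_model <- function(topology = c("noncompetitive", "competitive",
                                        "multistep"),
                           sites = list(dist = "uniform", mean = 1000,
                                        range = 0),
                           proteins = NULL, layers = NULL,
                           site_name = NULL) {
  topology <- match.arg(topology)
  sites$dist <- match.arg(sites$dist, c("uniform", "normal", "poisson"))
  sites$range <- sites$range %||% 0
  if (!is.numeric(sites$mean) || sites$mean < 0) {
    stopf("site distribution mean must be nonnegative")
  }
  if (sites$range < 0) stopf("site distribution range must be >= 0")

  check_protein <- function(spec, name) {
    if (is.null(spec$p) || spec$p <= 0 || spec$p >= 1) {
      stopf("protein '%s': binding-probability center must be in (0,1)", name)
    }
    if ((spec$w %||% 0) < 0) stopf("protein '%s': noise width must be >= 0", name)
    spec$w <- spec$w %||% 0
    spec$stoich <- spec$stoich %||% 1
    if (spec$stoich <= 0) stopf("protein '%s': stoichiometry must be > 0", name)
    spec
  }

  if (topology == "multistep") {
    if (is.null(layers) || length(layers) < 2) {
      stopf("multistep topology requires >= 2 layers")
    }
    prev <- NULL
    for (k in seq_along(layers)) {
      nms <- names(layers[[k]])
      if (is.null(nms) || any(nms == "")) stopf("layer %d proteins must be named", k)
      for (nm in nms) {
        layers[[k]][[nm]] <- check_protein(layers[[k]][[nm]], nm)
        par <- layers[[k]][[nm]]$parent
        if (k == 1L) {
          if (!is.null(par)) stopf("layer-1 proteins bind the site pool; no parent")
        } else {
          if (is.null(par) || !par %in% prev) {
            stopf("protein '%s' in layer %d needs a parent from layer %d",
                  nm, k, k - 1L)
          }
        }
      }
      prev <- nms
    }
  } else {
    if (is.null(proteins) || length(proteins) < 1L) {
      stopf("at least one recruited protein required")
    }
    nms <- names(proteins)
    if (is.null(nms) || any(nms == "")) stopf("proteins must be named")
    for (nm in nms) proteins[[nm]] <- check_protein(proteins[[nm]], nm)
    if (topology == "competitive") {
      psum <- sum(vapply(proteins, function(s) s$p, 0))
      if (psum > 1) {
        stopf("competitive topology requires sum of binding centers <= 1 (got %.3f)",
              psum)
      }
    }
  }
  if (is.null(site_name) && topology != "competitive") site_name <- "A"
  structure(list(topology = topology, sites = sites, proteins = proteins,
                 layers = layers, site_name = site_name),
            class = "fa_assembly_model")
}

#' Read an assembly model from a declarative config file
#'
#' The config (YAML or JSON) carries the constructor arguments:
#' `topology`, `sites`, `proteins` (or `layers`), `site_name`.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return An [assembly_model()].
#' @export
read_assembly_model <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  do.call(assembly_model, config)
}

#' Write a simulated dataset as CSV with a truth sidecar
#'
#' The total-level table goes to `path`; the drawn site counts, binding
#' probabilities, model and seed go to `<path>.json`.
#'
#' @param dataset An `fa_sim_dataset`.
#' @param path CSV output path.
#' @param dataset_id Dataset label.
#' @return `path`, invisibly.
#' @export
fa_write_sim_dataset <- function(dataset, path, dataset_id = "sim") {
  stopifnot(inherits(dataset, "fa_sim_dataset"))
  tl <- total_levels(dataset, dataset_id = dataset_id)
  fa_write_table(tl, path, extra = list(
    seed = dataset$seed,
    model = dataset$model[c("topology", "sites", "proteins", "layers",
                            "site_name")],
    truth = list(N = dataset$truth$N)))
  invisible(path)
}

# Draw per-adhesion site counts: nonnegative integers.
draw_sites <- function(sites, n) {
  x <- switch(sites$dist,
    uniform = runif(n, sites$mean - sites$range / 2,
                    sites$mean + sites$range / 2),
    normal  = rnorm(n, sites$mean, sites$range / 4),
    poisson = rpois(n, sites$mean))
  pmax(round(x), 0)
}

# Draw per-adhesion binding probabilities: uniform on p +/- w/2, clamped.
draw_p <- function(spec, n) {
  clamp01(runif(n, spec$p - spec$w / 2, spec$p + spec$w / 2))
}

#' Simulate a set of adhesions from an assembly model
#'
#' One site count N and one binding probability per protein are drawn per
#' adhesion; molecular counts are then binomial (noncompetitive, multistep)
#' or multinomial over the N sites (competitive) realizations.
#'
#' @param model An [assembly_model()].
#' @param n_adhesions Number of adhesions to simulate (>= 1).
#' @param seed Integer seed; identical (model, n, seed) gives identical
#'   output.
#' @return An `fa_sim_dataset`: list with `counts` (list of adhesion x
#'   protein matrices, one per layer), `truth` (drawn N and p values),
#'   `model`, `seed`.
#' @export
simulate_adhesion_set <- function(model, n_adhesions, seed) {
  stopifnot(inherits(model, "fa_assembly_model"))
  if (n_adhesions < 1) stopf("n_adhesions must be >= 1")
  set.seed(as.integer(seed))
  n <- as.integer(n_adhesions)
  N <- draw_sites(model$sites, n)

  if (model$topology == "noncompetitive") {
    nms <- names(model$proteins)
    pdraw <- vapply(model$proteins, draw_p, numeric(n), n = n)
    if (n == 1L) pdraw <- matrix(pdraw, nrow = 1, dimnames = list(NULL, nms))
    cnt <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
    for (j in seq_along(nms)) {
      size <- round(N * model$proteins[[j]]$stoich)
      cnt[, j] <- rbinom(n, size, pdraw[, j])
    }
    counts <- list(cnt)
    truth <- list(N = N, p = pdraw)
  } else if (model$topology == "competitive") {
    nms <- names(model$proteins)
    pdraw <- vapply(model$proteins, draw_p, numeric(n), n = n)
    if (n == 1L) pdraw <- matrix(pdraw, nrow = 1, dimnames = list(NULL, nms))
    # Joint allocation over N identical sites: at most one protein per site.
    # If clamped draws sum above 1 they are scaled back jointly.
    rs <- rowSums(pdraw)
    over <- rs > 1
    if (any(over)) pdraw[over, ] <- pdraw[over, , drop = FALSE] / rs[over]
    # Multinomial allocation drawn by its exact sequential-binomial
    # decomposition (vectorized over adhesions): protein j receives
    # Binomial(remaining sites, p_j / remaining probability).
    cnt <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
    rem_sites <- N
    rem_prob <- rep(1, n)
    for (j in seq_along(nms)) {
      pj <- ifelse(rem_prob > 0, pmin(pdraw[, j] / rem_prob, 1), 0)
      cnt[, j] <- rbinom(n, rem_sites, pj)
      rem_sites <- rem_sites - cnt[, j]
      rem_prob <- rem_prob - pdraw[, j]
    }
    counts <- list(cnt)
    truth <- list(N = N, p = pdraw)
  } else { # multistep
    counts <- vector("list", length(model$layers))
    pall <- list()
    parent_counts <- matrix(N, n, 1, dimnames = list(NULL, "..sites.."))
    for (k in seq_along(model$layers)) {
      layer <- model$layers[[k]]
      nms <- names(layer)
      cnt <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
      for (j in seq_along(nms)) {
        spec <- layer[[j]]
        par <- if (k == 1L) parent_counts[, 1] else parent_counts[, spec$parent]
        pj <- draw_p(spec, n)
        cnt[, j] <- rbinom(n, round(par * spec$stoich), pj)
        pall[[paste0("L", k, ".", nms[j])]] <- pj
      }
      counts[[k]] <- cnt
      parent_counts <- cnt
    }
    truth <- list(N = N, p = pall)
  }
  structure(list(counts = counts, truth = truth, model = model,
                 seed = as.integer(seed)),
            class = "fa_sim_dataset")
}

#' Total per-protein levels of a simulated dataset
#'
#' The total level of a protein in an adhesion is the sum of its counts over
#' all assemblies/layers in which it was recruited. The drawn site count is
#' reported as the recruiting component when the model carries a
#' `site_name`.
#'
#' @param dataset An `fa_sim_dataset`.
#' @param dataset_id Dataset label for the resulting table.
#' @return An [fa_density_table()] of total levels.
#' @export
total_levels <- function(dataset, dataset_id = "sim") {
  stopifnot(inherits(dataset, "fa_sim_dataset"))
  n <- length(dataset$truth$N)
  prot <- unique(unlist(lapply(dataset$counts, colnames)))
  tot <- matrix(0, n, length(prot), dimnames = list(NULL, prot))
  for (cnt in dataset$counts) {
    for (nm in colnames(cnt)) tot[, nm] <- tot[, nm] + cnt[, nm]
  }
  comps <- prot
  df <- tibble(dataset = rep(dataset_id, n), adhesion = seq_len(n))
  if (!is.null(dataset$model$site_name)) {
    sn <- dataset$model$site_name
    df[[sn]] <- as.numeric(dataset$truth$N)
    comps <- c(sn, comps)
  }
  for (nm in prot) df[[nm]] <- as.numeric(tot[, nm])
  fa_density_table(df, components = comps)
}

# Apply (noise, diversity) grid levels to a model template: the noise level
# sets every protein's probability width w, the diversity level sets the
# site-distribution range.
apply_grid_levels <- function(model, noise, diversity) {
  model$sites$range <- diversity
  if (model$topology == "multistep") {
    for (k in seq_along(model$layers)) {
      for (nm in names(model$layers[[k]])) model$layers[[k]][[nm]]$w <- noise
    }
  } else {
    for (nm in names(model$proteins)) model$proteins[[nm]]$w <- noise
  }
  model
}

# Which verdicts are consistent with an imposed (noise, diversity) change
# from category 1 to category 2. Pure changes pin the expected quadrant;
# mixed changes leave the ambiguous axis open (the "expected region" logic
# used when validating the inference on simulated grids).
consistent_verdicts <- function(dnoise, ddiv) {
  if (dnoise == 0 && ddiv == 0) return("inconclusive")
  if (ddiv == 0) {
    return(if (dnoise > 0) "noise_lower_in_1" else "noise_lower_in_2")
  }
  if (dnoise == 0) {
    return(if (ddiv > 0) "diversity_higher_in_2" else "diversity_higher_in_1")
  }
  # Both axes move: CV responds to both with the same sign only when they
  # agree; r2 responses oppose. Any verdict in the affected half-planes
  # (or inconclusive, if the effects cancel) is consistent.
  c(if (dnoise > 0) "noise_lower_in_1" else "noise_lower_in_2",
    if (ddiv > 0) "diversity_higher_in_2" else "diversity_higher_in_1",
    "inconclusive")
}

#' Validate the noise-inference rules on a simulated grid
#'
#' For every ordered pair of (noise width, diversity range) grid cells,
#' repeatedly simulates paired category datasets, runs the
#' delta-log(CV) / delta-r-squared inference on their total-level tables and
#' tabulates how often the verdict is consistent with the imposed change.
#'
#' @param model_template An [assembly_model()]; its per-protein widths and
#'   site range are overridden by the grid levels.
#' @param noise_levels,diversity_levels Numeric grids (>= 1 level each; at
#'   least 2 levels over the two axes combined).
#' @param n_adhesions Adhesions per simulated dataset.
#' @param reps Replicates per ordered cell pair.
#' @param seed Integer seed.
#' @param datasets_per_rep Independent dataset pairs entering each
#'   replicate's mean and SEM (mirroring the multi-dataset design of the
#'   study).
#' @return Tibble: one row per ordered cell pair with the imposed levels,
#'   the modal verdict and the fraction of consistent replicates.
#' @export
inference_validation_grid <- function(model_template, noise_levels,
                                      diversity_levels, n_adhesions = 2000,
                                      reps = 20, seed = 1,
                                      datasets_per_rep = 6) {
  stopifnot(inherits(model_template, "fa_assembly_model"))
  if (length(noise_levels) < 1 || length(diversity_levels) < 1 ||
      length(noise_levels) + length(diversity_levels) < 3) {
    stopf("need at least 2 levels across the noise and diversity axes")
  }
  if (reps < 1) stopf("reps must be >= 1")
  cells <- expand.grid(noise = noise_levels, diversity = diversity_levels,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- expand.grid(i = seq_len(nrow(cells)), j = seq_len(nrow(cells)),
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(pairs))
  sidx <- 0L
  for (k in seq_len(nrow(pairs))) {
    c1 <- cells[pairs$i[k], ]
    c2 <- cells[pairs$j[k], ]
    m1 <- apply_grid_levels(model_template, c1$noise, c1$diversity)
    m2 <- apply_grid_levels(model_template, c2$noise, c2$diversity)
    expected <- consistent_verdicts(c2$noise - c1$noise,
                                    c2$diversity - c1$diversity)
    verdicts <- character(reps)
    for (r in seq_len(reps)) {
      mats1 <- vector("list", datasets_per_rep)
      mats2 <- vector("list", datasets_per_rep)
      for (d in seq_len(datasets_per_rep)) {
        sidx <- sidx + 1L
        ds1 <- simulate_adhesion_set(m1, n_adhesions, derive_seed(seed, sidx))
        sidx <- sidx + 1L
        ds2 <- simulate_adhesion_set(m2, n_adhesions, derive_seed(seed, sidx))
        mats1[[d]] <- fa_density_matrix(total_levels(ds1))
        mats2[[d]] <- fa_density_matrix(total_levels(ds2))
      }
      dcv <- delta_log_cv(mats1, mats2, min_n = 5)
      dr2 <- delta_r2(mats1, mats2, min_n = 5)
      verdicts[r] <- infer_change(dcv, dr2)
    }
    out[[k]] <- tibble(
      noise1 = c1$noise, diversity1 = c1$diversity,
      noise2 = c2$noise, diversity2 = c2$diversity,
      reps = reps,
      modal_verdict = names(sort(table(verdicts), decreasing = TRUE))[1],
      fraction_consistent = mean(verdicts %in% expected))
  }
  do.call(rbind, out)
}
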