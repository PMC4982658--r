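# Shared fixture builders: tiny assembly models, density tables and
# fabricated predictor results. Everything is generated in code at test
# time under fixed seeds.

noncomp_model <- function(mean_sites = 1000, range = 0, pB = 0.4, pC = 0.3,
                          w = 0, dist = "uniform") {
  assembly_model("noncompetitive",
                 sites = list(dist = dist, mean = mean_sites, range = range),
                 proteins = list(B = list(p = pB, w = w),
                                 C = list(p = pC, w = w)))
}

comp_model <- function(mean_sites = 100, range = 0, pB = 0.4, pC = 0.4,
                       w = 0) {
  assembly_model("competitive",
                 sites = list(dist = "uniform", mean = mean_sites,
                              range = range),
                 proteins = list(B = list(p = pB, w = w),
                                 C = list(p = pC, w = w)))
}

twostep_model <- function(mean_sites = 1000, range = 300, w = 0.2) {
  assembly_model("multistep",
                 sites = list(dist = "uniform", mean = mean_sites,
                              range = range),
                 layers = list(
                   list(B = list(p = 0.5, w = w)),
                   list(D = list(p = 0.5, w = w, parent = "B"))))
}

# Minimal valid density table: n adhesions, 3 components, one dataset.
tiny_table <- function(n = 20, dataset = "R1O1", seed = 1,
                       components = c("u", "v", "w")) {
  set.seed(seed)
  df <- tibble::tibble(dataset = dataset, adhesion = seq_len(n),
                       area = stats::rlnorm(n, 1, 0.5),
                       eccentricity = stats::runif(n, 0.5, 0.95))
  for (cc in components) df[[cc]] <- stats::rlnorm(n, 3, 0.4)
  fa_density_table(df, components)
}

# Fabricated predictor result with prescribed per-adhesion errors.
fake_result <- function(target, inputs, errors, mse = mean(errors^2)) {
  structure(list(target = target, inputs = sort(inputs),
                 method = "fake", key = paste(sort(inputs), collapse = "+"),
                 mse = mse, r2 = NA_real_, sq_errors = errors^2,
                 session_mse = NULL, n_failed = 0L),
            class = "fa_predictor_result")
}

# Full fabricated result set over a component universe: per-subset noise
# scale chosen by `scale_fun(subset)`; n errors each.
fake_screen <- function(components, target, scale_fun, n = 200, seed = 1) {
  set.seed(seed)
  sets <- enumerate_input_sets(components, target)
  lapply(sets, function(s) {
    res <- fake_result(target, s, stats::rnorm(n, 0, scale_fun(s)))
    res$r2 <- 1 / (1 + scale_fun(s))
    res
  })
}

# Independent oracle: between-class variance of binned data maximized by
# explicit exhaustive search over all threshold pairs; ties resolved, as
# in the implementation's stated convention, by the tied cut pair closest
# to the component-wise median of all maximizers.
otsu_oracle <- function(values, n_bins) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bins <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1),
               n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cuts <- list()
  vals <- numeric(0)
  for (c1 in 1:(n_bins - 2)) {
    for (c2 in (c1 + 1):(n_bins - 1)) {
      cls <- cut(bins, c(0, c1, c2, n_bins), labels = FALSE)
      mu <- rep(NA_real_, 3)
      tp <- tapply(mids[bins], cls, mean)
      mu[as.integer(names(tp))] <- tp
      w <- tabulate(cls, 3) / length(bins)
      ok <- !is.na(mu)
      v <- sum(w[ok] * (mu[ok] - sum(w[ok] * mu[ok]) / sum(w[ok]))^2)
      cuts[[length(cuts) + 1]] <- c(c1, c2)
      vals <- c(vals, v)
    }
  }
  tied <- which(vals >= max(vals) - abs(max(vals)) * 1e-12)
  cand <- do.call(cbind, cuts[tied])
  med <- apply(cand, 1, stats::median)
  best <- cand[, which.min(colSums(abs(cand - med)))]
  edges[best + 1]
}

# Label-map pair with two disjoint square regions a given distance apart.
shifted_pair <- function(gap) {
  prev <- matrix(0L, 64, 64)
  cur <- matrix(0L, 64, 64)
  prev[10:13, 10:13] <- 1L
  cur[10:13, (10 + gap):(13 + gap)] <- 1L
  list(prev, cur)
}

# Six-dataset planted-structure study for the high-order screen: target
# is a noisy function of all four inputs.
planted_tables <- function(n = 5000, seed = 1, noise_sd = 0.3) {
  roster <- data.frame(dataset = c("R1O1", "R1O2", "R2O1", "R2O2",
                                   "R3O1", "R3O2"),
                       order = rep(c("O1", "O2"), 3))
  tabs <- lapply(seq_len(nrow(roster)), function(k) {
    set.seed(seed * 1000 + k)
    X <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
    y <- X[, 1] + 0.8 * X[, 2] - 0.5 * X[, 3] + 0.6 * X[, 4] * X[, 1] +
      stats::rnorm(n, 0, noise_sd)
    data.frame(X, tgt = y)
  })
  names(tabs) <- roster$dataset
  list(tables = tabs, labeling_order = roster$order)
}
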