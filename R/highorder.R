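# High-order relation screen: for a chosen target component, predictors
# (a small neural network and, as cross-check, a Random Forest) are
# trained on every non-empty subset of the remaining components. The
# subset lattice is turned into a DAG whose edges point toward the subset
# that predicts the target significantly better (F-test on per-adhesion
# squared errors); a node's L-score locates it between the single-input
# nodes and the prediction-optimal sinks. Subsets with high L reproducibly
# across datasets indicate that the target integrates multiple components.

subset_key <- function(members) paste(sort(members), collapse = "+")

#' Enumerate all input subsets for one target
#'
#' All non-empty subsets of the components other than the target, in
#' deterministic order (by size, then lexicographic). For the 10-component
#' panel this yields 511 subsets per target.
#'
#' @param components Component universe.
#' @param target Target component (must be in `components`).
#' @return List of character vectors.
#' @export
enumerate_input_sets <- function(components, target) {
  if (!target %in% components) stopf("target '%s' not in components", target)
  pool <- sort(setdiff(components, target))
  m <- length(pool)
  if (m < 1) stopf("no input components besides the target")
  sets <- list()
  for (size in seq_len(m)) {
    cmb <- combn(pool, size, simplify = FALSE)
    ord <- order(vapply(cmb, paste, "", collapse = "+"))
    sets <- c(sets, cmb[ord])
  }
  sets
}

new_predictor_result <- function(target, inputs, method, pred, obs,
                                 session_mse = NULL, n_failed = 0L,
                                 extra = list()) {
  err <- pred - obs
  structure(c(list(
    target = target, inputs = sort(inputs), method = method,
    key = subset_key(inputs),
    mse = mean(err^2),
    r2 = suppressWarnings(cor(pred, obs))^2,
    sq_errors = err^2,
    session_mse = session_mse, n_failed = n_failed), extra),
    class = "fa_predictor_result")
}

#' Fit the neural-network predictor for one input subset
#'
#' A perceptron with three hidden layers (each as wide as the input
#' subset, tanh units, linear output) is trained by Levenberg-Marquardt
#' backpropagation in `sessions` independent sessions, each on a random
#' 40/30/30 train/validation/test split with validation-based early
#' stopping. The final prediction is the mean over session networks,
#' evaluated on the complete dataset; performance is its MSE and
#' coefficient of determination against the observed target. A session
#' that fails to converge is retried once with a new split, then excluded.
#'
#' @param data Data frame or matrix holding numeric component columns
#'   (typically Box-Cox z-scores for one dataset).
#' @param inputs Character vector of input components (non-empty).
#' @param target Target component.
#' @param sessions Training sessions (50 for screens at desk scale; the
#'   full design uses 500).
#' @param seed Integer seed.
#' @param max_epochs,patience Levenberg-Marquardt epoch budget and early
#'   stopping patience.
#' @return An `fa_predictor_result`: `mse`, `r2`, per-adhesion
#'   `sq_errors`, per-session MSEs.
#' @export
fit_ann <- function(data, inputs, target, sessions = 50, seed = 1,
                    max_epochs = 12, patience = 3) {
  if (length(inputs) < 1) stopf("inputs must be non-empty")
  df <- as.data.frame(data)
  if (nrow(df) < 50) stopf("need >= 50 adhesions")
  X <- as.matrix(df[, inputs, drop = FALSE])
  y <- df[[target]]
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  if (any(sx == 0)) sx[sx == 0] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y); sy <- sd(y)
  if (sy == 0) stopf("constant target")
  ys <- (y - my) / sy
  set.seed(as.integer(seed))
  k <- length(inputs)
  fit <- mlp_sessions_cpp(Xs, ys, as.integer(sessions),
                          rep(as.integer(k), 3L),
                          as.integer(max_epochs), as.integer(patience))
  if (fit$n_ok == 0) stopf("all training sessions failed")
  pred <- fit$ensemble * sy + my
  new_predictor_result(target, inputs, "ann", pred, y,
                       session_mse = fit$session_mse * sy^2,
                       n_failed = fit$n_failed)
}

#' Fit the Random-Forest predictor for one input subset
#'
#' Regression forest with all input components candidate at every split
#' (`mtry = |inputs|`, bagging only), 500 trees by default. Complete-data
#' and out-of-bag performance are both recorded.
#'
#' @inheritParams fit_ann
#' @param n_trees Trees to grow.
#' @return An `fa_predictor_result` with an extra `oob_mse` field.
#' @export
fit_rf <- function(data, inputs, target, n_trees = 500, seed = 1) {
  if (length(inputs) < 1) stopf("inputs must be non-empty")
  df <- as.data.frame(data)
  if (nrow(df) < 50) stopf("need >= 50 adhesions")
  X <- df[, inputs, drop = FALSE]
  y <- df[[target]]
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   mtry = length(inputs))
  pred <- predict(rf, X)
  new_predictor_result(target, inputs, "rf", pred, y,
                       extra = list(oob_mse = mean((rf$predicted - y)^2)))
}

#' Correlate neural-network and Random-Forest performance
#'
#' Pearson correlation between the two methods' coefficients of
#' determination over matched (target, subset) keys, plus the mean signed
#' difference (ann minus rf).
#'
#' @param ann_results,rf_results Lists of `fa_predictor_result`.
#' @return List with `r`, `mean_diff`, `n`, and the matched `r2` tibble.
#' @export
compare_predictors <- function(ann_results, rf_results) {
  key_of <- function(res) paste(res$target, res$key, sep = "|")
  ka <- vapply(ann_results, key_of, "")
  kr <- vapply(rf_results, key_of, "")
  if (!setequal(ka, kr) || length(ka) != length(kr)) {
    stopf("ann and rf results must cover the same (target, subset) keys")
  }
  m <- match(ka, kr)
  r2a <- vapply(ann_results, `[[`, 0, "r2")
  r2r <- vapply(rf_results, `[[`, 0, "r2")[m]
  list(r = cor(r2a, r2r), mean_diff = mean(r2a - r2r), n = length(ka),
       r2 = tibble(key = ka, ann = r2a, rf = r2r))
}

# Two-sided variance-ratio F-test on two per-adhesion squared-error
# samples: F = MSE1 / MSE2 with (n1, n2) df.
mse_f_test <- function(se1, se2) {
  f <- mean(se1) / mean(se2)
  p <- pf(f, length(se1), length(se2))
  list(f = f, p = 2 * min(p, 1 - p))
}

#' Build the F-test-directed subset-lattice DAG for one target
#'
#' Nodes are all non-empty input subsets (511 for a 10-component panel);
#' edges join subsets differing by exactly one component and point toward
#' the node predicting the target significantly better (two-sided
#' variance-ratio F-test on per-adhesion squared errors at `alpha`);
#' non-significant pairs get no edge. Each node is scored
#' `L = L1 / (L1 + L2)`, with `L1`/`L2` the shortest edge distances (on
#' the existing edges, direction ignored) to the closest single-component
#' node and the closest null-out-degree node.
#'
#' @param results List of `fa_predictor_result` covering every subset for
#'   one target (e.g. from [screen_target()]).
#' @param alpha F-test significance level.
#' @return An `fa_relation_dag`: list with `nodes` tibble (`key`, `size`,
#'   `mse`, `r2`, `out_degree`, `L`), `edges` tibble, `target`, `alpha`.
#' @export
build_relation_dag <- function(results, alpha = 0.05) {
  target <- results[[1]]$target
  pool <- sort(unique(unlist(lapply(results, `[[`, "inputs"))))
  m <- length(pool)
  keys <- vapply(results, `[[`, "", "key")
  expect <- vapply(enumerate_input_sets(c(pool, target), target),
                   subset_key, "")
  if (!setequal(keys, expect) || length(keys) != length(expect)) {
    stopf("results must cover all %d subsets exactly once", 2^m - 1)
  }
  res <- results[match(expect, keys)]
  names(res) <- expect
  bit_members <- function(mask) pool[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0]
  mask_of <- vapply(res, function(r) {
    sum(bitwShiftL(1L, match(r$inputs, pool) - 1L))
  }, 0)
  key_by_mask <- setNames(names(res), mask_of)

  from <- character(0); to <- character(0)
  for (kk in names(res)) {
    mk <- as.integer(mask_of[[kk]])
    for (b in seq_len(m) - 1L) {
      bit <- bitwShiftL(1L, b)
      if (bitwAnd(mk, bit) == 0) next
      sub <- mk - bit
      if (sub == 0L) next
      k2 <- key_by_mask[[as.character(sub)]]
      ft <- mse_f_test(res[[k2]]$sq_errors, res[[kk]]$sq_errors)
      if (ft$p < alpha) {
        better <- if (res[[kk]]$mse < res[[k2]]$mse) kk else k2
        worse <- if (identical(better, kk)) k2 else kk
        from <- c(from, worse); to <- c(to, better)
      }
    }
  }
  edges <- tibble(from = from, to = to)
  nodes <- tibble(
    key = names(res),
    size = vapply(res, function(r) length(r$inputs), 0L),
    mse = vapply(res, `[[`, 0, "mse"),
    r2 = vapply(res, `[[`, 0, "r2"))
  nodes$out_degree <- vapply(nodes$key, function(k) sum(edges$from == k), 0L,
                             USE.NAMES = FALSE)
  nodes$L <- dag_l_scores(nodes, edges)
  structure(list(target = target, inputs = pool, nodes = nodes,
                 edges = edges, alpha = alpha),
            class = "fa_relation_dag")
}

# L per node: distances on the undirected graph of existing edges.
dag_l_scores <- function(nodes, edges) {
  n <- nrow(nodes)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$key))
  singles <- nodes$key[nodes$size == 1L]
  sinks <- nodes$key[nodes$out_degree == 0L]
  d1 <- if (length(singles)) {
    apply(igraph::distances(g, v = nodes$key, to = singles), 1, min)
  } else rep(Inf, n)
  d2 <- if (length(sinks)) {
    apply(igraph::distances(g, v = nodes$key, to = sinks), 1, min)
  } else rep(Inf, n)
  L <- ifelse(is.finite(d1) & is.finite(d2) & (d1 + d2) > 0,
              d1 / (d1 + d2), NA_real_)
  as.numeric(L)
}

#' L-score of a node
#'
#' @param dag An `fa_relation_dag`.
#' @param node Character vector of input components (or a subset key).
#' @return The node's L in `[0, 1]`, or `NA` where undefined.
#' @export
l_score <- function(dag, node) {
  stopifnot(inherits(dag, "fa_relation_dag"))
  key <- if (length(node) > 1) subset_key(node) else node
  i <- match(key, dag$nodes$key)
  if (is.na(i)) stopf("node '%s' not in DAG", key)
  dag$nodes$L[i]
}

#' Run the predictor screen over all subsets for one target
#'
#' @param data Data frame/matrix of component columns for one dataset.
#' @param target Target component.
#' @param components Component universe (default: all columns of `data`
#'   that are components).
#' @param sessions Training sessions per subset.
#' @param seed Integer seed (fanned out per subset).
#' @param method `"ann"` or `"rf"`.
#' @param ... Passed to [fit_ann()] / [fit_rf()].
#' @return List of `fa_predictor_result`, one per subset.
#' @export
screen_target <- function(data, target, components = colnames(data),
                          sessions = 50, seed = 1, method = c("ann", "rf"),
                          ...) {
  method <- match.arg(method)
  sets <- enumerate_input_sets(components, target)
  lapply(seq_along(sets), function(i) {
    if (method == "ann") {
      fit_ann(data, sets[[i]], target, sessions = sessions,
              seed = derive_seed(seed, i), ...)
    } else {
      fit_rf(data, sets[[i]], target, seed = derive_seed(seed, i), ...)
    }
  })
}

#' Select reproducible high-order relations across datasets
#'
#' A subset is selected when its L exceeds `threshold` in at least
#' `min_datasets` datasets with at least `min_per_order` datasets from
#' each labeling order. Selected relations report their subset size and
#' mean R-squared across datasets; relations with mean R-squared below
#' `r2_min` are flagged.
#'
#' @param dags Named list of `fa_relation_dag`, one per dataset.
#' @param labeling_order Character vector (per dataset, e.g. "O1"/"O2").
#' @param threshold L threshold (default 0.7).
#' @param min_datasets Minimum qualifying datasets (default 4).
#' @param min_per_order Minimum qualifying datasets per labeling order.
#' @param r2_min Mean-R2 flag level (default 0.6).
#' @return Tibble of selected relations: `key`, `size`, `n_datasets`,
#'   `mean_r2`, `low_r2`.
#' @export
select_high_order <- function(dags, labeling_order, threshold = 0.7,
                              min_datasets = 4, min_per_order = 2,
                              r2_min = 0.6) {
  if (length(dags) < min_datasets) {
    stopf("need at least %d datasets (got %d)", min_datasets, length(dags))
  }
  if (length(labeling_order) != length(dags)) {
    stopf("labeling_order must have one entry per dataset")
  }
  keys <- dags[[1]]$nodes$key
  Lmat <- vapply(dags, function(d) d$nodes$L[match(keys, d$nodes$key)],
                 numeric(length(keys)))
  R2mat <- vapply(dags, function(d) d$nodes$r2[match(keys, d$nodes$key)],
                  numeric(length(keys)))
  if (length(keys) == 1L) {
    Lmat <- matrix(Lmat, 1); R2mat <- matrix(R2mat, 1)
  }
  hits <- !is.na(Lmat) & Lmat > threshold
  n_hit <- rowSums(hits)
  per_order <- vapply(unique(labeling_order), function(o) {
    rowSums(hits[, labeling_order == o, drop = FALSE])
  }, numeric(length(keys)))
  if (length(keys) == 1L) per_order <- matrix(per_order, 1)
  sel <- n_hit >= min_datasets & apply(per_order >= min_per_order, 1, all)
  out <- tibble(key = keys[sel],
                size = dags[[1]]$nodes$size[match(keys[sel], dags[[1]]$nodes$key)],
                n_datasets = n_hit[sel],
                mean_r2 = rowMeans(R2mat, na.rm = TRUE)[sel])
  out$low_r2 <- out$mean_r2 < r2_min
  out
}
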