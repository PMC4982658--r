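# Subset enumeration, predictor training, the F-test DAG and the
# cross-dataset selection rule.

test_that("subset enumeration has cardinality 2^(k-1) - 1", {
  expect_length(enumerate_input_sets(fa_components_default(), "paxillin"),
                511)
  expect_length(enumerate_input_sets(c("a", "b"), "a"), 1)
  expect_length(enumerate_input_sets(c("a", "b", "c", "d"), "d"), 7)
  for (k in 2:6) {
    comps <- letters[1:k]
    expect_length(enumerate_input_sets(comps, comps[1]), 2^(k - 1) - 1)
  }
  # deterministic order: by size then lexicographic
  sets <- enumerate_input_sets(c("c", "a", "b"), "c")
  expect_identical(sets, list("a", "b", c("a", "b")))
  expect_error(enumerate_input_sets(c("a", "b"), "z"), "not in components")
})

test_that("the network recovers a noiseless linear target", {
  set.seed(61)
  n <- 600
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  df$t <- 2 * df$a - df$b + 0.5 * df$c
  r <- fit_ann(df, c("a", "b", "c"), "t", sessions = 8, seed = 3)
  expect_gt(r$r2, 0.99)
  # a target independent of the inputs is unpredictable
  set.seed(62)
  df2 <- data.frame(a = rnorm(5000), b = rnorm(5000), t = rnorm(5000))
  r0 <- fit_ann(df2, c("a", "b"), "t", sessions = 5, seed = 4)
  expect_lt(abs(r0$r2), 0.05)
  # fixed seed reproduces splits and aggregate error exactly
  ra <- fit_ann(df, c("a", "b"), "t", sessions = 5, seed = 7)
  rb <- fit_ann(df, c("a", "b"), "t", sessions = 5, seed = 7)
  expect_identical(ra$mse, rb$mse)
  expect_identical(ra$session_mse, rb$session_mse)
  expect_error(fit_ann(df, character(0), "t"), "non-empty")
})

test_that("the Random Forest recovers monotone structure and is stable
           under duplicated inputs", {
  set.seed(63)
  n <- 400
  df <- data.frame(a = rnorm(n))
  df$t <- df$a^3
  r <- fit_rf(df, "a", "t", n_trees = 200, seed = 5)
  expect_gt(r$r2, 0.95)
  df$a2 <- df$a
  rdup <- fit_rf(df, c("a", "a2"), "t", n_trees = 200, seed = 5)
  expect_lt(abs(rdup$r2 - r$r2), 0.02)
  ra <- fit_rf(df, "a", "t", n_trees = 100, seed = 6)
  rb <- fit_rf(df, "a", "t", n_trees = 100, seed = 6)
  expect_identical(ra$mse, rb$mse)
})

test_that("ann and rf performance agree on linear synthetic tables", {
  set.seed(64)
  n <- 400
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  df$t <- df$a + 0.6 * df$b + rnorm(n, 0, 0.3)
  comps <- c("a", "b", "c", "t")
  ann <- screen_target(df, "t", comps, sessions = 5, seed = 1, method = "ann")
  rf <- screen_target(df, "t", comps, sessions = 5, seed = 1, method = "rf",
                      n_trees = 100)
  cmp <- compare_predictors(ann, rf)
  expect_gt(cmp$r, 0.8)
  expect_equal(cmp$n, 7)
  # identical result lists correlate perfectly with zero difference
  self <- compare_predictors(ann, ann)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$mean_diff, 0)
  expect_error(compare_predictors(ann[1:3], rf), "same")
})

test_that("identical predictions yield an edgeless DAG", {
  comps <- c("a", "b", "c", "tgt")
  err <- rnorm(100)
  res <- lapply(enumerate_input_sets(comps, "tgt"), function(s) {
    fake_result("tgt", s, err)
  })
  dag <- build_relation_dag(res)
  expect_equal(nrow(dag$edges), 0)
  expect_equal(nrow(dag$nodes), 7)
})

test_that("edge direction follows the significantly better predictor and
           flips when the error samples swap", {
  comps <- c("a", "b", "tgt")
  set.seed(65)
  big <- rnorm(300, 0, 2); small <- rnorm(300, 0, 1); mid <- rnorm(300, 0, 1.9)
  res <- list(fake_result("tgt", "a", big),
              fake_result("tgt", "b", mid),
              fake_result("tgt", c("a", "b"), small))
  dag <- build_relation_dag(res)
  expect_true(all(dag$edges$to == "a+b"))
  # swapping the two samples reverses the direction
  res_sw <- list(fake_result("tgt", "a", small),
                 fake_result("tgt", "b", mid),
                 fake_result("tgt", c("a", "b"), big))
  dag_sw <- build_relation_dag(res_sw)
  expect_true(all(dag_sw$edges$from == "a+b"))
  expect_error(build_relation_dag(res[1:2]), "all 3 subsets")
})

test_that("DAG edges connect only subsets at Hamming distance one and
           L-scores sit at the stated landmarks", {
  comps <- c(paste0("p", 1:4), "tgt")
  # planted structure: error scale shrinks as more true inputs are used
  res <- fake_screen(comps, "tgt",
                     scale_fun = function(s) 2 / (1 + length(s)),
                     n = 400, seed = 66)
  dag <- build_relation_dag(res)
  split_key <- function(k) strsplit(k, "+", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(dag$edges))) {
    a <- split_key(dag$edges$from[i]); b <- split_key(dag$edges$to[i])
    expect_equal(length(union(a, b)) - length(intersect(a, b)), 1L)
  }
  nodes <- dag$nodes
  # the full set is the only sink and scores L = 1
  full <- nodes[nodes$size == 4, ]
  expect_equal(full$out_degree, 0L)
  expect_equal(full$L, 1)
  # connected singletons score L = 0
  singles <- nodes[nodes$size == 1 & nodes$out_degree > 0, ]
  expect_true(all(singles$L == 0))
  # pair nodes sit one edge from a singleton, two from the sink: L = 1/3
  expect_true(all(abs(nodes$L[nodes$size == 2] - 1 / 3) < 1e-12 |
                  is.na(nodes$L[nodes$size == 2])))
  expect_equal(l_score(dag, c("p1", "p2", "p3", "p4")), 1)
})

# Minimal hand-built DAG list for the selection rule.
fake_dag <- function(L_by_key, r2 = 0.8) {
  keys <- names(L_by_key)
  structure(list(
    target = "tgt", inputs = NULL,
    nodes = tibble::tibble(key = keys,
                           size = lengths(strsplit(keys, "+", fixed = TRUE)),
                           mse = 1, r2 = r2,
                           out_degree = 0L, L = unname(L_by_key)),
    edges = tibble::tibble(from = character(0), to = character(0)),
    alpha = 0.05), class = "fa_relation_dag")
}

test_that("selection demands L > 0.7 in >= 4 datasets balanced across
           labeling orders", {
  hiL <- c("a+b+c" = 0.9, "a" = 0)
  loL <- c("a+b+c" = 0.2, "a" = 0)
  orders <- c("O1", "O1", "O1", "O1", "O2", "O2")
  # qualifying datasets all from one order: rejected
  dags1 <- list(fake_dag(hiL), fake_dag(hiL), fake_dag(hiL), fake_dag(hiL),
                fake_dag(loL), fake_dag(loL))
  sel1 <- select_high_order(dags1, orders)
  expect_equal(nrow(sel1), 0)
  # 5 of 6 balanced datasets: selected
  dags2 <- list(fake_dag(hiL), fake_dag(hiL), fake_dag(hiL), fake_dag(loL),
                fake_dag(hiL), fake_dag(hiL))
  sel2 <- select_high_order(dags2, orders)
  expect_equal(sel2$key, "a+b+c")
  expect_equal(sel2$n_datasets, 5)
  expect_false(sel2$low_r2)
  # low mean R2 is flagged
  dags3 <- lapply(1:6, function(i) fake_dag(hiL, r2 = 0.3))
  sel3 <- select_high_order(dags3, orders)
  expect_true(sel3$low_r2)
  expect_error(select_high_order(dags2[1:3], orders[1:3]), "at least 4")
})
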