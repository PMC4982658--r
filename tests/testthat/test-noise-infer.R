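# The delta-log(CV) / delta-r2 inference statistic and its verdict rule.

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  x <- rlnorm(50, 2, 0.3)
  expect_equal(coefficient_of_variation(x),
               coefficient_of_variation(10 * x), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-5, 1)), "non-positive")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("pairwise r2 matches brute-force covariance arithmetic", {
  m <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 6,
                5, 5, 4, 8, 2), 5, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  pr <- pairwise_r2(m)
  brute <- function(x, y) {
    (sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)) / (sd(x) * sd(y))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(pr$r[i, j], brute(m[, i], m[, j]), tolerance = 1e-12)
    expect_equal(pr$r2[i, j], pr$r[i, j]^2, tolerance = 1e-15)
  }
  # duplicated column correlates perfectly
  dup <- cbind(m, d = m[, "a"])
  expect_equal(pairwise_r2(dup)$r["a", "d"], 1, tolerance = 1e-12)
  # independent columns at large n stay near zero
  set.seed(51)
  big <- matrix(rnorm(2e4), 1e4, 2)
  expect_lt(abs(pairwise_r2(big)$r[1, 2]), 0.05)
  # zero-variance columns are flagged undefined
  flat <- cbind(m, f = rep(1, 5))
  expect_warning(prf <- pairwise_r2(flat), "zero-variance")
  expect_true(is.na(prf$r["a", "f"]))
})

test_that("delta-log(CV) handles identity, doubling and the >=5 rule", {
  set.seed(52)
  mats <- lapply(1:3, function(i) {
    matrix(rlnorm(60, 3, 0.4), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  id <- delta_log_cv(mats, mats)
  expect_equal(id$mean, 0, tolerance = 1e-15)
  expect_equal(id$sem, 0, tolerance = 1e-15)
  # doubling every deviation doubles each CV exactly -> mean log(2)
  doubled <- lapply(mats, function(m) {
    t(t(m) * 0 + colMeans(m)) + 2 * sweep(m, 2, colMeans(m))
  })
  d <- delta_log_cv(mats, doubled)
  expect_equal(d$mean, log(2), tolerance = 1e-12)
  # a dataset with fewer than 5 adhesions in one category is excluded
  small <- mats
  small[[2]] <- small[[2]][1:4, , drop = FALSE]
  d2 <- delta_log_cv(mats, small)
  expect_equal(d2$n_datasets, 2)
  expect_equal(d2$excluded_datasets, 1)
  expect_error(delta_log_cv(list(mats[[1]][1:3, ]), list(mats[[1]][1:3, ])),
               ">= 5")
})

test_that("delta-r2 is the difference of squared correlations", {
  set.seed(53)
  mats <- lapply(1:2, function(i) {
    matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  id <- delta_r2(mats, mats)
  expect_equal(id$mean, 0, tolerance = 1e-15)
  # direct arithmetic on one dataset pair
  m1 <- mats[[1]]; m2 <- mats[[2]]
  r1 <- cor(m1); r2 <- cor(m2)
  manual <- mean((r2^2 - r1^2)[upper.tri(r1)])
  d <- delta_r2(list(m1), list(m2))
  expect_equal(d$mean, manual, tolerance = 1e-12)
  # bounded in [-1, 1] for arbitrary inputs
  for (k in 1:5) {
    a <- matrix(rnorm(45), 15, 3); b <- matrix(rnorm(45), 15, 3)
    dd <- delta_r2(list(a), list(b))
    expect_gte(dd$mean, -1); expect_lte(dd$mean, 1)
  }
})

test_that("antisymmetry holds exactly and verdicts swap consistently", {
  set.seed(54)
  mats1 <- lapply(1:3, function(i) matrix(rlnorm(60, 2, 0.3), 20, 3))
  mats2 <- lapply(1:3, function(i) matrix(rlnorm(60, 2, 0.6), 20, 3))
  for (fn in list(delta_log_cv, delta_r2, delta_fano)) {
    ab <- fn(mats1, mats2)
    ba <- fn(mats2, mats1)
    expect_equal(ab$mean, -ba$mean, tolerance = 1e-12)
    expect_equal(ab$sem, ba$sem, tolerance = 1e-12)
  }
  swap <- c(noise_lower_in_2 = "noise_lower_in_1",
            noise_lower_in_1 = "noise_lower_in_2",
            diversity_higher_in_2 = "diversity_higher_in_1",
            diversity_higher_in_1 = "diversity_higher_in_2",
            inconclusive = "inconclusive")
  for (k in 1:10) {
    m1 <- list(mean = rnorm(1, 0, 0.2), sem = abs(rnorm(1, 0, 0.05)))
    m2 <- list(mean = rnorm(1, 0, 0.2), sem = abs(rnorm(1, 0, 0.05)))
    neg <- function(x) list(mean = -x$mean, sem = x$sem)
    expect_equal(infer_change(neg(m1), neg(m2)),
                 unname(swap[infer_change(m1, m2)]))
  }
})

test_that("the verdict quadrants and SEM rule match the inference scheme", {
  d <- function(m, s) list(mean = m, sem = s)
  expect_equal(infer_change(d(-0.2, 0.05), d(0.10, 0.02)), "noise_lower_in_2")
  expect_equal(infer_change(d(0.2, 0.05), d(-0.10, 0.02)), "noise_lower_in_1")
  expect_equal(infer_change(d(0.2, 0.05), d(0.10, 0.02)),
               "diversity_higher_in_2")
  expect_equal(infer_change(d(-0.2, 0.05), d(-0.10, 0.02)),
               "diversity_higher_in_1")
  expect_equal(infer_change(d(-0.03, 0.05), d(0.10, 0.02)), "inconclusive")
  expect_equal(infer_change(d(-0.2, 0.05), d(0.01, 0.02)), "inconclusive")
})

test_that("the Fano variant is near zero for Poisson counts at any mean", {
  set.seed(55)
  mats1 <- lapply(1:4, function(i) {
    matrix(rpois(2000, 20), 1000, 2, dimnames = list(NULL, c("a", "b")))
  })
  mats2 <- lapply(1:4, function(i) {
    matrix(rpois(2000, 80), 1000, 2, dimnames = list(NULL, c("a", "b")))
  })
  d <- delta_fano(mats1, mats2)
  expect_lt(abs(d$mean), 0.15)   # Fano ~ 1 on both sides
  # while the CV change is strongly negative (CV shrinks as 1/sqrt(mean))
  dcv <- delta_log_cv(mats1, mats2)
  expect_lt(dcv$mean, -0.5)
})

test_that("compare_categories slices a study and returns a verdict", {
  cfg <- synthetic_study_config(seed = 56)
  st <- preprocess_study(generate_density_tables(cfg))
  cmp <- compare_categories(st, "density_cat", "low", "high")
  expect_s3_class(cmp, "fa_delta_stats")
  expect_true(cmp$verdict %in% c("noise_lower_in_1", "noise_lower_in_2",
                                 "diversity_higher_in_1",
                                 "diversity_higher_in_2", "inconclusive"))
  expect_gte(cmp$dlogcv$sem, 0)
  # restricting on a second axis narrows the data
  cmp2 <- compare_categories(st, "density_cat", "low", "high",
                             fix = "area_cat", fix_level = "S", min_n = 3)
  expect_lte(cmp2$n_datasets, cmp$n_datasets + 1L)
  expect_error(compare_categories(st, "nope", 1, 2), "not present")
})

test_that("equal-pixel subsampling preserves full-region densities when
           the sample is the whole region", {
  cfg <- synthetic_study_config(seed = 57, adhesions_per_cell = 10,
                                image_noise_sd = 0, shift = c(0, 0))
  iset <- generate_image_set(cfg)
  labs <- iset$labels
  chans <- iset$channels[1:3]
  ids <- sort(unique(labs[labs > 0]))
  cats <- rep(c("S", "L"), length.out = length(ids))
  full <- equal_pixel_control(labs, chans, cats, "S", "L",
                              mode = "fixed", n_pixels = 1e6, seed = 1)
  direct <- measure_regions(labs, chans)
  for (nm in names(chans)) {
    expect_equal(full$densities[[nm]], direct[[nm]], tolerance = 1e-12)
  }
  # fixed-seed subsampling is reproducible, and samples 10 px per adhesion
  s1 <- equal_pixel_control(labs, chans, cats, "S", "L",
                            mode = "fixed", n_pixels = 10, seed = 9)
  s2 <- equal_pixel_control(labs, chans, cats, "S", "L",
                            mode = "fixed", n_pixels = 10, seed = 9)
  expect_identical(s1$densities, s2$densities)
  expect_true(all(s1$densities$sampled_pixels <= 10 |
                  s1$densities$sampled_pixels ==
                  tabulate(labs[labs > 0])[ids]))
  # equal-mean mode brings category means of sampled counts together
  em <- equal_pixel_control(labs, chans, cats, "S", "L",
                            mode = "equal_mean", seed = 3)
  mns <- tapply(em$densities$sampled_pixels, em$densities$category, mean)
  expect_lt(abs(diff(mns)) / max(mns), 0.25)
})
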