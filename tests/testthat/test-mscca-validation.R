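test_that("size-one stable sets give plain Pearson correlations", {
  v <- make_views(90, p = c(1, 3, 3), seed = 1, shared = 0.5)
  fit <- refit_unpenalized(v, stable = list(NL = "nl1", UF = "uf2", IW = "iw3"))
  r <- cor(cbind(v$NL$nl1, v$UF$uf2, v$IW$iw3))
  expect_equal(fit$correlations$r, c(r[1, 2], r[1, 3], r[2, 3]),
               tolerance = 1e-10)
  expect_equal(fit$r_mean, mean(c(r[1, 2], r[1, 3], r[2, 3])), tolerance = 1e-10)
})

test_that("projecting the training set onto itself reproduces training correlations", {
  v <- make_views(120, p = c(1, 4, 3), seed = 2, shared = 0.4)
  fit <- refit_unpenalized(v)
  proj <- project_holdout(fit, v)
  expect_equal(proj$correlations$r, fit$correlations$r, tolerance = 1e-12)
})

test_that("holdout correlations track training on planted data", {
  v_tr <- make_views(800, p = c(1, 4, 4), seed = 3, shared = 0.4)
  v_te <- make_views(800, p = c(1, 4, 4), seed = 4, shared = 0.4)
  fit <- refit_unpenalized(v_tr)
  proj <- project_holdout(fit, v_te)
  expect_lt(abs(proj$r_mean - fit$r_mean), 3 / sqrt(800) * 3)
})

test_that("weights concentrated on a null variable give near-zero holdout correlation", {
  v_te <- make_views(500, p = c(1, 3, 3), seed = 5, shared = 0)
  w <- structure(list(weights = list(
    NL = c(nl1 = 1), UF = c(uf1 = 1), IW = c(iw1 = 1)),
    objective = 0, iterations = 0, converged = TRUE,
    l1_budgets = c(1, 1, 1), n = 500), class = "mscca_weights")
  proj <- project_holdout(w, v_te)
  expect_lt(abs(proj$r_mean), 4 / sqrt(500))
})

test_that("empty stable sets abort with advice", {
  v <- make_views(60, p = c(1, 3, 3), seed = 6)
  expect_error(refit_unpenalized(v, stable = list(NL = "nl1", UF = character(0),
                                                  IW = "iw1")),
               "threshold")
})

test_that("missing stable columns in the test data are reported", {
  v <- make_views(60, p = c(1, 3, 3), seed = 7, shared = 0.3)
  fit <- refit_unpenalized(v)
  v_te <- v
  v_te$UF <- v_te$UF[, 1:2]
  expect_error(project_holdout(fit, v_te), "lacks stable column")
})

test_that("an observed statistic above all permutations attains the add-one floor", {
  set.seed(8)
  z <- rnorm(200)
  v <- list(NL = zscore(cbind(nl = z + 0.1 * rnorm(200))),
            UF = zscore(cbind(u = z + 0.1 * rnorm(200))),
            IW = zscore(cbind(w = z + 0.1 * rnorm(200))))
  fit <- refit_unpenalized(v)
  pt <- permutation_test(fit, n_perm = 19, mode = "fixed_weights", seed = 9)
  expect_equal(pt$p_value[pt$statistic == "r_mean"], 1 / 20)
  pt2 <- permutation_test(fit, views = v, n_perm = 19, mode = "refit", seed = 10)
  expect_true(all(pt2$p_value >= 1 / 20))
})

test_that("permutation p-values are reproducible and in (0, 1]", {
  v <- make_views(100, p = c(1, 3, 3), seed = 11, shared = 0.2)
  fit <- refit_unpenalized(v)
  p1 <- permutation_test(fit, n_perm = 50, seed = 12)
  p2 <- permutation_test(fit, n_perm = 50, seed = 12)
  expect_identical(p1$p_value, p2$p_value)
  expect_true(all(p1$p_value > 0 & p1$p_value <= 1))
})

test_that("orthogonal views give a near-zero mean canonical correlation", {
  v <- make_views(900, p = c(1, 3, 3), seed = 13, shared = 0)
  fit <- refit_unpenalized(v)
  expect_lt(abs(fit$r_mean), 4 / sqrt(900))
})
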