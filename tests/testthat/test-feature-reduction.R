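test_that("residualizing on constant covariates just centers the input", {
  set.seed(1)
  y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  covs <- tibble::tibble(flat = rep(2, 20))
  res <- residualize(y, covs)
  expect_equal(as.matrix(res), scale(y, scale = FALSE), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a column equal to a covariate residualizes to zero", {
  set.seed(2)
  age <- rnorm(50)
  y <- cbind(dup = age)
  res <- residualize(y, cbind(age = age))
  expect_lt(sqrt(sum(res$dup^2)), 1e-10)
})

test_that("residuals recover noise built orthogonal to the covariate", {
  set.seed(3)
  n <- 100
  age <- rnorm(n)
  e <- rnorm(n)
  e <- e - age * sum(e * age) / sum(age * age)   # Gram-Schmidt
  e <- e - mean(e) + age * mean(age) * 0         # keep e centered-ish
  y <- cbind(out = 2 * age + e)
  res <- residualize(y, cbind(age = age))
  # residual equals e up to removal of its (tiny) mean component
  fit_e <- e - mean(e) - (age - mean(age)) *
    sum((e - mean(e)) * (age - mean(age))) / sum((age - mean(age))^2)
  expect_equal(res$out, fit_e, tolerance = 1e-10)
})

test_that("residual columns are orthogonal to every covariate column", {
  set.seed(4)
  n <- 200
  covs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  res <- as.matrix(residualize(y, covs))
  expect_lt(max(abs(crossprod(res, covs))), 1e-8 * n)
  expect_lt(max(abs(colSums(res))), 1e-8 * n)
})

test_that("rank-deficient covariates raise an error naming the collinear column", {
  set.seed(5)
  x1 <- rnorm(30)
  covs <- cbind(x1 = x1, x2 = 2 * x1)
  expect_error(residualize(cbind(y = rnorm(30)), covs), "x2")
})

test_that("frozen coefficients reproduce the training residualization on new data", {
  set.seed(6)
  covs <- tibble::tibble(age = rnorm(80), male = rbinom(80, 1, 0.5))
  y <- tibble::tibble(v = 1 + 0.5 * covs$age - covs$male + rnorm(80))
  r_train <- residualize(y, covs)
  r_redo <- residualize(y, covs, coefficients = attr(r_train, "coefficients"))
  expect_equal(as.matrix(r_redo), as.matrix(r_train), tolerance = 1e-12)
})

test_that("zscore centers and scales with the sample (n-1) convention", {
  z <- zscore(cbind(x = c(1, 2, 3)))
  expect_equal(z$x, c(-1, 0, 1))  # sample SD = 1
  expect_identical(attr(z, "sd_convention"), "sample (n-1)")
  set.seed(7)
  y <- matrix(rnorm(500) * 3 + 2, 100, 5, dimnames = list(NULL, paste0("c", 1:5)))
  z2 <- zscore(y)
  expect_lt(max(abs(colMeans(as.matrix(z2)))), 1e-12)
  expect_equal(unname(apply(as.matrix(z2), 2, sd)), rep(1, 5), tolerance = 1e-12)
  # idempotence
  z3 <- zscore(z2)
  expect_equal(as.matrix(z3), as.matrix(z2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zscore refuses zero-variance columns by name", {
  y <- cbind(ok = rnorm(10), flat = rep(1, 10))
  expect_error(zscore(y), "flat")
})

test_that("frozen z-scoring moments transfer to held-out rows", {
  set.seed(8)
  y <- matrix(rnorm(200, 5, 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  z_tr <- zscore(y[1:60, ])
  z_te <- zscore(y[61:100, ], center = attr(z_tr, "center"),
                 scale = attr(z_tr, "scale"))
  manual <- sweep(sweep(y[61:100, ], 2, attr(z_tr, "center")), 2,
                  attr(z_tr, "scale"), `/`)
  expect_equal(as.matrix(z_te), manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("drop_incomplete removes rows with missing values jointly", {
  a <- tibble::tibble(x = c(1, NA, 3, 4))
  b <- tibble::tibble(y = c(1, 2, NA, 4))
  expect_message(out <- drop_incomplete(a, b), "2 incomplete")
  expect_equal(nrow(out[[1]]), 2)
  expect_equal(attr(out, "n_dropped"), 2)
})
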