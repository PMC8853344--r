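test_that("two perfectly correlated members give the hand-computed component", {
  set.seed(1)
  base <- rnorm(200)
  y <- zscore(cbind(m1 = base, m2 = base))
  # correlation matrix [[1,1],[1,1]]: eigenvalues (2, 0),
  # first eigenvector (1, 1)/sqrt(2)
  cs_eig <- category_pca(y, list(cat = c("m1", "m2")),
                         loading_type = "eigenvector")
  expect_equal(cs_eig$loadings$loading, rep(1 / sqrt(2), 2), tolerance = 1e-10)
  cs_cmp <- category_pca(y, list(cat = c("m1", "m2")))
  expect_equal(cs_cmp$loadings$loading, rep(1, 2), tolerance = 1e-10)
  expect_equal(var(cs_cmp$scores$cat), 2, tolerance = 1e-10)
})

test_that("score variance equals the first eigenvalue of the retained correlation matrix", {
  set.seed(2)
  n <- 300
  f <- rnorm(n)
  y <- zscore(sapply(1:4, function(i) 0.8 * f + rnorm(n)))
  colnames(y) <- paste0("m", 1:4)
  names(y) <- paste0("m", 1:4)
  cs <- category_pca(y, list(g = paste0("m", 1:4)))
  lam1 <- eigen(cor(as.matrix(y)[, cs$retained_members$g]))$values[1]
  expect_equal(var(cs$scores$g), lam1, tolerance = 1e-8)
})

test_that("a wide category of near-independent members collapses under the 0.3 rule", {
  # with 16 weakly equicorrelated members the first eigenvector is close
  # to uniform, so every raw eigenvector entry is about 1/4 = 0.25 < 0.3
  # and the whole category is dropped
  set.seed(3)
  n <- 50000
  g <- rnorm(n)
  y <- sqrt(0.02) * g + sqrt(0.98) * matrix(rnorm(n * 16), n, 16)
  colnames(y) <- paste0("m", 1:16)
  y <- zscore(y)
  expect_warning(
    cs <- category_pca(y, list(indep = paste0("m", 1:16)),
                       loading_type = "eigenvector"),
    "excluded")
  expect_equal(ncol(cs$scores), 0)
  expect_length(cs$dropped_members$indep, 16)
})

test_that("single-member categories pass through with loading 1", {
  set.seed(4)
  y <- zscore(cbind(only = rnorm(50)))
  cs <- category_pca(y, list(solo = "only"))
  expect_equal(cs$scores$solo, y$only)
  expect_equal(cs$loadings$loading, 1.0)
})

test_that("scores are invariant to member ordering", {
  set.seed(5)
  n <- 150
  f <- rnorm(n)
  y <- zscore(sapply(1:3, function(i) 0.7 * f + rnorm(n)))
  colnames(y) <- c("a", "b", "c")
  names(y) <- c("a", "b", "c")
  s1 <- category_pca(y, list(g = c("a", "b", "c")))$scores$g
  s2 <- category_pca(y, list(g = c("c", "a", "b")))$scores$g
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("duplicate membership and unknown members are rejected", {
  y <- zscore(cbind(a = rnorm(20), b = rnorm(20)))
  expect_error(category_pca(y, list(g1 = "a", g2 = c("a", "b"))),
               "more than one category")
  expect_error(category_pca(y, list(g1 = c("a", "zzz"))), "absent")
})

test_that("re-running on category scores errors (scores are not re-grouped)", {
  set.seed(6)
  f <- rnorm(100)
  y <- zscore(sapply(1:4, function(i) 0.8 * f + rnorm(100)))
  colnames(y) <- paste0("m", 1:4)
  names(y) <- paste0("m", 1:4)
  groups <- list(g1 = c("m1", "m2"), g2 = c("m3", "m4"))
  cs <- category_pca(y, groups)
  expect_error(category_pca(zscore(cs$scores), groups), "absent")
})

test_that("prediction applies frozen components to new rows", {
  set.seed(7)
  n <- 200
  f <- rnorm(n)
  y <- zscore(sapply(1:3, function(i) 0.9 * f + rnorm(n)))
  colnames(y) <- paste0("m", 1:3)
  names(y) <- paste0("m", 1:3)
  cs <- category_pca(y, list(g = paste0("m", 1:3)))
  again <- predict(cs, y)
  expect_equal(again$g, cs$scores$g, tolerance = 1e-10)
})

test_that("category_pca demands z-normalized input", {
  y <- cbind(a = rnorm(30) * 5 + 3, b = rnorm(30))
  expect_error(category_pca(y, list(g = c("a", "b"))), "z-normalized")
})
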