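test_that("quartile stratification reproduces the cohort counts", {
  # 40078 test-set rows -> 10020 per stratum under round-half-up
  set.seed(1)
  n <- 40078
  d <- tibble::tibble(x = rnorm(n))
  s <- stratify_by_exposure(d, runif(n))
  expect_equal(unname(s$k), c(10020, 10020))
  expect_equal(nrow(s$high), 10020)
})

test_that("tiny stratification follows hand arithmetic and stable tie order", {
  d <- tibble::tibble(v = rnorm(8))
  s <- suppressWarnings(
    stratify_by_exposure(d, c(5, 1, 7, 3, 8, 2, 6, 4), method = "rank"))
  expect_equal(unname(s$k), c(2, 2))
  expect_equal(sort(s$high_idx), c(3, 5))
  # all-equal exposure: deterministic split by stable row order
  s2 <- suppressWarnings(stratify_by_exposure(d, rep(1, 8)))
  s3 <- suppressWarnings(stratify_by_exposure(d, rep(1, 8)))
  expect_identical(s2$high_idx, s3$high_idx)
  expect_equal(s2$low_idx, 1:2)
})

test_that("strata too small for the node count raise a warning", {
  d <- tibble::as_tibble(matrix(rnorm(40 * 10), 40, 10,
                                dimnames = list(NULL, paste0("n", 1:10))))
  expect_warning(stratify_by_exposure(d, rnorm(40)), "too small")
})

test_that("threshold stratification uses strict quantile cutoffs", {
  d <- tibble::tibble(x = rnorm(100))
  e <- as.numeric(1:100)
  s <- stratify_by_exposure(d, e, method = "threshold")
  qs <- quantile(e, c(0.25, 0.75))
  expect_equal(sort(s$high_idx), which(e > qs[2]))
  expect_equal(sort(s$low_idx), which(e < qs[1]))
})

test_that("a two-node network recovers the marginal correlation", {
  set.seed(2)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, sd = sqrt(1 - 0.36))
  net <- estimate_ggm(cbind(a = x, b = y))
  expect_equal(sum(net$adjacency) / 2, 1)
  expect_lt(abs(net$weights["a", "b"] - cor(x, y)), 1e-6)
})

test_that("independent columns give an (almost) empty network", {
  set.seed(3)
  d <- matrix(rnorm(5000 * 6), 5000, 6, dimnames = list(NULL, paste0("v", 1:6)))
  net <- estimate_ggm(d)
  expect_true(all(abs(tidy(net)$weight) < 0.05))
  expect_lt(global_strength(net), 0.1)
})

test_that("planted sparse structure is recovered with high sensitivity and specificity", {
  cfg <- synth_config(n_participants = 5000, seed = 3)
  st <- generate_stratified(cfg)
  net <- estimate_ggm(st$data_low, communities = st$communities,
                      lambda_grid_size = 40)
  tr <- st$truth$pcor_low
  est <- net$weights
  up <- upper.tri(tr)
  sens <- sum(est[up] != 0 & tr[up] != 0) / sum(tr[up] != 0)
  spec <- sum(est[up] == 0 & tr[up] == 0) / sum(tr[up] == 0)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  expect_lt(max(abs(est - tr)), 0.05)
})

test_that("stepwise refinement only ever lowers the EBIC", {
  cfg <- synth_config(n_participants = 800, seed = 5)
  st <- generate_stratified(cfg)
  net <- estimate_ggm(st$data_high, lambda_grid_size = 30, stepwise = TRUE)
  expect_true(all(diff(net$step_ebic) < 0))
  expect_equal(net$ebic, min(net$step_ebic), tolerance = 1e-6)
})

test_that("estimator contracts: symmetry, zero diagonal, bounded weights, p < n", {
  cfg <- synth_config(n_participants = 500, seed = 6)
  st <- generate_stratified(cfg)
  net <- estimate_ggm(st$data_low, lambda_grid_size = 25)
  expect_lt(max(abs(net$weights - t(net$weights))), 1e-12)
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(abs(net$weights) < 1))
  expect_error(estimate_ggm(st$data_low[1:10, ]), "more observations")
  d <- as.matrix(st$data_low[, 1:3])
  d[, 3] <- 1
  expect_error(estimate_ggm(d), "constant")
})

test_that("networks export to GraphML and edge-list CSV", {
  cfg <- synth_config(n_participants = 600, seed = 7)
  st <- generate_stratified(cfg)
  net <- estimate_ggm(st$data_high, communities = st$communities,
                      lambda_grid_size = 25)
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_graphml(net, gml)
  write_edgelist(net, csv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 12)
  edges <- utils::read.csv(csv)
  expect_equal(nrow(edges), sum(net$adjacency) / 2)
})
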