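test_that("inverting the stratum covariance recovers planted partial correlations", {
  cfg <- synth_config(n_participants = 10, seed = 1)
  st <- generate_stratified(cfg)
  for (nm in c("high", "low")) {
    theta <- st$truth[[paste0("theta_", nm)]]
    sigma <- solve(theta)
    kappa <- solve(sigma)
    pc <- -kappa / sqrt(diag(kappa) %o% diag(kappa))
    diag(pc) <- 0
    expect_lt(max(abs(pc - st$truth[[paste0("pcor_", nm)]])), 1e-10)
  }
})

test_that("an indefinite precision matrix is rejected with a diagnostic", {
  cfg <- synth_config(n_participants = 10, stratum_edge_shift = 0.9, seed = 1)
  expect_error(generate_stratified(cfg, within_pc = 0.4, base_cross_pc = 0.4),
               "positive definite")
})

test_that("the 7+5 roster carries the standard labels and plants (PV, Dpr)", {
  st <- generate_stratified(synth_config(n_participants = 10, seed = 2))
  expect_identical(names(st$communities),
                   c("AP", "GS", "ED", "ND", "DE", "DS", "PV",
                     "Dpr", "Dis", "Trd", "Nap", "Wst"))
  expect_identical(unname(st$communities[c("AP", "Dpr")]),
                   c("environment", "mental-physical"))
  high <- st$truth$planted_edges[st$truth$planted_edges$stratum == "high", ]
  expect_true(any(high$node_a == "PV" & high$node_b == "Dpr"))
})

test_that("a planted 0.3 partial correlation on (PV, Dpr) is recovered from the sample", {
  cfg <- synth_config(n_participants = 5000, stratum_edge_shift = 0, seed = 21)
  st <- generate_stratified(cfg, base_cross_pc = 0.3)
  kappa <- solve(cov(as.matrix(st$data_high)))
  pc <- -kappa / sqrt(diag(kappa) %o% diag(kappa))
  expect_lt(abs(pc["PV", "Dpr"] - 0.3), 0.05)
})

test_that("zero shift makes the strata exchangeable; positive shift raises true strength", {
  cfg0 <- synth_config(n_participants = 10, stratum_edge_shift = 0, seed = 3)
  st0 <- generate_stratified(cfg0)
  expect_identical(st0$truth$pcor_high, st0$truth$pcor_low)
  cfg1 <- synth_config(n_participants = 10, stratum_edge_shift = 0.15, seed = 3)
  st1 <- generate_stratified(cfg1)
  expect_gt(global_strength(st1$truth$pcor_high),
            global_strength(st1$truth$pcor_low))
})

test_that("with no cross-community edges every true bridge influence is 0", {
  cfg <- synth_config(n_participants = 10, stratum_edge_shift = 0, seed = 4)
  st <- generate_stratified(cfg, base_cross_pc = 0)
  suppressWarnings(
    b <- bridge_expected_influence(st$truth$pcor_low,
                                   communities = st$communities)
  )
  expect_true(all(b$bei$bei == 0))
  expect_true(b$degenerate)
})
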