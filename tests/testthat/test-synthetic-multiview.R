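test_that("config validation rejects impossible designs", {
  expect_error(synth_config(n_signal_categories = 50, n_categories = 44),
               "n_signal_categories")
  expect_error(synth_config(n_signal_wellbeing = 24, n_wellbeing = 23),
               "n_signal_wellbeing")
  expect_error(synth_config(ordinal_levels = 1), "ordinal_levels")
  expect_error(synth_config(within_category_rho = 1), "positive definite")
  expect_error(synth_config(within_category_rho = -0.1), "positive definite")
  expect_error(synth_config(latent_effect_exposure = Inf), "finite")
})

test_that("generation is bit-reproducible from config and seed", {
  cfg <- synth_config(n_participants = 300, seed = 42)
  d1 <- generate_multiview(cfg)
  d2 <- generate_multiview(cfg)
  expect_identical(d1$exposure, d2$exposure)
  expect_identical(d1$urban, d2$urban)
  expect_identical(d1$wellbeing, d2$wellbeing)
  expect_identical(d1$covariates, d2$covariates)
  d3 <- generate_multiview(synth_config(n_participants = 300, seed = 43))
  expect_false(identical(d1$exposure, d3$exposure))
})

test_that("exposure stays on the digital-number scale for any seed", {
  for (s in c(1, 7, 99, 12345)) {
    d <- generate_multiview(synth_config(n_participants = 200, seed = s))
    expect_gte(min(d$exposure$nle), 0)
    expect_lte(max(d$exposure$nle), 63)
  }
})

test_that("with no shared factor, cross-view correlations vanish", {
  n <- 4000
  cfg <- synth_config(n_participants = n, latent_effect_exposure = 0,
                      latent_effect_features = 0, latent_effect_wellbeing = 0,
                      covariate_effect = 0, seed = 9)
  d <- generate_multiview(cfg)
  rs <- abs(cor(d$exposure$nle, as.matrix(d$wellbeing)))
  expect_lt(max(rs), 4 / sqrt(n))
})

test_that("exposure-measure correlation matches the factor-model closed form", {
  # population correlation between the exposure latent part and a signal
  # measure is a*b / sqrt((a^2+1)(b^2+1)) when both noises have unit
  # variance; the affine rescaling to [0, 63] leaves correlations alone
  cfg <- synth_config(n_participants = 20000, covariate_effect = 0, seed = 31)
  d <- generate_multiview(cfg)
  a <- cfg$latent_effect_exposure
  b <- cfg$latent_effect_features
  expected <- a * b / sqrt((a^2 + 1) * (b^2 + 1))
  for (m in c("category_01_m1", "category_03_m4")) {
    expect_lt(abs(cor(d$exposure$nle, d$urban[[m]]) - expected), 0.02)
  }
  # non-signal measures are uncorrelated with the exposure
  expect_lt(abs(cor(d$exposure$nle, d$urban$category_44_m1)), 0.02)
})

test_that("marginal moments match the population values", {
  n <- 10000
  cfg <- synth_config(n_participants = n, seed = 5)
  d <- generate_multiview(cfg)
  b <- cfg$latent_effect_features
  # signal measure: mean 0, variance b^2 + 1; null measure: variance 1
  for (col in c("category_01_m1", "category_44_m3")) {
    x <- d$urban[[col]]
    sd_pop <- if (col == "category_01_m1") sqrt(b^2 + 1) else 1
    se_mean <- sd_pop / sqrt(n)
    expect_lt(abs(mean(x)), 5 * se_mean)
    se_sd <- sd_pop / sqrt(2 * (n - 1))
    expect_lt(abs(sd(x) - sd_pop), 5 * se_sd)
  }
})

test_that("truth object marks signal variables and zero loadings", {
  cfg <- synth_config(n_participants = 100, seed = 2)
  d <- generate_multiview(cfg)
  tr <- d$truth
  expect_length(tr$signal_category_ids, cfg$n_signal_categories)
  expect_length(tr$signal_wellbeing_ids, cfg$n_signal_wellbeing)
  null_measures <- setdiff(colnames(d$urban),
                           unlist(d$category_map[tr$signal_category_ids]))
  expect_true(all(tr$population_loadings[null_measures] == 0))
  sig_measures <- unlist(d$category_map[tr$signal_category_ids])
  expect_true(all(tr$population_loadings[sig_measures] == cfg$latent_effect_features))
})

test_that("ordinal wellbeing items use equiprobable levels", {
  d <- generate_multiview(synth_config(n_participants = 4000, ordinal_levels = 4,
                                       seed = 8))
  tab <- table(d$wellbeing$wellbeing_01)
  expect_length(tab, 4)
  expect_true(all(abs(tab / 4000 - 0.25) < 0.02))
})

test_that("datasets round-trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  d <- generate_multiview(synth_config(n_participants = 50, seed = 3))
  write_multiview(d, dir)
  expect_true(all(file.exists(file.path(
    dir, c("exposure.csv", "urban.csv", "wellbeing.csv", "covariates.csv",
           "category_map.json", "truth.json")))))
  back <- utils::read.csv(file.path(dir, "exposure.csv"))
  expect_equal(back$nle, d$exposure$nle, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$signal_category_ids), d$truth$signal_category_ids)
})
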