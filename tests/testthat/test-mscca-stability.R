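test_that("one trial yields frequencies in {0, 1}", {
  v <- make_views(100, p = c(1, 4, 4), seed = 1, shared = 0.3)
  st <- suppressWarnings(stability_selection(v, n_trials = 1, seed = 2))
  expect_true(all(st$frequencies$frequency %in% c(0, 1)))
})

test_that("frequencies are exact trial counts and stability is strict", {
  v <- make_views(150, p = c(1, 5, 4), seed = 3, shared = 0.3)
  st <- stability_selection(v, n_trials = 8, seed = 4)
  counts <- st$frequencies$frequency * 8
  expect_equal(counts, round(counts), tolerance = 1e-12)
  expect_identical(st$frequencies$stable, st$frequencies$frequency > 0.75)
})

test_that("a single-column view is always selected", {
  v <- make_views(120, p = c(1, 3, 3), seed = 5, shared = 0.4)
  st <- stability_selection(v, n_trials = 20, seed = 6)
  expect_equal(st$frequencies$frequency[st$frequencies$view == "NL"], 1)
})

test_that("a custom budget sampler at the minimum budget keeps one variable per view", {
  v <- make_views(120, p = c(1, 5, 5), seed = 7, shared = 0.4)
  st <- stability_selection(v, n_trials = 10, seed = 8,
                            budget_sampler = function(p) 1)
  per_view <- tapply(st$frequencies$frequency, st$frequencies$view, sum)
  # one selected variable per view per trial -> frequencies sum to 1
  expect_equal(as.numeric(per_view[c("UF", "IW")]), c(1, 1), tolerance = 1e-12)
})

test_that("stability selection warns when the subsample is too small", {
  v <- make_views(30, p = c(1, 12, 4), seed = 9)
  expect_warning(stability_selection(v, n_trials = 2, seed = 1,
                                     subsample_fraction = 0.5),
                 "small")
})

test_that("selection is reproducible from the seed", {
  v <- make_views(100, p = c(1, 4, 4), seed = 10, shared = 0.3)
  s1 <- stability_selection(v, n_trials = 15, seed = 11)
  s2 <- stability_selection(v, n_trials = 15, seed = 11)
  expect_identical(s1$frequencies, s2$frequencies)
})

test_that("strong planted variables at small scale are found stable", {
  # 3 of 8 variables in each of two views share a strong factor
  withr::with_seed(12, {
    n <- 600
    z <- rnorm(n)
    mk <- function(p, s, prefix) {
      m <- matrix(rnorm(n * p), n, p)
      m[, seq_len(s)] <- m[, seq_len(s)] + z
      colnames(m) <- paste0(prefix, seq_len(p))
      zscore(m)
    }
    v <- list(NL = zscore(cbind(nle = z + rnorm(n))),
              UF = mk(8, 3, "u"), IW = mk(8, 3, "w"))
  })
  st <- stability_selection(v, n_trials = 60, seed = 13)
  expect_true(all(c("u1", "u2", "u3") %in% st$stable_sets$UF))
  expect_true(all(c("w1", "w2", "w3") %in% st$stable_sets$IW))
})
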