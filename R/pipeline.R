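#' Random holdout split
#'
#' Uniformly random partition into training and test sets with
#' `n_test = floor(test_fraction * n_total)` (with `n_total = 200393`
#' and the default fraction this gives 160315 / 40078).
#'
#' @param n_total Number of participants.
#' @param test_fraction Fraction assigned to the test set.
#' @param seed Optional integer seed.
#' @return An object of class `split_spec`: `n_total`, `n_train`,
#'   `n_test`, sorted index vectors `train_idx` and `test_idx`, and the
#'   settings.
#' @export
split_holdout <- function(n_total, test_fraction = 0.2, seed = NULL) {
  if (n_total < 2) abort("n_total must be at least 2")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must lie strictly between 0 and 1")
  }
  n_test <- floor(test_fraction * n_total)
  test_idx <- with_seed(seed, sort(sample.int(n_total, n_test)))
  structure(list(
    n_total = as.integer(n_total),
    n_train = as.integer(n_total - n_test),
    n_test = as.integer(n_test),
    train_idx = setdiff(seq_len(n_total), test_idx),
    test_idx = test_idx,
    test_fraction = test_fraction,
    seed = seed
  ), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> n = %d: train %d (%.0f%%), test %d (%.0f%%)\n",
              x$n_total, x$n_train, 100 * (1 - x$test_fraction),
              x$n_test, 100 * x$test_fraction))
  invisible(x)
}

#' Control settings for the two-step pipeline
#'
#' @param test_fraction Holdout fraction (study design: 0.2).
#' @param n_trials Stability-selection trials (study design: 1000).
#' @param subsample_fraction Stability subsampling fraction (0.5).
#' @param threshold Stability frequency threshold (0.75, strict).
#' @param n_perm Permutations for the canonical-correlation tests and
#'   the network comparison test (study design: 1000).
#' @param n_boots Case-dropping bootstrap samples (study design: 1000).
#' @param drop_grid Case-dropping proportions.
#' @param gamma,lambda_grid_size,lambda_min_ratio GGM estimator settings.
#' @param stepwise Stepwise refinement for the observed stratum networks.
#' @param nct_stepwise Stepwise refinement inside NCT permutations
#'   (default `FALSE`; see [network_comparison_test()]).
#' @param lower_q,upper_q Exposure stratification quantiles.
#' @param loading_type Category-PCA loading convention.
#' @param communities Optional named community vector for the network
#'   nodes; defaults to view membership (urban categories =
#'   "environment", wellbeing = "mental-physical").
#' @param seed Master seed; every stochastic stage draws a named
#'   substream seed from it.
#' @return A list of class `pipeline_control`.
#' @export
pipeline_control <- function(test_fraction = 0.2,
                             n_trials = 1000,
                             subsample_fraction = 0.5,
                             threshold = 0.75,
                             n_perm = 1000,
                             n_boots = 1000,
                             drop_grid = seq(0.1, 0.7, by = 0.1),
                             gamma = 0,
                             lambda_grid_size = 100,
                             lambda_min_ratio = 0.01,
                             stepwise = TRUE,
                             nct_stepwise = FALSE,
                             lower_q = 0.25,
                             upper_q = 0.75,
                             loading_type = "component",
                             communities = NULL,
                             seed = 1L) {
  structure(as.list(environment()), class = "pipeline_control")
}

#' Run the full two-step analysis
#'
#' Orchestrates the whole pipeline: covariate residualization,
#' z-normalization and per-category PCA scoring (parameters estimated on
#' the training split and frozen for the test split); a random holdout
#' split; stability selection and the unpenalized multi-view refit on
#' the training set; projection of the training weights onto the test
#' set; permutation tests for both; then, on the test set only (to avoid
#' double-dipping), exposure-quartile stratification, per-stratum GGM
#' estimation, bridge expected influence, case-dropping bootstrap, and
#' the permutation network comparison test.
#'
#' Covariates: exposure and urban measures are residualized on age,
#' gender and population density; wellbeing items additionally on the
#' assessment centre (when a `centre` column is present).
#'
#' @param data A `multiview_data` object (see [generate_multiview()]) or
#'   a list with elements `exposure`, `urban`, `wellbeing`,
#'   `covariates`, `category_map`.
#' @param synth A [synth_config()] used to generate data when `data` is
#'   `NULL`.
#' @param control A [pipeline_control()].
#' @return An object of class `pipeline_report` carrying every stage
#'   result, the configuration, and all substream seeds. The report is
#'   bit-reproducible from the same data and control settings.
#' @export
run_pipeline <- function(data = NULL, synth = synth_config(),
                         control = pipeline_control()) {
  stopifnot(inherits(control, "pipeline_control"))
  if (is.null(data)) data <- generate_multiview(synth)
  for (el in c("exposure", "urban", "wellbeing", "covariates", "category_map")) {
    if (is.null(data[[el]])) abort(sprintf("data lacks element '%s'", el))
  }
  seeds <- derive_seeds(control$seed,
                        c("split", "stability", "perm_train", "perm_test",
                          "boot_high", "boot_low", "nct"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) {
    inform(sprintf("[pipeline] %-22s %7.1fs", name, proc.time()[["elapsed"]] - t0))
  }

  n <- nrow(data$exposure)
  cov_all <- data$covariates
  cov_exposure <- if ("centre" %in% names(cov_all)) {
    cov_all[, setdiff(names(cov_all), "centre"), drop = FALSE]
  } else cov_all
  covA <- expand_covariates(cov_exposure)
  covB <- expand_covariates(cov_all)

  split <- split_holdout(n, control$test_fraction, seed = seeds[["split"]])
  tr <- split$train_idx
  te <- split$test_idx
  stage("split")

  ## training-set preprocessing (parameters frozen for the test set) ----
  preprocess <- function(view, covx, idx, coefficients = NULL,
                         center = NULL, scale = NULL) {
    res <- residualize(view[idx, , drop = FALSE], covx[idx, , drop = FALSE],
                       coefficients = coefficients)
    z <- zscore(res, center = center, scale = scale)
    list(z = z, coefficients = attr(res, "coefficients"),
         center = attr(z, "center"), scale = attr(z, "scale"))
  }
  nl_tr <- preprocess(data$exposure, covA, tr)
  uf_tr <- preprocess(data$urban, covA, tr)
  iw_tr <- preprocess(data$wellbeing, covB, tr)
  cpca <- category_pca(uf_tr$z, data$category_map,
                       loading_type = control$loading_type)
  scores_tr <- cpca$scores
  scz_tr <- zscore(scores_tr)
  stage("preprocess (train)")

  nl_te <- preprocess(data$exposure, covA, te, nl_tr$coefficients,
                      nl_tr$center, nl_tr$scale)
  uf_te <- preprocess(data$urban, covA, te, uf_tr$coefficients,
                      uf_tr$center, uf_tr$scale)
  iw_te <- preprocess(data$wellbeing, covB, te, iw_tr$coefficients,
                      iw_tr$center, iw_tr$scale)
  scores_te <- predict(cpca, uf_te$z)
  scz_te <- zscore(scores_te, center = attr(scz_tr, "center"),
                   scale = attr(scz_tr, "scale"))
  stage("preprocess (test)")

  views_tr <- list(NL = nl_tr$z, UF = scz_tr, IW = iw_tr$z)
  views_te <- list(NL = nl_te$z, UF = scz_te, IW = iw_te$z)
  names(views_tr$NL) <- names(views_te$NL) <- "nle"

  ## step 1 -------------------------------------------------------------
  stability <- stability_selection(
    views_tr, n_trials = control$n_trials,
    subsample_fraction = control$subsample_fraction,
    threshold = control$threshold, seed = seeds[["stability"]])
  stage("stability selection")

  fit_train <- refit_unpenalized(views_tr, stability)
  stable <- stability$stable_sets
  views_tr_stable <- purrr::imap(views_tr, function(v, nm) {
    tibble::as_tibble(v)[, stable[[nm]], drop = FALSE]
  })
  views_te_stable <- purrr::imap(views_te, function(v, nm) {
    tibble::as_tibble(v)[, stable[[nm]], drop = FALSE]
  })
  fit_test <- project_holdout(fit_train, views_te_stable)
  stage("msCCA refit + holdout")

  perm_train <- permutation_test(fit_train, views = views_tr_stable,
                                 n_perm = control$n_perm, mode = "refit",
                                 seed = seeds[["perm_train"]])
  perm_test <- permutation_test(fit_test, n_perm = control$n_perm,
                                mode = "fixed_weights",
                                seed = seeds[["perm_test"]])
  stage("permutation tests")

  ## step 2 (test set only) ---------------------------------------------
  node_data <- dplyr::bind_cols(views_te_stable$UF, views_te_stable$IW)
  communities <- control$communities %||% stats::setNames(
    c(rep("environment", ncol(views_te_stable$UF)),
      rep("mental-physical", ncol(views_te_stable$IW))),
    names(node_data))
  strata <- stratify_by_exposure(node_data, data$exposure$nle[te],
                                 lower_q = control$lower_q,
                                 upper_q = control$upper_q)
  stage("stratification")

  est <- function(d) estimate_ggm(
    d, communities = communities, gamma = control$gamma,
    lambda_grid_size = control$lambda_grid_size,
    lambda_min_ratio = control$lambda_min_ratio,
    stepwise = control$stepwise)
  net_high <- est(strata$high)
  net_low <- est(strata$low)
  bridge_high <- bridge_expected_influence(net_high)
  bridge_low <- bridge_expected_influence(net_low)
  stage("stratum networks")

  boot_args <- list(communities = communities, statistic = "bridge",
                    n_boots = control$n_boots, drop_grid = control$drop_grid,
                    gamma = control$gamma,
                    lambda_grid_size = control$lambda_grid_size,
                    lambda_min_ratio = control$lambda_min_ratio)
  boot_high <- do.call(case_drop_bootstrap,
                       c(list(strata$high, seed = seeds[["boot_high"]]), boot_args))
  boot_low <- do.call(case_drop_bootstrap,
                      c(list(strata$low, seed = seeds[["boot_low"]]), boot_args))
  stage("case-dropping bootstrap")

  nct <- network_comparison_test(
    strata$high, strata$low, n_perm = control$n_perm,
    gamma = control$gamma, lambda_grid_size = control$lambda_grid_size,
    lambda_min_ratio = control$lambda_min_ratio,
    stepwise = control$nct_stepwise, seed = seeds[["nct"]])
  stage("network comparison test")

  structure(list(
    schema_version = "1.0",
    split = split,
    category_report = list(loadings = cpca$loadings,
                           dropped = cpca$dropped_members),
    stability = stability,
    mscca_train = fit_train,
    mscca_test = fit_test,
    perm_train = perm_train,
    perm_test = perm_test,
    communities = communities,
    stratum_sizes = strata$k,
    net_high = net_high,
    net_low = net_low,
    bridge_high = bridge_high,
    bridge_low = bridge_low,
    boot_high = boot_high,
    boot_low = boot_low,
    nct = nct,
    seeds = seeds,
    control = control,
    synth_config = if (inherits(data, "multiview_data")) data$config else NULL
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$split)
  cat(sprintf("  stable: %s\n",
              paste(sprintf("%s %d", names(x$stability$stable_sets),
                            lengths(x$stability$stable_sets)), collapse = ", ")))
  cat(sprintf("  r_mean: train %.4f (p = %.4g), test %.4f (p = %.4g)\n",
              x$mscca_train$r_mean, x$perm_train$p_value[1],
              x$mscca_test$r_mean, x$perm_test$p_value[1]))
  cat(sprintf("  strata: high n = %d, low n = %d\n",
              x$stratum_sizes[["high"]], x$stratum_sizes[["low"]]))
  cat(sprintf("  NCT: M = %.4f (p = %.4g), S = %.4f (p = %.4g)\n",
              x$nct$m_observed, x$nct$p_structure,
              x$nct$s_observed, x$nct$p_strength))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes a versioned, machine-readable summary of every stage:
#' split sizes, category loadings, selection frequencies and stable
#' sets, canonical correlations with p-values, stratum networks (as
#' edge lists), bridge results, CS coefficients, NCT statistics, and all
#' seeds.
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  ctl <- report$control
  ctl <- ctl[!vapply(ctl, is.null, logical(1))]
  out <- list(
    schema_version = report$schema_version,
    split = report$split[c("n_total", "n_train", "n_test", "test_fraction")],
    category_loadings = report$category_report$loadings,
    stability = list(
      frequencies = report$stability$frequencies,
      stable_sets = report$stability$stable_sets,
      n_trials = report$stability$n_trials,
      threshold = report$stability$threshold
    ),
    mscca = list(
      train = as.list(glance(report$mscca_train)),
      test = as.list(glance(report$mscca_test)),
      p_train = report$perm_train,
      p_test = report$perm_test
    ),
    communities = as.list(report$communities),
    stratum_sizes = as.list(report$stratum_sizes),
    networks = list(
      high = tidy(report$net_high),
      low = tidy(report$net_low),
      global_strength = list(high = global_strength(report$net_high),
                             low = global_strength(report$net_low))
    ),
    bridge = list(high = report$bridge_high$bei, low = report$bridge_low$bei),
    cs_coefficient = list(high = report$boot_high$cs_coefficient,
                          low = report$boot_low$cs_coefficient),
    nct = as.list(glance(report$nct)),
    seeds = as.list(report$seeds),
    control = ctl
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
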