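#' Generate a three-view participant dataset with planted latent structure
#'
#' Simulates the data layout of a population exposure study: a scalar
#' nighttime-light exposure on the 0-63 digital-number scale, grouped
#' urban-feature measures with within-category correlation, ordinal
#' wellbeing items, and covariates (age-like, gender-like, a five-level
#' population-density category and an assessment-centre factor). One
#' standard-normal latent factor `z` is shared by the signal variables of
#' all three views; covariates confound the exposure and the wellbeing
#' items, so downstream residualization has real work to do.
#'
#' The model, per participant:
#' * exposure latent part `a*z + e`, plus `covariate_effect` times a
#'   standardized covariate mix, affinely rescaled to `[0, 63]`;
#' * signal urban measure `b*z + sqrt(rho)*g + sqrt(1-rho)*e` with a
#'   category-shared factor `g` (non-signal categories have `b = 0`);
#' * signal wellbeing latent `w*z + covariate_effect*mix + e`, discretized
#'   at equiprobable thresholds into `ordinal_levels` levels.
#'
#' All idiosyncratic noise is i.i.d. standard normal, so e.g. the
#' population correlation between the exposure latent part and a signal
#' measure is `a*b / sqrt((a^2+1)*(b^2+1))`.
#'
#' @param config A [synth_config()].
#' @return A list of class `multiview_data` with tibbles `exposure`
#'   (column `nle`), `urban`, `wellbeing`, `covariates`, a `category_map`
#'   (named list: category -> member measure names) and a `truth` object
#'   (class `synth_truth`) holding signal ids and population loadings.
#' @seealso [generate_stratified()], [write_multiview()]
#' @export
generate_multiview <- function(config) {
  validate_synth_config(config)
  cfg <- config
  n <- cfg$n_participants

  with_seed(cfg$seed, {
    z <- rnorm(n)

    ## covariates ------------------------------------------------------
    age <- rnorm(n, 56.5, 7.9)
    gender <- sample(c("female", "male"), n, replace = TRUE)
    pd_levels <- c("urban", "town_fringe", "village", "hamlet", "dwelling")
    pd_probs <- c(0.85, 0.07, 0.05, 0.02, 0.01)
    pop_density <- sample(pd_levels, n, replace = TRUE, prob = pd_probs)
    centres <- sprintf("centre_%02d", 1:10)
    centre <- sample(centres, n, replace = TRUE)
    centre_offsets <- rnorm(10)
    names(centre_offsets) <- centres

    age_z <- (age - 56.5) / 7.9
    gender_z <- ifelse(gender == "male", 1, -1)
    pd_idx <- match(pop_density, pd_levels)
    pd_mu <- sum(pd_probs * seq_along(pd_levels))
    pd_sd <- sqrt(sum(pd_probs * seq_along(pd_levels)^2) - pd_mu^2)
    pd_z <- (pd_idx - pd_mu) / pd_sd
    ctr_z <- centre_offsets[centre]

    mix_exposure <- (age_z + gender_z + pd_z) / sqrt(3)
    mix_wellbeing <- (age_z + gender_z + pd_z + ctr_z) / 2

    ## exposure --------------------------------------------------------
    a <- cfg$latent_effect_exposure
    exposure_raw <- a * z + cfg$covariate_effect * mix_exposure + rnorm(n)
    rng <- range(exposure_raw)
    if (diff(rng) <= 0) {
      nle <- rep(31.5, n)
    } else {
      nle <- 63 * (exposure_raw - rng[1]) / (rng[2] - rng[1])
      nle <- pmin(pmax(nle, 0), 63)  # guard FP overshoot of the affine map
    }

    ## urban measures --------------------------------------------------
    b <- cfg$latent_effect_features
    rho <- cfg$within_category_rho
    K <- cfg$n_categories
    m_per <- cfg$measures_per_category
    cat_names <- sprintf("category_%02d", seq_len(K))
    urban <- matrix(0, n, K * m_per)
    col_names <- character(K * m_per)
    cat_loadings <- numeric(K * m_per)
    for (k in seq_len(K)) {
      bk <- if (k <= cfg$n_signal_categories) b else 0
      g <- rnorm(n)
      for (m in seq_len(m_per)) {
        j <- (k - 1) * m_per + m
        urban[, j] <- bk * z + sqrt(rho) * g + sqrt(1 - rho) * rnorm(n)
        col_names[j] <- sprintf("%s_m%d", cat_names[k], m)
        cat_loadings[j] <- bk
      }
    }
    colnames(urban) <- col_names
    category_map <- split(col_names, rep(cat_names, each = m_per))[cat_names]

    ## wellbeing items -------------------------------------------------
    w <- cfg$latent_effect_wellbeing
    L <- cfg$ordinal_levels
    W <- cfg$n_wellbeing
    wb_names <- sprintf("wellbeing_%02d", seq_len(W))
    wellbeing <- matrix(0L, n, W)
    wb_loadings <- numeric(W)
    for (j in seq_len(W)) {
      wj <- if (j <= cfg$n_signal_wellbeing) w else 0
      latent <- wj * z + cfg$covariate_effect * mix_wellbeing + rnorm(n)
      cuts <- quantile(latent, probs = seq_len(L - 1) / L, names = FALSE)
      wellbeing[, j] <- 1L + rowSums(outer(latent, cuts, `>`))
      wb_loadings[j] <- wj
    }
    colnames(wellbeing) <- wb_names

    truth <- structure(list(
      signal_category_ids = cat_names[seq_len(cfg$n_signal_categories)],
      signal_wellbeing_ids = wb_names[seq_len(cfg$n_signal_wellbeing)],
      population_loadings = c(
        stats::setNames(a, "nle"),
        stats::setNames(cat_loadings, col_names),
        stats::setNames(wb_loadings, wb_names)
      ),
      planted_edges = tibble::tibble(
        node_a = character(), node_b = character(),
        stratum = character(), pcor = numeric()
      ),
      latent = z
    ), class = "synth_truth")

    structure(list(
      exposure = tibble::tibble(nle = nle),
      urban = tibble::as_tibble(urban),
      wellbeing = tibble::as_tibble(wellbeing),
      covariates = tibble::tibble(
        age = age,
        gender = factor(gender, levels = c("female", "male")),
        pop_density = factor(pop_density, levels = pd_levels),
        centre = factor(centre, levels = centres)
      ),
      category_map = category_map,
      truth = truth,
      config = cfg
    ), class = "multiview_data")
  })
}

#' @export
print.multiview_data <- function(x, ...) {
  cat("<multiview_data>\n")
  cat(sprintf("  %d participants\n", nrow(x$exposure)))
  cat(sprintf("  exposure: nle in [%.2f, %.2f]\n",
              min(x$exposure$nle), max(x$exposure$nle)))
  cat(sprintf("  urban: %d measures in %d categories\n",
              ncol(x$urban), length(x$category_map)))
  cat(sprintf("  wellbeing: %d ordinal items\n", ncol(x$wellbeing)))
  cat(sprintf("  signal: %d categories, %d wellbeing items\n",
              length(x$truth$signal_category_ids),
              length(x$truth$signal_wellbeing_ids)))
  invisible(x)
}

#' Write a synthetic multi-view dataset to disk
#'
#' One CSV per view plus the covariates, a JSON category-grouping map and
#' a JSON ground-truth file. All schemas carry a `schema_version` field.
#'
#' @param data A `multiview_data` object from [generate_multiview()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiview <- function(data, dir) {
  stopifnot(inherits(data, "multiview_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data$exposure, file.path(dir, "exposure.csv"), row.names = FALSE)
  utils::write.csv(data$urban, file.path(dir, "urban.csv"), row.names = FALSE)
  utils::write.csv(data$wellbeing, file.path(dir, "wellbeing.csv"), row.names = FALSE)
  utils::write.csv(data$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(schema_version = "1.0"), data$category_map),
    file.path(dir, "category_map.json"))
  truth <- data$truth
  jsonlite::write_json(
    list(schema_version = "1.0",
         signal_category_ids = truth$signal_category_ids,
         signal_wellbeing_ids = truth$signal_wellbeing_ids,
         population_loadings = as.list(truth$population_loadings),
         planted_edges = truth$planted_edges),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
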