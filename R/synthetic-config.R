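#' Configuration for the synthetic multi-view generator
#'
#' Bundles every knob of the synthetic-data model: one scalar exposure
#' (nighttime light emission on the 0-63 digital-number scale), grouped
#' urban-feature measures, ordinal wellbeing items, shared latent factor,
#' covariate confounding, and the stratum-dependent network shift used by
#' [generate_stratified()].
#'
#' Defaults mirror a large population-cohort design
#' (44 urban-feature categories built from ~275 measures, 23 wellbeing
#' factors, 6 signal variables in each block) with moderate effect sizes
#' chosen so that cross-view canonical correlations land in the 0.1-0.3
#' range typical of population-scale exposure studies.
#'
#' @param n_participants Number of participants to simulate.
#' @param n_categories Number of urban-feature categories.
#' @param measures_per_category Measures per category (raw urban view has
#'   `n_categories * measures_per_category` columns).
#' @param n_wellbeing Number of ordinal wellbeing items.
#' @param n_signal_categories Number of categories whose measures load on
#'   the shared latent factor.
#' @param n_signal_wellbeing Number of wellbeing items loading on the
#'   shared latent factor.
#' @param latent_effect_exposure Loading of the exposure on the latent
#'   factor (unit-variance noise).
#' @param latent_effect_features Loading of each signal urban measure on
#'   the latent factor.
#' @param latent_effect_wellbeing Loading of each signal wellbeing latent
#'   item on the latent factor.
#' @param within_category_rho Correlation of the non-latent part shared by
#'   measures of one category, in `[0, 1)`.
#' @param covariate_effect Loading of the standardized covariate mix on
#'   exposure and wellbeing latents (confounding strength).
#' @param ordinal_levels Number of equiprobable ordinal levels for
#'   wellbeing items (>= 2).
#' @param stratum_edge_shift Partial-correlation offset added to the
#'   planted cross-community edges of the high-exposure stratum in
#'   [generate_stratified()].
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   same configuration and seed.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 500, seed = 7)
#' dat <- generate_multiview(cfg)
#' range(dat$exposure$nle)
synth_config <- function(n_participants = 4000,
                         n_categories = 44,
                         measures_per_category = 6,
                         n_wellbeing = 23,
                         n_signal_categories = 6,
                         n_signal_wellbeing = 6,
                         latent_effect_exposure = 0.45,
                         latent_effect_features = 0.10,
                         latent_effect_wellbeing = 0.22,
                         within_category_rho = 0.3,
                         covariate_effect = 0.3,
                         ordinal_levels = 4,
                         stratum_edge_shift = 0.15,
                         seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_categories = as.integer(n_categories),
    measures_per_category = as.integer(measures_per_category),
    n_wellbeing = as.integer(n_wellbeing),
    n_signal_categories = as.integer(n_signal_categories),
    n_signal_wellbeing = as.integer(n_signal_wellbeing),
    latent_effect_exposure = latent_effect_exposure,
    latent_effect_features = latent_effect_features,
    latent_effect_wellbeing = latent_effect_wellbeing,
    within_category_rho = within_category_rho,
    covariate_effect = covariate_effect,
    ordinal_levels = as.integer(ordinal_levels),
    stratum_edge_shift = stratum_edge_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_participants < 1) abort("n_participants must be positive")
  if (cfg$n_categories < 1 || cfg$measures_per_category < 1 || cfg$n_wellbeing < 1) {
    abort("block sizes must be positive")
  }
  if (cfg$n_signal_categories > cfg$n_categories) {
    abort("n_signal_categories must not exceed n_categories")
  }
  if (cfg$n_signal_wellbeing > cfg$n_wellbeing) {
    abort("n_signal_wellbeing must not exceed n_wellbeing")
  }
  if (cfg$ordinal_levels < 2) abort("ordinal_levels must be at least 2")
  effs <- c(cfg$latent_effect_exposure, cfg$latent_effect_features,
            cfg$latent_effect_wellbeing, cfg$covariate_effect)
  if (any(!is.finite(effs))) abort("effect loadings must be finite")
  # the factor construction has unit-variance idiosyncratic noise, so the
  # implied population covariance is positive definite iff the shared
  # within-category component has admissible variance
  if (cfg$within_category_rho < 0 || cfg$within_category_rho >= 1) {
    abort(paste0(
      "implied population covariance is not positive definite: ",
      "within_category_rho must lie in [0, 1), got ", cfg$within_category_rho))
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  participants: %d, seed: %d\n", x$n_participants, x$seed))
  cat(sprintf("  urban: %d categories x %d measures (%d signal)\n",
              x$n_categories, x$measures_per_category, x$n_signal_categories))
  cat(sprintf("  wellbeing: %d ordinal items, %d levels (%d signal)\n",
              x$n_wellbeing, x$ordinal_levels, x$n_signal_wellbeing))
  cat(sprintf("  loadings: exposure %.3g, features %.3g, wellbeing %.3g; rho %.2f; covariates %.3g\n",
              x$latent_effect_exposure, x$latent_effect_features,
              x$latent_effect_wellbeing, x$within_category_rho, x$covariate_effect))
  cat(sprintf("  stratum edge shift: %.3g\n", x$stratum_edge_shift))
  invisible(x)
}
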