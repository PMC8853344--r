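#' Case-dropping bootstrap stability of a network statistic
#'
#' Re-estimates the network on subsamples with an increasing proportion
#' of cases dropped and correlates the node statistic (bridge expected
#' influence by default, or node strength) with its full-sample value.
#' The CS coefficient is the largest drop proportion whose 2.5% quantile
#' of correlations stays at or above 0.7 (scanning the grid upward and
#' stopping at the first failure); 0 if none qualifies.
#'
#' @param data Data frame of node columns.
#' @param communities Named community vector (needed for the bridge
#'   statistic).
#' @param statistic `"bridge"` (bridge expected influence) or
#'   `"strength"` (node strength, sum of absolute incident weights).
#' @param n_boots Bootstrap samples per drop proportion (study design:
#'   1000).
#' @param drop_grid Proportions of cases to drop, within (0, 0.9].
#' @param seed Optional integer seed.
#' @param cor_threshold,quantile_level CS-coefficient convention
#'   (defaults 0.7 and 0.025).
#' @param ... Estimator settings passed to [estimate_ggm()] (the
#'   bootstrap uses `stepwise = FALSE` by default for tractability).
#' @return An object of class `case_drop_result`: per-proportion summary
#'   tibble (`prop`, `n_kept`, correlation quantiles, share of undefined
#'   correlations), the raw correlations, and `cs_coefficient`.
#' @export
case_drop_bootstrap <- function(data, communities = NULL,
                                statistic = c("bridge", "strength"),
                                n_boots = 1000,
                                drop_grid = seq(0.1, 0.7, by = 0.1),
                                seed = NULL,
                                cor_threshold = 0.7,
                                quantile_level = 0.025,
                                ...) {
  statistic <- match.arg(statistic)
  m <- as_view_matrix(data, "data")
  n <- nrow(m)
  p <- ncol(m)
  if (any(drop_grid <= 0 | drop_grid > 0.9)) abort("drop_grid must lie in (0, 0.9]")
  drop_grid <- sort(drop_grid)
  est_args <- list(...)
  if (is.null(est_args$stepwise)) est_args$stepwise <- FALSE

  node_stat <- function(net) {
    if (statistic == "bridge") {
      bridge_expected_influence(net, communities = communities)$bei$bei
    } else {
      colSums(abs(net$weights))
    }
  }
  fit_full <- do.call(estimate_ggm, c(list(data = m, communities = communities), est_args))
  stat_full <- node_stat(fit_full)
  if (sd(stat_full) == 0) {
    warn("full-sample statistic is constant across nodes; stability correlations are undefined")
  }

  rows <- list()
  cors_all <- list()
  with_seed(seed, {
    for (prop in drop_grid) {
      keep <- round((1 - prop) * n)
      if (keep < p + 5) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          prop = prop, n_kept = keep, estimable = FALSE,
          q025 = NA_real_, q500 = NA_real_, q975 = NA_real_,
          prop_undefined = NA_real_)
        next
      }
      cors <- rep(NA_real_, n_boots)
      for (b in seq_len(n_boots)) {
        idx <- sample.int(n, keep)
        net_b <- try(do.call(estimate_ggm,
                             c(list(data = m[idx, , drop = FALSE],
                                    communities = communities), est_args)),
                     silent = TRUE)
        if (inherits(net_b, "try-error")) next
        sb <- node_stat(net_b)
        if (sd(sb) == 0 || sd(stat_full) == 0) next  # undefined, left NA
        cors[b] <- cor(stat_full, sb)
      }
      ok <- !is.na(cors)
      rows[[length(rows) + 1]] <- tibble::tibble(
        prop = prop, n_kept = keep, estimable = TRUE,
        q025 = if (any(ok)) quantile(cors[ok], quantile_level, names = FALSE) else NA_real_,
        q500 = if (any(ok)) stats::median(cors[ok]) else NA_real_,
        q975 = if (any(ok)) quantile(cors[ok], 1 - quantile_level, names = FALSE) else NA_real_,
        prop_undefined = mean(!ok))
      cors_all[[as.character(prop)]] <- cors
    }
  })
  summary_tbl <- dplyr::bind_rows(rows)

  cs <- 0
  for (i in seq_len(nrow(summary_tbl))) {
    row <- summary_tbl[i, ]
    if (!isTRUE(row$estimable) || is.na(row$q025) || row$q025 < cor_threshold) break
    cs <- row$prop
  }

  structure(list(
    summary = summary_tbl,
    correlations = cors_all,
    cs_coefficient = cs,
    statistic = statistic,
    n_boots = as.integer(n_boots),
    cor_threshold = cor_threshold,
    quantile_level = quantile_level,
    stat_full = stat_full
  ), class = "case_drop_result")
}

#' @export
print.case_drop_result <- function(x, ...) {
  cat("<case_drop_result>\n")
  cat(sprintf("  statistic: %s, %d boots per drop proportion\n",
              x$statistic, x$n_boots))
  cat(sprintf("  CS coefficient (cor >= %.2f at the %.1f%% quantile): %.2f\n",
              x$cor_threshold, 100 * x$quantile_level, x$cs_coefficient))
  invisible(x)
}

#' @rdname case_drop_bootstrap
#' @param x A `case_drop_result`.
#' @param ... Unused.
#' @method tidy case_drop_result
#' @export
tidy.case_drop_result <- function(x, ...) x$summary

#' @rdname case_drop_bootstrap
#' @method glance case_drop_result
#' @export
glance.case_drop_result <- function(x, ...) {
  tibble::tibble(cs_coefficient = x$cs_coefficient,
                 statistic = x$statistic,
                 n_boots = x$n_boots)
}

#' @rdname case_drop_bootstrap
#' @param object A `case_drop_result`.
#' @method autoplot case_drop_result
#' @export
autoplot.case_drop_result <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$prop, .data$q500)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$cor_threshold, linetype = "dashed") +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = sprintf("correlation with full-sample %s", object$statistic)) +
    ggplot2::theme_minimal()
}
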