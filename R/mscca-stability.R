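#' Stability selection with random sparsity
#'
#' Repeats [fit_mscca()] on random row subsamples (without replacement)
#' with per-view L1 budgets drawn fresh each trial ("random sparsity"),
#' and records how often every variable receives a nonzero weight
#' (numeric zero: `|w| < 1e-12`). Variables with selection frequency
#' strictly above `threshold` form the stable set of their view. Each
#' subsample is re-standardized before fitting.
#'
#' The default budget sampler draws `c_k ~ Uniform[1, sqrt(p_k)]`
#' independently per view and trial; any function of the view dimension
#' can be plugged in instead.
#'
#' @param views Named list of z-normalized, row-aligned views.
#' @param n_trials Number of subsampling trials (study design: 1000).
#' @param subsample_fraction Fraction of rows per trial (study design: 0.5).
#' @param threshold Stability frequency threshold; stability requires
#'   frequency strictly greater than it (study design: 0.75, "more than
#'   75%").
#' @param budget_sampler Function `p -> c` drawing one L1 budget for a
#'   view of dimension `p`; default `runif(1, 1, sqrt(p))`.
#' @param seed Optional integer seed.
#' @param max_iter,tol Passed to [fit_mscca()].
#' @return An object of class `stability_result` with a per-variable
#'   tibble (`view`, `variable`, `frequency`, `stable`), the per-view
#'   stable sets, and the trial settings. Frequencies are exact counts
#'   over `n_trials`.
#' @export
stability_selection <- function(views, n_trials = 1000,
                                subsample_fraction = 0.5,
                                threshold = 0.75,
                                budget_sampler = NULL,
                                seed = NULL,
                                max_iter = 50, tol = 1e-6) {
  mats <- lapply(seq_along(views), function(i) {
    as_view_matrix(views[[i]], names(views)[i] %||% paste0("view", i))
  })
  names(mats) <- names(views) %||% paste0("view", seq_along(views))
  n <- check_aligned(mats)
  if (n_trials < 1) abort("n_trials must be at least 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("subsample_fraction must lie in (0, 1]")
  }
  p <- vapply(mats, ncol, integer(1))
  m <- floor(subsample_fraction * n)
  if (m < max(p) + 5) {
    warn(sprintf("subsample size %d is small relative to the widest view (p = %d); fits may be unstable",
                 m, max(p)))
  }
  if (is.null(budget_sampler)) {
    budget_sampler <- function(p) if (p <= 1) 1 else runif(1, 1, sqrt(p))
  }

  rescale <- function(x) {
    mu <- colMeans(x)
    s <- apply(x, 2, sd)
    s[s == 0 | !is.finite(s)] <- Inf  # degenerate column -> all-zero, never selected
    sweep(sweep(x, 2, mu, `-`), 2, s, `/`)
  }

  counts <- lapply(p, function(pk) rep(0L, pk))
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      idx <- sample.int(n, m)
      sub <- lapply(mats, function(x) rescale(x[idx, , drop = FALSE]))
      budgets <- vapply(p, budget_sampler, numeric(1))
      fit <- fit_mscca(sub, l1_budgets = budgets, max_iter = max_iter, tol = tol)
      for (k in seq_along(sub)) {
        counts[[k]] <- counts[[k]] + as.integer(abs(fit$weights[[k]]) > 1e-12)
      }
    }
  })

  freq_tbl <- purrr::imap_dfr(mats, function(x, view) {
    k <- match(view, names(mats))
    tibble::tibble(
      view = view,
      variable = colnames(x),
      frequency = counts[[k]] / n_trials
    )
  }) |>
    dplyr::mutate(stable = .data$frequency > threshold)

  stable_sets <- freq_tbl |>
    dplyr::filter(.data$stable) |>
    (\(d) split(d$variable, factor(d$view, levels = names(mats))))()

  structure(list(
    frequencies = freq_tbl,
    stable_sets = stable_sets,
    n_trials = as.integer(n_trials),
    subsample_fraction = subsample_fraction,
    threshold = threshold,
    subsample_size = m,
    seed = seed
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>\n")
  cat(sprintf("  %d trials, %.0f%% subsampling, stable if frequency > %.2f\n",
              x$n_trials, 100 * x$subsample_fraction, x$threshold))
  for (v in names(x$stable_sets)) {
    cat(sprintf("  %s: %d stable of %d\n", v, length(x$stable_sets[[v]]),
                sum(x$frequencies$view == v)))
  }
  invisible(x)
}

#' @rdname stability_selection
#' @param x A `stability_result`.
#' @param ... Unused.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) x$frequencies

#' @rdname stability_selection
#' @param object A `stability_result`.
#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, ...) {
  df <- object$frequencies
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$frequency),
    y = .data$frequency, colour = .data$stable)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$view), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "selection frequency",
                  colour = sprintf("> %.2f", object$threshold)) +
    ggplot2::theme_minimal()
}
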