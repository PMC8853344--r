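# Unpenalized refit on stable variables, hold-out projection, and
# permutation significance for the canonical correlations.

mscca_result_from_scores <- function(scores, weights = NULL) {
  K <- length(scores)
  vn <- names(scores)
  pairs <- utils::combn(K, 2)
  cors <- tibble::tibble(
    view_a = vn[pairs[1, ]],
    view_b = vn[pairs[2, ]],
    r = apply(pairs, 2, function(ij) {
      sa <- scores[[ij[1]]]; sb <- scores[[ij[2]]]
      if (sd(sa) == 0 || sd(sb) == 0) return(NA_real_)
      cor(sa, sb)
    })
  )
  structure(list(
    weights = weights,
    correlations = cors,
    r_mean = mean(cors$r),
    scores = scores,
    n = length(scores[[1]])
  ), class = "mscca_result")
}

#' Refit canonical weights on the stable variables without sparsity
#'
#' Restricts each view to its stable variables and reruns [fit_mscca()]
#' with the L1 budgets at their maximum (`sqrt(p_k)`, constraints
#' inactive), then reports the three pairwise Pearson correlations of
#' the view scores and their mean.
#'
#' @param views Named list of z-normalized, row-aligned views (full
#'   column sets).
#' @param stable A `stability_result` or a named list of stable column
#'   names per view.
#' @param max_iter,tol Passed to [fit_mscca()].
#' @return An object of class `mscca_result`: `weights`
#'   (`mscca_weights`), `correlations` (tibble `view_a`, `view_b`, `r`),
#'   `r_mean`, and the view scores.
#' @export
refit_unpenalized <- function(views, stable = NULL, max_iter = 200, tol = 1e-10) {
  mats <- lapply(seq_along(views), function(i) {
    as_view_matrix(views[[i]], names(views)[i] %||% paste0("view", i))
  })
  names(mats) <- names(views) %||% paste0("view", seq_along(views))
  if (inherits(stable, "stability_result")) stable <- stable$stable_sets
  if (!is.null(stable)) {
    for (v in names(stable)) {
      if (!v %in% names(mats)) abort(sprintf("stable set names view '%s' absent from views", v))
      if (length(stable[[v]]) == 0) {
        abort(sprintf("view '%s' has an empty stable set; review the stability threshold before refitting", v))
      }
      missing_cols <- setdiff(stable[[v]], colnames(mats[[v]]))
      if (length(missing_cols) > 0) {
        abort(sprintf("view '%s' lacks stable column(s): %s", v,
                      paste(missing_cols, collapse = ", ")))
      }
      mats[[v]] <- mats[[v]][, stable[[v]], drop = FALSE]
    }
  }
  p <- vapply(mats, ncol, integer(1))
  fit <- fit_mscca(mats, l1_budgets = sqrt(p), max_iter = max_iter, tol = tol)
  scores <- lapply(names(mats), function(v) drop(mats[[v]] %*% fit$weights[[v]]))
  names(scores) <- names(mats)
  mscca_result_from_scores(scores, fit)
}

#' Project training weights onto hold-out views
#'
#' Applies fixed (training-set) canonical weights to test-set views that
#' were preprocessed with the training residualization and z-scoring
#' parameters, and reports the pairwise correlations of the resulting
#' scores. No refitting takes place.
#'
#' @param weights An `mscca_weights` or `mscca_result` object from the
#'   training fit.
#' @param test_views Named list of preprocessed test views containing the
#'   weighted columns.
#' @return An `mscca_result` for the hold-out data.
#' @export
project_holdout <- function(weights, test_views) {
  if (inherits(weights, "mscca_result")) weights <- weights$weights
  stopifnot(inherits(weights, "mscca_weights"))
  w <- weights$weights
  mats <- lapply(seq_along(test_views), function(i) {
    as_view_matrix(test_views[[i]], names(test_views)[i] %||% paste0("view", i))
  })
  names(mats) <- names(test_views) %||% paste0("view", seq_along(test_views))
  if (!all(names(w) %in% names(mats))) {
    abort("test views must carry the same view names as the training weights")
  }
  check_aligned(mats)
  scores <- lapply(names(w), function(v) {
    missing_cols <- setdiff(names(w[[v]]), colnames(mats[[v]]))
    if (length(missing_cols) > 0) {
      abort(sprintf("test view '%s' lacks stable column(s): %s", v,
                    paste(missing_cols, collapse = ", ")))
    }
    drop(mats[[v]][, names(w[[v]]), drop = FALSE] %*% w[[v]])
  })
  names(scores) <- names(w)
  mscca_result_from_scores(scores, weights)
}

#' Permutation test for canonical correlations
#'
#' Breaks the cross-view links by independently permuting the row order
#' of every view except the first, `n_perm` times, and compares the
#' permuted correlations with the observed ones. In `fixed_weights` mode
#' the fitted scores are permuted and re-correlated (default for the
#' hold-out set); in `refit` mode the unpenalized refit is rerun on each
#' permuted dataset (default for the training set). P-values use the
#' add-one convention `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so
#' they are never zero; with `n_perm = 1000` and no exceedances the
#' smallest attainable value is about 0.001.
#'
#' @param result An `mscca_result` (observed fit).
#' @param views For `refit` mode: the stable-restricted, z-normalized
#'   views the result was fit on.
#' @param n_perm Number of permutations (study design: 1000).
#' @param mode `"fixed_weights"` or `"refit"`.
#' @param seed Optional integer seed.
#' @return A tibble of class `mscca_perm`: one row per statistic
#'   (`r_mean` and each pairwise correlation) with observed value and
#'   permutation p-value.
#' @export
permutation_test <- function(result, views = NULL, n_perm = 1000,
                             mode = c("fixed_weights", "refit"),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "mscca_result"))
  if (n_perm < 1) abort("n_perm must be at least 1")
  scores <- result$scores
  K <- length(scores)
  n <- length(scores[[1]])
  pairs <- utils::combn(K, 2)
  stat_names <- c("r_mean",
                  paste0("r_", result$correlations$view_a, "_",
                         result$correlations$view_b))
  observed <- c(result$r_mean, result$correlations$r)

  if (mode == "refit") {
    if (is.null(views)) abort("refit mode needs the views the result was fit on")
    mats <- lapply(seq_along(views), function(i) {
      as_view_matrix(views[[i]], names(views)[i] %||% paste0("view", i))
    })
    names(mats) <- names(views) %||% paste0("view", seq_along(views))
    check_aligned(mats)
  }

  exceed <- rep(0L, length(observed))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (mode == "fixed_weights") {
        perm_scores <- scores
        for (k in 2:K) perm_scores[[k]] <- scores[[k]][sample.int(n)]
        rs <- apply(pairs, 2, function(ij) {
          cor(perm_scores[[ij[1]]], perm_scores[[ij[2]]])
        })
      } else {
        perm_views <- mats
        for (k in 2:K) {
          perm_views[[k]] <- mats[[k]][sample.int(n), , drop = FALSE]
        }
        rs <- refit_unpenalized(perm_views)$correlations$r
      }
      perm_stats <- c(mean(rs), rs)
      exceed <- exceed + as.integer(perm_stats >= observed)
    }
  })

  out <- tibble::tibble(
    statistic = stat_names,
    observed = observed,
    p_value = (1 + exceed) / (1 + n_perm)
  )
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "mode") <- mode
  class(out) <- c("mscca_perm", class(out))
  out
}

#' @export
print.mscca_result <- function(x, ...) {
  cat("<mscca_result>\n")
  cat(sprintf("  n = %d\n", x$n))
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("  r_%s_%s = %.4f\n", x$correlations$view_a[i],
                x$correlations$view_b[i], x$correlations$r[i]))
  }
  cat(sprintf("  r_mean = %.4f\n", x$r_mean))
  invisible(x)
}

#' @rdname refit_unpenalized
#' @param x An `mscca_result`.
#' @param ... Unused.
#' @method tidy mscca_result
#' @export
tidy.mscca_result <- function(x, ...) x$correlations

#' @rdname refit_unpenalized
#' @method glance mscca_result
#' @export
glance.mscca_result <- function(x, ...) {
  wide <- stats::setNames(as.list(x$correlations$r),
                          paste0("r_", x$correlations$view_a, "_",
                                 x$correlations$view_b))
  tibble::as_tibble(c(list(r_mean = x$r_mean, n = x$n), wide))
}
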