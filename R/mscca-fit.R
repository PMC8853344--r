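# Multi-view sparse CCA: penalized block-coordinate ascent on the sum of
# pairwise cross-covariances of view scores, with unit-L2 and L1-budget
# constraints per view (the sum-correlation criterion on standardized
# data).

# Maximize w'v subject to ||w||_2 <= 1, ||w||_1 <= c:
# w = soft(v, delta) / ||soft(v, delta)||_2 with the smallest delta >= 0
# meeting the budget (bisection; delta = 0 if already feasible).
l1_constrained_direction <- function(v, c_budget) {
  if (max(abs(v)) < 1e-300) return(rep(0, length(v)))
  if (c_budget <= 1 + 1e-12) {
    # L1 = L2 = 1 forces a 1-sparse solution at the max-|v| coordinate
    w <- rep(0, length(v))
    i <- which.max(abs(v))
    w[i] <- sign(v[i])
    return(w)
  }
  nrm <- function(delta) {
    s <- sign(v) * pmax(abs(v) - delta, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) return(list(w = rep(0, length(v)), l1 = 0))
    list(w = s / n2, l1 = sum(abs(s)) / n2)
  }
  cand <- nrm(0)
  if (cand$l1 <= c_budget) return(cand$w)
  lo <- 0
  hi <- max(abs(v))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (nrm(mid)$l1 > c_budget) lo <- mid else hi <- mid
  }
  nrm(hi)$w
}

mscca_init <- function(cmats, budgets) {
  K <- length(cmats)
  lapply(seq_len(K), function(k) {
    m <- do.call(cbind, cmats[[k]][setdiff(seq_len(K), k)])
    w <- svd(m, nu = 1, nv = 0)$u[, 1]
    nz <- which(abs(w) > 1e-12)
    if (length(nz) > 0 && w[nz[1]] < 0) w <- -w
    if (sum(abs(w)) > budgets[k]) w <- l1_constrained_direction(w, budgets[k])
    w
  })
}

#' Fit multi-view sparse canonical weights
#'
#' Block coordinate ascent on the summed pairwise cross-covariance
#' objective `sum_{k<l} w_k' X_k' X_l w_l / (n-1)` over unit-norm weight
#' vectors with per-view L1 budgets `1 <= c_k <= sqrt(p_k)`. Each view
#' update is the exact constrained maximizer (soft-thresholding with a
#' bisection on the threshold), so the objective is non-decreasing across
#' sweeps; the trajectory is recorded. Input views must be z-normalized
#' (checked). Initialization is deterministic: the leading singular
#' vector of the concatenated cross-covariance blocks of each view, sign
#' fixed so the first nonzero entry is positive.
#'
#' When the first view has a single column (the exposure), the returned
#' weights are sign-fixed so its loading is +1 (all views flipped
#' together, which leaves the objective unchanged).
#'
#' @param views Named list of z-normalized, row-aligned data frames or
#'   matrices (e.g. `NL`, `UF`, `IW`).
#' @param l1_budgets Numeric vector of per-view L1 budgets in
#'   `[1, sqrt(p_k)]`; defaults to `sqrt(p_k)` (no sparsity).
#' @param max_iter Maximum number of sweeps.
#' @param tol Convergence tolerance on the objective change.
#' @return An object of class `mscca_weights`: named list `weights`
#'   (per-view named vectors, Euclidean norm 0 or 1), `objective`
#'   trajectory, `iterations`, `converged`.
#' @export
fit_mscca <- function(views, l1_budgets = NULL, max_iter = 100, tol = 1e-8) {
  if (!is.list(views) || length(views) < 2) abort("need at least two views")
  mats <- lapply(seq_along(views), function(i) {
    as_view_matrix(views[[i]], names(views)[i] %||% paste0("view", i))
  })
  names(mats) <- names(views) %||% paste0("view", seq_along(views))
  n <- check_aligned(mats)
  if (n < 3) abort("need at least three rows")
  for (k in seq_along(mats)) {
    mu <- colMeans(mats[[k]])
    s <- apply(mats[[k]], 2, sd)
    if (max(abs(mu)) > 1e-6 || max(abs(s - 1)) > 1e-3) {
      abort(sprintf("view '%s' is not z-normalized; fit_mscca requires standardized input (see zscore())",
                    names(mats)[k]))
    }
  }
  p <- vapply(mats, ncol, integer(1))
  if (is.null(l1_budgets)) l1_budgets <- sqrt(p)
  if (length(l1_budgets) != length(mats)) {
    abort("l1_budgets must have one entry per view")
  }
  if (any(l1_budgets < 1 - 1e-12) || any(l1_budgets > sqrt(p) + 1e-12)) {
    abort("each L1 budget must lie in [1, sqrt(p_k)] (L1 >= 1 is needed for a unit-L2 vector to exist)")
  }

  K <- length(mats)
  cmats <- lapply(seq_len(K), function(k) {
    lapply(seq_len(K), function(l) {
      if (l == k) NULL else crossprod(mats[[k]], mats[[l]]) / (n - 1)
    })
  })

  w <- mscca_init(cmats, l1_budgets)
  objective <- function(w) {
    s <- 0
    for (k in seq_len(K - 1)) for (l in (k + 1):K) {
      s <- s + drop(crossprod(w[[k]], cmats[[k]][[l]] %*% w[[l]]))
    }
    s
  }
  obj <- objective(w)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      v <- rep(0, p[k])
      for (l in setdiff(seq_len(K), k)) {
        v <- v + drop(cmats[[k]][[l]] %*% w[[l]])
      }
      w[[k]] <- l1_constrained_direction(v, l1_budgets[k])
    }
    obj_new <- objective(w)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) < tol) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }

  # exposure-view sign convention: single-column first view loads +1;
  # flipping every view leaves all pairwise terms unchanged
  if (p[1] == 1 && w[[1]][1] < 0) {
    w <- lapply(w, function(x) -x)
  }
  for (k in seq_len(K)) names(w[[k]]) <- colnames(mats[[k]])

  structure(list(
    weights = stats::setNames(w, names(mats)),
    objective = trace,
    iterations = length(trace) - 1,
    converged = converged,
    l1_budgets = l1_budgets,
    n = n
  ), class = "mscca_weights")
}

#' @export
print.mscca_weights <- function(x, ...) {
  cat("<mscca_weights>\n")
  nz <- vapply(x$weights, function(w) sum(abs(w) > 1e-12), integer(1))
  p <- vapply(x$weights, length, integer(1))
  cat(sprintf("  views: %s\n",
              paste(sprintf("%s (%d/%d nonzero)", names(x$weights), nz, p),
                    collapse = ", ")))
  cat(sprintf("  objective: %.6f after %d sweep(s)%s\n",
              x$objective[length(x$objective)], x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname fit_mscca
#' @param x An `mscca_weights` object.
#' @param ... Unused.
#' @method tidy mscca_weights
#' @export
tidy.mscca_weights <- function(x, ...) {
  purrr::imap_dfr(x$weights, function(w, view) {
    tibble::tibble(view = view, variable = names(w), weight = unname(w))
  })
}
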