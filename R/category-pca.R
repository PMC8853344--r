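#' Per-category PCA scores with the 0.3 positive-loading retention rule
#'
#' For each category of grouped (already z-normalized) measures, computes
#' the first principal component of the members' correlation matrix,
#' orients its sign so the majority of loadings are positive (ties: first
#' member's loading made nonnegative), drops members whose loading falls
#' below 0.3 (negative loadings are always dropped), refits the first
#' component on the retained members, and uses the projection onto that
#' component as the category score. Dropping and refitting is iterated to
#' a fixed point so every retained member's final loading is >= 0.3.
#' Categories losing all members are excluded with a warning.
#'
#' "Loading" defaults to the component loading (eigenvector entry scaled
#' by the square root of the first eigenvalue, i.e. the member-component
#' correlation); `loading_type = "eigenvector"` applies the 0.3 rule to
#' raw unit-eigenvector entries instead. `refit = FALSE` keeps the
#' original full-member component and merely projects the retained
#' members onto it.
#'
#' @param view A z-normalized data frame/matrix of measures.
#' @param groups Named list mapping category name -> member column names;
#'   every member must appear in exactly one category and exist in `view`.
#' @param loading_type `"component"` (default) or `"eigenvector"`.
#' @param refit Recompute the first PC on the retained members (default
#'   `TRUE`); otherwise project onto the original component.
#' @return An object of class `category_scores`: `scores` (tibble, one
#'   column per surviving category; column variance equals the first
#'   eigenvalue of the retained members' correlation matrix),
#'   `loadings` (tibble: category, member, loading), `retained_members`,
#'   `dropped_members`, and the settings used.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x[, 2] <- x[, 1] + rnorm(100, sd = 0.2)
#' colnames(x) <- c("a1", "a2", "b1")
#' cs <- category_pca(zscore(x), list(A = c("a1", "a2"), B = "b1"))
#' cs$loadings
category_pca <- function(view, groups,
                         loading_type = c("component", "eigenvector"),
                         refit = TRUE) {
  loading_type <- match.arg(loading_type)
  y <- as_view_matrix(view, "view")
  check_no_missing(y, "view")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list (category -> members)")
  }
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    abort(sprintf("measures appear in more than one category: %s",
                  paste(unique(members[duplicated(members)]), collapse = ", ")))
  }
  missing_m <- setdiff(members, colnames(y))
  if (length(missing_m) > 0) {
    abort(sprintf("category members absent from the input view: %s",
                  paste(head(missing_m, 5), collapse = ", ")))
  }
  if (any(lengths(groups) < 1)) abort("every category needs at least one member")
  # precondition: input is z-normalized
  mu <- colMeans(y[, members, drop = FALSE])
  s <- apply(y[, members, drop = FALSE], 2, sd)
  if (max(abs(mu)) > 1e-6 || max(abs(s - 1)) > 1e-3) {
    abort("input view must be z-normalized (see zscore())")
  }

  score_list <- list()
  loading_rows <- list()
  retained <- list()
  dropped <- list()

  first_pc <- function(xm) {
    r <- stats::cor(xm)
    e <- eigen(r, symmetric = TRUE)
    v <- e$vectors[, 1]
    lam <- e$values[1]
    # sign: majority of loadings positive; ties -> first member nonnegative
    pos <- sum(v > 0); neg <- sum(v < 0)
    if (neg > pos || (neg == pos && v[1] < 0)) v <- -v
    list(vec = v, lambda = lam)
  }

  for (cat_name in names(groups)) {
    mem <- groups[[cat_name]]
    if (length(mem) == 1) {
      score_list[[cat_name]] <- y[, mem]
      loading_rows[[cat_name]] <- tibble::tibble(
        category = cat_name, member = mem, loading = 1.0)
      retained[[cat_name]] <- mem
      dropped[[cat_name]] <- character(0)
      next
    }
    keep <- mem
    pc <- first_pc(y[, keep, drop = FALSE])
    loading_of <- function(pc) {
      if (loading_type == "component") pc$vec * sqrt(pc$lambda) else pc$vec
    }
    load <- loading_of(pc)
    gone <- character(0)
    repeat {
      low <- load < 0.3
      if (!any(low)) break
      gone <- c(gone, keep[low])
      keep <- keep[!low]
      if (length(keep) == 0) break
      if (length(keep) == 1) {
        load <- 1.0
        break
      }
      if (refit) {
        pc <- first_pc(y[, keep, drop = FALSE])
        load <- loading_of(pc)
      } else {
        # projection variant: keep original component restricted to the
        # survivors; no further dropping beyond the first pass
        sel <- match(keep, mem)
        load <- loading_of(pc)[sel]
        break
      }
    }
    if (length(keep) == 0) {
      warn(sprintf("category '%s': no member reached a 0.3 positive loading; category excluded", cat_name))
      dropped[[cat_name]] <- mem
      retained[[cat_name]] <- character(0)
      next
    }
    if (length(keep) == 1) {
      score_list[[cat_name]] <- y[, keep]
      loading_rows[[cat_name]] <- tibble::tibble(
        category = cat_name, member = keep, loading = 1.0)
    } else {
      score_list[[cat_name]] <- drop(y[, keep, drop = FALSE] %*% pc$vec)
      loading_rows[[cat_name]] <- tibble::tibble(
        category = cat_name, member = keep, loading = load)
    }
    retained[[cat_name]] <- keep
    dropped[[cat_name]] <- gone
  }

  structure(list(
    scores = tibble::as_tibble(score_list),
    loadings = dplyr::bind_rows(loading_rows),
    retained_members = retained,
    dropped_members = dropped,
    weights = lapply(names(retained), function(cn) {
      k <- retained[[cn]]
      if (length(k) == 0) return(NULL)
      if (length(k) == 1) return(stats::setNames(1.0, k))
      pc <- first_pc(y[, k, drop = FALSE])
      stats::setNames(pc$vec, k)
    }) |> stats::setNames(names(retained)),
    loading_type = loading_type,
    refit = refit
  ), class = "category_scores")
}

#' Apply fitted category components to new data
#'
#' Projects new (already residualized and z-normalized with training
#' parameters) measures onto the training-set category components.
#'
#' @param object A `category_scores` fit.
#' @param newdata Data frame/matrix containing the retained member
#'   columns.
#' @param ... Unused.
#' @return A tibble of category scores for `newdata`.
#' @export
predict.category_scores <- function(object, newdata, ...) {
  y <- as_view_matrix(newdata, "newdata")
  out <- list()
  for (cat_name in names(object$weights)) {
    wgt <- object$weights[[cat_name]]
    if (is.null(wgt)) next
    missing_m <- setdiff(names(wgt), colnames(y))
    if (length(missing_m) > 0) {
      abort(sprintf("newdata lacks member column(s): %s",
                    paste(missing_m, collapse = ", ")))
    }
    out[[cat_name]] <- drop(y[, names(wgt), drop = FALSE] %*% wgt)
  }
  tibble::as_tibble(out)
}

#' @export
print.category_scores <- function(x, ...) {
  cat("<category_scores>\n")
  cat(sprintf("  %d categories scored, %d excluded\n",
              ncol(x$scores),
              sum(vapply(x$retained_members, length, integer(1)) == 0)))
  cat(sprintf("  loading type: %s; refit after dropping: %s\n",
              x$loading_type, x$refit))
  invisible(x)
}

#' @rdname category_pca
#' @param x A `category_scores` object.
#' @param ... Unused.
#' @method tidy category_scores
#' @export
tidy.category_scores <- function(x, ...) x$loadings
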