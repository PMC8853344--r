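#' Expand covariates to numeric indicator columns
#'
#' Factor and character covariates are expanded to 0/1 indicators with
#' the first (reference) level dropped; numeric columns pass through.
#'
#' @param covariates A data frame of covariates.
#' @return A tibble of numeric columns.
#' @export
expand_covariates <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  mm <- stats::model.matrix(~ ., data = covariates)
  tibble::as_tibble(mm[, colnames(mm) != "(Intercept)", drop = FALSE])
}

#' Residualize a view on covariates
#'
#' Replaces each column by its least-squares residual on an intercept
#' plus all covariate columns. When `coefficients` (from a previous fit,
#' e.g. on a training split) are supplied, they are applied as-is instead
#' of being re-estimated, so hold-out data can be residualized with
#' training parameters.
#'
#' @param view Data frame or matrix of numeric columns to residualize.
#' @param covariates Numeric covariate columns (categoricals already
#'   expanded to indicators; see [expand_covariates()]).
#' @param coefficients Optional coefficient matrix from a previous call
#'   (attribute `"coefficients"` of its result).
#' @return A tibble of residual columns with attribute `"coefficients"`
#'   (rows: intercept + covariates; columns: view variables).
#' @export
residualize <- function(view, covariates, coefficients = NULL) {
  y <- as_view_matrix(view, "view")
  x <- as_view_matrix(covariates, "covariates")
  check_no_missing(y, "view")
  check_no_missing(x, "covariates")
  if (nrow(y) != nrow(x)) abort("view and covariates are not row-aligned")
  if (is.null(coefficients)) {
    # constant covariate columns are absorbed by the intercept
    keep <- apply(x, 2, function(col) stats::var(col) > 0)
    x <- x[, keep, drop = FALSE]
    xmat <- cbind(`(Intercept)` = 1, x)
    qrx <- qr(xmat)
    if (qrx$rank < ncol(xmat)) {
      aliased <- colnames(xmat)[qrx$pivot[(qrx$rank + 1):ncol(xmat)]]
      abort(sprintf("covariate matrix is rank-deficient; collinear columns: %s",
                    paste(aliased, collapse = ", ")))
    }
    coefficients <- qr.coef(qrx, y)
    rownames(coefficients) <- colnames(xmat)
  } else {
    needed <- setdiff(rownames(coefficients), "(Intercept)")
    missing_cov <- setdiff(needed, colnames(x))
    if (length(missing_cov) > 0) {
      abort(sprintf("covariates lack column(s) required by the supplied coefficients: %s",
                    paste(missing_cov, collapse = ", ")))
    }
    xmat <- cbind(`(Intercept)` = 1, x[, needed, drop = FALSE])
    missing_cols <- setdiff(colnames(y), colnames(coefficients))
    if (length(missing_cols) > 0) {
      abort(sprintf("supplied coefficients lack columns: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    coefficients <- coefficients[, colnames(y), drop = FALSE]
  }
  res <- y - xmat %*% coefficients
  out <- tibble::as_tibble(res)
  attr(out, "coefficients") <- coefficients
  out
}

#' Z-normalize the columns of a view
#'
#' Centers and scales every column to mean 0 and standard deviation 1
#' using the sample (n-1) convention. Supplying `center`/`scale` applies
#' previously estimated parameters (training moments) instead.
#'
#' @param view Data frame or matrix of numeric columns.
#' @param center,scale Optional named vectors of training means/SDs.
#' @return A tibble with attributes `"center"`, `"scale"` and
#'   `"sd_convention"` (`"sample (n-1)"`).
#' @export
zscore <- function(view, center = NULL, scale = NULL) {
  y <- as_view_matrix(view, "view")
  check_no_missing(y, "view")
  if (is.null(center) != is.null(scale)) {
    abort("supply both `center` and `scale`, or neither")
  }
  if (is.null(center)) {
    center <- colMeans(y)
    scale <- apply(y, 2, sd)
    zero_var <- colnames(y)[scale == 0 | !is.finite(scale)]
    if (length(zero_var) > 0) {
      abort(sprintf("zero-variance column(s): %s", paste(zero_var, collapse = ", ")))
    }
  } else {
    center <- center[colnames(y)]
    scale <- scale[colnames(y)]
    if (anyNA(center) || anyNA(scale)) {
      abort("`center`/`scale` must be named and cover every view column")
    }
  }
  z <- sweep(sweep(y, 2, center, `-`), 2, scale, `/`)
  out <- tibble::as_tibble(z)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "sd_convention") <- "sample (n-1)"
  out
}
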