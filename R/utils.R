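# internal helpers shared across modules

# round-half-up, used for the quartile stratum size (0.25 * 40078 -> 10020)
round_half_up <- function(x) floor(x + 0.5)

as_view_matrix <- function(x, arg = "view") {
  if (is.matrix(x)) {
    if (!is.numeric(x)) abort(sprintf("`%s` must be numeric", arg))
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("`%s` has non-numeric columns: %s", arg,
                    paste(bad, collapse = ", ")))
    }
    return(as.matrix(x))
  }
  if (is.numeric(x)) {
    m <- matrix(x, ncol = 1)
    colnames(m) <- arg
    return(m)
  }
  abort(sprintf("`%s` must be a data frame, matrix or numeric vector", arg))
}

check_aligned <- function(views) {
  ns <- vapply(views, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    abort(sprintf("views are not row-aligned: n = %s",
                  paste(ns, collapse = ", ")))
  }
  invisible(ns[[1]])
}

check_no_missing <- function(m, arg = "view") {
  if (anyNA(m)) abort(sprintf("`%s` contains missing values; use drop_incomplete() first", arg))
  invisible(m)
}

# Derive named substream seeds from one master seed so every stochastic
# stage is independently reproducible. Kept below .Machine$integer.max.
derive_seeds <- function(master, names) {
  stopifnot(is.numeric(master), length(master) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Drop rows with missing values across aligned views
#'
#' Complete-case filter applied jointly to a set of row-aligned tables.
#' The number of dropped participants is reported via a message.
#'
#' @param ... Row-aligned data frames (or matrices).
#' @return A list of tibbles with incomplete rows removed; the number of
#'   dropped rows is attached as attribute `"n_dropped"`.
#' @export
drop_incomplete <- function(...) {
  views <- list(...)
  if (length(views) == 1 && is.list(views[[1]]) && !is.data.frame(views[[1]])) {
    views <- views[[1]]
  }
  mats <- lapply(views, as_view_matrix)
  check_aligned(mats)
  ok <- Reduce(`&`, lapply(mats, function(m) stats::complete.cases(m)))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("drop_incomplete(): removed %d incomplete row(s)", n_dropped))
  }
  out <- lapply(views, function(v) tibble::as_tibble(as.data.frame(v)[ok, , drop = FALSE]))
  attr(out, "n_dropped") <- n_dropped
  out
}
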