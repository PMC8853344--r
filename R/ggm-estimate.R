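#' Quartile stratification by exposure
#'
#' Splits rows into the k highest- and k lowest-exposure participants
#' with `k = round-half-up(lower_q * n)` (rank method, the default: with
#' `n = 40078` this gives 10020 per stratum). Boundary ties are broken
#' by stable row order. The `"threshold"` method instead keeps rows
#' strictly above/below the `upper_q`/`lower_q` empirical quantiles.
#'
#' @param data Data frame of node variables (rows aligned to `exposure`).
#' @param exposure Numeric vector or one-column data frame of exposure
#'   values.
#' @param lower_q,upper_q Quantile bounds (default 0.25/0.75).
#' @param method `"rank"` (top-k/bottom-k) or `"threshold"` (strict
#'   quantile cutoffs).
#' @return A list with tibbles `high` and `low`, the row indices
#'   `high_idx`/`low_idx`, and `k`.
#' @export
stratify_by_exposure <- function(data, exposure, lower_q = 0.25,
                                 upper_q = 0.75,
                                 method = c("rank", "threshold")) {
  method <- match.arg(method)
  x <- as_view_matrix(exposure, "exposure")
  if (ncol(x) != 1) abort("exposure must be a single column")
  x <- drop(x)
  d <- tibble::as_tibble(data)
  if (length(x) != nrow(d)) abort("exposure is not aligned to data rows")
  n <- length(x)
  if (method == "rank") {
    k_low <- round_half_up(lower_q * n)
    k_high <- round_half_up((1 - upper_q) * n)
    # stable order: ties keep original row order
    low_idx <- order(x, method = "radix")[seq_len(k_low)]
    high_idx <- order(-x, method = "radix")[seq_len(k_high)]
  } else {
    qs <- quantile(x, c(lower_q, upper_q), names = FALSE)
    low_idx <- which(x < qs[1])
    high_idx <- which(x > qs[2])
  }
  min_rows <- ncol(d) + 5
  if (length(low_idx) < min_rows || length(high_idx) < min_rows) {
    warn(sprintf("stratum too small to estimate a %d-node network (fewer than %d rows)",
                 ncol(d), min_rows))
  }
  list(
    high = d[high_idx, , drop = FALSE],
    low = d[low_idx, , drop = FALSE],
    high_idx = high_idx,
    low_idx = low_idx,
    k = c(high = length(high_idx), low = length(low_idx))
  )
}

#' Estimate a Gaussian graphical model with EBIC model selection
#'
#' Reimplements the stepwise GGM selection popular in network
#' psychometrics: (a) a graphical-lasso path over a log-spaced lambda
#' grid from the empty-graph lambda down to `lambda_min_ratio` times it;
#' (b) each distinct edge set on the path is refit as an unregularized
#' Gaussian model and scored by EBIC with parameter `gamma`; (c) from
#' the best path model, a greedy stepwise search tests all single-edge
#' additions and removals (unregularized refits) and accepts the move
#' that most decreases EBIC until a local minimum (ties prefer removal,
#' then the lowest edge index). Edge weights are the partial
#' correlations of the final unregularized fit, zeroed off the selected
#' edge set.
#'
#' @param data Data frame/matrix of numeric node columns (`n > p`), or
#'   `NULL` when `input_cor` is given.
#' @param communities Optional named character vector assigning each node
#'   to a community (used by [bridge_expected_influence()]).
#' @param gamma EBIC hyperparameter (default 0).
#' @param lambda_grid_size Number of lambda values on the path.
#' @param lambda_min_ratio Smallest lambda as a fraction of the
#'   empty-graph lambda.
#' @param stepwise Run the greedy stepwise refinement (default `TRUE`).
#' @param input_cor Optional pre-computed correlation matrix (e.g.
#'   polychoric, computed elsewhere); requires `n` rows to be given via
#'   `n_obs`.
#' @param n_obs Number of observations behind `input_cor`.
#' @return An object of class `ggm_network`: `nodes`, `community`,
#'   `weights` (symmetric partial-correlation matrix, zero diagonal),
#'   `adjacency`, `ebic`, EBIC trajectories, and the settings.
#' @export
estimate_ggm <- function(data = NULL, communities = NULL, gamma = 0,
                         lambda_grid_size = 100, lambda_min_ratio = 0.01,
                         stepwise = TRUE, input_cor = NULL, n_obs = NULL) {
  if (is.null(input_cor)) {
    m <- as_view_matrix(data, "data")
    check_no_missing(m, "data")
    n <- nrow(m)
    p <- ncol(m)
    if (n <= p) abort(sprintf("need more observations than nodes (n = %d, p = %d)", n, p))
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("constant column(s): %s", paste(colnames(m)[sds == 0], collapse = ", ")))
    }
    S <- cor(m)
    nodes <- colnames(m)
  } else {
    if (is.null(n_obs)) abort("supply n_obs with input_cor")
    S <- as.matrix(input_cor)
    n <- as.integer(n_obs)
    p <- ncol(S)
    nodes <- colnames(S) %||% paste0("V", seq_len(p))
  }
  if (any(!is.finite(S))) abort("correlation matrix has non-finite entries (singular input?)")

  fit <- ggm_select_cpp(S, as.integer(n), gamma, as.integer(lambda_grid_size),
                        lambda_min_ratio, isTRUE(stepwise))
  wts <- fit$pcor
  dimnames(wts) <- list(nodes, nodes)
  adj <- fit$adj
  dimnames(adj) <- list(nodes, nodes)
  if (!is.null(communities)) {
    if (is.null(names(communities))) {
      if (length(communities) != p) abort("communities must be named or one per node")
      names(communities) <- nodes
    }
    missing_nodes <- setdiff(nodes, names(communities))
    if (length(missing_nodes) > 0) {
      abort(sprintf("communities missing for node(s): %s",
                    paste(missing_nodes, collapse = ", ")))
    }
    communities <- communities[nodes]
  }

  structure(list(
    nodes = nodes,
    community = communities,
    weights = wts,
    adjacency = adj,
    ebic = fit$ebic,
    path_ebic = fit$path_ebic,
    path_edges = fit$path_edges,
    step_ebic = fit$step_ebic,
    n = n,
    settings = list(gamma = gamma, lambda_grid_size = lambda_grid_size,
                    lambda_min_ratio = lambda_min_ratio, stepwise = isTRUE(stepwise))
  ), class = "ggm_network")
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over all node pairs.
#'
#' @param net A `ggm_network` or a symmetric weight matrix.
#' @return A single number.
#' @export
global_strength <- function(net) {
  w <- if (inherits(net, "ggm_network")) net$weights else as.matrix(net)
  sum(abs(w[upper.tri(w)]))
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- length(x$nodes)
  ne <- sum(x$adjacency[upper.tri(x$adjacency)])
  cat("<ggm_network>\n")
  cat(sprintf("  %d nodes, %d edges, n = %d\n", p, ne, x$n))
  cat(sprintf("  global strength = %.4f, EBIC = %.2f\n",
              global_strength(x), x$ebic))
  if (!is.null(x$community)) {
    cat(sprintf("  communities: %s\n",
                paste(sprintf("%s (%d)", names(table(x$community)),
                              table(x$community)), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname estimate_ggm
#' @param x A `ggm_network`.
#' @param ... Unused.
#' @method tidy ggm_network
#' @export
tidy.ggm_network <- function(x, ...) {
  idx <- which(upper.tri(x$weights) & x$adjacency == 1, arr.ind = TRUE)
  out <- tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    weight = x$weights[idx]
  )
  if (!is.null(x$community)) {
    out$from_community <- unname(x$community[out$from])
    out$to_community <- unname(x$community[out$to])
    out$bridge_edge <- out$from_community != out$to_community
  }
  out
}

#' @rdname estimate_ggm
#' @method glance ggm_network
#' @export
glance.ggm_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = sum(x$adjacency[upper.tri(x$adjacency)]),
    global_strength = global_strength(x),
    ebic = x$ebic,
    n = x$n
  )
}

#' @rdname estimate_ggm
#' @param object A `ggm_network`.
#' @method autoplot ggm_network
#' @export
autoplot.ggm_network <- function(object, ...) {
  w <- object$weights
  df <- tibble::as_tibble(as.data.frame(as.table(w), stringsAsFactors = FALSE))
  names(df) <- c("from", "to", "weight")
  df$from <- factor(df$from, levels = object$nodes)
  df$to <- factor(df$to, levels = rev(object$nodes))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1) * max(abs(w), 0.1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export a network as GraphML or a weighted edge list
#'
#' @param net A `ggm_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "ggm_network"))
  edges <- tidy(net)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(
      name = net$nodes,
      community = if (is.null(net$community)) NA_character_ else unname(net$community)
    ))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "ggm_network"))
  utils::write.csv(tidy(net), path, row.names = FALSE)
  invisible(path)
}
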