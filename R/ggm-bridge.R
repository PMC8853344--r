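#' 1-step bridge expected influence
#'
#' For every node, the signed sum of its edge weights to nodes in other
#' predefined communities. Nodes ranking in the top 20% (by value,
#' `ceiling(0.2 * p)` nodes; ties at the cutoff are all included) are
#' flagged as bridge nodes.
#'
#' @param net A `ggm_network` with a `community` assignment, or a weight
#'   matrix (then supply `communities`).
#' @param communities Named community vector when `net` is a matrix.
#' @param top_fraction Fraction of nodes flagged as bridges (default 0.2).
#' @return An object of class `bridge_result`: tibble `bei` (`node`,
#'   `community`, `bei`, `bridge`), the cutoff used, and a `degenerate`
#'   flag set when all values tie (e.g. an empty network), in which case
#'   the first `ceiling(0.2 * p)` nodes in roster order are flagged.
#' @export
bridge_expected_influence <- function(net, communities = NULL,
                                      top_fraction = 0.2) {
  if (inherits(net, "ggm_network")) {
    w <- net$weights
    communities <- communities %||% net$community
  } else {
    w <- as.matrix(net)
  }
  if (is.null(communities)) abort("communities must be assigned to every node")
  nodes <- colnames(w) %||% names(communities)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(w)))
  communities <- communities[nodes]
  if (anyNA(communities)) abort("communities must cover every node")
  p <- length(nodes)
  if (length(unique(communities)) < 2) {
    warn("single community: all bridge expected influences are 0")
  }

  other <- outer(communities, communities, `!=`)
  bei <- rowSums(w * other)
  names(bei) <- nodes

  m <- ceiling(top_fraction * p)
  ord <- order(bei, decreasing = TRUE)
  cutoff <- bei[ord[m]]
  degenerate <- length(unique(round(bei, 12))) == 1
  if (degenerate) {
    bridge <- seq_len(p) %in% seq_len(m)  # tie rule: first m in roster order
    warn("all bridge expected influences tie; bridge set taken in roster order (degenerate)")
  } else {
    bridge <- bei >= cutoff
  }

  structure(list(
    bei = tibble::tibble(
      node = nodes,
      community = unname(communities),
      bei = unname(bei),
      bridge = unname(bridge)
    ),
    top_fraction = top_fraction,
    n_top = m,
    cutoff = unname(cutoff),
    degenerate = degenerate
  ), class = "bridge_result")
}

#' @export
print.bridge_result <- function(x, ...) {
  cat("<bridge_result>\n")
  br <- x$bei$node[x$bei$bridge]
  cat(sprintf("  bridge nodes (top %.0f%%): %s%s\n", 100 * x$top_fraction,
              paste(br, collapse = ", "),
              if (x$degenerate) " [degenerate: all values tie]" else ""))
  invisible(x)
}

#' @rdname bridge_expected_influence
#' @param x A `bridge_result`.
#' @param ... Unused.
#' @method tidy bridge_result
#' @export
tidy.bridge_result <- function(x, ...) x$bei

#' @rdname bridge_expected_influence
#' @param object A `bridge_result`.
#' @method autoplot bridge_result
#' @export
autoplot.bridge_result <- function(object, ...) {
  df <- object$bei
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$node, .data$bei),
    y = .data$bei, fill = .data$bridge)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$community), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "1-step bridge expected influence",
                  fill = "bridge") +
    ggplot2::theme_minimal()
}
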