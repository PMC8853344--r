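#' Generate two exposure strata with a planted network difference
#'
#' Draws two multivariate-normal samples ("high" and "low" exposure
#' strata) whose precision matrices share a sparse base structure:
#' within-community chains among environment nodes and among
#' mental-physical symptom nodes, plus a declared set of cross-community
#' edges. The high stratum adds `stratum_edge_shift` (from the config) to
#' the planted cross-community partial correlations, so its true global
#' strength exceeds the low stratum's whenever the shift is positive.
#'
#' With `nodes_env = 7` and `nodes_sym = 5` the nodes carry the standard
#' roster labels (AP, GS, ED, ND, DE, DS, PV / Dpr, Dis, Trd, Nap, Wst);
#' otherwise generic `env_*` / `sym_*` labels are used. The planted
#' cross-community edges pair the last environment nodes with the first
#' symptom nodes, so the roster default plants (PV, Dpr), (DS, Dis),
#' (DE, Trd).
#'
#' @param config A [synth_config()]; `n_participants` rows are drawn per
#'   stratum and `stratum_edge_shift` sets the high-stratum offset.
#' @param nodes_env Number of environment-community nodes.
#' @param nodes_sym Number of mental-physical-community nodes.
#' @param within_pc Partial correlation of within-community chain edges.
#' @param base_cross_pc Base partial correlation of the planted
#'   cross-community edges (shared by both strata).
#' @param n_cross Number of planted cross-community edges.
#' @return A list of class `stratified_data`: tibbles `data_high` and
#'   `data_low`, the `communities` assignment, and a `truth` object whose
#'   `planted_edges` tibble lists every nonzero edge of each stratum's
#'   population network (exact partial correlations).
#' @export
generate_stratified <- function(config, nodes_env = 7, nodes_sym = 5,
                                within_pc = 0.25, base_cross_pc = 0.1,
                                n_cross = 3) {
  validate_synth_config(config)
  pe <- as.integer(nodes_env)
  ps <- as.integer(nodes_sym)
  if (pe < 1 || ps < 1) abort("both communities need at least one node")
  p <- pe + ps
  n_cross <- min(as.integer(n_cross), pe, ps)

  if (pe == 7 && ps == 5) {
    nodes <- c("AP", "GS", "ED", "ND", "DE", "DS", "PV",
               "Dpr", "Dis", "Trd", "Nap", "Wst")
  } else {
    nodes <- c(sprintf("env_%02d", seq_len(pe)), sprintf("sym_%02d", seq_len(ps)))
  }
  communities <- stats::setNames(
    c(rep("environment", pe), rep("mental-physical", ps)), nodes)

  ## partial-correlation skeleton -------------------------------------
  pc_base <- matrix(0, p, p, dimnames = list(nodes, nodes))
  add_edge <- function(pc, i, j, v) { pc[i, j] <- v; pc[j, i] <- v; pc }
  if (pe > 1) for (i in seq_len(pe - 1)) pc_base <- add_edge(pc_base, i, i + 1, within_pc)
  if (ps > 1) for (i in seq_len(ps - 1)) pc_base <- add_edge(pc_base, pe + i, pe + i + 1, within_pc)
  cross_pairs <- cbind(pe + 1 - seq_len(n_cross), pe + seq_len(n_cross))
  for (r in seq_len(nrow(cross_pairs))) {
    pc_base <- add_edge(pc_base, cross_pairs[r, 1], cross_pairs[r, 2], base_cross_pc)
  }
  pc_high <- pc_base
  for (r in seq_len(nrow(cross_pairs))) {
    i <- cross_pairs[r, 1]; j <- cross_pairs[r, 2]
    pc_high[i, j] <- pc_high[i, j] + config$stratum_edge_shift
    pc_high[j, i] <- pc_high[i, j]
  }

  theta_from_pc <- function(pc) {
    th <- -pc
    diag(th) <- 1
    th
  }
  theta_low <- theta_from_pc(pc_base)
  theta_high <- theta_from_pc(pc_high)
  for (nm in c("low", "high")) {
    th <- if (nm == "low") theta_low else theta_high
    ev <- min(eigen(th, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-8) {
      abort(sprintf(
        "stratum '%s' precision matrix is not positive definite (min eigenvalue %.3g); reduce within_pc, base_cross_pc or stratum_edge_shift",
        nm, ev))
    }
  }

  draw <- function(theta, n) {
    sigma <- solve(theta)
    ch <- chol(sigma)
    x <- matrix(rnorm(n * p), n, p) %*% ch
    colnames(x) <- nodes
    tibble::as_tibble(x)
  }

  edges_of <- function(pc, stratum) {
    idx <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
    tibble::tibble(
      node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
      stratum = stratum, pcor = pc[idx]
    )
  }

  with_seed(config$seed, {
    data_high <- draw(theta_high, config$n_participants)
    data_low <- draw(theta_low, config$n_participants)
    truth <- structure(list(
      signal_category_ids = character(),
      signal_wellbeing_ids = character(),
      population_loadings = stats::setNames(numeric(0), character(0)),
      planted_edges = dplyr::bind_rows(edges_of(pc_high, "high"),
                                       edges_of(pc_base, "low")),
      pcor_high = pc_high,
      pcor_low = pc_base,
      theta_high = theta_high,
      theta_low = theta_low
    ), class = "synth_truth")
    structure(list(
      data_high = data_high,
      data_low = data_low,
      communities = communities,
      truth = truth,
      config = config
    ), class = "stratified_data")
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth>\n")
  cat(sprintf("  signal categories: %s\n",
              paste(x$signal_category_ids, collapse = ", ")))
  cat(sprintf("  signal wellbeing: %s\n",
              paste(x$signal_wellbeing_ids, collapse = ", ")))
  cat(sprintf("  planted edges: %d\n", nrow(x$planted_edges)))
  invisible(x)
}
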