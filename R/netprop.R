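# Network smoothing of specificity scores: symmetric Laplacian
# normalization of the weighted adjacency matrix, iterative propagation
# with a sharing coefficient, subtraction of a topology-bias term obtained
# by propagating the mean score from every node, and top-fraction
# extraction.

#' Symmetric Laplacian normalization of a network
#'
#' Returns `W~ = D^(-1/2) W D^(-1/2)` as a sparse matrix over all network
#' nodes (including isolated ones, whose rows and columns are zero). The
#' spectral radius of `W~` is at most 1, so propagation with a sharing
#' coefficient below 1 converges geometrically.
#'
#' @param net a `ppi_network` (see [read_network()]).
#' @return A sparse symmetric matrix with node ids as dimnames.
#' @export
normalize_adjacency <- function(net) {
  nodes <- network_nodes(net)
  i <- match(net$from, nodes)
  j <- match(net$to, nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(net$weight, net$weight),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  out <- Matrix::Diagonal(x = inv_sqrt) %*% W %*% Matrix::Diagonal(x = inv_sqrt)
  dimnames(out) <- list(nodes, nodes)
  out
}

#' Iterative score propagation
#'
#' Iterates `F <- alpha W~ F + (1 - alpha) F0` for `iters` steps starting
#' from `F0`. For `alpha < 1` this converges geometrically to the closed
#' form `(1 - alpha) (I - alpha W~)^(-1) F0`.
#'
#' @param f0 named (or node-ordered) numeric vector of initial scores.
#' @param w_norm normalized adjacency from [normalize_adjacency()].
#' @param alpha sharing coefficient in [0, 1) (default 0.5).
#' @param iters number of iterations (default 30).
#' @return The propagated score vector, named by node.
#' @export
propagate <- function(f0, w_norm, alpha = 0.5, iters = 30) {
  if (alpha < 0 || alpha >= 1) stop_contract("alpha must lie in [0, 1)")
  nodes <- rownames(w_norm)
  if (!is.null(names(f0))) {
    if (!setequal(names(f0), nodes)) {
      stop_contract("score vector names do not match the network nodes")
    }
    f0 <- f0[nodes]
  } else if (length(f0) != nrow(w_norm)) {
    stop_contract("score vector length does not match the network")
  }
  f <- f0
  for (it in seq_len(iters)) {
    f <- alpha * as.numeric(w_norm %*% f) + (1 - alpha) * f0
  }
  names(f) <- nodes
  f
}

#' Closed-form propagation limit
#'
#' Solves `(I - alpha W~) F = (1 - alpha) F0` directly; the fixed point of
#' [propagate()]. Intended for small graphs and as an independent check.
#'
#' @inheritParams propagate
#' @return The limiting score vector, named by node.
#' @export
propagate_closed_form <- function(f0, w_norm, alpha = 0.5) {
  nodes <- rownames(w_norm)
  if (!is.null(names(f0))) f0 <- f0[nodes]
  A <- Matrix::Diagonal(nrow(w_norm)) - alpha * w_norm
  setNames(as.numeric(Matrix::solve(A, (1 - alpha) * f0)), nodes)
}

#' Propagation with topology-bias correction
#'
#' Propagates the initial scores, then propagates a constant vector equal
#' to their mean; the latter captures how much score a node accumulates
#' purely through its network neighbourhood ("topology bias") and is
#' subtracted. With constant initial scores the corrected scores are zero
#' everywhere.
#'
#' @param f0 named numeric vector of initial (specificity) scores, >= 0.
#' @param net a `ppi_network`, or a pre-normalized sparse matrix.
#' @param alpha sharing coefficient (default 0.5).
#' @param iters iterations (default 30).
#' @return A `propagation_result` tibble: `node`, `f0`, `f`, `bias`,
#'   `f_corr`, `rank` (1 = highest corrected score).
#' @export
topology_bias_correct <- function(f0, net, alpha = 0.5, iters = 30) {
  w_norm <- if (inherits(net, "ppi_network")) normalize_adjacency(net) else net
  nodes <- rownames(w_norm)
  if (!is.null(names(f0))) f0 <- f0[nodes]
  f <- propagate(f0, w_norm, alpha, iters)
  bias <- propagate(rep(mean(f0), length(f0)), w_norm, alpha, iters)
  f_corr <- f - bias
  out <- tibble(node = nodes, f0 = as.numeric(f0), f = as.numeric(f),
                bias = as.numeric(bias), f_corr = f_corr)
  out$rank <- rank(-out$f_corr, ties.method = "min")
  structure(out, alpha = alpha, iters = iters,
            class = c("propagation_result", class(out)))
}

#' Select the top-scoring fraction of nodes
#'
#' Returns the `floor(fraction * n)` highest-scoring nodes; ties at the
#' cut are broken deterministically by ascending node identifier.
#'
#' @param result a `propagation_result` (or tibble with `node` and a score
#'   column).
#' @param fraction fraction of nodes to keep (default 0.02).
#' @param score_col score column used for ranking (default `"f_corr"`).
#' @return Character vector of selected node ids.
#' @export
select_top <- function(result, fraction = 0.02, score_col = "f_corr") {
  if (fraction <= 0 || fraction > 1) stop_contract("fraction must lie in (0, 1]")
  n_keep <- floor(fraction * nrow(result))
  if (n_keep == 0) {
    rlang::warn("top-fraction selection is empty at this network size")
    return(character())
  }
  ord <- order(-result[[score_col]], result$node)
  result$node[ord][seq_len(n_keep)]
}

#' Connected components of an induced subgraph
#'
#' Induces the subgraph on the given nodes and returns its connected
#' components, largest first, with edge counts and density.
#'
#' @param nodes character vector of node ids (subset of the network).
#' @param net a `ppi_network`.
#' @return Tibble: `component` (integer id, 1 = largest), `node`; attribute
#'   `summary` is a per-component tibble (`component`, `n_nodes`,
#'   `n_edges`, `density`).
#' @export
extract_subnetworks <- function(nodes, net) {
  unknown <- setdiff(nodes, network_nodes(net))
  if (length(unknown)) {
    stop_contract("nodes not in the network: %s",
                  paste(head(unknown, 5), collapse = ", "))
  }
  g <- igraph::induced_subgraph(as_igraph(net), nodes)
  comp <- igraph::components(g)
  membership <- tibble(node = igraph::V(g)$name,
                       raw = as.integer(comp$membership))
  size_rank <- rank(-comp$csize, ties.method = "first")
  membership$component <- as.integer(size_rank[membership$raw])
  membership <- arrange(select(membership, "component", "node"),
                        .data$component, .data$node)
  summary <- membership |>
    group_by(.data$component) |>
    summarise(n_nodes = dplyr::n(), .groups = "drop")
  n_edges <- vapply(seq_len(comp$no), function(ci) {
    sub <- igraph::induced_subgraph(g, membership$node[membership$component == ci])
    as.integer(igraph::ecount(sub))
  }, integer(1))
  summary$n_edges <- n_edges
  summary$density <- ifelse(summary$n_nodes > 1,
                            summary$n_edges / choose(summary$n_nodes, 2), 0)
  attr(membership, "summary") <- summary
  membership
}

#' Smooth specificity scores over the network, per sample
#'
#' For each fusion sample, maps that sample's specificity scores onto the
#' network nodes (proteins without a score contribute 0), runs
#' [topology_bias_correct()], and flags the top `fraction` of nodes.
#'
#' @param spec a `specificity_table` from [specificity_scores()].
#' @param net a `ppi_network` whose nodes use the same identifier namespace
#'   as the specificity table (supply `mapping` otherwise).
#' @param mapping optional two-column tibble (`group_id`, `node`) mapping
#'   protein ids onto network node ids.
#' @param alpha,iters propagation parameters.
#' @param fraction top fraction to flag per sample (default 0.02).
#' @return Tibble: per (sample, node) the propagation result columns plus
#'   `selected`.
#' @export
smooth_scores <- function(spec, net, mapping = NULL, alpha = 0.5, iters = 30,
                          fraction = 0.02) {
  w_norm <- normalize_adjacency(net)
  nodes <- rownames(w_norm)
  spec <- as_tibble(spec)
  if (!is.null(mapping)) {
    spec <- inner_join(spec, mapping, by = "group_id")
  } else {
    spec$node <- spec$group_id
  }
  purrr::map(unique(spec$sample), function(s) {
    sub <- filter(spec, .data$sample == s)
    f0 <- setNames(rep(0, length(nodes)), nodes)
    hit <- sub$node %in% nodes
    f0[sub$node[hit]] <- sub$score[hit]
    res <- topology_bias_correct(f0, w_norm, alpha = alpha, iters = iters)
    res$sample <- s
    res$selected <- res$node %in% select_top(res, fraction = fraction)
    relocate(res, "sample")
  }) |> dplyr::bind_rows()
}
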