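#' Global efficiency of a directed graph
#'
#' Mean inverse directed shortest-path length over ordered node pairs,
#' with `1/Inf = 0` for unreachable pairs: `E = mean_{i != j} 1 / d(i, j)`.
#' A complete digraph has efficiency 1; an empty graph 0.
#'
#' @param adjacency Binary adjacency matrix (rows = source) or an
#'   `effective_network`.
#' @return Efficiency in `[0, 1]`, or `NA` for graphs with fewer than two
#'   nodes.
#' @export
global_efficiency <- function(adjacency) {
  adj <- as_adjacency(adjacency)
  n <- nrow(adj)
  if (n < 2) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  inv <- 1 / d                       # unreachable pairs: 1/Inf = 0
  mean(inv[row(inv) != col(inv)])
}

as_adjacency <- function(x) {
  if (inherits(x, "effective_network")) return(x$adjacency)
  if (inherits(x, "culture_network")) return(x$adjacency)
  as.matrix(x)
}

#' Louvain community detection on the largest connected component
#'
#' Restricts the graph to its largest weakly-connected component, collapses
#' directions, and maximizes Newman-Girvan modularity with the Louvain
#' algorithm (`restarts` runs, best modularity kept; deterministic under
#' `seed`). Alongside the modularity `Q` the literal ratio of intra- to
#' inter-modular directed edge counts is reported (`Q_ratio`), since both
#' readings of "community statistic" are in circulation.
#'
#' @param adjacency Binary adjacency matrix or `effective_network`.
#' @param seed Integer seed.
#' @param resolution Louvain resolution parameter.
#' @param restarts Number of Louvain restarts.
#' @return A list with `membership` (named by node index within the input
#'   graph), `component` (node indices of the analysed component), `Q`,
#'   `Q_ratio`, `sizes` and `mean_size`.
#' @export
detect_communities <- function(adjacency, seed = 1L, resolution = 1,
                               restarts = 10) {
  adj <- as_adjacency(adjacency)
  n <- nrow(adj)
  if (n == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  und <- igraph::as_undirected(sub, mode = "collapse")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(und, resolution = resolution)
      if (is.null(best) ||
          igraph::modularity(cl) > igraph::modularity(best)) best <- cl
    }
  })
  memb <- igraph::membership(best)
  q <- igraph::modularity(best)
  sizes <- as.integer(table(memb))
  sub_adj <- adj[keep, keep, drop = FALSE]
  same <- outer(memb, memb, "==")
  intra <- sum(sub_adj[same])
  inter <- sum(sub_adj[!same])
  q_ratio <- if (inter > 0) intra / inter else Inf
  list(membership = stats::setNames(as.integer(memb), keep),
       component = keep, Q = q, Q_ratio = q_ratio, sizes = sizes,
       mean_size = mean(sizes))
}

#' Connector hubs from participation coefficient and within-module degree
#'
#' Computes, on the union of in- and out-edges, each node's participation
#' coefficient \eqn{P_i = 1 - \sum_m (k_{i,m}/k_i)^2} and within-module
#' degree z-score \eqn{z_i}, and classifies as connector hubs the nodes with
#' `z >= z_hub` and `P > p_hub` (network-cartography convention; the z cutoff
#' is relaxed to 1.5 for sparse culture graphs). Isolated nodes have `P = 0`
#' and take their module's z-score convention (`z = 0` when the module
#' degree spread is zero).
#'
#' @param adjacency Binary adjacency matrix or `effective_network`.
#' @param membership Module label per analysed node, named by node index
#'   (e.g. from [detect_communities()]).
#' @param z_hub,p_hub Hub thresholds.
#' @return A list with `n_connector_hubs`, and per-node `P`, `z`, `is_hub`.
#' @export
classify_connector_hubs <- function(adjacency, membership, z_hub = 1.5,
                                    p_hub = 0.3) {
  adj <- as_adjacency(adjacency)
  nodes <- as.integer(names(membership))
  if (is.null(nodes) || anyNA(nodes)) nodes <- seq_along(membership)
  a <- adj[nodes, nodes, drop = FALSE]
  u <- ((a + t(a)) > 0) * 1L   # union of in- and out-edges, undirected
  mods <- as.integer(membership)
  n <- length(nodes)
  ki <- rowSums(u)
  kim <- rowsum(t(u), mods)            # modules x nodes: edges into module m
  p <- 1 - rowSums((t(kim) / pmax(ki, 1))^2)
  p[ki == 0] <- 0
  kin <- kim[cbind(match(mods, sort(unique(mods))), seq_len(n))]
  z <- numeric(n)
  for (m in unique(mods)) {
    idx <- which(mods == m)
    mu <- mean(kin[idx]); sdv <- stats::sd(kin[idx])
    z[idx] <- if (!is.na(sdv) && sdv > 0) (kin[idx] - mu) / sdv else 0
  }
  hub <- z >= z_hub & p > p_hub
  list(n_connector_hubs = sum(hub),
       P = stats::setNames(p, nodes), z = stats::setNames(z, nodes),
       is_hub = stats::setNames(hub, nodes))
}

#' Topology summary of an effective network
#'
#' Bundles the network observables of a recording: directed global
#' efficiency, Louvain communities on the largest connected component
#' (modularity `Q`, intra/inter edge ratio, mean community size) and the
#' connector-hub count.
#'
#' @param net An `effective_network` (or adjacency matrix).
#' @param seed Integer seed for Louvain restarts.
#' @param ... Passed to [classify_connector_hubs()].
#' @return An object of class `topology_summary` (named list).
#' @export
topology_summary <- function(net, seed = 1L, ...) {
  adj <- as_adjacency(net)
  eff <- global_efficiency(adj)
  comm <- detect_communities(adj, seed = seed)
  hubs <- classify_connector_hubs(adj, comm$membership, ...)
  structure(list(global_efficiency = eff, Q = comm$Q,
                 Q_ratio = comm$Q_ratio,
                 mean_community_size = comm$mean_size,
                 n_communities = length(comm$sizes),
                 community_sizes = comm$sizes,
                 n_connector_hubs = hubs$n_connector_hubs,
                 membership = comm$membership,
                 P = hubs$P, z = hubs$z),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Network topology summary\n")
  cat(sprintf("  global efficiency   : %.3f\n", x$global_efficiency))
  cat(sprintf("  communities         : %d (mean size %.1f), Q = %.3f\n",
              x$n_communities, x$mean_community_size, x$Q))
  cat(sprintf("  connector hubs      : %d\n", x$n_connector_hubs))
  invisible(x)
}
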