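#' Planted-partition ground-truth network
#'
#' Draws a directed graph with a planted modular (stochastic block) structure:
#' nodes are split into `n_modules` groups of near-equal size (sizes differ by
#' at most one) and each ordered pair of distinct nodes receives an edge with
#' probability `p_intra` when the nodes share a module and `p_inter`
#' otherwise. No self-loops are created.
#'
#' @param n_neurons Number of nodes (>= 1).
#' @param n_modules Number of planted modules (>= 1, <= `n_neurons`).
#' @param p_intra,p_inter Edge probabilities in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An object of class `culture_network`: a list with `adjacency`
#'   (n x n binary matrix, rows = presynaptic) and `modules` (integer module
#'   label per node).
#' @examples
#' net <- make_ground_truth_network(60, 3, 0.4, 0.05, seed = 1)
#' table(net$modules)
#' @export
make_ground_truth_network <- function(n_neurons, n_modules, p_intra, p_inter,
                                      seed = NULL) {
  if (n_neurons < 1) stop("'n_neurons' must be >= 1")
  if (n_modules < 1) stop("'n_modules' must be >= 1")
  if (n_modules > n_neurons)
    stop("'n_modules' cannot exceed 'n_neurons'")
  if (p_intra < 0 || p_intra > 1 || p_inter < 0 || p_inter > 1)
    stop("edge probabilities must lie in [0, 1]")
  modules <- rep(seq_len(n_modules), length.out = n_neurons)
  modules <- sort(modules)
  with_seed(seed, {
    same <- outer(modules, modules, "==")
    pm <- ifelse(same, p_intra, p_inter)
    adj <- matrix(as.integer(stats::runif(n_neurons^2) < pm),
                  n_neurons, n_neurons)
    diag(adj) <- 0L
    structure(list(adjacency = adj, modules = modules),
              class = "culture_network")
  })
}

#' @export
print.culture_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("Directed culture network: %d nodes, %d edges, %d modules\n",
              n, sum(x$adjacency), length(unique(x$modules))))
  invisible(x)
}
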