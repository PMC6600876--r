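#' @importFrom stats sd setNames
NULL

.weights_of <- function(network) {
  if (inherits(network, "weighted_network")) network$weights else as.matrix(network)
}

# igraph shortest-path distances for a matrix of edge *lengths*
# (0 = no edge); returns Inf for unreachable pairs, 0 on the diagonal.
.length_distances <- function(lengths) {
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  unname(d)
}

#' Node degree
#'
#' Number of nonzero connections per node, `k_i = #\{j : w_ij > 0\}`.
#'
#' @param network a [weighted_network()] or symmetric weight matrix.
#' @return integer vector, one value per region.
#' @export
node_degree <- function(network) {
  w <- .weights_of(network)
  as.integer(rowSums(w > 0))
}

#' Node strength
#'
#' Sum of incident edge weights per node, `s_i = sum_j w_ij`.
#'
#' @inheritParams node_degree
#' @return numeric vector, one value per region.
#' @export
node_strength <- function(network) {
  rowSums(.weights_of(network))
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering using the geometric-mean-of-triangles form
#' with max-weight normalization (the Brain Connectivity Toolbox
#' convention): with normalized weights `u = w / max(w)`,
#' \deqn{C_i = \frac{\sum_{j,h} (u_{ij} u_{ih} u_{jh})^{1/3}}{k_i (k_i - 1)}.}
#' Nodes with degree below 2 have `C_i = 0`; an empty network returns all
#' zeros.
#'
#' @inheritParams node_degree
#' @return numeric vector in `[0, 1]`, one value per region.
#' @export
clustering_weighted <- function(network) {
  w <- .weights_of(network)
  if (any(w < 0)) stop("weights must be nonnegative")
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  u3 <- (w / mx)^(1 / 3)
  cyc <- diag(u3 %*% u3 %*% u3)      # 2 * sum over triangles at i
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, cyc / denom, 0)
  pmin(pmax(out, 0), 1)
}

#' Weighted shortest-path lengths
#'
#' All-pairs shortest-path distances with edge length the reciprocal of
#' the connection weight (`1/w_ij`), so stronger connections are shorter.
#' Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @inheritParams node_degree
#' @param length_transform function mapping positive weights to lengths
#'   (default reciprocal).
#' @return n-by-n numeric matrix of distances.
#' @export
shortest_path_lengths <- function(network, length_transform = function(w) 1 / w) {
  w <- .weights_of(network)
  if (any(w < 0)) stop("weights must be nonnegative")
  lengths <- matrix(0, nrow(w), ncol(w))
  nz <- w > 0
  lengths[nz] <- length_transform(w[nz])
  .length_distances(lengths)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' \deqn{E_{glob} = \frac{1}{n(n-1)} \sum_{i \ne j} 1 / d_{ij},}
#' with `1/Inf = 0` for disconnected pairs. Lies in `[0, 1]` when all
#' weights are in `[0, 1]`.
#'
#' @inheritParams node_degree
#' @return numeric scalar.
#' @export
global_efficiency <- function(network) {
  w <- .weights_of(network)
  n <- nrow(w)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  d <- shortest_path_lengths(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' Efficiency of each node's neighborhood, following the Brain Connectivity
#' Toolbox weighted convention: for node `i` with neighbors `V` and degree
#' `k_i`,
#' \deqn{E_{loc,i} = \frac{1}{k_i(k_i-1)} \sum_{j \ne h \in V}
#'   \left(w_{ij} w_{ih}\right)^{1/3} / d_{jh}(V),}
#' where `d_jh(V)` is the shortest-path distance within the subgraph
#' induced by `V` using edge lengths `(1/w)^{1/3}`. Nodes with fewer than
#' two neighbors score 0. On a unit-weight clique every node scores 1.
#' Weights are expected in `[0, 1]` (FA scale) for the result to stay in
#' `[0, 1]`.
#'
#' @inheritParams node_degree
#' @return numeric vector, one value per region.
#' @export
local_efficiency <- function(network) {
  w <- .weights_of(network)
  if (any(w < 0)) stop("weights must be nonnegative")
  n <- nrow(w)
  out <- numeric(n)
  adj <- w > 0
  for (i in seq_len(n)) {
    v <- which(adj[i, ])
    k <- length(v)
    if (k < 2) next
    sub <- w[v, v, drop = FALSE]
    lens <- matrix(0, k, k)
    nz <- sub > 0
    lens[nz] <- (1 / sub[nz])^(1 / 3)
    d <- .length_distances(lens)
    e <- 1 / d
    diag(e) <- 0
    e[!is.finite(e)] <- 0
    sw <- w[i, v]^(1 / 3)
    out[i] <- sum(outer(sw, sw) * e) / (k * (k - 1))
  }
  out
}

#' Node eccentricity
#'
#' Largest finite shortest-path distance from each node to any other node
#' (reciprocal-weight lengths). Isolated nodes score 0.
#'
#' @inheritParams node_degree
#' @return numeric vector, one value per region.
#' @export
node_eccentricity <- function(network) {
  d <- shortest_path_lengths(network)
  diag(d) <- 0
  apply(d, 1, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0) 0 else max(f)
  })
}

#' Summarize a network's node and global metrics
#'
#' Computes per-node degree, strength, clustering coefficient and local
#' efficiency, and the global summary: arithmetic means of degree,
#' strength and clustering plus global efficiency.
#'
#' @param network a [weighted_network()].
#' @param local whether to compute local efficiency (the most expensive
#'   metric); when `FALSE` the column is omitted.
#' @return list with elements `nodes` (data.frame: region, degree,
#'   strength, clustering, local_efficiency) and `global` (named numeric:
#'   mean_degree, mean_strength, mean_clustering, global_efficiency).
#' @export
summarize_network <- function(network, local = TRUE) {
  w <- .weights_of(network)
  labels <- if (inherits(network, "weighted_network")) {
    network$parcellation$label
  } else {
    rownames(w) %||% paste0("region", seq_len(nrow(w)))
  }
  deg <- node_degree(w)
  str_ <- node_strength(w)
  clu <- clustering_weighted(w)
  nodes <- data.frame(region = labels, degree = deg, strength = str_,
                      clustering = clu, stringsAsFactors = FALSE)
  if (local) nodes$local_efficiency <- local_efficiency(w)
  eg <- if (max(w) > 0) global_efficiency(w) else 0
  list(nodes = nodes,
       global = c(mean_degree = mean(deg), mean_strength = mean(str_),
                  mean_clustering = mean(clu), global_efficiency = eg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
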