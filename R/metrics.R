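# Global and nodal graph topology. Binary networks use hop-count shortest
# paths; weighted networks use 1/w edge lengths (strong edges are short) and
# Onnela's weighted clustering. Conventions for sparse graphs: Lp averages
# over connected ordered pairs only (with a disconnected flag), efficiency
# terms for unreachable pairs are 0, and nodes with < 2 neighbours
# contribute 0 to Cp and Eloc.

net_parts <- function(net) {
  A <- as_adjacency(net)
  if (is.logical(A)) A <- A * 1
  weighted <- if (inherits(net, "imn_network")) net$mode == "weighted"
  else any(A != 0 & A != 1)
  list(A = A, weighted = weighted)
}

# All-pairs shortest-path lengths; Inf where unreachable. Binary graphs use
# a vectorised level-synchronous BFS (far cheaper than building an igraph
# object per call inside the local-efficiency loop); weighted graphs use
# igraph's Dijkstra on 1/w edge lengths.
net_distances <- function(A, weighted) {
  if (!weighted) return(bfs_distances(A))
  g <- as_igraph(A, weighted = TRUE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

bfs_distances <- function(A) {
  n <- nrow(A)
  L <- (A != 0) * 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reached <- diag(n) > 0
  frontier <- reached
  d <- 0
  while (any(frontier)) {
    d <- d + 1
    nxt <- (frontier %*% L > 0) & !reached
    if (!any(nxt)) break
    D[nxt] <- d
    reached <- reached | nxt
    frontier <- nxt
  }
  D
}

#' Clustering coefficient (Cp)
#'
#' Mean local clustering over all nodes: per node, the fraction of realised
#' triangles among its neighbour pairs (binary), or Onnela's geometric-mean
#' weighted generalisation with weights scaled by the network maximum.
#' Nodes of degree < 2 contribute 0.
#'
#' @param net an `imn_network` or adjacency matrix.
#' @return Cp in `[0, 1]` for binary networks.
#' @export
clustering_coefficient <- function(net) {
  p <- net_parts(net)
  if (!p$weighted) {
    B <- (p$A != 0) * 1
    k <- rowSums(B)
    tri <- diag(B %*% B %*% B)        # 2 x triangles at each node
    mean(ifelse(k >= 2, tri / (k * (k - 1)), 0))
  } else {
    W <- (p$A / max(p$A))^(1 / 3)
    k <- rowSums(p$A != 0)
    tri <- diag(W %*% W %*% W)
    ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    mean(ci)
  }
}

#' Characteristic path length (Lp)
#'
#' Mean shortest-path length over all connected ordered node pairs. If the
#' graph is disconnected the mean is taken over reachable pairs only and
#' the result carries `attr(, "disconnected") = TRUE` (with a warning
#' unless `warn = FALSE`), so affected subjects can be flagged rather than
#' producing infinite path lengths.
#'
#' @param net an `imn_network` or adjacency matrix.
#' @param warn warn when the graph is disconnected.
#' @return Lp (>= 1 for binary graphs) with a `disconnected` attribute.
#' @export
characteristic_path_length <- function(net, warn = TRUE) {
  p <- net_parts(net)
  if (all(p$A == 0)) stop("network has no edges")
  D <- net_distances(p$A, p$weighted)
  off <- D[row(D) != col(D)]
  disc <- any(is.infinite(off))
  if (disc && warn) warning("graph is disconnected; Lp over connected pairs")
  res <- mean(off[is.finite(off)])
  attr(res, "disconnected") <- disc
  res
}

#' Global, local and nodal efficiency (Eg, Eloc, Ne)
#'
#' `global_efficiency` is the mean over ordered node pairs of the inverse
#' shortest-path length (0 for unreachable pairs); `nodal_efficiency` of
#' node *i* is the same mean restricted to pairs involving *i*;
#' `local_efficiency` is the mean over nodes of the global efficiency of
#' the subgraph induced by each node's neighbours (0 when a node has fewer
#' than 2 neighbours).
#'
#' @param net an `imn_network` or adjacency matrix.
#' @param node optional node index/indices for `nodal_efficiency`; default
#'   all nodes.
#' @return efficiencies in `[0, 1]` for binary networks.
#' @export
global_efficiency <- function(net) {
  p <- net_parts(net)
  D <- net_distances(p$A, p$weighted)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (nrow(D) * (nrow(D) - 1))
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(net, node = NULL) {
  p <- net_parts(net)
  D <- net_distances(p$A, p$weighted)
  inv <- 1 / D
  diag(inv) <- 0
  ne <- rowSums(inv) / (nrow(D) - 1)
  names(ne) <- rownames(p$A)
  if (is.null(node)) ne else ne[node]
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(net) {
  p <- net_parts(net)
  n <- nrow(p$A)
  el <- vapply(seq_len(n), function(i) {
    nb <- which(p$A[i, ] != 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(structure(
      list(adjacency = p$A[nb, nb, drop = FALSE],
           mode = if (p$weighted) "weighted" else "binary"),
      class = "imn_network"))
  }, numeric(1))
  mean(el)
}

#' Degree and betweenness centrality (Dc, Bc)
#'
#' `degree_centrality` is the number of edges at a node (binary) or the
#' node strength, i.e. summed edge weights (weighted). Betweenness counts,
#' over unordered source-target pairs excluding the node, the fraction of
#' shortest paths passing through it (Brandes algorithm via igraph; 1/w
#' edge lengths in weighted mode).
#'
#' @param net an `imn_network` or adjacency matrix.
#' @param node optional node index/indices; default all nodes.
#' @return numeric vector (or scalar for a single `node`).
#' @export
degree_centrality <- function(net, node = NULL) {
  p <- net_parts(net)
  dc <- if (p$weighted) rowSums(p$A) else rowSums(p$A != 0)
  names(dc) <- rownames(p$A)
  if (is.null(node)) dc else dc[node]
}

#' @rdname degree_centrality
#' @export
betweenness_centrality <- function(net, node = NULL) {
  p <- net_parts(net)
  g <- as_igraph(p$A, weighted = p$weighted)
  w <- if (p$weighted) 1 / igraph::E(g)$weight else NA
  bc <- igraph::betweenness(g, weights = w)
  names(bc) <- rownames(p$A)
  if (is.null(node)) bc else bc[node]
}

#' Small-world indices via degree-preserving null networks
#'
#' Generates `n_null` Maslov-Sneppen rewired networks (degree sequence
#' preserved, `100 * edge_count` attempted edge swaps each) and returns
#' `gamma = Cp / mean(Cp_null)`, `lambda = Lp / mean(Lp_null)` and
#' `sigma = gamma / lambda`. `sigma > 1` (driven by `gamma > 1` at
#' `lambda ~ 1`) is the usual small-world signature. A complete graph
#' cannot be rewired, so its nulls equal the original and all three indices
#' are 1. Weighted networks are rewired on their binary support and weights
#' are not permuted; small-world normalisation is conventionally reported
#' for the binary topology.
#'
#' @param net an `imn_network` or adjacency matrix.
#' @param n_null number of null networks (default 100).
#' @param seed optional integer seed for the rewiring RNG.
#' @return named numeric vector `c(gamma, lambda, sigma)`.
#' @export
small_world <- function(net, n_null = 100L, seed = NULL) {
  p <- net_parts(net)
  if (n_null < 1L) stop("`n_null` must be >= 1")
  g <- as_igraph((p$A != 0) * 1, weighted = FALSE)
  cp <- clustering_coefficient(p$A != 0)
  lp <- as.numeric(characteristic_path_length(p$A * 1, warn = FALSE))
  nulls <- with_seed(seed, {
    replicate(n_null, {
      gr <- igraph::rewire(
        g, igraph::keeping_degseq(loops = FALSE,
                                  niter = 100 * igraph::ecount(g)))
      Ar <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
      c(clustering_coefficient(Ar),
        as.numeric(characteristic_path_length(Ar, warn = FALSE)))
    })
  })
  gamma <- cp / mean(nulls[1L, ])
  lambda <- lp / mean(nulls[2L, ])
  c(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Integrate a metric curve over the sparsity grid
#'
#' The area under the curve (AUC) of a topological attribute evaluated at
#' each sparsity level is its threshold-free composite summary, computed by
#' the trapezoid rule. `NaN` values in the curve propagate with a warning.
#'
#' @param curve attribute values, one per sparsity level.
#' @param grid the sparsity levels (see [sparsity_grid()]).
#' @return the AUC, a single number.
#' @examples
#' auc_over_sparsity(rep(1, 34), sparsity_grid())  # 0.33
#' @export
auc_over_sparsity <- function(curve, grid) trapz(curve, grid)

# Attribute curves across the sparsity grid for one similarity matrix.
# Returns global and nodal curves plus per-level disconnectedness flags.
network_curves <- function(C, grid = sparsity_grid(),
                           mode = c("binary", "weighted"),
                           n_null = 0L, seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(C)
  ns <- length(grid)
  gattrs <- c("Cp", "Lp", "Eg", "Eloc", "gamma", "lambda", "sigma")
  global <- matrix(NA_real_, ns, length(gattrs),
                   dimnames = list(NULL, gattrs))
  nodal <- lapply(c(Ne = 1, Dc = 1, Bc = 1), function(.)
    matrix(NA_real_, ns, n, dimnames = list(NULL, rownames(C))))
  disconnected <- logical(ns)
  for (s in seq_len(ns)) {
    net <- threshold_network(C, grid[s], mode)
    p <- net_parts(net)
    D <- net_distances(p$A, p$weighted)
    off <- D[row(D) != col(D)]
    disconnected[s] <- any(is.infinite(off))
    inv <- 1 / D
    diag(inv) <- 0
    global[s, "Cp"] <- clustering_coefficient(net)
    global[s, "Lp"] <- mean(off[is.finite(off)])
    global[s, "Eg"] <- sum(inv) / (n * (n - 1))
    global[s, "Eloc"] <- local_efficiency(net)
    if (n_null > 0L) {
      sw <- small_world(net, n_null = n_null,
                        seed = if (is.null(seed)) NULL else mix_seed(seed, s))
      global[s, c("gamma", "lambda", "sigma")] <- sw
    }
    nodal$Ne[s, ] <- rowSums(inv) / (n - 1)
    nodal$Dc[s, ] <- degree_centrality(net)
    nodal$Bc[s, ] <- betweenness_centrality(net)
  }
  list(grid = grid, global = global, nodal = nodal,
       disconnected = disconnected)
}
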