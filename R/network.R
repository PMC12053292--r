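#' Sparsity grid for network thresholding
#'
#' The default analysis grid runs from 0.063 in steps of 0.01 up to (but not
#' reaching) 0.4, i.e. 34 levels ending at 0.393; this range keeps networks
#' sparse enough for small-world estimation while dense enough to stay
#' connected at the upper end. Because 0.063 + k*0.01 never equals 0.4
#' exactly, `include_endpoint = TRUE` appends 0.4 as a 35th level.
#'
#' @param from,to,by grid limits and step.
#' @param include_endpoint append `to` if the arithmetic grid stops short
#'   of it.
#' @return numeric vector of strictly increasing sparsity levels in (0, 0.5].
#' @examples
#' g <- sparsity_grid()
#' length(g)  # 34
#' @export
sparsity_grid <- function(from = 0.063, to = 0.4, by = 0.01,
                          include_endpoint = FALSE) {
  if (from <= 0 || to > 0.5 || by <= 0 || from > to)
    stop("grid must satisfy 0 < from <= to <= 0.5, by > 0")
  k <- floor((to - from) / by + 1e-9)
  g <- from + by * (0:k)
  if (include_endpoint && g[length(g)] < to - 1e-12) g <- c(g, to)
  g
}

#' Threshold a similarity matrix into a binary or weighted network
#'
#' Ranks the `n(n-1)/2` upper-triangle similarities in decreasing order and
#' retains exactly `E = round(S * n(n-1)/2)` edges (round half away from
#' zero), so every subject's network has the identical number of nodes and
#' edges at a given sparsity `S`. The realised KLS threshold is the smallest
#' retained similarity. Ties at the threshold are broken by ascending
#' `(i, j)` lexicographic order for reproducibility. Binary mode sets
#' retained entries to 1; weighted mode keeps the KLS values.
#'
#' @param C symmetric similarity matrix (e.g. from [similarity_matrix()]);
#'   the diagonal is ignored.
#' @param S target sparsity in (0, 1).
#' @param mode `"binary"` or `"weighted"`.
#' @return an object of class `"imn_network"`: list with `adjacency`
#'   (symmetric, zero diagonal), `mode`, `sparsity`, `kls_threshold` and
#'   `edge_count`.
#' @examples
#' C <- similarity_matrix(replicate(6, rnorm(50, 2, .3), simplify = FALSE))
#' net <- threshold_network(C, 0.2)
#' net$edge_count  # round(0.2 * 15) = 3
#' @export
threshold_network <- function(C, S, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  C <- unclass(C)
  n <- nrow(C)
  if (n < 3L || max(abs(C - t(C))) > 1e-12 * max(1, max(abs(C))))
    stop("`C` must be a symmetric matrix with n >= 3")
  if (S <= 0 || S >= 1) stop("sparsity must lie in (0, 1)")
  m <- n * (n - 1) / 2
  E <- as.integer(round_half_up(S * m))
  if (E < 1L || E > m)
    stop("edge count ", E, " outside [1, ", m, "] at sparsity ", S)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  w <- C[upper.tri(C)]
  keep <- order(-w, ut[, 1L], ut[, 2L])[seq_len(E)]
  A <- matrix(0, n, n, dimnames = dimnames(C))
  vals <- if (mode == "binary") rep(1, E) else w[keep]
  A[ut[keep, , drop = FALSE]] <- vals
  A <- A + t(A)
  structure(list(adjacency = A, mode = mode, sparsity = S,
                 kls_threshold = min(w[keep]), edge_count = E),
            class = "imn_network")
}

#' @export
print.imn_network <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges (S = %.3f, KLS_thr = %.4f)\n",
              x$mode, nrow(x$adjacency), x$edge_count, x$sparsity,
              x$kls_threshold))
  invisible(x)
}

# Coerce an imn_network or a plain adjacency matrix to adjacency.
as_adjacency <- function(net) {
  if (inherits(net, "imn_network")) net$adjacency
  else if (is.matrix(net)) net
  else stop("expected an `imn_network` or an adjacency matrix")
}

# igraph object from a symmetric adjacency matrix via its upper-triangle
# edge list (skips graph_from_adjacency_matrix's symmetry re-check, which
# dominates run time when thousands of small graphs are built)
as_igraph <- function(net, weighted = NULL) {
  A <- as_adjacency(net)
  if (is.null(weighted))
    weighted <- if (inherits(net, "imn_network")) net$mode == "weighted"
  else any(A != 0 & A != 1)
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(nrow(A), directed = FALSE)
  g <- igraph::add_edges(g, t(ut))
  if (weighted) igraph::E(g)$weight <- A[ut]
  g
}
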