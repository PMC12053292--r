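# Independent brute-force oracles for graph topology (Floyd-Warshall
# distances, combinatorial shortest-path counting, triangle enumeration)
# and closed forms for Gaussian Kullback-Leibler divergence. Deliberately
# naive and igraph-free so they can arbitrate the package implementation.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# number of shortest paths from s to every node, from the distance matrix
oracle_sigma_from <- function(A, D, s) {
  n <- nrow(A)
  sig <- numeric(n)
  sig[s] <- 1
  for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
    for (v in which(D[s, ] == d)) {
      pred <- which(A[, v] > 0 & D[s, ] == d - 1)
      sig[v] <- sum(sig[pred])
    }
  }
  sig
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sig <- t(sapply(seq_len(n), function(s) oracle_sigma_from(A, D, s)))
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  bc
}

oracle_global_metrics <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  inv <- 1 / D
  diag(inv) <- 0
  cp <- mean(sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) links <- links + 1
    links / (k * (k - 1) / 2)
  }))
  eloc <- mean(sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    S <- A[nb, nb, drop = FALSE]
    Ds <- oracle_distances(S)
    invs <- 1 / Ds
    diag(invs) <- 0
    sum(invs) / (nrow(S) * (nrow(S) - 1))
  }))
  list(Cp = cp,
       Lp = mean(off[is.finite(off)]),
       Eg = sum(inv) / (n * (n - 1)),
       Eloc = eloc,
       Ne = rowSums(inv) / (n - 1),
       Dc = rowSums(A > 0),
       Bc = oracle_betweenness(A))
}

random_adjacency <- function(n, p = 0.4, min_edges = 1) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(runif(length(up)) < p)
    A <- A + t(A)
    if (sum(A) / 2 >= min_edges) return(A)
  }
}

# symmetric KL divergence between N(m1, s1^2) and N(m2, s2^2), closed form
gaussian_sym_kl <- function(m1, s1, m2, s2) {
  kl <- function(ma, sa, mb, sb)
    log(sb / sa) + (sa^2 + (ma - mb)^2) / (2 * sb^2) - 0.5
  kl(m1, s1, m2, s2) + kl(m2, s2, m1, s1)
}

# canonical test graphs
star_graph <- function(n = 5) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  A
}
complete_graph <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}
path_graph <- function(n = 3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}
ring_lattice <- function(n = 60, k = 6) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  A
}
watts_strogatz <- function(n = 60, k = 6, p = 0.05) {
  A <- ring_lattice(n, k)
  up <- which(upper.tri(A) & A == 1)
  for (e in up) {
    if (runif(1) < p) {
      i <- row(A)[e]
      free <- which(A[i, ] == 0 & seq_len(n) != i)
      if (length(free)) {
        j <- if (length(free) == 1) free else sample(free, 1)
        A[e] <- A[col(A)[e], i] <- 0
        A[i, j] <- A[j, i] <- 1
      }
    }
  }
  A
}

# tiny cohort spec used across tests: small regions/vertices keep KDE cost low
tiny_spec <- function(seed, n_per_cell = 4, n_regions = 8, metrics = "FD",
                      effects = list(), ...) {
  cohort_spec(n_per_cell = n_per_cell, groups = "PD-pRBD",
              sexes = c("M", "F"), n_regions = n_regions,
              vertices_per_region = c(30, 50), metrics = metrics,
              effects = effects, seed = seed, ...)
}
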