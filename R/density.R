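#' Gaussian kernel density estimate on an explicit grid
#'
#' Estimates the probability density function of a vector of vertex-wise
#' cortical values with a Gaussian kernel, evaluated exactly (no binning) on
#' a uniform grid spanning `[min(x) - 3h, max(x) + 3h]`, and renormalised so
#' its trapezoidal integral is 1. The bandwidth `h` defaults to Silverman's
#' rule of thumb ([stats::bw.nrd0()]).
#'
#' @param values numeric vector of at least 10 finite observations.
#' @param grid_size number of evaluation points (default 256).
#' @param bandwidth_rule `"silverman"` (the default, via [stats::bw.nrd0()])
#'   or `"sj"` (Sheather-Jones, via [stats::bw.SJ()]).
#' @param grid optional explicit evaluation grid (strictly increasing);
#'   overrides `grid_size` and the automatic support.
#' @param floor density floor, expressed relative to the density peak,
#'   applied before renormalisation; prevents `log(0)` in later divergence
#'   computations while keeping similarities invariant to affine rescaling
#'   of the data. Default `1e-10`.
#' @return an object of class `"imn_density"`: a list with elements `grid`,
#'   `density` and `bandwidth`.
#' @seealso [symmetric_kld()], [similarity_matrix()]
#' @examples
#' d <- estimate_density(rnorm(500))
#' trapz(d$density, d$grid)  # ~1
#' @export
estimate_density <- function(values, grid_size = 256L,
                             bandwidth_rule = c("silverman", "sj"),
                             grid = NULL, floor = 1e-10) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  values <- as.numeric(values)
  if (length(values) < 10L || !all(is.finite(values)))
    stop("need >= 10 finite values")
  if (stats::var(values) == 0)
    stop("all values identical: bandwidth degenerates to zero; ",
         "add minimal jitter or supply a wider grid")
  h <- switch(bandwidth_rule,
              silverman = stats::bw.nrd0(values),
              sj = stats::bw.SJ(values))
  if (!is.finite(h) || h <= 0)
    stop("bandwidth is zero; add minimal jitter or supply a wider grid")
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h,
                length.out = as.integer(grid_size))
  } else {
    if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  }
  dens <- kde_eval(values, h, grid)
  dens <- pmax(dens, floor * max(dens))
  dens <- dens / trapz(dens, grid)
  structure(list(grid = grid, density = dens, bandwidth = h),
            class = "imn_density")
}

# Exact Gaussian KDE evaluation: mean of kernels centred at each datum,
# written out as exp(-z^2/2) to keep the per-pair loop cheap. Chunked over
# the grid to bound memory for large samples.
kde_eval <- function(x, h, grid) {
  n <- length(x)
  const <- n * h * sqrt(2 * pi)
  out <- numeric(length(grid))
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, length(grid), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(grid))
    z <- outer(grid[idx], x, "-") / h
    out[idx] <- .rowSums(exp(-0.5 * z * z), length(idx), n) / const
  }
  out
}

#' Symmetric Kullback-Leibler divergence between two density estimates
#'
#' Computes `KL(P||Q) + KL(Q||P)` by trapezoidal integration over the common
#' evaluation grid. Both densities must have been estimated on the same grid
#' (see [similarity_matrix()] for the per-pair common-grid construction) and
#' floored away from zero.
#'
#' @param p,q objects of class `"imn_density"` (or lists with `grid` and
#'   `density`) sharing one grid.
#' @return a non-negative number; 0 if and only if the densities are
#'   pointwise identical.
#' @examples
#' x <- rnorm(1000); d <- estimate_density(x)
#' symmetric_kld(d, d)  # 0
#' @export
symmetric_kld <- function(p, q) {
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-12)
    stop("density estimates are not on a common grid")
  fp <- p$density
  fq <- q$density
  if (any(fp <= 0) || any(fq <= 0))
    stop("densities must be floored strictly above zero")
  trapz(fp * log(fp / fq), p$grid) + trapz(fq * log(fq / fp), q$grid)
}

#' KLD-based similarity (KLS)
#'
#' Maps a non-negative symmetric Kullback-Leibler divergence onto the
#' similarity scale `(0, 1]` by `exp(-kld)`: identical distributions score
#' 1, and similarity decreases strictly as divergence grows.
#'
#' @param kld_value non-negative numeric (vectorised).
#' @return similarity value(s) in `(0, 1]`.
#' @examples
#' kls(0)    # 1
#' kls(1)    # exp(-1)
#' @export
kls <- function(kld_value) {
  if (anyNA(kld_value) || any(kld_value < 0))
    stop("`kld_value` must be non-negative")
  exp(-kld_value)
}

#' Build a subject's KLS similarity matrix
#'
#' For one subject and one cortical metric, estimates the density of every
#' region's vertex values and fills the symmetric matrix `C = [c_ij]` where
#' `c_ij = exp(-(KL(P_i||P_j) + KL(P_j||P_i)))`. For each unordered region
#' pair the two densities are evaluated on one shared uniform grid spanning
#' `[min(both) - 3*h_max, max(both) + 3*h_max]`, where `h_max` is the larger
#' of the two Silverman bandwidths, so the divergence integrals share
#' support. The diagonal is set to 1 and is excluded from edge selection by
#' [threshold_network()].
#'
#' @param x either a named list of numeric vectors (one per region, in
#'   region order) or a long data frame with columns `region_id` and `value`
#'   (e.g. one subject/metric slice of a vertex table).
#' @param grid_size points in each pair's common grid (default 256).
#' @param bandwidth_rule passed to [estimate_density()].
#' @param floor density floor relative to each density's peak (default
#'   `1e-10`).
#' @param labels optional region labels for dimnames; defaults to names of
#'   `x` or `region_label` column.
#' @return a symmetric numeric matrix of class `"imn_similarity"` with unit
#'   diagonal and entries in `(0, 1]`.
#' @examples
#' vals <- replicate(5, rnorm(60, mean = 2.5, sd = 0.3), simplify = FALSE)
#' C <- similarity_matrix(vals)
#' all(C == t(C))
#' @export
similarity_matrix <- function(x, grid_size = 256L,
                              bandwidth_rule = c("silverman", "sj"),
                              floor = 1e-10, labels = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  vals <- as_region_values(x)
  if (is.null(labels)) labels <- names(vals)
  n <- length(vals)
  if (n < 3L) stop("need at least 3 regions")
  bw_fun <- switch(bandwidth_rule, silverman = stats::bw.nrd0,
                   sj = stats::bw.SJ)
  h <- vapply(vals, function(v) {
    if (length(v) < 10L || !all(is.finite(v)))
      stop("every region needs >= 10 finite values")
    if (stats::var(v) == 0) return(0)
    bw_fun(v)
  }, numeric(1))
  if (any(h <= 0))
    stop("bandwidth is zero for region(s) ",
         paste(which(h <= 0), collapse = ", "),
         " (all values identical?); add minimal jitter")
  rng <- vapply(vals, range, numeric(2))
  C <- diag(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hm <- max(h[i], h[j])
      lo <- min(rng[1L, i], rng[1L, j]) - 3 * hm
      hi <- max(rng[2L, i], rng[2L, j]) + 3 * hm
      grid <- seq(lo, hi, length.out = as.integer(grid_size))
      dx <- grid[2L] - grid[1L]
      fi <- floor_norm(kde_eval(vals[[i]], h[i], grid), floor, dx)
      fj <- floor_norm(kde_eval(vals[[j]], h[j], grid), floor, dx)
      kld <- uni_trapz(fi * log(fi / fj), dx) + uni_trapz(fj * log(fj / fi), dx)
      C[i, j] <- C[j, i] <- exp(-max(kld, 0))
    }
  }
  dimnames(C) <- list(labels, labels)
  class(C) <- c("imn_similarity", class(C))
  C
}

# uniform-grid trapezoid and floor+renormalise fast paths for the pair loop.
# The floor is relative to the density peak, which keeps the divergence
# exactly invariant under common affine rescaling of the data.
uni_trapz <- function(f, dx) dx * (sum(f) - (f[1L] + f[length(f)]) / 2)
floor_norm <- function(f, floor, dx) {
  f <- pmax(f, floor * max(f))
  f / uni_trapz(f, dx)
}

# Accepts a named list of vectors or a long data frame slice.
as_region_values <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("region_id", "value") %in% names(x)))
      stop("data frame input needs columns `region_id` and `value`")
    ids <- sort(unique(x$region_id))
    if (!identical(as.integer(ids), seq_along(ids)))
      stop("region ids must form a complete 1..n set; missing: ",
           paste(setdiff(seq_len(max(ids)), ids), collapse = ", "))
    labs <- if ("region_label" %in% names(x)) {
      vapply(ids, function(i) as.character(x$region_label[x$region_id == i][1L]),
             character(1))
    } else paste0("R", ids)
    out <- lapply(ids, function(i) as.numeric(x$value[x$region_id == i]))
    names(out) <- labs
    out
  } else if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("R", seq_along(x))
    x
  } else stop("`x` must be a data frame or a list of numeric vectors")
}

#' @export
print.imn_similarity <- function(x, ...) {
  cat("KLS similarity matrix:", nrow(x), "regions\n")
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal range [%.4f, %.4f], median %.4f\n",
              min(off), max(off), stats::median(off)))
  invisible(x)
}
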