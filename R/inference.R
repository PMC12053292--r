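# Covariate-adjusted permutation inference on AUC attributes, BH-FDR over
# nodes, and Pearson correlations with clinical scores. The scheme is
# residualise-then-permute: AUC values are replaced by residuals of an OLS
# fit on the covariates (pooled across both cells, intercept included), and
# cell labels are then permuted.

#' Residualise AUC values on covariates
#'
#' Replaces each column of `x` by the residuals of an ordinary
#' least-squares fit on the covariates (with intercept), pooled across all
#' rows. Residuals have mean zero and are orthogonal to every covariate.
#'
#' @param x numeric vector or matrix (rows = subjects, columns = e.g.
#'   nodes).
#' @param covariates data frame or matrix of numeric covariates (rows
#'   aligned with `x`); `NULL` or zero columns returns centred values.
#' @return adjusted values with the same shape as `x`.
#' @examples
#' adjust_covariates(1:10, data.frame(age = rep(50, 10)))  # centred
#' @export
adjust_covariates <- function(x, covariates = NULL) {
  v <- is.null(dim(x))
  X <- if (v) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    res <- scale(X, scale = FALSE)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    if (!all(is.finite(Z))) stop("covariates must be finite and complete")
    if (nrow(Z) != nrow(X)) stop("covariate rows do not match values")
    # drop constant covariates (absorbed by the intercept)
    keep <- apply(Z, 2L, function(z) stats::var(z) > 0)
    Z <- Z[, keep, drop = FALSE]
    M <- cbind(Intercept = 1, Z)
    q <- qr(M)
    if (q$rank < ncol(M)) {
      bad <- colnames(M)[-seq_len(q$rank)]
      stop("collinear covariate design; offending column(s): ",
           paste(bad, collapse = ", "))
    }
    res <- stats::lm.fit(M, X)$residuals
  }
  res <- unname(res)
  if (v) drop(res) else res
}

#' Two-sample permutation test on adjusted values
#'
#' Observed statistic is `mean(a) - mean(b)`. Cell labels are shuffled
#' `n_perm` times and the two-tailed p-value is
#' `(1 + #{|perm stat| >= |observed|}) / (n_perm + 1)`, which is strictly
#' positive and valid at the nominal level.
#'
#' @param a,b numeric vectors (the two cells' adjusted values), each of
#'   length >= 2.
#' @param n_perm number of label permutations (the reference analysis uses
#'   10000).
#' @param seed integer seed for the shuffles.
#' @return a list with `observed`, `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = NULL) {
  if (length(a) < 2L || length(b) < 2L) stop("each cell needs >= 2 values")
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  obs <- mean(a) - mean(b)
  perm <- perm_stats(cbind(c(a, b)), length(a), n_perm, seed)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p, n_perm = as.integer(n_perm), seed = seed)
}

# Shared-shuffle permutation null: X is (n_a + n_b) x k; returns an
# n_perm x k matrix of mean differences under label permutation. The same
# shuffles apply to every column, preserving cross-node dependence.
perm_stats <- function(X, n_a, n_perm, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_b <- n - n_a
  tot <- colSums(X)
  with_seed(seed, {
    out <- matrix(0, n_perm, ncol(X))
    for (i in seq_len(n_perm)) {
      ia <- sample.int(n, n_a)
      sa <- colSums(X[ia, , drop = FALSE])
      out[i, ] <- sa / n_a - (tot - sa) / n_b
    }
    out
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over one family of node-level
#' p-values (thin wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p p-values in (0, 1].
#' @return q-values, clipped at 1, monotone in p-rank.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_bh <- function(p) {
  if (any(p <= 0 | p > 1 | !is.finite(p))) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with a two-tailed p-value
#'
#' Sample correlation with significance from the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return a list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need n >= 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one of the inputs")
  r <- stats::cor(x, y)
  list(r = r, p = pearson_p_from_r(r, length(x)), n = length(x))
}

#' @rdname pearson_with_p
#' @param r a correlation coefficient.
#' @param n the sample size it was computed from.
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3L) stop("need n >= 3")
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Compare network attributes between two cohort cells
#'
#' For every (metric, attribute) the AUC values of the two cells are pooled,
#' residualised on the covariates, and compared with a two-sample
#' permutation test. Node-level attributes (Ne, Dc, Bc) share one set of
#' label shuffles across nodes and receive Benjamini-Hochberg FDR
#' correction across the regions within each (metric, attribute) family;
#' global attributes are reported with raw permutation p-values.
#'
#' @param cohort an `"imn_cohort"` fit with a clinical table.
#' @param group restrict the contrast to this group (e.g. `"PD-pRBD"`);
#'   `NULL` uses all subjects.
#' @param between clinical column defining the cells (default `"sex"`).
#' @param a,b the two cell labels (cell `a` minus cell `b`).
#' @param metrics,attributes subsets to test (default: everything fitted).
#' @param covariates clinical columns to residualise on (default age,
#'   education, LEDD).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed; fixed seed gives identical p-values.
#' @return an object of class `"imn_contrast"`: list with `results` (data
#'   frame: metric, attribute, node, observed, p, q), `contrast`, `n_a`,
#'   `n_b`, `n_perm`, `seed`.
#' @export
imn_compare <- function(cohort, group = NULL, between = "sex", a = "M",
                        b = "F", metrics = NULL, attributes = NULL,
                        covariates = c("age", "education", "LEDD"),
                        n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(cohort, "imn_cohort"))
  clin <- cohort$clinical
  if (is.null(clin)) stop("cohort has no clinical table")
  if (!is.null(group)) clin <- clin[clin$group == group, , drop = FALSE]
  sub_a <- clin$subject[clin[[between]] == a]
  sub_b <- clin$subject[clin[[between]] == b]
  if (length(sub_a) < 2L || length(sub_b) < 2L)
    stop("cell ", if (length(sub_a) < 2L) a else b,
         " has fewer than 2 subjects")
  subjects <- c(sub_a, sub_b)
  n_a <- length(sub_a)
  covs <- if (length(covariates))
    clin[match(subjects, clin$subject), covariates, drop = FALSE] else NULL
  metrics <- metrics %||% unique(cohort$auc$metric)
  attributes <- attributes %||% unique(cohort$auc$attribute)
  rows <- list()
  k <- 0L
  for (m in metrics) {
    for (att in intersect(attributes, unique(
      cohort$auc$attribute[cohort$auc$metric == m]))) {
      V <- auc_values(cohort, m, att, subjects)
      k <- k + 1L
      sd_k <- if (is.null(seed)) NULL else mix_seed(seed, k)
      if (is.null(dim(V))) {                    # global attribute
        if (anyNA(V)) next
        adj <- adjust_covariates(V, covs)
        pt <- permutation_test(adj[seq_len(n_a)], adj[-seq_len(n_a)],
                               n_perm = n_perm, seed = sd_k)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, attribute = att, node = NA_character_,
          observed = pt$observed, p = pt$p, q = NA_real_,
          stringsAsFactors = FALSE)
      } else {                                  # nodal attribute
        adj <- adjust_covariates(V, covs)
        obs <- colMeans(adj[seq_len(n_a), , drop = FALSE]) -
          colMeans(adj[-seq_len(n_a), , drop = FALSE])
        perm <- perm_stats(adj, n_a, n_perm, sd_k)
        p <- (1 + colSums(abs(perm) >= rep(abs(obs), each = n_perm))) /
          (n_perm + 1)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, attribute = att, node = colnames(V),
          observed = unname(obs), p = unname(p), q = unname(fdr_bh(p)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 contrast = list(group = group, between = between,
                                 a = a, b = b, covariates = covariates),
                 n_a = n_a, n_b = length(sub_b),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "imn_contrast")
}

#' @export
print.imn_contrast <- function(x, alpha = 0.05, ...) {
  ct <- x$contrast
  cat(sprintf("Permutation contrast: %s vs %s (%s)%s, n = %d/%d, %d perms\n",
              ct$a, ct$b, ct$between,
              if (!is.null(ct$group)) paste0(" within ", ct$group) else "",
              x$n_a, x$n_b, x$n_perm))
  r <- x$results
  gl <- r[is.na(r$node), c("metric", "attribute", "observed", "p")]
  cat("\nGlobal attributes:\n")
  print(gl, row.names = FALSE, digits = 4)
  nd <- r[!is.na(r$node) & r$q < alpha, , drop = FALSE]
  cat(sprintf("\nNodal attributes with q < %.2f: %d of %d tests\n",
              alpha, nrow(nd), sum(!is.na(r$node))))
  if (nrow(nd)) print(nd, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.imn_contrast <- function(object, ...) print(object, ...)

#' Correlate network attributes with a clinical score
#'
#' Pearson correlation (with two-tailed t-based p-values) between each
#' global attribute's AUC and a clinical score, computed separately within
#' each (group, sex) cell, mirroring within-cell clinical correlation
#' analyses at the 0.05 level (uncorrected).
#'
#' @param cohort an `"imn_cohort"` fit with a clinical table.
#' @param score clinical column to correlate against.
#' @param metrics,attributes subsets (default: all fitted global
#'   attributes).
#' @param groups,sexes cells to analyse (default: all present).
#' @return data frame: group, sex, metric, attribute, score, r, p, n.
#' @export
imn_correlate <- function(cohort, score, metrics = NULL, attributes = NULL,
                          groups = NULL, sexes = NULL) {
  stopifnot(inherits(cohort, "imn_cohort"))
  clin <- cohort$clinical
  if (is.null(clin) || !score %in% names(clin))
    stop("clinical table lacks score column `", score, "`")
  metrics <- metrics %||% unique(cohort$auc$metric)
  glb <- unique(cohort$auc$attribute[is.na(cohort$auc$node)])
  attributes <- attributes %||% glb
  groups <- groups %||% unique(clin$group)
  sexes <- sexes %||% unique(clin$sex)
  rows <- list()
  for (g in groups) for (sx in sexes) {
    subs <- clin$subject[clin$group == g & clin$sex == sx]
    if (length(subs) < 3L) next
    y <- clin[[score]][match(subs, clin$subject)]
    for (m in metrics) for (att in intersect(attributes, glb)) {
      v <- auc_values(cohort, m, att, subs)
      if (anyNA(v) || stats::var(v) == 0 || stats::var(y) == 0) next
      pr <- pearson_with_p(v, y)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, sex = sx, metric = m, attribute = att, score = score,
        r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
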