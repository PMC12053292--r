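#' Fit an individual morphological network
#'
#' The central model fit of the package: from one subject's vertex-wise
#' values for one cortical metric it (1) builds the KLS similarity matrix
#' ([similarity_matrix()]), (2) thresholds it to binary or weighted
#' networks at every level of the sparsity grid ([threshold_network()]),
#' (3) evaluates global (Cp, Lp, Eg, Eloc and, when `n_null > 0`, gamma,
#' lambda, sigma) and nodal (Ne, Dc, Bc) attributes at each level, and (4)
#' integrates each attribute curve over the grid into its AUC summary
#' ([auc_over_sparsity()]).
#'
#' @param x one subject's data: a long data frame with columns `region_id`
#'   and `value` (and optionally `metric`, filtered by the `metric`
#'   argument), a named list of per-region numeric vectors, or a
#'   precomputed `"imn_similarity"` matrix.
#' @param metric metric name used to slice a multi-metric data frame (and
#'   recorded in the fit).
#' @param sparsity sparsity grid, default [sparsity_grid()].
#' @param mode `"binary"` (default) or `"weighted"` network construction.
#' @param n_null null networks per sparsity level for the normalised
#'   small-world indices (default 100; set 0 to skip gamma/lambda/sigma).
#' @param seed seed for the null-model rewiring RNG.
#' @param grid_size,bandwidth_rule KDE settings, see [similarity_matrix()].
#' @param subject optional subject identifier stored in the fit.
#' @return an object of class `"imn"` with components `similarity`, `grid`,
#'   `curves` (global attribute matrix), `nodal` (list of node-level curve
#'   matrices), `auc_global`, `auc_nodal`, `disconnected` (per-level flag),
#'   `mode`, `labels`.
#' @examples
#' vals <- replicate(8, rnorm(60, 2.5, 0.3), simplify = FALSE)
#' fit <- imn(vals, sparsity = sparsity_grid(0.2, 0.4, 0.05), n_null = 0)
#' coef(fit)
#' @export
imn <- function(x, metric = NULL, sparsity = sparsity_grid(),
                mode = c("binary", "weighted"), n_null = 100L, seed = NULL,
                grid_size = 256L, bandwidth_rule = "silverman",
                subject = NULL) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(x, "imn_similarity")) {
    C <- x
  } else {
    if (is.data.frame(x)) {
      if (!is.null(metric) && "metric" %in% names(x))
        x <- x[x$metric == metric, , drop = FALSE]
      if (is.null(subject) && "subject" %in% names(x) &&
          length(unique(x$subject)) == 1L)
        subject <- x$subject[1L]
      if (is.data.frame(x) && "subject" %in% names(x) &&
          length(unique(x$subject)) > 1L)
        stop("`x` contains several subjects; fit one at a time ",
             "or use imn_cohort()")
    }
    C <- similarity_matrix(x, grid_size = grid_size,
                           bandwidth_rule = bandwidth_rule)
  }
  cv <- network_curves(C, grid = sparsity, mode = mode,
                       n_null = n_null, seed = seed)
  auc_global <- apply(cv$global, 2L, function(y)
    if (anyNA(y)) NA_real_ else trapz(y, sparsity))
  auc_nodal <- do.call(rbind, lapply(cv$nodal, function(M)
    apply(M, 2L, trapz, x = sparsity)))
  structure(list(similarity = C, grid = sparsity, curves = cv$global,
                 nodal = cv$nodal, auc_global = as.list(auc_global),
                 auc_nodal = auc_nodal, disconnected = cv$disconnected,
                 mode = mode, n_null = n_null, labels = rownames(C),
                 subject = subject, metric = metric, call = cl),
            class = "imn")
}

#' @export
print.imn <- function(x, ...) {
  cat("Individual morphological network",
      if (!is.null(x$subject)) paste0("(", x$subject,
                                      if (!is.null(x$metric))
                                        paste0(", ", x$metric), ")"),
      "\n")
  cat(sprintf("  %d regions, %s networks over %d sparsity levels [%.3f, %.3f]\n",
              length(x$labels), x$mode, length(x$grid), min(x$grid),
              max(x$grid)))
  ag <- unlist(x$auc_global)
  ag <- ag[!is.na(ag)]
  cat("  global AUCs:",
      paste(sprintf("%s=%.3f", names(ag), ag), collapse = ", "), "\n")
  if (any(x$disconnected))
    cat("  note:", sum(x$disconnected),
        "sparsity level(s) gave a disconnected graph\n")
  invisible(x)
}

#' @export
summary.imn <- function(object, ...) {
  print(object)
  cat("\nNodal AUC summary (per attribute, across regions):\n")
  print(t(apply(object$auc_nodal, 1L, summary)))
  invisible(object)
}

#' @export
coef.imn <- function(object, which = c("global", "nodal"), ...) {
  which <- match.arg(which)
  if (which == "global") unlist(object$auc_global) else object$auc_nodal
}

#' @export
as.matrix.imn <- function(x, ...) unclass(x$similarity)

#' Plot attribute curves across sparsity
#'
#' Draws each global attribute's value against the sparsity grid, the
#' curves whose areas form the AUC summaries.
#'
#' @param x an `"imn"` fit.
#' @param attributes which global attributes to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.imn <- function(x, attributes = c("Cp", "Lp", "Eg", "Eloc"), ...) {
  Y <- x$curves[, attributes, drop = FALSE]
  graphics::matplot(x$grid, Y, type = "l", lty = 1, lwd = 2,
                    xlab = "sparsity S", ylab = "attribute value", ...)
  graphics::legend("topright", legend = colnames(Y), lty = 1, lwd = 2,
                   col = seq_len(ncol(Y)), bty = "n")
  invisible(x)
}

#' Fit individual networks for every subject in a cohort
#'
#' Applies [imn()] to each (subject, metric) slice of a vertex table and
#' collects the AUC summaries into one tidy table ready for group
#' inference ([imn_compare()]) and clinical correlation
#' ([imn_correlate()]).
#'
#' @param x a `"cohort"` from [generate_cohort()], or a long vertex data
#'   frame with columns `subject`, `region_id`, `metric`, `value`.
#' @param clinical clinical table (one row per subject); taken from the
#'   cohort object when `x` is one.
#' @param metrics metrics to fit (default: all present).
#' @param sparsity,mode,n_null,seed,grid_size passed to [imn()]; null-model
#'   seeds are derived per subject from `seed`.
#' @param keep_similarity also return the per-(subject, metric) KLS
#'   matrices (as `$similarity`, named `subject.metric`).
#' @return an object of class `"imn_cohort"`: list with `auc` (long data
#'   frame: subject, metric, attribute, node, auc), `clinical`, `grid`,
#'   `mode`, `labels`, `disconnected` (per subject/metric any-level flag).
#' @export
imn_cohort <- function(x, clinical = NULL, metrics = NULL,
                       sparsity = sparsity_grid(),
                       mode = c("binary", "weighted"), n_null = 100L,
                       seed = NULL, grid_size = 256L,
                       keep_similarity = FALSE) {
  mode <- match.arg(mode)
  if (inherits(x, "cohort")) {
    clinical <- clinical %||% x$clinical
    x <- x$vertex
  }
  need <- c("subject", "region_id", "metric", "value")
  if (!all(need %in% names(x)))
    stop("vertex table needs columns ", paste(need, collapse = ", "))
  metrics <- metrics %||% unique(x$metric)
  subjects <- unique(x$subject)
  rows <- list()
  disc <- list()
  sims <- if (keep_similarity) list() else NULL
  labels <- NULL
  for (m in metrics) {
    xm <- x[x$metric == m, , drop = FALSE]
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      fit <- imn(xm[xm$subject == s, , drop = FALSE], metric = m,
                 sparsity = sparsity, mode = mode, n_null = n_null,
                 seed = if (is.null(seed)) NULL else mix_seed(seed, si),
                 grid_size = grid_size, subject = s)
      labels <- fit$labels
      ag <- unlist(fit$auc_global)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, metric = m, attribute = names(ag), node = NA_character_,
        auc = unname(ag), stringsAsFactors = FALSE)
      an <- fit$auc_nodal
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, metric = m,
        attribute = rep(rownames(an), times = ncol(an)),
        node = rep(colnames(an), each = nrow(an)),
        auc = as.vector(an), stringsAsFactors = FALSE)
      disc[[length(disc) + 1L]] <- data.frame(
        subject = s, metric = m, disconnected = any(fit$disconnected),
        stringsAsFactors = FALSE)
      if (keep_similarity) sims[[paste(s, m, sep = ".")]] <- fit$similarity
    }
  }
  structure(list(auc = do.call(rbind, rows), clinical = clinical,
                 grid = sparsity, mode = mode, n_null = n_null,
                 labels = labels, disconnected = do.call(rbind, disc),
                 similarity = sims),
            class = "imn_cohort")
}

#' @export
print.imn_cohort <- function(x, ...) {
  cat("imn cohort fit:", length(unique(x$auc$subject)), "subjects,",
      length(unique(x$auc$metric)), "metric(s),", length(x$labels),
      "regions,", x$mode, "mode\n")
  if (!is.null(x$disconnected) && any(x$disconnected$disconnected))
    cat("  note:", sum(x$disconnected$disconnected),
        "subject-metric fits had a disconnected level\n")
  invisible(x)
}

#' @export
summary.imn_cohort <- function(object, ...) {
  print(object)
  g <- object$auc[is.na(object$auc$node), ]
  cat("\nGlobal AUC means by metric:\n")
  print(tapply(g$auc, list(g$metric, g$attribute), mean))
  invisible(object)
}

# Extract one attribute's AUC values aligned with a set of subjects.
# Global attribute -> named vector; nodal attribute -> subjects x nodes.
auc_values <- function(cohort, metric, attribute, subjects) {
  a <- cohort$auc
  a <- a[a$metric == metric & a$attribute == attribute, , drop = FALSE]
  if (all(is.na(a$node))) {
    out <- a$auc[match(subjects, a$subject)]
    names(out) <- subjects
    out
  } else {
    a <- a[!is.na(a$node) & a$subject %in% subjects, , drop = FALSE]
    M <- matrix(NA_real_, length(subjects), length(cohort$labels),
                dimnames = list(subjects, cohort$labels))
    M[cbind(match(a$subject, subjects), match(a$node, cohort$labels))] <- a$auc
    M
  }
}
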