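# Synthetic cohorts of vertex-wise cortical metrics. The generator stands in
# for access-controlled imaging cohorts: each region has a stable base
# distribution (location-scale family), named (group, sex) cells can receive
# regional mean shifts / SD scalings, and clinical scores can be coupled to
# a subject's own network topology so the correlation stage is testable
# end-to-end.

# Desikan-Killiany cortical parcel names (34 per hemisphere).
dk_names <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

region_labels <- function(n_regions) {
  if (n_regions == 68L) c(paste0("lh.", dk_names), paste0("rh.", dk_names))
  else sprintf("R%03d", seq_len(n_regions))
}

#' Specify a synthetic cohort
#'
#' Defines the shape of a simulated cohort: one cell per (group, sex)
#' combination with `n_per_cell` subjects, `n_regions` cortical regions
#' whose vertex counts are drawn once (uniformly within
#' `vertices_per_region`) and shared by all subjects, and per-region
#' Gaussian base distributions with mean ~ U(1.5, 3.5) (a cortical
#' thickness-like scale, mm) and SD ~ U(0.2, 0.5). Effects shift/scale
#' named cells' regional distributions; a score coupling ties a clinical
#' score to each subject's own network attribute AUC.
#'
#' @param n_per_cell subjects per (group, sex) cell (>= 2).
#' @param groups,sexes cell labels.
#' @param n_regions number of cortical regions (>= 3; 68 gives
#'   Desikan-Killiany labels).
#' @param vertices_per_region length-2 range of per-region vertex counts
#'   (each >= 10).
#' @param metrics cortical metrics to simulate, subset of
#'   `c("CT", "GI", "SD", "FD")`.
#' @param effects list of effects from [region_effect()].
#' @param score_coupling optional [score_coupling()] specification.
#' @param base `"gaussian"` (default) or `"lognormal"` vertex-value family.
#' @param seed integer; fixed seed gives bit-identical cohorts.
#' @return an object of class `"cohort_spec"`.
#' @examples
#' sp <- cohort_spec(n_per_cell = 5, n_regions = 10,
#'                   vertices_per_region = c(30, 60), metrics = "FD")
#' @export
cohort_spec <- function(n_per_cell = 30L,
                        groups = c("HC", "PDnon-pRBD", "PD-pRBD"),
                        sexes = c("M", "F"),
                        n_regions = 68L,
                        vertices_per_region = c(200L, 600L),
                        metrics = c("CT", "GI", "SD", "FD"),
                        effects = list(),
                        score_coupling = NULL,
                        base = c("gaussian", "lognormal"),
                        seed = 1L) {
  base <- match.arg(base)
  metrics <- match.arg(metrics, c("CT", "GI", "SD", "FD"),
                       several.ok = TRUE)
  if (n_per_cell < 2L) stop("`n_per_cell` must be >= 2")
  if (n_regions < 3L) stop("`n_regions` must be >= 3")
  if (length(vertices_per_region) == 1L)
    vertices_per_region <- rep(vertices_per_region, 2L)
  if (min(vertices_per_region) < 10L)
    stop("`vertices_per_region` must be >= 10")
  for (e in effects) {
    if (!inherits(e, "region_effect"))
      stop("each effect must come from region_effect()")
    if (any(e$regions < 1L) || any(e$regions > n_regions))
      stop("effect region ids outside 1..", n_regions, ": ",
           paste(setdiff(e$regions, seq_len(n_regions)), collapse = ", "))
    if (!e$group %in% groups || !e$sex %in% sexes)
      stop("effect cell (", e$group, ", ", e$sex, ") not in the cohort")
    if (!e$metric %in% metrics)
      stop("effect metric ", e$metric, " not simulated")
    if (!is.finite(e$shift) || !is.finite(e$scale) || e$scale <= 0)
      stop("effect shift must be finite and scale > 0")
  }
  structure(list(n_per_cell = as.integer(n_per_cell), groups = groups,
                 sexes = sexes, n_regions = as.integer(n_regions),
                 vertices_per_region = as.integer(vertices_per_region),
                 metrics = metrics, effects = effects,
                 score_coupling = score_coupling, base = base,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Regional distribution effect for one cohort cell
#'
#' Shifts the mean of the named regions by `shift` regional SD units and
#' multiplies their SD by `scale`, for subjects in the (`group`, `sex`)
#' cell and the given metric only.
#'
#' @param group,sex the cell receiving the effect.
#' @param regions integer region ids (1-based).
#' @param metric the affected cortical metric.
#' @param shift mean shift in units of the region's base SD.
#' @param scale SD multiplier (> 0), default 1.
#' @return an object of class `"region_effect"`.
#' @export
region_effect <- function(group, sex, regions, metric, shift, scale = 1) {
  structure(list(group = group, sex = sex, regions = as.integer(regions),
                 metric = metric, shift = shift, scale = scale),
            class = "region_effect")
}

#' Couple a clinical score to a network attribute
#'
#' The named score is generated in a second pass as
#' `intercept + slope * AUC(attribute) + N(0, noise_sd)`, where the AUC is
#' computed from the subject's own simulated network (binary mode) for the
#' given metric — so downstream correlation analyses have a known ground
#' truth.
#'
#' @param score score name (e.g. `"HVLT_DR"`).
#' @param metric cortical metric whose network drives the score.
#' @param attribute global attribute name (`"Eg"`, `"Lp"`, `"Cp"` or
#'   `"Eloc"`).
#' @param slope,intercept linear coupling coefficients.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param grid sparsity grid used for the coupling AUC.
#' @param grid_size KDE grid size for the coupling pass.
#' @return an object of class `"score_coupling"`.
#' @export
score_coupling <- function(score, metric, attribute = "Eg", slope = 1,
                           intercept = 0, noise_sd = 1,
                           grid = sparsity_grid(), grid_size = 256L) {
  if (!attribute %in% c("Eg", "Lp", "Cp", "Eloc"))
    stop("coupling attribute must be one of Eg, Lp, Cp, Eloc")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(score = score, metric = metric, attribute = attribute,
                 slope = slope, intercept = intercept, noise_sd = noise_sd,
                 grid = grid, grid_size = as.integer(grid_size)),
            class = "score_coupling")
}

#' Generate a synthetic cohort
#'
#' Draws vertex-wise cortical values and a clinical table according to a
#' [cohort_spec()]. Region base parameters and vertex counts come from a
#' dedicated RNG substream of the spec seed; each subject's vertex values
#' come from a substream keyed by (seed, subject, region), so output is
#' bit-identical for a fixed seed and insensitive to generation order.
#' Effects are applied as deterministic location-scale transforms of the
#' base draws, so a cohort with zero effects is identical to one generated
#' without them.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `"cohort"`: list with `vertex` (long data
#'   frame: subject, group, sex, region_id, region_label, metric, value),
#'   `clinical` (one row per subject: subject, group, sex, age, education,
#'   LEDD, scores) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_per_cell = 3, n_regions = 6,
#'   vertices_per_region = c(20, 30), metrics = "CT", seed = 7))
#' head(co$vertex)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nr <- spec$n_regions
  labs <- region_labels(nr)
  nm <- length(spec$metrics)

  # region base parameters + vertex counts: one dedicated substream
  pars <- with_seed(mix_seed(spec$seed, 0L), {
    nv <- sample(spec$vertices_per_region[1L]:spec$vertices_per_region[2L],
                 nr, replace = TRUE)
    mu <- matrix(stats::runif(nr * nm, 1.5, 3.5), nr, nm,
                 dimnames = list(NULL, spec$metrics))
    sdv <- matrix(stats::runif(nr * nm, 0.2, 0.5), nr, nm,
                  dimnames = list(NULL, spec$metrics))
    list(nv = nv, mu = mu, sd = sdv)
  })

  cells <- expand.grid(sex = spec$sexes, group = spec$groups,
                       stringsAsFactors = FALSE)[, c("group", "sex")]
  n_sub <- nrow(cells) * spec$n_per_cell
  subj <- sprintf("S%04d", seq_len(n_sub))
  group <- rep(cells$group, each = spec$n_per_cell)
  sex <- rep(cells$sex, each = spec$n_per_cell)

  # net shift / scale per (cell, metric, region)
  eff_shift <- array(0, dim = c(nrow(cells), nr, nm))
  eff_scale <- array(1, dim = c(nrow(cells), nr, nm))
  for (e in spec$effects) {
    ci <- which(cells$group == e$group & cells$sex == e$sex)
    mi <- match(e$metric, spec$metrics)
    eff_shift[ci, e$regions, mi] <- eff_shift[ci, e$regions, mi] + e$shift
    eff_scale[ci, e$regions, mi] <- eff_scale[ci, e$regions, mi] * e$scale
  }
  cell_of <- rep(seq_len(nrow(cells)), each = spec$n_per_cell)

  nv_tot <- sum(pars$nv)
  value <- numeric(n_sub * nv_tot * nm)
  region_id <- rep(rep.int(seq_len(nr), pars$nv), times = nm)
  for (s in seq_len(n_sub)) {
    for (r in seq_len(nr)) {
      z <- with_seed(mix_seed(spec$seed, s, r),
                     matrix(stats::rnorm(pars$nv[r] * nm), ncol = nm))
      for (m in seq_len(nm)) {
        mu <- pars$mu[r, m] + eff_shift[cell_of[s], r, m] * pars$sd[r, m]
        sg <- pars$sd[r, m] * eff_scale[cell_of[s], r, m]
        v <- if (spec$base == "gaussian") mu + sg * z[, m]
        else exp(log(mu) + (sg / mu) * z[, m])
        value[value_index(s, r, m, pars$nv, nv_tot, nm)] <- v
      }
    }
  }

  vertex <- data.frame(
    subject = rep(subj, each = nv_tot * nm),
    group = rep(group, each = nv_tot * nm),
    sex = rep(sex, each = nv_tot * nm),
    region_id = rep.int(region_id, n_sub),
    region_label = labs[rep.int(region_id, n_sub)],
    metric = rep(rep(spec$metrics, each = nv_tot), times = n_sub),
    value = value,
    stringsAsFactors = FALSE)

  clinical <- data.frame(subject = subj, group = group, sex = sex,
                         stringsAsFactors = FALSE)
  clin_draw <- t(vapply(seq_len(n_sub), function(s) {
    with_seed(mix_seed(spec$seed, s, nr + 1L), {
      c(age = round(stats::rnorm(1, 62, 8), 1),
        education = round(pmin(pmax(stats::rnorm(1, 14, 3), 6), 22)),
        ledd = round(pmax(stats::rnorm(1, 450, 150), 0)))
    })
  }, numeric(3)))
  clinical$age <- clin_draw[, "age"]
  clinical$education <- clin_draw[, "education"]
  clinical$LEDD <- ifelse(group == "HC", 0, clin_draw[, "ledd"])

  sc <- spec$score_coupling
  if (is.null(sc)) {
    clinical$HVLT_DR <- vapply(seq_len(n_sub), function(s)
      with_seed(mix_seed(spec$seed, s, nr + 2L),
                round(pmin(pmax(stats::rnorm(1, 9, 2), 0), 12), 0)),
      numeric(1))
  } else {
    att <- vapply(seq_len(n_sub), function(s) {
      sl <- vertex[vertex$subject == subj[s] & vertex$metric == sc$metric, ]
      fit <- imn(sl, sparsity = sc$grid, mode = "binary", n_null = 0L,
                 grid_size = sc$grid_size)
      fit$auc_global[[sc$attribute]]
    }, numeric(1))
    noise <- vapply(seq_len(n_sub), function(s)
      with_seed(mix_seed(spec$seed, s, nr + 2L),
                stats::rnorm(1, 0, max(sc$noise_sd, .Machine$double.eps))),
      numeric(1))
    if (sc$noise_sd == 0) noise <- noise * 0
    clinical[[sc$score]] <- sc$intercept + sc$slope * att + noise
  }

  structure(list(vertex = vertex, clinical = clinical, spec = spec),
            class = "cohort")
}

# linear indices of (subject s, region r, metric m) vertex block inside the
# value vector laid out as subject-major, then metric, then region
value_index <- function(s, r, m, nv, nv_tot, nm) {
  start <- (s - 1L) * nv_tot * nm + (m - 1L) * nv_tot +
    (if (r > 1L) sum(nv[seq_len(r - 1L)]) else 0L)
  start + seq_len(nv[r])
}

#' Generate the matched zero-effect cohort
#'
#' Identical to [generate_cohort()] with the effect list emptied: same
#' seed, same base draws, no cell receives any shift. Used for type-I error
#' and FDR calibration.
#'
#' @param spec a [cohort_spec()].
#' @return a `"cohort"` object.
#' @export
null_cohort <- function(spec) {
  spec$effects <- list()
  generate_cohort(spec)
}

#' @export
print.cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$clinical), "subjects,",
      x$spec$n_regions, "regions,",
      paste(x$spec$metrics, collapse = "/"), "\n")
  cat("  cells:", paste(unique(paste(x$clinical$group, x$clinical$sex,
                                     sep = "/")), collapse = ", "), "\n")
  cat("  effects:", length(x$spec$effects), " seed:", x$spec$seed, "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `vertex.csv` (long format: subject, region_id, region_label,
#' metric, value) and `clinical.csv` into `dir`.
#'
#' @param cohort a `"cohort"` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    cohort$vertex[, c("subject", "region_id", "region_label", "metric",
                      "value")],
    file.path(dir, "vertex.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}
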