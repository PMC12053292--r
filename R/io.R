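# Readers, writers and the one-call reproducible pipeline.

#' Read and validate a long-format vertex table
#'
#' Expects a CSV with columns `subject`, `region_id`, `region_label`,
#' `metric`, `value`. Validates that values are numeric and finite, that
#' every (subject, metric) carries the complete `1..n` region set, and that
#' each (subject, region, metric) has at least 10 vertices.
#'
#' @param path CSV file path.
#' @return the validated data frame, with a `completeness` attribute (one
#'   row per subject/metric: n_regions, min_vertices).
#' @export
read_vertex_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) stop("vertex table is empty: ", path)
  need <- c("subject", "region_id", "region_label", "metric", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("vertex table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(x$value) || !all(is.finite(x$value)))
    stop("`value` must be numeric and finite")
  if (!is.numeric(x$region_id)) stop("`region_id` must be numeric")
  n <- max(x$region_id)
  comp <- list()
  for (s in unique(x$subject)) for (m in unique(x$metric)) {
    xs <- x[x$subject == s & x$metric == m, ]
    if (nrow(xs) == 0L) next
    ids <- sort(unique(xs$region_id))
    missing_ids <- setdiff(seq_len(n), ids)
    if (length(missing_ids))
      stop("subject ", s, " (", m, ") is missing region(s) ",
           paste(missing_ids, collapse = ", "))
    cnt <- table(xs$region_id)
    if (any(cnt < 10L))
      stop("subject ", s, " (", m, ") has < 10 vertices in region(s) ",
           paste(names(cnt)[cnt < 10L], collapse = ", "))
    comp[[length(comp) + 1L]] <- data.frame(
      subject = s, metric = m, n_regions = length(ids),
      min_vertices = min(cnt), stringsAsFactors = FALSE)
  }
  attr(x, "completeness") <- do.call(rbind, comp)
  x
}

#' Write similarity matrices
#'
#' `write_similarity_tsv` writes one dense square TSV per matrix (region
#' labels as header and row names); `similarity_long` stacks matrices into
#' a long data frame (subject, metric, region_i, region_j, kls) over the
#' upper triangle.
#'
#' @param C a similarity matrix.
#' @param path output TSV path.
#' @export
write_similarity_tsv <- function(C, path) {
  utils::write.table(as.matrix(unclass(C)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @param sims named list of matrices (names `subject.metric`, as produced
#'   by `imn_cohort(..., keep_similarity = TRUE)`).
#' @export
similarity_long <- function(sims) {
  do.call(rbind, lapply(names(sims), function(nm) {
    C <- unclass(sims[[nm]])
    sm <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    ut <- which(upper.tri(C), arr.ind = TRUE)
    data.frame(subject = sm[1L], metric = sm[2L],
               region_i = rownames(C)[ut[, 1L]],
               region_j = colnames(C)[ut[, 2L]],
               kls = C[ut], stringsAsFactors = FALSE)
  }))
}

# ---- pipeline -------------------------------------------------------------

default_config <- function() {
  list(
    simulate = list(n_per_cell = 10, groups = c("PD-pRBD"),
                    sexes = c("M", "F"), n_regions = 20,
                    vertices_per_region = c(60, 120), metrics = "FD",
                    effects = list()),
    metrics = NULL,                       # default: all simulated/ingested
    sparsity = list(from = 0.063, to = 0.4, by = 0.01,
                    include_endpoint = FALSE),
    mode = "binary",
    n_null = 0,
    n_perm = 1000,
    grid_size = 256,
    covariates = c("age", "education", "LEDD"),
    contrasts = list(list(group = "PD-pRBD", between = "sex",
                          a = "M", b = "F")),
    correlations = list(),
    seed = 1)
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), c(names(base), "input"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- base
  # wholesale assignment: several fields hold unnamed lists, which
  # modifyList() would mangle; only the sparsity block merges field-wise
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (!is.null(config$sparsity))
    cfg$sparsity <- utils::modifyList(base$sparsity, config$sparsity)
  if (!is.null(config$input)) {
    cfg$simulate <- NULL
    for (f in unlist(config$input))
      if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  if (!cfg$mode %in% c("binary", "weighted")) stop("mode must be binary|weighted")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  cfg
}

#' Run the full analysis pipeline
#'
#' One reproducible call: simulate (or ingest) vertex data, fit every
#' subject's individual morphological network, integrate attributes over
#' the sparsity grid, run the configured permutation contrasts and clinical
#' correlations, and write tidy CSV artifacts plus a JSON manifest
#' recording the configuration, its hash, the seed and the package
#' version. Reruns with the same configuration and seed are byte-identical.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognised fields: `simulate` (arguments to [cohort_spec()];
#'   `effects` entries are lists of [region_effect()] arguments) or `input`
#'   (list with `vertex` and `clinical` CSV paths), `metrics`, `sparsity`
#'   (from/to/by/include_endpoint), `mode`, `n_null`, `n_perm`,
#'   `grid_size`, `covariates`, `contrasts`, `correlations` (each a list
#'   with a `score` and optional cells), `seed`.
#' @param out output directory.
#' @param seed overrides the config seed when non-NULL.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the cohort fit, contrast and correlation
#'   tables, and the manifest.
#' @export
run_pipeline <- function(config = list(), out, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)

  if (!is.null(cfg$simulate)) {
    say("simulate", "generating synthetic cohort")
    sim <- cfg$simulate
    sim$effects <- lapply(sim$effects, function(e) do.call(region_effect, e))
    sim$seed <- cfg$seed
    cohort <- generate_cohort(do.call(cohort_spec, sim))
    vertex <- cohort$vertex
    clinical <- cohort$clinical
    write_cohort(cohort, out)
  } else {
    say("ingest", "reading ", config$input$vertex)
    vertex <- read_vertex_table(config$input$vertex)
    clinical <- utils::read.csv(config$input$clinical,
                                stringsAsFactors = FALSE)
  }

  grid <- sparsity_grid(cfg$sparsity$from, cfg$sparsity$to, cfg$sparsity$by,
                        isTRUE(cfg$sparsity$include_endpoint))
  say("network", "fitting individual networks (", cfg$mode, " mode, ",
      length(grid), " sparsity levels)")
  fit <- imn_cohort(vertex, clinical = clinical, metrics = cfg$metrics,
                    sparsity = grid, mode = cfg$mode, n_null = cfg$n_null,
                    seed = mix_seed(cfg$seed, 101L),
                    grid_size = cfg$grid_size, keep_similarity = TRUE)
  utils::write.csv(similarity_long(fit$similarity),
                   file.path(out, "similarity.csv"), row.names = FALSE)
  utils::write.csv(fit$auc, file.path(out, "auc.csv"), row.names = FALSE)

  results <- NULL
  for (i in seq_along(cfg$contrasts)) {
    ct <- cfg$contrasts[[i]]
    say("compare", ct$a, " vs ", ct$b, " (", ct$between, ") in ",
        ct$group %||% "all")
    cmp <- imn_compare(fit, group = ct$group, between = ct$between %||% "sex",
                       a = ct$a, b = ct$b, covariates = cfg$covariates,
                       n_perm = cfg$n_perm, seed = mix_seed(cfg$seed, 202L, i))
    r <- cmp$results
    r$contrast <- paste0(ct$group %||% "all", ":", ct$a, "-", ct$b)
    results <- rbind(results, r)
  }
  if (!is.null(results))
    utils::write.csv(results, file.path(out, "results.csv"),
                     row.names = FALSE)

  cors <- NULL
  for (cr in cfg$correlations) {
    say("correlate", cr$score)
    cors <- rbind(cors, imn_correlate(fit, score = cr$score,
                                      groups = cr$groups %||% NULL,
                                      sexes = cr$sexes %||% NULL))
  }
  if (!is.null(cors))
    utils::write.csv(cors, file.path(out, "correlations.csv"),
                     row.names = FALSE)

  say("manifest", "writing run manifest")
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tf <- file.path(out, "config.json")
  writeLines(cfg_json, tf)
  manifest <- list(
    package = "morphnet",
    version = as.character(utils::packageVersion("morphnet")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tf)),
    outputs = sort(setdiff(list.files(out), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, results = results, correlations = cors,
                 manifest = manifest))
}
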