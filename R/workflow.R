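#' Read and validate a retrieval run configuration
#'
#' A run is described by one YAML file covering every pipeline stage:
#' molecule (base XYZ path and label scheme), database generation, kinematic
#' grid, amplitude model, dataset preparation, CNN hyperparameters, ensemble
#' seeds, and the synthetic-experiment settings (hidden truth labels and
#' Poisson count level). Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to a YAML run configuration.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("config is missing field: ", field)
  }
  for (f in c("molecule", "database", "output_dir")) need(f)
  kind <- cfg$molecule$scheme %||% stop("config field molecule$scheme missing")
  if (!kind %in% c("c2h2", "cs2", "cartesian")) {
    stop("molecule$scheme must be one of c2h2, cs2, cartesian")
  }
  if (!is.null(cfg$molecule$xyz)) {
    p <- cfg$molecule$xyz
    if (!file.exists(p)) p <- file.path(cfg$config_dir, cfg$molecule$xyz)
    if (!file.exists(p)) {
      stop("config field molecule$xyz points to a missing file: ",
           cfg$molecule$xyz)
    }
    cfg$molecule$xyz <- p
  } else if (kind == "cartesian") {
    stop("cartesian scheme requires config field molecule$xyz")
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Instantiate scheme, deformation spec, grid and amplitude model from a
# validated config list.
build_run_objects <- function(cfg) {
  base <- if (!is.null(cfg$molecule$xyz)) read_xyz(cfg$molecule$xyz)
  scheme <- switch(cfg$molecule$scheme,
    c2h2 = scheme_c2h2(),
    cs2 = scheme_cs2(),
    cartesian = scheme_cartesian(base, as.integer(cfg$molecule$tracked_atoms)))
  db <- cfg$database
  spec <- if ((db$mode %||% "parameter-grid") == "parameter-grid") {
    deformation_spec("parameter-grid", scheme,
                     parameters = db$parameters,
                     sampling = db$sampling %||% "uniform",
                     count = db$count, seed = db$seed %||% 1L)
  } else {
    deformation_spec("group-deformation", scheme,
                     base_structure = base,
                     groups = db$groups,
                     count = db$count,
                     shift_range = unlist(db$shift_range %||% c(-0.3, 0.3)),
                     global_scale = unlist(db$global_scale %||% c(0.9, 1.1)),
                     seed = db$seed %||% 1L)
  }
  g <- cfg$grid %||% list()
  grid <- dcs_grid(seq(g$e_min %||% 50, g$e_max %||% 300,
                       length.out = g$n_energy %||% 64),
                   seq(g$a_min %||% 30, g$a_max %||% 180,
                       length.out = g$n_angle %||% 64))
  cn <- cfg$cnn %||% list()
  config <- cnn_config(
    conv_layers = lapply(cn$conv_layers %||% list(c(32, 5), c(32, 3), c(32, 3)),
                         unlist),
    fc_depth = cn$fc_depth %||% 30L, fc_width = cn$fc_width %||% 64L,
    batch_size = cn$batch_size %||% 120L,
    learning_rate = cn$learning_rate %||% 1e-3,
    epochs = cn$epochs %||% 50L, batch_norm = cn$batch_norm %||% TRUE,
    optimizer = cn$optimizer %||% "sgd")
  list(base = base, scheme = scheme, spec = spec, grid = grid,
       model = amplitude_model(cfg$model %||% "screened-born"),
       cnn = config,
       reference = reference_structure(cfg, scheme, base))
}

# The subtraction reference: the equilibrium geometry. For internal
# coordinate schemes it is built from config-provided equilibrium labels;
# for cartesian schemes it is the base structure itself.
reference_structure <- function(cfg, scheme, base) {
  eq <- cfg$molecule$equilibrium_labels
  if (!is.null(eq)) return(structure_from_params(scheme, unlist(eq)))
  if (scheme$kind == "cartesian") return(base)
  stop("config field molecule$equilibrium_labels required for scheme ",
       scheme$kind)
}

run_seeds <- function(cfg) {
  ens <- cfg$ensemble %||% list()
  seeds <- unlist(ens$seeds %||% seq_len(ens$k %||% 2L))
  as.integer(seeds)
}

#' Run the full structure-retrieval pipeline
#'
#' Database generation, IAM simulation, dataset preparation, ensemble CNN
#' training, retrieval from a Poisson-noised synthetic measurement, and
#' evaluation, with all artifacts and a reproducibility manifest written to
#' the configured output directory. Rerunning with an identical config
#' reproduces every deterministic artifact.
#'
#' @param config A `run_config` (from [read_run_config()]) or a path to one.
#' @param verbose Per-stage progress messages?
#' @return List with `prediction` (`structure_prediction`), `reports` (per
#'   member `train_report`s), `correlation` (`correlation_report` between
#'   the measured and the predicted-structure map) and `manifest`.
#' @export
run_retrieval <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-12s %6.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }
  obj <- t_stage("setup", build_run_objects(config))
  exp_cfg <- config$experiment %||% list()
  truth <- unlist(exp_cfg$truth_labels %||%
                    structure_labels(obj$scheme, obj$reference))
  seeds <- run_seeds(config)

  # synthetic measurement of the hidden truth structure
  truth_structure <- structure_from_params(obj$scheme, truth)
  truth_map <- t_stage("simulate", dcs_map(truth_structure, obj$model, obj$grid))
  counts <- poissonize(truth_map, exp_cfg$total_counts %||% 1e7,
                       seed = exp_cfg$noise_seed %||% 1L)
  reference_map <- dcs_map(obj$reference, obj$model, obj$grid)
  input <- difference_map(counts_to_map(counts), reference_map)

  builder <- function(seed) {
    spec <- obj$spec
    spec$seed <- spec$seed + seed
    db <- generate_database(spec)
    assemble_dataset(db, obj$reference, obj$grid, obj$model,
                     fractions = unlist((config$prep %||% list())$fractions %||%
                                          c(0.8, 0.1, 0.1)),
                     seed = ((config$prep %||% list())$split_seed %||% 1L) + seed)
  }
  prediction <- t_stage("train", ensemble_retrieve(
    builder, obj$cnn, seeds, input,
    counts = counts, reference_map = reference_map,
    verbose = if (verbose) 10L else 0L))

  correlation <- t_stage("evaluate", {
    predicted_map <- dcs_map(structure_from_params(obj$scheme,
                                                   prediction$labels),
                             obj$model, obj$grid)
    bootstrap_ci(as.vector(normalize_map(counts_to_map(counts))),
                 as.vector(normalize_map(predicted_map)),
                 level = 0.90, B = 1000L,
                 seed = exp_cfg$noise_seed %||% 1L)
  })

  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- write_run_artifacts(out_dir, config, obj, prediction,
                                  correlation, truth, seeds)
  say("artifacts written to %s", out_dir)
  list(prediction = prediction, reports = prediction$reports,
       correlation = correlation, manifest = manifest, truth = truth)
}

write_run_artifacts <- function(out_dir, config, obj, prediction,
                                correlation, truth, seeds) {
  label_names <- obj$scheme$label_names
  pred_df <- data.frame(label = label_names, truth = truth,
                        predicted = prediction$labels,
                        model_error = prediction$model_error,
                        experimental_error = prediction$experimental_error,
                        total_error = prediction$total_error)
  jsonlite::write_json(pred_df, file.path(out_dir, "prediction.json"),
                       digits = NA, pretty = TRUE)
  write_train_report(prediction$reports[[1L]],
                     file.path(out_dir, "train_report.csv"))
  jsonlite::write_json(unclass(correlation),
                       file.path(out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_copy <- config
  cfg_copy$config_dir <- NULL
  cfg_path <- file.path(out_dir, "config_snapshot.yaml")
  yaml::write_yaml(cfg_copy, cfg_path)
  # hash the scientific configuration only: where the artifacts land must
  # not change what the run computes
  cfg_sci <- cfg_copy
  cfg_sci$output_dir <- NULL
  hash_path <- tempfile(fileext = ".yaml")
  on.exit(unlink(hash_path), add = TRUE)
  yaml::write_yaml(cfg_sci, hash_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dcsnet")),
    config_md5 = unname(tools::md5sum(hash_path)),
    seeds = list(ensemble = seeds,
                 database = obj$spec$seed,
                 noise = (config$experiment %||% list())$noise_seed %||% 1L,
                 split = (config$prep %||% list())$split_seed %||% 1L),
    n_structures = obj$spec$count,
    grid = list(n_energy = length(obj$grid$energies),
                n_angle = length(obj$grid$angles)),
    labels = label_names)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Parameter-recovery experiment with a known synthetic truth
#'
#' Runs the full retrieval on a synthetic measurement of a hidden
#' ground-truth structure and reports, per label dimension, the truth, the
#' prediction, the absolute error, and a pass/fail flag against configured
#' tolerances. If the truth lies outside the database parameter ranges the
#' report records an extrapolation warning.
#'
#' @param config A `run_config` or path to one; `experiment$truth_labels`
#'   defines the hidden truth and `experiment$tolerances` (scalar or per
#'   label) the pass thresholds.
#' @param verbose Progress messages?
#' @return List of class `recovery_report`: `table` (one row per label),
#'   `pass` (all labels within tolerance), `extrapolation` flag, plus the
#'   underlying `run_retrieval()` result.
#' @export
run_synthetic_experiment <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  res <- run_retrieval(config, verbose = verbose)
  exp_cfg <- config$experiment %||% list()
  tol <- unlist(exp_cfg$tolerances %||% 0.05)
  if (length(tol) == 1L) tol <- rep(tol, length(res$truth))
  extrapolation <- FALSE
  obj <- build_run_objects(config)
  if (obj$spec$mode == "parameter-grid") {
    lo <- vapply(obj$spec$parameters, function(p) p$min, numeric(1))
    hi <- vapply(obj$spec$parameters, function(p) p$max, numeric(1))
    if (any(res$truth < lo | res$truth > hi)) {
      extrapolation <- TRUE
      warning("truth labels outside database ranges: extrapolation regime")
    }
  }
  abs_err <- abs(res$prediction$labels - res$truth)
  table <- data.frame(label = obj$scheme$label_names, truth = res$truth,
                      predicted = res$prediction$labels,
                      abs_error = abs_err, tolerance = tol,
                      pass = abs_err <= tol)
  out <- structure(list(table = table, pass = all(table$pass),
                        extrapolation = extrapolation, run = res),
                   class = "recovery_report")
  jsonlite::write_json(table, file.path(config$output_dir, "recovery.json"),
                       digits = NA, pretty = TRUE)
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s%s\n",
              if (x$pass) "PASS" else "FAIL",
              if (x$extrapolation) " (extrapolation regime)" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
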