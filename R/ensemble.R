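#' Ensemble structure retrieval
#'
#' Trains the model several times on independently generated datasets (one
#' seed per member) and averages the member predictions for the same input.
#' Repeated retraining probes the spread induced by random initialization
#' and batch shuffling; the reported model error is the per-dimension
#' test-split MAE averaged over members, and the experimental error (when a
#' counts map is supplied) comes from [error_budget()]. The total error is
#' the element-wise sum of the two components.
#'
#' @param dataset_builder Function `(seed) -> dcs_dataset` producing one
#'   member's dataset.
#' @param config A [cnn_config()]; each member trains with its own seed.
#' @param seeds Integer vector of `k >= 2` member seeds.
#' @param input The `dcs_diff` to retrieve a structure from.
#' @param counts Optional `counts_map` behind `input`, enabling the
#'   experimental-error component.
#' @param reference_map Optional `dcs_map` of the subtraction reference
#'   (required with `counts`).
#' @param verbose Passed to [train_cnn()].
#' @return Object of class `structure_prediction`: `labels` (ensemble-mean
#'   label vector), `model_error`, `experimental_error`, `total_error`
#'   (all per-dimension), `member_labels` (k x d matrix), `seeds`, and the
#'   member `reports`.
#' @export
ensemble_retrieve <- function(dataset_builder, config, seeds, input,
                              counts = NULL, reference_map = NULL,
                              verbose = 0L) {
  stopifnot(is.function(dataset_builder), inherits(config, "cnn_config"))
  if (length(seeds) < 2L) stop("ensemble needs at least two member seeds")
  members <- vector("list", length(seeds))
  reports <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    ds <- dataset_builder(seeds[i])
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    mdl <- build_model(cfg, input_shape = c(length(ds$grid$energies),
                                            length(ds$grid$angles)),
                       n_labels = ncol(ds$labels))
    fit <- tryCatch(train_cnn(mdl, ds, cfg, verbose = verbose),
                    error = function(e) {
                      stop(sprintf("ensemble member with seed %d failed: %s",
                                   seeds[i], conditionMessage(e)))
                    })
    members[[i]] <- fit$model
    reports[[i]] <- fit$report
  }
  d <- members[[1L]]$n_labels
  member_labels <- t(matrix(vapply(members, function(m) predict(m, input),
                                   numeric(d)), nrow = d))
  model_error <- rowMeans(matrix(vapply(reports, function(r) r$test_mae_dim,
                                        numeric(d)), nrow = d))
  experimental_error <- rep(0, d)
  if (!is.null(counts)) {
    if (is.null(reference_map)) stop("counts given without reference_map")
    experimental_error <- error_budget(members, input, counts, reference_map)
  }
  structure(list(labels = colMeans(member_labels),
                 model_error = model_error,
                 experimental_error = experimental_error,
                 total_error = model_error + experimental_error,
                 member_labels = member_labels,
                 seeds = as.integer(seeds), reports = reports,
                 members = members),
            class = "structure_prediction")
}

#' @export
print.structure_prediction <- function(x, ...) {
  cat(sprintf("<structure_prediction> ensemble of %d model(s)\n",
              length(x$seeds)))
  for (j in seq_along(x$labels)) {
    cat(sprintf("  label %d: %.3f +/- %.3f (model %.3f + experimental %.3f)\n",
                j, x$labels[j], x$total_error[j], x$model_error[j],
                x$experimental_error[j]))
  }
  invisible(x)
}
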