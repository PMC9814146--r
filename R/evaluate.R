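#' Mean absolute error
#'
#' The prediction error of the retrieval: mean of `|predicted - true|` over
#' all label components and samples, in physical label units.
#'
#' @param predicted,true Numeric vectors or matrices of equal shape.
#' @return Non-negative scalar.
#' @export
mae <- function(predicted, true) {
  predicted <- as.matrix(predicted); true <- as.matrix(true)
  if (!all(dim(predicted) == dim(true))) stop("shapes differ")
  mean(abs(predicted - true))
}

#' Pearson product-moment correlation
#'
#' Used to judge how strongly the (flattened, normalized) theoretical map of
#' a predicted structure correlates with the measured map.
#'
#' @param x,y Numeric vectors of equal length `>= 2` with non-zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Bootstrap confidence interval for a Pearson correlation
#'
#' Percentile interval over seeded paired resamples, with an ordinary
#' least-squares line through the scatter for plotting.
#'
#' @param x,y Paired numeric vectors.
#' @param level Confidence level (default 0.90).
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; fixed seed gives identical bounds.
#' @return Object of class `correlation_report`: `pearson_r`, `slope`,
#'   `intercept`, `ci_lower`, `ci_upper`, `level`, `B`, `n_degenerate`
#'   (resamples skipped for zero variance) and `seed`.
#' @export
bootstrap_ci <- function(x, y, level = 0.90, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100")
  r <- pearson(x, y)
  n <- length(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rs <- numeric(B)
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) {
      rs[b] <- NA_real_
      n_degenerate <- n_degenerate + 1L
      next
    }
    rs[b] <- stats::cor(xb, yb)
  }
  rs <- rs[!is.na(rs)]
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(rs, c(a, 1 - a), type = 7))
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(pearson_r = r, slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 ci_lower = ci[1L], ci_upper = ci[2L], level = level,
                 B = as.integer(B), n_degenerate = n_degenerate,
                 seed = as.integer(seed)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> r = %.4f, %.0f%% CI [%.4f, %.4f] (B = %d)\n",
              x$pearson_r, 100 * x$level, x$ci_lower, x$ci_upper, x$B))
  invisible(x)
}

#' Experimental (Poisson) error propagated into structure labels
#'
#' Bounds the effect of counting noise on the retrieved structure: the
#' measured counts map is replaced by its one-standard-error extrema
#' ([poisson_extrema()]), each extremum is turned into a difference map
#' against the same reference and passed through the model; the
#' experimental error per label dimension is the larger absolute deviation
#' of the two extremum predictions from the nominal one.
#'
#' @param models A trained `cnn_model` or list of them (predictions are
#'   averaged across members, as in the retrieval ensemble).
#' @param nominal_input The `dcs_diff` actually used for the retrieval.
#' @param counts The `counts_map` the nominal input came from (same grid).
#' @param reference_map The `dcs_map` of the subtraction reference.
#' @return Numeric vector of per-dimension experimental errors (label
#'   units).
#' @export
error_budget <- function(models, nominal_input, counts, reference_map) {
  if (inherits(models, "cnn_model")) models <- list(models)
  stopifnot(inherits(nominal_input, "dcs_diff"),
            inherits(counts, "counts_map"), inherits(reference_map, "dcs_map"))
  if (!grids_identical(counts$grid, reference_map$grid)) {
    stop("counts and reference are on different grids")
  }
  d <- models[[1L]]$n_labels
  ens_predict <- function(input) {
    rowMeans(matrix(vapply(models, function(m) predict(m, input),
                           numeric(d)), nrow = d))
  }
  ext <- poisson_extrema(counts)
  p_nom <- ens_predict(nominal_input)
  p_lo <- ens_predict(difference_map(ext$lower, reference_map))
  p_hi <- ens_predict(difference_map(ext$upper, reference_map))
  pmax(abs(p_lo - p_nom), abs(p_hi - p_nom))
}

#' Brute-force calculation-time scaling estimate
#'
#' Cost of the exhaustive alternative to learned retrieval: sampling every
#' degree of freedom of an N-atom molecule at n steps requires `n * 3^N`
#' map calculations.
#'
#' @param n Steps per degree of freedom (>= 1).
#' @param N Number of atoms (>= 1).
#' @param t_map Minutes to compute a single map (> 0).
#' @return List with `configurations` (`n * 3^N`) and `hours`
#'   (`configurations * t_map / 60`).
#' @examples
#' scaling_estimate(5, 20, 5)$hours  # ~1.45e9 h
#' @export
scaling_estimate <- function(n, N, t_map) {
  stopifnot(n >= 1, N >= 1, t_map > 0)
  configurations <- n * 3^N
  list(configurations = configurations, hours = configurations * t_map / 60)
}
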