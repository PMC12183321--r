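#' Z-normalize a glucose curve
#'
#' Centers and scales the 16 values to mean 0 and (sample) SD 1, so
#' downstream analysis sees curve *shape* rather than amplitude.
#'
#' @param curve A complete canonical [glucose_curve()], or a numeric vector.
#' @return Numeric vector, mean 0 and SD 1.
#' @export
znormalize <- function(curve) {
  v <- if (inherits(curve, "glucose_curve")) curve$values else as.numeric(curve)
  if (anyNA(v)) stop("curve has missing values; impute first", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("constant curve cannot be Z-normalized", call. = FALSE)
  (v - mean(v)) / s
}

#' Cubic smoothing spline on the curve's own grid
#'
#' Fits the penalized cubic smoothing spline
#' \deqn{p \sum_i (y_i - f(t_i))^2 + (1 - p) \int f''(t)^2 dt}
#' and evaluates it at the input times. The exposed `smoothing_parameter`
#' `s = 1 - p` runs from 0 (natural-spline interpolation) to 1 (least-squares
#' straight line); the default 0.35 lightly smooths a 16-point curve.
#' Exactly linear inputs are reproduced unchanged for every parameter value
#' (lines lie in the penalty's null space).
#'
#' @param z Numeric values (typically a Z-normalized curve).
#' @param times Sampling times, minutes; default the canonical grid.
#' @param smoothing_parameter In `[0, 1]`.
#' @return Smoothed values at `times`.
#' @export
smooth_curve <- function(z, times = ogtt_grid(), smoothing_parameter = 0.35) {
  if (!is.numeric(smoothing_parameter) || length(smoothing_parameter) != 1 ||
      smoothing_parameter < 0 || smoothing_parameter > 1) {
    stop("smoothing_parameter must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(z) == length(times))
  if (smoothing_parameter == 0) {
    return(stats::spline(times, z, xout = times, method = "natural")$y)
  }
  if (smoothing_parameter == 1) {
    return(unname(stats::fitted(stats::lm(z ~ times))))
  }
  p <- 1 - smoothing_parameter
  # smooth.spline rescales x to [0,1]; convert the raw-units penalty weight
  # (1-p)/p to the rescaled axis (factor range^3 from the substitution in
  # the integral of the squared second derivative)
  r <- diff(range(times))
  lambda <- ((1 - p) / p) / r^3
  fit <- stats::smooth.spline(times, z, lambda = lambda, all.knots = TRUE,
                              keep.data = FALSE)
  stats::predict(fit, x = times)$y
}

#' Preprocess a curve for the reduced representation
#'
#' Impute, Z-normalize, then smooth: the pipeline applied identically to
#' training and held-out curves.
#'
#' @param curve A canonical [glucose_curve()].
#' @inheritParams smooth_curve
#' @return Length-16 numeric vector.
#' @export
preprocess_curve <- function(curve, smoothing_parameter = 0.35) {
  curve <- impute_curve(curve)
  smooth_curve(znormalize(curve), times = curve$times,
               smoothing_parameter = smoothing_parameter)
}

#' Fit the PCA basis of the reduced curve representation
#'
#' Mean-centred PCA (no rescaling; inputs are already Z-normalized per
#' curve) of the training matrix of preprocessed curves; the top two
#' components are retained. Loadings have a fixed sign convention (largest
#' magnitude element positive) so scores are reproducible.
#'
#' @param training Matrix (curves in rows, 16 columns) or list of
#'   preprocessed length-16 vectors. At least 3 curves.
#' @return List of class `reduced_rep_basis`: `mean_vector` (length 16),
#'   `loadings` (16 x 2, orthonormal columns), `explained_variance`
#'   (fractions, non-increasing), `sdev` (all components).
#' @export
fit_reduced_rep <- function(training) {
  X <- if (is.list(training)) do.call(rbind, training) else as.matrix(training)
  if (nrow(X) < 3) stop("need at least 3 training curves", call. = FALSE)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  W <- pca$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  ev <- pca$sdev^2
  structure(list(mean_vector = pca$center,
                 loadings = W,
                 explained_variance = ev[1:2] / sum(ev),
                 sdev = pca$sdev),
            class = "reduced_rep_basis")
}

#' @export
print.reduced_rep_basis <- function(x, ...) {
  cat(sprintf("<reduced_rep_basis> PC1/PC2 explain %.1f%% / %.1f%%\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Project curves onto a fitted reduced-representation basis
#'
#' `X_reduced = (X - mean_vector) %*% W`: centre with the *training* mean and
#' multiply by the training loading matrix, so held-out curves never
#' influence the basis.
#'
#' @param basis A [fit_reduced_rep()] object.
#' @param curve Length-16 preprocessed vector, or a matrix of such rows.
#' @return Numeric length-2 vector (or n x 2 matrix) of PC scores.
#' @export
project_reduced_rep <- function(basis, curve) {
  stopifnot(inherits(basis, "reduced_rep_basis"))
  X <- if (is.matrix(curve)) curve else matrix(curve, nrow = 1)
  if (ncol(X) != length(basis$mean_vector)) {
    stop("curve length does not match the fitted basis", call. = FALSE)
  }
  scores <- sweep(X, 2, basis$mean_vector) %*% basis$loadings
  if (!is.matrix(curve)) unname(drop(scores)) else scores
}
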