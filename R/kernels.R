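#' Covariance kernel specification
#'
#' Describes one of three stationary covariance functions over inter-electrode
#' distance d, plus the independent observation-noise variance that enters the
#' training covariance diagonal:
#' \itemize{
#'   \item \code{rbf}: sigma2 * exp(-d^2 / (2 l^2)) -- smooth threshold fields.
#'   \item \code{matern15}: sigma2 * (1 + sqrt(3) d / l) * exp(-sqrt(3) d / l)
#'     (Matern, nu = 3/2) -- tolerates sharper spatial transitions.
#'   \item \code{hybrid}: sigma2 * [alpha * RBF(d; l1)/sigma2 +
#'     (1 - alpha) * Matern(d; l2)/sigma2], a convex mix of the two
#'     unit-variance components under a single signal variance.
#' }
#' Default optimization bounds are (0.1, 10) for the signal variance,
#' (1, 50) pitch units for every length scale, (1e-5, 1) for the noise
#' variance and (0, 1) for the mixing weight; they presume targets
#' standardized to unit scale (see \code{\link{transform_targets}}).
#'
#' @param family \code{"rbf"}, \code{"matern15"} or \code{"hybrid"}.
#' @param signal_variance marginal variance at d = 0 (transformed-target
#'   units squared).
#' @param length_scale correlation decay distance in pitch units (rbf,
#'   matern15).
#' @param length_scale_rbf,length_scale_matern separate length scales of the
#'   hybrid's smooth and non-smooth components.
#' @param mix_weight hybrid weight alpha in [0, 1]; 1 is pure RBF, 0 pure
#'   Matern.
#' @param noise_variance observation-noise variance added on the diagonal of
#'   the training covariance (non-negative).
#' @param bounds named list of \code{c(lower, upper)} pairs overriding the
#'   defaults, keyed by parameter name.
#' @return An object of class \code{kernel_spec}.
#' @examples
#' ks <- kernel_spec("matern15", signal_variance = 1, length_scale = 3)
#' kernel_value(ks, d = 0:3)
#' @export
kernel_spec <- function(family = c("rbf", "matern15", "hybrid"),
                        signal_variance = 1.0, length_scale = 3.0,
                        length_scale_rbf = 3.0, length_scale_matern = 3.0,
                        mix_weight = 0.5, noise_variance = 0.1,
                        bounds = list()) {
  family <- match.arg(family)
  def_bounds <- list(signal_variance = c(0.1, 10),
                     length_scale = c(1, 50),
                     length_scale_rbf = c(1, 50),
                     length_scale_matern = c(1, 50),
                     mix_weight = c(0, 1),
                     noise_variance = c(1e-5, 1))
  for (nm in names(bounds)) {
    if (!nm %in% names(def_bounds)) .stopf("unknown bound '%s'", nm)
    def_bounds[[nm]] <- as.numeric(bounds[[nm]])
  }
  if (signal_variance <= 0) .stopf("signal_variance must be positive")
  if (noise_variance < 0) .stopf("noise_variance must be non-negative")
  if (family == "hybrid") {
    if (mix_weight < 0 || mix_weight > 1) .stopf("mix_weight must lie in [0, 1]")
    if (length_scale_rbf <= 0 || length_scale_matern <= 0)
      .stopf("length scales must be positive")
  } else {
    if (length_scale <= 0) .stopf("length_scale must be positive")
  }
  structure(
    list(family = family, signal_variance = signal_variance,
         length_scale = length_scale, length_scale_rbf = length_scale_rbf,
         length_scale_matern = length_scale_matern, mix_weight = mix_weight,
         noise_variance = noise_variance, nu = 1.5, bounds = def_bounds),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "hybrid") {
    cat(sprintf(
      "hybrid kernel: sigma2=%.4g, alpha=%.3f, l_rbf=%.4g, l_matern=%.4g, sigma_n2=%.4g\n",
      x$signal_variance, x$mix_weight, x$length_scale_rbf,
      x$length_scale_matern, x$noise_variance))
  } else {
    cat(sprintf("%s kernel: sigma2=%.4g, l=%.4g, sigma_n2=%.4g\n",
                x$family, x$signal_variance, x$length_scale, x$noise_variance))
  }
  invisible(x)
}

# unit-variance component profiles
.k_rbf_unit <- function(d, l) exp(-d^2 / (2 * l^2))
.k_matern15_unit <- function(d, l) {
  s <- sqrt(3) * d / l
  (1 + s) * exp(-s)
}

#' Kernel covariance at a distance
#'
#' Evaluates the kernel's stationary profile k(d). The observation-noise term
#' is deliberately not included here; it enters only on the diagonal of
#' \code{\link{kernel_matrix}} (the Kronecker-delta noise term).
#'
#' @param spec a \code{kernel_spec}.
#' @param d non-negative distance(s) in pitch units; vectorized.
#' @return Covariance value(s); \code{kernel_value(spec, 0)} equals the
#'   signal variance for every family.
#' @export
kernel_value <- function(spec, d) {
  if (any(d < 0)) .stopf("distances must be non-negative")
  s2 <- spec$signal_variance
  switch(spec$family,
    rbf = s2 * .k_rbf_unit(d, spec$length_scale),
    matern15 = s2 * .k_matern15_unit(d, spec$length_scale),
    hybrid = s2 * (spec$mix_weight * .k_rbf_unit(d, spec$length_scale_rbf) +
                   (1 - spec$mix_weight) *
                     .k_matern15_unit(d, spec$length_scale_matern)))
}

#' Kernel covariance matrix between two point sets
#'
#' Entry (i, j) is \code{kernel_value(spec, ||x1_i - x2_j||)}. With
#' \code{include_noise = TRUE} the noise variance is added on the diagonal
#' (only valid when \code{X1} and \code{X2} index the same points), giving the
#' training covariance K + sigma_n^2 I.
#'
#' @param spec a \code{kernel_spec}.
#' @param X1,X2 numeric matrices of positions (rows = points, columns =
#'   coordinates); \code{X2} defaults to \code{X1}.
#' @param include_noise add the diagonal noise term.
#' @return A \code{nrow(X1) x nrow(X2)} covariance matrix; symmetric positive
#'   semi-definite when \code{X1 == X2}.
#' @export
kernel_matrix <- function(spec, X1, X2 = NULL, include_noise = FALSE) {
  X1 <- as.matrix(X1)
  if (is.null(X2)) X2 <- X1 else X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2))
    .stopf("position matrices must share coordinate dimension (%d vs %d)",
           ncol(X1), ncol(X2))
  # cross-distance via the expanded square; clamp round-off negatives
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  d <- sqrt(pmax(d2, 0))
  K <- kernel_value(spec, d)
  if (include_noise) {
    if (nrow(X1) != nrow(X2))
      .stopf("include_noise requires X1 and X2 to index the same points")
    K <- K + diag(spec$noise_variance, nrow(X1))
  }
  K
}
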