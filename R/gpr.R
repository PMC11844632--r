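#' Target transform for GP fitting
#'
#' Thresholds span more than an order of magnitude, so the model works on
#' log10 thresholds standardized to zero mean and unit variance over the
#' training electrodes. On that scale the default hyperparameter bounds
#' (signal variance 0.1-10) are meaningful. The descriptor stores the
#' centering constants for exact inversion.
#'
#' @param map a \code{threshold_map}.
#' @param ids training electrode ids (0-based, active and measured).
#' @param use_log apply log10 before standardizing (default TRUE).
#' @return List with \code{values} (transformed targets) and
#'   \code{transform} (descriptor: \code{use_log}, \code{center},
#'   \code{scale}, \code{scale_clamped}). A training set with zero spread
#'   gets \code{scale = 1} and \code{scale_clamped = TRUE} rather than an
#'   error.
#' @export
transform_targets <- function(map, ids, use_log = TRUE) {
  act <- .active_ids(map$grid)
  if (!all(ids %in% act)) .stopf("transform_targets: ids must be active electrodes")
  y <- .thr(map, ids)
  if (use_log) y <- log10(y)
  center <- mean(y)
  scale <- sqrt(mean((y - center)^2))  # population sd
  clamped <- FALSE
  if (!is.finite(scale) || scale < 1e-12) {
    scale <- 1
    clamped <- TRUE
  }
  list(values = (y - center) / scale,
       transform = list(use_log = use_log, center = center, scale = scale,
                        scale_clamped = clamped))
}

#' Invert the target transform
#'
#' Maps transformed-space values back to linear microamps (or to the raw
#' scale when the transform had \code{use_log = FALSE}).
#'
#' @param values transformed values.
#' @param transform descriptor from \code{\link{transform_targets}}.
#' @export
inverse_transform <- function(values, transform) {
  x <- values * transform$scale + transform$center
  if (transform$use_log) 10^x else x
}

# forward transform of raw uA values under an existing descriptor
.forward_transform <- function(values_uA, transform) {
  x <- if (transform$use_log) log10(values_uA) else values_uA
  (x - transform$center) / transform$scale
}

#' Gaussian-process log marginal likelihood
#'
#' LML = -1/2 y' K^-1 y - 1/2 log|K| - (n/2) log(2 pi), with
#' K the kernel matrix over X including the diagonal noise term. This is the
#' objective maximized during hyperparameter fitting.
#'
#' @param spec a \code{kernel_spec}.
#' @param X training positions (n x 2 matrix).
#' @param y transformed training targets (length n).
#' @param jitter diagonal regularizer added before factorization.
#' @return The LML scalar. Errors (with the offending parameters in the
#'   message) if K is not positive definite after jitter.
#' @export
log_marginal_likelihood <- function(spec, X, y, jitter = 1e-10) {
  v <- .lml(spec, X, y, jitter)
  if (!is.finite(v))
    .stopf(paste0("covariance matrix not positive definite ",
                  "(family=%s, sigma2=%g, sigma_n2=%g)"),
           spec$family, spec$signal_variance, spec$noise_variance)
  v
}

# internal LML: returns -Inf on factorization failure (used as optimizer
# penalty) instead of erroring
.lml <- function(spec, X, y, jitter = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  K <- kernel_matrix(spec, X, include_noise = TRUE) + diag(jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(-0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi))
}

# --- hyperparameter vectorization -------------------------------------------
# Positive parameters are optimized on the log scale; the hybrid mixing
# weight alpha stays on its natural [0, 1] scale.

.par_names <- function(family) {
  if (family == "hybrid")
    c("signal_variance", "length_scale_rbf", "length_scale_matern",
      "mix_weight", "noise_variance")
  else c("signal_variance", "length_scale", "noise_variance")
}

.spec_to_par <- function(spec) {
  nms <- .par_names(spec$family)
  vapply(nms, function(nm) {
    v <- spec[[nm]]
    if (nm == "mix_weight") v else log(v)
  }, 1.0)
}

.par_to_spec <- function(par, family, bounds) {
  nms <- .par_names(family)
  vals <- as.list(par)
  names(vals) <- nms
  for (nm in nms) if (nm != "mix_weight") vals[[nm]] <- exp(vals[[nm]])
  do.call(kernel_spec, c(list(family = family, bounds = bounds), vals))
}

.par_bounds <- function(family, bounds) {
  nms <- .par_names(family)
  lower <- vapply(nms, function(nm)
    if (nm == "mix_weight") bounds[[nm]][1] else log(bounds[[nm]][1]), 1.0)
  upper <- vapply(nms, function(nm)
    if (nm == "mix_weight") bounds[[nm]][2] else log(bounds[[nm]][2]), 1.0)
  list(lower = lower, upper = upper)
}

#' Fit a Gaussian-process threshold model
#'
#' The central fitting function. Thresholds at the training electrodes are
#' log10-standardized (see \code{\link{transform_targets}}), and the kernel
#' hyperparameters are chosen by maximizing the log marginal likelihood over
#' the bounded box via multi-start L-BFGS-B: one start at the spec's initial
#' values, the rest drawn log-uniformly within the bounds from the seeded
#' generator. Censored electrodes (recorded at the safety limit, true
#' threshold unknown) are excluded from training by default.
#'
#' @param map a \code{threshold_map}.
#' @param train_ids electrode ids to train on (0-based, active). Censored
#'   ids are dropped unless \code{include_censored}.
#' @param family kernel family (\code{"rbf"}, \code{"matern15"},
#'   \code{"hybrid"}).
#' @param use_log model log10 thresholds (default) rather than linear uA.
#' @param n_restarts number of optimizer starts (>= 1).
#' @param include_censored keep censored electrodes in the training set,
#'   taking the recorded maximum at face value.
#' @param seed integer seed driving the restart draws; fixed seed and inputs
#'   give an identical fit.
#' @param optimize if \code{FALSE}, skip LML maximization and use
#'   \code{spec}'s parameters as-is (useful for fixed-hyperparameter
#'   acquisition loops).
#' @param spec optional \code{kernel_spec} supplying initial values and
#'   bounds; default \code{kernel_spec(family)}.
#' @param jitter diagonal regularizer for the Cholesky factorization.
#' @return An object of class \code{gp_fit}; see
#'   \code{\link{predict.gp_fit}}, \code{coef}, \code{summary},
#'   \code{residuals}, \code{simulate} and \code{plot} methods.
#' @examples
#' map <- generate_map(make_preset("smooth", seed = 1))
#' plan <- sample_poisson_disk(map$grid, 20, seed = 2)
#' fit <- gp_fit(map, plan$ordered_ids, family = "matern15", seed = 3)
#' coef(fit)
#' @export
gp_fit <- function(map, train_ids, family = c("matern15", "rbf", "hybrid"),
                   use_log = TRUE, n_restarts = 10, include_censored = FALSE,
                   seed = 1, optimize = TRUE, spec = NULL, jitter = 1e-10) {
  family <- match.arg(family)
  train_ids <- as.integer(train_ids)
  act <- .active_ids(map$grid)
  if (!all(train_ids %in% act))
    .stopf("train_ids must be active electrode ids")
  if (anyDuplicated(train_ids)) .stopf("train_ids must be unique")
  if (!include_censored) {
    keep <- !map$censored[train_ids + 1L]
    train_ids <- train_ids[keep]
  }
  if (length(train_ids) < 1)
    .stopf("no usable training electrodes (all censored?)")
  if (length(train_ids) < 2)
    warning("fitting a GP on a single electrode; predictions revert to the prior",
            call. = FALSE)
  if (is.null(spec)) spec <- kernel_spec(family)
  if (spec$family != family) .stopf("spec family does not match 'family'")

  tt <- transform_targets(map, train_ids, use_log = use_log)
  X <- .grid_pos(map$grid, train_ids)
  y <- tt$values
  bounds <- spec$bounds
  lml_init <- .lml(spec, X, y, jitter)

  if (optimize && length(train_ids) >= 2) {
    pb <- .par_bounds(family, bounds)
    p0 <- pmin(pmax(.spec_to_par(spec), pb$lower), pb$upper)
    starts <- .with_seed(seed, {
      s <- list(p0)
      if (n_restarts > 1) for (i in 2:n_restarts)
        s[[i]] <- stats::runif(length(p0), pb$lower, pb$upper)
      s
    })
    objective <- function(par) {
      sp <- .par_to_spec(par, family, bounds)
      -.lml(sp, X, y, jitter)
    }
    best <- NULL
    for (st in starts) {
      res <- tryCatch(
        stats::optim(st, objective, method = "L-BFGS-B",
                     lower = pb$lower, upper = pb$upper,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      cand <- if (!is.null(res) && is.finite(res$value))
        list(par = res$par, value = res$value) else NULL
      # optimizer contract: never return a point worse than its start
      v0 <- objective(st)
      if (is.finite(v0) && (is.null(cand) || v0 < cand$value))
        cand <- list(par = st, value = v0)
      if (!is.null(cand) && (is.null(best) || cand$value < best$value))
        best <- cand
    }
    if (is.null(best))
      .stopf("GP fit failed: all %d optimizer restarts were numerically unstable",
             n_restarts)
    spec <- .par_to_spec(best$par, family, bounds)
    lml <- -best$value
  } else {
    lml <- lml_init
    if (!is.finite(lml))
      .stopf("covariance matrix not positive definite at the supplied parameters")
  }

  # cache the factorization for prediction
  n <- length(y)
  K <- kernel_matrix(spec, X, include_noise = TRUE) + diag(jitter, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))

  structure(
    list(kernel_spec = spec, family = family, transform = tt$transform,
         train_ids = train_ids, X = X, y = y, lml = lml,
         lml_init = lml_init, n_restarts = n_restarts, seed = as.integer(seed),
         optimized = optimize, jitter = jitter, map_label = map$label,
         grid = map$grid, chol_K = L, alpha = alpha,
         train_uA = .thr(map, train_ids)),
    class = "gp_fit")
}

#' Posterior prediction from a fitted GP
#'
#' Standard GP posterior in transformed space: mean k*' (K + sigma_n^2 I)^-1
#' y and predictive variance k** + sigma_n^2 - k*' (K + sigma_n^2 I)^-1 k*
#' (the noise term is treated as part of the kernel, so the reported
#' uncertainty is that of a new measurement); the mean is inverted back to
#' linear microamps. The posterior standard deviation (transformed space) is
#' the uncertainty used by adaptive sampling.
#'
#' @param object a \code{gp_fit}.
#' @param query_ids electrode ids to predict (0-based; default all active
#'   electrodes of the training grid). Inactive electrodes may be queried --
#'   predicting unmeasurable sites is the point of the model.
#' @param ... unused.
#' @return Data frame with \code{electrode_id}, \code{mean_uA},
#'   \code{mean_transformed}, \code{std_transformed}.
#' @export
predict.gp_fit <- function(object, query_ids = NULL, ...) {
  if (is.null(query_ids)) query_ids <- .active_ids(object$grid)
  query_ids <- as.integer(query_ids)
  if (length(query_ids) == 0)
    return(data.frame(electrode_id = integer(0), mean_uA = numeric(0),
                      mean_transformed = numeric(0),
                      std_transformed = numeric(0)))
  if (!all(query_ids %in% object$grid$electrode_ids))
    .stopf("query_ids must exist on the grid")
  Xq <- .grid_pos(object$grid, query_ids)
  Ks <- kernel_matrix(object$kernel_spec, Xq, object$X)   # n_q x n_train
  mean_t <- as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$chol_K), t(Ks))              # n_train x n_q
  # predictive (new-measurement) variance: latent variance plus the
  # observation-noise term, as when the noise is part of the kernel
  var_t <- object$kernel_spec$signal_variance +
    object$kernel_spec$noise_variance - colSums(V^2)
  if (any(var_t < -1e-10))
    warning("posterior variance clamped below -1e-10; ill-conditioned kernel",
            call. = FALSE)
  var_t <- pmax(var_t, 0)
  data.frame(electrode_id = query_ids,
             mean_uA = inverse_transform(mean_t, object$transform),
             mean_transformed = mean_t,
             std_transformed = sqrt(var_t))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("GP threshold model (%s kernel), %d training electrodes\n",
              x$family, length(x$train_ids)))
  print(x$kernel_spec)
  cat(sprintf("  log marginal likelihood: %.4f%s\n", x$lml,
              if (x$optimized) sprintf(" (%d restarts)", x$n_restarts) else
                " (fixed hyperparameters)"))
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) {
  sp <- object$kernel_spec
  nms <- .par_names(object$family)
  out <- vapply(nms, function(nm) sp[[nm]], 1.0)
  names(out) <- nms
  out
}

#' @export
summary.gp_fit <- function(object, ...) {
  pr <- predict(object, object$train_ids)
  res <- object$train_uA - pr$mean_uA
  out <- list(family = object$family, coef = coef(object),
              lml = object$lml, n_train = length(object$train_ids),
              transform = object$transform,
              train_mape = mape(object$train_uA, pr$mean_uA),
              resid_range_uA = range(res))
  class(out) <- "summary.gp_fit"
  out
}

#' @export
print.summary.gp_fit <- function(x, ...) {
  cat(sprintf("GP threshold model (%s kernel)\n", x$family))
  cat("Hyperparameters:\n")
  print(round(x$coef, 4))
  cat(sprintf("Training electrodes: %d   LML: %.4f\n", x$n_train, x$lml))
  cat(sprintf("In-sample MAPE: %.2f%%   residual range: [%.1f, %.1f] uA\n",
              x$train_mape, x$resid_range_uA[1], x$resid_range_uA[2]))
  invisible(x)
}

#' @export
residuals.gp_fit <- function(object, type = c("uA", "transformed"), ...) {
  type <- match.arg(type)
  pr <- predict(object, object$train_ids)
  if (type == "uA") object$train_uA - pr$mean_uA
  else object$y - pr$mean_transformed
}

#' Draw threshold maps from the GP posterior
#'
#' Joint draws from the posterior over the queried electrodes, returned in
#' linear microamps. Useful for visualizing calibration uncertainty.
#'
#' @param object a \code{gp_fit}.
#' @param nsim number of posterior draws.
#' @param seed RNG seed.
#' @param query_ids electrodes to simulate at (default all active).
#' @param ... unused.
#' @return Matrix of size \code{length(query_ids) x nsim} in uA.
#' @export
simulate.gp_fit <- function(object, nsim = 1, seed = 1, query_ids = NULL, ...) {
  if (is.null(query_ids)) query_ids <- .active_ids(object$grid)
  query_ids <- as.integer(query_ids)
  Xq <- .grid_pos(object$grid, query_ids)
  Ks <- kernel_matrix(object$kernel_spec, Xq, object$X)
  mean_t <- as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$chol_K), t(Ks))
  Kqq <- kernel_matrix(object$kernel_spec, Xq)
  Sigma <- Kqq - crossprod(V) +
    diag(object$kernel_spec$noise_variance, nrow(Kqq))
  Sigma <- (Sigma + t(Sigma)) / 2 + diag(1e-10, nrow(Sigma))
  Ls <- chol(Sigma)
  draws <- .with_seed(seed, {
    z <- matrix(stats::rnorm(nrow(Sigma) * nsim), nrow(Sigma), nsim)
    mean_t + t(Ls) %*% z
  })
  out <- apply(draws, 2, inverse_transform, transform = object$transform)
  out <- matrix(out, nrow = length(query_ids))
  rownames(out) <- query_ids
  out
}

#' Plot a fitted threshold map
#'
#' Image of the posterior-mean threshold over the full grid on a log color
#' scale, with training electrodes marked.
#'
#' @param x a \code{gp_fit}.
#' @param ... passed to \code{image}.
#' @export
plot.gp_fit <- function(x, ...) {
  g <- x$grid
  pr <- predict(x, g$electrode_ids)
  z <- matrix(log10(pr$mean_uA), nrow = g$n_cols, ncol = g$n_rows)
  graphics::image(x = (0:(g$n_cols - 1)) * g$pitch,
                  y = (0:(g$n_rows - 1)) * g$pitch, z = z,
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "column (pitch units)", ylab = "row (pitch units)",
                  main = sprintf("Predicted thresholds (log10 uA), %s kernel",
                                 x$family), ...)
  tr <- .grid_pos(g, x$train_ids)
  graphics::points(tr[, 1], tr[, 2], pch = 4, lwd = 2)
  invisible(x)
}
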