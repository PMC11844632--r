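# Synthetic threshold-map generator. Real perceptual threshold maps combine
# smooth global trends (gradual changes in tissue-electrode coupling) with
# sharp local discontinuities (scarring, poor contact); the generator
# emulates both so the full benchmark runs without any clinical data.

#' Configuration for the synthetic threshold-map generator
#'
#' The latent log10-threshold field is a draw from a spatially correlated
#' Gaussian field (squared-exponential covariance) around a constant
#' baseline, optionally perturbed by rectangular "patch" offsets that model
#' sharp local discontinuities. Independent per-electrode measurement noise
#' is added, values are converted to microamps, optionally snapped onto the
#' discrete amplitude ladder, clamped to the ladder range, and censored at
#' the maximum. Electrodes drop out as inactive with a fixed probability.
#'
#' @param n_rows,n_cols,pitch grid geometry (default 6 x 10, unit pitch).
#' @param field_length_scale correlation length of the latent field in
#'   pitch units.
#' @param field_sd standard deviation of the latent field (log10-uA units).
#' @param baseline mean latent level, log10-uA (default log10(150), mid-range
#'   thresholds).
#' @param patches list of patches, each
#'   \code{list(row, col, height, width, offset)} with 0-based top-left
#'   corner and additive log10 offset; the string \code{"random"} places one
#'   seeded random 2 x 3 patch with offset +0.5; \code{list()} disables
#'   patches.
#' @param dead_electrode_prob probability an electrode is inactive.
#' @param measurement_noise_sd per-electrode noise sd (log10-uA units).
#' @param ladder \code{\link{amplitude_ladder}} giving range and censoring
#'   limit.
#' @param snap_to_ladder snap thresholds to the nearest ladder value.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @param label map label.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_rows = 6, n_cols = 10, pitch = 1.0,
                             field_length_scale = 3.0, field_sd = 0.25,
                             baseline = log10(150), patches = "random",
                             dead_electrode_prob = 0.05,
                             measurement_noise_sd = 0.02,
                             ladder = amplitude_ladder(),
                             snap_to_ladder = TRUE, seed = 0,
                             label = NULL) {
  if (field_length_scale <= 0) .stopf("field_length_scale must be positive")
  if (field_sd < 0 || measurement_noise_sd < 0)
    .stopf("field_sd and measurement_noise_sd must be non-negative")
  if (dead_electrode_prob < 0 || dead_electrode_prob >= 1)
    .stopf("dead_electrode_prob must lie in [0, 1)")
  if (!identical(patches, "random") && !identical(patches, "random2")) {
    for (p in patches) {
      if (!all(c("row", "col", "height", "width", "offset") %in% names(p)))
        .stopf("each patch needs row, col, height, width, offset")
      if (p$row < 0 || p$col < 0 || p$row + p$height > n_rows ||
          p$col + p$width > n_cols)
        .stopf("patch [%d:%d, %d:%d] exceeds the %d x %d grid",
               p$row, p$row + p$height, p$col, p$col + p$width, n_rows, n_cols)
    }
  }
  if (is.null(label)) label <- sprintf("synthetic-seed%d", seed)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         field_length_scale = field_length_scale, field_sd = field_sd,
         baseline = baseline, patches = patches,
         dead_electrode_prob = dead_electrode_prob,
         measurement_noise_sd = measurement_noise_sd, ladder = ladder,
         snap_to_ladder = snap_to_ladder, seed = as.integer(seed),
         label = label),
    class = "synthetic_config")
}

#' Generator presets spanning the regimes of real threshold maps
#'
#' \describe{
#'   \item{smooth}{no patches: a purely smooth field, the easiest regime for
#'     interpolation.}
#'   \item{patchy}{two 2 x 3 patches with offsets +0.5 and -0.5: sharp local
#'     discontinuities on top of the smooth trend, the regime where a
#'     non-smooth (Matern) kernel helps.}
#'   \item{censored-heavy}{baseline raised to log10(500) so a substantial
#'     fraction of electrodes censors at the 677 uA limit.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed for the resulting config.
#' @param ... further overrides passed to \code{\link{synthetic_config}}.
#' @return A \code{synthetic_config}.
#' @export
make_preset <- function(name = c("smooth", "patchy", "censored-heavy"),
                        seed = 0, ...) {
  name <- match.arg(name)
  args <- switch(name,
    smooth = list(patches = list()),
    patchy = list(patches = "random2"),
    `censored-heavy` = list(patches = list(), baseline = log10(500)))
  args$seed <- seed
  args$label <- sprintf("%s-seed%d", name, seed)
  utils::modifyList(do.call(synthetic_config, args), list(...))
}

# resolve "random"/"random2" patch sentinels into concrete rectangles
# (must be called inside the seeded block)
.resolve_patches <- function(config) {
  p <- config$patches
  if (identical(p, "random") || identical(p, "random2")) {
    k <- if (identical(p, "random")) 1 else 2
    offs <- if (k == 1) 0.5 else c(0.5, -0.5)
    p <- lapply(seq_len(k), function(i) {
      list(row = sample(0:(config$n_rows - 2), 1),
           col = sample(0:(config$n_cols - 3), 1),
           height = 2, width = 3, offset = offs[i])
    })
  }
  p
}

#' Generate a synthetic threshold map
#'
#' Draws one map from the generative model described in
#' \code{\link{synthetic_config}}. Identical config (including seed) gives a
#' bit-identical map.
#'
#' @param config a \code{synthetic_config}.
#' @return A \code{threshold_map}.
#' @examples
#' map <- generate_map(make_preset("smooth", seed = 42))
#' map
#' @export
generate_map <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  full <- electrode_grid(config$n_rows, config$n_cols, config$pitch)
  n <- length(full$electrode_ids)
  D <- grid_distances(full)
  lad <- config$ladder

  out <- .with_seed(config$seed, {
    patches <- .resolve_patches(config)
    latent <- rep(config$baseline, n)
    if (config$field_sd > 0) {
      Sigma <- config$field_sd^2 *
        exp(-D^2 / (2 * config$field_length_scale^2)) + diag(1e-10, n)
      latent <- latent + as.numeric(t(chol(Sigma)) %*% stats::rnorm(n))
    }
    for (p in patches) {
      inside <- full$rows >= p$row & full$rows < p$row + p$height &
                full$cols >= p$col & full$cols < p$col + p$width
      latent[inside] <- latent[inside] + p$offset
    }
    observed <- latent
    if (config$measurement_noise_sd > 0)
      observed <- observed + stats::rnorm(n, 0, config$measurement_noise_sd)
    uA <- pmin(pmax(10^observed, lad$minimum), lad$maximum)
    if (config$snap_to_ladder) uA <- .snap_ladder(uA, lad)
    dead <- stats::runif(n) < config$dead_electrode_prob
    # a grid needs at least 2 active electrodes to be meaningful
    if (sum(!dead) < 2) dead[] <- FALSE
    list(uA = uA, dead = dead, patches = patches)
  })

  grid <- electrode_grid(config$n_rows, config$n_cols, config$pitch,
                         inactive_ids = full$electrode_ids[out$dead])
  thr <- out$uA
  thr[out$dead] <- NA
  threshold_map(grid, thr, ladder = lad, label = config$label)
}
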