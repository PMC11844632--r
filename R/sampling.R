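# Electrode-selection strategies: which electrodes to measure, in what order.

.new_plan <- function(strategy, ids, n_requested, seed, params) {
  structure(
    list(strategy = strategy, ordered_ids = as.integer(ids),
         n_requested = as.integer(n_requested), seed = as.integer(seed),
         params = params),
    class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("Sampling plan (%s): %d electrodes, seed %d\n",
              x$strategy, length(x$ordered_ids), x$seed))
  cat("  ids:", paste(x$ordered_ids, collapse = " "), "\n")
  invisible(x)
}

.check_sample_n <- function(grid, n) {
  n_act <- sum(grid$active)
  if (n < 1 || n > n_act)
    .stopf("requested %d electrodes but only %d are active", n, n_act)
}

#' Uniform random electrode sampling
#'
#' Baseline strategy: draws n distinct active electrodes uniformly without
#' replacement. Unbiased but prone to spatial clustering, which leaves grid
#' regions uncovered at small n.
#'
#' @param grid an \code{electrode_grid}.
#' @param n number of electrodes (1 to the active count).
#' @param seed RNG seed; same seed, same plan.
#' @return A \code{sampling_plan} with ids in draw order.
#' @export
sample_uniform <- function(grid, n, seed = 1) {
  .check_sample_n(grid, n)
  ids <- .with_seed(seed, sample(.active_ids(grid), n))
  .new_plan("uniform", ids, n, seed, list())
}

#' Poisson-disk (blue-noise) electrode sampling
#'
#' Spatially structured selection enforcing a minimum pairwise spacing,
#' adapted to the discrete electrode set. Starting from a seeded random
#' electrode, candidates are proposed inside the annulus
#' [r, annulus[2] * r] around already-selected electrodes and accepted only
#' if at least r away from every selected electrode; a frontier point retires
#' after \code{k_attempts} failed proposals. Because the benchmark needs
#' exactly n electrodes, when the process exhausts its frontier before
#' reaching n the radius shrinks by \code{shrink} and sampling resumes; the
#' final radius is recorded in \code{params$radius} and every pairwise
#' distance in the plan is at least that radius.
#'
#' @param grid an \code{electrode_grid}.
#' @param n number of electrodes.
#' @param seed RNG seed.
#' @param r0 initial disk radius in pitch units; default
#'   \code{sqrt(W * H / n)} for grid extent W x H.
#' @param annulus proposal annulus as multiples of the current radius
#'   (default \code{c(1, 2)}, the Bridson convention).
#' @param k_attempts proposal attempts per frontier electrode.
#' @param shrink radius shrink factor applied when the frontier empties
#'   before n electrodes are selected.
#' @return A \code{sampling_plan}; \code{params$radius} holds the final
#'   minimum-spacing radius.
#' @export
sample_poisson_disk <- function(grid, n, seed = 1, r0 = NULL,
                                annulus = c(1, 2), k_attempts = 30,
                                shrink = 0.8) {
  .check_sample_n(grid, n)
  act <- .active_ids(grid)
  pos <- .grid_pos(grid, act)
  if (is.null(r0)) {
    W <- grid$n_cols * grid$pitch
    H <- grid$n_rows * grid$pitch
    r0 <- sqrt(W * H / n)
  }
  D <- as.matrix(stats::dist(pos))  # distances among active electrodes
  eps <- 1e-9

  out <- .with_seed(seed, {
    r <- r0
    start <- sample(length(act), 1)
    selected <- start                 # indices into act
    frontier <- start
    while (length(selected) < n) {
      if (length(frontier) == 0) {
        r <- r * shrink
        frontier <- selected
        next
      }
      fi <- if (length(frontier) == 1) frontier else sample(frontier, 1)
      cand <- setdiff(which(D[fi, ] >= annulus[1] * r - eps &
                            D[fi, ] <= annulus[2] * r + eps), selected)
      accepted <- FALSE
      if (length(cand) > 0) {
        tries <- if (length(cand) == 1) cand else sample(cand)
        tries <- tries[seq_len(min(length(tries), k_attempts))]
        for (ci in tries) {
          if (all(D[ci, selected] >= r - eps)) {
            selected <- c(selected, ci)
            frontier <- c(frontier, ci)
            accepted <- TRUE
            break
          }
        }
      }
      if (!accepted) frontier <- setdiff(frontier, fi)
    }
    list(ids = act[selected], radius = r)
  })
  .new_plan("spatial", out$ids, n, seed,
            list(radius = out$radius, r0 = r0, annulus = annulus,
                 k_attempts = k_attempts, shrink = shrink))
}

#' Adaptive variance-based electrode sampling
#'
#' Uncertainty-driven acquisition: an initial uniformly drawn subset is
#' measured, a GP is fit on it, and the unmeasured active electrode with the
#' largest posterior standard deviation is selected next; the model is
#' refit after each addition until \code{n_total} electrodes are selected.
#' Ties in the acquisition are broken toward the lowest electrode id so
#' plans are deterministic.
#'
#' @param map a \code{threshold_map} (the strategy needs measured values to
#'   update the model, unlike the geometry-only strategies).
#' @param n_total total electrodes to select.
#' @param family kernel family used for the acquisition model.
#' @param n_init size of the uniformly drawn initial subset; with
#'   \code{n_total = n_init} the plan equals \code{sample_uniform}'s.
#' @param seed RNG seed (drives the initial draw and the per-step fits).
#' @param refit re-optimize hyperparameters each step (default); with
#'   \code{FALSE}, \code{spec}'s hyperparameters stay frozen, which is much
#'   faster and often adequate for acquisition.
#' @param spec optional \code{kernel_spec} (initial values, or the frozen
#'   values when \code{refit = FALSE}).
#' @param n_restarts optimizer restarts per refit.
#' @param use_log,include_censored passed to \code{\link{gp_fit}}.
#' @return A \code{sampling_plan}; ids are in selection order.
#' @export
sample_adaptive <- function(map, n_total, family = "matern15", n_init = 5,
                            seed = 1, refit = TRUE, spec = NULL,
                            n_restarts = 10, use_log = TRUE,
                            include_censored = FALSE) {
  grid <- map$grid
  .check_sample_n(grid, n_total)
  if (n_init < 1 || n_init > n_total)
    .stopf("n_init must lie in [1, n_total]")
  act <- .active_ids(grid)
  selected <- sample_uniform(grid, n_init, seed)$ordered_ids
  step <- 0L
  while (length(selected) < n_total) {
    step <- step + 1L
    fit <- gp_fit(map, selected, family = family, use_log = use_log,
                  n_restarts = n_restarts, include_censored = include_censored,
                  seed = .hash_seed(seed, "adaptive", step),
                  optimize = refit, spec = spec)
    rest <- sort(setdiff(act, selected))
    pr <- predict(fit, rest)
    nxt <- rest[which.max(pr$std_transformed)]  # first max = lowest id
    selected <- c(selected, nxt)
  }
  .new_plan("adaptive", selected, n_total, seed,
            list(n_init = n_init, family = family, refit = refit))
}

#' Write / read a sampling plan as JSON
#'
#' Serializes the plan (strategy, ordered ids, seed, strategy parameters) so
#' a benchmark run is exactly replayable.
#'
#' @param plan a \code{sampling_plan}.
#' @param path JSON file path.
#' @export
write_sampling_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sampling_plan
#' @export
read_sampling_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .new_plan(obj$strategy, obj$ordered_ids, obj$n_requested, obj$seed,
            as.list(obj$params))
}
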