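# Accuracy metric, the kernel x strategy x sample-size benchmark, and the
# paired nonparametric comparisons between benchmark conditions.

#' Mean absolute percent error
#'
#' MAPE = (1/N) * sum(|y_i - yhat_i| / y_i) * 100, computed in linear
#' microamps. Relative error weights electrodes comparably even when
#' thresholds span orders of magnitude.
#'
#' @param actual measured thresholds (uA, all > 0).
#' @param predicted predicted thresholds (same length).
#' @return MAPE in percent.
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10
#' @export
mape <- function(actual, predicted) {
  if (length(actual) == 0) .stopf("MAPE is undefined on empty input")
  if (length(actual) != length(predicted))
    .stopf("actual and predicted must have equal length")
  if (any(actual <= 0)) .stopf("MAPE requires strictly positive actual values")
  mean(abs(actual - predicted) / actual) * 100
}

#' Evaluate one train/test split
#'
#' Fits a GP on the plan's electrodes and scores MAPE on the held-out set:
#' active, non-censored electrodes not in the plan (censored electrodes are
#' excluded from scoring by default because their recorded value is only a
#' lower bound on the true threshold).
#'
#' @param map a \code{threshold_map}.
#' @param plan a \code{sampling_plan}.
#' @param family kernel family.
#' @param seed seed for the fit's optimizer restarts (default: the plan's).
#' @param use_log,n_restarts,include_censored passed to \code{\link{gp_fit}}.
#' @param include_censored_eval score censored electrodes too (sensitivity
#'   analysis only).
#' @return One-row data frame: \code{map_label, family, strategy, n_sampled,
#'   seed, mape, n_heldout, lml, valid}. When no held-out electrode is
#'   evaluable the row is flagged \code{valid = FALSE} with \code{NA} MAPE
#'   rather than dropped.
#' @export
evaluate_once <- function(map, plan, family = "matern15", seed = plan$seed,
                          use_log = TRUE, n_restarts = 10,
                          include_censored = FALSE,
                          include_censored_eval = FALSE) {
  fit <- gp_fit(map, plan$ordered_ids, family = family, use_log = use_log,
                n_restarts = n_restarts, include_censored = include_censored,
                seed = seed)
  heldout <- setdiff(.measured_ids(map, include_censored = include_censored_eval),
                     plan$ordered_ids)
  if (length(heldout) == 0) {
    return(data.frame(map_label = map$label, family = family,
                      strategy = plan$strategy,
                      n_sampled = length(plan$ordered_ids),
                      seed = seed, mape = NA_real_, n_heldout = 0L,
                      lml = fit$lml, valid = FALSE,
                      stringsAsFactors = FALSE))
  }
  pr <- predict(fit, heldout)
  m <- mape(.thr(map, heldout), pr$mean_uA)
  data.frame(map_label = map$label, family = family, strategy = plan$strategy,
             n_sampled = length(plan$ordered_ids), seed = seed, mape = m,
             n_heldout = length(heldout), lml = fit$lml, valid = TRUE,
             stringsAsFactors = FALSE)
}

# build a plan for one benchmark cell
.make_plan <- function(map, strategy, n, seed, family = "matern15",
                       adaptive_opts = list()) {
  switch(strategy,
    uniform = sample_uniform(map$grid, n, seed),
    spatial = sample_poisson_disk(map$grid, n, seed),
    adaptive = do.call(sample_adaptive,
                       c(list(map = map, n_total = n, family = family,
                              seed = seed), adaptive_opts)),
    .stopf("unknown sampling strategy '%s'", strategy))
}

#' Run the kernel x strategy x sample-size benchmark
#'
#' For every combination of map, strategy, training-set size and iteration, a
#' sampling plan is drawn with a seed derived deterministically from
#' \code{base_seed} and the cell's coordinates, the GP is fit for each kernel
#' family and scored on the held-out electrodes. The plan seed is shared
#' across families, so kernel comparisons are paired on identical training
#' sets (for the geometry-driven strategies the plans themselves are
#' identical; the adaptive strategy rebuilds its model-dependent plan per
#' family from the same seed).
#'
#' @param maps a \code{threshold_map} or list of them.
#' @param families kernel families to compare.
#' @param strategies sampling strategies (\code{"uniform"},
#'   \code{"spatial"}, \code{"adaptive"}).
#' @param n_grid training-set sizes.
#' @param iterations repeats per cell (re-randomizing plan and optimizer).
#' @param base_seed root seed for the whole run.
#' @param n_restarts,use_log,include_censored passed to the per-cell fits.
#' @param adaptive_opts extra arguments for \code{\link{sample_adaptive}}
#'   (e.g. \code{list(refit = FALSE, spec = ...)}).
#' @param record_file optional CSV path; each record is appended as soon as
#'   it is computed so an interrupted run leaves a valid partial table.
#' @param verbose print progress lines.
#' @return An object of class \code{benchmark_result} holding the long-form
#'   record table; see \code{summary} and \code{plot} methods and
#'   \code{\link{compare_wilcoxon}}.
#' @export
run_benchmark <- function(maps, families = c("rbf", "matern15", "hybrid"),
                          strategies = c("uniform", "spatial", "adaptive"),
                          n_grid = c(10, 20, 30, 40, 50), iterations = 10,
                          base_seed = 0, n_restarts = 10, use_log = TRUE,
                          include_censored = FALSE, adaptive_opts = list(),
                          record_file = NULL, verbose = FALSE) {
  if (inherits(maps, "threshold_map")) maps <- list(maps)
  labels <- vapply(maps, function(m) m$label, "")
  if (anyDuplicated(labels)) .stopf("map labels must be unique")
  rows <- list()
  wrote_header <- FALSE
  for (mi in seq_along(maps)) {
    map <- maps[[mi]]
    n_usable <- length(.measured_ids(map, include_censored = include_censored))
    for (strategy in strategies) {
      for (n in n_grid) {
        for (iter in seq_len(iterations)) {
          plan_seed <- .hash_seed(base_seed, map$label, strategy, n, iter)
          for (family in families) {
            rec <- tryCatch({
              plan <- .make_plan(map, strategy, n, plan_seed,
                                 family = family,
                                 adaptive_opts = adaptive_opts)
              evaluate_once(map, plan, family = family,
                            seed = .hash_seed(plan_seed, family),
                            use_log = use_log, n_restarts = n_restarts,
                            include_censored = include_censored)
            }, error = function(e) {
              data.frame(map_label = map$label, family = family,
                         strategy = strategy, n_sampled = n,
                         seed = plan_seed, mape = NA_real_, n_heldout = 0L,
                         lml = NA_real_, valid = FALSE,
                         stringsAsFactors = FALSE)
            })
            rec$seed <- plan_seed   # the pairing key shared across families
            rec$iteration <- iter
            rows[[length(rows) + 1]] <- rec
            if (!is.null(record_file)) {
              utils::write.table(rec, record_file, sep = ",",
                                 col.names = !wrote_header,
                                 row.names = FALSE, append = wrote_header)
              wrote_header <- TRUE
            }
            if (verbose)
              cat(sprintf("%s %s %s n=%d iter=%d mape=%.2f\n", map$label,
                          strategy, family, n, iter, rec$mape))
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  structure(
    list(records = records, families = families, strategies = strategies,
         n_grid = n_grid, iterations = iterations, base_seed = base_seed),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d records (%d maps x %d strategies x %d kernels x %d sizes x %d iterations)\n",
              nrow(x$records), length(unique(x$records$map_label)),
              length(x$strategies), length(x$families), length(x$n_grid),
              x$iterations))
  invisible(x)
}

#' Aggregate a benchmark to mean and SEM per cell
#'
#' @param object a \code{benchmark_result}.
#' @param by_map keep maps separate (default) or pool them.
#' @param ... unused.
#' @return Data frame with mean MAPE, SEM (sample sd / sqrt(records)) and
#'   record count per (map,) family, strategy, n cell; invalid records are
#'   excluded.
#' @export
summary.benchmark_result <- function(object, by_map = TRUE, ...) {
  rec <- object$records[object$records$valid, ]
  keys <- c(if (by_map) "map_label", "family", "strategy", "n_sampled")
  agg <- stats::aggregate(rec["mape"], rec[keys], function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- cbind(agg[keys], as.data.frame(agg$mape))
  names(out) <- c(keys, "mean_mape", "sem", "n_records")
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Write benchmark tables to CSV
#'
#' @param result a \code{benchmark_result}.
#' @param long_path path for the long-form record table.
#' @param summary_path optional path for the mean/SEM summary.
#' @export
write_benchmark <- function(result, long_path, summary_path = NULL) {
  utils::write.csv(result$records, long_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(summary.benchmark_result(result), summary_path,
                     row.names = FALSE)
  invisible(long_path)
}

#' Plot MAPE against the number of sampled electrodes
#'
#' One line per kernel family with SEM error bars, for a chosen map and
#' strategy; dashed horizontal references at 10/15/20/50 percent MAPE.
#'
#' @param x a \code{benchmark_result}.
#' @param map_label map to plot (default: first).
#' @param strategy strategy to plot (default: first).
#' @param ref_levels dashed reference MAPE levels.
#' @param ... passed to \code{matplot}.
#' @export
plot.benchmark_result <- function(x, map_label = NULL, strategy = NULL,
                                  ref_levels = c(10, 15, 20, 50), ...) {
  s <- summary.benchmark_result(x)
  if (is.null(map_label)) map_label <- s$map_label[1]
  if (is.null(strategy)) strategy <- s$strategy[1]
  s <- s[s$map_label == map_label & s$strategy == strategy, ]
  fams <- sort(unique(s$family))
  ns <- sort(unique(s$n_sampled))
  M <- sapply(fams, function(f) {
    sf <- s[s$family == f, ]
    sf$mean_mape[match(ns, sf$n_sampled)]
  })
  cols <- seq_along(fams)
  graphics::matplot(ns, M, type = "b", pch = 19, lty = 1, col = cols,
                    xlab = "sampled electrodes", ylab = "MAPE (%)",
                    main = sprintf("%s / %s sampling", map_label, strategy),
                    ...)
  for (j in seq_along(fams)) {
    sf <- s[s$family == fams[j], ]
    sem <- sf$sem[match(ns, sf$n_sampled)]
    graphics::arrows(ns, M[, j] - sem, ns, M[, j] + sem, angle = 90,
                     code = 3, length = 0.03, col = cols[j])
  }
  graphics::abline(h = ref_levels, lty = 2, col = "grey60")
  graphics::legend("topright", legend = fams, col = cols, lty = 1, pch = 19,
                   bty = "n")
  invisible(x)
}

# exact two-sided signed-rank p-value by convolution over the rank-sum
# distribution (handles average ranks for ties; ranks doubled to integers)
.signed_rank_exact_p <- function(d) {
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  r2 <- round(2 * r)                   # integer weights
  total <- sum(r2)
  # distribution of sum of a random subset of r2 (each included w.p. 1/2)
  probs <- c(1, rep(0, total))         # probs[s + 1] = P(sum = s)
  for (w in r2) {
    shifted <- c(rep(0, w), probs[seq_len(length(probs) - w)])
    probs <- 0.5 * probs + 0.5 * shifted
  }
  mu <- total / 2
  dev <- abs(round(2 * v) - mu)
  support <- 0:total
  sum(probs[abs(support - mu) >= dev - 1e-9])
}

#' Paired Wilcoxon signed-rank comparison of two benchmark conditions
#'
#' Compares MAPE between two conditions differing in exactly one factor
#' (kernel family or sampling strategy), pairing records on map, the other
#' factor, training-set size and iteration. Zero differences are dropped
#' (classic Wilcoxon convention). The null distribution is exact (by
#' enumeration over sign assignments, tie-aware) for up to 25 non-zero
#' pairs and a normal approximation with continuity and tie correction
#' beyond that.
#'
#' @param result a \code{benchmark_result}.
#' @param condition_a,condition_b one-element named lists selecting the
#'   contrast, e.g. \code{list(family = "matern15")} vs
#'   \code{list(family = "rbf")}; both must name the same single factor.
#' @param scope \code{"pooled"} (all maps) or one map label.
#' @return List with \code{statistic} (V, the positive-rank sum),
#'   \code{p.value}, \code{n_pairs} (non-zero pairs), \code{estimate}
#'   (median paired MAPE difference, a - b), \code{method}, and
#'   \code{undefined = TRUE} when no non-zero pair exists.
#' @export
compare_wilcoxon <- function(result, condition_a, condition_b,
                             scope = "pooled") {
  if (length(condition_a) != 1 || length(condition_b) != 1 ||
      !identical(names(condition_a), names(condition_b)))
    .stopf("conditions must each set the same single factor (family or strategy)")
  factor_name <- names(condition_a)
  if (!factor_name %in% c("family", "strategy"))
    .stopf("contrast factor must be 'family' or 'strategy'")
  rec <- result$records[result$records$valid, ]
  if (!identical(scope, "pooled")) rec <- rec[rec$map_label == scope, ]
  keys <- setdiff(c("map_label", "family", "strategy", "n_sampled", "iteration"),
                  factor_name)
  a <- rec[rec[[factor_name]] == condition_a[[1]], c(keys, "mape")]
  b <- rec[rec[[factor_name]] == condition_b[[1]], c(keys, "mape")]
  m <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
  d <- m$mape_a - m$mape_b
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) < 1)
    return(list(statistic = NA_real_, p.value = NA_real_,
                n_pairs = 0L, estimate = NA_real_,
                method = "undefined (no non-zero pairs)", undefined = TRUE))
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  n <- length(nz)
  if (n <= 25) {
    p <- .signed_rank_exact_p(nz)
    method <- "exact signed-rank (tie-aware enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = v, p.value = min(p, 1), n_pairs = n,
       estimate = stats::median(d), method = method, undefined = FALSE)
}
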