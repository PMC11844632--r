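#' Rectangular electrode-grid geometry
#'
#' Builds the discrete 2-D geometry of an implant electrode array. Electrode
#' ids are row-major integers starting at 0; electrode (r, c) sits at position
#' (c * pitch, r * pitch), so with the default unit pitch all distances are
#' expressed in inter-electrode spacings. The default 6 x 10 layout matches
#' the Argus II epiretinal array.
#'
#' @param n_rows,n_cols grid dimensions (counts, >= 1).
#' @param pitch center-to-center electrode spacing (> 0); the distance unit
#'   for all kernels and sampling radii.
#' @param inactive_ids integer ids of electrodes without measurable
#'   thresholds (broken or disconnected); masked out of sampling and fitting.
#' @return An object of class \code{electrode_grid}: ids, row/col indices,
#'   an \code{n x 2} position matrix and an active mask.
#' @examples
#' g <- electrode_grid()                 # 6 x 10, all 60 active
#' g2 <- electrode_grid(inactive_ids = c(0, 59))
#' sum(g2$active)                        # 58
#' @export
electrode_grid <- function(n_rows = 6, n_cols = 10, pitch = 1.0,
                           inactive_ids = integer(0)) {
  if (n_rows < 1 || n_cols < 1) .stopf("grid must have at least 1 row and 1 column")
  if (pitch <= 0) .stopf("pitch must be positive")
  n <- n_rows * n_cols
  ids <- 0:(n - 1)
  rows <- ids %/% n_cols
  cols <- ids %% n_cols
  positions <- cbind(x = cols * pitch, y = rows * pitch)
  inactive_ids <- as.integer(inactive_ids)
  if (length(inactive_ids) && (any(inactive_ids < 0) || any(inactive_ids >= n)))
    .stopf("inactive_ids must be electrode ids in [0, %d]", n - 1)
  active <- !(ids %in% inactive_ids)
  if (sum(active) < 2)
    .stopf("invalid grid: fewer than 2 active electrodes")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         electrode_ids = ids, rows = rows, cols = cols,
         positions = positions, active = active),
    class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("Electrode grid: %d x %d (pitch %g), %d/%d active\n",
              x$n_rows, x$n_cols, x$pitch, sum(x$active),
              length(x$electrode_ids)))
  invisible(x)
}

#' Pairwise electrode distances
#'
#' Euclidean distance matrix between all electrode positions, in pitch units.
#'
#' @param grid an \code{electrode_grid}.
#' @return A symmetric matrix with zero diagonal, indexed in id order.
#' @export
grid_distances <- function(grid) {
  as.matrix(stats::dist(grid$positions))
}

# positions of a set of electrode ids (0-based) as an n x 2 matrix
.grid_pos <- function(grid, ids) {
  grid$positions[match(ids, grid$electrode_ids), , drop = FALSE]
}

.active_ids <- function(grid) grid$electrode_ids[grid$active]

#' Logarithmic stimulus amplitude ladder
#'
#' The discrete set of current amplitudes a threshold estimate can take:
#' \code{n_steps} log-spaced values from \code{minimum} to \code{maximum}
#' inclusive (a geometric sequence). The default 40-677 uA / 60-step ladder is
#' the Argus II calibration range; 677 uA is the device safety limit at which
#' thresholds are censored.
#'
#' @param minimum,maximum range endpoints in uA (0 < minimum < maximum).
#' @param n_steps number of ladder values (>= 2).
#' @return An object of class \code{amplitude_ladder} with a \code{values}
#'   vector.
#' @export
amplitude_ladder <- function(minimum = 40, maximum = 677, n_steps = 60) {
  if (minimum <= 0) .stopf("ladder minimum must be positive (log spacing)")
  if (maximum <= minimum) .stopf("ladder maximum must exceed minimum")
  if (n_steps < 2) .stopf("ladder needs at least 2 steps")
  values <- 10^seq(log10(minimum), log10(maximum), length.out = n_steps)
  values[1] <- minimum
  values[n_steps] <- maximum
  structure(list(minimum = minimum, maximum = maximum,
                 n_steps = as.integer(n_steps), values = values),
            class = "amplitude_ladder")
}

#' @export
print.amplitude_ladder <- function(x, ...) {
  cat(sprintf("Amplitude ladder: %d log-spaced steps, %g-%g uA\n",
              x$n_steps, x$minimum, x$maximum))
  invisible(x)
}

# nearest ladder value in log space (the ladder is geometric)
.snap_ladder <- function(values_uA, ladder) {
  lv <- log10(ladder$values)
  idx <- vapply(log10(values_uA), function(v) which.min(abs(lv - v)), 1L)
  ladder$values[idx]
}

#' Per-electrode perceptual threshold map
#'
#' Couples an electrode grid with measured perceptual thresholds (uA) and
#' censoring flags. Thresholds exist only on active electrodes and live on
#' the amplitude ladder's range; an electrode whose true threshold exceeds
#' the ladder maximum is recorded at that maximum and flagged censored.
#'
#' @param grid an \code{electrode_grid}.
#' @param thresholds numeric vector, one entry per electrode in id order
#'   (uA); must be \code{NA} exactly on inactive electrodes.
#' @param censored optional logical vector per electrode; if omitted, derived
#'   as \code{thresholds == ladder$maximum}. Must agree with that rule.
#' @param ladder the \code{amplitude_ladder} defining the valid range.
#' @param pulse_width_ms,frequency_hz stimulus metadata (fixed-pulse
#'   calibration protocol; frequency is typically 6 or 20 Hz).
#' @param label free-text identifier used in benchmark tables.
#' @return An object of class \code{threshold_map}.
#' @export
threshold_map <- function(grid, thresholds, censored = NULL,
                          ladder = amplitude_ladder(),
                          pulse_width_ms = 0.45, frequency_hz = 20,
                          label = "map") {
  n <- length(grid$electrode_ids)
  if (length(thresholds) != n)
    .stopf("thresholds must have one entry per electrode (%d)", n)
  if (any(is.na(thresholds) != !grid$active))
    .stopf("thresholds must be defined exactly on active electrodes")
  meas <- thresholds[grid$active]
  if (any(meas < ladder$minimum - 1e-9) || any(meas > ladder$maximum + 1e-9))
    .stopf("thresholds must lie within the ladder range [%g, %g] uA",
           ladder$minimum, ladder$maximum)
  at_max <- !is.na(thresholds) & abs(thresholds - ladder$maximum) < 1e-9
  if (is.null(censored)) {
    censored <- at_max
  } else {
    censored <- as.logical(censored)
    if (length(censored) != n)
      .stopf("censored must have one entry per electrode")
    censored[!grid$active] <- FALSE
    if (any(censored != at_max))
      .stopf("censored flag must be TRUE exactly where threshold equals the %g uA maximum",
             ladder$maximum)
  }
  censored[!grid$active] <- FALSE
  structure(
    list(grid = grid, thresholds = thresholds, censored = censored,
         ladder = ladder, pulse_width_ms = pulse_width_ms,
         frequency_hz = frequency_hz, label = label),
    class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  act <- x$grid$active
  cat(sprintf("Threshold map '%s': %d x %d grid, %d active, %d censored\n",
              x$label, x$grid$n_rows, x$grid$n_cols, sum(act),
              sum(x$censored)))
  cat(sprintf("  thresholds %.1f-%.1f uA; pulse %g ms at %g Hz\n",
              min(x$thresholds[act]), max(x$thresholds[act]),
              x$pulse_width_ms, x$frequency_hz))
  invisible(x)
}

# measured (active) ids; optionally excluding censored electrodes
.measured_ids <- function(map, include_censored = TRUE) {
  ids <- .active_ids(map$grid)
  if (!include_censored) ids <- ids[!map$censored[ids + 1L]]
  ids
}

# threshold lookup by 0-based id
.thr <- function(map, ids) map$thresholds[ids + 1L]

#' Write a threshold map to CSV or JSON
#'
#' CSV has one row per electrode with columns \code{electrode_id, row, col,
#' active, threshold_uA, censored} (threshold empty on inactive electrodes).
#' JSON mirrors the same fields plus the stimulus metadata and grid pitch.
#' Values round-trip exactly through \code{\link{read_threshold_map}}.
#'
#' @param map a \code{threshold_map}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}; inferred from the file
#'   extension by default.
#' @export
write_threshold_map <- function(map, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  g <- map$grid
  thr <- ifelse(is.na(map$thresholds), "",
                sprintf("%.17g", map$thresholds))
  df <- data.frame(electrode_id = g$electrode_ids, row = g$rows, col = g$cols,
                   active = as.integer(g$active), threshold_uA = thr,
                   censored = as.integer(map$censored))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(n_rows = g$n_rows, n_cols = g$n_cols, pitch = g$pitch,
                pulse_width_ms = map$pulse_width_ms,
                frequency_hz = map$frequency_hz, label = map$label,
                ladder = list(minimum = map$ladder$minimum,
                              maximum = map$ladder$maximum,
                              n_steps = map$ladder$n_steps),
                electrodes = df)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a threshold map written by \code{\link{write_threshold_map}}
#'
#' @param path CSV or JSON file path.
#' @param pitch electrode pitch to assume for CSV input (the CSV schema does
#'   not carry it); ignored for JSON.
#' @param ladder amplitude ladder to attach for CSV input; ignored for JSON.
#' @param label map label for CSV input.
#' @return A \code{threshold_map}.
#' @export
read_threshold_map <- function(path, pitch = 1.0, ladder = amplitude_ladder(),
                               label = basename(path)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- obj$electrodes
    grid <- electrode_grid(obj$n_rows, obj$n_cols, obj$pitch,
                           inactive_ids = df$electrode_id[df$active == 0])
    lad <- amplitude_ladder(obj$ladder$minimum, obj$ladder$maximum,
                            obj$ladder$n_steps)
    thr <- suppressWarnings(as.numeric(df$threshold_uA))
    return(threshold_map(grid, thr[order(df$electrode_id)],
                         ladder = lad, pulse_width_ms = obj$pulse_width_ms,
                         frequency_hz = obj$frequency_hz, label = obj$label))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("electrode_id", "row", "col", "active", "threshold_uA", "censored")
  if (!all(need %in% names(df)))
    .stopf("threshold-map CSV must have columns: %s", paste(need, collapse = ", "))
  df <- df[order(df$electrode_id), ]
  n_rows <- max(df$row) + 1L
  n_cols <- max(df$col) + 1L
  grid <- electrode_grid(n_rows, n_cols, pitch,
                         inactive_ids = df$electrode_id[df$active == 0])
  thr <- suppressWarnings(as.numeric(df$threshold_uA))
  threshold_map(grid, thr, ladder = ladder, label = label)
}
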