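#' Canonical per-sensor feature names, in extraction order
#' @export
FEATURE_NAMES <- c("sharpe_fwd_25", "sharpe_back_25", "sharpe_fwd_50",
                   "sharpe_back_50", "min_derivative", "max_derivative",
                   "integral", "delta_r", "log_sum", "minimum", "maximum")

#' Sharpe-style variability index
#'
#' Ratio between the mean and the (sample) standard deviation of a leading
#' or trailing window of the signal. The window holds the first (forward)
#' or last (back) `ceiling(fraction * n)` points, which guarantees a
#' non-empty window for any fraction > 0.
#'
#' @param values Numeric signal.
#' @param fraction Window fraction, conventionally 0.25 or 0.5.
#' @param direction `"forward"` (leading window) or `"back"` (trailing).
#' @return mean/SD over the window.
#' @examples
#' sharpe(c(1, 2, 3, 4), 0.5, "forward")  # 1.5 / sd(c(1,2)) = 2.1213
#' sharpe(c(1, 2, 3, 4), 0.5, "back")     # 3.5 / sd(c(3,4)) = 4.9497
#' @export
sharpe <- function(values, fraction, direction = c("forward", "back")) {
  direction <- match.arg(direction)
  n <- length(values)
  w <- ceiling(fraction * n)
  if (w < 2)
    stop("sharpe window must hold at least 2 points", call. = FALSE)
  win <- if (direction == "forward") values[seq_len(w)]
         else values[seq.int(n - w + 1L, n)]
  s <- stats::sd(win)
  if (!is.finite(s) || s == 0)
    stop(structure(
      class = c("voclass_undefined_feature", "error", "condition"),
      list(message = sprintf("sharpe undefined: zero SD in %s %d%% window",
                             direction, round(100 * fraction)),
           call = sys.call(-1))))
  mean(win) / s
}

#' Extrema of the first derivative
#'
#' Minimum and maximum of the first finite differences dv/dt of the signal
#' over the given interval.
#'
#' @param values Numeric signal (>= 2 points).
#' @param times Matching time stamps in seconds.
#' @return Named numeric: `min_derivative`, `max_derivative` (units 1/s).
#' @export
derivative_extrema <- function(values, times) {
  if (length(values) < 2L || length(values) != length(times))
    stop("need at least two (value, time) pairs", call. = FALSE)
  d <- diff(values) / diff(times)
  c(min_derivative = min(d), max_derivative = max(d))
}

#' Trapezoidal integral of a sampled signal
#'
#' @param values Numeric signal (>= 2 points).
#' @param times Matching time stamps in seconds.
#' @return Area in value-seconds.
#' @export
trace_integral <- function(values, times) {
  if (length(values) < 2L || length(values) != length(times))
    stop("need at least two (value, time) pairs", call. = FALSE)
  pracma::trapz(times, values)
}

#' Extract the eleven per-sensor descriptors
#'
#' Computes, on a normalized trace: the four Sharpe-style indices
#' (leading/trailing 25% and 50% windows of the full track), the derivative
#' extrema and trapezoidal integral over the analysis interval (where the
#' gas interaction happens), the max-minus-min excursion `delta_r`, the sum
#' of natural logarithms `log_sum` (valid because R/R0 > 0), and the track
#' minimum and maximum.
#'
#' The analysis interval for the derivative/integral features is the closed
#' time window `[t1, t1 + analysis_s]`, including the boundary sample at the
#' start of recovery when one exists, so its integration span equals the
#' scheduled analysis duration. `interval = "full"` switches both features
#' to the whole track.
#'
#' @param ntrace A [normalize_trace()] result.
#' @param interval Interval policy for derivative/integral: `"analysis"`
#'   (default) or `"full"`.
#' @param log_sum_mode `"sum_log"` (default, sum of logs) or `"log_sum"`
#'   (log of the sum).
#' @param sentinel Value substituted (with a warning) when a Sharpe index is
#'   undefined because its window has zero SD.
#' @return Named numeric vector of length 11 in [FEATURE_NAMES] order.
#' @export
extract_features <- function(ntrace, interval = c("analysis", "full"),
                             log_sum_mode = c("sum_log", "log_sum"),
                             sentinel = 0) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  interval <- match.arg(interval)
  log_sum_mode <- match.arg(log_sum_mode)
  v <- ntrace$r_over_r0
  t <- ntrace$time_s
  sch <- ntrace$schedule
  t1 <- sch$stabilization_s
  t2 <- t1 + sch$analysis_s
  idx <- if (interval == "analysis") which(t >= t1 & t <= t2)
         else seq_along(v)

  safe_sharpe <- function(fraction, direction) {
    tryCatch(sharpe(v, fraction, direction),
             voclass_undefined_feature = function(e) {
               warning(conditionMessage(e), "; substituting sentinel ",
                       sentinel, call. = FALSE)
               sentinel
             })
  }
  der <- derivative_extrema(v[idx], t[idx])
  out <- c(
    sharpe_fwd_25 = safe_sharpe(0.25, "forward"),
    sharpe_back_25 = safe_sharpe(0.25, "back"),
    sharpe_fwd_50 = safe_sharpe(0.5, "forward"),
    sharpe_back_50 = safe_sharpe(0.5, "back"),
    der["min_derivative"], der["max_derivative"],
    integral = trace_integral(v[idx], t[idx]),
    delta_r = max(v) - min(v),
    log_sum = if (log_sum_mode == "sum_log") sum(log(v)) else log(sum(v)),
    minimum = min(v),
    maximum = max(v))
  names(out) <- FEATURE_NAMES
  out
}

#' Assemble the cycle-by-feature matrix
#'
#' Normalizes every trace of every cycle and stacks the per-sensor feature
#' blocks into one row per cycle. Columns are sensor-major
#' (`<sensor_id>__<feature>`), 6 x 11 = 66 for the standard array, in a
#' deterministic order taken from the first cycle.
#'
#' @param cycles List of `measurement_cycle` objects sharing one sensor
#'   layout.
#' @param labels Optional class labels (one per cycle); defaults to each
#'   cycle's `class` field.
#' @param standardize If TRUE, center/scale each column (recorded in
#'   attributes `center`/`scale`).
#' @param ... Passed to [extract_features()].
#' @return List with `features` (numeric matrix, rows named by cycle id)
#'   and `labels` (factor).
#' @export
build_feature_matrix <- function(cycles, labels = NULL, standardize = FALSE,
                                 ...) {
  if (length(cycles) == 0L) stop("no cycles supplied", call. = FALSE)
  sensors <- names(cycles[[1]]$traces)
  rows <- lapply(cycles, function(cy) {
    if (!identical(names(cy$traces), sensors))
      stop("cycle ", cy$cycle_id, " has a different sensor set",
           call. = FALSE)
    unlist(lapply(cy$traces, function(tr)
      extract_features(normalize_trace(tr), ...)))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- as.vector(t(outer(sensors, FEATURE_NAMES, paste,
                                   sep = "__")))
  rownames(X) <- unname(vapply(cycles, `[[`, character(1), "cycle_id"))
  if (is.null(labels))
    labels <- vapply(cycles, `[[`, character(1), "class")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- scale(X, center = ctr, scale = scl)
    attr(X, "center") <- ctr
    attr(X, "scale") <- scl
  }
  list(features = X, labels = factor(labels))
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated, one header line; feature columns named
#' `<sensor_id>__<feature>` plus a trailing `class` label column.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a list with `features` and `labels`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(cycle_id = rownames(fm$features), fm$features,
                   class = as.character(fm$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("cycle_id", "class")),
                    drop = FALSE])
  rownames(X) <- df$cycle_id
  list(features = X, labels = factor(df$class))
}
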