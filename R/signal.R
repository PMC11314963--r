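#' Sensor resistance trace
#'
#' Container for one sensor's resistance time series over a measurement
#' cycle. Time starts at 0 and increases strictly; resistances are positive.
#'
#' @param sensor_id Sensor label.
#' @param time_s Time in seconds, starting at 0, strictly increasing.
#' @param resistance_ohm Resistance in Ohm, all > 0, same length as `time_s`.
#' @param schedule The [phase_schedule()] the cycle was recorded under.
#' @param doping Optional sensing-layer doping label (metadata).
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(sensor_id, time_s, resistance_ohm, schedule,
                         doping = NA_character_) {
  if (length(time_s) == 0L || length(time_s) != length(resistance_ohm))
    stop("time_s and resistance_ohm must be non-empty and equal length",
         call. = FALSE)
  if (time_s[1] != 0) stop("time must start at 0", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(resistance_ohm)) || any(resistance_ohm <= 0))
    stop("resistances must be finite and > 0", call. = FALSE)
  stopifnot(inherits(schedule, "phase_schedule"))
  structure(
    list(sensor_id = as.character(sensor_id), time_s = time_s,
         resistance_ohm = resistance_ohm, schedule = schedule,
         doping = doping),
    class = "sensor_trace")
}

#' Segment a trace into schedule phases
#'
#' Assigns every sample to the stabilization, analysis or recovery phase by
#' its time stamp. Ranges are half-open on the time axis
#' (`[0, t1)`, `[t1, t2)`, `[t2, end]`), so the three index sets partition
#' the trace exactly; samples recorded past the scheduled span fall into
#' recovery. A trace shorter than the schedule is rejected.
#'
#' @param trace A [sensor_trace()] (or [normalize_trace()] output).
#' @param schedule Phase schedule; defaults to the one stored on the trace.
#' @return Named list of integer index vectors `stabilization`, `analysis`,
#'   `recovery`.
#' @examples
#' tr <- simulate_trace(default_sensor_array()$S1, 0.3,
#'                      noise = noise_model(0, 0))
#' seg <- segment_phases(tr)
#' lengths(seg)  # 100, 200, 500 at 1 Hz
#' @export
segment_phases <- function(trace, schedule = trace$schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  t <- trace$time_s
  dt <- 1 / schedule$sample_rate_hz
  if (t[length(t)] + dt < total_seconds(schedule))
    stop("trace is shorter than the phase schedule", call. = FALSE)
  t1 <- schedule$stabilization_s
  t2 <- t1 + schedule$analysis_s
  seg <- list(stabilization = which(t < t1),
              analysis = which(t >= t1 & t < t2),
              recovery = which(t >= t2))
  if (length(seg$stabilization) == 0L || length(seg$analysis) == 0L)
    stop("schedule leaves an empty stabilization or analysis phase",
         call. = FALSE)
  seg
}

#' Normalize a trace to its baseline resistance (R/R0)
#'
#' Divides the resistance series by R0, the mean resistance over the
#' stabilization phase. Using the phase mean rather than the literal first
#' sample makes R0 robust to single-sample noise. The result is
#' dimensionless, so arrays whose sensors sit at different absolute
#' baselines become comparable.
#'
#' @param trace A [sensor_trace()].
#' @return An object of class `normalized_trace` with fields `sensor_id`,
#'   `time_s`, `r_over_r0`, `r0` and `schedule`.
#' @export
normalize_trace <- function(trace) {
  if (inherits(trace, "normalized_trace")) {
    # fixed point: renormalizing leaves the ratio trace unchanged (r0 -> ~1)
    seg <- segment_phases(trace)
    r0 <- mean(trace$r_over_r0[seg$stabilization])
    return(structure(
      list(sensor_id = trace$sensor_id, time_s = trace$time_s,
           r_over_r0 = trace$r_over_r0 / r0, r0 = r0,
           schedule = trace$schedule),
      class = "normalized_trace"))
  }
  stopifnot(inherits(trace, "sensor_trace"))
  seg <- segment_phases(trace)
  r0 <- mean(trace$resistance_ohm[seg$stabilization])
  structure(
    list(sensor_id = trace$sensor_id, time_s = trace$time_s,
         r_over_r0 = trace$resistance_ohm / r0, r0 = r0,
         schedule = trace$schedule),
    class = "normalized_trace")
}

#' Relative response amplitude of a normalized trace
#'
#' The response magnitude used for per-sensor summaries: the drop from the
#' baseline ratio (1 by construction) to the minimum R/R0 during the
#' analysis phase, `1 - min(R/R0 | analysis)`. Non-negative for sensors
#' that respond by losing resistance.
#'
#' @param ntrace A [normalize_trace()] result.
#' @param seg Phase segmentation; defaults to [segment_phases()] of the trace.
#' @return Dimensionless response amplitude.
#' @export
delta_response <- function(ntrace, seg = segment_phases(ntrace)) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  if (length(seg$analysis) == 0L)
    stop("analysis phase is empty", call. = FALSE)
  1 - min(ntrace$r_over_r0[seg$analysis])
}

#' Summarize every sensor of a cycle
#'
#' Runs normalize -> segment -> delta_response for each trace of a
#' measurement cycle.
#'
#' @param cycle A `measurement_cycle` (see [simulate_cycle()]).
#' @return Data frame with one row per sensor: `cycle_id`, `sensor_id`,
#'   `r0`, `delta_r_rel`.
#' @export
cycle_summary <- function(cycle) {
  stopifnot(inherits(cycle, "measurement_cycle"))
  rows <- lapply(cycle$traces, function(tr) {
    nt <- normalize_trace(tr)
    data.frame(cycle_id = cycle$cycle_id, sensor_id = tr$sensor_id,
               r0 = nt$r0, delta_r_rel = delta_response(nt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read measurement cycles as long-format delimited text
#'
#' One row per sample with columns `cycle_id`, `sensor_id`, `doping`,
#' `time_s`, `resistance_ohm`, `phase`; tab-separated with one header line.
#' `read_traces()` reconstructs the cycles given the recording schedule.
#'
#' @param cycles List of `measurement_cycle` objects.
#' @param path Output/input file path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns a list of `measurement_cycle` objects (class labels, if any,
#'   are not stored in the trace file).
#' @export
write_traces <- function(cycles, path) {
  rows <- lapply(cycles, function(cy) {
    do.call(rbind, lapply(cy$traces, function(tr) {
      seg <- segment_phases(tr)
      phase <- character(length(tr$time_s))
      for (p in names(seg)) phase[seg[[p]]] <- p
      data.frame(cycle_id = cy$cycle_id, sensor_id = tr$sensor_id,
                 doping = tr$doping, time_s = tr$time_s,
                 resistance_ohm = tr$resistance_ohm, phase = phase,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param schedule The [phase_schedule()] the file was recorded under.
#' @export
read_traces <- function(path, schedule = phase_schedule()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("cycle_id", "sensor_id", "time_s", "resistance_ohm")
  if (!all(needed %in% names(df)))
    stop("trace file lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  lapply(split(df, df$cycle_id), function(d) {
    traces <- lapply(split(d, d$sensor_id), function(s) {
      s <- s[order(s$time_s), ]
      sensor_trace(s$sensor_id[1], s$time_s, s$resistance_ohm, schedule,
                   doping = if ("doping" %in% names(s)) s$doping[1]
                            else NA_character_)
    })
    structure(list(cycle_id = d$cycle_id[1], class = NA_character_,
                   traces = traces, schedule = schedule),
              class = "measurement_cycle")
  })
}
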