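#' Measurement-cycle phase schedule
#'
#' One electronic-nose measurement cycle is split into three phases:
#' sensor stabilization under filtered air, sample analysis while the
#' headspace is drawn over the array, and sensor recovery back to baseline.
#' Durations are in seconds; the trace is sampled at `sample_rate_hz`.
#'
#' @param stabilization_s Stabilization phase duration in seconds.
#' @param analysis_s Analysis phase duration in seconds.
#' @param recovery_s Recovery phase duration in seconds.
#' @param sample_rate_hz Sampling frequency in Hz.
#' @return An object of class `phase_schedule`.
#' @examples
#' sched <- phase_schedule()           # 100 s / 200 s / 500 s at 1 Hz
#' n_points(sched)                     # 800
#' @export
phase_schedule <- function(stabilization_s = 100, analysis_s = 200,
                           recovery_s = 500, sample_rate_hz = 1) {
  for (v in c(stabilization_s, analysis_s, recovery_s, sample_rate_hz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("phase durations and sample rate must be single positive numbers",
           call. = FALSE)
  }
  structure(
    list(stabilization_s = stabilization_s, analysis_s = analysis_s,
         recovery_s = recovery_s, sample_rate_hz = sample_rate_hz),
    class = "phase_schedule")
}

#' Total duration and point count of a schedule
#' @param schedule A [phase_schedule()].
#' @return `total_seconds()`: duration in seconds; `n_points()`: number of
#'   samples in one cycle, `round(total duration * rate)`.
#' @export
total_seconds <- function(schedule) {
  schedule$stabilization_s + schedule$analysis_s + schedule$recovery_s
}

#' @rdname total_seconds
#' @export
n_points <- function(schedule) {
  as.integer(round(total_seconds(schedule) * schedule$sample_rate_hz))
}

#' MOX sensor profile
#'
#' Static description of one metal-oxide sensor in the array: its tin-dioxide
#' sensing layer (pure or noble-metal doped), clean-air baseline resistance,
#' and first-order response/recovery time constants. n-type MOX layers lose
#' resistance when reducing volatiles react at the heated surface, so the
#' simulated response is a resistance drop.
#'
#' @param sensor_id Short label, e.g. `"S1"`.
#' @param doping One of `"SnO2"`, `"SnO2+Pd"`, `"SnO2+Au"`.
#' @param baseline_resistance Clean-air resistance in Ohm (> 0).
#' @param response_tau_s Adsorption (response) time constant in seconds;
#'   `0` means an instantaneous step response.
#' @param recovery_tau_s Desorption (recovery) time constant in seconds.
#' @return An object of class `sensor_profile`.
#' @export
sensor_profile <- function(sensor_id, doping = c("SnO2", "SnO2+Pd", "SnO2+Au"),
                           baseline_resistance, response_tau_s = 20,
                           recovery_tau_s = 80) {
  doping <- match.arg(doping)
  if (!is.numeric(baseline_resistance) || baseline_resistance <= 0)
    stop("baseline_resistance must be > 0", call. = FALSE)
  if (response_tau_s < 0 || recovery_tau_s < 0)
    stop("time constants must be >= 0", call. = FALSE)
  structure(
    list(sensor_id = as.character(sensor_id), doping = doping,
         baseline_resistance = baseline_resistance,
         response_tau_s = response_tau_s, recovery_tau_s = recovery_tau_s),
    class = "sensor_profile")
}

#' Default six-sensor array
#'
#' Two pure SnO2 sensors, two SnO2+Pd and two SnO2+Au, with baseline
#' resistances in the 10^4--10^5 Ohm range typical of heated thick-film MOX
#' layers, response time constants of tens of seconds and slower recovery.
#'
#' @return A named list of six [sensor_profile()] objects.
#' @export
default_sensor_array <- function() {
  specs <- list(
    list("S1", "SnO2",    2.0e5, 20, 80),
    list("S2", "SnO2",    1.5e5, 25, 90),
    list("S3", "SnO2+Pd", 8.0e4, 15, 70),
    list("S4", "SnO2+Pd", 6.0e4, 18, 75),
    list("S5", "SnO2+Au", 1.2e5, 22, 85),
    list("S6", "SnO2+Au", 9.0e4, 17, 65))
  arr <- lapply(specs, function(s)
    sensor_profile(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]]))
  names(arr) <- vapply(arr, `[[`, character(1), "sensor_id")
  arr
}

#' Class-dependent sensor response amplitudes
#'
#' Encodes, for every (sensor, class) pair, the fractional resistance drop
#' the sensor shows when exposed to that class's headspace. `separation`
#' scales the between-class amplitude differences: 0 collapses all classes
#' onto the sensor base amplitudes, 1 is the default class structure.
#'
#' @param amplitudes Numeric matrix, sensors in rows, classes in columns,
#'   entries in `[0, 1)`; dimnames required.
#' @param separation Non-negative scalar recorded with the matrix.
#' @return An object of class `class_response_matrix`.
#' @seealso [default_response_matrix()]
#' @export
class_response_matrix <- function(amplitudes, separation = 1) {
  if (!is.matrix(amplitudes) || is.null(rownames(amplitudes)) ||
      is.null(colnames(amplitudes)))
    stop("amplitudes must be a matrix with sensor rownames and class colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(amplitudes)))
    stop("class labels must be unique", call. = FALSE)
  if (any(amplitudes < 0) || any(amplitudes >= 1))
    stop("amplitudes must lie in [0, 1)", call. = FALSE)
  structure(
    list(classes = colnames(amplitudes), amplitudes = amplitudes,
         separation = separation),
    class = "class_response_matrix")
}

# Per-diet amplitude fingerprints across the six sensors (fraction of
# resistance drop at separation 1). CONTROL is the reference pattern.
.diet_patterns <- function() {
  rbind(
    CONTROL = c(0, 0, 0, 0, 0, 0),
    LL      = c(1, 1, 0, -1, 0, -1) * 0.05,
    LD      = c(1, -1, 1, 0, -1, 0) * 0.05,
    ST      = c(-1, 0, -1, 1, 1, 0) * 0.05)
}

#' Default diet-by-state response matrix
#'
#' Builds amplitudes for the diet (CONTROL, LL, LD, ST) by cooking-state
#' (RAW, CK) classes. Each sensor has a doping-dependent base amplitude;
#' cooking adds a sensor-specific shift (cooked meat releases more volatiles),
#' and each diet adds a six-sensor fingerprint pattern. Both class effects
#' are multiplied by `separation`.
#'
#' @param states Character vector of cooking states to include
#'   (`c("RAW", "CK")`, or a single state for a four-class diet problem).
#' @param diets Character vector of diet codes.
#' @param separation Scaling of between-class amplitude differences.
#' @return A [class_response_matrix()] with classes named `<STATE>_<DIET>`.
#' @export
default_response_matrix <- function(states = c("RAW", "CK"),
                                    diets = c("CONTROL", "LL", "LD", "ST"),
                                    separation = 1) {
  stopifnot(all(states %in% c("RAW", "CK")), length(states) >= 1)
  base <- c(S1 = 0.45, S2 = 0.42, S3 = 0.55, S4 = 0.52, S5 = 0.35, S6 = 0.32)
  cooked_shift <- c(0.12, 0.10, 0.15, 0.13, 0.08, 0.06)
  pat <- .diet_patterns()
  stopifnot(all(diets %in% rownames(pat)))
  classes <- as.vector(outer(states, diets, paste, sep = "_"))
  amp <- sapply(classes, function(cl) {
    parts <- strsplit(cl, "_", fixed = TRUE)[[1]]
    shift <- if (parts[1] == "CK") cooked_shift else 0
    pmin(pmax(base + separation * (shift + pat[parts[2], ]), 0.02), 0.95)
  })
  class_response_matrix(amp, separation = separation)
}

#' Multiplicative noise and drift model
#'
#' Resistance noise is multiplicative log-normal (resistances are positive
#' and span decades across sensors); the baseline drifts linearly as a
#' fraction of the signal per second.
#'
#' @param multiplicative_sigma Relative (log-scale) noise SD, >= 0.
#' @param drift_per_s Linear baseline drift, fraction per second.
#' @param seed Optional integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sigma = 0.01, drift_per_s = 2e-5,
                        seed = NULL) {
  if (multiplicative_sigma < 0)
    stop("multiplicative_sigma must be >= 0", call. = FALSE)
  structure(
    list(multiplicative_sigma = multiplicative_sigma,
         drift_per_s = drift_per_s, seed = seed),
    class = "noise_model")
}

#' Experiment design bookkeeping
#'
#' Sample counts and per-sample replication for a combined GC-MS /
#' electronic-nose campaign. The default mirrors a 48-sample study with
#' triplicate GC-MS analyses and ten e-nose measurements per sample.
#'
#' @param n_samples Total number of biological samples.
#' @param gcms_replicates GC-MS analyses per sample.
#' @param enose_replicates Electronic-nose measurement cycles per sample.
#' @param cycle_minutes Nominal duration of one e-nose cycle in minutes
#'   (metadata; the operative cycle length is the phase schedule).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_samples = 48, gcms_replicates = 3,
                              enose_replicates = 10, cycle_minutes = 13) {
  counts <- c(n_samples, gcms_replicates, enose_replicates)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("design counts must be non-negative integers", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         gcms_replicates = as.integer(gcms_replicates),
         enose_replicates = as.integer(enose_replicates),
         cycle_minutes = cycle_minutes),
    class = "experiment_design")
}

#' Design totals
#'
#' Totals implied by an [experiment_design()]: the overall number of
#' analyses (GC-MS plus e-nose) and the wall-clock length of one sample's
#' e-nose session.
#'
#' @param design An [experiment_design()].
#' @return List with `total_analyses` and `enose_session_minutes`.
#' @examples
#' design_summary(experiment_design(48, 3, 10, 13))
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  list(
    total_analyses = design$n_samples *
      (design$gcms_replicates + design$enose_replicates),
    enose_session_minutes = design$enose_replicates * design$cycle_minutes)
}
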