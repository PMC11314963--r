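#' Simulate one MOX sensor resistance trace
#'
#' Deterministic response model plus noise. During stabilization the
#' resistance sits at the sensor baseline; during analysis it decays
#' exponentially toward `baseline * (1 - amplitude)` with the sensor's
#' response time constant; during recovery it relaxes back toward baseline
#' with the (slower) recovery constant. Noise is multiplicative log-normal
#' and a linear baseline drift is applied; all simulated values stay > 0.
#'
#' @param profile A [sensor_profile()].
#' @param amplitude Fractional resistance drop at full response, in `[0, 1)`.
#' @param schedule A [phase_schedule()].
#' @param noise A [noise_model()]; if its `seed` is non-NULL the RNG is
#'   seeded before drawing noise.
#' @return A `sensor_trace` (see [sensor_trace()]).
#' @examples
#' tr <- simulate_trace(default_sensor_array()$S1, amplitude = 0.4,
#'                      schedule = phase_schedule(),
#'                      noise = noise_model(seed = 1))
#' @export
simulate_trace <- function(profile, amplitude, schedule = phase_schedule(),
                           noise = noise_model()) {
  stopifnot(inherits(profile, "sensor_profile"),
            inherits(schedule, "phase_schedule"),
            inherits(noise, "noise_model"))
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)", call. = FALSE)
  base <- profile$baseline_resistance

  n <- n_points(schedule)
  t <- (seq_len(n) - 1) / schedule$sample_rate_hz
  t1 <- schedule$stabilization_s
  t2 <- t1 + schedule$analysis_s

  r <- rep(base, n)
  in_ana <- t >= t1 & t < t2
  in_rec <- t >= t2
  if (profile$response_tau_s > 0) {
    r[in_ana] <- base *
      (1 - amplitude * (1 - exp(-(t[in_ana] - t1) / profile$response_tau_s)))
    v_end <- base *
      (1 - amplitude * (1 - exp(-(t2 - t1) / profile$response_tau_s)))
  } else {
    r[in_ana] <- base * (1 - amplitude)
    v_end <- base * (1 - amplitude)
  }
  if (profile$recovery_tau_s > 0) {
    r[in_rec] <- base - (base - v_end) *
      exp(-(t[in_rec] - t2) / profile$recovery_tau_s)
  }

  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  r <- r * (1 + noise$drift_per_s * t)
  if (noise$multiplicative_sigma > 0)
    r <- r * exp(stats::rnorm(n, 0, noise$multiplicative_sigma))

  sensor_trace(profile$sensor_id, t, r, schedule, doping = profile$doping)
}

#' Simulate one six-sensor measurement cycle
#'
#' Draws one trace per sensor in the array, using the exposed class's
#' amplitude column of the response matrix.
#'
#' @param array Named list of six [sensor_profile()]s.
#' @param crm A [class_response_matrix()].
#' @param class_label Class to simulate; must be one of `crm$classes`.
#' @param schedule,noise See [simulate_trace()]. If `noise$seed` is set the
#'   RNG is seeded once for the whole cycle.
#' @param cycle_id Identifier stored in the cycle metadata.
#' @return A `measurement_cycle`: list with `cycle_id`, `class`, `traces`
#'   (named list of `sensor_trace`) and `schedule`.
#' @export
simulate_cycle <- function(array, crm, class_label,
                           schedule = phase_schedule(),
                           noise = noise_model(), cycle_id = "cycle1") {
  stopifnot(inherits(crm, "class_response_matrix"))
  if (!class_label %in% crm$classes)
    stop("unknown class label: ", class_label, call. = FALSE)
  sensor_ids <- vapply(array, `[[`, character(1), "sensor_id")
  missing <- setdiff(sensor_ids, rownames(crm$amplitudes))
  if (length(missing))
    stop("response matrix lacks sensors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  trace_noise <- noise_model(noise$multiplicative_sigma, noise$drift_per_s,
                             seed = NULL)
  traces <- lapply(array, function(p)
    simulate_trace(p, crm$amplitudes[p$sensor_id, class_label],
                   schedule, trace_noise))
  names(traces) <- sensor_ids
  structure(
    list(cycle_id = cycle_id, class = class_label, traces = traces,
         schedule = schedule),
    class = "measurement_cycle")
}

#' Simulate a full e-nose dataset
#'
#' Class-balanced dataset of measurement cycles: `n_samples` biological
#' samples split evenly across the response-matrix classes, each measured
#' `enose_replicates` times. Reproducible under `seed`.
#'
#' @param design An [experiment_design()]; `n_samples` must be a multiple of
#'   the number of classes.
#' @param crm A [class_response_matrix()].
#' @param array Sensor array, as in [simulate_cycle()].
#' @param schedule,noise See [simulate_trace()].
#' @param seed Integer seed for the whole dataset.
#' @return List with `cycles` (list of `measurement_cycle`) and `labels`
#'   (factor, one per cycle).
#' @export
simulate_dataset <- function(design, crm, array = default_sensor_array(),
                             schedule = phase_schedule(),
                             noise = noise_model(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(crm, "class_response_matrix"))
  k <- length(crm$classes)
  if (k < 1) stop("response matrix has no classes", call. = FALSE)
  if (design$n_samples < k || design$n_samples %% k != 0)
    stop("n_samples must be a positive multiple of the number of classes",
         call. = FALSE)
  if (design$enose_replicates < 1)
    stop("need at least one e-nose replicate per sample", call. = FALSE)
  per_class <- design$n_samples %/% k

  set.seed(as.integer(seed))
  trace_noise <- noise_model(noise$multiplicative_sigma, noise$drift_per_s,
                             seed = NULL)
  cycles <- list()
  labels <- character(0)
  for (cl in crm$classes) {
    for (s in seq_len(per_class)) {
      for (r in seq_len(design$enose_replicates)) {
        id <- sprintf("%s_s%02d_r%02d", cl, s, r)
        cycles[[id]] <- simulate_cycle(array, crm, cl, schedule,
                                       trace_noise, cycle_id = id)
        labels <- c(labels, cl)
      }
    }
  }
  list(cycles = cycles, labels = factor(labels, levels = crm$classes))
}

#' Default VOC compound library for peak-table simulation
#'
#' Per class (diet-by-state), the mean integrated area and log-scale
#' dispersion of a panel of volatiles commonly reported in poultry
#' headspace. Hexanal dominates the aldehydes everywhere; cooking scales
#' aldehydes, alcohols and ketones up and carboxylic acids down relative to
#' raw, with small diet-specific modifiers; retention times are fixed per
#' compound so sampled tables are chromatographically ordered.
#'
#' @param classes Class labels to generate (default all eight
#'   `<STATE>_<DIET>` combinations).
#' @param dispersion Log-scale SD applied to every compound (0 = areas equal
#'   to library means).
#' @return Data frame with columns `class_label`, `compound`,
#'   `chemical_class`, `retention_time_min`, `mean_area`, `dispersion`.
#' @export
default_compound_library <- function(
    classes = as.vector(outer(c("RAW", "CK"), c("CONTROL", "LL", "LD", "ST"),
                              paste, sep = "_")),
    dispersion = 0.15) {
  base <- data.frame(
    compound = c("hexanal", "heptanal", "octanal", "nonanal", "benzaldehyde",
                 "1-octen-3-ol", "1-hexanol", "1-heptanol",
                 "2-heptanone", "3-octanone", "2-nonanone",
                 "heptane, 2,2,4,6,6-pentamethyl-", "tridecane", "tetradecane",
                 "ethyl hexanoate",
                 "1-octene",
                 "hexanoic acid", "octanoic acid", "nonanoic acid",
                 "dibutyl ether"),
    chemical_class = c(rep("aldehyde", 5), rep("alcohol", 3),
                       rep("ketone", 3), rep("alkane", 3), "ester",
                       "alkene", rep("carboxylic acid", 3), "ether"),
    retention_time_min = c(3.1, 4.6, 6.2, 7.9, 7.2,
                           5.4, 3.8, 5.0,
                           4.2, 5.8, 7.5,
                           6.8, 10.5, 11.8,
                           6.5,
                           2.4,
                           8.6, 10.1, 11.2,
                           4.9),
    mean_area = c(52000, 9000, 6000, 11000, 3000,
                  18000, 4000, 2500,
                  1200, 900, 800,
                  15000, 5000, 3500,
                  700,
                  4500,
                  2000, 3000, 3500,
                  600),
    stringsAsFactors = FALSE)
  # class-level multipliers: cooking boosts oxidation products, raw keeps acids
  class_mult <- function(cl) {
    parts <- strsplit(cl, "_", fixed = TRUE)[[1]]
    cooked <- parts[1] == "CK"
    m <- c(aldehyde = if (cooked) 1.6 else 1, alcohol = if (cooked) 1.4 else 1,
           ketone = if (cooked) 1.5 else 1, alkane = 1, alkene = 1,
           ester = if (cooked) 1.2 else 1,
           "carboxylic acid" = if (cooked) 0.6 else 1.3,
           ether = if (cooked) 1.2 else 1)
    diet_m <- switch(parts[2],
      CONTROL = c(aldehyde = 1.0, alcohol = 1.0),
      LL = c(aldehyde = 1.1, ketone = 0.7),
      LD = c("carboxylic acid" = 1.4, alcohol = 0.8),
      ST = c(ketone = if (cooked) 2.5 else 1, alcohol = 1.1))
    m[names(diet_m)] <- m[names(diet_m)] * diet_m
    m
  }
  do.call(rbind, lapply(classes, function(cl) {
    m <- class_mult(cl)
    data.frame(class_label = cl, compound = base$compound,
               chemical_class = base$chemical_class,
               retention_time_min = base$retention_time_min,
               mean_area = base$mean_area * m[base$chemical_class],
               dispersion = dispersion,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Simulate a GC-MS peak table for one sample class
#'
#' Samples one integrated-peak area per library compound for the given
#' class; areas are log-normal around the library means (`dispersion` is the
#' log-scale SD, so dispersion 0 returns the means exactly). Rows are
#' ordered by strictly increasing retention time.
#'
#' @param class_label Sample class, must appear in `compound_library`.
#' @param compound_library As returned by [default_compound_library()].
#' @param seed Optional integer seed.
#' @param sample_id,replicate_id Metadata stored on the table.
#' @return A [peak_table()].
#' @export
simulate_peak_table <- function(class_label,
                                compound_library = default_compound_library(),
                                seed = NULL, sample_id = class_label,
                                replicate_id = 1L) {
  lib <- compound_library[compound_library$class_label == class_label, ]
  if (nrow(lib) == 0)
    stop("compound library has no entries for class ", class_label,
         call. = FALSE)
  if (anyDuplicated(lib$retention_time_min))
    stop("library retention times must be distinct within a class",
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  area <- lib$mean_area * exp(stats::rnorm(nrow(lib), 0, lib$dispersion))
  tbl <- data.frame(retention_time_min = lib$retention_time_min,
                    compound = lib$compound,
                    chemical_class = lib$chemical_class,
                    area = area, stringsAsFactors = FALSE)
  tbl <- tbl[order(tbl$retention_time_min), , drop = FALSE]
  peak_table(tbl, sample_id = sample_id, replicate_id = replicate_id)
}
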