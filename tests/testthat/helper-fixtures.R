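# Small builders shared across test files.

quiet_noise <- function(seed = NULL) noise_model(0, 0, seed = seed)

# Instantaneous-response sensor: trace is a closed-form step, handy for
# exact expectations.
step_sensor <- function(baseline = 1e5) {
  sensor_profile("S1", "SnO2", baseline,
                 response_tau_s = 0, recovery_tau_s = 0)
}

noiseless_cycle_set <- function(separation = 1, states = "CK",
                                samples = 1, reps = 2, seed = 1) {
  crm <- default_response_matrix(states = states, separation = separation)
  design <- experiment_design(n_samples = samples * length(crm$classes),
                              enose_replicates = reps)
  simulate_dataset(design, crm, noise = quiet_noise(), seed = seed)
}

# Manual normalized trace, for interval/rescaling properties.
manual_ntrace <- function(values, schedule) {
  structure(list(sensor_id = "S1",
                 time_s = (seq_along(values) - 1) / schedule$sample_rate_hz,
                 r_over_r0 = values, r0 = 1, schedule = schedule),
            class = "normalized_trace")
}

# Gaussian class data with shared covariance, for LDA oracle checks.
gaussian_classes <- function(n_per_class, means, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(means)
  X <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per_class * ncol(means), sd = sd),
                 n_per_class), 2, means[j, ], "+")))
  list(X = X, y = factor(rep(rownames(means) %||% seq_len(k),
                             each = n_per_class)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal peak table for GC-MS unit tests.
make_table <- function(areas, classes = NULL, compounds = NULL,
                       rep_id = 1L) {
  n <- length(areas)
  peak_table(data.frame(
    retention_time_min = seq(2, by = 0.5, length.out = n),
    compound = compounds %||% paste0("cmp", seq_len(n)),
    chemical_class = classes %||% rep("aldehyde", n),
    area = areas, stringsAsFactors = FALSE),
    sample_id = "s1", replicate_id = rep_id)
}

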