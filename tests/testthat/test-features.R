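test_that("sharpe matches hand-computed windows", {
  # [1,2,3,4], fraction 0.5: forward window {1,2}, back window {3,4}
  expect_equal(sharpe(c(1, 2, 3, 4), 0.5, "forward"),
               1.5 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(sharpe(c(1, 2, 3, 4), 0.5, "forward"), 2.1213203,
               tolerance = 1e-6)
  expect_equal(sharpe(c(1, 2, 3, 4), 0.5, "back"), 4.9497475,
               tolerance = 1e-6)
  # ceiling window: fraction 0.25 of 5 points -> 2-point window
  expect_equal(sharpe(c(1, 3, 9, 9, 9), 0.25, "forward"),
               mean(c(1, 3)) / sd(c(1, 3)))
  expect_error(sharpe(rep(1, 8), 0.25, "forward"),
               class = "voclass_undefined_feature")
  expect_error(sharpe(c(1, 2, 3, 4), 0.1, "forward"), "2 points")
})

test_that("derivative extrema follow finite differences", {
  expect_equal(derivative_extrema(c(0, 2, 4, 6), 0:3),
               c(min_derivative = 2, max_derivative = 2))
  expect_equal(derivative_extrema(c(1, 0, 1), 0:2),
               c(min_derivative = -1, max_derivative = 1))
  dec <- derivative_extrema(exp(-(0:20) / 5), 0:20)
  expect_lte(dec["max_derivative"], 0)
  expect_error(derivative_extrema(1, 1), "two")
})

test_that("trapezoidal integral matches constants and a dense oracle", {
  expect_equal(trace_integral(rep(3, 11), 0:10), 30)
  expect_equal(trace_integral(c(0, 1), c(0, 1)), 0.5)
  # refinement oracle: Riemann midpoint sum on a smooth function
  f <- function(x) sin(x) + 0.5 * x
  t <- seq(0, pi, length.out = 4001)
  mid <- (t[-1] + t[-length(t)]) / 2
  riemann <- sum(f(mid) * diff(t))
  expect_equal(trace_integral(f(t), t), riemann, tolerance = 1e-6)
})

test_that("extract_features returns the 11 descriptors in canonical order", {
  sched <- phase_schedule()
  tr <- simulate_trace(step_sensor(), 0, sched, quiet_noise())
  f <- suppressWarnings(extract_features(normalize_trace(tr)))
  expect_identical(names(f), FEATURE_NAMES)
  expect_equal(unname(f["delta_r"]), 0)
  expect_equal(unname(f["minimum"]), 1)
  expect_equal(unname(f["maximum"]), 1)
  expect_equal(unname(f["log_sum"]), 0)          # ln 1 = 0 over the track
  expect_equal(unname(f["integral"]), 200)       # unit signal over 200 s
  expect_true(all(is.finite(f)))
})

test_that("delta_r is exactly the max-minus-min excursion", {
  v <- c(rep(1, 4), 0.4, 0.7, 1.0, 0.9)
  nt <- manual_ntrace(v, phase_schedule(2, 3, 3))
  f <- suppressWarnings(extract_features(nt))
  expect_identical(unname(f["delta_r"]),
                   max(v) - min(v))
  expect_equal(unname(f["minimum"]), 0.4)
  expect_equal(unname(f["maximum"]), 1.0)
})

test_that("log_sum config switches between sum-of-logs and log-of-sum", {
  tr <- simulate_trace(default_sensor_array()$S6, 0.3,
                       noise = noise_model(0.01, 0, seed = 4))
  nt <- normalize_trace(tr)
  a <- extract_features(nt, log_sum_mode = "sum_log")
  b <- extract_features(nt, log_sum_mode = "log_sum")
  expect_equal(unname(a["log_sum"]), sum(log(nt$r_over_r0)))
  expect_equal(unname(b["log_sum"]), log(sum(nt$r_over_r0)))
})

test_that("time rescaling scales derivatives and integral, not the rest", {
  set.seed(9)
  v <- 1 - 0.3 * c(rep(0, 10), seq(0, 1, length.out = 20),
                   seq(1, 0.2, length.out = 30)) +
    rnorm(60, 0, 0.005)
  f1 <- extract_features(manual_ntrace(v, phase_schedule(10, 20, 30, 1)))
  # same samples read at half the rate: every dt doubles
  f2 <- extract_features(manual_ntrace(v, phase_schedule(20, 40, 60, 0.5)))
  expect_equal(unname(f2["integral"]), unname(2 * f1["integral"]))
  expect_equal(unname(f2["min_derivative"]),
               unname(f1["min_derivative"] / 2))
  expect_equal(unname(f2["max_derivative"]),
               unname(f1["max_derivative"] / 2))
  same <- c("sharpe_fwd_25", "sharpe_back_25", "sharpe_fwd_50",
            "sharpe_back_50", "delta_r", "log_sum", "minimum", "maximum")
  expect_equal(f2[same], f1[same])
})

test_that("feature extraction is deterministic", {
  tr <- simulate_trace(default_sensor_array()$S2, 0.5,
                       noise = noise_model(0.02, 1e-5, seed = 6))
  nt <- normalize_trace(tr)
  expect_identical(extract_features(nt), extract_features(nt))
})

test_that("build_feature_matrix stacks 66 named columns per cycle", {
  ds <- noiseless_cycle_set(samples = 1, reps = 2, states = "CK")
  fm <- build_feature_matrix(ds$cycles, ds$labels)
  expect_identical(dim(fm$features), c(8L, 66L))
  expect_identical(colnames(fm$features)[1:2],
                   c("S1__sharpe_fwd_25", "S1__sharpe_back_25"))
  expect_identical(levels(fm$labels),
                   c("CK_CONTROL", "CK_LL", "CK_LD", "CK_ST"))

  # permuting cycles permutes rows identically
  perm <- c(3, 1, 4, 2, 8, 5, 6, 7)
  fm2 <- build_feature_matrix(ds$cycles[perm], ds$labels[perm])
  expect_identical(fm2$features, fm$features[perm, ])

  # identical cycles give identical rows
  twin <- build_feature_matrix(ds$cycles[c(1, 1)], ds$labels[c(1, 1)])
  expect_identical(twin$features[1, ], twin$features[2, ])
})

test_that("feature matrices round-trip through delimited text", {
  ds <- noiseless_cycle_set(samples = 1, reps = 1, states = "CK")
  fm <- build_feature_matrix(ds$cycles, ds$labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$features, fm$features, tolerance = 1e-12)
  expect_identical(as.character(back$labels), as.character(fm$labels))
})
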