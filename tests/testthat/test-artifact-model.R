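test_that("the artifact model evaluates its harmonics correctly", {
  expect_equal(evaluate_artifact(0, 1, 0, 0, 1, 0), 1)
  expect_equal(evaluate_artifact(0.25, 1, 0, 0, 1, 0), 0, tolerance = 1e-12)
  expect_equal(evaluate_artifact(0, 1, 0.5, 0, 1, 0), -1)
  expect_equal(evaluate_artifact(0, 1, 0, 2.5, 1, 0), 3.5)
  expect_error(evaluate_artifact(0, 1, 0, 0, c(1, 2), 1), "length")
})

test_that("the design matrix has the documented layout and periodicity", {
  expect_equal(design_matrix(0, 1, 0, 1, include_mean = TRUE),
               matrix(c(1, 1, 0), 1))
  X <- design_matrix(seq(0, 1, length.out = 10), 150.6, 0.3, 5,
                     include_mean = TRUE)
  expect_identical(dim(X), c(10L, 11L))
  X1 <- design_matrix(seq(0, 1, length.out = 10), 150.6, 1.3, 5,
                      include_mean = TRUE)
  expect_equal(X1, X, tolerance = 1e-12)
  expect_error(design_matrix(numeric(0), 1, 0, 1), "non-empty")
})

test_that("amplitudes are recovered exactly on noiseless data", {
  inst <- make_test_instance(seed = 11)
  fit <- fit_amplitudes(inst$rec, inst$params$omega, inst$params$deltas,
                        K = inst$params$K)
  expect_lt(fit$diagnostics$g_value, 1e-16 * sum(inst$rec$value^2))
  expect_equal(fit$alphas, inst$params$alphas, tolerance = 1e-8)
  expect_equal(fit$betas, inst$params$betas, tolerance = 1e-8)
  expect_equal(fit$alpha0, 0, tolerance = 1e-8)
})

test_that("residual variance on pure Gaussian noise matches theory", {
  # 11 fitted parameters on N iid N(0,1) samples leave ~(1 - 11/N) variance
  ratios <- vapply(1:20, function(s) {
    rec <- withr::with_seed(s, segmented_recording(rnorm(1e4), fs = 1000))
    fit <- fit_amplitudes(rec, 150.6117, 0, K = 5)
    fit$diagnostics$g_value / 1e4
  }, numeric(1))
  expect_true(all(ratios > 0.9 & ratios < 1.1))
})

test_that("integer shifts of a phase leave the fit unchanged", {
  inst <- make_test_instance(seed = 3, noise_sd = 0.2)
  d2 <- inst$params$deltas + c(0, 3, 0)
  f1 <- fit_amplitudes(inst$rec, inst$params$omega, inst$params$deltas, 3)
  f2 <- fit_amplitudes(inst$rec, inst$params$omega, d2, 3)
  expect_equal(f2$diagnostics$g_value, f1$diagnostics$g_value,
               tolerance = 1e-12)
  expect_equal(f2$alphas, f1$alphas, tolerance = 1e-10)
})

test_that("g matches an independent dense least-squares oracle", {
  for (s in 1:4) {
    inst <- make_test_instance(seed = s, noise_sd = 0.5)
    om <- inst$params$omega + 0.05
    dl <- inst$params$deltas + c(0, 0.02, -0.01)
    g_pkg <- objective_g(inst$rec, om, dl, K = 4)
    g_ora <- oracle_g(inst$rec, om, dl, K = 4)
    expect_equal(g_pkg, g_ora, tolerance = 1e-10)
  }
})

test_that("scaling the data scales g quadratically and amplitudes linearly", {
  inst <- make_test_instance(seed = 9, noise_sd = 0.3)
  f1 <- fit_amplitudes(inst$rec, inst$params$omega, inst$params$deltas, 3)
  scaled <- inst$rec
  scaled$value <- scaled$value * 3.7
  f2 <- fit_amplitudes(scaled, inst$params$omega, inst$params$deltas, 3)
  expect_equal(f2$diagnostics$g_value, 3.7^2 * f1$diagnostics$g_value,
               tolerance = 1e-10)
  expect_equal(f2$alphas, 3.7 * f1$alphas, tolerance = 1e-10)
})

test_that("subtracting the true artifact leaves the underlying signal", {
  sim <- simulate_example2(seed = 5)
  rec <- subtract_artifact(sim$observed, sim$true_params)
  expect_lt(relative_rmse(sim$truth_signal, rec), 1e-8)

  # noiseless artifact minus its own parameters is numerically zero
  inst <- make_test_instance(seed = 2)
  resid <- subtract_artifact(inst$rec, inst$params)
  expect_lt(max(abs(resid$value)), 1e-10 * max(abs(inst$rec$value)))
})

test_that("fitting the mean amplitude yields a mean-zero recovered signal", {
  inst <- make_test_instance(seed = 7, noise_sd = 0.4)
  shifted <- inst$rec
  shifted$value <- shifted$value + 2.5
  fit <- fit_amplitudes(shifted, inst$params$omega, inst$params$deltas, 3,
                        include_mean = TRUE)
  params <- artifact_params(inst$params$omega, inst$params$deltas,
                            fit$alpha0, fit$alphas, fit$betas)
  recovered <- subtract_artifact(shifted, params)
  expect_lt(abs(mean(recovered$value)), 1e-10 * stats::sd(shifted$value))
})

test_that("artifact parameters roundtrip through JSON", {
  inst <- make_test_instance(seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_artifact_params(inst$params, path)
  back <- read_artifact_params(path)
  expect_equal(back$omega, inst$params$omega)
  expect_equal(back$deltas, inst$params$deltas)
  expect_equal(back$alphas, inst$params$alphas)
  expect_equal(back$K, inst$params$K)
})
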