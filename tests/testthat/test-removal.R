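test_that("the envelope objective vanishes at the truth and is fs-periodic", {
  sim <- simulate_example1(seed = 2)
  tp <- sim$true_params
  g0 <- objective_g(sim$observed, tp$omega, tp$deltas, 5)
  expect_lt(g0, 1e-16 * sum(sim$observed$value^2))
  g1 <- objective_g(sim$observed, 150.6, 0, 5)
  g2 <- objective_g(sim$observed, 150.6 + 1000, 0, 5)
  expect_equal(g2, g1, tolerance = 1e-10)
})

test_that("analytic derivatives of g match central finite differences", {
  for (s in 1:3) {
    inst <- make_test_instance(seed = s, noise_sd = 0.3)
    om <- inst$params$omega + 0.04
    dl <- inst$params$deltas + c(0, 0.015, -0.02)
    gh <- g_gradient_hessian(inst$rec, om, dl, K = 3)
    fd <- fd_gradient(function(o, d) objective_g(inst$rec, o, d, K = 3),
                      om, dl)
    expect_equal(gh$gradient, fd, tolerance = 1e-5)
    # Hessian columns against finite differences of the analytic gradient
    h <- 1e-5
    fdH <- sapply(seq_along(fd), function(q) {
      if (q == 1) {
        gp <- g_gradient_hessian(inst$rec, om + h, dl, 3)$gradient
        gm <- g_gradient_hessian(inst$rec, om - h, dl, 3)$gradient
      } else {
        dp <- dl; dm <- dl
        dp[q] <- dp[q] + h; dm[q] <- dm[q] - h
        gp <- g_gradient_hessian(inst$rec, om, dp, 3)$gradient
        gm <- g_gradient_hessian(inst$rec, om, dm, 3)$gradient
      }
      (gp - gm) / (2 * h)
    })
    expect_equal(gh$hessian, fdH, tolerance = 1e-4)
  }
})

test_that("the phase gradient is invariant to the phase representative", {
  inst <- make_test_instance(seed = 5, noise_sd = 0.2)
  om <- inst$params$omega + 0.02
  d1 <- inst$params$deltas
  d2 <- d1 + c(0, 1, 0)
  g1 <- g_gradient_hessian(inst$rec, om, d1, 3)
  g2 <- g_gradient_hessian(inst$rec, om, d2, 3)
  expect_equal(g1$gradient, g2$gradient, tolerance = 1e-10)
})

test_that("at a noiseless minimizer the gradient vanishes and g is locally convex", {
  inst <- make_test_instance(seed = 8)
  gh <- g_gradient_hessian(inst$rec, inst$params$omega, inst$params$deltas, 3)
  # normalized-coordinate gradient: omega component in Hz * fs
  grad_norm <- max(abs(gh$gradient * c(recording_fs(inst$rec), 1, 1)))
  expect_lt(grad_norm, 1e-6)
  ev <- eigen(gh$hessian, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-6 * max(abs(ev))))
})

test_that("Newton refinement started at the truth stops immediately", {
  sim <- simulate_example1(seed = 4)
  fit <- newton_refine(sim$observed, sim$true_params$omega,
                       sim$true_params$deltas, removal_config())
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_true(all(diff(fit$g_trace) <= 1e-12 * abs(fit$g_trace[1]) + 1e-300))
})

test_that("the objective trace is monotone non-increasing", {
  for (s in 1:4) {
    inst <- make_test_instance(seed = s, noise_sd = 0.5)
    fit <- newton_refine(inst$rec, inst$params$omega + 0.02,
                         (inst$params$deltas + c(0, 0.05, -0.05)) %% 1,
                         removal_config(K_hat = 3, maxiter = 50))
    tr <- fit$g_trace
    expect_true(all(diff(tr) <= 1e-12 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("noiseless multi-segment parameters are recovered to high accuracy", {
  for (s in 1:3) {
    inst <- make_test_instance(seed = 20 + s, n_segments = 4,
                               segment_len = 300)
    fit <- newton_refine(inst$rec, inst$params$omega + 0.01,
                         inst$params$deltas, removal_config(K_hat = 3))
    expect_lt(100 * abs(fit$params$omega - inst$params$omega) /
                inst$params$omega, 1e-8)
    dphi <- (fit$params$deltas - inst$params$deltas) %% 1
    expect_lt(max(pmin(dphi, 1 - dphi)), 1e-8)
  }
})

test_that("refinement reports non-convergence when capped", {
  inst <- make_test_instance(seed = 6, noise_sd = 0.5)
  fit <- newton_refine(inst$rec, inst$params$omega + 0.05,
                       inst$params$deltas, removal_config(K_hat = 3,
                                                          maxiter = 1,
                                                          tol1 = 1e-300,
                                                          tol2 = 1e-300))
  expect_false(fit$converged)
  expect_identical(fit$reason, "maxiter")
})

test_that("tidy and glance summarize a removal fit", {
  sim <- simulate_example1(seed = 3)
  fit <- newton_refine(sim$observed, 150.6, NULL, removal_config())
  td <- tidy(fit)
  expect_identical(nrow(td), 5L)
  expect_named(td, c("harmonic", "frequency_hz", "alpha", "beta",
                     "amplitude", "phase_cycles"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
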