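test_that("the alignment energy is 1-periodic in each phase and zero for zero signal", {
  inst <- make_test_instance(seed = 1, noise_sd = 0.2)
  e1 <- energy(inst$rec, 150.6, inst$params$deltas)
  e2 <- energy(inst$rec, 150.6, inst$params$deltas + c(0, 1, 0))
  expect_equal(e2, e1, tolerance = 1e-12)
  zero <- segmented_recording(list(rep(0, 50), rep(0, 40)), fs = 100)
  expect_identical(energy(zero, 10, c(0, 0.3)), 0)
})

test_that("for an on-grid tone the energy is maximized at that grid frequency", {
  fs <- 200; N <- 400
  f0 <- 35 # on the DFT grid: 35 = 70 * fs / N
  rec <- segmented_recording(cos(2 * pi * f0 * (0:(N - 1)) / fs), fs)
  grid <- (1:(N / 2 - 1)) * fs / N
  es <- vapply(grid, function(f) energy(rec, f, 0), numeric(1))
  expect_equal(grid[which.max(es)], f0)
})

test_that("energy matches the explicit trapezoid-weight oracle", {
  for (s in 1:4) {
    inst <- make_test_instance(seed = s, noise_sd = 0.4)
    om <- inst$params$omega + 0.07
    dl <- inst$params$deltas + c(0, 0.1, -0.2)
    expect_equal(energy(inst$rec, om, dl),
                 oracle_energy(inst$rec, om, dl), tolerance = 1e-10)
  }
})

test_that("analytic derivatives of the energy match finite differences", {
  inst <- make_test_instance(seed = 12, noise_sd = 0.3)
  om <- inst$params$omega + 0.03
  dl <- inst$params$deltas + c(0, 0.02, -0.05)
  eh <- energy_gradient_hessian(inst$rec, om, dl)
  fd <- fd_gradient(function(o, d) energy(inst$rec, o, d), om, dl)
  expect_equal(eh$gradient, fd, tolerance = 1e-5)
  e1 <- energy_gradient_hessian(inst$rec, om, dl + c(0, 1, 0))
  expect_equal(e1$gradient, eh$gradient, tolerance = 1e-10)
})

test_that("ascent from a maximizer stops immediately with a monotone trace", {
  inst <- make_test_instance(seed = 4)
  cfg <- init_config(m0 = 150.6, delta_omega = 5, num_init = 1, seed = 1)
  top <- ascend(inst$rec, inst$params$omega, inst$params$deltas, cfg)
  again <- ascend(inst$rec, top$omega, top$deltas, cfg)
  expect_lte(again$iterations, 1L)
  for (s in 1:4) {
    start <- withr::with_seed(s, list(o = runif(1, 145.6, 155.6),
                                      d = c(0, runif(2))))
    fit <- ascend(inst$rec, start$o, start$d, cfg)
    expect_true(all(diff(fit$energy_trace) >= -1e-9 * max(fit$energy_trace)))
  }
})

test_that("ascent started inside the main lobe converges to an accurate frequency", {
  # the energy main lobe of a 10 s record is ~0.1 Hz wide; a start inside
  # it must climb to the (trapezoid-discretized) maximizer
  sim <- simulate_example1(seed = 6)
  cfg <- init_config(m0 = 150.6, delta_omega = 5, num_init = 1, seed = 1)
  fit <- ascend(sim$observed, 150.64, NULL, cfg)
  expect_lt(100 * abs(fit$omega - 150.6117) / 150.6117, 1e-4)
})

test_that("multi-start initialization is deterministic and consistent", {
  inst <- make_test_instance(seed = 2, noise_sd = 0.2)
  cfg <- init_config(m0 = 150.6, delta_omega = 5, num_init = 5, seed = 99)
  a <- init_artifact(inst$rec, cfg)
  b <- init_artifact(inst$rec, cfg)
  expect_identical(a$omega, b$omega)
  expect_identical(a$per_start_energies, b$per_start_energies)
  expect_equal(a$energy, max(a$per_start_energies))

  # a single start equals ascending from the single drawn start
  cfg1 <- init_config(m0 = 150.6, delta_omega = 5, num_init = 1, seed = 7)
  one <- init_artifact(inst$rec, cfg1)
  draw <- withr::with_seed(7L, list(o = runif(1, 145.6, 155.6),
                                    d = matrix(runif(2), 1)))
  manual <- ascend(inst$rec, draw$o, c(0, draw$d[1, ]), cfg1)
  expect_identical(one$omega, manual$omega)
  expect_identical(one$energy, manual$energy)
})

test_that("the multi-start maximum is non-decreasing in the number of starts", {
  inst <- make_test_instance(seed = 10, noise_sd = 0.3)
  # nested start sets: one draw of 6 starts, prefixes of growing length
  cfg <- init_config(m0 = 150.6, delta_omega = 5, num_init = 6, seed = 5)
  starts <- withr::with_seed(5L, {
    list(o = runif(6, 145.6, 155.6), d = matrix(runif(6 * 2), 6))
  })
  per_start <- vapply(1:6, function(i) {
    ascend(inst$rec, starts$o[i], c(0, starts$d[i, ]), cfg)$energy
  }, numeric(1))
  energies <- vapply(c(1, 3, 6), function(m) max(per_start[1:m]), numeric(1))
  expect_true(all(diff(energies) >= 0))
})

test_that("phase alignment at the true frequency recovers the true phases", {
  inst <- make_test_instance(seed = 15, n_segments = 5, segment_len = 400)
  d <- phase_align(inst$rec, inst$params$omega)
  dphi <- (d - inst$params$deltas) %% 1
  expect_lt(max(pmin(dphi, 1 - dphi)), 0.02)
})

test_that("Newton refinement improves on the initializer frequency", {
  for (s in 1:3) {
    sim <- simulate_example1(seed = 30 + s)
    res <- run_pipeline(sim$observed,
                        init_config(m0 = 150.6, delta_omega = 5,
                                    num_init = 10, seed = 40 + s),
                        removal_config(), true_params = sim$true_params,
                        spectra = FALSE)
    expect_lte(res$report$freq_rel_error_pct,
               res$report$init_freq_rel_error_pct)
  }
})
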