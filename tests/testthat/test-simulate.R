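test_that("the artifact-only example has the documented shape", {
  sim <- simulate_example1(seed = 1)
  expect_identical(n_segments(sim$observed), 1L)
  expect_identical(nrow(sim$observed), 10000L)
  expect_identical(recording_fs(sim$observed), 1000)
  expect_true(all(sim$truth_signal$value == 0))
  expect_identical(simulate_example1(seed = 1)$observed$value,
                   sim$observed$value)
})

test_that("the chirp example has the right amplitude ratio and sweep", {
  sim <- simulate_example2(seed = 2)
  ratio <- sqrt(mean(sim$truth_artifact$value^2)) /
    sqrt(mean(sim$truth_signal$value^2))
  expect_gte(ratio, 13)
  expect_lte(ratio, 17)
  expect_equal(sim$observed$value,
               sim$truth_signal$value + sim$truth_artifact$value,
               tolerance = 1e-12)
  # near the end of the 10 s record the chirp sits near its 500 Hz target
  tail_freq <- dft_peak_frequency(utils::tail(sim$truth_signal$value, 1000),
                                  1000)
  expect_gt(tail_freq, 440)
  expect_lte(tail_freq, 500)
})

test_that("the aliased gapped example matches its generative description", {
  sim <- simulate_example3(seed = 3)
  expect_identical(n_segments(sim$observed), 10L)
  expect_identical(segment_lengths(sim$observed), rep(250L, 10))
  expect_identical(recording_fs(sim$observed), 250)
  expect_equal(alias_frequency(sim$spec$xi_true, 250), 99.3883,
               tolerance = 1e-12)
  expect_lt(abs(mean(sim$truth_signal$value)),
            0.05 * stats::sd(sim$truth_signal$value))
  ratio <- sqrt(mean(sim$truth_artifact$value^2)) /
    sqrt(mean(sim$truth_signal$value^2))
  expect_gte(ratio, 1.2)
  expect_lte(ratio, 1.6)
  expect_identical(length(sim$gaps), 9L)
  expect_true(all(sim$gaps > 0 & sim$gaps < 500))
})

test_that("simulated outputs are additive and parameter-consistent", {
  for (s in 1:3) {
    sim <- simulate_example3(seed = s)
    expect_equal(sim$observed$value,
                 sim$truth_signal$value + sim$truth_artifact$value,
                 tolerance = 1e-12)
    regen <- reconstruct_artifact(sim$observed, sim$true_params)
    expect_equal(regen$value, sim$truth_artifact$value, tolerance = 1e-10)
    expect_identical(simulate_example3(seed = s)$observed$value,
                     sim$observed$value)
  }
})

test_that("frequency-error sensitivity of harmonic regression is monotone", {
  tab <- figure_freq_sensitivity(n_trials = 5,
                                 freq_errors = c(0, 1e-6, 1e-5, 1e-4),
                                 n_samples = 5000, seed = 2)
  expect_identical(nrow(tab), 4L)
  expect_lt(tab$mean_relative_rmse_pct[1], 1e-8)
  expect_true(all(diff(tab$mean_relative_rmse_pct) > 0))
})

test_that("the full method beats the DFT baseline on shared draws", {
  tab <- figure_dft_comparison(sample_counts = c(2000, 8000), n_trials = 3,
                               num_init = 6, seed = 11)
  expect_true(all(tab$full_rel_err_pct <= tab$dft_rel_err_pct))
  # DFT error shrinks with record length (finer grid)
  expect_lt(tab$dft_rel_err_pct[2], tab$dft_rel_err_pct[1])
})
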