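rms <- function(x) sqrt(mean(x^2))

#' Simulation specification
#'
#' Full generative description of a synthetic experiment: a truncated-
#' Fourier artifact with pulse-like decaying harmonic amplitudes (rescaled
#' to a target RMS ratio against the underlying signal when one is present), an
#' optional underlying signal (linear chirp or a sum of random sinusoid
#' snippets), iid Gaussian noise, and fixed-length segments separated by
#' random-length gaps. Gap lengths include a uniform fractional part so the
#' implied true phase shifts are generic in `[0, 1)`.
#'
#' @param fs sampling rate in Hz.
#' @param xi_true true artifact fundamental frequency in Hz.
#' @param K_true number of artifact harmonics.
#' @param signal_kind `"none"`, `"chirp"` (linear, 0 Hz up to
#'   `chirp_f1`), or `"snippets"` (random sinusoid snippets, demeaned).
#' @param n_segments number of contiguous segments.
#' @param segment_len samples per segment.
#' @param gap_range range (in samples, real-valued) of the uniform gap
#'   lengths between segments.
#' @param amplitude_ratio target ratio of artifact RMS to underlying-signal
#'   RMS (`NA` = leave the standard-normal amplitudes unscaled).
#' @param amplitude_decay harmonic amplitude decay exponent: harmonic `k`
#'   has magnitude `1 / k^amplitude_decay` (before the overall rescaling).
#'   The default 1 emulates the spectral decay of a bandlimited pulse-like
#'   stimulation artifact, whose fundamental dominates — the working
#'   assumption of the removal method. 0 gives equally strong harmonics.
#' @param amplitude_rule `"pulse"`: a fixed waveform shape with a random
#'   phase per harmonic — magnitudes deterministic at `1/k^decay`, phases
#'   uniform; `"gaussian"`: fully random amplitudes,
#'   `N(0, 1) / k^decay` per cosine/sine coefficient.
#' @param noise `"none"` or `"match_signal"` (noise sd equal to the RMS of
#'   the snippet signal, i.e. 0 dB SNR within the underlying signal).
#' @param chirp_f1 chirp end frequency in Hz.
#' @param snippet_freq_range,snippet_dur_range snippet frequency (Hz) and
#'   duration (s) ranges.
#' @param seed optional RNG seed.
#' @return a `sim_spec` list, to be passed to [simulate_recording()].
#' @export
sim_spec <- function(fs, xi_true = 150.6117, K_true = 5,
                     signal_kind = c("none", "chirp", "snippets"),
                     n_segments = 1, segment_len = 1e4,
                     gap_range = c(0, 500), amplitude_ratio = NA,
                     amplitude_decay = 1,
                     amplitude_rule = c("pulse", "gaussian"),
                     noise = c("none", "match_signal"), chirp_f1 = 500,
                     snippet_freq_range = NULL,
                     snippet_dur_range = c(0.1, 1.0), seed = NULL) {
  signal_kind <- match.arg(signal_kind)
  noise <- match.arg(noise)
  amplitude_rule <- match.arg(amplitude_rule)
  if (is.null(snippet_freq_range)) snippet_freq_range <- c(1, fs / 2)
  stopifnot(fs > 0, xi_true > 0, K_true >= 1, n_segments >= 1,
            segment_len >= 1)
  structure(list(fs = fs, xi_true = xi_true, K_true = as.integer(K_true),
                 signal_kind = signal_kind,
                 n_segments = as.integer(n_segments),
                 segment_len = as.integer(segment_len),
                 gap_range = gap_range, amplitude_ratio = amplitude_ratio,
                 amplitude_decay = amplitude_decay,
                 amplitude_rule = amplitude_rule,
                 noise = noise, chirp_f1 = chirp_f1,
                 snippet_freq_range = snippet_freq_range,
                 snippet_dur_range = snippet_dur_range, seed = seed),
            class = "sim_spec")
}

snippet_signal <- function(t_global, freq_range, dur_range) {
  t_end <- max(t_global) + 1e-9
  starts <- numeric(0); freqs <- numeric(0); amps <- numeric(0)
  t0 <- 0
  while (t0 < t_end) {
    starts <- c(starts, t0)
    freqs <- c(freqs, stats::runif(1, freq_range[1], freq_range[2]))
    amps <- c(amps, stats::rnorm(1))
    t0 <- t0 + stats::runif(1, dur_range[1], dur_range[2])
  }
  idx <- findInterval(t_global, starts)
  amps[idx] * sin(2 * pi * freqs[idx] * (t_global - starts[idx]))
}

#' Generate a synthetic recording from a specification
#'
#' @param spec a [sim_spec()].
#' @return a `sim_output` list: `observed`, `truth_signal` (underlying
#'   signal plus noise), `truth_artifact` (all [segmented_recording()]s
#'   satisfying `observed = truth_signal + truth_artifact` samplewise),
#'   `true_params` (an [artifact_params()] whose phase shifts are implied
#'   by the cumulative gap times), `gaps` (drawn gap lengths in samples),
#'   and the `spec`.
#' @export
simulate_recording <- function(spec) {
  gen <- function() {
    fs <- spec$fs; K <- spec$K_true; xi <- spec$xi_true
    ns <- spec$n_segments; len <- spec$segment_len

    decay <- seq_len(K)^(-spec$amplitude_decay)
    if (spec$amplitude_rule == "pulse") {
      phi <- stats::runif(K, 0, 2 * pi)
      alphas <- cos(phi) * decay
      betas <- sin(phi) * decay
    } else {
      alphas <- stats::rnorm(K) * decay
      betas <- stats::rnorm(K) * decay
    }

    gaps <- if (ns > 1) {
      stats::runif(ns - 1, spec$gap_range[1], spec$gap_range[2])
    } else numeric(0)
    seg_starts <- cumsum(c(0, gaps + len))  # in samples (real-valued)
    deltas <- (xi * seg_starts / fs) %% 1
    deltas[1] <- 0

    seg_id <- rep(seq_len(ns) - 1L, each = len)
    j <- rep(seq_len(len) - 1L, times = ns)
    t_local <- j / fs
    t_global <- (seg_starts[seg_id + 1L] + j) / fs

    base <- xi * t_local + deltas[seg_id + 1L]
    artifact <- numeric(length(j))
    for (k in seq_len(K)) {
      ph <- 2 * pi * k * base
      artifact <- artifact + alphas[k] * cos(ph) + betas[k] * sin(ph)
    }

    B <- switch(spec$signal_kind,
      none = numeric(length(j)),
      chirp = {
        T_total <- max(t_global) + 1 / fs
        sin(2 * pi * (spec$chirp_f1 / (2 * T_total)) * t_global^2)
      },
      snippets = {
        s <- snippet_signal(t_global, spec$snippet_freq_range,
                            spec$snippet_dur_range)
        s - mean(s)
      }
    )
    eta <- if (spec$noise == "match_signal") {
      stats::rnorm(length(j), sd = rms(B))
    } else numeric(length(j))
    underlying <- B + eta

    if (!is.na(spec$amplitude_ratio) && rms(underlying) > 0) {
      sc <- spec$amplitude_ratio * rms(underlying) / rms(artifact)
      artifact <- artifact * sc
      alphas <- alphas * sc
      betas <- betas * sc
    }

    mk <- function(vals) {
      as_recording(tibble::tibble(segment_id = seg_id, sample_index = j,
                                  value = vals), fs)
    }
    structure(
      list(observed = mk(artifact + underlying),
           truth_signal = mk(underlying),
           truth_artifact = mk(artifact),
           true_params = artifact_params(xi, deltas, 0, alphas, betas),
           gaps = gaps,
           spec = spec),
      class = "sim_output"
    )
  }
  if (!is.null(spec$seed)) withr::with_seed(as.integer(spec$seed), gen())
  else gen()
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output: %d segment(s) x %d samples, fs = %g Hz, xi = %.4f Hz (alias %.4f Hz)>\n",
    x$spec$n_segments, x$spec$segment_len, x$spec$fs, x$spec$xi_true,
    alias_frequency(x$spec$xi_true, x$spec$fs)))
  invisible(x)
}

#' Simulated example: well-sampled artifact, no underlying signal
#'
#' Single segment of 10^4 samples at 1000 Hz containing only a 5-harmonic
#' artifact at 150.6117 Hz (no underlying signal, no noise, no gaps).
#'
#' @param seed RNG seed.
#' @return a `sim_output` (see [simulate_recording()]).
#' @export
simulate_example1 <- function(seed = NULL) {
  simulate_recording(sim_spec(fs = 1000, signal_kind = "none",
                              n_segments = 1, segment_len = 1e4,
                              seed = seed))
}

#' Simulated example: well-sampled artifact over a chirp
#'
#' Single segment of 10^4 samples at 1000 Hz: a linear chirp sweeping 0 to
#' 500 Hz plus a 5-harmonic artifact at 150.6117 Hz whose RMS is 15 times
#' the chirp's.
#'
#' @inheritParams simulate_example1
#' @return a `sim_output`.
#' @export
simulate_example2 <- function(seed = NULL) {
  simulate_recording(sim_spec(fs = 1000, signal_kind = "chirp",
                              n_segments = 1, segment_len = 1e4,
                              amplitude_ratio = 15, seed = seed))
}

#' Simulated example: aliased artifact, neural-like signal, missing data
#'
#' Ten segments of 250 samples at 250 Hz. The artifact fundamental
#' (150.6117 Hz) exceeds Nyquist and aliases to 99.3883 Hz; the underlying
#' signal is a demeaned sum of random sinusoid snippets plus iid Gaussian
#' noise (noise sd = snippet RMS); gaps between segments are uniform on
#' (0, 500) samples with fractional parts, so the implied phase shifts are
#' generic; artifact RMS is 1.4 times the underlying signal's.
#'
#' @inheritParams simulate_example1
#' @return a `sim_output`.
#' @export
simulate_example3 <- function(seed = NULL) {
  simulate_recording(sim_spec(fs = 250, signal_kind = "snippets",
                              n_segments = 10, segment_len = 250,
                              gap_range = c(0, 500), amplitude_ratio = 1.4,
                              noise = "match_signal", seed = seed))
}

#' Frequency-error sensitivity of fixed-frequency harmonic regression
#'
#' For each relative frequency perturbation, draws fresh artifact-only
#' records (K = 5 harmonics, standard-normal amplitudes, fs = 1000 Hz,
#' fundamental uniform on (25, 200) Hz), fits harmonic regression at the
#' perturbed frequency, and averages the relative RMSE of the
#' reconstructed artifact against the true artifact.
#'
#' @param n_trials trials per grid point.
#' @param freq_errors relative frequency perturbations.
#' @param n_samples record length.
#' @param seed RNG seed.
#' @return a tibble with `rel_freq_error` and `mean_relative_rmse_pct`.
#' @export
figure_freq_sensitivity <- function(n_trials = 40,
                                    freq_errors = c(0, 1e-6, 1e-5, 1e-4, 1e-3),
                                    n_samples = 1e4, seed = NULL) {
  run <- function() {
    purrr::map_dfr(freq_errors, function(e) {
      errs <- purrr::map_dbl(seq_len(n_trials), function(i) {
        xi <- stats::runif(1, 25, 200)
        sim <- simulate_recording(sim_spec(fs = 1000, xi_true = xi,
                                           signal_kind = "none",
                                           segment_len = n_samples))
        hr <- harmonic_regression_fixed(sim$observed, xi * (1 + e), K = 5,
                                        truth_artifact = sim$truth_artifact)
        hr$report$artifact_relative_rmse_pct
      })
      tibble::tibble(rel_freq_error = e, mean_relative_rmse_pct = mean(errs))
    })
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' DFT baseline versus full method: frequency error by record length
#'
#' For each record length, draws artifact-only records (as in
#' [figure_freq_sensitivity()]) and estimates the fundamental frequency
#' two ways on the same draws: the DFT peak-energy baseline, and the full
#' chain (multi-start energy ascent initialized around the true nominal
#' frequency, then Newton refinement of the envelope objective). Reports
#' mean relative frequency errors in percent.
#'
#' @param sample_counts record lengths to test.
#' @param n_trials trials per length.
#' @param num_init random starts for the initializer.
#' @param seed RNG seed.
#' @return a tibble with `n_samples`, `dft_rel_err_pct`,
#'   `full_rel_err_pct`.
#' @export
figure_dft_comparison <- function(sample_counts = c(1e3, 1e4, 1e5),
                                  n_trials = 10, num_init = 25,
                                  seed = NULL) {
  run <- function() {
    purrr::map_dfr(sample_counts, function(N) {
      errs <- purrr::map_dfr(seq_len(n_trials), function(i) {
        xi <- stats::runif(1, 25, 200)
        sim <- simulate_recording(sim_spec(fs = 1000, xi_true = xi,
                                           signal_kind = "none",
                                           segment_len = N))
        dft <- dft_peak_frequency(sim$observed$value, 1000)
        # the full method needs no oracle: its search window is centered
        # on the coarse DFT estimate it is meant to improve upon
        res <- run_pipeline(sim$observed,
                            init_config(m0 = dft, delta_omega = 5,
                                        num_init = num_init,
                                        seed = sample.int(2^30, 1)),
                            removal_config(K_hat = 5), spectra = FALSE)
        tibble::tibble(dft = 100 * abs(dft - xi) / xi,
                       full = 100 * abs(res$report$omega_hz - xi) / xi)
      })
      tibble::tibble(n_samples = N,
                     dft_rel_err_pct = mean(errs$dft),
                     full_rel_err_pct = mean(errs$full))
    })
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}
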