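#' Relative root-mean-squared error (percent)
#'
#' `100 * sqrt(sum((f - fhat)^2) / sum(f^2))`, the package's reconstruction
#' error metric: the RMS of the estimation error relative to the RMS of the
#' true signal, in percent.
#'
#' @param truth true signal: numeric vector or [segmented_recording()].
#' @param estimate estimated signal of the same length.
#' @return relative RMSE in percent.
#' @examples
#' relative_rmse(c(2), c(1))  # 50
#' @export
relative_rmse <- function(truth, estimate) {
  f <- if (is.data.frame(truth)) truth$value else as.double(truth)
  fh <- if (is.data.frame(estimate)) estimate$value else as.double(estimate)
  if (length(f) != length(fh)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  denom <- sum(f^2)
  if (denom == 0) {
    stop("relative RMSE undefined: truth has zero energy", call. = FALSE)
  }
  100 * sqrt(sum((f - fh)^2) / denom)
}

#' DFT peak-energy frequency estimate (baseline)
#'
#' Estimates a signal's dominant frequency as the DFT grid frequency
#' `i * fs / N`, `i = 1, ..., floor(N/2) - 1`, maximizing the squared DFT
#' magnitude (the zero bin is excluded; ties go to the lowest frequency).
#' This is the standard baseline whose resolution is limited to the grid
#' spacing `fs / N`, which is why it cannot initialize harmonic regression
#' accurately enough on realistic record lengths.
#'
#' @param values numeric sample vector (single contiguous segment).
#' @param fs sampling rate in Hz.
#' @return estimated frequency in Hz.
#' @export
dft_peak_frequency <- function(values, fs) {
  values <- as.double(values)
  N <- length(values)
  if (N < 2L) stop("need at least 2 samples", call. = FALSE)
  mag2 <- Mod(stats::fft(values))^2
  idx <- seq(2L, max(2L, floor(N / 2)))  # bins 1 .. N/2 - 1 (0-based)
  if (max(mag2[idx]) <= 0 || stats::sd(values) == 0) {
    stop("no spectral peak: input is constant", call. = FALSE)
  }
  i <- idx[which.max(mag2[idx])] - 1L
  i * fs / N
}

#' Harmonic regression at a fixed frequency (baseline)
#'
#' Amplitude-only least-squares fit of the harmonic model at a given,
#' fixed fundamental frequency (and known phase shifts), followed by
#' subtraction. This is what the full method reduces to when frequency and
#' phases are not refined; its reconstruction error grows steeply with the
#' frequency error.
#'
#' @param rec a [segmented_recording()].
#' @param omega fixed fundamental frequency in Hz.
#' @param K number of harmonics.
#' @param deltas known phase shifts (default: all zero).
#' @param truth optional true underlying signal (recording or vector) for
#'   the error report.
#' @param truth_artifact optional true artifact for the artifact-error
#'   report.
#' @param include_mean fit the mean amplitude.
#' @return a list: `recovered` recording, `params` ([artifact_params()]),
#'   and `report` (one-row tibble with `freq_hz` and, when truths are
#'   supplied, `relative_rmse_pct` / `artifact_relative_rmse_pct`).
#' @export
harmonic_regression_fixed <- function(rec, omega, K, deltas = NULL,
                                      truth = NULL, truth_artifact = NULL,
                                      include_mean = TRUE) {
  if (is.null(deltas)) deltas <- rep(0, n_segments(rec))
  fit <- fit_amplitudes(rec, omega, deltas, K, include_mean)
  params <- artifact_params(omega, deltas, fit$alpha0, fit$alphas, fit$betas)
  recovered <- subtract_artifact(rec, params)
  report <- tibble::tibble(
    freq_hz = omega,
    g_value = fit$diagnostics$g_value,
    relative_rmse_pct = if (!is.null(truth)) {
      relative_rmse(truth, recovered)
    } else NA_real_,
    artifact_relative_rmse_pct = if (!is.null(truth_artifact)) {
      relative_rmse(truth_artifact, reconstruct_artifact(rec, params))
    } else NA_real_
  )
  list(recovered = recovered, params = params, report = report)
}

#' Alias (fold) a frequency into the first Nyquist zone
#'
#' Under uniform sampling at `fs`, a tone at `xi` Hz is indistinguishable
#' from its alias in `[0, fs/2]`: `r = xi mod fs`, folded to `fs - r` when
#' `r` exceeds the Nyquist frequency. Stimulation frequencies above
#' Nyquist appear digitally at this aliased frequency.
#'
#' @param xi frequency in Hz (vectorized).
#' @param fs sampling rate in Hz.
#' @return the aliased frequency in `[0, fs/2]`.
#' @examples
#' alias_frequency(150.6117, 250)  # 99.3883
#' @export
alias_frequency <- function(xi, fs) {
  stopifnot(all(xi > 0), fs > 0)
  r <- xi %% fs
  ifelse(r <= fs / 2, r, fs - r)
}

#' Closest alias image of a frequency estimate
#'
#' Under uniform sampling at `fs`, the harmonic model is exactly invariant
#' under `(omega, delta) -> (s * omega + m * fs, s * delta)` for any sign
#' `s` and integer `m`: all alias images reproduce the same samples. A
#' fitted frequency is therefore identifiable only up to this equivalence,
#' and error metrics against a known truth must be computed on the image
#' closest to it. Returns the equivalent `(omega, sign)` pair minimizing
#' `|s * omega + m * fs - reference|`.
#'
#' @param omega fitted frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param reference the frequency to fold towards (e.g. the true
#'   fundamental).
#' @return a list with `omega` (the closest image, in Hz) and `sign`
#'   (`+1` or `-1`; when `-1`, phases compare as `(-delta) mod 1`).
#' @export
closest_alias_image <- function(omega, fs, reference) {
  best <- NULL
  for (s in c(1, -1)) {
    m <- round((reference - s * omega) / fs)
    cand <- s * omega + m * fs
    if (is.null(best) || abs(cand - reference) < abs(best$omega - reference)) {
      best <- list(omega = cand, sign = s)
    }
  }
  best
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed, 50%-overlapping
#' blocks; one-sided density scaling.
#'
#' @param values numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param nperseg block length in samples; shrunk (with a warning) to
#'   `max(8, floor(N/4))` when the input is shorter.
#' @param overlap fractional block overlap.
#' @return a tibble with `frequency` (Hz) and `power` (units^2 / Hz).
#' @export
welch_psd <- function(values, fs, nperseg = 1024, overlap = 0.5) {
  values <- as.double(values)
  N <- length(values)
  if (N < nperseg) {
    nperseg <- max(8L, floor(N / 4))
    warning("input shorter than the Welch block; shrinking block to ",
            nperseg, " samples", call. = FALSE)
  }
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, N - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg %/% 1) / nperseg)  # periodic Hann
  U <- sum(win^2)
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- values[s:(s + nperseg - 1L)] * win
    p <- Mod(stats::fft(seg))^2 / (U * fs)
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  tibble::tibble(frequency = (seq_len(nfreq) - 1) * fs / nperseg,
                 power = psd * dbl)
}

#' Spectral report for a recording
#'
#' Welch PSD and short-time spectrogram of a recording's samples
#' (segments concatenated; the unknown gaps are ignored for display
#' purposes), plus band power extracted at requested frequencies.
#'
#' @param rec a [segmented_recording()].
#' @param bands optional frequencies (Hz) at which to report band power.
#' @param nperseg Welch / STFT block length.
#' @param overlap fractional overlap.
#' @return a `spectral_report` list: `psd` tibble, `spectrogram` tibble
#'   (`time`, `frequency`, `power_db`), and `band_power` tibble
#'   (`frequency`, `power`, `power_db`).
#' @export
spectral_report <- function(rec, bands = NULL, nperseg = 1024,
                            overlap = 0.5) {
  fs <- recording_fs(rec)
  values <- rec$value
  psd <- welch_psd(values, fs, nperseg, overlap)
  nps <- min(nperseg, max(8L, floor(length(values) / 4)))
  sg <- signal::specgram(values, n = nps, Fs = fs,
                         overlap = floor(nps * overlap))
  spec <- tibble::tibble(
    time = rep(as.double(sg$t), each = length(sg$f)),
    frequency = rep(as.double(sg$f), times = length(sg$t)),
    power_db = 10 * log10(as.vector(Mod(sg$S)^2) + .Machine$double.xmin)
  )
  band_power <- NULL
  if (!is.null(bands)) {
    idx <- vapply(bands, function(b) which.min(abs(psd$frequency - b)),
                  integer(1))
    band_power <- tibble::tibble(
      frequency = bands,
      bin_frequency = psd$frequency[idx],
      power = psd$power[idx],
      power_db = 10 * log10(psd$power[idx] + .Machine$double.xmin)
    )
  }
  structure(list(psd = psd, spectrogram = spec, band_power = band_power,
                 fs = fs),
            class = "spectral_report")
}

#' Band-power drop between two spectral reports (dB)
#'
#' @param before,after `spectral_report`s computed with the same settings
#'   and `bands`.
#' @return a tibble with `frequency` and `drop_db` (positive = power
#'   removed).
#' @export
band_power_drop <- function(before, after) {
  stopifnot(!is.null(before$band_power), !is.null(after$band_power))
  tibble::tibble(
    frequency = before$band_power$frequency,
    drop_db = before$band_power$power_db - after$band_power$power_db
  )
}

#' Plot a spectral report
#'
#' @param object a `spectral_report`.
#' @param ... unused.
#' @return a ggplot of the Welch PSD in dB.
#' @export
autoplot.spectral_report <- function(object, ...) {
  df <- dplyr::mutate(object$psd,
                      power_db = 10 * log10(.data$power + .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (dB)")
}
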