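#' Artifact parameters
#'
#' Parameters of the truncated-Fourier artifact model
#' \deqn{a(t) = \alpha_0 + \sum_{k=1}^{K} \alpha_k \cos(2\pi k(\omega t + \delta))
#'            + \beta_k \sin(2\pi k(\omega t + \delta)),}
#' where \eqn{\omega} is the fundamental frequency in Hz, \eqn{\delta} a
#' phase shift in cycles (one cycle = one artifact period), and
#' \eqn{\alpha_k, \beta_k} the harmonic amplitudes. A fitted multi-segment
#' model carries one \eqn{\delta_i} per segment, with \eqn{\delta_0 = 0} by
#' convention (phases are identifiable only relative to segment 0, and only
#' modulo 1).
#'
#' @param omega fundamental frequency in Hz (> 0).
#' @param deltas per-segment phase shifts in cycles; `deltas[1]` must be 0.
#' @param alpha0 mean amplitude (default 0).
#' @param alphas,betas numeric vectors of cosine / sine amplitudes, one per
#'   harmonic (equal length `K >= 1`).
#' @return an `artifact_params` object.
#' @export
artifact_params <- function(omega, deltas = 0, alpha0 = 0, alphas, betas) {
  if (length(omega) != 1L || !is.finite(omega) || omega <= 0) {
    stop("`omega` must be a single positive frequency in Hz", call. = FALSE)
  }
  if (length(alphas) != length(betas) || length(alphas) < 1L) {
    stop("`alphas` and `betas` must have equal length K >= 1", call. = FALSE)
  }
  if (length(deltas) < 1L || abs(deltas[1]) > 0) {
    stop("`deltas[1]` must be 0 (segment 0 is the phase reference)",
         call. = FALSE)
  }
  if (!all(is.finite(c(deltas, alpha0, alphas, betas)))) {
    stop("artifact parameters must be finite", call. = FALSE)
  }
  structure(
    list(omega = as.double(omega), deltas = as.double(deltas),
         alpha0 = as.double(alpha0), alphas = as.double(alphas),
         betas = as.double(betas), K = length(alphas)),
    class = "artifact_params"
  )
}

#' @export
print.artifact_params <- function(x, ...) {
  cat(sprintf("<artifact_params: omega = %.6f Hz, K = %d, %d phase shift(s)>\n",
              x$omega, x$K, length(x$deltas) - 1L))
  cat("  alpha0:", format(x$alpha0, digits = 4), "\n")
  cat("  harmonic amplitudes sqrt(alpha_k^2 + beta_k^2):",
      paste(format(sqrt(x$alphas^2 + x$betas^2), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy an artifact parameter set
#'
#' @param x an `artifact_params` object.
#' @param ... unused.
#' @return a tibble with one row per harmonic: `harmonic`, frequency in Hz,
#'   `alpha`, `beta`, the polar `amplitude` and `phase` (cycles).
#' @export
tidy.artifact_params <- function(x, ...) {
  k <- seq_len(x$K)
  tibble::tibble(
    harmonic = k,
    frequency_hz = k * x$omega,
    alpha = x$alphas,
    beta = x$betas,
    amplitude = sqrt(x$alphas^2 + x$betas^2),
    phase_cycles = atan2(x$betas, x$alphas) / (2 * pi)
  )
}

#' Evaluate the artifact model
#'
#' @param times sample times in seconds.
#' @param omega fundamental frequency in Hz.
#' @param delta phase shift in cycles.
#' @param alpha0 mean amplitude.
#' @param alphas,betas harmonic amplitude vectors (equal length).
#' @return the artifact waveform evaluated at `times`.
#' @examples
#' evaluate_artifact(c(0, 0.25), omega = 1, delta = 0,
#'                   alpha0 = 0, alphas = 1, betas = 0)
#' @export
evaluate_artifact <- function(times, omega, delta, alpha0, alphas, betas) {
  if (length(alphas) != length(betas)) {
    stop("`alphas` and `betas` must have the same length", call. = FALSE)
  }
  K <- length(alphas)
  out <- rep(alpha0, length(times))
  for (k in seq_len(K)) {
    ph <- 2 * pi * k * (omega * times + delta)
    out <- out + alphas[k] * cos(ph) + betas[k] * sin(ph)
  }
  out
}

#' Harmonic design matrix
#'
#' Columns are `1` (if `include_mean`), then
#' `cos(2 pi k (omega t + delta)), sin(2 pi k (omega t + delta))` for
#' `k = 1..K`, in that order.
#'
#' @inheritParams evaluate_artifact
#' @param K number of harmonics (>= 1).
#' @param include_mean include a constant column for the mean amplitude.
#' @return a `length(times) x (2K + include_mean)` matrix.
#' @export
design_matrix <- function(times, omega, delta, K, include_mean = TRUE) {
  if (length(times) == 0L) stop("`times` must be non-empty", call. = FALSE)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  M <- 2L * K + as.integer(include_mean)
  X <- matrix(0, length(times), M)
  col <- 1L
  if (include_mean) {
    X[, 1L] <- 1
    col <- 2L
  }
  for (k in seq_len(K)) {
    ph <- 2 * pi * k * (omega * times + delta)
    X[, col] <- cos(ph)
    X[, col + 1L] <- sin(ph)
    col <- col + 2L
  }
  X
}

# ---- variable-projection kernel -------------------------------------------
#
# All inner solves work in the normalized frequency nu = omega / fs, so the
# phase of harmonic k at sample j of segment i is 2*pi*k*(nu*j + delta_i).
# This keeps the frequency coordinate on the same O(1) scale as the phase
# coordinates regardless of record length.

# Stacked design matrix over segments at (nu, deltas).
vp_design <- function(fl, nu, deltas, K, include_mean) {
  M <- 2L * K + as.integer(include_mean)
  X <- matrix(0, length(fl$y), M)
  col <- 1L
  if (include_mean) {
    X[, 1L] <- 1
    col <- 2L
  }
  base <- nu * fl$j + deltas[fl$seg]
  for (k in seq_len(K)) {
    ph <- 2 * pi * k * base
    X[, col] <- cos(ph)
    X[, col + 1L] <- sin(ph)
    col <- col + 2L
  }
  X
}

# Closed-form inner least-squares fit of the amplitudes. Rank-revealing:
# falls back to the minimum-norm SVD solution when the (possibly aliased)
# harmonic columns collide.
vp_fit <- function(fl, nu, deltas, K, include_mean) {
  X <- vp_design(fl, nu, deltas, K, include_mean)
  M <- ncol(X)
  if (length(fl$y) < M) {
    stop("insufficient samples: need at least ", M, " for K = ", K,
         call. = FALSE)
  }
  qrx <- qr(X)
  rank_deficient <- qrx$rank < M
  rd <- abs(diag(qr.R(qrx)))
  condition_estimate <- max(rd) / max(min(rd), .Machine$double.xmin)
  if (!rank_deficient) {
    coef <- qr.coef(qrx, fl$y)
    resid <- fl$y - X %*% coef
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    keep <- sv$d > tol
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], fl$y)) / sv$d[keep])
    coef <- drop(coef)
    resid <- fl$y - X %*% coef
    condition_estimate <- sv$d[1] / max(sv$d[length(sv$d)], .Machine$double.xmin)
  }
  resid <- drop(resid)
  list(X = X, qrx = qrx, coef = drop(coef), resid = resid,
       g = sum(resid^2), rank_deficient = rank_deficient,
       condition_estimate = condition_estimate)
}

# Split a stacked coefficient vector into (alpha0, alphas, betas).
vp_split_coef <- function(coef, K, include_mean) {
  if (include_mean) {
    alpha0 <- coef[1]
    rest <- coef[-1]
  } else {
    alpha0 <- 0
    rest <- coef
  }
  idx <- seq_len(K)
  list(alpha0 = alpha0, alphas = rest[2 * idx - 1], betas = rest[2 * idx])
}

#' Closed-form amplitude fit at fixed frequency and phases
#'
#' Solves the inner linear least-squares problem of the variable-projection
#' (envelope) objective: given the nonlinear parameters — fundamental
#' frequency `omega` and per-segment phase shifts `deltas` — the harmonic
#' amplitudes minimizing the stacked residual sum of squares over all
#' segments have a closed form. The residual sum of squares at the optimum
#' is the envelope objective `g(omega, deltas)`.
#'
#' The stacked system is solved by a rank-revealing QR factorization; if
#' the harmonic columns (nearly) collide — which can happen when aliased
#' harmonics fold onto the same digital frequency — the minimum-norm SVD
#' solution is returned and flagged in the diagnostics.
#'
#' @param rec a [segmented_recording()].
#' @param omega fundamental frequency in Hz.
#' @param deltas phase shifts in cycles, length `n_segments(rec)`,
#'   `deltas[1] = 0`.
#' @param K number of harmonics to fit.
#' @param include_mean fit the mean amplitude `alpha0` (default TRUE; the
#'   recovered signal then has mean zero).
#' @return a list with `alpha0`, `alphas`, `betas`, and `diagnostics`
#'   (`g_value` = residual sum of squares, `condition_estimate`,
#'   `rank_deficient`).
#' @export
fit_amplitudes <- function(rec, omega, deltas, K, include_mean = TRUE) {
  fl <- rec_flat(rec)
  check_deltas(deltas, fl$n_seg)
  fit <- vp_fit(fl, omega / fl$fs, deltas, K, include_mean)
  amp <- vp_split_coef(fit$coef, K, include_mean)
  list(
    alpha0 = amp$alpha0, alphas = amp$alphas, betas = amp$betas,
    diagnostics = list(g_value = fit$g,
                       condition_estimate = fit$condition_estimate,
                       rank_deficient = fit$rank_deficient)
  )
}

check_deltas <- function(deltas, n_seg) {
  if (length(deltas) != n_seg) {
    stop("`deltas` must have length ", n_seg, " (one per segment)",
         call. = FALSE)
  }
  if (abs(deltas[1]) > 0) {
    stop("`deltas[1]` must be 0 (segment 0 is the phase reference)",
         call. = FALSE)
  }
  invisible(deltas)
}

#' Reconstruct the artifact on a recording's sample grid
#'
#' @param rec a [segmented_recording()] supplying the segment structure.
#' @param params an [artifact_params()] whose `deltas` match the segments.
#' @return a recording whose values are the model artifact.
#' @export
reconstruct_artifact <- function(rec, params) {
  fl <- rec_flat(rec)
  check_deltas(params$deltas, fl$n_seg)
  # per-segment phase: shift each segment by its delta through the phase
  # argument rather than the time axis
  a <- rep(params$alpha0, length(fl$y))
  base <- params$omega * fl$j / fl$fs + params$deltas[fl$seg]
  for (k in seq_len(params$K)) {
    ph <- 2 * pi * k * base
    a <- a + params$alphas[k] * cos(ph) + params$betas[k] * sin(ph)
  }
  rec_replace_values(rec, a)
}

#' Subtract a fitted artifact from a recording
#'
#' Evaluates the artifact model segment-wise at the sample times `j / fs`
#' (with each segment's own phase shift) and subtracts it, leaving the
#' recovered underlying signal. When the model was fitted with
#' `include_mean = TRUE`, the recovered recording has overall mean zero up
#' to numerical precision.
#'
#' @inheritParams reconstruct_artifact
#' @return the recovered [segmented_recording()].
#' @export
subtract_artifact <- function(rec, params) {
  art <- reconstruct_artifact(rec, params)
  rec_replace_values(rec, rec$value - art$value)
}

#' Serialize artifact parameters to / from JSON
#'
#' Keys: `omega_hz`, `deltas`, `alpha0`, `alphas`, `betas`, `K`.
#'
#' @param params an [artifact_params()].
#' @param path file path.
#' @return `write_artifact_params()` returns `path` invisibly;
#'   `read_artifact_params()` returns an [artifact_params()].
#' @export
write_artifact_params <- function(params, path) {
  jsonlite::write_json(
    list(omega_hz = params$omega, deltas = params$deltas,
         alpha0 = params$alpha0, alphas = params$alphas,
         betas = params$betas, K = params$K),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_artifact_params
#' @export
read_artifact_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  artifact_params(omega = x$omega_hz, deltas = x$deltas, alpha0 = x$alpha0,
                  alphas = x$alphas, betas = x$betas)
}
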