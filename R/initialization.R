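#' Initializer configuration
#'
#' Controls the multi-start modified-Newton ascent on the cross-segment
#' alignment energy. The frequency search window is
#' `[m0 - delta_omega, m0 + delta_omega]`; `m0` is typically the nominal
#' device stimulation frequency and the window is applied to the nominal
#' frequency even when it exceeds the Nyquist frequency — the model
#' evaluated at the sample times aliases naturally, so no explicit folding
#' of the search space is needed.
#'
#' @param m0 center of the frequency search window in Hz.
#' @param delta_omega half-width of the window in Hz.
#' @param num_init number of random starts.
#' @param maxiter per-start iteration cap.
#' @param tol1 gradient tolerance (infinity norm, normalized coordinates).
#' @param tol2 relative energy-increase tolerance.
#' @param seed optional RNG seed for the random starts; if `NULL` the
#'   current RNG state is used.
#' @return an `init_config` list.
#' @export
init_config <- function(m0, delta_omega = 5, num_init = 25, maxiter = 5000,
                        tol1 = 1e-8, tol2 = 1e-8, seed = NULL) {
  stopifnot(m0 > 0, delta_omega > 0, num_init >= 1, maxiter >= 1,
            tol1 > 0, tol2 > 0)
  structure(list(m0 = m0, delta_omega = delta_omega,
                 num_init = as.integer(num_init),
                 maxiter = as.integer(maxiter), tol1 = tol1, tol2 = tol2,
                 seed = seed),
            class = "init_config")
}

# ---- alignment energy -----------------------------------------------------
#
# F(omega, deltas) = sum_l integral_0^{T_l} S_l(t) exp(-2 pi i (omega t +
# delta_l)) dt, approximated segmentwise by the trapezoidal rule on the
# uniform sample grid (endpoint weights 1/(2 fs), interior weights 1/fs).
# E = |F|^2. Maximizing E aligns all segments in phase with a single
# complex exponential; it is 1-periodic in every delta_l.

trapezoid_weights <- function(fl) {
  w <- rep(1 / fl$fs, length(fl$y))
  ends <- cumsum(fl$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  half <- fl$lengths > 1L
  w[starts[half]] <- 0.5 / fl$fs
  w[ends[half]] <- 0.5 / fl$fs
  w
}

energy_core <- function(fl, nu, deltas, derivatives = FALSE) {
  w <- trapezoid_weights(fl)
  psi <- 2 * pi * (nu * fl$j + deltas[fl$seg])
  q <- (w * fl$y) * complex(real = cos(psi), imaginary = -sin(psi))
  FF <- sum(q)
  out <- list(F = FF, E = Re(FF * Conj(FF)))
  if (derivatives) {
    A <- vp_amat(fl)
    Fp <- -2i * pi * drop(crossprod(A, q))
    Fpq <- -4 * pi^2 * crossprod(A, A * q)
    grad <- 2 * Re(Conj(FF) * Fp)
    H <- 2 * Re(outer(Fp, Conj(Fp))) + 2 * Re(Conj(FF) * Fpq)
    out$grad <- grad
    out$hess <- (H + t(H)) / 2
  }
  out
}

#' Cross-segment alignment energy
#'
#' @param rec a [segmented_recording()].
#' @param omega frequency in Hz.
#' @param deltas phase shifts in cycles (`deltas[1] = 0`).
#' @return the scalar energy `E = |F|^2`, where `F` sums the trapezoid-rule
#'   Fourier integrals of all segments phase-shifted by their `delta`s.
#' @export
energy <- function(rec, omega, deltas) {
  fl <- rec_flat(rec)
  check_deltas(deltas, fl$n_seg)
  energy_core(fl, omega / fl$fs, deltas)$E
}

#' Gradient and Hessian of the alignment energy
#'
#' Analytic derivatives of the trapezoid-discretized energy (the discrete
#' sum is differentiated, not the continuous integral) with respect to
#' `(omega, delta_1, ..., delta_n)`. The frequency coordinate is in Hz.
#'
#' @inheritParams energy
#' @return a list with `gradient` (length `n + 1`) and `hessian`.
#' @export
energy_gradient_hessian <- function(rec, omega, deltas) {
  fl <- rec_flat(rec)
  check_deltas(deltas, fl$n_seg)
  ec <- energy_core(fl, omega / fl$fs, deltas, derivatives = TRUE)
  scale <- c(1 / fl$fs, rep(1, fl$n_seg - 1L))
  list(gradient = ec$grad * scale, hessian = ec$hess * tcrossprod(scale))
}

#' Single-start modified-Newton ascent on the alignment energy
#'
#' Ascends `E` from one starting point. Each step solves
#' `(-H + tau I) d = grad` where the diagonal shift `tau` (modified
#' Cholesky repair) is the smallest power-of-ten multiple of the identity
#' making the factorization of `-H` succeed, followed by Armijo
#' backtracking on `-E`; the energy trace is therefore non-decreasing.
#'
#' @param rec a [segmented_recording()].
#' @param omega_start starting frequency in Hz.
#' @param deltas_start starting phase shifts (`deltas_start[1] = 0`).
#' @param config an [init_config()].
#' @return an `init_fit` object with `omega`, `deltas` (wrapped to
#'   `[0, 1)`), `energy`, `energy_trace`, `iterations`, `converged`.
#' @export
ascend <- function(rec, omega_start, deltas_start = NULL, config) {
  fl <- rec_flat(rec)
  if (is.null(deltas_start)) deltas_start <- rep(0, fl$n_seg)
  check_deltas(deltas_start, fl$n_seg)

  x <- c(omega_start / fl$fs, deltas_start[-1])
  ec <- energy_core(fl, x[1], c(0, x[-1]), derivatives = TRUE)
  trace <- ec$E
  converged <- FALSE
  reason <- "maxiter"
  iter <- 0L

  while (iter < config$maxiter) {
    iter <- iter + 1L
    if (!is.finite(ec$E)) stop("energy diverged", call. = FALSE)
    if (max(abs(ec$grad)) <= config$tol1) {
      converged <- TRUE; reason <- "gradient"; iter <- iter - 1L
      break
    }
    R <- pd_chol(-ec$hess)
    d <- backsolve(R, forwardsolve(t(R), ec$grad))
    slope <- sum(d * ec$grad)
    if (!is.finite(slope) || slope <= 0) {
      d <- ec$grad
      slope <- sum(ec$grad^2)
    }
    alpha <- 1
    accepted <- FALSE
    for (bt in 0:50) {
      x_new <- x + alpha * d
      ec_new <- energy_core(fl, x_new[1], c(0, x_new[-1]))
      if (is.finite(ec_new$E) && ec_new$E >= ec$E + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      converged <- TRUE; reason <- "line_search_stall"; iter <- iter - 1L
      break
    }
    increase <- ec_new$E - ec$E
    x <- x_new
    if (length(x) > 1L) x[-1] <- x[-1] %% 1
    trace <- c(trace, ec_new$E)
    ec <- energy_core(fl, x[1], c(0, x[-1]), derivatives = TRUE)
    if (increase / max(abs(ec_new$E), .Machine$double.xmin) <= config$tol2) {
      converged <- TRUE; reason <- "objective"
      break
    }
  }

  structure(
    list(omega = x[1] * fl$fs,
         deltas = c(0, if (length(x) > 1L) x[-1] %% 1),
         energy = utils::tail(trace, 1),
         energy_trace = trace,
         iterations = iter,
         converged = converged,
         reason = reason,
         fs = fl$fs),
    class = "init_fit"
  )
}

#' Closed-form phase alignment at a fixed frequency
#'
#' For a fixed frequency the alignment energy has an exact maximizer in
#' the phases: writing `F_l` for segment `l`'s trapezoid-rule Fourier
#' integral at `omega`, `|sum_l exp(-2 pi i delta_l) F_l|` is maximal when
#' every term is rotated onto a common phase, i.e.
#' `delta_l = (arg F_l - arg F_0) / (2 pi)` (mod 1), with `delta_0 = 0`.
#' Useful as a deterministic starting point at a nominal device frequency.
#'
#' @param rec a [segmented_recording()].
#' @param omega frequency in Hz.
#' @return phase shifts in cycles (length `n_segments(rec)`, first entry 0).
#' @export
phase_align <- function(rec, omega) {
  fl <- rec_flat(rec)
  w <- trapezoid_weights(fl)
  psi <- 2 * pi * (omega / fl$fs) * fl$j
  q <- (w * fl$y) * complex(real = cos(psi), imaginary = -sin(psi))
  Fl <- vapply(seq_len(fl$n_seg),
               function(i) sum(q[fl$seg == i]), complex(1))
  d <- (Arg(Fl) - Arg(Fl[1])) / (2 * pi)
  d <- d %% 1
  d[1] <- 0
  d
}

#' Multi-start frequency and phase initializer
#'
#' Runs [ascend()] from `num_init` random starts — frequencies uniform on
#' `[m0 - delta_omega, m0 + delta_omega]`, phase shifts uniform on
#' `[0, 1)^n` — and returns the start achieving the maximal alignment
#' energy (ties broken by the lowest start index). Fully reproducible when
#' `config$seed` is set.
#'
#' @param rec a [segmented_recording()].
#' @param config an [init_config()].
#' @return an `init_fit` with the winning `omega`, `deltas`, `energy`, plus
#'   `start_index` and `per_start_energies`.
#' @export
init_artifact <- function(rec, config) {
  n <- n_gaps(rec)
  draw <- function() {
    list(
      omega = stats::runif(config$num_init, config$m0 - config$delta_omega,
                           config$m0 + config$delta_omega),
      deltas = matrix(stats::runif(config$num_init * n), config$num_init, n)
    )
  }
  starts <- if (!is.null(config$seed)) {
    withr::with_seed(as.integer(config$seed), draw())
  } else {
    draw()
  }
  fits <- vector("list", config$num_init)
  energies <- rep(-Inf, config$num_init)
  for (s in seq_len(config$num_init)) {
    fit <- tryCatch(
      ascend(rec, starts$omega[s],
             c(0, if (n > 0) starts$deltas[s, ]), config),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      fits[[s]] <- fit
      energies[s] <- fit$energy
    }
  }
  if (all(!is.finite(energies))) {
    stop("all initializer starts diverged", call. = FALSE)
  }
  best <- which.max(energies)  # ties: lowest index
  out <- fits[[best]]
  out$start_index <- best
  out$per_start_energies <- energies
  ok <- !vapply(fits, is.null, logical(1))
  out$starts <- tibble::tibble(
    start = which(ok),
    omega = vapply(fits[ok], `[[`, numeric(1), "omega"),
    energy = energies[ok],
    iterations = vapply(fits[ok], `[[`, integer(1), "iterations"),
    deltas = lapply(fits[ok], `[[`, "deltas")
  )
  out
}

#' @export
print.init_fit <- function(x, ...) {
  cat(sprintf("<init_fit: omega = %.6f Hz, energy = %.6g, %d iteration(s)>\n",
              x$omega, x$energy, x$iterations))
  if (!is.null(x$start_index)) {
    cat(sprintf("  winning start %d of %d\n", x$start_index,
                length(x$per_start_energies)))
  }
  invisible(x)
}

#' Tidy / glance methods for initializer fits
#'
#' `tidy()` returns one row per random start with its achieved energy;
#' `glance()` a one-row summary of the winning start.
#'
#' @param x an `init_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.init_fit <- function(x, ...) {
  if (is.null(x$per_start_energies)) {
    return(tibble::tibble(start = 1L, energy = x$energy, winner = TRUE))
  }
  tibble::tibble(
    start = seq_along(x$per_start_energies),
    energy = x$per_start_energies,
    winner = seq_along(x$per_start_energies) == x$start_index
  )
}

#' @rdname tidy.init_fit
#' @export
glance.init_fit <- function(x, ...) {
  tibble::tibble(
    omega_hz = x$omega,
    alias_hz = alias_frequency(x$omega, x$fs),
    energy = x$energy,
    iterations = x$iterations,
    converged = x$converged,
    start_index = x$start_index %||% NA_integer_
  )
}
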