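#' Removal configuration
#'
#' Controls the Newton descent on the envelope objective `g`. Defaults are
#' the settings used throughout the package's simulated examples.
#'
#' @param K_hat number of harmonics to fit (the method's single real tuning
#'   parameter).
#' @param maxiter iteration cap.
#' @param tol1 gradient tolerance: stop when the infinity norm of the
#'   gradient of `g` in normalized coordinates (frequency measured in
#'   cycles/sample) falls at or below `tol1`.
#' @param tol2 objective tolerance: stop when the relative decrease of `g`
#'   in one iteration falls at or below `tol2`.
#' @param include_mean fit the mean amplitude `alpha0` (recovered signal
#'   then has mean zero).
#' @param hessian `"exact"` for the full implicit-differentiation Hessian of
#'   the envelope, `"gauss_newton"` to drop the residual-weighted curvature
#'   term.
#' @return a `removal_config` list.
#' @export
removal_config <- function(K_hat = 5, maxiter = 1000, tol1 = 1e-8,
                           tol2 = 1e-16, include_mean = TRUE,
                           hessian = c("exact", "gauss_newton")) {
  stopifnot(K_hat >= 1, maxiter >= 1, tol1 > 0, tol2 > 0)
  structure(list(K_hat = as.integer(K_hat), maxiter = as.integer(maxiter),
                 tol1 = tol1, tol2 = tol2, include_mean = isTRUE(include_mean),
                 hessian = match.arg(hessian)),
            class = "removal_config")
}

#' Envelope objective g
#'
#' `g(omega, deltas)` is the residual sum of squares of the harmonic
#' regression after the amplitudes have been minimized out in closed form
#' (variable projection). It is 1-periodic in every phase shift and, for
#' uniform sampling, `fs`-periodic in `omega`.
#'
#' @inheritParams fit_amplitudes
#' @return the scalar objective value.
#' @export
objective_g <- function(rec, omega, deltas, K, include_mean = TRUE) {
  fl <- rec_flat(rec)
  check_deltas(deltas, fl$n_seg)
  vp_fit(fl, omega / fl$fs, deltas, K, include_mean)$g
}

# ---- analytic derivatives of the envelope ---------------------------------
#
# Let X(theta) be the stacked design, beta = argmin |y - X b|, r = y - X beta,
# g = |r|^2, with theta = (nu, delta_1..delta_n) and phases
# phi = 2 pi k (nu j + delta_seg), linear in theta. Writing the column-wise
# phase derivatives D1[,c] = f_c'(phi) 2 pi k_c and
# D2[,c] = f_c''(phi) (2 pi k_c)^2, and the row scalings a_p (a_nu = j,
# a_delta_i = 1{segment i}), we have X_p = a_p * D1 and X_pq = a_p a_q * D2.
# Envelope theorem: grad_p = -2 r' X_p beta. Implicit differentiation of the
# normal equations gives beta_q = (X'X)^{-1} (X_q' r - X' X_q beta), and
#   H_pq = 2 [ (X_q beta)'(X_p beta) - r' X_pq beta - rhs_p' (X'X)^{-1} rhs_q ]
# with rhs_p = X_p' r - X' X_p beta, which is symmetric by construction.
# Dropping the r' X_pq beta term yields the Gauss-Newton surrogate.

vp_deriv_mats <- function(fl, nu, deltas, K, include_mean) {
  M <- 2L * K + as.integer(include_mean)
  D1 <- matrix(0, length(fl$y), M)
  D2 <- matrix(0, length(fl$y), M)
  col <- if (include_mean) 2L else 1L
  base <- nu * fl$j + deltas[fl$seg]
  for (k in seq_len(K)) {
    tpk <- 2 * pi * k
    ph <- tpk * base
    s <- sin(ph); c <- cos(ph)
    D1[, col] <- -tpk * s
    D1[, col + 1L] <- tpk * c
    D2[, col] <- -tpk^2 * c
    D2[, col + 1L] <- -tpk^2 * s
    col <- col + 2L
  }
  list(D1 = D1, D2 = D2)
}

# Row-scaling matrix: column 1 is the frequency coordinate (j for the
# normalized parametrization), columns 2..(n+1) are segment indicators.
vp_amat <- function(fl) {
  P <- fl$n_seg  # 1 (frequency) + n phases
  A <- matrix(0, length(fl$y), P)
  A[, 1L] <- fl$j
  if (P > 1L) {
    for (i in 2L:P) A[, i] <- as.double(fl$seg == i)
  }
  A
}

vp_grad_hess <- function(fl, nu, deltas, K, include_mean,
                         hessian = "exact", fit = NULL) {
  if (is.null(fit)) fit <- vp_fit(fl, nu, deltas, K, include_mean)
  dm <- vp_deriv_mats(fl, nu, deltas, K, include_mean)
  A <- vp_amat(fl)
  beta <- fit$coef
  r <- fit$resid
  v <- drop(dm$D1 %*% beta)            # per-row d(model)/d(phase-block)
  grad <- -2 * drop(crossprod(A, r * v))
  A1 <- crossprod(A * v)
  RHS <- crossprod(dm$D1, A * r) - crossprod(fit$X, A * v)
  G <- crossprod(fit$X)
  S <- tryCatch({
    cG <- chol(G)
    backsolve(cG, forwardsolve(t(cG), RHS))
  }, error = function(e) {
    # rank-deficient inner fit: derivatives at the minimum-norm solution
    sv <- svd(G)
    keep <- sv$d > max(sv$d[1], 1) * .Machine$double.eps * nrow(G)
    sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], RHS) / sv$d[keep])
  })
  H <- A1 - crossprod(RHS, S)
  if (identical(hessian, "exact")) {
    w <- drop(dm$D2 %*% beta)
    H <- H - crossprod(A, (r * w) * A)
  }
  H <- 2 * (H + t(H)) / 2
  list(g = fit$g, grad = grad, hess = H, fit = fit)
}

#' Gradient and Hessian of the envelope objective
#'
#' Analytic derivatives of `g` with respect to `(omega, delta_1, ...,
#' delta_n)`, obtained by the envelope theorem (gradient) and implicit
#' differentiation of the inner amplitude solution (Hessian). The frequency
#' coordinate is reported in Hz.
#'
#' @inheritParams objective_g
#' @param hessian `"exact"` or `"gauss_newton"` (see [removal_config()]).
#' @return a list with `gradient` (length `n + 1`; first entry d/d omega in
#'   1/Hz units) and `hessian` (`(n+1) x (n+1)`).
#' @export
g_gradient_hessian <- function(rec, omega, deltas, K, include_mean = TRUE,
                               hessian = "exact") {
  fl <- rec_flat(rec)
  check_deltas(deltas, fl$n_seg)
  gh <- vp_grad_hess(fl, omega / fl$fs, deltas, K, include_mean, hessian)
  # chain rule from normalized nu = omega/fs back to Hz
  scale <- c(1 / fl$fs, rep(1, fl$n_seg - 1L))
  list(gradient = gh$grad * scale,
       hessian = gh$hess * tcrossprod(scale))
}

# Positive-definite repair by diagonal shift: smallest tau (powers of 10
# from machine-epsilon scale) such that chol(H + tau I) succeeds. Returns
# the Cholesky factor.
pd_chol <- function(H) {
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (!is.null(R)) return(R)
  scale <- max(abs(diag(H)), 1)
  tau <- scale * .Machine$double.eps
  for (i in 1:40) {
    R <- tryCatch(chol(H + diag(tau, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    tau <- tau * 10
  }
  stop("Hessian repair failed: matrix cannot be made positive definite",
       call. = FALSE)
}

#' Newton refinement of frequency and phase shifts
#'
#' Minimizes the envelope objective `g` over the fundamental frequency and
#' the per-segment phase shifts by a safeguarded Newton descent: the
#' amplitudes are eliminated in closed form at every step, the Hessian is
#' repaired to positive definite by a diagonal shift when needed, and an
#' Armijo backtracking line search guarantees a monotone objective trace.
#' Internally the frequency is optimized in normalized units
#' (cycles/sample); the interface is in Hz.
#'
#' @param rec a [segmented_recording()].
#' @param omega0 starting frequency in Hz (e.g. from [init_artifact()]).
#' @param deltas0 starting phase shifts in cycles (`deltas0[1] = 0`);
#'   defaults to all zero.
#' @param config a [removal_config()].
#' @return a `removal_fit` object: `params` ([artifact_params()] from a
#'   final inner fit), `recovered` (artifact-subtracted recording),
#'   `g_trace`, `grad_norm_final` (infinity norm, normalized coordinates),
#'   `iterations`, `converged`, `reason`, and inner-fit `diagnostics`.
#' @export
newton_refine <- function(rec, omega0, deltas0 = NULL,
                          config = removal_config()) {
  fl <- rec_flat(rec)
  if (is.null(deltas0)) deltas0 <- rep(0, fl$n_seg)
  check_deltas(deltas0, fl$n_seg)
  stopifnot(omega0 > 0)
  K <- config$K_hat
  inc <- config$include_mean

  x <- c(omega0 / fl$fs, deltas0[-1])
  eval_at <- function(x) vp_fit(fl, x[1], c(0, x[-1]), K, inc)

  g_trace <- numeric(0)
  converged <- FALSE
  reason <- "maxiter"
  iter <- 0L
  grad_norm <- NA_real_
  gh <- vp_grad_hess(fl, x[1], c(0, x[-1]), K, inc, config$hessian)
  g_trace <- gh$g

  while (iter < config$maxiter) {
    iter <- iter + 1L
    grad_norm <- max(abs(gh$grad))
    if (!is.finite(gh$g)) stop("objective diverged (non-finite g)", call. = FALSE)
    if (grad_norm <= config$tol1) {
      converged <- TRUE; reason <- "gradient"; iter <- iter - 1L
      break
    }
    R <- pd_chol(gh$hess)
    d <- -backsolve(R, forwardsolve(t(R), gh$grad))
    slope <- sum(d * gh$grad)
    if (!is.finite(slope) || slope >= 0) {
      d <- -gh$grad
      slope <- -sum(gh$grad^2)
    }
    alpha <- 1
    accepted <- FALSE
    for (bt in 0:50) {
      x_new <- x + alpha * d
      fit_new <- tryCatch(eval_at(x_new), error = function(e) NULL)
      if (!is.null(fit_new) && is.finite(fit_new$g) &&
          fit_new$g <= gh$g + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      converged <- TRUE; reason <- "line_search_stall"; iter <- iter - 1L
      break
    }
    decrease <- gh$g - fit_new$g
    rel_decrease <- decrease / max(gh$g, .Machine$double.xmin)
    # wrap phases to [0,1); g is exactly 1-periodic so this is free
    x <- x_new
    if (length(x) > 1L) x[-1] <- x[-1] %% 1
    g_trace <- c(g_trace, fit_new$g)
    gh <- vp_grad_hess(fl, x[1], c(0, x[-1]), K, inc, config$hessian)
    if (rel_decrease <= config$tol2) {
      converged <- TRUE; reason <- "objective"
      break
    }
  }
  grad_norm <- max(abs(gh$grad))

  omega <- x[1] * fl$fs
  deltas <- c(0, if (length(x) > 1L) x[-1] %% 1)
  final <- fit_amplitudes(rec, omega, deltas, K, inc)
  params <- artifact_params(omega, deltas, final$alpha0, final$alphas,
                            final$betas)
  structure(
    list(params = params,
         recovered = subtract_artifact(rec, params),
         g_trace = g_trace,
         grad_norm_final = grad_norm,
         iterations = iter,
         converged = converged,
         reason = reason,
         diagnostics = final$diagnostics,
         fs = fl$fs,
         config = config),
    class = "removal_fit"
  )
}

#' @export
print.removal_fit <- function(x, ...) {
  cat(sprintf("<removal_fit: omega = %.8f Hz (alias %.6f Hz), K = %d>\n",
              x$params$omega, alias_frequency(x$params$omega, x$fs),
              x$params$K))
  cat(sprintf("  g = %.6g after %d iteration(s); |grad|_inf = %.3g; %s (%s)\n",
              utils::tail(x$g_trace, 1), x$iterations, x$grad_norm_final,
              if (x$converged) "converged" else "not converged", x$reason))
  invisible(x)
}

#' Tidy / glance methods for removal fits
#'
#' `tidy()` returns the per-harmonic amplitude table of the fitted artifact
#' model; `glance()` returns a one-row model summary.
#'
#' @param x a `removal_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.removal_fit <- function(x, ...) tidy(x$params)

#' @rdname tidy.removal_fit
#' @export
glance.removal_fit <- function(x, ...) {
  tibble::tibble(
    omega_hz = x$params$omega,
    alias_hz = alias_frequency(x$params$omega, x$fs),
    K = x$params$K,
    n_gaps = length(x$params$deltas) - 1L,
    g_final = utils::tail(x$g_trace, 1),
    grad_norm = x$grad_norm_final,
    iterations = x$iterations,
    converged = x$converged,
    reason = x$reason
  )
}

#' Plot the objective trace of a removal fit
#'
#' @param object a `removal_fit`.
#' @param ... unused.
#' @return a ggplot object (log-scale objective versus iteration).
#' @export
autoplot.removal_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$g_trace) - 1L,
                       g = object$g_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$g)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Newton iteration", y = "envelope objective g")
}
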