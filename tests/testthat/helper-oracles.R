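# Independent oracles used to cross-check the package's fast paths.
# They are deliberately written as plain loops over the model definition,
# sharing no code with the implementation.

# Dense least-squares oracle for the envelope objective: build the stacked
# harmonic design column by column at local times j/fs and compute the
# residual sum of squares of an SVD-based minimum-norm solve.
oracle_g <- function(rec, omega, deltas, K, include_mean = TRUE) {
  fs <- recording_fs(rec)
  vals <- segment_values(rec)
  X <- NULL
  y <- NULL
  for (i in seq_along(vals)) {
    t <- (seq_along(vals[[i]]) - 1) / fs
    cols <- list()
    if (include_mean) cols <- c(cols, list(rep(1, length(t))))
    for (k in seq_len(K)) {
      cols <- c(cols, list(cos(2 * pi * k * (omega * t + deltas[i]))),
                list(sin(2 * pi * k * (omega * t + deltas[i]))))
    }
    X <- rbind(X, do.call(cbind, cols))
    y <- c(y, vals[[i]])
  }
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-12
  theta <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  sum((y - X %*% theta)^2)
}

# Explicit trapezoid-weight alignment-energy oracle.
oracle_energy <- function(rec, omega, deltas) {
  fs <- recording_fs(rec)
  vals <- segment_values(rec)
  FF <- 0 + 0i
  for (i in seq_along(vals)) {
    n <- length(vals[[i]])
    w <- rep(1 / fs, n)
    if (n > 1) w[c(1, n)] <- 0.5 / fs
    t <- (seq_len(n) - 1) / fs
    FF <- FF + sum(w * vals[[i]] * exp(-2i * pi * (omega * t + deltas[i])))
  }
  Mod(FF)^2
}

# Central finite differences of a scalar function over (omega, deltas),
# stepping h in each coordinate (omega in Hz, deltas in cycles).
fd_gradient <- function(f, omega, deltas, h = 1e-5) {
  n <- length(deltas) - 1L
  g <- numeric(n + 1L)
  g[1] <- (f(omega + h, deltas) - f(omega - h, deltas)) / (2 * h)
  for (i in seq_len(n)) {
    dp <- deltas; dm <- deltas
    dp[i + 1L] <- dp[i + 1L] + h
    dm[i + 1L] <- dm[i + 1L] - h
    g[i + 1L] <- (f(omega, dp) - f(omega, dm)) / (2 * h)
  }
  g
}

# Small multi-segment artifact + noise fixture with known parameters.
make_test_instance <- function(seed, n_segments = 3, segment_len = 200,
                               fs = 250, noise_sd = 0, K = 3) {
  withr::with_seed(seed, {
    xi <- 150.6117
    deltas <- c(0, runif(n_segments - 1))
    phi <- runif(K, 0, 2 * pi)
    alphas <- cos(phi) / seq_len(K)
    betas <- sin(phi) / seq_len(K)
    vals <- lapply(seq_len(n_segments), function(i) {
      t <- (seq_len(segment_len) - 1) / fs
      evaluate_artifact(t, xi, deltas[i], 0, alphas, betas) +
        rnorm(segment_len, sd = noise_sd)
    })
    list(rec = segmented_recording(vals, fs),
         params = artifact_params(xi, deltas, 0, alphas, betas))
  })
}
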