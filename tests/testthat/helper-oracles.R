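# Independent brute-force oracles used across the suite. These use plain
# dense linear algebra (solve / det / integrate), deliberately avoiding
# the package's Cholesky code paths.

# dense multivariate-normal log density
mvn_logdens_oracle <- function(y, mu, S) {
  n <- length(y)
  r <- y - mu
  -0.5 * drop(t(r) %*% solve(S, r)) -
    0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi)
}

# dense GP posterior mean/variance oracle
gp_posterior_oracle <- function(K, Ks, kss, y, mu, mus, noise) {
  Cinv <- solve(K + diag(noise, nrow(K)))
  mean <- mus + drop(t(Ks) %*% Cinv %*% (y - mu))
  var <- kss - diag(t(Ks) %*% Cinv %*% Ks)
  list(mean = mean, var = var)
}

# Matern 3/2 covariance, elementwise closed form
matern32_oracle <- function(x1, x2, variance, lengthscale) {
  a <- sqrt(3) * abs(x1 - x2) / lengthscale
  variance * (1 + a) * exp(-a)
}

# numeric inverse Fourier transform of the Gaussian-mixture spectral
# density: k(tau) = sum_q w_q \int N(w; mu_q, s_q^2) cos(2 pi tau w) dw
sm_ift_oracle <- function(tau, weights, means, scales) {
  vapply(tau, function(t) {
    sum(vapply(seq_along(weights), function(q) {
      weights[q] * stats::integrate(
        function(w) stats::dnorm(w, means[q], scales[q]) * cos(2 * pi * t * w),
        -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1)))
  }, numeric(1))
}

# FFT periodogram argmax frequency on an even grid
fft_peak_oracle <- function(x, y) {
  n <- length(y)
  dx <- x[2] - x[1]
  p <- Mod(stats::fft(y - mean(y)))^2
  k <- seq_len(floor(n / 2))
  freqs <- (k - 1) / (n * dx)
  freqs[which.max(p[k])]
}

# small helper: a dataset mirrored symmetrically about 0
mirrored_dataset <- function(n_half, f, sigma, seed) {
  set.seed(seed)
  xp <- runif(n_half, 1e-3, 1)
  yp <- f(xp) + rnorm(n_half, 0, sigma)
  observed_data(c(-xp, xp), c(yp, yp), partition = partition_threshold(0))
}
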