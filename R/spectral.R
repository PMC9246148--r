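# Spectral mixture kernel initialization: Lomb-Scargle periodogram of the
# (possibly unevenly sampled) series, then a Gaussian-mixture fit to the
# normalized spectrum. Component means/scales/weights seed the SM kernel.

#' Lomb-Scargle periodogram
#'
#' Classical normalized Lomb-Scargle periodogram, valid for unevenly
#' sampled data. Frequencies are in cycles per unit of `x`.
#'
#' @param x sample locations (need not be evenly spaced).
#' @param y responses; centered internally.
#' @param freq optional frequency grid; by default 5000 points from just
#'   above 0 up to the pseudo-Nyquist limit 1 / (2 * median spacing).
#' @return data.frame with columns `freq` and `power`.
#' @export
lomb_scargle <- function(x, y, freq = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 8) stop("Lomb-Scargle needs at least 8 observations")
  if (diff(range(x)) <= 0) stop("x values must not all be identical")
  if (is.null(freq)) {
    dx <- median(diff(sort(x)))
    f_max <- 1 / (2 * dx)
    freq <- seq(f_max / 5000, f_max, length.out = 5000)
  }
  yc <- y - mean(y)
  vy <- stats::var(y)
  power <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * x)), sum(cos(2 * w * x))) / (2 * w)
    ct <- cos(w * (x - tau)); st <- sin(w * (x - tau))
    pc <- sum(yc * ct)^2 / sum(ct^2)
    ps <- sum(yc * st)^2 / sum(st^2)
    (pc + ps) / 2
  }, numeric(1))
  if (vy > 0) power <- power / vy
  power[!is.finite(power)] <- 0
  data.frame(freq = freq, power = power)
}

# weighted 1-D Gaussian mixture EM over a fixed grid; weights p sum to 1.
# Deterministic: means initialized at weighted quantiles.
weighted_gmm_1d <- function(grid, p, Q, max_iter = 500, tol = 1e-9) {
  stopifnot(Q >= 1, length(grid) == length(p), all(p >= 0))
  p <- p / sum(p)
  cdf <- cumsum(p)
  qlev <- (seq_len(Q) - 0.5) / Q
  mu <- vapply(qlev, function(q) grid[which.max(cdf >= q)], numeric(1))
  span <- diff(range(grid))
  s_floor <- max(span / length(grid), 1e-12)
  s <- rep(max(span / (4 * Q), s_floor), Q)
  pi_q <- rep(1 / Q, Q)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(Q), function(q)
      pi_q[q] * stats::dnorm(grid, mu[q], s[q]), numeric(length(grid)))
    tot <- rowSums(dens)
    ll <- sum(p * log(pmax(tot, 1e-300)))
    r <- dens / pmax(tot, 1e-300)
    for (q in seq_len(Q)) {
      wq <- sum(p * r[, q])
      pi_q[q] <- wq
      if (wq > 1e-12) {
        mu[q] <- sum(p * r[, q] * grid) / wq
        s[q] <- sqrt(max(sum(p * r[, q] * (grid - mu[q])^2) / wq, s_floor^2))
      }
    }
    pi_q <- pi_q / sum(pi_q)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(pi_q, decreasing = TRUE)
  list(weights = pi_q[ord], means = pmax(mu[ord], 0), scales = pmax(s[ord], s_floor))
}

#' Initialize spectral mixture parameters from data
#'
#' Computes the Lomb-Scargle periodogram of `(x, y)`, fits a Q-component
#' Gaussian mixture to the normalized spectrum, and maps the mixture to
#' spectral-mixture kernel parameters: component means become the SM mean
#' frequencies, component standard deviations the SM scales, and mixing
#' proportions (scaled by the sample variance of `y`) the SM weights, so
#' that k(0) matches the empirical signal variance. The white-noise floor
#' of the periodogram (its median power) is subtracted before the mixture
#' fit so the components concentrate on genuine spectral peaks rather
#' than on the flat noise background.
#'
#' @param x,y observations (at least 8, `x` not all identical).
#' @param Q number of mixture components to return.
#' @param freq optional frequency grid forwarded to [lomb_scargle()].
#' @return an [sm_params()] object.
#' @export
init_spectral_mixture <- function(x, y, Q, freq = NULL) {
  if (Q < 1) stop("Q must be a positive integer")
  ls <- lomb_scargle(x, y, freq = freq)
  ls$power <- pmax(ls$power - stats::median(ls$power), 0)
  ls$power[ls$power < 0.1 * max(ls$power)] <- 0
  vy <- stats::var(as.numeric(y))
  if (sum(ls$power) <= 0 || vy <= 0) {
    # flat spectrum (e.g. constant y): all mass at DC
    dx <- diff(ls$freq[1:2])
    return(sm_params(weights = rep(max(vy, 1e-8) / Q, Q),
                     means = rep(0, Q),
                     scales = rep(dx, Q)))
  }
  fit <- weighted_gmm_1d(ls$freq, ls$power, Q)
  sm_params(weights = pmax(fit$weights, 1e-8) * vy,
            means = fit$means,
            scales = fit$scales)
}
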