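# The continuous model M0 (one GP over all data) and the discontinuous
# model M1 (independent GPs per side of the threshold), plus effect-size
# extraction for the three designs:
#   rd  -- scalar jump at the threshold, Gaussian N(m, s^2) with s^2 = 2 sigma_n^2
#   its -- effect curve m(x) = post fit minus pre-fit extrapolation, x >= x0
#   geo -- effect curve along a 2-D boundary polyline

STATIONARY_FAMILIES <- c("constant", "exp", "matern32", "rbf", "sm")

# default kernel spec for a named family, scaled to the data
default_kernel <- function(name, X, y) {
  vy <- max(stats::var(y), 1e-8)
  span <- max(apply(X, 2, function(c) diff(range(c))), 1e-8)
  switch(name,
    constant = kernel_spec("constant", variance = vy),
    linear = kernel_spec("linear",
                         variance = vy / max(stats::var(X[, 1]), 1e-8),
                         offset = 0, bias = vy),
    exp = kernel_spec("exp", variance = vy, lengthscale = 0.3 * span),
    matern32 = kernel_spec("matern32", variance = vy, lengthscale = 0.3 * span),
    rbf = kernel_spec("rbf", variance = vy, lengthscale = 0.3 * span),
    stop("unknown kernel name: ", name))
}

# fit with spectral-mixture component count selected by BIC evidence
# fitter(kernel) must return a bndd_gp
select_q_fit <- function(X, y, q_max, fitter) {
  best <- NULL; since_best <- 0L
  for (Q in seq_len(q_max)) {
    sm <- tryCatch(init_spectral_mixture(X[, 1], y, Q), error = function(e) NULL)
    if (is.null(sm)) next
    fit <- tryCatch(fitter(kernel_spec("sm", sm = sm)), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$bic_evidence > best$bic_evidence) {
      best <- fit; since_best <- 0L
    } else {
      # larger Q pays 3 more BIC-penalized parameters per component; stop
      # once two successive sizes fail to improve the evidence
      since_best <- since_best + 1L
      if (since_best >= 2L) break
    }
  }
  if (is.null(best)) stop("spectral mixture fit failed for all Q")
  best
}

#' Fit the continuous model M0
#'
#' A single GP regression over all observations, ignoring the partition.
#'
#' @param data a [observed_data()] object.
#' @param kernel a [kernel_spec()], or a kernel name among
#'   `"constant"`, `"linear"`, `"exp"`, `"matern32"`, `"rbf"`, `"sm"`.
#'   For `"sm"` the number of mixture components is selected by BIC
#'   evidence over `1..q_max`, each initialized from the Lomb-Scargle
#'   periodogram.
#' @param mean_spec `"empirical_constant"` or `"changepoint_constant"`
#'   (two optimized constants blended at `x0`, for designs where the null
#'   model should absorb a level shift).
#' @param x0 threshold, needed by the changepoint mean.
#' @param q_max maximum number of spectral mixture components.
#' @param n_restarts,seed,maxit forwarded to [fit_gp()].
#' @return a fitted `bndd_gp` with `mode = "continuous"`.
#' @export
fit_continuous <- function(data, kernel, mean_spec = "empirical_constant",
                           x0 = NULL, q_max = 6, n_restarts = 10,
                           seed = NULL, maxit = 200) {
  stopifnot(inherits(data, "bndd_data"))
  if (is.character(kernel) && kernel == "sm") {
    fit <- select_q_fit(data$X, data$y, q_max, function(k)
      fit_gp(data, k, mean_spec = mean_spec, x0 = x0,
             n_restarts = n_restarts, seed = seed, maxit = maxit))
  } else {
    if (is.character(kernel)) kernel <- default_kernel(kernel, data$X, data$y)
    fit <- fit_gp(data, kernel, mean_spec = mean_spec, x0 = x0,
                  n_restarts = n_restarts, seed = seed, maxit = maxit)
  }
  fit$mode <- "continuous"
  fit
}

#' Fit the discontinuous model M1
#'
#' The latent processes before and after the threshold are independent, so
#' the joint Gram matrix is block-diagonal. In `rd` and `geo` modes both
#' blocks share a single hyperparameter set, optimized against the joint
#' (sum of blocks) marginal likelihood, so M1 has exactly as many
#' hyperparameters as M0 with the same kernel. In `its` mode each side
#' gets its own hyperparameters (the intervention may change length-scales
#' or frequencies) and the model is two separate GPs whose log marginals
#' add; the BIC penalty uses the total n.
#'
#' Mean functions are empirical constants (fixed, never counted as
#' hyperparameters): in `rd`/`geo` mode both blocks share the global
#' empirical mean -- exactly as M0 does, so the models differ only in the
#' covariance structure -- while in `its` mode each side uses its own
#' empirical mean (the two-regime model).
#'
#' @param data a [observed_data()] object.
#' @param partition a `bndd_partition`; defaults to `data$partition`.
#' @param kernel kernel spec or name, as in [fit_continuous()].
#' @param mode one of `"rd"`, `"its"`, `"geo"`.
#' @param shared_hyperparameters in `its` mode only: fit a single
#'   hyperparameter set across both blocks (the plain block-diagonal
#'   discontinuous model) instead of per-side sets. With shared
#'   hyperparameters M1 and M0 have the same parameter count, so the
#'   Bayes factor isolates the independence structure at the threshold;
#'   per-side hyperparameters additionally allow a regime change in
#'   length-scales/frequencies at the price of a BIC complexity penalty.
#'   `rd`/`geo` always share.
#' @param q_max,n_restarts,seed,maxit as in [fit_continuous()].
#' @return a fitted `bndd_gp` with blocks `pre` and `post`.
#' @export
fit_discontinuous <- function(data, partition = NULL, kernel,
                              mode = c("rd", "its", "geo"), q_max = 6,
                              n_restarts = 10, seed = NULL, maxit = 200,
                              shared_hyperparameters = FALSE) {
  stopifnot(inherits(data, "bndd_data"))
  mode <- match.arg(mode)
  if (is.null(partition)) partition <- data$partition
  if (is.null(partition)) stop("a partition is required for M1")
  side <- assign_side(partition, data$X)
  for (s in c("pre", "post"))
    if (sum(side == s) < 2)
      stop("side '", s, "' has fewer than 2 observations")
  blocks <- lapply(c(pre = "pre", post = "post"), function(s) {
    i <- side == s
    list(X = data$X[i, , drop = FALSE], y = data$y[i])
  })
  n <- length(data$y)

  if (mode == "its" && !shared_hyperparameters) {
    # independent hyperparameters per side: two separate GPs
    seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
    fits <- lapply(1:2, function(i) {
      b <- blocks[[i]]
      d <- observed_data(b$X, b$y)
      if (is.character(kernel) && kernel == "sm") {
        select_q_fit(b$X, b$y, q_max, function(k)
          fit_gp(d, k, n_restarts = n_restarts, seed = seeds[[i]],
                 maxit = maxit))
      } else {
        k <- if (is.character(kernel)) default_kernel(kernel, b$X, b$y)
             else kernel
        fit_gp(d, k, n_restarts = n_restarts, seed = seeds[[i]],
               maxit = maxit)
      }
    })
    core <- list(
      blocks = list(pre = fits[[1]]$blocks[[1]], post = fits[[2]]$blocks[[1]]),
      kernel = list(pre = fits[[1]]$kernel, post = fits[[2]]$kernel),
      noise_variance = c(pre = fits[[1]]$noise_variance,
                         post = fits[[2]]$noise_variance),
      log_marginal = fits[[1]]$log_marginal + fits[[2]]$log_marginal,
      l = fits[[1]]$l + fits[[2]]$l,
      warn = fits[[1]]$warn || fits[[2]]$warn)
    m <- new_bndd_gp(core, n = n, mean_spec = "two_constants",
                     partition = partition, mode = "its")
    return(m)
  }

  # rd / geo (and shared-hyperparameter its): one theta_1 for both blocks
  if (is.character(kernel) && kernel == "sm") {
    fit_shared <- function(k) {
      core <- fit_gp_core(blocks, k, mean_type = "fixed",
                          mean_const = mean(data$y),
                          n_restarts = n_restarts, seed = seed, maxit = maxit)
      new_bndd_gp(core, n = n, mean_spec = "empirical_constant",
                  partition = partition, mode = mode)
    }
    best <- select_q_fit(data$X, data$y, q_max, fit_shared)
    return(best)
  }
  k <- if (is.character(kernel)) default_kernel(kernel, data$X, data$y)
       else kernel
  core <- fit_gp_core(blocks, k, mean_type = "fixed", mean_const = mean(data$y),
                      n_restarts = n_restarts, seed = seed, maxit = maxit)
  new_bndd_gp(core, n = n, mean_spec = "empirical_constant",
              partition = partition, mode = mode)
}

new_effect <- function(mode, m, s2, grid = NULL, sd = NULL, summary) {
  structure(list(mode = mode, m = m, s2 = s2, grid = grid, sd = sd,
                 summary = summary), class = "bndd_effect")
}

#' Regression-discontinuity effect size
#'
#' Under M1 the effect is the difference of the one-sided limits of the
#' latent function at the threshold; since each one-sided GP posterior
#' mean is continuous, the limits are evaluated exactly at x0. The result
#' is a Gaussian: d | D, M1 ~ N(m, s^2) with m the difference of the two
#' one-sided posterior means at x0 and, for stationary kernels,
#' s^2 = 2 sigma_n^2.
#'
#' @param m1 a discontinuous `bndd_gp` fitted in `rd` mode (shared
#'   hyperparameters).
#' @param x0 threshold; defaults to the partition threshold.
#' @param s2_method `"noise"` uses s^2 = 2 sigma_n^2 (stationary kernels);
#'   `"predictive"` sums the two one-sided latent predictive variances at
#'   x0. Non-stationary kernels (linear) fall back to `"predictive"` with
#'   a notice.
#' @return a `bndd_effect` with scalar mean `m`, variance `s2`, and
#'   `summary = m`.
#' @export
rd_effect_size <- function(m1, x0 = NULL, s2_method = c("noise", "predictive")) {
  stopifnot(inherits(m1, "bndd_gp"), length(m1$blocks) == 2)
  s2_method <- match.arg(s2_method)
  if (is.null(x0)) {
    if (is.null(m1$partition) || m1$partition$kind != "threshold")
      stop("x0 is required when the partition is not a threshold")
    x0 <- m1$partition$x0
  }
  post <- block_predict(m1$blocks$post, x0)
  pre <- block_predict(m1$blocks$pre, x0)
  m <- post$mean - pre$mean
  fam <- if (is.list(m1$kernel) && !inherits(m1$kernel, "bndd_kernel"))
    m1$kernel$pre$family else m1$kernel$family
  if (!(fam %in% STATIONARY_FAMILIES) && s2_method == "noise") {
    message("non-stationary kernel '", fam,
            "': using one-sided posterior predictive variances for s^2")
    s2_method <- "predictive"
  }
  s2 <- if (s2_method == "noise") {
    2 * unname(m1$noise_variance[1])
  } else {
    post$var + pre$var
  }
  new_effect("rd", m = m, s2 = unname(s2), summary = m)
}

#' Interrupted-time-series effect curve
#'
#' m(x) = (post-model posterior mean at x) - (pre-model posterior mean
#' extrapolated to x) for x >= x0, with constant variance
#' s_n^2 = sigma_nA^2 + sigma_nB^2. The dynamic effect is summarized by
#' the maximum of |m(x)| over the grid.
#'
#' @param m1 a discontinuous `bndd_gp` fitted in `its` mode.
#' @param x_grid evaluation grid; default 200 evenly spaced points from x0
#'   to `max(x) + horizon`.
#' @param n_grid grid size when `x_grid` is NULL.
#' @param horizon extra extrapolation range beyond the last observation.
#' @return a `bndd_effect` with curve `m`, variance `s2`, the grid, and
#'   `summary = max |m(x)|`.
#' @export
its_effect_curve <- function(m1, x_grid = NULL, n_grid = 200, horizon = 0) {
  stopifnot(inherits(m1, "bndd_gp"), length(m1$blocks) == 2)
  if (is.null(x_grid)) {
    x0 <- m1$partition$x0
    xmax <- max(m1$blocks$post$X[, 1]) + horizon
    x_grid <- seq(x0, xmax, length.out = n_grid)
  }
  if (length(x_grid) < 1) stop("evaluation grid is empty")
  post <- block_predict(m1$blocks$post, x_grid)
  pre <- block_predict(m1$blocks$pre, x_grid)
  m <- post$mean - pre$mean
  sn2 <- unname(m1$blocks$pre$noise_variance + m1$blocks$post$noise_variance)
  new_effect("its", m = m, s2 = sn2, grid = x_grid,
             summary = max(abs(m)))
}

# arc-length-uniform sample points along a polyline
polyline_points <- function(V, n_points) {
  seg <- sqrt(rowSums(diff(V)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], length.out = n_points)
  t(vapply(s, function(si) {
    j <- max(which(cum <= si + 1e-12)); j <- min(j, nrow(V) - 1)
    f <- if (seg[j] > 0) (si - cum[j]) / seg[j] else 0
    V[j, ] + f * (V[j + 1, ] - V[j, ])
  }, numeric(2)))
}

#' Geographic-boundary effect curve
#'
#' Evaluates the effect d(s) = (post-side posterior mean) - (pre-side
#' posterior mean) at arc-length-uniform points along the boundary
#' polyline, with pointwise variance the sum of the two one-sided latent
#' predictive variances (bands of one standard deviation).
#'
#' @param m1 a discontinuous `bndd_gp` fitted in `geo` mode on 2-D inputs.
#' @param boundary m x 2 matrix of polyline vertices; defaults to the
#'   model's partition polyline.
#' @param n_points number of evaluation points along the boundary.
#' @return a `bndd_effect` with curve `m`, pointwise variance `s2`,
#'   `sd = sqrt(s2)`, `grid` (the boundary points with arc length), and
#'   `summary = max |d(s)|`.
#' @export
geo_effect_curve <- function(m1, boundary = NULL, n_points = 50) {
  stopifnot(inherits(m1, "bndd_gp"), length(m1$blocks) == 2)
  if (is.null(boundary)) {
    if (is.null(m1$partition) || m1$partition$kind != "polyline")
      stop("boundary points are required")
    boundary <- m1$partition$vertices
  }
  B <- as_input_matrix(boundary)
  P <- polyline_points(B, n_points)
  post <- block_predict(m1$blocks$post, P)
  pre <- block_predict(m1$blocks$pre, P)
  d <- post$mean - pre$mean
  v <- post$var + pre$var
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  new_effect("geo", m = d, s2 = v, sd = sqrt(v),
             grid = list(points = P, arclength = s),
             summary = max(abs(d)))
}
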