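# Exact GP regression with Gaussian noise: closed-form marginal likelihood
# via Cholesky, analytic gradients on a softplus-unconstrained scale,
# multi-restart quasi-Newton optimization, posterior prediction, and the
# BIC approximation to the model evidence. A model may consist of several
# independent blocks (the discontinuous design): the joint Gram matrix is
# block-diagonal, so log marginals and gradients simply add over blocks.

#' Observed data container
#'
#' @param x inputs: numeric vector (RD/ITS) or n x 2 matrix (geo).
#' @param y numeric responses, same length.
#' @param partition optional `bndd_partition` attaching side labels.
#' @return object of class `bndd_data` with fields `X` (matrix), `y`,
#'   `partition`.
#' @export
observed_data <- function(x, y, partition = NULL) {
  X <- as_input_matrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("x and y must have the same length")
  if (length(y) < 2) stop("need at least 2 observations")
  if (!all(is.finite(y))) stop("responses must be finite")
  if (!is.null(partition)) stopifnot(inherits(partition, "bndd_partition"))
  structure(list(X = X, y = y, partition = partition), class = "bndd_data")
}

GP_JITTER_REL <- 1e-6  # relative jitter added to Gram diagonals

# mean vector for one block
block_mean <- function(mean_type, X, y, pars = NULL, x0 = NULL, steep = NULL) {
  switch(mean_type,
    empirical = rep(mean(y), nrow(X)),
    fixed = rep(pars[1], nrow(X)),
    changepoint = {
      s <- stats::plogis((X[, 1] - x0) / steep)
      pars[1] + (pars[2] - pars[1]) * s
    })
}

# number of packed parameters for a kernel spec
n_kernel_params <- function(kernel) length(kernel_param_info(kernel)$values)

# joint log marginal likelihood and gradient for blocks sharing one kernel,
# one noise variance, and (optionally) changepoint mean parameters.
# z = [kernel z..., noise z, (c1, c2)]
gp_eval <- function(z, blocks, kernel, mean_type, x0 = NULL, steep = NULL,
                    mean_const = NULL, want_grad = TRUE) {
  info <- kernel_param_info(kernel)
  nk <- length(info$values)
  theta <- to_constrained(z[seq_len(nk)], info$transform)
  names(theta) <- names(info$values)
  kern <- kernel_set_params(kernel, theta)
  noise <- softplus(z[nk + 1]) + 1e-10
  mean_pars <- switch(mean_type, changepoint = z[nk + 2:3],
                      fixed = mean_const, NULL)

  lml <- 0
  grad <- numeric(length(z))
  fail <- list(value = -1e10, grad = numeric(length(z)), ok = FALSE)
  for (b in blocks) {
    n <- length(b$y)
    K <- eval_kernel(kern, b$X)
    jit <- GP_JITTER_REL * max(mean(diag(K)), 1e-6)
    C <- K + diag(noise + jit, n)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(fail)
    mu <- block_mean(mean_type, b$X, b$y, mean_pars, x0, steep)
    r <- b$y - mu
    alpha <- backsolve(ch, forwardsolve(t(ch), r))
    lml <- lml - 0.5 * sum(r * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
    if (want_grad) {
      P <- tcrossprod(alpha) - chol2inv(ch)
      G <- kernel_grad_matrices(kern, b$X)
      for (i in seq_len(nk)) grad[i] <- grad[i] + 0.5 * sum(P * G[[i]])
      grad[nk + 1] <- grad[nk + 1] + 0.5 * sum(diag(P))
      if (mean_type == "changepoint") {
        s <- stats::plogis((b$X[, 1] - x0) / steep)
        grad[nk + 2] <- grad[nk + 2] + sum(alpha * (1 - s))
        grad[nk + 3] <- grad[nk + 3] + sum(alpha * s)
      }
    }
  }
  if (want_grad) {
    grad[seq_len(nk)] <- grad[seq_len(nk)] *
      transform_jacobian(z[seq_len(nk)], info$transform)
    grad[nk + 1] <- grad[nk + 1] * stats::plogis(z[nk + 1])
  }
  if (!is.finite(lml)) return(fail)
  list(value = lml, grad = grad, ok = TRUE, kernel = kern, noise = noise,
       mean_pars = mean_pars)
}

# random restart starting points on the unconstrained scale
restart_starts <- function(kernel, blocks, mean_type, x0, steep,
                           noise_init, n_restarts) {
  info <- kernel_param_info(kernel)
  yall <- unlist(lapply(blocks, `[[`, "y"))
  Xall <- do.call(rbind, lapply(blocks, `[[`, "X"))
  vy <- max(stats::var(yall), 1e-8)
  span <- max(apply(Xall, 2, function(c) diff(range(c))), 1e-8)
  z0 <- to_unconstrained(info$values, info$transform)
  base <- c(z0, softplus_inv(noise_init))
  if (mean_type == "changepoint") {
    side <- Xall[, 1] >= x0
    m1 <- if (any(!side)) mean(yall[!side]) else mean(yall)
    m2 <- if (any(side)) mean(yall[side]) else mean(yall)
    base <- c(base, m1, m2)
  }
  starts <- list(base)
  fam <- kernel$family
  for (r in seq_len(max(n_restarts - 1, 0))) {
    vals <- info$values
    if ("variance" %in% names(vals))
      vals[["variance"]] <- vy * exp(stats::rnorm(1, 0, 0.5))
    if ("lengthscale" %in% names(vals))
      vals[["lengthscale"]] <- stats::runif(1, 0.1, 2) * span
    if (fam == "linear") {
      vals[["offset"]] <- stats::runif(1, min(Xall), max(Xall))
      vals[["bias"]] <- vy * exp(stats::rnorm(1, 0, 0.5))
    }
    if (fam == "sm")
      vals <- pmax(vals * exp(stats::rnorm(length(vals), 0, 0.25)), 1e-8)
    zi <- to_unconstrained(vals, info$transform)
    st <- c(zi, softplus_inv(0.1 * vy * exp(stats::rnorm(1, 0, 0.5))))
    if (mean_type == "changepoint")
      st <- c(st, base[length(base) - 1], base[length(base)])
    starts[[r + 1]] <- st
  }
  starts
}

# core fitter over blocks with shared hyperparameters
fit_gp_core <- function(blocks, kernel, mean_type = "empirical",
                        x0 = NULL, steep = NULL, mean_const = NULL,
                        noise_init = NULL, n_restarts = 10, seed = NULL,
                        maxit = 200) {
  if (!is.null(seed)) set.seed(seed)
  yall <- unlist(lapply(blocks, `[[`, "y"))
  if (mean_type == "fixed" && is.null(mean_const)) mean_const <- mean(yall)
  if (is.null(noise_init)) noise_init <- max(0.1 * stats::var(yall), 1e-6)
  starts <- restart_starts(kernel, blocks, mean_type, x0, steep,
                           noise_init, n_restarts)
  cache <- new.env()
  evalz <- function(z) {
    key <- paste(z, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- gp_eval(z, blocks, kernel, mean_type, x0, steep, mean_const)
      cache$key <- key
    }
    cache$res
  }
  fn <- function(z) evalz(z)$value
  gr <- function(z) evalz(z)$grad
  best <- NULL; warn <- FALSE
  for (st in starts) {
    init_val <- fn(st)
    opt <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B",
                   control = list(fnscale = -1, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) {
      cand <- list(par = st, value = init_val)
      warn <- TRUE
    } else {
      cand <- list(par = opt$par, value = opt$value)
    }
    if (cand$value < init_val) cand <- list(par = st, value = init_val)
    if (is.null(best) || cand$value > best$value) best <- cand
  }
  res <- gp_eval(best$par, blocks, kernel, mean_type, x0, steep, mean_const,
                 want_grad = FALSE)
  kern <- res$kernel; noise <- res$noise
  out_blocks <- lapply(blocks, function(b) {
    n <- length(b$y)
    K <- eval_kernel(kern, b$X)
    jit <- GP_JITTER_REL * max(mean(diag(K)), 1e-6)
    ch <- chol(K + diag(noise + jit, n))
    mu <- block_mean(mean_type, b$X, b$y, res$mean_pars, x0, steep)
    alpha <- backsolve(ch, forwardsolve(t(ch), b$y - mu))
    list(X = b$X, y = b$y, kernel = kern, noise_variance = noise,
         mean_type = mean_type, mean_pars = res$mean_pars,
         x0 = x0, steep = steep, mu_train = mu, chol = ch, alpha = alpha)
  })
  l <- length(best$par)  # kernel params + noise (+ changepoint constants)
  list(blocks = out_blocks, kernel = kern, noise_variance = noise,
       log_marginal = best$value, l = l, warn = warn,
       mean_pars = res$mean_pars)
}

#' Log marginal likelihood of a GP with Gaussian noise
#'
#' Computes log N(y | mu, K + sigma_n^2 I) by Cholesky factorization, the
#' closed-form GP marginal likelihood.
#'
#' @param data a [observed_data()] object.
#' @param kernel a [kernel_spec()] (or discontinuous wrapper).
#' @param noise_variance observation noise variance sigma_n^2 (> 0).
#' @param mean mean of the GP: `NULL` for the empirical mean of `y`, or a
#'   numeric scalar/vector.
#' @return the log marginal likelihood in nats.
#' @export
log_marginal_likelihood <- function(data, kernel, noise_variance, mean = NULL) {
  stopifnot(inherits(data, "bndd_data"), noise_variance > 0)
  n <- length(data$y)
  K <- eval_kernel(kernel, data$X)
  jit <- GP_JITTER_REL * max(mean(diag(K)), 1e-6)
  C <- K + diag(noise_variance + jit, n)
  ch <- tryCatch(chol(C), error = function(e)
    stop("Gram matrix is not positive definite even after jitter"))
  mu <- if (is.null(mean)) rep(mean(data$y), n) else rep_len(as.numeric(mean), n)
  r <- data$y - mu
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * sum(r * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
}

#' Fit a Gaussian process by maximizing the marginal likelihood
#'
#' Multi-restart L-BFGS optimization over softplus-unconstrained kernel
#' hyperparameters and noise variance, with analytic gradients. The first
#' restart starts at the supplied kernel parameters; further restarts
#' randomize length-scales log-uniformly over [0.1, 2] x range(x), the
#' variance around var(y), and the noise around 0.1 var(y).
#'
#' @param data a [observed_data()] object.
#' @param kernel starting [kernel_spec()].
#' @param mean_spec `"empirical_constant"` (fixed at the empirical mean of
#'   y, not counted as a hyperparameter) or `"changepoint_constant"` (a
#'   sigmoid blend of two optimized constants at `x0`; both counted).
#' @param x0 threshold, required by `"changepoint_constant"`.
#' @param steepness sigmoid steepness of the changepoint mean, in x units;
#'   default 1 percent of the x range.
#' @param n_restarts number of optimizer restarts (default 10).
#' @param seed optional integer seed; the same seed and data give
#'   bit-identical fits.
#' @param maxit L-BFGS iteration cap per restart.
#' @return object of class `bndd_gp` with the optimized kernel, noise
#'   variance, `log_marginal`, hyperparameter count `l`, and
#'   `bic_evidence = log_marginal - (l/2) log n`.
#' @export
fit_gp <- function(data, kernel, mean_spec = c("empirical_constant",
                                               "changepoint_constant"),
                   x0 = NULL, steepness = NULL, n_restarts = 10,
                   seed = NULL, maxit = 200) {
  stopifnot(inherits(data, "bndd_data"), inherits(kernel, "bndd_kernel"))
  mean_spec <- match.arg(mean_spec)
  mt <- if (mean_spec == "changepoint_constant") "changepoint" else "empirical"
  if (mt == "changepoint") {
    if (is.null(x0)) stop("changepoint_constant mean requires x0")
    if (is.null(steepness)) steepness <- 0.01 * diff(range(data$X[, 1]))
  }
  core <- fit_gp_core(list(list(X = data$X, y = data$y)), kernel,
                      mean_type = mt, x0 = x0, steep = steepness,
                      n_restarts = n_restarts, seed = seed, maxit = maxit)
  new_bndd_gp(core, n = length(data$y), mean_spec = mean_spec,
              partition = data$partition)
}

new_bndd_gp <- function(core, n, mean_spec, partition = NULL, mode = NULL) {
  if (n < 2) stop("need n >= 2 observations")
  structure(list(blocks = core$blocks, kernel = core$kernel,
                 noise_variance = core$noise_variance,
                 log_marginal = core$log_marginal, l = core$l, n = n,
                 bic_evidence = core$log_marginal - core$l / 2 * log(n),
                 mean_spec = mean_spec, partition = partition, mode = mode,
                 warn = core$warn),
            class = "bndd_gp")
}

#' BIC approximation to the model evidence
#'
#' log p(D | M) ~ log p(y | x, theta_hat, M) - (l / 2) log n, where l
#' counts every optimized hyperparameter (kernel parameters, the noise
#' variance, and optimized mean constants).
#'
#' @param model a fitted `bndd_gp`.
#' @param n number of observations (defaults to the training size).
#' @return the BIC evidence in nats.
#' @export
bic_evidence <- function(model, n = model$n) {
  stopifnot(inherits(model, "bndd_gp"))
  if (n < 2) stop("n must be at least 2")
  model$log_marginal - model$l / 2 * log(n)
}

# prediction from one block
block_predict <- function(b, Xs, include_noise = FALSE) {
  Xs <- as_input_matrix(Xs)
  if (ncol(Xs) != ncol(b$X)) stop("prediction inputs have wrong dimensionality")
  Ks <- eval_kernel(b$kernel, b$X, Xs)
  mu_s <- block_mean(b$mean_type, Xs, b$y, b$mean_pars, b$x0, b$steep)
  mean <- mu_s + drop(crossprod(Ks, b$alpha))
  V <- forwardsolve(t(b$chol), Ks)
  kss <- diag(eval_kernel(b$kernel, Xs))
  var <- pmax(kss - colSums(V^2), 0)
  if (include_noise) var <- var + b$noise_variance
  list(mean = mean, var = var)
}

# full latent posterior covariance at Xs from one block
block_posterior_cov <- function(b, Xs) {
  Xs <- as_input_matrix(Xs)
  Ks <- eval_kernel(b$kernel, b$X, Xs)
  Kss <- eval_kernel(b$kernel, Xs)
  V <- forwardsolve(t(b$chol), Ks)
  S <- Kss - crossprod(V)
  S + diag(1e-8 * max(mean(diag(Kss)), 1e-8), nrow(Xs))
}

#' Posterior predictive mean and variance
#'
#' @param model a fitted `bndd_gp`.
#' @param X_star prediction inputs.
#' @param include_noise add the observation noise variance to the latent
#'   predictive variance.
#' @param side for discontinuous models: predict from the `"pre"` or
#'   `"post"` block for all points; `NULL` routes each point to the block
#'   of its own side under the model's partition.
#' @return list with elements `mean` and `var`.
#' @export
posterior_predict <- function(model, X_star, include_noise = FALSE,
                              side = NULL) {
  stopifnot(inherits(model, "bndd_gp"))
  Xs <- as_input_matrix(X_star)
  if (length(model$blocks) == 1)
    return(block_predict(model$blocks[[1]], Xs, include_noise))
  if (!is.null(side)) {
    side <- match.arg(side, c("pre", "post"))
    return(block_predict(model$blocks[[side]], Xs, include_noise))
  }
  lab <- assign_side(model$partition, Xs)
  mean <- numeric(nrow(Xs)); var <- numeric(nrow(Xs))
  for (s in unique(lab)) {
    i <- lab == s
    p <- block_predict(model$blocks[[s]], Xs[i, , drop = FALSE], include_noise)
    mean[i] <- p$mean; var[i] <- p$var
  }
  list(mean = mean, var = var)
}

#' Draw joint samples from the latent posterior
#'
#' @param model a fitted `bndd_gp`.
#' @param X_star prediction inputs.
#' @param n_samples number of function draws.
#' @param side block to sample from for discontinuous models.
#' @return matrix with `n_samples` rows, one column per prediction point.
#' @export
posterior_sample <- function(model, X_star, n_samples = 1, side = NULL) {
  stopifnot(inherits(model, "bndd_gp"))
  b <- if (length(model$blocks) == 1) model$blocks[[1]]
       else model$blocks[[match.arg(side, c("pre", "post"))]]
  Xs <- as_input_matrix(X_star)
  p <- block_predict(b, Xs)
  S <- block_posterior_cov(b, Xs)
  ch <- chol(S)
  Z <- matrix(stats::rnorm(n_samples * nrow(Xs)), n_samples)
  sweep(Z %*% ch, 2, p$mean, "+")
}

#' @export
print.bndd_gp <- function(x, ...) {
  cat("Gaussian process fit (", x$kernel$family, " kernel, ",
      length(x$blocks), " block(s))\n", sep = "")
  cat("  log marginal likelihood:", format(x$log_marginal, digits = 6), "\n")
  cat("  BIC evidence:", format(x$bic_evidence, digits = 6),
      " (l =", x$l, ", n =", x$n, ")\n")
  cat("  noise variance:", format(x$noise_variance, digits = 4), "\n")
  invisible(x)
}
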