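# Seeded simulation generators for the two study designs, the two-stage
# GP significance test, and benchmark runners with an ARMA extrapolation
# baseline for the interrupted-time-series design.

RD_FUNCTIONS <- c("linear", "quad", "cubic", "lee", "cate1", "cate2",
                  "ludwig", "curvature")

polyval <- function(coef, x) {
  # coef in increasing power order
  out <- 0
  for (j in rev(seq_along(coef))) out <- out * x + coef[j]
  out
}

#' Piecewise-polynomial test functions for regression discontinuity
#'
#' The eight latent functions used in the RD simulation study: fifth-order
#' (and lower) polynomials, several with different branches before and
#' after the threshold x0 = 0 (pre-branch for x < 0, post-branch for
#' x >= 0). `quad` and `cubic` change only curvature at 0; `lee` and
#' `curvature` have equal levels but unequal one-sided slopes at 0 (a
#' discontinuity in the derivative, not the function); `linear`, `cate1`
#' and `cate2` are single global polynomials.
#'
#' @param name one of `"linear"`, `"quad"`, `"cubic"`, `"lee"`, `"cate1"`,
#'   `"cate2"`, `"ludwig"`, `"curvature"`.
#' @param x evaluation points (the study draws x from U(-1, 1)).
#' @return f(x), without any jump term.
#' @export
rd_function <- function(name, x) {
  if (!(name %in% RD_FUNCTIONS)) stop("unknown RD function: ", name)
  x <- as.numeric(x)
  post <- x >= 0
  f <- switch(name,
    linear = 0.23 + 0.89 * x,
    quad = ifelse(post, 4 * x^2, 3 * x^2),
    cubic = ifelse(post, 4 * x^3, 3 * x^3),
    lee = ifelse(post,
      polyval(c(0.48, 0.84, -3.0, 7.99, -9.01, 3.56), x),
      polyval(c(0.48, 1.27, 7.18, 20.21, 21.54, 7.33), x)),
    cate1 = polyval(c(0.42, 0.84, -3.0, 7.99, -9.01, 3.56), x),
    cate2 = polyval(c(0.42, 0.84, 0, 7.99, -9.01, 3.56), x),
    ludwig = ifelse(post,
      polyval(c(3.71, 18.49, -54.81, 74.3, -45.02, 9.83), x),
      polyval(c(3.71, 2.3, 3.28, 1.45, 0.23, 0.03), x)),
    curvature = ifelse(post,
      polyval(c(0.48, 0.84, -0.3, -2.397, -0.901, 3.56), x),
      polyval(c(0.48, 1.27, -3.44, 14.147, 23.694, 10.995), x)))
  f
}

#' Generate a regression-discontinuity dataset
#'
#' x_i ~ U(-1, 1) iid; y_i = f(x_i) + d * [x_i >= 0] + N(0, sigma^2),
#' with threshold x0 = 0. The returned data carry the threshold partition.
#'
#' @param function_name latent function name, see [rd_function()].
#' @param d true jump added on the treated side (x >= 0).
#' @param sigma noise standard deviation (study default 1).
#' @param n number of observations (study default 100).
#' @param seed optional seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return a [observed_data()] object with a threshold partition at 0.
#' @export
generate_rd_dataset <- function(function_name, d = 0, sigma = 1, n = 100,
                                seed = NULL) {
  stopifnot(sigma > 0, n >= 10)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n, -1, 1)
  y <- rd_function(function_name, x) + d * (x >= 0) +
    stats::rnorm(n, 0, sigma)
  observed_data(x, y, partition = partition_threshold(0))
}

#' True latent signal of the interrupted-time-series simulation
#'
#' f(x) = sin(12 x) + (2/3) cos(25 x) before the threshold; after it the
#' angular frequencies are shifted by alpha:
#' f(x) = sin((12 + alpha) x) + (2/3) cos((25 + alpha) x).
#'
#' @param x evaluation points.
#' @param alpha post-threshold frequency shift.
#' @param branch `"auto"` applies the shift for x >= 0; `"pre"` evaluates
#'   the unshifted formula everywhere (the counterfactual continuation);
#'   `"post"` the shifted formula everywhere.
#' @return f(x).
#' @export
its_true_signal <- function(x, alpha = 0, branch = c("auto", "pre", "post")) {
  branch <- match.arg(branch)
  x <- as.numeric(x)
  pre <- sin(12 * x) + 2 / 3 * cos(25 * x)
  post <- sin((12 + alpha) * x) + 2 / 3 * cos((25 + alpha) * x)
  switch(branch, auto = ifelse(x >= 0, post, pre), pre = pre, post = post)
}

#' Generate an interrupted-time-series dataset
#'
#' n evenly spaced observations over `x_range` (default [-1, 1], threshold
#' at 0), y = f(x) + N(0, sigma2) with the frequency shift alpha applied
#' on the post side; sigma2 defaults to the study setting 0.2.
#'
#' @param alpha post-threshold frequency shift.
#' @param sigma2 observation noise variance.
#' @param n number of observations (study default 200).
#' @param x_range interval straddling 0.
#' @param seed optional seed.
#' @return a [observed_data()] object with a threshold partition at 0.
#' @export
generate_its_dataset <- function(alpha = 0, sigma2 = 0.2, n = 200,
                                 x_range = c(-1, 1), seed = NULL) {
  stopifnot(sigma2 > 0, n >= 10, x_range[1] < 0, x_range[2] > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(x_range[1], x_range[2], length.out = n)
  y <- its_true_signal(x, alpha) + stats::rnorm(n, 0, sqrt(sigma2))
  observed_data(x, y, partition = partition_threshold(0))
}

#' Two-stage GP significance test
#'
#' The baseline that first estimates the conditional effect distribution
#' d | D, M1 ~ N(m, s^2) and then tests the null d = 0 with a two-sided
#' z-test, z = m / s.
#'
#' @param effect an RD-mode `bndd_effect`.
#' @return two-sided p-value.
#' @export
two_stage_gp_test <- function(effect) {
  stopifnot(inherits(effect, "bndd_effect"), effect$mode == "rd")
  s <- sqrt(effect$s2)
  if (s <= 0) stop("effect standard deviation is zero")
  2 * stats::pnorm(-abs(effect$m) / s)
}

#' Run the regression-discontinuity benchmark
#'
#' For each latent function, jump size d and replicate: generate a
#' dataset, fit M0 and M1 with every candidate kernel, and record the
#' per-kernel conditional effect, log Bayes factor and two-stage p-value,
#' plus one `"bma"` row per dataset with the kernel-averaged conditional
#' effect, the spike-and-slab point estimate E[d | D] and the total log
#' Bayes factor.
#'
#' @param d_grid jump sizes (study grid 0, 0.5, ..., 4).
#' @param functions subset of [rd_function()] names.
#' @param kernels candidate kernel names.
#' @param reps replicates per condition.
#' @param seed base seed; replicate r of condition i uses a derived seed.
#' @param n,sigma dataset size and noise sd.
#' @param n_restarts optimizer restarts per fit.
#' @return tidy data.frame: one row per (function, d, rep, kernel or
#'   "bma") with columns `effect_m1`, `effect_bma`, `abs_err_m1`,
#'   `abs_err_bma`, `log_bf`, `p_two_stage`, `failed` count.
#' @export
run_rd_benchmark <- function(d_grid = seq(0, 4, by = 0.5),
                             functions = RD_FUNCTIONS,
                             kernels = c("linear", "exp", "matern32", "rbf"),
                             reps = 20, seed = 1, n = 100, sigma = 1,
                             n_restarts = 3) {
  if (length(kernels) < 1) stop("kernel set must not be empty")
  if (length(d_grid) < 1) stop("d grid must not be empty")
  rows <- list(); ri <- 0L
  cond <- 0L
  for (fn in functions) for (d in d_grid) for (r in seq_len(reps)) {
    cond <- cond + 1L
    ds <- (as.integer(seed) + 7919L * cond) %% 2147483647L
    data <- generate_rd_dataset(fn, d = d, sigma = sigma, n = n, seed = ds)
    res <- tryCatch(
      rd_compare(data, kernels, n_restarts = n_restarts, seed = ds),
      error = function(e) NULL)
    if (is.null(res)) next
    for (k in seq_along(res$per_kernel$name)) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        func = fn, d = d, rep = r, kernel = res$per_kernel$name[k],
        effect_m1 = res$per_kernel$m[k], effect_bma = NA_real_,
        abs_err_m1 = abs(res$per_kernel$m[k] - d), abs_err_bma = NA_real_,
        log_bf = res$per_kernel$log_bf10[k],
        p_two_stage = res$per_kernel$p_two_stage[k])
    }
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      func = fn, d = d, rep = r, kernel = "bma",
      effect_m1 = res$effect_m1_marginal, effect_bma = res$effect_bma,
      abs_err_m1 = abs(res$effect_m1_marginal - d),
      abs_err_bma = abs(res$effect_bma - d),
      log_bf = res$log_bf_total, p_two_stage = NA_real_)
  }
  do.call(rbind, rows)
}

# fit all kernels on one RD dataset; shared by the benchmark and the CLI
rd_compare <- function(data, kernels, n_restarts = 3, seed = NULL,
                       model_prior = c(0.5, 0.5), q_max = 6, maxit = 200) {
  tabs <- list(); effs <- list()
  for (i in seq_along(kernels)) {
    k <- kernels[i]
    sk <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
    m0 <- fit_continuous(data, k, q_max = q_max, n_restarts = n_restarts,
                         seed = sk, maxit = maxit)
    m1 <- fit_discontinuous(data, kernel = k, mode = "rd", q_max = q_max,
                            n_restarts = n_restarts, seed = sk, maxit = maxit)
    eff <- suppressMessages(rd_effect_size(m1))
    effs[[k]] <- eff
    tabs[[i]] <- data.frame(
      name = k, log_ev_m0 = m0$bic_evidence, log_ev_m1 = m1$bic_evidence,
      log_bf10 = m1$bic_evidence - m0$bic_evidence,
      m = eff$m, s2 = eff$s2, p_two_stage = two_stage_gp_test(eff))
  }
  per_kernel <- do.call(rbind, tabs)
  bma <- kernel_bma(per_kernel)
  post <- model_posterior(
    c(logsumexp(per_kernel$log_ev_m0 - log(nrow(per_kernel))),
      logsumexp(per_kernel$log_ev_m1 - log(nrow(per_kernel)))),
    prior = model_prior)
  m1_marg <- sum(bma$kernel_posterior_m1 * per_kernel$m)
  list(per_kernel = per_kernel, effects = effs,
       log_bf_total = bma$log_bf_total,
       kernel_posterior_m1 = bma$kernel_posterior_m1,
       model_posterior = post,
       effect_m1_marginal = m1_marg,
       effect_bma = post[2] * m1_marg)
}

# ARMA baseline: order chosen by grid search on BIC, fit to the
# pre-threshold series only
arma_baseline <- function(y_pre, p_max = 5, q_max = 5, d_vals = c(0, 1)) {
  best <- NULL
  for (d in d_vals) for (p in 0:p_max) for (q in 0:q_max) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(y_pre, order = c(p, d, q))),
      error = function(e) NULL)
    if (is.null(fit)) next
    bic <- tryCatch(stats::BIC(fit), error = function(e) Inf)
    if (is.null(best) || bic < best$bic)
      best <- list(fit = fit, bic = bic, order = c(p, d, q))
  }
  if (is.null(best)) stop("all ARMA fits failed")
  best
}

#' Run the interrupted-time-series extrapolation benchmark
#'
#' For each frequency shift alpha and replicate: generate a dataset, fit
#' the spectral-mixture GP to the pre-threshold series, extrapolate past
#' the threshold, and compare posterior-sample RMSE against the true
#' (unshifted) continuation with an ARMA baseline whose order is chosen
#' by BIC grid search.
#'
#' @param alpha_grid frequency shifts to evaluate.
#' @param reps replicates per alpha.
#' @param seed base seed.
#' @param n,sigma2 dataset size and noise variance.
#' @param q_max maximum spectral mixture components.
#' @param n_restarts optimizer restarts per fit.
#' @param n_posterior posterior draws used for the RMSE.
#' @param arma_p_max,arma_q_max ARMA order grid bounds.
#' @return tidy data.frame: one row per (alpha, rep, method) with the
#'   RMSE; failed replicates are excluded with `failed = TRUE` rows.
#' @export
run_its_benchmark <- function(alpha_grid = c(0, 2, 4, 6, 8), reps = 20,
                              seed = 1, n = 200, sigma2 = 0.2, q_max = 6,
                              n_restarts = 2, n_posterior = 30,
                              arma_p_max = 5, arma_q_max = 5) {
  rows <- list(); ri <- 0L; cond <- 0L
  for (alpha in alpha_grid) for (r in seq_len(reps)) {
    cond <- cond + 1L
    ds <- (as.integer(seed) + 104729L * cond) %% 2147483647L
    data <- generate_its_dataset(alpha = alpha, sigma2 = sigma2, n = n,
                                 seed = ds)
    pre <- data$X[, 1] < 0
    x_post <- data$X[pre == FALSE, 1]
    truth <- its_true_signal(x_post, alpha, branch = "pre")
    bndd_rmse <- tryCatch({
      dpre <- observed_data(data$X[pre, 1], data$y[pre])
      fit <- select_q_fit(dpre$X, dpre$y, q_max, function(k)
        fit_gp(dpre, k, n_restarts = n_restarts, seed = ds, maxit = 200))
      set.seed(ds)
      draws <- posterior_sample(fit, x_post, n_samples = n_posterior)
      mean(apply(draws, 1, function(s) sqrt(mean((s - truth)^2))))
    }, error = function(e) NA_real_)
    arma_rmse <- tryCatch({
      ab <- arma_baseline(data$y[pre], p_max = arma_p_max, q_max = arma_q_max)
      pr <- stats::predict(ab$fit, n.ahead = length(x_post))
      set.seed(ds + 1L)
      rmses <- replicate(n_posterior, {
        s <- stats::rnorm(length(x_post), pr$pred, pr$se)
        sqrt(mean((s - truth)^2))
      })
      mean(rmses)
    }, error = function(e) NA_real_)
    for (meth in c("bndd_sm", "arma")) {
      v <- if (meth == "bndd_sm") bndd_rmse else arma_rmse
      ri <- ri + 1L
      rows[[ri]] <- data.frame(alpha = alpha, rep = r, method = meth,
                               rmse = v, failed = is.na(v))
    }
  }
  do.call(rbind, rows)
}
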