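# Continuous vs discontinuous model fits and effect-size extraction for
# the three designs.

test_that("continuous fit equals a plain GP fit on the same inputs", {
  data <- generate_rd_dataset("quad", d = 1, sigma = 1, n = 40, seed = 21)
  k <- kernel_spec("rbf", variance = 1, lengthscale = 0.4)
  m0 <- fit_continuous(data, k, n_restarts = 2, seed = 5)
  plain <- fit_gp(data, k, n_restarts = 2, seed = 5)
  expect_identical(m0$kernel, plain$kernel)
  expect_identical(m0$log_marginal, plain$log_marginal)
  expect_identical(m0$bic_evidence, plain$bic_evidence)
})

test_that("ITS joint log marginal is the sum of the per-side log marginals", {
  data <- generate_its_dataset(alpha = 2, n = 60, seed = 22)
  k <- kernel_spec("rbf", variance = 1, lengthscale = 0.2)
  m1 <- fit_discontinuous(data, kernel = k, mode = "its",
                          n_restarts = 2, seed = 6)
  side <- assign_side(data$partition, data$X)
  lml_sides <- vapply(c("pre", "post"), function(s) {
    b <- m1$blocks[[s]]
    log_marginal_likelihood(observed_data(b$X, b$y), b$kernel,
                            b$noise_variance)
  }, numeric(1))
  expect_equal(m1$log_marginal, sum(lml_sides), tolerance = 1e-8)
  expect_equal(m1$l,
               bndd:::n_kernel_params(m1$blocks$pre$kernel) + 1 +
               bndd:::n_kernel_params(m1$blocks$post$kernel) + 1)
})

test_that("cross-side predictive covariance is exactly zero", {
  data <- generate_rd_dataset("linear", d = 2, sigma = 0.5, n = 40, seed = 23)
  m1 <- fit_discontinuous(data, kernel = "rbf", mode = "rd",
                          n_restarts = 2, seed = 7)
  dk <- make_discontinuous_kernel(m1$kernel, data$partition)
  expect_identical(eval_kernel(dk, -0.4, 0.4)[1, 1], 0)
  # a post-side prediction uses no pre-side information: perturbing the
  # pre block leaves it untouched
  p1 <- posterior_predict(m1, 0.5, side = "post")
  m1b <- m1
  m1b$blocks$pre$alpha <- m1$blocks$pre$alpha * 2
  p2 <- posterior_predict(m1b, 0.5, side = "post")
  expect_identical(p1$mean, p2$mean)
})

test_that("a side with fewer than 2 points is rejected by name", {
  d <- observed_data(c(-1, 1, 2, 3), rnorm(4),
                     partition = partition_threshold(0))
  expect_error(fit_discontinuous(d, kernel = "rbf", mode = "rd"), "'pre'")
})

test_that("RD effect size recovers an injected jump", {
  ms <- vapply(1:8, function(s) {
    data <- generate_rd_dataset("linear", d = 4, sigma = 1, n = 100, seed = 300 + s)
    m1 <- fit_discontinuous(data, kernel = "linear", mode = "rd",
                            n_restarts = 2, seed = s)
    suppressMessages(rd_effect_size(m1)$m)
  }, numeric(1))
  expect_lt(abs(median(ms) - 4), 1)
})

test_that("RD effect variance is twice the fitted noise variance for stationary kernels", {
  data <- generate_rd_dataset("lee", d = 1, sigma = 1, n = 60, seed = 25)
  for (fam in c("exp", "matern32", "rbf")) {
    m1 <- fit_discontinuous(data, kernel = fam, mode = "rd",
                            n_restarts = 2, seed = 8)
    eff <- rd_effect_size(m1)
    expect_identical(eff$s2, 2 * m1$noise_variance)
  }
  # the linear kernel is non-stationary: predictive fallback, with notice
  m1l <- fit_discontinuous(data, kernel = "linear", mode = "rd",
                           n_restarts = 2, seed = 8)
  expect_message(effl <- rd_effect_size(m1l), "non-stationary")
  p_pre <- posterior_predict(m1l, 0, side = "pre")
  p_post <- posterior_predict(m1l, 0, side = "post")
  expect_equal(effl$s2, p_pre$var + p_post$var, tolerance = 1e-12)
})

test_that("mirror-symmetric data give a near-zero RD effect", {
  ms <- vapply(1:10, function(s) {
    d <- mirrored_dataset(100, function(x) sin(2 * x), sigma = 1, seed = 400 + s)
    m1 <- fit_discontinuous(d, kernel = "rbf", mode = "rd",
                            n_restarts = 2, seed = s)
    rd_effect_size(m1)$m
  }, numeric(1))
  expect_lt(abs(median(ms)), 0.2)
})

test_that("RD effect mean matches the blockwise dense-algebra oracle", {
  data <- generate_rd_dataset("cubic", d = 2, sigma = 0.8, n = 50, seed = 26)
  m1 <- fit_discontinuous(data, kernel = "matern32", mode = "rd",
                          n_restarts = 2, seed = 9)
  eff <- rd_effect_size(m1)
  side <- assign_side(data$partition, data$X)
  gmean <- mean(data$y)  # both blocks share the global empirical mean
  oracle_mean <- function(s) {
    x <- data$X[side == s, 1]; y <- data$y[side == s]
    K <- eval_kernel(m1$kernel, x)
    jit <- 1e-6 * mean(diag(K))
    o <- gp_posterior_oracle(K + diag(jit, length(x)),
                             eval_kernel(m1$kernel, x, 0),
                             diag(eval_kernel(m1$kernel, 0)), y,
                             rep(gmean, length(y)), gmean,
                             m1$noise_variance)
    o$mean
  }
  expect_equal(eff$m, oracle_mean("post") - oracle_mean("pre"),
               tolerance = 1e-8)
})

test_that("effect mean is equivariant under adding a constant to the responses", {
  data <- generate_rd_dataset("quad", d = 1.5, sigma = 0.5, n = 60, seed = 27)
  m1a <- fit_discontinuous(data, kernel = "rbf", mode = "rd",
                           n_restarts = 2, seed = 10)
  data2 <- observed_data(data$X, data$y + 57.3, partition = data$partition)
  m1b <- fit_discontinuous(data2, kernel = "rbf", mode = "rd",
                           n_restarts = 2, seed = 10)
  expect_equal(rd_effect_size(m1a)$m, rd_effect_size(m1b)$m,
               tolerance = 1e-6)
})

test_that("ITS effect curve is near zero when the two regimes coincide", {
  # same latent signal on both sides, equal hyperparameters: the
  # extrapolated pre fit should match the post fit closely
  x <- seq(-1, 1, length.out = 120)
  y <- sin(3 * x)
  d <- observed_data(x, y, partition = partition_threshold(0))
  k <- kernel_spec("rbf", variance = 1, lengthscale = 0.5)
  blocks <- lapply(c(pre = "pre", post = "post"), function(s) {
    i <- if (s == "pre") x < 0 else x >= 0
    list(X = matrix(x[i]), y = y[i])
  })
  core <- bndd:::fit_gp_core(blocks, k, n_restarts = 2, seed = 11)
  m1 <- bndd:::new_bndd_gp(core, n = 120, mean_spec = "two_constants",
                           partition = partition_threshold(0), mode = "its")
  eff <- its_effect_curve(m1, x_grid = seq(0, 0.5, length.out = 50))
  expect_lt(max(abs(eff$m)), 0.1)
})

test_that("ITS effect variance adds the two sides' noise variances and the grid stays post-threshold", {
  data <- generate_its_dataset(alpha = 4, n = 120, seed = 28)
  m1 <- fit_discontinuous(data, kernel = "rbf", mode = "its",
                          n_restarts = 2, seed = 12)
  eff <- its_effect_curve(m1)
  expect_equal(eff$s2,
               unname(m1$blocks$pre$noise_variance +
                      m1$blocks$post$noise_variance))
  expect_true(all(eff$grid >= 0))
  expect_equal(eff$summary, max(abs(eff$m)))
  expect_error(its_effect_curve(m1, x_grid = numeric(0)), "empty")
})

test_that("geo effect curve recovers a constant offset across the boundary", {
  set.seed(29)
  n <- 120
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  f <- sin(2 * X[, 1]) + cos(2 * X[, 2])
  offset <- 2
  post <- X[, 1] < 0  # left of the vertical boundary is the post side
  y <- f + offset * post + rnorm(n, 0.0, 0.1)
  V <- rbind(c(0, -1.2), c(0, 1.2))
  d <- observed_data(X, y, partition = partition_polyline(V))
  m1 <- fit_discontinuous(d, kernel = "rbf", mode = "geo",
                          n_restarts = 2, seed = 13)
  eff <- geo_effect_curve(m1, n_points = 21)
  interior <- 5:17
  expect_true(all(abs(eff$m[interior] - offset) < 0.2))
  # shared smooth surface (offset 0): effect small relative to its sd
  y0 <- f + rnorm(n, 0, 0.1)
  d0 <- observed_data(X, y0, partition = partition_polyline(V))
  m10 <- fit_discontinuous(d0, kernel = "rbf", mode = "geo",
                           n_restarts = 2, seed = 13)
  eff0 <- geo_effect_curve(m10, n_points = 21)
  expect_true(max(abs(eff0$m) - 3 * eff0$sd) < 0)
})

test_that("1-D data embedded in the plane reproduce the RD effect at the crossing", {
  data <- generate_rd_dataset("linear", d = 3, sigma = 0.5, n = 60, seed = 31)
  m1 <- fit_discontinuous(data, kernel = "rbf", mode = "rd",
                          n_restarts = 2, seed = 14)
  eff_rd <- rd_effect_size(m1)
  # same observations as points (x, 0) with a vertical boundary at x0 = 0
  X2 <- cbind(data$X[, 1], 0)
  V <- rbind(c(0, 1), c(0, -1))  # oriented so x >= 0 is the post side
  d2 <- observed_data(X2, data$y, partition = partition_labels(
    ifelse(data$X[, 1] >= 0, "post", "pre")))
  k1d <- m1$kernel  # identical kernel: distances match in the embedding
  blocks <- lapply(c(pre = "pre", post = "post"), function(s) {
    i <- d2$partition$labels == s
    list(X = d2$X[i, , drop = FALSE], y = d2$y[i])
  })
  core <- bndd:::fit_gp_core(blocks, k1d, n_restarts = 1, seed = 14, maxit = 0)
  # freeze at the 1-D optimum: rebuild blocks with the fitted kernel/noise
  for (s in c("pre", "post")) {
    b <- core$blocks[[s]]
    K <- eval_kernel(m1$kernel, b$X)
    ch <- chol(K + diag(m1$noise_variance + 1e-6 * mean(diag(K)), nrow(b$X)))
    core$blocks[[s]]$kernel <- m1$kernel
    core$blocks[[s]]$noise_variance <- m1$noise_variance
    core$blocks[[s]]$mean_type <- "fixed"
    core$blocks[[s]]$mean_pars <- mean(data$y)
    core$blocks[[s]]$chol <- ch
    core$blocks[[s]]$alpha <- backsolve(ch, forwardsolve(t(ch),
                                                         b$y - mean(data$y)))
  }
  m1g <- structure(list(blocks = core$blocks, kernel = m1$kernel,
                        noise_variance = m1$noise_variance,
                        partition = partition_polyline(V)),
                   class = "bndd_gp")
  pd <- block_pred_diff <- posterior_predict(m1g, rbind(c(0, 0)), side = "post")$mean -
    posterior_predict(m1g, rbind(c(0, 0)), side = "pre")$mean
  expect_equal(unname(pd), eff_rd$m, tolerance = 1e-6)
})

test_that("null data favour the continuous model more often than not", {
  bf <- vapply(1:10, function(s) {
    data <- generate_rd_dataset("linear", d = 0, sigma = 1, n = 60, seed = 500 + s)
    m0 <- fit_continuous(data, "rbf", n_restarts = 2, seed = s)
    m1 <- fit_discontinuous(data, kernel = "rbf", mode = "rd",
                            n_restarts = 2, seed = s)
    m1$bic_evidence - m0$bic_evidence
  }, numeric(1))
  expect_gt(sum(bf < 0), 5)
})
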