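# Covariance library: closed forms, PSD-ness, the spectral mixture
# transform pair, and the discontinuity mask.

test_that("constant and exponentiated-quadratic kernels match their closed forms", {
  k <- kernel_spec("constant", variance = 2.5)
  expect_equal(eval_kernel(k, c(-1, 0.3), c(2, 7)),
               matrix(2.5, 2, 2))
  k2 <- kernel_spec("rbf", variance = 1.7, lengthscale = 0.4)
  expect_equal(diag(eval_kernel(k2, c(0.1, -0.5, 2))), rep(1.7, 3))
  expect_equal(eval_kernel(k2, 0, 0.4)[1, 1], 1.7 * exp(-0.5))
})

test_that("matern32 Gram matrix is PSD and matches the elementwise oracle", {
  set.seed(11)
  x <- runif(5, -1, 1)
  k <- kernel_spec("matern32", variance = 1.3, lengthscale = 0.6)
  K <- eval_kernel(k, x)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  K_oracle <- outer(x, x, matern32_oracle, variance = 1.3, lengthscale = 0.6)
  expect_equal(K, K_oracle, tolerance = 1e-12)
})

test_that("stationary kernels depend on inputs only through their distance", {
  set.seed(21)
  for (fam in c("exp", "matern32", "rbf")) {
    k <- kernel_spec(fam, variance = 1.1, lengthscale = 0.7)
    x <- runif(6, -2, 2)
    for (shift in c(-3.2, 0.5, 11)) {
      expect_equal(eval_kernel(k, x), eval_kernel(k, x + shift),
                   tolerance = 1e-12)
    }
  }
  sm <- sm_params(weights = c(0.4, 0.6), means = c(1.5, 3), scales = c(0.2, 0.4))
  ks <- kernel_spec("sm", sm = sm)
  x <- runif(6, -2, 2)
  expect_equal(eval_kernel(ks, x), eval_kernel(ks, x + 2.7), tolerance = 1e-12)
})

test_that("invalid hyperparameters and mismatched dimensions are rejected", {
  expect_error(kernel_spec("rbf", variance = -1), "positive")
  expect_error(kernel_spec("matern32", lengthscale = 0), "positive")
  expect_error(sm_params(numeric(0), numeric(0), numeric(0)), "Q >= 1")
  expect_error(sm_params(c(1, 1), c(1), c(1, 1)), "length Q")
  k <- kernel_spec("rbf")
  expect_error(eval_kernel(k, matrix(1:4, 2), matrix(1:3, 1)), "dimensionality")
})

test_that("spectral mixture value matches its definition and the inverse-FT oracle", {
  sm <- sm_params(weights = c(0.3, 1.2), means = c(0.8, 2.5),
                  scales = c(0.15, 0.6))
  # tau = 0: cos and exp terms are 1, leaving the weight sum
  expect_equal(spectral_mixture_value(0, sm), 0.3 + 1.2)
  # single zero-frequency component degenerates to pure Gaussian decay
  sm1 <- sm_params(1, 0, 0.5)
  tau <- seq(0, 2, by = 0.25)
  expect_equal(spectral_mixture_value(tau, sm1),
               exp(-2 * pi^2 * tau^2 * 0.25), tolerance = 1e-12)
  # general case equals the numeric inverse Fourier transform of the
  # Gaussian-mixture spectral density
  set.seed(3)
  w <- runif(3, 0.1, 2); mu <- runif(3, 0, 4); s <- runif(3, 0.05, 0.8)
  smr <- sm_params(w, mu, s)
  tau <- seq(0, 1.5, length.out = 9)
  expect_equal(spectral_mixture_value(tau, smr),
               sm_ift_oracle(tau, w, mu, s), tolerance = 1e-7)
})

test_that("zero-frequency spectral mixture is a sum of exponentiated-quadratic kernels", {
  w <- c(0.5, 1.5); s <- c(0.3, 0.9)
  sm <- sm_params(weights = w, means = c(0, 0), scales = s)
  x <- seq(-1, 1, length.out = 7)
  K <- eval_kernel(kernel_spec("sm", sm = sm), x)
  # SM scale s corresponds to an RBF length-scale 1 / (2 pi s)
  K_rbf <- eval_kernel(kernel_spec("rbf", variance = w[1],
                                   lengthscale = 1 / (2 * pi * s[1])), x) +
    eval_kernel(kernel_spec("rbf", variance = w[2],
                            lengthscale = 1 / (2 * pi * s[2])), x)
  expect_equal(K, K_rbf, tolerance = 1e-12)
})

test_that("threshold partition puts the boundary point on the post side", {
  p <- partition_threshold(0)
  expect_identical(assign_side(p, c(-0.5, 0, 0.5)), c("pre", "post", "post"))
  p2 <- partition_threshold(1.5)
  expect_identical(assign_side(p2, c(1.49, 1.5)), c("pre", "post"))
})

test_that("polyline partition splits the plane by the boundary", {
  # vertical boundary x1 = 0, oriented upward: left side (x1 < 0) is post
  V <- rbind(c(0, -2), c(0, 2))
  p <- partition_polyline(V)
  X <- rbind(c(-1, 0), c(1, 0), c(0, 1))
  expect_identical(assign_side(p, X), c("post", "pre", "post"))
})

test_that("discontinuity mask zeroes cross-side covariances and keeps blocks intact", {
  base <- kernel_spec("matern32", variance = 1.2, lengthscale = 0.5)
  dk <- make_discontinuous_kernel(base, partition_threshold(0))
  expect_equal(eval_kernel(dk, -0.5, 0.5)[1, 1], 0)
  expect_equal(eval_kernel(dk, 0.5, 0.5)[1, 1],
               eval_kernel(base, 0.5, 0.5)[1, 1])
  # side-sorted Gram is block-diagonal with blocks bit-identical to the base
  x <- c(sort(runif(4, -1, -0.01)), sort(runif(3, 0, 1)))
  K <- eval_kernel(dk, x)
  expect_identical(K[1:4, 5:7], matrix(0, 4, 3))
  expect_identical(K[1:4, 1:4], eval_kernel(base, x[1:4]))
  expect_identical(K[5:7, 5:7], eval_kernel(base, x[5:7]))
})

test_that("block Gram inverse equals the assembled blockwise inverses", {
  set.seed(42)
  x <- c(runif(6, -1, -0.01), runif(5, 0, 1))
  base <- kernel_spec("rbf", variance = 1, lengthscale = 0.4)
  dk <- make_discontinuous_kernel(base, partition_threshold(0))
  sn2 <- 0.3
  C <- eval_kernel(dk, x) + diag(sn2, 11)
  Cinv_dense <- solve(C)
  A <- eval_kernel(base, x[1:6]) + diag(sn2, 6)
  B <- eval_kernel(base, x[7:11]) + diag(sn2, 5)
  Cinv_blocks <- matrix(0, 11, 11)
  Cinv_blocks[1:6, 1:6] <- solve(A)
  Cinv_blocks[7:11, 7:11] <- solve(B)
  expect_equal(Cinv_dense, Cinv_blocks, tolerance = 1e-8)
})

test_that("per-side base kernels are honoured by the mask", {
  kp <- kernel_spec("rbf", variance = 1, lengthscale = 0.2)
  kq <- kernel_spec("rbf", variance = 3, lengthscale = 0.8)
  dk <- make_discontinuous_kernel(list(pre = kp, post = kq),
                                  partition_threshold(0))
  expect_equal(eval_kernel(dk, -0.3, -0.3)[1, 1], 1)
  expect_equal(eval_kernel(dk, 0.3, 0.3)[1, 1], 3)
  expect_equal(eval_kernel(dk, -0.3, 0.3)[1, 1], 0)
})
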