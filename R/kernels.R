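# Covariance-function library: stationary and degenerate kernels, the
# spectral mixture kernel, and the discontinuity mask that makes the
# Gram matrix block-diagonal across the threshold.

KERNEL_FAMILIES <- c("constant", "linear", "exp", "matern32", "rbf", "sm")

#' Create a covariance-function specification
#'
#' @param family one of `"constant"`, `"linear"`, `"exp"` (exponential,
#'   Matern 1/2), `"matern32"` (Matern 3/2), `"rbf"` (exponentiated
#'   quadratic) or `"sm"` (spectral mixture).
#' @param variance signal variance (> 0); ignored by `"sm"`.
#' @param lengthscale length-scale (> 0) for the stationary families.
#' @param offset,bias offset c and bias b of the linear kernel
#'   k(x, x') = variance * (x - c)(x' - c) + bias; the offset is
#'   unconstrained, the bias positive.
#' @param sm a [sm_params()] object; required when `family = "sm"`.
#'
#' @details The linear kernel carries a learnable offset and bias so the
#'   implied function class is intercept + slope. The Matern 3/2 and
#'   exponential kernels use their closed forms with fixed smoothness;
#'   a Matern kernel with smoothness p + 1/2 is sensitive to
#'   discontinuities in up to the p-th derivative, which is what makes the
#'   kernel choice a design choice about the alleged effect.
#' @return an object of class `bndd_kernel`.
#' @export
kernel_spec <- function(family, variance = 1, lengthscale = 1,
                        offset = 0, bias = 1, sm = NULL) {
  family <- match.arg(family, KERNEL_FAMILIES)
  if (family == "sm") {
    if (is.null(sm)) stop("family 'sm' requires `sm = sm_params(...)`")
    stopifnot(inherits(sm, "bndd_sm_params"))
  } else {
    if (!is.finite(variance) || variance <= 0)
      stop("kernel variance must be a positive finite number")
    if (family %in% c("exp", "matern32", "rbf") &&
        (!is.finite(lengthscale) || lengthscale <= 0))
      stop("kernel lengthscale must be a positive finite number")
    if (family == "linear" && (!is.finite(bias) || bias <= 0))
      stop("linear kernel bias must be positive")
  }
  structure(list(family = family, variance = variance,
                 lengthscale = lengthscale, offset = offset, bias = bias,
                 sm = sm),
            class = "bndd_kernel")
}

#' Spectral mixture parameters
#'
#' A stationary covariance whose spectral density is a Q-component Gaussian
#' mixture: component q has weight `weights[q]`, mean frequency `means[q]`
#' (cycles per unit of x) and spectral standard deviation `scales[q]`.
#'
#' @param weights nonnegative component weights; `sum(weights)` is the
#'   signal variance k(0).
#' @param means nonnegative mean frequencies, cycles per unit of x.
#' @param scales positive spectral standard deviations; 1/scale acts as the
#'   length-scale of the corresponding component.
#' @return an object of class `bndd_sm_params`.
#' @export
sm_params <- function(weights, means, scales) {
  Q <- length(weights)
  if (Q < 1) stop("spectral mixture needs at least one component (Q >= 1)")
  if (length(means) != Q || length(scales) != Q)
    stop("weights, means and scales must all have length Q")
  if (any(!is.finite(c(weights, means, scales))))
    stop("spectral mixture parameters must be finite")
  if (any(weights < 0)) stop("spectral mixture weights must be nonnegative")
  if (any(means < 0)) stop("spectral mixture mean frequencies must be nonnegative")
  if (any(scales <= 0)) stop("spectral mixture scales must be positive")
  structure(list(Q = Q, weights = as.numeric(weights),
                 means = as.numeric(means), scales = as.numeric(scales)),
            class = "bndd_sm_params")
}

#' Spectral mixture covariance value
#'
#' Evaluates k(tau) = sum_q w_q cos(2 pi tau mu_q) exp(-2 pi^2 tau^2 sigma_q^2),
#' the inverse Fourier transform of the Gaussian-mixture spectral density.
#' At tau = 0 this equals `sum(weights)`.
#'
#' @param tau nonnegative distance(s) |x - x'|.
#' @param params a [sm_params()] object.
#' @return covariance value(s), same shape as `tau`.
#' @export
spectral_mixture_value <- function(tau, params) {
  stopifnot(inherits(params, "bndd_sm_params"))
  if (any(tau < 0)) stop("tau must be nonnegative")
  out <- 0
  for (q in seq_len(params$Q)) {
    out <- out + params$weights[q] *
      cos(2 * pi * tau * params$means[q]) *
      exp(-2 * pi^2 * tau^2 * params$scales[q]^2)
  }
  out
}

# coerce inputs to an n x d matrix (d = 1 for RD/ITS, 2 for geo)
as_input_matrix <- function(x) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("inputs must be finite")
  X
}

# cross Euclidean distance matrix
cross_dist <- function(X, X2) {
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  sqrt(pmax(d2, 0))
}

#' Evaluate a kernel Gram matrix
#'
#' @param spec a [kernel_spec()] (or discontinuous wrapper from
#'   [make_discontinuous_kernel()]).
#' @param X,X2 input points: numeric vectors (1-D) or n x d matrices.
#'   `X2` defaults to `X`, giving the symmetric Gram matrix.
#' @return the matrix K with `K[i, j] = k(X[i], X2[j])`; symmetric and
#'   positive semi-definite (up to jitter) when `X2 = X`.
#' @export
eval_kernel <- function(spec, X, X2 = X) {
  UseMethod("eval_kernel")
}

#' @export
eval_kernel.bndd_kernel <- function(spec, X, X2 = X) {
  X <- as_input_matrix(X); X2 <- as_input_matrix(X2)
  if (ncol(X) != ncol(X2)) stop("X and X2 have mismatched dimensionality")
  switch(spec$family,
    constant = matrix(spec$variance, nrow(X), nrow(X2)),
    linear = {
      spec$variance * tcrossprod(X - spec$offset, X2 - spec$offset) + spec$bias
    },
    exp = {
      D <- cross_dist(X, X2)
      spec$variance * exp(-D / spec$lengthscale)
    },
    matern32 = {
      a <- sqrt(3) * cross_dist(X, X2) / spec$lengthscale
      spec$variance * (1 + a) * exp(-a)
    },
    rbf = {
      D <- cross_dist(X, X2)
      spec$variance * exp(-D^2 / (2 * spec$lengthscale^2))
    },
    sm = {
      D <- cross_dist(X, X2)
      spectral_mixture_value(D, spec$sm)
    })
}

# ---- partitions -----------------------------------------------------------

#' Threshold partition (1-D designs)
#'
#' Assigns side labels by the sharp rule: a point is "post" (treated)
#' iff x >= x0; the boundary point x = x0 itself is post.
#'
#' @param x0 scalar threshold on the assignment variable.
#' @return an object of class `bndd_partition`.
#' @export
partition_threshold <- function(x0) {
  stopifnot(is.numeric(x0), length(x0) == 1, is.finite(x0))
  structure(list(kind = "threshold", x0 = x0), class = "bndd_partition")
}

#' Polyline boundary partition (2-D geographic designs)
#'
#' Assigns each point to the side of an ordered polyline: the nearest
#' boundary segment is found and the sign of the 2-D cross product of the
#' segment direction with the point decides the side ("post" for the left
#' side, including points exactly on the boundary).
#'
#' @param vertices m x 2 matrix of ordered polyline vertices (m >= 2).
#' @return an object of class `bndd_partition`.
#' @export
partition_polyline <- function(vertices) {
  V <- as_input_matrix(vertices)
  if (ncol(V) != 2 || nrow(V) < 2)
    stop("boundary polyline needs an m x 2 matrix with m >= 2")
  structure(list(kind = "polyline", vertices = V), class = "bndd_partition")
}

#' Explicit side labels
#'
#' @param labels character vector of "pre"/"post" labels, one per observation.
#' @return an object of class `bndd_partition`.
#' @export
partition_labels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("pre", "post")))
    stop("labels must all be 'pre' or 'post'")
  structure(list(kind = "labels", labels = labels), class = "bndd_partition")
}

# signed distance-free side assignment for a polyline
polyline_side <- function(V, X) {
  n <- nrow(X); m <- nrow(V) - 1
  side <- character(n)
  for (i in seq_len(n)) {
    p <- X[i, ]
    best <- Inf; s_best <- 1
    for (j in seq_len(m)) {
      a <- V[j, ]; b <- V[j + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      proj <- a + t * ab
      d2 <- sum((p - proj)^2)
      if (d2 < best) {
        best <- d2
        s_best <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
      }
    }
    side[i] <- if (s_best >= 0) "post" else "pre"
  }
  side
}

#' Assign side labels to observations
#'
#' @param partition a `bndd_partition`.
#' @param X input points (vector or matrix, as in [eval_kernel()]).
#' @return character vector of `"pre"` / `"post"`, one per row of `X`.
#' @export
assign_side <- function(partition, X) {
  stopifnot(inherits(partition, "bndd_partition"))
  X <- as_input_matrix(X)
  switch(partition$kind,
    threshold = ifelse(X[, 1] >= partition$x0, "post", "pre"),
    polyline = polyline_side(partition$vertices, X),
    labels = {
      if (length(partition$labels) != nrow(X))
        stop("label partition length does not match the data")
      partition$labels
    })
}

# ---- discontinuity mask ---------------------------------------------------

#' Discontinuity-masking kernel wrapper
#'
#' Wraps a base kernel so that covariances across the threshold are exactly
#' zero: k1(x, x') = k(x, x') if x and x' lie on the same side of the
#' partition, and 0 otherwise. On side-sorted inputs the Gram matrix is
#' block-diagonal, so the two sides are independent Gaussian processes.
#'
#' @param base a [kernel_spec()], or a named list `list(pre = , post = )`
#'   of two kernels for per-side hyperparameters (interrupted time series).
#' @param partition a `bndd_partition`.
#' @return an object of class `bndd_dkernel` usable with [eval_kernel()].
#' @export
make_discontinuous_kernel <- function(base, partition) {
  stopifnot(inherits(partition, "bndd_partition"))
  if (inherits(base, "bndd_kernel")) {
    base <- list(pre = base, post = base)
  } else {
    stopifnot(is.list(base), inherits(base$pre, "bndd_kernel"),
              inherits(base$post, "bndd_kernel"))
  }
  structure(list(base = base, partition = partition),
            class = c("bndd_dkernel"))
}

#' @export
eval_kernel.bndd_dkernel <- function(spec, X, X2 = X) {
  X <- as_input_matrix(X); X2 <- as_input_matrix(X2)
  s1 <- assign_side(spec$partition, X)
  s2 <- assign_side(spec$partition, X2)
  K <- matrix(0, nrow(X), nrow(X2))
  for (side in c("pre", "post")) {
    i <- s1 == side; j <- s2 == side
    if (any(i) && any(j))
      K[i, j] <- eval_kernel(spec$base[[side]],
                             X[i, , drop = FALSE], X2[j, , drop = FALSE])
  }
  K
}

# ---- parameter packing / transforms --------------------------------------

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
softplus_inv <- function(t) ifelse(t > 30, t, log(expm1(t)))

# hyperparameter vector on the constrained scale + transform flags
kernel_param_info <- function(spec) {
  switch(spec$family,
    constant = list(values = c(variance = spec$variance),
                    transform = "softplus"),
    linear = list(values = c(variance = spec$variance, offset = spec$offset,
                             bias = spec$bias),
                  transform = c("softplus", "identity", "softplus")),
    exp = ,
    matern32 = ,
    rbf = list(values = c(variance = spec$variance,
                          lengthscale = spec$lengthscale),
               transform = c("softplus", "softplus")),
    sm = {
      Q <- spec$sm$Q
      vals <- c(spec$sm$weights, spec$sm$means, spec$sm$scales)
      names(vals) <- c(paste0("w", 1:Q), paste0("mu", 1:Q), paste0("sigma", 1:Q))
      list(values = vals, transform = rep("softplus", 3 * Q))
    })
}

to_unconstrained <- function(values, transform) {
  ifelse(transform == "softplus", softplus_inv(pmax(values, 1e-10)), values)
}
to_constrained <- function(z, transform) {
  ifelse(transform == "softplus", softplus(z), z)
}
# d(constrained)/d(unconstrained)
transform_jacobian <- function(z, transform) {
  ifelse(transform == "softplus", stats::plogis(z), 1)
}

kernel_set_params <- function(spec, values) {
  switch(spec$family,
    constant = { spec$variance <- values[["variance"]] },
    linear = {
      spec$variance <- values[["variance"]]
      spec$offset <- values[["offset"]]
      spec$bias <- values[["bias"]]
    },
    exp = ,
    matern32 = ,
    rbf = {
      spec$variance <- values[["variance"]]
      spec$lengthscale <- values[["lengthscale"]]
    },
    sm = {
      Q <- spec$sm$Q
      spec$sm$weights <- pmax(unname(values[1:Q]), 0)
      spec$sm$means <- pmax(unname(values[Q + 1:Q]), 0)
      spec$sm$scales <- pmax(unname(values[2 * Q + 1:Q]), 1e-10)
    })
  spec
}

# list of dK/dtheta matrices (constrained scale), in kernel_param_info order
kernel_grad_matrices <- function(spec, X) {
  X <- as_input_matrix(X)
  n <- nrow(X)
  ones <- matrix(1, n, n)
  switch(spec$family,
    constant = list(variance = ones),
    linear = {
      Xc <- X - spec$offset
      dv <- tcrossprod(Xc, Xc)
      rs <- rowSums(Xc)
      dc <- -spec$variance * (outer(rs, rep(1, n)) + outer(rep(1, n), rs))
      list(variance = dv, offset = dc, bias = ones)
    },
    exp = {
      D <- cross_dist(X, X)
      E <- exp(-D / spec$lengthscale)
      list(variance = E,
           lengthscale = spec$variance * E * D / spec$lengthscale^2)
    },
    matern32 = {
      D <- cross_dist(X, X)
      a <- sqrt(3) * D / spec$lengthscale
      E <- exp(-a)
      list(variance = (1 + a) * E,
           lengthscale = spec$variance * 3 * D^2 / spec$lengthscale^3 * E)
    },
    rbf = {
      D <- cross_dist(X, X)
      E <- exp(-D^2 / (2 * spec$lengthscale^2))
      list(variance = E,
           lengthscale = spec$variance * E * D^2 / spec$lengthscale^3)
    },
    sm = {
      D <- cross_dist(X, X)
      Q <- spec$sm$Q
      out <- vector("list", 3 * Q)
      for (q in 1:Q) {
        w <- spec$sm$weights[q]; mu <- spec$sm$means[q]; s <- spec$sm$scales[q]
        Cq <- cos(2 * pi * D * mu)
        Eq <- exp(-2 * pi^2 * D^2 * s^2)
        out[[q]] <- Cq * Eq
        out[[Q + q]] <- -2 * pi * D * w * sin(2 * pi * D * mu) * Eq
        out[[2 * Q + q]] <- w * Cq * Eq * (-4 * pi^2 * D^2 * s)
      }
      names(out) <- names(kernel_param_info(spec)$values)
      out
    })
}
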