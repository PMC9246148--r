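# Data readers, analysis configuration, the end-to-end analysis driver,
# and the JSON report writer.

#' Analysis configuration
#'
#' @param mode `"rd"`, `"its"` or `"geo"`.
#' @param threshold scalar threshold x0 (required for rd/its). The sharp
#'   rule assigns x = x0 to the post (treated) side.
#' @param boundary polyline vertices (m x 2 matrix or path to a
#'   two-column CSV of ordered vertices; required for geo).
#' @param kernels candidate kernel names; see [fit_continuous()].
#' @param model_prior prior (p(M0), p(M1)); uniform by default,
#'   overridable e.g. for multiplicity control.
#' @param m0_mean mean function of the continuous model:
#'   `"empirical_constant"` or `"changepoint_constant"`.
#' @param q_max maximum spectral mixture components.
#' @param n_restarts optimizer restarts per fit.
#' @param n_bma_samples Monte Carlo draws for the model-averaged effect.
#' @param seed integer seed driving every stochastic stage (restart
#'   initialization and BMA sampling) through derived per-stage seeds.
#' @param out optional path for the JSON report.
#' @return an `bndd_config` list.
#' @export
analysis_config <- function(mode = c("rd", "its", "geo"), threshold = NULL,
                            boundary = NULL, kernels = c("linear", "exp",
                                                         "matern32", "rbf"),
                            model_prior = c(0.5, 0.5),
                            m0_mean = "empirical_constant", q_max = 6,
                            n_restarts = 10, n_bma_samples = 50000,
                            seed = 1, out = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("rd", "its") && is.null(threshold))
    stop("mode '", mode, "' requires a threshold")
  if (mode == "geo" && is.null(boundary))
    stop("mode 'geo' requires a boundary polyline")
  if (length(kernels) < 1) stop("at least one kernel is required")
  structure(list(mode = mode, threshold = threshold, boundary = boundary,
                 kernels = kernels, model_prior = model_prior,
                 m0_mean = m0_mean, q_max = q_max, n_restarts = n_restarts,
                 n_bma_samples = n_bma_samples, seed = as.integer(seed),
                 out = out),
            class = "bndd_config")
}

#' Load a dataset from CSV/TSV
#'
#' Expects a header with columns `x`, `y` (rd/its) or `x1`, `x2`, `y`
#' (geo). Rows with missing values are dropped with a message.
#'
#' @param path file path; tab-separated if the extension is `.tsv`.
#' @param mode analysis mode, determines the required columns.
#' @return a [observed_data()] object (partition attached later by
#'   [run_analysis()]).
#' @export
load_dataset <- function(path, mode = c("rd", "its", "geo")) {
  mode <- match.arg(mode)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- if (mode == "geo") c("x1", "x2", "y") else c("x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(df[, need])
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing values")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 4) stop("fewer than 4 usable rows")
  if (mode == "geo") {
    observed_data(cbind(df$x1, df$x2), df$y)
  } else {
    observed_data(df$x, df$y)
  }
}

load_boundary <- function(boundary) {
  if (is.character(boundary)) {
    df <- utils::read.csv(boundary, header = TRUE)
    if (ncol(df) < 2) stop("boundary file needs two columns of vertices")
    boundary <- as.matrix(df[, 1:2])
  }
  as_input_matrix(boundary)
}

#' Run a full discontinuity analysis
#'
#' Fits the continuous model M0 and the discontinuous model M1 for every
#' candidate kernel, computes BIC evidences, per-kernel log Bayes
#' factors, the kernel-averaged total log Bayes factor, the model
#' posterior, the conditional effect-size distribution (from the kernel
#' with the highest M1 evidence), and Monte Carlo draws from the
#' spike-and-slab model-averaged effect (kernel sampled proportional to
#' its M1 evidence, then the kernel's Gaussian slab). Kernels that fail
#' to fit are excluded with a warning.
#'
#' @param config an [analysis_config()].
#' @param data a [observed_data()] object.
#' @return object of class `bndd_comparison`; see [write_report()] for
#'   the serialized schema.
#' @export
run_analysis <- function(config, data) {
  stopifnot(inherits(config, "bndd_config"), inherits(data, "bndd_data"))
  mode <- config$mode
  partition <- if (mode == "geo") partition_polyline(load_boundary(config$boundary))
               else partition_threshold(config$threshold)
  data$partition <- partition
  seed <- config$seed

  per_kernel <- list(); effects <- list(); fits1 <- list()
  for (i in seq_along(config$kernels)) {
    k <- config$kernels[i]
    sk <- (seed + 101L * i) %% 2147483647L
    row <- tryCatch({
      m0 <- fit_continuous(data, k, mean_spec = config$m0_mean,
                           x0 = config$threshold, q_max = config$q_max,
                           n_restarts = config$n_restarts, seed = sk)
      m1 <- fit_discontinuous(data, partition, kernel = k, mode = mode,
                              q_max = config$q_max,
                              n_restarts = config$n_restarts, seed = sk)
      eff <- switch(mode,
        rd = suppressMessages(rd_effect_size(m1)),
        its = its_effect_curve(m1),
        geo = geo_effect_curve(m1))
      fits1[[k]] <- m1
      effects[[k]] <- eff
      data.frame(name = k, log_ev_m0 = m0$bic_evidence,
                 log_ev_m1 = m1$bic_evidence,
                 log_bf10 = m1$bic_evidence - m0$bic_evidence)
    }, error = function(e) {
      warning("kernel '", k, "' failed to fit and is excluded: ",
              conditionMessage(e))
      NULL
    })
    per_kernel[[i]] <- row
  }
  per_kernel <- do.call(rbind, per_kernel)
  if (is.null(per_kernel) || nrow(per_kernel) == 0)
    stop("no kernel could be fitted")

  bma_k <- kernel_bma(per_kernel)
  log_ev_m0 <- logsumexp(per_kernel$log_ev_m0) - log(nrow(per_kernel))
  log_ev_m1 <- logsumexp(per_kernel$log_ev_m1) - log(nrow(per_kernel))
  post <- model_posterior(c(log_ev_m0, log_ev_m1), prior = config$model_prior)

  best_k <- per_kernel$name[which.max(per_kernel$log_ev_m1)]
  eff <- effects[[best_k]]

  # scalar effect for the spike-and-slab average: the RD jump, or the
  # effect-curve value at the point of maximum absolute effect
  scal <- scalar_effect(eff)
  set.seed((seed + 17L) %% 2147483647L)
  nk <- nrow(per_kernel)
  kidx <- sample.int(nk, config$n_bma_samples, replace = TRUE,
                     prob = bma_k$kernel_posterior_m1)
  spike <- stats::runif(config$n_bma_samples) < post[1]
  scals <- lapply(effects[per_kernel$name], scalar_effect)
  m_k <- vapply(scals, `[[`, numeric(1), "m")
  s_k <- sqrt(vapply(scals, `[[`, numeric(1), "s2"))
  samples <- ifelse(spike, 0,
                    stats::rnorm(config$n_bma_samples, m_k[kidx], s_k[kidx]))
  # kernel-marginal conditional effect, consistent with the draws
  m_marginal <- sum(bma_k$kernel_posterior_m1 * m_k)

  result <- structure(list(
    mode = mode, kernels = per_kernel$name, per_kernel = per_kernel,
    log_bf_total = bma_k$log_bf_total,
    model_prior = config$model_prior, model_posterior = unname(post),
    effect = eff, effect_kernel = best_k,
    fits = fits1,
    bma = list(samples = samples,
               mean = unname(post[2] * m_marginal),
               conditional_mean = unname(m_marginal),
               spike_mass = mean(spike),
               quantiles = stats::quantile(samples,
                                           c(0.025, 0.25, 0.5, 0.75, 0.975))),
    seed = seed), class = "bndd_comparison")
  if (!is.null(config$out)) write_report(result, config$out)
  result
}

scalar_effect <- function(eff) {
  switch(eff$mode,
    rd = list(m = eff$m, s2 = eff$s2),
    its = {
      i <- which.max(abs(eff$m))
      list(m = eff$m[i], s2 = eff$s2)
    },
    geo = {
      i <- which.max(abs(eff$m))
      list(m = eff$m[i], s2 = eff$s2[i])
    })
}

#' Write (or re-write) a JSON analysis report
#'
#' Schema: `{mode, kernels, per_kernel: [{name, log_ev_m0, log_ev_m1,
#' log_bf10}], log_bf_total, model_posterior: {m0, m1}, effect: {m, s2,
#' summary}, bma: {mean, quantiles, spike_mass}, seed}`. Writing a report
#' read back with [read_report()] reproduces the same bytes.
#'
#' @param result a `bndd_comparison`, or a list previously returned by
#'   [read_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- if (inherits(result, "bndd_comparison")) build_report(result)
         else result
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

build_report <- function(result) {
  pk <- result$per_kernel
  per_kernel <- lapply(seq_len(nrow(pk)), function(i)
    list(name = pk$name[i], log_ev_m0 = pk$log_ev_m0[i],
         log_ev_m1 = pk$log_ev_m1[i], log_bf10 = pk$log_bf10[i]))
  q <- result$bma$quantiles
  list(mode = result$mode,
       kernels = as.list(result$kernels),
       per_kernel = per_kernel,
       log_bf_total = result$log_bf_total,
       model_posterior = list(m0 = result$model_posterior[1],
                              m1 = result$model_posterior[2]),
       effect = list(m = if (length(result$effect$m) == 1) result$effect$m
                         else as.list(result$effect$m),
                     s2 = if (length(result$effect$s2) == 1) result$effect$s2
                          else as.list(result$effect$s2),
                     summary = result$effect$summary),
       bma = list(mean = result$bma$mean,
                  quantiles = list(q025 = unname(q[1]), q25 = unname(q[2]),
                                   q50 = unname(q[3]), q75 = unname(q[4]),
                                   q975 = unname(q[5])),
                  spike_mass = result$bma$spike_mass),
       seed = result$seed)
}

#' Read a JSON analysis report
#'
#' @param path path to a report written by [write_report()].
#' @return the report as a nested list (scalars unboxed).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' @export
print.bndd_comparison <- function(x, ...) {
  cat("Discontinuity analysis (mode:", x$mode, ")\n")
  print(x$per_kernel, row.names = FALSE)
  cat("total log BF10:", format(x$log_bf_total, digits = 4), "\n")
  cat("model posterior: p(M0|D) =", format(x$model_posterior[1], digits = 4),
      ", p(M1|D) =", format(x$model_posterior[2], digits = 4), "\n")
  cat("effect (", x$effect_kernel, " kernel): summary =",
      format(x$effect$summary, digits = 4), "\n")
  cat("BMA effect mean:", format(x$bma$mean, digits = 4),
      ", spike mass:", format(x$bma$spike_mass, digits = 4), "\n")
  invisible(x)
}
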