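#' Monte Carlo evaluation of an acquisition design
#'
#' The design-evaluation engine: for each of `n_mc` trials, simulate noisy
#' measurements of the monoexponential signal at the design's b-values,
#' fit `(m0, D)` by log-linear least squares, and accumulate the empirical
#' bias and standard deviation of both estimates. Bias is reported as
#' `E[D_hat] - D` and `E[m0_hat] - m0`; Monte Carlo standard errors of the
#' bias estimates (`std / sqrt(n_mc)`) are included so that design
#' differences can be judged against simulation noise.
#'
#' All trials are generated vectorized from a single seeded stream, so a
#' given `(design, params, noise, n_mc, seed)` always reproduces the same
#' result. For variance-reduced comparisons between designs of equal size,
#' pre-drawn standard-normal matrices can be supplied via `noise_draws`
#' (see [compare_designs()]).
#'
#' @param design an [acq_design()] or numeric vector of b-values
#'   (nondegenerate).
#' @param params an [adc_params()] object (true `m0`, `D`).
#' @param noise a [noise_spec()].
#' @param n_mc number of Monte Carlo trials (>= 2). The default matches the
#'   package's full-scale experiments.
#' @param seed optional integer seed.
#' @param noise_draws optional list with `n_mc x N` standard-normal matrices
#'   `zr` and (for Rician noise) `zi`; overrides `seed`.
#' @return An object of class `mc_result`: list with `bias_D`, `std_D`,
#'   `bias_m0`, `std_m0`, `mc_se_D`, `mc_se_m0`, `n_mc`, `n_failed`, plus
#'   `bias_lnm0` and `std_lnm0` -- the moments of `ln m0_hat`, on the scale
#'   where the least-squares theory is exact (the estimator is unbiased in
#'   `(ln m0, D)`; `m0_hat = exp(...)` carries a small convexity bias even
#'   under ideal noise).
#' @examples
#' evaluate_design(design_dopt(10, 0, 2000), adc_params(500, 1e-3),
#'                 noise_spec("rician", 50), n_mc = 1000, seed = 1)
#' @export
evaluate_design <- function(design, params, noise, n_mc = 20000,
                            seed = NULL, noise_draws = NULL) {
  design <- .as_design(design)
  stopifnot(inherits(params, "adc_params"), inherits(noise, "noise_spec"),
            n_mc >= 2)
  if (is_degenerate(design)) {
    stop("degenerate design: all b-values equal, cannot be evaluated")
  }
  b <- design$b
  N <- length(b)
  s <- adc_signal(params, b)

  if (is.null(noise_draws)) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
    }
    zr <- matrix(stats::rnorm(n_mc * N), n_mc, N)
    zi <- if (noise$family == "rician") {
      matrix(stats::rnorm(n_mc * N), n_mc, N)
    }
  } else {
    zr <- noise_draws$zr
    zi <- noise_draws$zi
    stopifnot(nrow(zr) == n_mc, ncol(zr) == N)
  }

  S <- matrix(s, n_mc, N, byrow = TRUE)
  if (noise$family == "rician") {
    M <- sqrt((S + noise$sigma * zr)^2 + (noise$sigma * zi)^2)
    failed <- rowSums(M > 0) < N
    if (any(failed)) {
      # Rician magnitudes are positive with probability 1; a nonpositive
      # draw means corrupted inputs, not bad luck.
      stop("internal error: ", sum(failed),
           " trial(s) produced nonpositive Rician magnitudes")
    }
    Y <- log(M)
  } else {
    Y <- log(S) + noise$sigma * zr
    failed <- rep(FALSE, n_mc)
  }

  X <- qr.coef(qr(design_matrix(design)), t(Y))   # 2 x n_mc
  D_hat <- X[2, !failed]
  m0_hat <- exp(X[1, !failed])
  n_used <- length(D_hat)

  std_D <- stats::sd(D_hat)
  std_m0 <- stats::sd(m0_hat)
  structure(
    list(bias_D = mean(D_hat) - params$D,
         std_D = std_D,
         bias_m0 = mean(m0_hat) - params$m0,
         std_m0 = std_m0,
         bias_lnm0 = mean(X[1, !failed]) - log(params$m0),
         std_lnm0 = stats::sd(X[1, !failed]),
         mc_se_D = std_D / sqrt(n_used),
         mc_se_m0 = std_m0 / sqrt(n_used),
         n_mc = n_used,
         n_failed = sum(failed)),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC evaluation (n_mc = %d, failed = %d)\n", x$n_mc,
              x$n_failed))
  cat(sprintf("  D:  bias %+.4g  sd %.4g  (mc se %.2g)\n",
              x$bias_D, x$std_D, x$mc_se_D))
  cat(sprintf("  m0: bias %+.4g  sd %.4g  (mc se %.2g)\n",
              x$bias_m0, x$std_m0, x$mc_se_m0))
  invisible(x)
}

#' @export
as.data.frame.mc_result <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Sensitivity sweep over a model or acquisition parameter
#'
#' Evaluates one or more design methods while sweeping a single variable --
#' the true diffusivity `D`, the number of measurements `N`, the upper
#' b-value bound `b_max`, or the `SNR` (`m0 / sigma_G`) -- holding all other
#' settings at the values in `fixed`. Designs are regenerated for each
#' swept value when the variable changes them (`N`, `b_max`). Within each
#' swept value all methods share the same noise draws (common random
#' numbers), so method contrasts are not diluted by independent simulation
#' noise; in particular, methods that coincide (D-optimal and equidistant
#' at `N = 2`) give identical rows.
#'
#' @param variable one of `"D"`, `"N"`, `"b_max"`, `"SNR"`.
#' @param values values the variable sweeps over.
#' @param methods design methods, any of `"dopt"`, `"ed"`, `"gcrlb"`.
#' @param fixed named list supplying the non-swept settings: `m0`, `D`,
#'   `N`, `b_min`, `b_max`, `snr`.
#' @param n_mc Monte Carlo trials per cell.
#' @param seed integer seed; each swept value gets the substream
#'   `seed + index - 1`.
#' @return A long-format data.frame: one row per (value, method), carrying
#'   the swept variable, the full fixed-parameter context, the seed, and
#'   the [evaluate_design()] summaries.
#' @examples
#' design_sweep("N", c(2, 6, 10), methods = c("dopt", "ed"),
#'              n_mc = 500, seed = 1)
#' @export
design_sweep <- function(variable = c("D", "N", "b_max", "SNR"), values,
                         methods = c("dopt", "ed"),
                         fixed = list(), n_mc = 20000, seed = NULL) {
  variable <- match.arg(variable)
  stopifnot(length(values) >= 1)
  fx <- utils::modifyList(
    list(m0 = 500, D = 1e-3, N = 10, b_min = 0, b_max = 2000, snr = 10),
    fixed
  )
  rows <- list()
  for (i in seq_along(values)) {
    p <- fx
    p[[switch(variable, D = "D", N = "N", b_max = "b_max", SNR = "snr")]] <-
      values[i]
    sub_seed <- if (is.null(seed)) NULL else seed + i - 1L
    params <- adc_params(p$m0, p$D)
    noise <- noise_spec("rician", p$m0 / p$snr)
    draws <- .draw_noise(n_mc, p$N, rician = TRUE, seed = sub_seed)
    for (method in methods) {
      des <- resolve_design(method, p$N, p$b_min, p$b_max)
      res <- evaluate_design(des, params, noise, n_mc = n_mc,
                             noise_draws = draws)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = variable, value = values[i], method = method,
        m0 = p$m0, D = p$D, N = p$N, b_min = p$b_min, b_max = p$b_max,
        snr = p$snr, seed = if (is.null(seed)) NA_integer_ else seed,
        as.data.frame(res)
      )
    }
  }
  do.call(rbind, rows)
}

#' Head-to-head design comparison with common random numbers
#'
#' Evaluates several design methods at one fixed parameter setting, reusing
#' the identical noise draws for every method so the observed differences
#' reflect the designs, not the simulation noise. All methods must resolve
#' to designs of the same size `N`.
#'
#' @inheritParams design_sweep
#' @param params an [adc_params()] object.
#' @param noise a [noise_spec()].
#' @param N,b_min,b_max shared acquisition constraints.
#' @param seed integer seed for the shared draws.
#' @return A data.frame, one row per method, with the design's b-values as
#'   a comma-separated string and the [evaluate_design()] summaries.
#' @examples
#' compare_designs(c("dopt", "gcrlb"), adc_params(500, 3e-3),
#'                 noise_spec("rician", 50), N = 10, b_min = 0,
#'                 b_max = 2000, n_mc = 500, seed = 1)
#' @export
compare_designs <- function(methods, params, noise, N, b_min = 0,
                            b_max = 2000, n_mc = 20000, seed = NULL) {
  stopifnot(length(methods) >= 1)
  designs <- lapply(methods, resolve_design, N = N, b_min = b_min,
                    b_max = b_max)
  draws <- .draw_noise(n_mc, N, rician = noise$family == "rician",
                       seed = seed)
  rows <- lapply(seq_along(methods), function(i) {
    res <- evaluate_design(designs[[i]], params, noise, n_mc = n_mc,
                           noise_draws = draws)
    data.frame(
      method = methods[i],
      b_values = paste(format(designs[[i]]$b, trim = TRUE),
                       collapse = ","),
      as.data.frame(res)
    )
  })
  do.call(rbind, rows)
}

.draw_noise <- function(n_mc, N, rician = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  }
  list(zr = matrix(stats::rnorm(n_mc * N), n_mc, N),
       zi = if (rician) matrix(stats::rnorm(n_mc * N), n_mc, N))
}
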