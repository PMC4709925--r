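#' Monoexponential model parameters
#'
#' The unknowns of the ADC signal model `m = m0 exp(-b D)`: the unweighted
#' signal amplitude `m0` (arbitrary intensity units) and the apparent
#' diffusion coefficient `D` (mm^2/s). The log-linear parameterization
#' `x = (ln m0, D)` used by the least-squares estimator is derived, never
#' stored independently.
#'
#' @param m0 unweighted signal amplitude, > 0.
#' @param D apparent diffusion coefficient (mm^2/s), > 0.
#' @return An object of class `adc_params`: list with `m0`, `D` and the
#'   derived vector `x = c(log(m0), D)`.
#' @examples
#' adc_params(500, 1e-3)
#' @export
adc_params <- function(m0, D) {
  stopifnot(length(m0) == 1L, length(D) == 1L, m0 > 0, D > 0)
  structure(list(m0 = m0, D = D, x = c(log(m0), D)), class = "adc_params")
}

#' @export
print.adc_params <- function(x, ...) {
  cat("Monoexponential parameters: m0 =", x$m0, ", D =", x$D, "mm^2/s\n")
  invisible(x)
}

#' Noise-free monoexponential signal
#'
#' Evaluates `m0 exp(-b D)` at one or more b-values.
#'
#' @param params an [adc_params()] object.
#' @param b b-value(s), s/mm^2, >= 0.
#' @return Signal intensities, strictly positive; equals `m0` at `b = 0`.
#' @examples
#' adc_signal(adc_params(500, 1e-3), c(0, 2000))
#' @export
adc_signal <- function(params, b) {
  stopifnot(inherits(params, "adc_params"))
  if (any(b < 0)) stop("b-values must be nonnegative")
  params$m0 * exp(-b * params$D)
}

#' Design matrix of the log-linearized model
#'
#' Taking logs of the signal model gives `ln m_i = ln m0 - b_i D`, a linear
#' model in `x = (ln m0, D)` with design matrix rows `(1, -b_i)`. The minus
#' sign lives in the matrix, so the estimate of `D` is read directly from
#' the second coefficient with no sign flip.
#'
#' @param design an [acq_design()] or numeric vector of b-values.
#' @return An `N x 2` matrix with rows `(1, -b_i)` in design order.
#' @export
design_matrix <- function(design) {
  design <- .as_design(design)
  cbind(1, -design$b, deparse.level = 0)
}

#' Information matrix of a design
#'
#' `M = A'A` for the log-linear design matrix `A`:
#' `[[N, -sum(b)], [-sum(b), sum(b^2)]]`. Its inverse (scaled by the noise
#' variance) is the covariance of the least-squares estimate, so designs are
#' ranked by `det(M)`.
#'
#' @inheritParams design_matrix
#' @return Symmetric 2 x 2 matrix.
#' @export
information_matrix <- function(design) {
  design <- .as_design(design)
  b <- design$b
  matrix(c(length(b), -sum(b), -sum(b), sum(b^2)), 2, 2)
}

#' Determinant of the information matrix (closed form)
#'
#' `det(M) = N sum(b^2) - (sum b)^2`, the D-optimality objective. It depends
#' only on the spread of the b-values: it is invariant under shifting all
#' b-values by a constant and scales as `c^2` under `b -> c b`. It is zero
#' exactly when all b-values coincide (degenerate design).
#'
#' @inheritParams design_matrix
#' @return Nonnegative scalar.
#' @examples
#' det_information(c(0, 2000))            # (b1 - b2)^2 = 4e6
#' det_information(c(100, 2100))          # same: translation invariant
#' @export
det_information <- function(design) {
  design <- .as_design(design)
  b <- design$b
  length(b) * sum(b^2) - sum(b)^2
}

#' Least-squares covariance of the log-linear estimate
#'
#' Under independent zero-mean noise of constant variance `sigma^2` on the
#' log-measurements, the least-squares estimate of `x = (ln m0, D)` is
#' unbiased with covariance `sigma^2 M^{-1}`. The (2,2) entry is the
#' variance of the ADC estimate; it equals `sigma^2 N / det(M)`.
#'
#' @inheritParams design_matrix
#' @param sigma log-domain noise standard deviation, >= 0.
#' @return 2 x 2 covariance matrix.
#' @export
lse_covariance <- function(design, sigma) {
  design <- .as_design(design)
  stopifnot(sigma >= 0)
  d <- det_information(design)
  if (d <= 0) {
    stop("degenerate design: information matrix is singular ",
         "(all b-values equal)")
  }
  M <- information_matrix(design)
  sigma^2 * matrix(c(M[2, 2], -M[1, 2], -M[2, 1], M[1, 1]), 2, 2) / d
}
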