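#' Log-linear least-squares fit of the monoexponential model
#'
#' Takes logs of the measured signals, `y_i = ln m_i`, and solves the linear
#' model `y = A x` with `A` rows `(1, -b_i)` and `x = (ln m0, D)` by
#' least squares. The solve uses a QR factorization of `A` (numerically
#' stable; agrees with the normal-equations solution to machine precision).
#' Noise-free inputs are recovered exactly. The ADC estimate is the second
#' coefficient directly -- the sign convention is carried by the design
#' matrix.
#'
#' Nonpositive measurements abort the fit with an error naming the
#' offending indices: under the Rician magnitude model they cannot occur,
#' so their presence indicates a pipeline bug upstream. For exploratory use
#' with other data, `clip_floor` replaces measurements below it by the
#' floor value before taking logs; it is off by default.
#'
#' @param design an [acq_design()] or numeric vector of b-values.
#' @param m measured signal intensities, same length as the design.
#' @param clip_floor optional positive floor applied to the measurements
#'   before the log transform (off by default).
#' @return An object of class `adc_fit`: list with `m0_hat`, `D_hat`,
#'   `x_hat = c(log(m0_hat), D_hat)`, and log-domain `residuals`.
#' @examples
#' d <- acq_design(c(0, 2000))
#' fit_loglinear(d, c(500, 500 * exp(-2)))  # recovers m0 = 500, D = 1e-3
#' @export
fit_loglinear <- function(design, m, clip_floor = NULL) {
  design <- .as_design(design)
  if (length(m) != length(design$b)) {
    stop("got ", length(m), " measurements for a design of size ",
         length(design$b))
  }
  if (is_degenerate(design)) {
    stop("degenerate design: all b-values equal, (m0, D) not separable")
  }
  if (!is.null(clip_floor)) {
    stopifnot(clip_floor > 0)
    m <- pmax(m, clip_floor)
  }
  bad <- which(!(m > 0))
  if (length(bad)) {
    stop("nonpositive measurement(s) at index ",
         paste(bad, collapse = ", "),
         ": log-linear fitting requires m > 0")
  }
  A <- design_matrix(design)
  y <- log(m)
  qrA <- qr(A)
  x <- qr.coef(qrA, y)
  structure(
    list(m0_hat = exp(x[1]), D_hat = x[2], x_hat = unname(x),
         residuals = unname(y - drop(A %*% x))),
    class = "adc_fit"
  )
}

#' @export
print.adc_fit <- function(x, ...) {
  cat("Log-linear LSE fit: m0_hat =", format(x$m0_hat),
      ", D_hat =", format(x$D_hat), "mm^2/s\n")
  invisible(x)
}
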