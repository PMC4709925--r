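#' Acquisition design: an ordered multiset of b-values
#'
#' An acquisition design is the set of diffusion weightings (b-values, in
#' s/mm^2) applied during an ADC measurement, together with the feasibility
#' bounds of the scanner protocol. Repeated b-values are allowed and
#' meaningful (they are repeated measurements).
#'
#' @param b numeric vector of b-values (s/mm^2), length >= 2.
#' @param b_min,b_max feasibility bounds; default to the range of `b`.
#' @return An object of class `adc_design`: a list with elements `b`,
#'   `b_min`, `b_max`.
#' @examples
#' acq_design(c(0, 0, 2000))
#' @export
acq_design <- function(b, b_min = min(b), b_max = max(b)) {
  b <- as.numeric(b)
  if (length(b) < 2L) {
    stop("a design needs at least 2 measurements, got ", length(b))
  }
  if (anyNA(b)) stop("b-values must not contain NA")
  if (!is.finite(b_min) || !is.finite(b_max) || b_min > b_max) {
    stop("invalid bounds: b_min = ", b_min, ", b_max = ", b_max)
  }
  if (any(b < b_min) || any(b > b_max)) {
    stop("b-values outside [b_min, b_max]")
  }
  structure(list(b = b, b_min = b_min, b_max = b_max), class = "adc_design")
}

#' @export
print.adc_design <- function(x, ...) {
  cat("Acquisition design (N = ", length(x$b), ", b in [",
      x$b_min, ", ", x$b_max, "] s/mm^2)\n", sep = "")
  cat("  b:", paste(format(x$b, trim = TRUE), collapse = ", "), "\n")
  if (is_degenerate(x)) cat("  [degenerate: all b-values equal]\n")
  invisible(x)
}

#' @export
length.adc_design <- function(x) length(x$b)

#' Is a design degenerate (non-estimable)?
#'
#' A design with fewer than two distinct b-values has a singular information
#' matrix: the intercept and the decay rate cannot be separated.
#'
#' @param design an [acq_design()] object.
#' @return `TRUE` if all b-values are equal.
#' @export
is_degenerate <- function(design) {
  stopifnot(inherits(design, "adc_design"))
  length(unique(design$b)) < 2L
}

.as_design <- function(x) {
  if (inherits(x, "adc_design")) x else acq_design(x)
}

#' Closed-form D-optimal design
#'
#' The design maximizing `det(M)` subject to `b_min <= b_i <= b_max` places
#' every measurement at the two endpoints of the feasible b-range: `n` at
#' `b_min` and `N - n` at `b_max`, with `n = N/2` for even `N` and
#' `n = (N + 1)/2` for odd `N`. The solution is independent of the imaged
#' parameters (m0, D) -- the key practical advantage over designs that
#' minimize a parameter-dependent Cramer-Rao bound.
#'
#' For odd `N` the mirrored split (majority at `b_max`) attains the same
#' determinant; the canonical output puts the extra measurement at `b_min`,
#' where the signal -- and hence the SNR under magnitude noise -- is
#' highest. Use `majority = "bmax"` for the mirrored variant.
#'
#' @param N number of measurements, >= 2.
#' @param b_min,b_max feasible b-value range (s/mm^2), `b_min < b_max`.
#' @param majority where the extra point goes for odd `N`.
#' @return An [acq_design()] with all `b_min` values first.
#' @examples
#' design_dopt(3, 0, 2000)   # (0, 0, 2000)
#' design_dopt(10, 0, 2000)  # five at 0, five at 2000
#' @export
design_dopt <- function(N, b_min, b_max, majority = c("bmin", "bmax")) {
  majority <- match.arg(majority)
  .check_Nrange(N, b_min, b_max)
  n <- if (N %% 2L == 0L) N / 2 else (N + 1) / 2
  if (majority == "bmax") n <- N - n
  acq_design(c(rep(b_min, n), rep(b_max, N - n)), b_min, b_max)
}

#' Equidistant design
#'
#' `N` b-values uniformly spaced on `[b_min, b_max]`, endpoints included --
#' the conventional choice in much of the ADC literature, and the main
#' comparison baseline for the D-optimal design.
#'
#' @inheritParams design_dopt
#' @return An [acq_design()].
#' @export
design_equidistant <- function(N, b_min, b_max) {
  .check_Nrange(N, b_min, b_max)
  acq_design(seq(b_min, b_max, length.out = N), b_min, b_max)
}

#' Gaussian-CRLB reference designs
#'
#' Fixed reference designs transcribed from prior work that minimizes the
#' Gaussian-noise Cramer-Rao lower bound of the ADC estimate over the
#' diffusivity range \[0.1, 3\] x 10^-3 mm^2/s: the two-point design
#' `{0, 820}` and the ten-point design `{0, 0, 700 x 6, b_max, b_max}`.
#' These values were not derived by this package; they exist as reference
#' comparators. For other `N`, use [design_crlb_numeric()].
#'
#' @param N number of measurements; only 2 and 10 are tabulated.
#' @param b_max upper b-value bound, used by the ten-point design.
#' @return An [acq_design()].
#' @export
design_gcrlb <- function(N, b_max = 2000) {
  if (N == 2L) {
    acq_design(c(0, 820), 0, max(b_max, 820))
  } else if (N == 10L) {
    acq_design(c(0, 0, rep(700, 6), b_max, b_max), 0, b_max)
  } else {
    stop("reference GCRLB designs are tabulated only for N = 2 or 10; ",
         "use design_crlb_numeric() for other N")
  }
}

#' Numerically CRLB-optimal design under Gaussian magnitude noise
#'
#' Minimizes the Cramer-Rao lower bound of the ADC estimate for the
#' nonlinear model `m = m0 exp(-b D)` observed with i.i.d. Gaussian noise of
#' standard deviation `sigma_G` on the signal magnitude. The Fisher
#' information is built from the signal gradient
#' `(exp(-bD), -m0 b exp(-bD))`; the bound on `Var(D-hat)` is the (2,2)
#' entry of its inverse. Unlike the D-optimal design, the minimizer depends
#' on the assumed `D` (its characteristic spacing scales as 1/D), which is
#' precisely why a parameter-independent alternative is attractive.
#'
#' A multi-start box-constrained quasi-Newton search (L-BFGS-B) over the
#' b-values is used; starts include the D-optimal split, an equidistant
#' spread and random points.
#'
#' @inheritParams design_dopt
#' @param D assumed diffusivity (mm^2/s), > 0.
#' @param m0 assumed unweighted signal amplitude, > 0.
#' @param sigma_G Gaussian noise standard deviation, > 0.
#' @param n_starts number of random restarts in addition to the two
#'   deterministic starts.
#' @param seed optional seed for the random restarts.
#' @return An [acq_design()] (b-values sorted ascending).
#' @export
design_crlb_numeric <- function(N, b_min, b_max, D, m0, sigma_G,
                                n_starts = 20, seed = NULL) {
  .check_Nrange(N, b_min, b_max)
  stopifnot(D > 0, m0 > 0, sigma_G > 0)
  # log of the CRLB: normalizes the objective's magnitude so the
  # quasi-Newton stopping rules behave across b/D scales
  crlb_D <- function(b) {
    g1 <- exp(-b * D)
    g2 <- -m0 * b * g1
    J <- crossprod(cbind(g1, g2)) / sigma_G^2
    d <- J[1, 1] * J[2, 2] - J[1, 2]^2
    if (d <= .Machine$double.eps * J[1, 1] * J[2, 2]) return(Inf)
    log(J[1, 1]) - log(d)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  }
  starts <- c(
    list(design_dopt(N, b_min, b_max)$b,
         design_equidistant(N, b_min, b_max)$b),
    replicate(n_starts, sort(stats::runif(N, b_min, b_max)),
              simplify = FALSE)
  )
  best <- NULL
  best_val <- Inf
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, crlb_D, method = "L-BFGS-B",
                   lower = rep(b_min, N), upper = rep(b_max, N),
                   control = list(parscale = rep(b_max - b_min, N),
                                  factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best_val) {
      best_val <- fit$value
      best <- fit$par
    }
  }
  if (is.null(best)) {
    stop("CRLB minimization failed to converge from any start")
  }
  acq_design(sort(best), b_min, b_max)
}

#' Exhaustive grid-search oracle for the D-optimal design
#'
#' Enumerates every multiset of `N` b-values drawn from a uniform grid of
#' `grid_points` points on `[b_min, b_max]` and returns the one maximizing
#' `det(M)`. Intended as an independent certificate of the closed-form rule
#' on small instances, not as a production design generator. Ties are broken
#' by the lexicographically smallest sorted multiset, so results are
#' deterministic.
#'
#' @inheritParams design_dopt
#' @param grid_points number of grid points (>= 2). The number of multisets,
#'   `choose(grid_points + N - 1, N)`, must not exceed 1e7.
#' @return An [acq_design()] (b-values nondecreasing).
#' @export
design_grid_search <- function(N, b_min, b_max, grid_points = 21) {
  .check_Nrange(N, b_min, b_max)
  stopifnot(grid_points >= 2)
  if (choose(grid_points + N - 1, N) > 1e7) {
    stop("grid too large: choose(", grid_points + N - 1, ", ", N,
         ") multisets exceeds the 1e7 enumeration guard")
  }
  grid <- seq(b_min, b_max, length.out = grid_points)
  idx <- .multisets(grid_points, N)           # rows nondecreasing, lex order
  B <- matrix(grid[idx], nrow = nrow(idx))
  s1 <- rowSums(B)
  s2 <- rowSums(B^2)
  det_all <- N * s2 - s1^2
  best <- which.max(det_all)                  # first max = lex-smallest tie
  acq_design(B[best, ], b_min, b_max)
}

# All nondecreasing index tuples of length N over 1..G, in lexicographic
# order (combinations with repetition).
.multisets <- function(G, N) {
  cmb <- utils::combn(G + N - 1, N)           # strictly increasing tuples
  t(cmb - (seq_len(N) - 1L))                  # shift back to nondecreasing
}

.check_Nrange <- function(N, b_min, b_max) {
  if (length(N) != 1L || N < 2 || N != round(N)) {
    stop("N must be a single integer >= 2, got ", N)
  }
  if (!(b_min < b_max)) {
    stop("need b_min < b_max, got [", b_min, ", ", b_max, "]")
  }
  invisible(TRUE)
}

#' Resolve a design-method name to a design
#'
#' Maps the method names used by the sweep/comparison engines and the
#' command line (`"dopt"`, `"ed"`, `"gcrlb"`) to concrete designs under
#' shared `(N, b_min, b_max)`.
#'
#' @inheritParams design_dopt
#' @param method one of `"dopt"`, `"ed"`, `"gcrlb"`.
#' @return An [acq_design()].
#' @export
resolve_design <- function(method, N, b_min, b_max) {
  switch(match.arg(method, c("dopt", "ed", "gcrlb")),
    dopt  = design_dopt(N, b_min, b_max),
    ed    = design_equidistant(N, b_min, b_max),
    gcrlb = design_gcrlb(N, b_max)
  )
}
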