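---
title: "D-optimal b-value selection and its Monte Carlo evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{D-optimal b-value selection and its Monte Carlo evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcdesign)
```

## The model and the design problem

ADC imaging fits the monoexponential decay $m = m_0 e^{-bD}$ to signals
acquired at a handful of diffusion weightings $b$ (s/mm²). The standard
computationally cheap estimator takes logs, $y_i = \ln m_i$, and solves
the linear model $y = A x$ with $x = (\ln m_0, D)$ and design-matrix rows
$(1, -b_i)$ by least squares. If the noise on $y$ is independent,
zero-mean and of constant variance $\sigma^2$, the estimator is unbiased
with covariance $\sigma^2 M^{-1}$, $M = A^\top A$.

Experiment design asks where to put the $b_i$ inside the feasible range
$[b_{\min}, b_{\max}]$ (bounded below by perfusion contamination and above
by SNR decay and non-Gaussian diffusion). The D-optimality criterion
maximizes

$$\det M = N \sum_i b_i^2 - \Big(\sum_i b_i\Big)^2,$$

which depends only on the spread of the b-values — it is invariant under a
common shift and scales as $c^2$ under $b \to c\,b$. The maximizer over
the box is the two-level endpoint design: $n$ measurements at $b_{\min}$
and $N - n$ at $b_{\max}$, with $n = N/2$ (even $N$) or $(N+1)/2$ (odd
$N$). Because the criterion involves no model parameters, the same design
is optimal for every tissue — the practical advantage over designs that
minimize the Gaussian-noise Cramér–Rao bound of $D$, which move with the
assumed diffusivity.

For odd $N$ the mirrored split (majority at $b_{\max}$) attains the same
determinant. `design_dopt()` canonically puts the extra measurement at
$b_{\min}$, where the signal — and therefore the SNR of a magnitude
measurement — is highest; the mirrored variant is available via
`majority = "bmax"`. The certification oracle `design_grid_search()`
breaks such ties by the lexicographically smallest sorted multiset, purely
so that its output is deterministic.

## Noise: what is assumed and what is simulated

The magnitude of a single-coil MRI signal with independent Gaussian noise
of standard deviation $\sigma_G$ on the real and imaginary channels is
Rician. Throughout the package SNR means $m_0 / \sigma_G$. The log-linear
theory above assumes zero-mean, equal-variance noise on $\ln m$, which the
Rician channel satisfies only approximately. `log_noise_moments()` and
`noise_diagnostics()` quantify the approximation: the mean log-offset
$E[\ln|m + w|] - \ln m$ is negligible already at moderate SNR (at
$n_{\mathrm{mc}} = 20000$ it is indistinguishable from zero for
SNR $\geq 5$ — it sits below the Monte Carlo noise floor, which is why the
package's monotonicity checks on it carry a 3-standard-error slack), while
the variance of $\ln|m+w|$ approaches its delta-method limit
$\sigma_G^2/m^2$ from above, with the gap essentially closed by SNR 10–20.
Both assumptions therefore degrade exactly where the design problem is
hardest: high $b$, high $D$, low signal.

Two noise families are exposed via `noise_spec()`:

- `"rician"` — the realistic channel used for all headline experiments;
- `"gaussian-log"` — additive i.i.d. Gaussian noise directly on $\ln m$.
  Under this channel the covariance formula $\sigma^2 M^{-1}$ is *exact*,
  so it serves as the closed-form oracle against which the Monte Carlo
  engine is validated (bias of $(\ln \hat m_0, \hat D)$ within Monte Carlo
  error of zero; `std_D` within 5% of the closed form at
  $n_{\mathrm{mc}} = 20000$). Note the exactness is on the
  $(\ln m_0, D)$ scale: $\hat m_0 = e^{\hat x_1}$ carries a small
  convexity bias even under ideal noise, which is why `evaluate_design()`
  reports `bias_lnm0`/`std_lnm0` alongside the natural-scale moments.

Noncentral-$\chi$ noise from multi-coil phased arrays is out of scope; the
design problem under it is not tractable in this framework.

## Estimation choices

`fit_loglinear()` solves the normal equations through a QR factorization
of $A$ (never forming $(A^\top A)^{-1}$), recovers noise-free inputs
exactly, and reads $\hat D$ directly as the second coefficient — the sign
convention lives in the design matrix. Nonpositive measurements abort the
fit naming the offending index: a Rician magnitude is positive with
probability one, so a nonpositive value signals a broken pipeline, not an
unlucky draw. A `clip_floor` escape hatch exists for exploratory use on
other data and is off by default. Degenerate designs (all b-values equal,
singular $M$) are representable but every consumer that needs
invertibility raises an error rather than silently regularizing.

## The Monte Carlo engine

`evaluate_design()` implements the evaluation loop: simulate noisy
measurements at the design's b-values, fit, accumulate. Bias is
$E[\hat D] - D$ and $E[\hat m_0] - m_0$; spread is the empirical standard
deviation; both come with Monte Carlo standard errors
($\mathrm{sd}/\sqrt{n_{\mathrm{mc}}}$) so that design differences can be
judged against simulation noise. All trials are drawn vectorized from one
seeded stream — determinism is per `(inputs, seed)`, and seeded calls
restore the caller's RNG state. `compare_designs()` reuses identical
standard-normal draws across methods (common random numbers), so observed
contrasts reflect the designs alone; `design_sweep()` does the same within
each swept value, which also makes the D-optimal and equidistant rows
*identical* at $N = 2$, where the two designs coincide.

Default $n_{\mathrm{mc}} = 20000$ trials, matching the full-scale
experiments; the headline checks in the test suite run at this size, while
unit tests use a few hundred to a few thousand trials. The pixelwise
phantom tests use maps of 16–24 pixels a side with 2000 trials per
intensity level; full-scale map runs (64×64, 20000 trials) are a
command-line call away.

Failed trials (any nonpositive simulated magnitude) are counted in
`n_failed`; under Rician noise the engine treats any such trial as an
internal error and aborts, because it cannot occur with correct inputs.

## Reference and numeric CRLB designs

The tabulated `design_gcrlb()` two-point $\{0, 820\}$ and ten-point
$\{0, 0, 700\times 6, b_{\max}\times 2\}$ designs are transcribed
reference values from prior work on Gaussian-CRLB-optimal ADC designs for
$D \in [0.1, 3]\times 10^{-3}$ mm²/s; this package did not derive them,
and the interior value 700 is held fixed for every $b_{\max}$ since no
dependence is documented. For other settings `design_crlb_numeric()`
minimizes a standard Gaussian-noise Cramér–Rao bound of $\hat D$ for the
two-parameter nonlinear model (Fisher information from the signal
gradient $(e^{-bD}, -m_0 b\, e^{-bD})$), defined by this package as a
comparison tool. Numerically it minimizes the *logarithm* of the bound
with L-BFGS-B under box constraints, with `parscale` set to the b-range —
the raw bound spans many orders of magnitude over the box and defeats the
optimizer's default stopping rules — from the D-optimal and equidistant
starts plus random restarts. Its minimizer moves with $D$ (characteristic
spacing $\propto 1/D$, collapsing to the boundary on short b-ranges),
which is precisely the behavior the D-optimal design avoids.

## The phantom experiment

`make_phantom()` builds a deterministic 2-D intensity map (piecewise
blocks, a quantized gradient, or concentric rings; integer levels in the
8-bit range; a zero background frame) and `pixelwise_eval()` runs the
engine with the pixel intensity as true $m_0$ at fixed per-channel
$\sigma_G$ (default 5, i.e. SNR $= I(i,j)/5$ varies across the image),
$N = 20$ measurements on $[0, 2000]$, $D = 10^{-3}$ mm²/s. Zero-intensity
pixels are masked rather than fitted ($\ln 0$ is undefined). Each distinct
intensity level gets the seed substream `seed + level`, so results depend
only on (intensity, seed) — equal pixels give equal results, and a
constant map reproduces a scalar `evaluate_design()` call exactly.

The phantom emulates one thing only: the dependence of estimation error
on the local signal level under a spatially constant noise floor. It has
no anatomy, no spatial noise correlation, no partial-volume mixing, no
perfusion (IVIM) or kurtosis component, and single-coil Rician noise
only — passing its tests says nothing about those effects in real data.

## Parameter defaults

| parameter | default | units | why |
|---|---|---|---|
| `b_min`, `b_max` | 0, 2000 | s/mm² | brain-imaging range; the literature also uses 700 (kidney) and 1500 (head/neck), both covered by the `b_max` sweep |
| `m0` | 500 | intensity | conventional amplitude for simulated single-coil data |
| `D` | 1e-3 | mm²/s | mid-range human-brain diffusivity |
| SNR | 10 | — | regime where the log-noise assumptions hold yet Rician effects are visible |
| `n_mc` | 20000 | trials | Monte Carlo SE of a bias estimate ≈ 0.7% of the corresponding sd |

Where experiment descriptions state both 2000 and 1500 for `b_max`, the
package defaults to 2000 and leaves `b_max` a plain argument everywhere.

## Known limitations

- The headline negative result is real and reproducible: at SNR 10 with
  the optimal ten-point design, the relative error of the mean ADC
  estimate exceeds 10% for $D$ above about $1.1\times10^{-3}$ mm²/s —
  high diffusivities (e.g. kidney) cannot be estimated accurately by
  log-linear LSE at this SNR regardless of design.
- Only the log-linear LSE is implemented; median, ML and weighted LS
  estimators would change the optimal-design problem itself.
- Multi-exponential, IVIM and kurtosis signal models are out of scope, as
  are multi-coil noncentral-$\chi$ noise and spatially correlated noise.
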