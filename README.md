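# adcdesign

Choosing b-values for apparent diffusion coefficient (ADC) imaging — and,
more generally, sampling points for any monoexponential model fit.

## The problem

A diffusion-weighted MRI signal follows the monoexponential model

    m = m0 · exp(−b D)

where `b` (s/mm²) is the diffusion weighting set by the pulse sequence,
`m0` the unweighted signal amplitude, and `D` (mm²/s) the apparent
diffusion coefficient. Given a scan-time budget of `N` measurements and a
feasible range `b_min ≤ b ≤ b_max`, which b-values should be acquired so
that the log-linear least-squares estimate of `(m0, D)` is as precise as
possible?

Taking logs gives a linear model `y = A x` with `y_i = ln m_i`,
`x = (ln m0, D)` and design matrix rows `(1, −b_i)`. Under i.i.d. zero-mean
noise on `y` the least-squares estimator has covariance `σ² M⁻¹` with
information matrix `M = AᵀA`, and

    det(M) = N Σ b_i² − (Σ b_i)².

The D-optimal design maximizes `det(M)`. The solution has a closed form:
put `n` measurements at `b_min` and `N − n` at `b_max`, with `n = N/2` for
even `N` and `n = (N+1)/2` for odd `N`. Notably it does not depend on the
imaged parameters — unlike designs that minimize the Gaussian-noise
Cramér–Rao bound of `D`, which must be re-derived per tissue type.

The package provides:

- design generators: closed-form D-optimal, equidistant (`ED`), tabulated
  Gaussian-CRLB reference designs, a numeric Gaussian-CRLB minimizer, and
  an exhaustive grid-search oracle that certifies the closed form on small
  instances;
- Rician magnitude-noise simulation and log-domain noise diagnostics
  (when do the zero-mean / equal-variance assumptions on `ln m` hold?);
- log-linear least-squares fitting;
- a Monte Carlo engine measuring bias and standard deviation of the
  estimates for any design, with sensitivity sweeps over `D`, `N`,
  `b_max` and SNR, and common-random-number design comparisons;
- a synthetic intensity phantom for pixelwise design comparison maps;
- a command-line interface (`inst/cli/adcdesign.R`).

## Worked example

Compare the D-optimal and equidistant ten-point designs on `[0, 2000]`
s/mm² at `m0 = 500`, `D = 1e-3` mm²/s, SNR 10 (Rician noise, `σ_G = 50`),
sharing noise draws across the two designs:

```r
library(adcdesign)

design_dopt(10, 0, 2000)
#> Acquisition design (N = 10, b in [0, 2000] s/mm^2)
#>   b: 0, 0, 0, 0, 0, 2000, 2000, 2000, 2000, 2000

cmp <- compare_designs(c("dopt", "ed"), adc_params(500, 1e-3),
                       noise_spec("rician", 50), N = 10, b_min = 0,
                       b_max = 2000, n_mc = 20000, seed = 1)
cmp[, c("method", "bias_D", "std_D", "bias_m0", "std_m0")]
#>   method    bias_D    std_D bias_m0 std_m0
#> 1   dopt -6.40e-05 0.000135   0.369   22.6
#> 2     ed -4.32e-05 0.000200  -7.327   67.0
```

The D-optimal design estimates `D` with a ~33% smaller standard deviation
than the equidistant design, and `m0` with a third of the spread and an
order of magnitude less bias — the noise draws are identical, so the
difference is purely the placement of the b-values. The same engine
reproduces the accuracy limit of ADC imaging: even with the optimal
design, the relative error of the mean `D` estimate exceeds 10% once
`D > 1.1e-3` mm²/s at SNR 10 (see below).

Command line:

```sh
Rscript inst/cli/adcdesign.R design --method dopt --n 3 --bmin 0 --bmax 2000
# 0,0,2000
Rscript inst/cli/adcdesign.R sweep --variable D --values 0.5e-3,1e-3,2e-3 \
    --methods dopt,ed --nmc 20000 --seed 1 --out sweep.csv
```

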