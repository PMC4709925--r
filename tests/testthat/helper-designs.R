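# Random feasible, nondegenerate designs for property tests.
random_design <- function(N = sample(2:12, 1), b_min = 0, b_max = 2000) {
  repeat {
    b <- round(runif(N, b_min, b_max), 3)
    if (length(unique(b)) >= 2) break
  }
  acq_design(b, b_min, b_max)
}
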