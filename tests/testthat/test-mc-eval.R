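test_that("zero noise gives zero bias and zero spread", {
  r <- evaluate_design(design_dopt(4, 0, 2000), adc_params(500, 1e-3),
                       noise_spec("rician", 0), n_mc = 50, seed = 1)
  expect_equal(r$bias_D, 0)
  expect_equal(r$std_D, 0)
  expect_equal(r$bias_m0, 0, tolerance = 1e-10)
  expect_equal(r$std_m0, 0, tolerance = 1e-10)
  expect_equal(r$n_failed, 0L)
})

test_that("Gaussian-log channel reproduces the closed-form LSE covariance", {
  sigma <- 0.1
  for (b in list(c(0, 2000), design_dopt(10, 0, 2000)$b,
                 design_equidistant(6, 0, 1500)$b)) {
    d <- acq_design(b)
    r <- evaluate_design(d, adc_params(500, 1e-3),
                         noise_spec("gaussian-log", sigma),
                         n_mc = 20000, seed = 314)
    V <- lse_covariance(d, sigma)
    expect_lt(abs(r$std_D - sqrt(V[2, 2])), 0.05 * sqrt(V[2, 2]))
    expect_lt(abs(r$std_lnm0 - sqrt(V[1, 1])), 0.05 * sqrt(V[1, 1]))
    # unbiased in (ln m0, D)
    expect_lt(abs(r$bias_D), 3 * r$mc_se_D)
    expect_lt(abs(r$bias_lnm0), 3 * r$std_lnm0 / sqrt(r$n_mc))
  }
})

test_that("Gaussian-log precision of D is independent of the true D", {
  d <- design_dopt(10, 0, 2000)
  stds <- vapply(c(0.3e-3, 1e-3, 3e-3), function(D) {
    evaluate_design(d, adc_params(500, D), noise_spec("gaussian-log", 0.1),
                    n_mc = 20000, seed = 99)$std_D
  }, 0)
  se <- stds[1] * sqrt(2 / 20000)
  expect_true(all(abs(stds - stds[1]) < 6 * se))
})

test_that("Rician bias vanishes in the high-SNR, low-attenuation regime", {
  # SNR 100 and b_max * D = 0.5: Gaussian-approximation regime
  r <- evaluate_design(design_dopt(10, 0, 500), adc_params(500, 1e-3),
                       noise_spec("rician", 5), n_mc = 20000, seed = 4)
  expect_lt(abs(r$bias_D) / 1e-3, 0.01)
})

test_that("MC standard error fields follow std / sqrt(n)", {
  r <- evaluate_design(c(0, 1000, 2000), adc_params(500, 1e-3),
                       noise_spec("rician", 50), n_mc = 500, seed = 2)
  expect_equal(r$mc_se_D, r$std_D / sqrt(500))
  expect_equal(r$mc_se_m0, r$std_m0 / sqrt(500))
  expect_equal(r$n_mc, 500)
})

test_that("degenerate designs are rejected before simulation", {
  expect_error(
    evaluate_design(acq_design(rep(1000, 4)), adc_params(500, 1e-3),
                    noise_spec("rician", 50), n_mc = 10),
    "degenerate"
  )
})

test_that("evaluation is reproducible given the seed", {
  args <- list(design_dopt(6, 0, 2000), adc_params(500, 1e-3),
               noise_spec("rician", 50))
  r1 <- do.call(evaluate_design, c(args, n_mc = 1000, seed = 7))
  r2 <- do.call(evaluate_design, c(args, n_mc = 1000, seed = 7))
  expect_identical(r1, r2)
})

test_that("compare_designs shares noise draws across methods", {
  cmp <- compare_designs(c("dopt", "dopt"), adc_params(500, 1e-3),
                         noise_spec("rician", 50), N = 10,
                         n_mc = 500, seed = 5)
  expect_identical(cmp$std_D[1], cmp$std_D[2])
  expect_identical(cmp$bias_m0[1], cmp$bias_m0[2])
})

test_that("GCRLB reference underestimates m0 at high diffusivity", {
  cmp <- compare_designs(c("dopt", "gcrlb"), adc_params(500, 3e-3),
                         noise_spec("rician", 50), N = 10, b_min = 0,
                         b_max = 2000, n_mc = 20000, seed = 10)
  b_gcrlb <- cmp[cmp$method == "gcrlb", ]
  b_dopt <- cmp[cmp$method == "dopt", ]
  expect_lt(b_gcrlb$bias_m0, 0)
  expect_gt(abs(b_gcrlb$bias_m0), abs(b_dopt$bias_m0))
})

test_that("two-point comparison: endpoint design beats the 820 reference", {
  cmp <- compare_designs(c("dopt", "gcrlb"), adc_params(500, 0.3e-3),
                         noise_spec("rician", 50), N = 2, b_min = 0,
                         b_max = 2000, n_mc = 20000, seed = 11)
  expect_lt(cmp$std_D[cmp$method == "dopt"],
            cmp$std_D[cmp$method == "gcrlb"])
})

test_that("sweep rows carry full context and collapse to evaluate_design", {
  tab <- design_sweep("D", 1.5e-3, methods = "dopt", n_mc = 400, seed = 3)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("variable", "value", "method", "m0", "D", "N",
                    "b_min", "b_max", "snr", "seed", "bias_D", "std_D",
                    "n_failed") %in% names(tab)))
  direct <- evaluate_design(design_dopt(10, 0, 2000),
                            adc_params(500, 1.5e-3),
                            noise_spec("rician", 50), n_mc = 400,
                            seed = 3)
  expect_equal(tab$std_D, direct$std_D)
  expect_equal(tab$bias_D, direct$bias_D)
})

test_that("N sweep: methods coincide at N = 2 and precision grows with N", {
  tab <- design_sweep("N", c(2, 6, 12, 20), methods = c("dopt", "ed"),
                      n_mc = 4000, seed = 13)
  at2 <- tab[tab$value == 2, ]
  expect_identical(at2$std_D[1], at2$std_D[2])
  dopt <- tab[tab$method == "dopt", ]
  expect_true(all(diff(dopt$std_D) < 0))
})

test_that("b_max and SNR sweeps regenerate designs per value", {
  tab <- design_sweep("b_max", c(1000, 2000), methods = "dopt",
                      n_mc = 2000, seed = 14)
  # larger b-range -> tighter D estimate
  expect_lt(tab$std_D[tab$value == 2000], tab$std_D[tab$value == 1000])
  tab2 <- design_sweep("SNR", c(5, 20), methods = "dopt", n_mc = 2000,
                       seed = 15)
  expect_lt(tab2$std_D[tab2$value == 20], tab2$std_D[tab2$value == 5])
})
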