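test_that("engineering stress is force over initial cross-section", {
  smp <- tensile_sample(length_mm = 20, width_mm = 5, thickness_mm = 0.55)
  expect_equal(smp$A0, 2.75)
  rec <- tibble::tibble(time_s = 0:2, force_N = c(0, 1, 2), length_mm = c(20, 20.5, 21))
  out <- compute_stress(rec, smp)
  expect_equal(out$stress_MPa, c(0, 1 / 2.75, 2 / 2.75))
  # linearity: doubling the force doubles the stress
  out2 <- compute_stress(dplyr::mutate(rec, force_N = 2 * force_N), smp)
  expect_equal(out2$stress_MPa, 2 * out$stress_MPa)
  expect_error(
    compute_stress(rec, structure(list(A0 = 0, L0 = 20), class = "tensile_sample")),
    class = "onlens_invalid_sample"
  )
  expect_error(tensile_sample(width_mm = -1), class = "onlens_invalid_sample")
})

test_that("engineering strain is the relative length change", {
  smp <- tensile_sample(length_mm = 20)
  rec <- tibble::tibble(time_s = 0:2, force_N = 0, length_mm = c(20, 21, 22))
  out <- compute_strain(rec, smp)
  expect_equal(out$strain, c(0, 0.05, 0.10))
})

test_that("the 10 percent-per-minute loading maps strain to time as t * 0.1/60", {
  rec <- synth_tensile("H77p0", n_points = 50, strain_max = 0.1)
  smp <- tensile_sample()
  strain <- compute_strain(rec, smp)$strain
  expect_equal(strain, rec$time_s * 0.1 / 60, tolerance = 1e-12)
})

test_that("fit_modulus recovers an exact linear law with zero standard error", {
  curve <- tibble::tibble(strain = seq(0, 0.1, length.out = 20), stress_MPa = 0.3 * strain)
  fit <- fit_modulus(curve)
  expect_equal(fit$modulus, 0.3, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-14)
  # invariant to uniform subsampling of a noise-free line
  fit2 <- fit_modulus(curve[seq(1, 20, by = 3), ])
  expect_equal(fit2$modulus, fit$modulus, tolerance = 1e-12)
  expect_error(
    fit_modulus(tibble::tibble(strain = c(0.1, 0.1), stress_MPa = c(1, 2))),
    class = "onlens_fit_error"
  )
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_modulus(tibble::tibble(
    strain = seq(0, 0.1, length.out = 30),
    stress_MPa = 0.2 * seq(0, 0.1, length.out = 30) + 0.001
  ))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept_MPa", "modulus_MPa"))
  expect_equal(td$estimate[2], fit$modulus)
  gl <- glance(fit)
  expect_equal(gl$modulus_MPa, fit$modulus)
  expect_equal(gl$n, 30)
})

test_that("noise-free synthetic records recover each stored modulus through the full pipeline", {
  for (m in hydrogel_materials()$material) {
    stored <- get_material(m)$modulus
    rec <- synth_tensile(m, n_points = 120)
    fit <- modulus_from_records(rec, tensile_sample())
    expect_equal(fit$modulus, stored, tolerance = 1e-10)
    expect_lt(abs(fit$intercept), 1e-12)
  }
})

test_that("synthetic records are reproducible under a fixed seed", {
  a <- synth_tensile("H77p0", noise_sd = 0.01, seed = 7)
  b <- synth_tensile("H77p0", noise_sd = 0.01, seed = 7)
  expect_identical(a, b)
  c <- synth_tensile("H77p0", noise_sd = 0.01, seed = 8)
  expect_false(identical(a, c))
  expect_error(synth_tensile("H77p0", noise_sd = -1))
})

test_that("tensile records round-trip through CSV", {
  rec <- synth_tensile("H64p0", n_points = 25, noise_sd = 0.005, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_tensile_csv(rec, f)
  back <- read_tensile_csv(f)
  expect_equal(back$force_N, rec$force_N, tolerance = 1e-9)
  expect_equal(names(back), c("time_s", "force_N", "length_mm"))
})

test_that("averaging per-strip fits matches the mean-and-spread presentation", {
  fits <- lapply(c(0.19, 0.20, 0.21), function(E) {
    fit_modulus(tibble::tibble(strain = seq(0, 0.1, length.out = 10), stress_MPa = E * seq(0, 0.1, length.out = 10)))
  })
  avg <- average_modulus(fits)
  expect_equal(avg$modulus_MPa, 0.2, tolerance = 1e-10)
  expect_equal(avg$sd_MPa, sd(c(0.19, 0.20, 0.21)), tolerance = 1e-10)
  expect_equal(avg$n_samples, 3)
})

test_that("noisy recovery is unbiased and the fitted SE calibrates the error", {
  # Monte-Carlo over 500 seeds at the stated noise model
  smp <- tensile_sample()
  E <- get_material("H77p0")$modulus
  n <- 200
  noise_sd <- 0.01
  res <- vapply(1:500, function(s) {
    rec <- synth_tensile("H77p0", smp, n_points = n, noise_sd = noise_sd, seed = s)
    fit <- modulus_from_records(rec, smp)
    c(err = fit$modulus - E, se = fit$se)
  }, numeric(2))
  err <- res[1, ]
  covered <- abs(err) <= 3 * res[2, ]
  expect_gte(mean(covered), 0.99)
  # no systematic bias: mean error is at the Monte-Carlo noise floor
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
  # error spread is on the scale the fitted SE predicts
  expect_lt(sd(err), 2 * mean(res[2, ]))
  expect_gt(sd(err), mean(res[2, ]) / 2)
})
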