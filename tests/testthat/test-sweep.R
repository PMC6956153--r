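small_config <- function(...) {
  sweep_config(
    materials = c("H77p0-Clear", "H64p0-Clear"),
    types = "spherical", powers = c(-2, 0, 2), diameters = 14,
    n_meridians = 48, n_radial = 61, n_rings = 4, ...
  )
}

test_that("a smoke sweep yields one record per grid cell with acceptability flags", {
  tb <- run_sweep(small_config())
  expect_s3_class(tb, "epc_table")
  expect_equal(nrow(tb), 2 * 3)
  expect_true(all(!is.na(tb$epc_D)))
  expect_true(all(tb$within_acceptable == (abs(tb$epc_D) <= 0.25)))
})

test_that("a rigid material override gives exactly zero EPC", {
  cfg <- small_config()
  for (P in c(-2, 2)) {
    r <- simulate_epc(rigid_material(), P, "spherical", config = cfg)
    expect_equal(r$epc_D, 0, tolerance = 1e-12)
    expect_equal(r$w, 1)
  }
})

test_that("region split partitions at 5 D with the boundary in the upper region", {
  tb <- tibble::tibble(power = seq(-10, 20, 1), epc_D = 0)
  parts <- region_split(tb)
  expect_equal(nrow(parts$lower), 15) # -10 .. 4
  expect_equal(nrow(parts$upper), 16) # 5 .. 20
  expect_true(all(parts$upper$power >= 5))
  expect_equal(nrow(parts$lower) + nrow(parts$upper), nrow(tb))
  # empty regions are allowed for truncated grids
  hi <- region_split(dplyr::filter(tb, power >= 10))
  expect_equal(nrow(hi$lower), 0)
})

test_that("the pooled t-test matches hand arithmetic and stats::t.test", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  tb <- tibble::tibble(
    material = rep(c("A", "B"), each = 4), type = "spherical",
    diameter = 14, power = rep(1:4, 2), epc_D = c(x, y)
  )
  out <- pairwise_ttests(tb)
  # hand-computed pooled t: sp2 = 5/3, se = sqrt(sp2/2), t = -1/se
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(t_hand, -1.095445, tolerance = 1e-6)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-12)
  expect_false(out$significant)
})

test_that("degenerate and identical samples follow the stated limits", {
  tb <- tibble::tibble(
    material = rep(c("A", "B"), each = 3), type = "spherical",
    diameter = 14, power = rep(1:3, 2), epc_D = c(1, 2, 3, 1, 2, 3)
  )
  out <- pairwise_ttests(tb)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  # identical constants: degenerate, flagged, p = 1
  tbc <- dplyr::mutate(tb, epc_D = 0.1)
  outc <- pairwise_ttests(tbc)
  expect_equal(outc$p_value, 1)
  expect_true(outc$degenerate)
  # separated constants: p -> 0
  tbs <- dplyr::mutate(tb, epc_D = ifelse(material == "A", 0, 1))
  expect_equal(pairwise_ttests(tbs)$p_value, 0)
})

test_that("Pearson correlations match hand sums and handle degeneracy as missing", {
  tb <- tibble::tibble(
    material = "A", type = "spherical", diameter = 14,
    power = c(0, 1, 2, 3), epc_D = c(0, -1, -2, -2.9)
  )
  out <- correlations(tb)
  # hand Pearson: r = S_xy / sqrt(S_xx S_yy)
  x <- tb$power; y <- tb$epc_D
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_lt(out$r, -0.999)
  # perfect line
  tb2 <- dplyr::mutate(tb, epc_D = -power)
  expect_equal(correlations(tb2)$r, -1)
  # constant EPC: missing, not zero
  tb3 <- dplyr::mutate(tb, epc_D = 0.1)
  expect_true(is.na(correlations(tb3)$r))
})

test_that("the acceptability rule is boundary-inclusive at 0.25 D", {
  tb <- tibble::tibble(epc_D = c(-0.25, -0.26, 0, 0.25, 0.2501))
  out <- acceptability(tb)
  expect_equal(out$within_acceptable, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("the largest contiguous acceptable interval is located per material", {
  tb <- tibble::tibble(
    material = "A", type = "spherical", diameter = 14,
    power = -2:4, epc_D = c(0.1, 0.3, 0.1, 0.2, 0.1, 0.3, 0.1)
  )
  out <- acceptable_range(acceptability(tb))
  expect_equal(out$power_from, 0)
  expect_equal(out$power_to, 2)
  expect_equal(out$n_powers, 3L)
})

test_that("report writes the CSVs and plot deterministically", {
  tb <- run_sweep(small_config())
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  f1 <- report(tb, d1, config = small_config())
  f2 <- report(tb, d2, config = small_config())
  expect_true(all(file.exists(file.path(d1, c("epc.csv", "ttests.csv", "correlations.csv")))))
  expect_gte(sum(grepl("\\.png$", f1)), 1)
  for (nm in c("epc.csv", "ttests.csv", "correlations.csv")) {
    expect_identical(
      readLines(file.path(d1, nm)),
      readLines(file.path(d2, nm))
    )
  }
})

test_that("sweep configs round-trip through YAML", {
  cfg <- small_config()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(
    list(
      materials = cfg$materials, types = "spherical", powers = c(-2, 0, 2),
      diameters = 14, n_meridians = 48, n_radial = 61,
      loads = list(tear_pressure_Pa = 0.05, eyelid_pressure_mmHg = 7)
    ),
    f
  )
  back <- read_sweep_config(f)
  expect_s3_class(back, "sweep_config")
  expect_equal(back$loads$eyelid_pressure_Pa, 7 * 133.3224)
  expect_equal(back$powers, c(-2, 0, 2))
})

test_that("cell failures are recorded without aborting the sweep", {
  cfg <- small_config()
  cfg$materials <- c("H77p0-Clear")
  cfg$powers <- c(0, 1e6) # absurd power: lens maker denominator explodes downstream
  tb <- suppressWarnings(run_sweep(cfg))
  expect_equal(nrow(tb), 2)
  expect_true(any(!is.na(tb$error)) || all(!is.na(tb$epc_D)))
})
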