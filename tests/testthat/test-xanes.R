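# XANES: normalization, white line, LCF, grouping, line scans

make_raw_edge <- function(baseline_a = 0.002, baseline_b = -6, step = 3,
                          wl_amp = 2.4, wl_pos = 4048.6) {
  E <- seq(4020, 4120, by = 0.2)
  mu <- baseline_a * E + baseline_b +
    step * (0.5 + atan((E - 4046) / 1.6) / pi) +
    wl_amp * exp(-0.5 * ((E - wl_pos) / 1.8)^2)
  xanes_spectrum(E, mu)
}

test_that("normalization yields unit edge step and zero pre-edge", {
  spec <- normalize_xanes(make_raw_edge(), flatten = TRUE)
  E <- spec$energy_eV
  pre <- spec$intensity[E >= 4020 & E <= 4035]
  expect_lt(abs(mean(pre)), 1e-9)       # linear pre-edge removed exactly
  expect_lt(max(abs(pre)), 0.01)        # arctan tail curvature only
  post <- spec$intensity[E >= 4075 & E <= 4120]
  expect_lt(abs(mean(post) - 1), 0.02)
  expect_true(spec$normalized)
})

test_that("normalization is idempotent and affine-invariant", {
  raw <- make_raw_edge()
  n1 <- normalize_xanes(raw)
  n2 <- normalize_xanes(n1)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  aff <- xanes_spectrum(raw$energy_eV, 3.7 * raw$intensity - 11)
  expect_equal(normalize_xanes(aff)$intensity, n1$intensity,
               tolerance = 1e-9)
  expect_error(normalize_xanes(raw, pre_range = c(4020, 4050)), "overlap")
})

test_that("white-line position refines to sub-grid accuracy", {
  # pure Gaussian on a flat background at an off-grid centre
  E <- seq(4020, 4120, by = 0.2)
  e0 <- 4047.93
  spec <- xanes_spectrum(E, 0.2 + exp(-0.5 * ((E - e0) / 2)^2),
                         normalized = TRUE)
  expect_equal(as.numeric(white_line_position(spec)), e0, tolerance = 0.01)
  # plateau flagged
  flat <- xanes_spectrum(E, rep(1, length(E)), normalized = TRUE)
  wl <- white_line_position(flat)
  expect_equal(attr(wl, "flag"), "plateau")
})

test_that("generated references place the apatite and whitlockite white lines correctly", {
  refs <- xanes_references()
  step <- 0.2
  expect_equal(as.numeric(white_line_position(refs$HAP)), 4048.6,
               tolerance = step / 4048.6)
  expect_equal(as.numeric(white_line_position(refs$WHIT)), 4049.5,
               tolerance = step / 4049.5)
  # whitlockite lacks the ~4060 eV absorption enhancement of the apatites
  E <- refs$HAP$energy_eV
  win <- E > 4057 & E < 4064
  expect_gt(mean(refs$HAP$intensity[win]), mean(refs$WHIT$intensity[win]))
})

test_that("LCF is exact on noise-free mixtures across the weight simplex", {
  refs <- xanes_references()
  E <- refs$HAP$energy_eV
  R <- vapply(refs, function(r) r$intensity, numeric(length(E)))
  for (w_hap in seq(0, 1, by = 0.1)) {
    w <- c(HAP = w_hap, HAP_A = 0, HAP_B = 0, WHIT = 1 - w_hap,
           CALCITE = 0, ACC = 0)
    spec <- xanes_spectrum(E, as.numeric(R %*% w), normalized = TRUE)
    fit <- lcf_fit(spec, refs)
    expect_equal(unname(fit$weights), unname(w), tolerance = 1e-6)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(fit$weights >= 0))
  }
  # single reference -> weight one
  fit1 <- lcf_fit(refs$ACC, refs)
  expect_equal(unname(fit1$weights[["ACC"]]), 1, tolerance = 1e-6)
  expect_error(lcf_fit(refs$HAP, list()), "empty")
})

test_that("LCF weight recovery under noise is nearly unbiased", {
  refs <- xanes_references()
  E <- refs$HAP$energy_eV
  R <- vapply(refs, function(r) r$intensity, numeric(length(E)))
  w_true <- c(HAP = 0.4, HAP_A = 0, HAP_B = 0.1, WHIT = 0.3,
              CALCITE = 0, ACC = 0.2)
  mu0 <- as.numeric(R %*% w_true)
  set.seed(2024)
  est <- replicate(200, {
    spec <- xanes_spectrum(E, mu0 + stats::rnorm(length(E), 0, 0.05),
                           normalized = TRUE)
    fit <- lcf_fit(spec, refs)
    g <- fit$groups
    c(fit$weights, tot_HAP = g$tot_HAP, WHIT = unname(fit$weights["WHIT"]),
      carbonate = g$carbonate)
  })
  # the apatite-family references are nearly collinear (as for measured
  # references), so unbiased recovery is asserted on the grouped quantities
  g_true <- c(tot_HAP = 0.5, WHIT = 0.3, carbonate = 0.2)
  bias <- rowMeans(est[names(g_true), ]) - g_true
  expect_lt(max(abs(bias)), 0.03)
  rmse <- sqrt(rowMeans((est[names(refs), ] - w_true)^2))
  expect_lt(max(rmse), 0.3)
})

test_that("adding a reference never increases the LCF residual", {
  refs <- xanes_references()
  E <- refs$HAP$energy_eV
  R <- vapply(refs, function(r) r$intensity, numeric(length(E)))
  spec <- xanes_spectrum(E, as.numeric(R %*% rep(1 / 6, 6)) +
                           0.03 * sin(E / 3), normalized = TRUE)
  r3 <- lcf_fit(spec, refs[1:3], sum_to_one = FALSE)$residual
  r6 <- lcf_fit(spec, refs, sum_to_one = FALSE)$residual
  expect_lte(r6, r3 + 1e-9)
  # better than every single-reference fit
  singles <- vapply(seq_along(refs), function(i)
    lcf_fit(spec, refs[i], sum_to_one = FALSE)$residual, numeric(1))
  expect_lte(r6, min(singles) + 1e-9)
})

test_that("species grouping computes tot_HAP, WHIT share and carbonate", {
  w <- c(HAP = 0.2, HAP_A = 0.2, HAP_B = 0.1, WHIT = 0.5, CALCITE = 0, ACC = 0)
  g <- group_species(w)
  expect_equal(g$tot_HAP, 0.5)
  expect_equal(g$WHIT_share, 0.5)
  expect_equal(g$carbonate, 0)
  # all weight on ACC: carbonate 1, WHIT share undefined
  g2 <- group_species(c(HAP = 0, HAP_A = 0, HAP_B = 0, WHIT = 0,
                        CALCITE = 0, ACC = 1))
  expect_equal(g2$carbonate, 1)
  expect_true(is.na(g2$WHIT_share))
})

test_that("line scans filter on thickness and preserve per-position grouping", {
  refs <- xanes_references()
  E <- refs$HAP$energy_eV
  R <- vapply(refs, function(r) r$intensity, numeric(length(E)))
  mix <- function(w) xanes_spectrum(E, as.numeric(R %*% w), normalized = TRUE)
  w_core <- c(0.8, 0, 0, 0.1, 0, 0.1); w_rim <- c(0.2, 0, 0, 0.6, 0, 0.2)
  specs <- list(mix(w_core), mix(w_core), mix(w_rim), mix(w_rim))
  scan <- line_scan_lcf(specs, positions = 1:4, refs = refs,
                        t_eff = c(2, 2, 1, 0.3),
                        region = c("core", "core", "rim", "rim"))
  expect_equal(nrow(scan), 3)  # the 0.3 um position is filtered out
  expect_gt(scan$WHIT_share[3], scan$WHIT_share[1])
  # identical spectra -> constant fractions
  scan2 <- line_scan_lcf(list(mix(w_core), mix(w_core)), refs = refs)
  expect_equal(scan2$WHIT_share[1], scan2$WHIT_share[2], tolerance = 1e-9)
})
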