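# quantification: thickness maps, spectrum fits, binning, carbonate model

test_that("effective thickness inverts Beer-Lambert exactly", {
  det <- tiny_det()
  Tr <- matrix(c(1, exp(-1), 0.5, 1.02), 2, 2)
  cube <- spectrum_cube(array(0, c(2, 2, det$n_channels)), Tr, det = det,
                        E_in = 2.5)
  expect_warning(th <- effective_thickness_map(cube, "HAP"), "clipped")
  delta <- attenuation_length("HAP", 2.5)
  expect_equal(th[1, 1], 0)
  expect_equal(th[2, 1], delta, tolerance = 1e-12)
  expect_equal(th[1, 2], -log(0.5) * delta, tolerance = 1e-12)
  expect_equal(th[2, 2], 0)  # I > I0 clipped
  expect_equal(attr(th, "n_clipped"), 1L)
  # invalid transmission flagged as NA, never zero
  Tr2 <- matrix(c(0.5, 0, -0.1, 0.9), 2, 2)
  cube2 <- spectrum_cube(array(0, c(2, 2, det$n_channels)), Tr2, det = det,
                         E_in = 2.5)
  th2 <- effective_thickness_map(cube2, "HAP")
  expect_true(is.na(th2[2, 1]) && is.na(th2[1, 2]))
})

test_that("thickness round trip through the renderer recovers the scene to 1%", {
  sc <- tiny_scene("benign", seed = 5, n = 12)
  # single-matrix scene: exact inverse
  sc$regions$core$matrix_mix <- c(HAP_B = 1)
  sc$regions$rim$matrix_mix <- c(HAP_B = 1)
  sc$regions$periphery$matrix_mix <- c(HAP_B = 1)
  sc$paraffin_um <- 0
  det <- tiny_det()
  Tr <- render_transmission(sc, 2.5)
  cube <- spectrum_cube(array(0, c(12, 12, det$n_channels)), Tr, det = det,
                        E_in = 2.5)
  th <- effective_thickness_map(cube, "HAP_B")
  sel <- sc$thickness > 0
  expect_lt(max(abs(th[sel] / sc$thickness[sel] - 1)), 0.01)
})

test_that("fit recovers a simulated composition exactly (noise-free master oracle)", {
  det <- tiny_det()
  geom <- geometry_model()
  for (E_in in c(2.1, 2.5, 4.2)) for (t in c(0.7, 4)) {
    # Sr/Y are fitted only below the P edge; the admissible composition for
    # the identity check carries them only there
    traces <- if (E_in < 2.1455)
      c(Na = 0.008, Mg = 0.012, S = 0.004, Cl = 0.003, Sr = 2e-4, Y = 4e-4)
    else c(Na = 0.008, Mg = 0.012, S = 0.004, Cl = 0.003)
    m <- mc_matrices()$HAP_B
    ref <- if (E_in > 4.0381) "Ca" else if (E_in > 2.1455) "P" else "O"
    w_ref <- theoretical_mass_fraction(m, ref)$value
    # composition with the reference element pinned at its registry value
    comp <- comp_with_traces("HAP_B", traces)
    scale <- w_ref / comp[[ref]]
    comp[ref] <- w_ref
    others <- setdiff(names(comp), ref)
    comp[others] <- comp[others] * (1 - w_ref) / sum(comp[others])
    line_set <- if (E_in < 2.1455) c("O", "Na", "Mg", "Si", "Sr", "Y") else
      c("O", "Na", "Mg", "Si", "P", "S", "Cl", "Ca")
    sp <- simulate_spectrum(comp, t = t, matrix = m, E_in = E_in, det = det,
                            geom = geom, flux_time = 2e6, background = 0)
    fit <- fit_spectrum(sp, t = t, matrix = m, det = det, geom = geom,
                        line_set = line_set, bg_window = 0)
    # reference element equals the registry value bit-exactly
    expect_identical(fit$w[[ref]], w_ref)
    excitable <- names(fit$w)[names(fit$w) %in% names(comp)]
    for (el in excitable) {
      if (comp[[el]] < 1e-12) next
      expect_equal(fit$w[[el]], comp[[el]], tolerance = 1e-6)
    }
    expect_length(fit$flags, 0)
  }
})

test_that("degenerate spectra are flagged, not quantified", {
  det <- tiny_det()
  fit <- fit_spectrum(rep(0, det$n_channels), E_in = 2.5, t = 2,
                      matrix = "HAP_B", det = det)
  expect_true("unquantifiable" %in% fit$flags)
  expect_true(all(is.na(fit$w) | fit$w == 0))
})

test_that("Mg at the percent level survives Poisson noise within 20%", {
  det <- tiny_det()
  m <- mc_matrices()$HAP
  comp <- m$composition * 0.99
  comp["Mg"] <- 0.01
  errs <- vapply(1:5, function(s) {
    sp <- simulate_spectrum(comp, t = 4, matrix = m, E_in = 2.5, det = det,
                            flux_time = 1e8, background = 2,
                            poisson = TRUE, seed = 100 + s)
    fit <- fit_spectrum(sp, t = 4, matrix = m, det = det, bg_window = 0)
    fit$w[["Mg"]] / 0.01 - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.20)
})

test_that("omitting escape modelling biases P and S upward at 4.2 keV", {
  det <- tiny_det()
  m <- mc_matrices()$HAP_B
  sp <- simulate_spectrum(m$composition, t = 4, matrix = m, E_in = 4.2,
                          det = det, flux_time = 2e6, background = 0)
  with_esc <- fit_spectrum(sp, t = 4, matrix = m, det = det, bg_window = 0)
  no_esc <- fit_spectrum(sp, t = 4, matrix = m,
                         det = tiny_det(escape_fraction = 0), bg_window = 0)
  expect_gt(no_esc$w[["P"]], with_esc$w[["P"]])
  expect_gte(no_esc$w[["S"]], with_esc$w[["S"]])
  expect_gt(no_esc$w[["P"]], m$reference_fractions[["P"]])
})

test_that("cube fits are spatially uniform on a uniform phantom and masked below threshold", {
  det <- tiny_det()
  m <- mc_matrices()$HAP_B
  n <- 4
  comp <- m$composition * 0.99; comp["Mg"] <- 0.01
  counts <- array(0, c(n, n, det$n_channels))
  set.seed(7)
  mu <- simulate_spectrum(comp, t = 3, matrix = m, E_in = 2.5, det = det,
                          flux_time = 2e7, background = 0.5)$counts
  for (i in 1:n) for (j in 1:n)
    counts[i, j, ] <- stats::rpois(det$n_channels, mu)
  Tr <- matrix(exp(-3 / attenuation_length(m, 2.5)), n, n)
  cube <- spectrum_cube(counts, Tr, det = det, E_in = 2.5, live_time = 6)
  th <- effective_thickness_map(cube, m)
  maps <- fit_cube(cube, th, matrix = m)
  wmg <- maps$w$Mg
  expect_true(all(is.finite(wmg)))
  # scatter consistent with counting noise: weak Mg line ~10%, strong P tight
  expect_lt(stats::sd(wmg) / mean(wmg), 0.2)
  expect_lt(stats::sd(maps$w$O) / mean(maps$w$O), 0.1)
  expect_true(all(maps$intensity$P > 0))
  # all pixels below the contour -> fully masked output (NA, never zero)
  thin <- structure(matrix(0.2, n, n), class = c("thickness_map", "matrix"))
  maps2 <- fit_cube(cube, thin, matrix = m)
  expect_true(all(is.na(unlist(maps2$w))))
})

test_that("trace rescaling applies the printed formula and preserves ratios", {
  w21 <- list(Mg = matrix(0.02, 2, 2), Sr = matrix(0.002, 2, 2),
              Y = matrix(0.004, 2, 2))
  out <- rescale_trace_fractions(w21, matrix(0.01, 2, 2))
  expect_equal(out$Sr, matrix(0.001, 2, 2))
  expect_equal(out$Y / out$Sr, matrix(2, 2, 2))
  # identity when the Mg maps agree
  out2 <- rescale_trace_fractions(w21, w21$Mg)
  expect_equal(out2$Sr, w21$Sr)
  # masked where w_Mg(2.1) = 0
  w21$Mg[1, 1] <- 0
  out3 <- rescale_trace_fractions(w21, matrix(0.01, 2, 2))
  expect_true(is.na(out3$Sr[1, 1]))
})

test_that("thickness binning is flat for a homogeneous sample and exact for single-pixel bins", {
  det <- tiny_det()
  m <- mc_matrices()$HAP_B
  comp <- m$composition * 0.99; comp["Mg"] <- 0.01
  n <- 3
  counts <- array(0, c(n, n, det$n_channels))
  tvals <- matrix(seq(1, 5, length.out = n * n), n, n)
  for (i in 1:n) for (j in 1:n)
    counts[i, j, ] <- simulate_spectrum(comp, t = tvals[i, j], matrix = m,
                                        E_in = 2.5, det = det,
                                        flux_time = 2e6)$counts
  Tr <- exp(-tvals / attenuation_length(m, 2.5))
  cube <- spectrum_cube(counts, Tr, det = det, E_in = 2.5)
  th <- effective_thickness_map(cube, m)
  bins <- bin_by_thickness(cube, th, edges = c(0.5, 2, 3.5, 6), matrix = m,
                           bg_window = 0)
  expect_lt(diff(range(bins$w_Mg)), 0.05 * mean(bins$w_Mg))
  # one pixel per bin reproduces the per-pixel fit
  edges1 <- c(tvals[1, 1] - 0.01, tvals[1, 1] + 0.01)
  b1 <- bin_by_thickness(cube, th, edges = edges1, matrix = m, bg_window = 0)
  f1 <- fit_spectrum(counts[1, 1, ], E_in = 2.5, t = th[1, 1], matrix = m,
                     det = det, bg_window = 0)
  expect_equal(b1$w_Mg, f1$w[["Mg"]], tolerance = 1e-6)
  expect_equal(b1$n_pixels, 1L)
})

test_that("carbonate dilution model inverts the mixing fraction", {
  w_p_hap <- theoretical_mass_fraction("HAP", "P")$value
  # alpha = 0 everywhere: flat at the registry value
  b0 <- data.frame(t_mean = c(1, 2, 3, 4), w_P = rep(w_p_hap, 4))
  m0 <- carbonate_dilution_model(b0)
  expect_equal(m0$slope, 0, tolerance = 1e-12)
  expect_equal(m0$alpha$alpha, rep(0, 4), tolerance = 1e-12)
  # alpha = 0.5 halves the phosphorus fraction
  b5 <- data.frame(t_mean = c(1, 2, 3), w_P = rep(w_p_hap / 2, 3))
  expect_equal(carbonate_dilution_model(b5)$alpha$alpha, rep(0.5, 3),
               tolerance = 1e-12)
  # linear alpha(t) gradient: slope recovered within 5%
  tt <- seq(0.5, 4.5, length.out = 6)
  alpha_t <- 0.4 - 0.08 * tt
  bl <- data.frame(t_mean = tt, w_P = (1 - alpha_t) * w_p_hap)
  ml <- carbonate_dilution_model(bl)
  expect_equal(ml$slope, 0.08 * w_p_hap, tolerance = 0.05)
  expect_equal(ml$alpha$alpha, alpha_t, tolerance = 1e-9)
  expect_error(carbonate_dilution_model(b0[1:2, ]), "at least 3")
  expect_error(carbonate_dilution_model(
    data.frame(t_mean = rep(2, 4), w_P = rep(0.1, 4))), "degenerate")
})

test_that("carbonate dilution survives the full simulate/fit chain", {
  det <- tiny_det()
  hap <- mc_matrices()$HAP
  cal <- mc_matrices()$CALCITE
  # undiluted P level on the Ca-referenced scale of this chain
  w_p_hap <- hap$composition[["P"]] * 0.39 / hap$composition[["Ca"]]
  # linear dilution gradient alpha(t) = 0.45 - 0.1 t
  tt <- c(4, 3, 2, 1)
  alphas <- 0.45 - 0.1 * tt
  rows <- lapply(seq_along(alphas), function(k) {
    a <- alphas[k]
    comp <- hap$composition * (1 - a)
    for (el in names(cal$composition))
      comp[el] <- (if (is.na(comp[el])) 0 else comp[el]) +
        a * cal$composition[[el]]
    mmix <- matrix_model("mix", comp, (1 - a) * hap$density + a * cal$density)
    sp <- simulate_spectrum(comp, t = tt[k], matrix = mmix, E_in = 4.2,
                            det = det, flux_time = 2e6, background = 0)
    fit <- fit_spectrum(sp, t = tt[k], matrix = hap, det = det,
                        bg_window = 0, w_ref = 0.39)
    data.frame(t_mean = tt[k], w_P = fit$w[["P"]], alpha_true = a)
  })
  tab <- do.call(rbind, rows)
  cm <- carbonate_dilution_model(tab, w_p_hap = w_p_hap)
  # recovered slope within 5% of the generated dilution gradient
  expect_equal(cm$slope, 0.1 * w_p_hap, tolerance = 0.05)
  expect_lt(max(abs(cm$alpha$alpha - tab$alpha_true)), 0.05)
})
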