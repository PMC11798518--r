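# WAXS: peak positions, refinement, classification, collagen, integration

test_that("reflection positions follow the hexagonal closed form", {
  hap <- mc_phases()$HAP_HC
  pp <- phase_peak_positions(hap, q_max = 35)
  q002 <- pp$q_nm[pp$h == 0 & pp$k == 0 & pp$l == 2]
  expect_equal(q002, 4 * pi / (hap$c / 10), tolerance = 1e-12)
  q100 <- pp$q_nm[pp$h == 1 & pp$k == 0 & pp$l == 0]
  q200 <- pp$q_nm[pp$h == 2 & pp$k == 0 & pp$l == 0]
  expect_equal(q200, 2 * q100, tolerance = 1e-12)
  expect_true(all(diff(pp$q_nm) > 0))
  # positions strictly decrease when the cell grows
  big <- hap; big$a <- hap$a * 1.02; big$c <- hap$c * 1.02
  pb <- phase_peak_positions(big, q_max = 35)
  common <- merge(pp, pb, by = c("h", "k", "l"))
  expect_true(all(common$q_nm.y < common$q_nm.x))
})

test_that("rhombohedral reflection conditions hold for whitlockite", {
  whit <- mc_phases()$WHIT
  pp <- phase_peak_positions(whit, q_max = 20)
  has <- function(h, k, l) any(pp$h == h & pp$k == k & pp$l == l)
  expect_true(has(0, 0, 3))    # (003) allowed
  expect_false(has(0, 0, 1))   # (001) forbidden
  expect_false(has(0, 0, 2))   # (002) forbidden
  expect_true(has(1, 1, 0))    # (110) allowed
  expect_false(has(1, 0, 0))   # (100) forbidden
})

test_that("Scherrer width/domain conversion closes the round trip", {
  for (D in c(46, 96, 129, 244)) {
    b <- scherrer_width_q(D, K = 0.9)
    expect_equal(scherrer_domain(b, K = 0.9), D, tolerance = 1e-10)
  }
  # anisotropic model interpolates between the axial and equatorial sizes
  ph <- mc_phases()$HAP_HC
  expect_equal(domain_size_hkl(ph, 1), ph$domain_ax)
  expect_equal(domain_size_hkl(ph, 0), ph$domain_eq)
  mid <- domain_size_hkl(ph, sqrt(0.5))
  expect_true(mid > min(ph$domain_ax, ph$domain_eq) &&
                mid < max(ph$domain_ax, ph$domain_eq))
})

test_that("refinement recovers the generating apatite cell and domains", {
  ph <- mc_phases()$HAP_HC
  prof <- synth_profile(ph, q = seq(5, 35, by = 0.02), instr_fwhm = 0.05)
  start <- ph
  start$a <- ph$a * 1.01; start$c <- ph$c * 1.01
  start$domain_ax <- 200; start$domain_eq <- 100
  ref <- refine_profile(prof, start, instr_fwhm = 0.05)
  expect_true(ref$converged)
  got <- ref$phases[[1]]
  expect_equal(round(got$a, 4), 9.3897)
  expect_equal(round(got$c, 4), 6.8652)
  expect_lt(abs(got$domain_ax / 244 - 1), 0.02)
  expect_lt(abs(got$domain_eq / 129 - 1), 0.02)
})

test_that("refinement recovers the whitlockite cell under reflection conditions", {
  ph <- mc_phases()$WHIT
  prof <- synth_profile(ph, q = seq(5, 35, by = 0.02), instr_fwhm = 0.05)
  start <- ph
  start$a <- ph$a * 1.01; start$c <- ph$c * 1.01
  start$domain_ax <- 60; start$domain_eq <- 60
  ref <- refine_profile(prof, start, instr_fwhm = 0.05)
  got <- ref$phases[[1]]
  expect_equal(round(got$a, 4), 10.3211)
  expect_equal(round(got$c, 4), 36.9674)
  expect_lt(abs(got$domain_ax / 46 - 1), 0.02)
})

test_that("refined parameters are invariant under intensity scaling", {
  ph <- mc_phases()$HAP_LC
  q <- seq(5, 35, by = 0.02)
  prof <- synth_profile(ph, q = q, instr_fwhm = 0.05)
  prof2 <- waxs_profile(q, 2 * prof$intensity)
  start <- ph; start$a <- ph$a * 1.005; start$c <- ph$c * 0.995
  r1 <- refine_profile(prof, start, instr_fwhm = 0.05)
  r2 <- refine_profile(prof2, start, instr_fwhm = 0.05)
  expect_equal(r1$phases[[1]]$a, r2$phases[[1]]$a, tolerance = 1e-8)
  expect_equal(r1$phases[[1]]$c, r2$phases[[1]]$c, tolerance = 1e-8)
  expect_equal(r1$phases[[1]]$domain_ax, r2$phases[[1]]$domain_ax,
               tolerance = 1e-6)
  expect_error(refine_profile(prof, phase_model("x", 9.4, 6.9,
                                                domain_ax = 100,
                                                domain_eq = 100),
                              min_peaks = 1e4), "fewer than")
})

test_that("classification separates distinct profile families exactly", {
  q <- seq(5.75, 34.4, by = 0.05)
  fam1 <- synth_profile(mc_phases()$HAP_HC, q = q, instr_fwhm = 0.05)$intensity
  fam2 <- synth_profile(mc_phases()$WHIT, q = q, instr_fwhm = 0.05)$intensity
  profs <- rbind(matrix(rep(fam1, 6), 6, byrow = TRUE) *
                   matrix(runif(6, 0.5, 2), 6, length(q)),
                 matrix(rep(fam2, 4), 4, byrow = TRUE) *
                   matrix(runif(4, 0.5, 2), 4, length(q)))
  cls <- classify_profiles(profs, q, n_components = 2,
                           background_component = FALSE)
  expect_length(unique(cls$labels[1:6]), 1)
  expect_length(unique(cls$labels[7:10]), 1)
  expect_true(cls$labels[1] != cls$labels[7])
  # all-identical profiles collapse to one component
  same <- matrix(rep(fam1, 5), 5, byrow = TRUE)
  expect_warning(cls1 <- classify_profiles(same, q, n_components = 3),
                 "exceeds distinct")
  expect_equal(cls1$n_components, 1)
  expect_true(all(cls1$labels == 0))
  # permutation invariance of the labelling
  perm <- c(7, 1, 9, 3, 2, 8, 4, 10, 5, 6)
  cls_p <- classify_profiles(profs[perm, ], q, n_components = 2,
                             background_component = FALSE)
  expect_equal(cls_p$labels, cls$labels[perm])
})

test_that("narrow whitlockite peaks survive a 4-point window but fade at 10", {
  # smoothing controls the detectability of a sparse family whose extra peaks
  # are instrument-limited narrow: after heavy smoothing it correlates more
  # strongly with the plain apatite family, so the classifier separates it
  # less readily
  q <- seq(5.75, 34.4, by = 0.05)
  whit_sharp <- phase_model("WHIT_sharp", 10.3211, 36.9674, "rhombohedral",
                            domain_ax = 400, domain_eq = 400)
  hap <- synth_profile(mc_phases()$HAP_LC, q = q, instr_fwhm = 0.05)$intensity
  mix <- 0.9 * hap + 0.1 *
    synth_profile(whit_sharp, q = q, instr_fwhm = 0.05)$intensity
  sm <- function(x, w) mcxray:::.boxcar(x, w)
  cor4 <- cor(sm(hap, 4), sm(mix, 4))
  cor10 <- cor(sm(hap, 10), sm(mix, 10))
  expect_gt(cor10, cor4)
  # with the 4-point window the mixed family still earns its own component
  profs <- rbind(matrix(rep(hap, 5), 5, byrow = TRUE),
                 matrix(rep(mix, 2), 2, byrow = TRUE))
  cls <- classify_profiles(profs, q, smooth_window = 4, n_components = 2)
  expect_true(cls$labels[6] != cls$labels[1])
})

test_that("collagen D-spacing is recovered from its diffraction orders", {
  D <- 61.6
  q <- seq(0.05, 0.8, by = 0.002)
  mk <- function(orders) {
    y <- 0.02
    for (n in orders)
      y <- y + (1 / n) * exp(-0.5 * ((q - 2 * pi * n / D) / 0.006)^2)
    waxs_profile(q, y)
  }
  d5 <- collagen_d_spacing(mk(1:5))
  expect_equal(as.numeric(d5), 61.6, tolerance = 0.1 / 61.6)
  # peaks exactly on the regression line give D exactly
  expect_equal(as.numeric(collagen_d_spacing(mk(1:3))), D, tolerance = 1e-3)
  # one missing order does not matter
  d_gap <- collagen_d_spacing(mk(c(1, 2, 4, 5)))
  expect_equal(as.numeric(d_gap), D, tolerance = 1e-3)
  expect_equal(attr(d_gap, "orders"), c(1, 2, 4, 5))
  expect_error(collagen_d_spacing(waxs_profile(q, rep(1, length(q)))),
               "at least 2")
})

test_that("azimuthal integration reproduces ring geometry and anisotropy", {
  lam <- 0.09117; L <- 308.3; px <- 0.172
  n <- 121; ctr <- c(61, 61)
  xs <- matrix(rep(1:n, each = n), n) - ctr[1]
  ys <- matrix(rep(1:n, n), n) - ctr[2]
  r <- sqrt(xs^2 + ys^2)
  ring_r <- 40
  frame <- exp(-0.5 * ((r - ring_r) / 1.2)^2)
  out <- azimuthal_integrate(frame, ctr, L, lam, pixel_mm = px,
                             n_qbins = 300)
  q_expected <- (4 * pi / lam) * sin(0.5 * atan(ring_r * px / L))
  q_peak <- out$average$q[which.max(out$average$intensity)]
  expect_equal(q_peak, q_expected, tolerance = 0.01)
  # isotropic ring: every segment peaks at the same q
  seg_peaks <- vapply(out$segments, function(s)
    s$q[which.max(s$intensity)], numeric(1))
  expect_lt(diff(range(seg_peaks)), 0.05 * q_expected)
  # two-arc anisotropy: only the horizontal segments carry the peak
  phi <- atan2(ys, xs)
  arc <- frame * (abs(cos(phi)) > 0.92)
  out2 <- azimuthal_integrate(arc, ctr, L, lam, pixel_mm = px, n_qbins = 300)
  seg_max <- vapply(out2$segments, function(s)
    if (length(s$intensity)) max(s$intensity) else 0, numeric(1))
  hot <- which(seg_max > 0.5 * max(seg_max)) - 1L
  expect_true(all(hot %in% c(0, 1, 7, 8, 15)))
  expect_error(azimuthal_integrate(frame, c(-5, 10), L, lam), "outside")
})
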