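# Forward XRF spectrum model: detector response, self-absorption, line
# sensitivities, spectrum synthesis.

.SI_ESCAPE_KEV <- 1.742   # Si Ka escaping the sensor
.SI_EDGE_KEV <- 1.8389    # escape requires photon above the Si K edge

#' Energy-dispersive detector model
#'
#' Resolution model FWHM(E)^2 = fwhm_noise^2 + fano_k * E, calibrated by
#' default so that FWHM = 150 eV at 5.9 keV (Mn Ka convention) with an 80 eV
#' electronic noise floor. Escape peaks appear at E - 1.742 keV for lines above
#' the Si K edge, with a fixed escape fraction.
#'
#' @param n_channels number of detector channels.
#' @param gain keV per channel.
#' @param offset energy of channel 1, keV.
#' @param fwhm_noise electronic noise contribution to FWHM, keV.
#' @param fwhm_anchor,anchor_keV resolution anchor: FWHM at this energy.
#' @param escape_fraction fraction of a line's counts moved to its escape peak.
#' @return object of class \code{detector_model}.
#' @export
detector_model <- function(n_channels = 1024, gain = 0.005, offset = 0,
                           fwhm_noise = 0.080, fwhm_anchor = 0.150,
                           anchor_keV = 5.9, escape_fraction = 0.015) {
  stopifnot(gain > 0, n_channels > 0, fwhm_anchor > fwhm_noise,
            escape_fraction >= 0, escape_fraction < 0.1)
  fano_k <- (fwhm_anchor^2 - fwhm_noise^2) / anchor_keV
  structure(list(n_channels = as.integer(n_channels), gain = gain,
                 offset = offset, fwhm_noise = fwhm_noise, fano_k = fano_k,
                 escape_energy = .SI_ESCAPE_KEV,
                 escape_fraction = escape_fraction),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model>", x$n_channels, "channels, gain", x$gain, "keV/ch\n")
  cat(sprintf("  FWHM %.0f eV at 5.9 keV, escape fraction %.1f%%\n",
              1000 * detector_fwhm(x, 5.9), 100 * x$escape_fraction))
  invisible(x)
}

#' Detector FWHM at an energy
#' @param det a \code{detector_model}.
#' @param energy keV.
#' @return FWHM in keV.
#' @export
detector_fwhm <- function(det, energy) {
  sqrt(det$fwhm_noise^2 + det$fano_k * energy)
}

#' Channel energy axis of a detector
#' @param det a \code{detector_model}.
#' @return numeric vector of channel energies, keV.
#' @export
channel_energies <- function(det) {
  det$offset + det$gain * (seq_len(det$n_channels) - 1L)
}

#' Measurement geometry
#'
#' @param incidence_deg angle between beam and sample surface (default 84).
#' @param exit_deg angle between sample surface and detector axis (default 6).
#' @param opening_deg detector half-opening, carried as metadata for the
#'   geometry sensitivity utility.
#' @return object of class \code{geometry_model}.
#' @export
geometry_model <- function(incidence_deg = 84, exit_deg = 6, opening_deg = 2) {
  stopifnot(incidence_deg > 0, incidence_deg <= 90,
            exit_deg > 0, exit_deg <= 90)
  structure(list(incidence_deg = incidence_deg, exit_deg = exit_deg,
                 opening_deg = opening_deg), class = "geometry_model")
}

#' Self-absorption factor for a fluorescence line
#'
#' Attenuation of incident beam and outgoing fluorescence integrated over a
#' homogeneous layer of thickness t:
#' A = (1 - exp(-chi rho t)) / (chi rho t), with
#' chi = (mu/rho)(E_in)/sin(alpha) + (mu/rho)(E_line)/sin(beta).
#' A is 1 at t = 0 and decreases monotonically with t.
#'
#' @param t layer thickness, um (vectorized).
#' @param matrix matrix model or name.
#' @param E_in excitation energy, keV.
#' @param E_line fluorescence line energy, keV.
#' @param geom a \code{geometry_model}.
#' @return attenuation factor in (0, 1].
#' @export
self_absorption_factor <- function(t, matrix, E_in, E_line,
                                   geom = geometry_model()) {
  stopifnot(all(t >= 0))
  m <- .get_matrix(matrix)
  chi <- mass_attenuation(m, E_in) / sin(geom$incidence_deg * pi / 180) +
    mass_attenuation(m, E_line) / sin(geom$exit_deg * pi / 180)
  x <- chi * m$density * t * 1e-4  # t um -> cm
  ifelse(x < 1e-12, 1, (1 - exp(-x)) / pmax(x, 1e-300))
}

# K (or L3) shell fraction of total photoabsorption, from the edge jump in the
# pinned tabulation: (r - 1) / r with r = mu(edge+) / mu(edge-)
.shell_fraction <- function(element, edge_keV) {
  lo <- element_mass_attenuation(element, edge_keV * (1 - 8e-4))
  hi <- element_mass_attenuation(element, edge_keV * (1 + 8e-4))
  r <- hi / lo
  (r - 1) / r
}

# Per-element line table with sensitivities (excluding the mass fraction):
# counts per unit (flux*time) per unit mass fraction, before self-absorption.
.excitable_lines <- function(elements, E_in) {
  lines <- emission_lines()
  lines <- lines[lines$element %in% elements & lines$edge_keV < E_in, ,
                 drop = FALSE]
  if (!nrow(lines)) return(lines)
  tau <- vapply(seq_len(nrow(lines)), function(i)
    element_mass_attenuation(lines$element[i], E_in), numeric(1))
  sf <- vapply(seq_len(nrow(lines)), function(i)
    .shell_fraction(lines$element[i], lines$edge_keV[i]), numeric(1))
  lines$sensitivity <- tau * sf * lines$fluor_yield * lines$rel_intensity
  lines
}

# Gaussian peak in channel space, unit area (in counts over channels)
.gauss_peak <- function(energy_axis, center, fwhm, gain) {
  sigma <- fwhm / 2.35482
  gain * stats::dnorm(energy_axis, mean = center, sd = sigma)
}

# Peak profile of one physical line including its escape peak; unit area in
# the parent line (escape adds escape_fraction on top, moved down in energy)
.line_profile <- function(energy_axis, E_line, det) {
  p <- .gauss_peak(energy_axis, E_line, detector_fwhm(det, E_line), det$gain)
  if (E_line > .SI_EDGE_KEV && det$escape_fraction > 0) {
    Ee <- E_line - det$escape_energy
    p <- (1 - det$escape_fraction) * p +
      det$escape_fraction * .gauss_peak(energy_axis, Ee,
                                        detector_fwhm(det, Ee), det$gain)
  }
  p
}

#' Simulate an energy-dispersive XRF spectrum
#'
#' Forward model: for every emission line of the composition whose excitation
#' edge lies below \code{E_in}, counts proportional to mass fraction times the
#' line sensitivity (photoabsorption at \code{E_in} x shell fraction x
#' fluorescence yield x line fraction) times the thickness self-absorption
#' factor, convolved with the detector response. Lines above the Si K edge
#' contribute escape peaks at E - 1.742 keV. An elastic peak sits at
#' \code{E_in}; a flat continuum background can be added. Poisson noise is
#' optional and seeded.
#'
#' @param composition named mass fractions of the emitting layer.
#' @param t layer thickness, um.
#' @param matrix matrix model (or name) governing absorption in the layer.
#' @param E_in excitation energy, keV.
#' @param det,geom detector and geometry models.
#' @param flux_time overall counts scale (incident photons x live time x
#'   solid angle, arbitrary units).
#' @param elastic_fraction elastic peak area as a fraction of
#'   \code{flux_time}.
#' @param background flat continuum counts per channel.
#' @param poisson if TRUE, draw Poisson counts.
#' @param seed RNG seed used when \code{poisson} is TRUE.
#' @return object of class \code{xrf_spectrum}: list with \code{counts},
#'   \code{energy_keV}, \code{E_in}.
#' @export
simulate_spectrum <- function(composition, t, matrix, E_in,
                              det = detector_model(), geom = geometry_model(),
                              flux_time = 1e6, elastic_fraction = 0.02,
                              background = 0, poisson = FALSE, seed = NULL) {
  stopifnot(t >= 0, E_in > 0)
  m <- .get_matrix(matrix)
  eaxis <- channel_energies(det)
  mu <- rep(background, det$n_channels)
  lines <- .excitable_lines(names(composition)[composition > 0], E_in)
  if (nrow(lines)) {
    for (i in seq_len(nrow(lines))) {
      el <- lines$element[i]
      A <- self_absorption_factor(t, m, E_in, lines$energy_keV[i], geom)
      area <- flux_time * composition[[el]] * lines$sensitivity[i] * A * 1e-3
      mu <- mu + area * .line_profile(eaxis, lines$energy_keV[i], det)
    }
  }
  if (elastic_fraction > 0 && E_in <= max(eaxis))
    mu <- mu + flux_time * elastic_fraction *
      .gauss_peak(eaxis, E_in, detector_fwhm(det, E_in), det$gain)
  counts <- mu
  if (poisson) {
    counts <- .with_seed(seed, stats::rpois(length(mu), mu))
  }
  structure(list(counts = counts, energy_keV = eaxis, E_in = E_in),
            class = "xrf_spectrum")
}

#' @export
print.xrf_spectrum <- function(x, ...) {
  cat("<xrf_spectrum> E_in =", x$E_in, "keV,", length(x$counts), "channels,",
      format(round(sum(x$counts))), "total counts\n")
  invisible(x)
}

#' @export
plot.xrf_spectrum <- function(x, log = "y", ...) {
  graphics::plot(x$energy_keV, pmax(x$counts, 0.5), type = "l", log = log,
                 xlab = "energy (keV)", ylab = "counts", ...)
  invisible(x)
}

# run expr under a temporary seed without disturbing the global RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
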