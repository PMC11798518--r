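# Thickness-constrained XRF quantification: Beer-Lambert thickness maps,
# SNIP background, per-pixel spectrum fits to matrix-referenced mass
# fractions, trace rescaling, thickness binning, carbonate dilution.

#' Raster-scan XRF spectrum cube
#'
#' Container for a raster grid of energy-dispersed spectra at one excitation
#' energy plus the co-registered transmitted intensity.
#'
#' @param counts array \code{[nrow, ncol, n_channels]} of detector counts.
#' @param transmission matrix \code{[nrow, ncol]} of transmitted intensity I.
#' @param i0 incident intensity (scalar or matrix).
#' @param det the \code{detector_model} the spectra were recorded with
#'   (carries the channel-to-keV calibration).
#' @param E_in excitation energy, keV.
#' @param live_time live time per pixel, s.
#' @return object of class \code{spectrum_cube}.
#' @export
spectrum_cube <- function(counts, transmission, i0 = 1, det = detector_model(),
                          E_in, live_time = 1) {
  stopifnot(length(dim(counts)) == 3L, all(counts >= 0),
            nrow(transmission) == dim(counts)[1],
            ncol(transmission) == dim(counts)[2], E_in > 0, live_time > 0)
  structure(list(counts = counts, transmission = transmission, i0 = i0,
                 det = det, E_in = E_in, live_time = live_time),
            class = "spectrum_cube")
}

#' @export
print.spectrum_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat("<spectrum_cube>", d[1], "x", d[2], "pixels,", d[3], "channels, E_in =",
      x$E_in, "keV\n")
  invisible(x)
}

#' SNIP-style continuum background estimate
#'
#' Iterative low-clipping in the log-log-square-root domain with a shrinking
#' window; the standard parameter-light background model for energy-dispersive
#' spectra.
#'
#' @param counts spectrum counts.
#' @param window starting half-window in channels.
#' @return background estimate, same length as \code{counts}.
#' @export
snip_background <- function(counts, window = 24) {
  n <- length(counts)
  v <- log(log(sqrt(pmax(counts, 0) + 1) + 1) + 1)
  for (m in seq(window, 1)) {
    if (n <= 2 * m) next
    i <- (m + 1):(n - m)
    v[i] <- pmin(v[i], 0.5 * (v[i - m] + v[i + m]))
  }
  (exp(exp(v) - 1) - 1)^2 - 1
}

#' Effective matrix thickness from transmission
#'
#' Beer-Lambert inversion t_eff = -ln(I/I0) * delta(matrix, E_in) per pixel,
#' in um. Pixels with I > I0 (noise) are clipped to t = 0 and counted; pixels
#' with I <= 0 are flagged invalid (NA).
#'
#' @param cube a \code{spectrum_cube} with transmission recorded.
#' @param matrix assumed matrix (model or registry name).
#' @return object of class \code{thickness_map}: matrix of t_eff (um) with
#'   attributes \code{matrix_name}, \code{E_in}, \code{delta_um},
#'   \code{n_clipped}.
#' @export
effective_thickness_map <- function(cube, matrix = "HAP_B") {
  m <- .get_matrix(matrix)
  delta <- attenuation_length(m, cube$E_in)
  Tr <- cube$transmission / cube$i0
  invalid <- !is.finite(Tr) | Tr <= 0
  n_clipped <- sum(Tr > 1, na.rm = TRUE)
  Tr[Tr > 1] <- 1
  Tr[invalid] <- 1
  t <- -log(Tr) * delta
  t[invalid] <- NA_real_
  if (n_clipped > 0)
    warning(n_clipped, " pixel(s) with I > I0 clipped to t = 0")
  structure(t, class = c("thickness_map", "matrix"),
            matrix_name = m$name, E_in = cube$E_in, delta_um = delta,
            n_clipped = n_clipped)
}

#' @export
print.thickness_map <- function(x, ...) {
  cat("<thickness_map>", nrow(x), "x", ncol(x), "px, matrix",
      attr(x, "matrix_name"), "at", attr(x, "E_in"), "keV\n")
  cat(sprintf("  t_eff range %.3g - %.3g um (%d clipped)\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              attr(x, "n_clipped")))
  invisible(x)
}

#' @export
plot.thickness_map <- function(x, contours = c(0.3, 0.5, 1.0), ...) {
  z <- t(x[nrow(x):1, , drop = FALSE])
  graphics::image(z, useRaster = TRUE, axes = FALSE,
                  main = "effective thickness (um)", ...)
  graphics::contour(z, levels = contours, add = TRUE,
                    col = c("white", "red", "black")[seq_along(contours)])
  invisible(x)
}

# reference element convention by excitation energy: heaviest excited matrix
# element (Ca above its K edge, P above its K edge, else O)
.default_reference <- function(E_in) {
  if (E_in > 4.0381) "Ca" else if (E_in > 2.1455) "P" else "O"
}

#' Fit one XRF spectrum to matrix-referenced mass fractions
#'
#' Estimates a SNIP continuum, then solves non-negative least squares for the
#' line areas of each requested element on the forward model's fixed line
#' positions (escape peaks included), with the pixel's effective thickness
#' entering through the per-line self-absorption factor. Mass fractions are
#' computed relative to the reference element, whose mass fraction is fixed to
#' the matrix registry value:
#' w_Z = (A_Z / S_Z) / (A_ref / S_ref) * w_ref.
#'
#' @param spectrum an \code{xrf_spectrum}, or a counts vector.
#' @param E_in excitation energy, keV (taken from the spectrum if present).
#' @param t effective thickness at this pixel, um.
#' @param matrix assumed matrix.
#' @param det,geom detector and geometry models.
#' @param line_set elements to fit (lines not excitable at \code{E_in} are
#'   dropped automatically).
#' @param reference reference element; default by excitation energy (Ca above
#'   the Ca K edge, P above the P K edge, else O).
#' @param w_ref reference mass fraction; default the matrix's theoretical
#'   value for the reference element.
#' @param bg_window SNIP half-window (channels); 0 disables background
#'   estimation.
#' @return object of class \code{xrf_fit} with elements \code{w} (named mass
#'   fractions), \code{w_se}, \code{areas}, \code{area_se}, \code{background},
#'   \code{fitted}, \code{chisq}, \code{flags}, \code{condition}.
#' @export
fit_spectrum <- function(spectrum, E_in = NULL, t, matrix = "HAP_B",
                         det = detector_model(), geom = geometry_model(),
                         line_set = c("O", "Na", "Mg", "Si", "P", "S", "Cl", "Ca"),
                         reference = NULL, w_ref = NULL, bg_window = 24) {
  if (inherits(spectrum, "xrf_spectrum")) {
    counts <- spectrum$counts
    if (is.null(E_in)) E_in <- spectrum$E_in
  } else counts <- as.numeric(spectrum)
  stopifnot(!is.null(E_in), t >= 0, length(counts) == det$n_channels)
  m <- .get_matrix(matrix)
  if (is.null(reference)) reference <- .default_reference(E_in)
  if (is.null(w_ref)) w_ref <- theoretical_mass_fraction(m, reference)$value

  eaxis <- channel_energies(det)
  lines <- .excitable_lines(line_set, E_in)
  elements <- unique(lines$element)
  if (!reference %in% elements)
    stop("reference element '", reference, "' has no excitable line at E_in = ",
         E_in, " keV")

  # one design column per element: sensitivity- and absorption-weighted sum of
  # its line profiles, so the NNLS coefficient is proportional to w_Z
  X <- matrix(0, length(eaxis), length(elements),
              dimnames = list(NULL, elements))
  S_el <- stats::setNames(numeric(length(elements)), elements)
  for (i in seq_len(nrow(lines))) {
    el <- lines$element[i]
    A <- self_absorption_factor(t, m, E_in, lines$energy_keV[i], geom)
    sa <- lines$sensitivity[i] * A
    X[, el] <- X[, el] + sa * .line_profile(eaxis, lines$energy_keV[i], det)
    S_el[el] <- S_el[el] + sa
  }
  # elastic scattering column plus a flat continuum column that absorbs the
  # (downward-biased) remainder of the SNIP estimate under Poisson noise
  X <- cbind(X, elastic = .gauss_peak(eaxis, E_in, detector_fwhm(det, E_in),
                                      det$gain),
             const = rep(1, length(eaxis)))

  bg <- if (bg_window > 0) snip_background(counts, bg_window) else
    rep(0, length(counts))
  y <- counts - bg

  flags <- character(0)
  if (sum(counts) <= 0) {
    coef <- stats::setNames(rep(0, ncol(X)), colnames(X))
    flags <- "unquantifiable"
    cond <- NA_real_
    se <- coef
  } else {
    keep <- colSums(X^2) > 0
    sol <- pracma::lsqnonneg(X[, keep, drop = FALSE], y)
    coef <- stats::setNames(rep(0, ncol(X)), colnames(X))
    coef[colnames(X)[keep]] <- sol$x
    cond <- kappa(crossprod(X[, keep, drop = FALSE]), exact = FALSE)^0.5
    if (is.finite(cond) && cond > 1e8) flags <- c(flags, "ill-conditioned")
    # Poisson-weighted linear-model standard errors for the retained columns
    w <- 1 / pmax(counts, 1)
    XtWX <- crossprod(X[, keep, drop = FALSE] * sqrt(w))
    se <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
    cv <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e) NULL)
    if (!is.null(cv)) se[colnames(X)[keep]] <- cv
  }
  fitted <- as.numeric(X %*% coef) + bg

  c_el <- coef[elements]
  if (c_el[reference] <= 0) flags <- c(flags, "unquantifiable")
  wfrac <- if (c_el[reference] > 0)
    c_el / c_el[reference] * w_ref else stats::setNames(
      rep(NA_real_, length(elements)), elements)
  w_se <- if (c_el[reference] > 0)
    se[elements] / c_el[reference] * w_ref else wfrac
  areas <- c_el * S_el * 1e-3
  dof <- max(length(y) - sum(coef > 0), 1)
  chisq <- sum((counts - fitted)^2 / pmax(fitted, 1)) / dof

  structure(list(w = wfrac, w_se = w_se, areas = areas,
                 area_se = se[elements] * S_el * 1e-3,
                 elastic = coef[["elastic"]], reference = reference,
                 w_ref = w_ref, background = bg, fitted = fitted,
                 chisq = chisq, flags = flags, condition = cond,
                 E_in = E_in, t = t, matrix_name = m$name),
            class = "xrf_fit")
}

#' @export
print.xrf_fit <- function(x, ...) {
  cat("<xrf_fit> E_in =", x$E_in, "keV, t =", signif(x$t, 3), "um, matrix",
      x$matrix_name, "\n")
  cat("  reference:", x$reference, "at w =", x$w_ref, "\n")
  print(round(x$w, 5))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.xrf_fit <- function(object, ...) object$w

#' @export
summary.xrf_fit <- function(object, ...) {
  data.frame(element = names(object$w), w = unname(object$w),
             w_se = unname(object$w_se), area = unname(object$areas),
             row.names = NULL)
}

#' @export
fitted.xrf_fit <- function(object, ...) object$fitted

#' Fit every pixel of a spectrum cube
#'
#' Runs \code{\link{fit_spectrum}} per pixel with that pixel's effective
#' thickness, producing mass-fraction maps (masked where the effective
#' thickness is below \code{mask_um}) and intensity maps in counts/s.
#' Single-pixel failures are flagged, never fatal.
#'
#' @param cube a \code{spectrum_cube}.
#' @param thickness a \code{thickness_map} co-registered with \code{cube}.
#' @param matrix,geom,line_set,reference,w_ref,bg_window passed to
#'   \code{\link{fit_spectrum}}.
#' @param mask_um mass fractions are reported only where t_eff >= this value
#'   (masked pixels are NA, never zero).
#' @return object of class \code{mass_fraction_maps}: list of per-element
#'   matrices \code{w}, per-element intensity maps, \code{mask}, \code{flags}.
#' @export
fit_cube <- function(cube, thickness, matrix = "HAP_B",
                     geom = geometry_model(),
                     line_set = c("O", "Na", "Mg", "Si", "P", "S", "Cl", "Ca"),
                     reference = NULL, w_ref = NULL, bg_window = 24,
                     mask_um = 0.5) {
  stopifnot(all(dim(thickness) == dim(cube$counts)[1:2]))
  d <- dim(cube$counts)
  lines <- .excitable_lines(line_set, cube$E_in)
  elements <- unique(lines$element)
  wmaps <- imaps <- stats::setNames(
    rep(list(matrix(NA_real_, d[1], d[2])), length(elements)), elements)
  flags <- matrix("", d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    t_ij <- thickness[i, j]
    if (!is.finite(t_ij)) { flags[i, j] <- "invalid-thickness"; next }
    fit <- tryCatch(
      fit_spectrum(cube$counts[i, j, ], E_in = cube$E_in, t = t_ij,
                   matrix = matrix, det = cube$det, geom = geom,
                   line_set = line_set, reference = reference, w_ref = w_ref,
                   bg_window = bg_window),
      error = function(e) NULL)
    if (is.null(fit)) { flags[i, j] <- "fit-error"; next }
    if (length(fit$flags)) flags[i, j] <- paste(fit$flags, collapse = ";")
    for (el in elements) {
      imaps[[el]][i, j] <- fit$areas[[el]] / cube$live_time
      if (t_ij >= mask_um) wmaps[[el]][i, j] <- fit$w[[el]]
    }
  }
  structure(list(w = wmaps, intensity = imaps, mask = thickness >= mask_um,
                 flags = flags, elements = elements,
                 reference = if (is.null(reference))
                   .default_reference(cube$E_in) else reference,
                 E_in = cube$E_in, mask_um = mask_um),
            class = "mass_fraction_maps")
}

#' @export
print.mass_fraction_maps <- function(x, ...) {
  cat("<mass_fraction_maps> E_in =", x$E_in, "keV, elements:",
      paste(x$elements, collapse = " "), "\n")
  cat("  reference", x$reference, "; mask at t_eff >=", x$mask_um, "um (",
      sum(x$mask, na.rm = TRUE), "quantified pixels )\n")
  invisible(x)
}

#' Rescale trace-element fractions across excitation energies
#'
#' Sr and Y are only excitable below the P edge (2.1 keV scan), where the O
#' reference makes absolute fractions unreliable; they are put on the 2.5 keV
#' scale via w(Z) = w(Z, 2.1 keV) * w(Mg, 2.5 keV) / w(Mg, 2.1 keV).
#' Ratios among the rescaled elements are preserved; pixels with
#' w(Mg, 2.1) <= 0 are masked.
#'
#' @param w_21 named list of mass-fraction matrices from the 2.1 keV fit; must
#'   contain \code{Mg} and the elements in \code{elements}.
#' @param w_mg_25 matrix (or scalar) of w(Mg) from the 2.5 keV fit.
#' @param elements elements to rescale.
#' @return named list of rescaled matrices.
#' @export
rescale_trace_fractions <- function(w_21, w_mg_25, elements = c("Sr", "Y")) {
  stopifnot("Mg" %in% names(w_21), all(elements %in% names(w_21)))
  ratio <- w_mg_25 / w_21$Mg
  ratio[!is.finite(ratio) | w_21$Mg <= 0] <- NA_real_
  lapply(stats::setNames(elements, elements), function(el) w_21[[el]] * ratio)
}

#' Group spectra into effective-thickness bins and fit the bin averages
#'
#' Pixels are grouped by effective thickness, spectra within a bin are
#' averaged, and each averaged spectrum is fitted once with the bin's mean
#' thickness. This suppresses pixel noise and geometry systematics, giving
#' mass fraction versus thickness curves. Empty bins are dropped and reported.
#'
#' @param cube,thickness,matrix,geom,line_set,reference,w_ref,bg_window as in
#'   \code{\link{fit_cube}}.
#' @param edges bin edges in um.
#' @return data frame of class \code{thickness_bins}: one row per retained
#'   bin with mean thickness, pixel count, and w/w_se columns per element.
#' @export
bin_by_thickness <- function(cube, thickness,
                             edges = c(0.3, 0.5, 1, 1.5, 2, 3, 4, 5, 7),
                             matrix = "HAP_B", geom = geometry_model(),
                             line_set = c("O", "Na", "Mg", "Si", "P", "S", "Cl", "Ca"),
                             reference = NULL, w_ref = NULL, bg_window = 24) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  d <- dim(cube$counts)
  tvec <- as.numeric(thickness)
  cmat <- matrix(aperm(cube$counts, c(3, 1, 2)), nrow = d[3])  # ch x pixel
  bin <- cut(tvec, edges, labels = FALSE)
  rows <- list()
  dropped <- 0L
  for (b in seq_len(length(edges) - 1L)) {
    idx <- which(bin == b & is.finite(tvec))
    if (!length(idx)) { dropped <- dropped + 1L; next }
    avg <- rowMeans(cmat[, idx, drop = FALSE])
    tbar <- mean(tvec[idx])
    fit <- fit_spectrum(avg, E_in = cube$E_in, t = tbar, matrix = matrix,
                        det = cube$det, geom = geom, line_set = line_set,
                        reference = reference, w_ref = w_ref,
                        bg_window = bg_window)
    row <- data.frame(bin = b, t_lo = edges[b], t_hi = edges[b + 1L],
                      t_mean = tbar, n_pixels = length(idx))
    for (el in names(fit$w)) {
      row[[paste0("w_", el)]] <- fit$w[[el]]
      row[[paste0("se_", el)]] <- fit$w_se[[el]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("thickness_bins", "data.frame"),
            dropped_bins = dropped, E_in = cube$E_in,
            reference = if (is.null(reference))
      .default_reference(cube$E_in) else reference)
}

#' Carbonate-dilution model of the phosphorus fraction
#'
#' In a mixture of apatite with a fraction alpha of a P-free but Ca-containing
#' species (e.g. carbonate), the effective P fraction is
#' w_P,eff = (1 - alpha) * w_P,HAP, and since the optical density is linear in
#' composition, w_P depends approximately linearly on effective thickness.
#' Fits that linear trend and inverts alpha = 1 - w_P / w_P,HAP per bin.
#'
#' @param bins a \code{thickness_bins} table (or data frame with
#'   \code{t_mean} and \code{w_P} columns).
#' @param w_p_hap theoretical P fraction of the undiluted apatite; default the
#'   HAP registry value.
#' @return object of class \code{carbonate_model}: list with \code{slope},
#'   \code{intercept}, \code{alpha} (per bin), \code{fit} (the lm).
#' @export
carbonate_dilution_model <- function(bins,
                                     w_p_hap = theoretical_mass_fraction("HAP", "P")$value) {
  df <- as.data.frame(bins)
  stopifnot(all(c("t_mean", "w_P") %in% names(df)))
  df <- df[is.finite(df$w_P) & is.finite(df$t_mean), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 bins with finite w_P")
  if (diff(range(df$t_mean)) < 1e-9) stop("degenerate thickness range")
  fit <- stats::lm(w_P ~ t_mean, data = df)
  alpha <- 1 - df$w_P / w_p_hap
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 alpha = data.frame(t_mean = df$t_mean, alpha = alpha),
                 w_p_hap = w_p_hap, fit = fit),
            class = "carbonate_model")
}

#' @export
print.carbonate_model <- function(x, ...) {
  cat("<carbonate_model> w_P =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "* t_eff\n")
  cat("  implied carbonate fraction alpha:",
      paste(signif(x$alpha$alpha, 3), collapse = " "), "\n")
  invisible(x)
}
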