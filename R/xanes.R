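# Ca K-edge XANES: normalization, white-line position, reference generation,
# non-negative linear-combination fitting, species grouping, line scans.

#' Construct a XANES spectrum
#'
#' @param energy_eV strictly increasing energy grid (Ca K-edge region,
#'   roughly 4020--4120 eV).
#' @param intensity raw or normalized absorption.
#' @param mode detection mode tag, propagated to results as a caveat
#'   (fluorescence-yield spectra are not over-absorption corrected).
#' @param normalized logical; TRUE if already edge-step normalized.
#' @return object of class \code{xanes_spectrum}.
#' @export
xanes_spectrum <- function(energy_eV, intensity,
                           mode = c("transmission", "fluorescence-yield",
                                    "electron-yield"),
                           normalized = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(energy_eV) == length(intensity), all(diff(energy_eV) > 0))
  structure(list(energy_eV = energy_eV, intensity = intensity, mode = mode,
                 normalized = normalized),
            class = "xanes_spectrum")
}

#' @export
print.xanes_spectrum <- function(x, ...) {
  cat("<xanes_spectrum>", length(x$energy_eV), "points,",
      min(x$energy_eV), "-", max(x$energy_eV), "eV,", x$mode,
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' @export
plot.xanes_spectrum <- function(x, ...) {
  graphics::plot(x$energy_eV, x$intensity, type = "l", xlab = "energy (eV)",
                 ylab = if (x$normalized) "normalized absorption" else
                   "absorption", ...)
  invisible(x)
}

# edge position estimate: maximum derivative inside (pre_hi, post_lo)
.edge_position <- function(E, mu, lo, hi) {
  i <- which(E > lo & E < hi)
  d <- diff(mu[i]) / diff(E[i])
  E[i][which.max(d)]
}

#' Normalize a XANES spectrum
#'
#' Standard edge-step normalization: a linear fit over the pre-edge range is
#' subtracted, then the spectrum is divided by the edge step, taken as the
#' post-edge linear fit evaluated at the edge position. The result has
#' pre-edge mean ~0 and edge step 1. Idempotent, and invariant under affine
#' transforms of the input.
#'
#' @param spec a \code{xanes_spectrum}.
#' @param pre_range,post_range energy ranges (eV) used for the pre- and
#'   post-edge linear fits; must not straddle the edge.
#' @param flatten if TRUE the post-edge slope is also removed above the edge.
#' @return normalized \code{xanes_spectrum}.
#' @export
normalize_xanes <- function(spec, pre_range = c(4020, 4035),
                            post_range = c(4075, 4120), flatten = FALSE) {
  E <- spec$energy_eV; mu <- spec$intensity
  if (pre_range[1] < min(E) || post_range[2] > max(E) + 1e-9)
    stop("normalization ranges outside the energy grid")
  e0 <- .edge_position(E, mu, min(E), max(E))
  if (pre_range[2] >= e0 || post_range[1] <= e0)
    stop("normalization ranges overlap the edge at ", round(e0, 1), " eV")
  ipre <- E >= pre_range[1] & E <= pre_range[2]
  ipost <- E >= post_range[1] & E <= post_range[2]
  if (sum(ipre) < 2 || sum(ipost) < 2) stop("too few points in fit ranges")
  pre_fit <- stats::lm.fit(cbind(1, E[ipre]), mu[ipre])$coefficients
  mu1 <- mu - (pre_fit[1] + pre_fit[2] * E)
  post_fit <- stats::lm.fit(cbind(1, E[ipost]), mu1[ipost])$coefficients
  step <- post_fit[1] + post_fit[2] * e0
  if (!is.finite(step) || step <= 0) stop("non-positive edge step")
  mu2 <- mu1 / step
  if (flatten) {
    post_line <- (post_fit[1] + post_fit[2] * E) / step
    above <- E > e0
    mu2[above] <- mu2[above] - (post_line[above] - 1)
  }
  xanes_spectrum(E, mu2, mode = spec$mode, normalized = TRUE)
}

#' White-line position
#'
#' Energy of the absorption maximum inside a window, refined by a local
#' parabola through the maximum and its two neighbours. A plateau returns the
#' lowest-energy maximum with a flag.
#'
#' @param spec a normalized \code{xanes_spectrum}.
#' @param window energy window (eV) to search.
#' @return position in eV, with attribute \code{flag} set on a plateau.
#' @export
white_line_position <- function(spec, window = c(4040, 4060)) {
  E <- spec$energy_eV; mu <- spec$intensity
  i <- which(E >= window[1] & E <= window[2])
  if (length(i) < 3) stop("window contains fewer than 3 grid points")
  mmax <- max(mu[i])
  at <- i[which(mu[i] == mmax)]
  flag <- if (length(at) > 1) "plateau" else NULL
  k <- at[1]
  if (k <= 1 || k >= length(E)) return(structure(E[k], flag = flag))
  # parabola through (E[k-1..k+1], mu[k-1..k+1])
  x <- E[(k - 1):(k + 1)]; y <- mu[(k - 1):(k + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  pos <- if (a < 0) -b / (2 * a) else x[2]
  if (pos < x[1] || pos > x[3]) pos <- x[2]
  structure(pos, flag = flag)
}

# parametric reference shapes: arctan edge + Gaussian white line (+ shoulder)
# + exponentially damped post-edge cosine
.xanes_shape <- function(E, e0, wl_pos, wl_amp, wl_fwhm,
                         sh_pos = NA, sh_amp = 0, sh_fwhm = 6,
                         wig_amp = 0.08, wig_period = 35, wig_phase = 0,
                         wig_tau = 60) {
  s <- wl_fwhm / 2.35482
  mu <- 0.5 + atan((E - e0) / 1.6) / pi
  mu <- mu + wl_amp * exp(-0.5 * ((E - wl_pos) / s)^2)
  if (!is.na(sh_pos) && sh_amp > 0)
    mu <- mu + sh_amp * exp(-0.5 * ((E - sh_pos) / (sh_fwhm / 2.35482))^2)
  post <- E > e0
  mu[post] <- mu[post] + wig_amp * exp(-(E[post] - e0) / wig_tau) *
    cos(2 * pi * (E[post] - e0) / wig_period + wig_phase)
  mu
}

#' Parametric Ca K-edge reference library
#'
#' Generates normalized reference spectra for the six species used in
#' linear-combination fitting: HAP, A- and B-type carbonated apatite, WHIT,
#' calcite and ACC. The shapes encode the qualitative contrasts of measured
#' references: the apatite white line at ~4048.6 eV, the whitlockite white
#' line shifted to ~4049.5 eV, an enhanced apatite absorption around 4060 eV
#' that whitlockite lacks, and broad featureless ACC. Measured references can
#' replace these via two-column text files (see \code{\link{read_xanes}}).
#'
#' @param energy_eV common energy grid, eV.
#' @return named list of normalized \code{xanes_spectrum} objects, class
#'   \code{xanes_reference_set}.
#' @export
xanes_references <- function(energy_eV = seq(4020, 4120, by = 0.2)) {
  E <- energy_eV
  shapes <- list(
    HAP = .xanes_shape(E, 4045.5, 4048.6, 0.95, 4.2, sh_pos = 4060.5,
                       sh_amp = 0.24, wig_period = 33, wig_phase = 0.3),
    HAP_A = .xanes_shape(E, 4045.5, 4048.6, 0.87, 4.6, sh_pos = 4060.0,
                         sh_amp = 0.27, wig_period = 34, wig_phase = 0.6),
    HAP_B = .xanes_shape(E, 4045.6, 4048.6, 1.02, 4.0, sh_pos = 4061.0,
                         sh_amp = 0.21, wig_period = 32, wig_phase = 0.0),
    WHIT = .xanes_shape(E, 4046.0, 4049.5, 1.05, 4.0, sh_pos = 4062,
                        sh_amp = 0.05, wig_period = 40, wig_phase = 1.2),
    CALCITE = .xanes_shape(E, 4044.8, 4048.2, 1.25, 3.2, sh_pos = 4053.5,
                           sh_amp = 0.30, wig_period = 26, wig_phase = 2.0),
    ACC = .xanes_shape(E, 4045.0, 4047.8, 0.70, 7.5, sh_amp = 0,
                       wig_amp = 0.03, wig_period = 45, wig_phase = 0.8)
  )
  refs <- lapply(shapes, function(mu)
    normalize_xanes(xanes_spectrum(E, mu, mode = "electron-yield")))
  structure(refs, class = "xanes_reference_set")
}

#' @export
print.xanes_reference_set <- function(x, ...) {
  cat("<xanes_reference_set>", length(x), "references:",
      paste(names(x), collapse = " "), "\n")
  invisible(x)
}

# resample a reference to a target grid (linear interpolation)
.resample_xanes <- function(ref, energy_eV) {
  stats::approx(ref$energy_eV, ref$intensity, xout = energy_eV, rule = 2)$y
}

#' Linear-combination fit of a XANES spectrum
#'
#' Non-negative least squares of a normalized spectrum against a reference
#' library, optionally constrained to weights summing to one. References are
#' resampled to the spectrum grid; the fit range defaults to the near-edge
#' region. A diagnostic cross-correlation energy shift between spectrum and
#' the best single reference is reported but never applied.
#'
#' @param spec normalized \code{xanes_spectrum}.
#' @param refs a \code{xanes_reference_set} (or named list of spectra).
#' @param sum_to_one constrain weights to sum to 1 (default TRUE).
#' @param fit_range energy range used in the fit, eV.
#' @return object of class \code{xanes_lcf}: \code{weights}, \code{residual}
#'   (norm), \code{groups} (tot_HAP, WHIT_share, carbonate), \code{condition},
#'   \code{fitted}, \code{mode}.
#' @export
lcf_fit <- function(spec, refs, sum_to_one = TRUE,
                    fit_range = c(4035, 4090)) {
  if (!length(refs)) stop("reference set is empty")
  E <- spec$energy_eV
  i <- which(E >= fit_range[1] & E <= fit_range[2])
  y <- spec$intensity[i]
  X <- vapply(refs, function(r) .resample_xanes(r, E)[i], numeric(length(i)))
  cond <- kappa(crossprod(X), exact = FALSE)^0.5
  flags <- if (is.finite(cond) && cond > 1e8) "rank-deficient" else character(0)
  if (sum_to_one) {
    # soft equality row; the exact unit sum is restored by renormalization
    lambda <- 10 * max(abs(y))
    sol <- pracma::lsqnonneg(rbind(X, lambda), c(y, lambda))
    wts <- sol$x
    s <- sum(wts)
    if (s > 0) wts <- wts / s  # exact unit sum
  } else {
    wts <- pracma::lsqnonneg(X, y)$x
  }
  names(wts) <- names(refs)
  fitted <- as.numeric(X %*% wts)
  res <- sqrt(sum((y - fitted)^2))
  # diagnostic shift vs best single reference (not applied)
  best <- which.max(vapply(seq_len(ncol(X)), function(j)
    stats::cor(y, X[, j]), numeric(1)))
  cc <- stats::ccf(y, X[, best], lag.max = 10, plot = FALSE)
  shift <- cc$lag[which.max(cc$acf)] * mean(diff(E[i]))
  structure(list(weights = wts, residual = res,
                 groups = .group_weights(wts), condition = cond,
                 flags = flags, fitted = fitted, energy_eV = E[i],
                 observed = y, mode = spec$mode, shift_diag_eV = shift),
            class = "xanes_lcf")
}

.group_weights <- function(w) {
  gn <- function(x) if (is.na(x)) 0 else x
  tot_hap <- gn(w["HAP"]) + gn(w["HAP_A"]) + gn(w["HAP_B"])
  whit <- gn(w["WHIT"])
  carb <- gn(w["CALCITE"]) + gn(w["ACC"])
  share <- if (tot_hap + whit > 0) whit / (whit + tot_hap) else NA_real_
  list(tot_HAP = unname(tot_hap), WHIT_share = unname(share),
       carbonate = unname(carb))
}

#' Grouped species fractions from an LCF result
#'
#' tot_HAP = w_HAP + w_HAP_A + w_HAP_B; WHIT_share = w_WHIT / (w_WHIT +
#' tot_HAP), the fraction of whitlockite among the calcium phosphates;
#' carbonate = w_CALCITE + w_ACC. WHIT_share is NA (flagged) when no calcium
#' phosphate is present.
#'
#' @param res a \code{xanes_lcf} (or named weight vector).
#' @return list with \code{tot_HAP}, \code{WHIT_share}, \code{carbonate}.
#' @export
group_species <- function(res) {
  w <- if (inherits(res, "xanes_lcf")) res$weights else res
  .group_weights(w)
}

#' @export
print.xanes_lcf <- function(x, ...) {
  cat("<xanes_lcf> residual", signif(x$residual, 4), "(", x$mode, ")\n")
  print(round(x$weights, 4))
  g <- x$groups
  cat(sprintf("  tot_HAP %.3f  WHIT_share %s  carbonate %.3f\n", g$tot_HAP,
              if (is.na(g$WHIT_share)) "NA" else sprintf("%.3f", g$WHIT_share),
              g$carbonate))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.xanes_lcf <- function(object, ...) object$weights

#' @export
fitted.xanes_lcf <- function(object, ...) object$fitted

#' @export
residuals.xanes_lcf <- function(object, ...) object$observed - object$fitted

#' @export
plot.xanes_lcf <- function(x, ...) {
  graphics::plot(x$energy_eV, x$observed, pch = 16, cex = 0.4,
                 xlab = "energy (eV)", ylab = "normalized absorption", ...)
  graphics::lines(x$energy_eV, x$fitted, col = "red")
  invisible(x)
}

#' LCF along a line scan
#'
#' Applies \code{\link{lcf_fit}} and \code{\link{group_species}} per position,
#' keeping only positions where the effective thickness exceeds
#' \code{t_min_um}.
#'
#' @param spectra list of normalized \code{xanes_spectrum}, ordered along the
#'   scan.
#' @param positions numeric positions (or labels) of the spectra.
#' @param refs reference set.
#' @param t_eff optional effective thickness per position, um.
#' @param t_min_um thickness filter (default 0.5 um).
#' @param region optional character labels (e.g. "sample"/"rim").
#' @param ... passed to \code{\link{lcf_fit}}.
#' @return data frame of class \code{xanes_scan}: position, region, weights
#'   and grouped fractions per retained position.
#' @export
line_scan_lcf <- function(spectra, positions = seq_along(spectra), refs,
                          t_eff = NULL, t_min_um = 0.5, region = NULL, ...) {
  stopifnot(length(spectra) == length(positions))
  keep <- if (is.null(t_eff)) rep(TRUE, length(spectra)) else t_eff > t_min_um
  rows <- lapply(which(keep), function(k) {
    fit <- lcf_fit(spectra[[k]], refs, ...)
    g <- fit$groups
    cbind(data.frame(position = positions[k],
                     region = if (is.null(region)) NA_character_ else region[k],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fit$weights)),
          data.frame(tot_HAP = g$tot_HAP, WHIT_share = g$WHIT_share,
                     carbonate = g$carbonate, residual = fit$residual))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("xanes_scan", "data.frame"), t_min_um = t_min_um)
}
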