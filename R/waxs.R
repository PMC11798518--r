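# WAXS/SAXS profile analysis: azimuthal integration, least-correlated-profile
# classification, phase peak positions, whole-pattern refinement with
# anisotropic Scherrer domain sizes, collagen D-spacing.

#' 1D scattering profile
#'
#' @param q momentum transfer grid, nm^-1, strictly increasing.
#' @param intensity non-negative intensities.
#' @param segment optional azimuthal segment index (0--15).
#' @return object of class \code{waxs_profile}.
#' @export
waxs_profile <- function(q, intensity, segment = NA_integer_) {
  stopifnot(length(q) == length(intensity), all(diff(q) > 0),
            all(intensity >= -1e-9))
  structure(list(q = q, intensity = pmax(intensity, 0), segment = segment),
            class = "waxs_profile")
}

#' @export
print.waxs_profile <- function(x, ...) {
  cat("<waxs_profile>", length(x$q), "points, q", min(x$q), "-", max(x$q),
      "nm^-1\n")
  invisible(x)
}

#' @export
plot.waxs_profile <- function(x, ...) {
  graphics::plot(x$q, x$intensity, type = "l", xlab = "q (nm^-1)",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Crystallographic phase model
#'
#' Hexagonal-setting cell (a = b, c) with anisotropic crystalline domain
#' sizes: \code{domain_ax} along [00l] and \code{domain_eq} along [hk0]
#' (e.g. [110]). For rhombohedral lattices in the hexagonal setting the
#' obverse reflection condition -h + k + l = 3n is applied. Relative
#' reflection intensities are free scalars, set at synthesis or refined.
#'
#' @param name identifier.
#' @param a,c cell parameters, Angstrom.
#' @param system "hexagonal" or "rhombohedral" (hexagonal setting).
#' @param domain_ax,domain_eq domain sizes along [00l] / [hk0], Angstrom.
#' @param K Scherrer constant (fixed convention, default 0.9).
#' @return object of class \code{phase_model}.
#' @export
phase_model <- function(name, a, c, system = c("hexagonal", "rhombohedral"),
                        domain_ax = 200, domain_eq = 200, K = 0.9) {
  system <- match.arg(system)
  stopifnot(a > 0, c > 0, domain_ax > 0, domain_eq > 0, K > 0)
  structure(list(name = name, a = a, c = c, system = system,
                 domain_ax = domain_ax, domain_eq = domain_eq, K = K),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase_model> %s (%s): a = %.4f A, c = %.4f A, domains %0.0f/%0.0f A\n",
              x$name, x$system, x$a, x$c, x$domain_ax, x$domain_eq))
  invisible(x)
}

#' Built-in phase registry
#'
#' Hydroxyapatite (hexagonal) in high- and low-crystallinity variants and
#' whitlockite (rhombohedral, hexagonal setting) with refined literature cell
#' parameters and domain sizes.
#'
#' @return named list of \code{phase_model} objects.
#' @export
mc_phases <- function() {
  list(
    HAP_HC = phase_model("HAP_HC", 9.3897, 6.8652, "hexagonal", 244, 129),
    HAP_LC = phase_model("HAP_LC", 9.3897, 6.8652, "hexagonal", 96, 53),
    WHIT = phase_model("WHIT", 10.3211, 36.9674, "rhombohedral", 46, 46)
  )
}

# does any symmetry-equivalent of (h,k,l) satisfy -H + K + L = 3n?
.rhomb_allowed <- function(h, k, l) {
  hk <- rbind(c(h, k), c(k, h), c(-h - k, h), c(h, -h - k),
              c(k, -h - k), c(-h - k, k))
  for (i in seq_len(nrow(hk))) for (L in c(l, -l))
    if ((-hk[i, 1] + hk[i, 2] + L) %% 3 == 0) return(TRUE)
  FALSE
}

#' Reflection positions of a phase
#'
#' Hexagonal-setting plane spacing 1/d^2 = (4/3)(h^2 + hk + k^2)/a^2 + l^2/c^2
#' and q = 2 pi / d, enumerated up to \code{q_max} and sorted ascending.
#' Reflections merging to the same q keep one entry. For rhombohedral phases
#' the obverse-setting reflection condition is applied.
#'
#' @param phase a \code{phase_model}.
#' @param q_max upper limit, nm^-1.
#' @param q_min lower limit, nm^-1.
#' @return data frame with columns h, k, l, d_nm, q_nm and the angle cosine
#'   to the c axis (\code{cos_phi}).
#' @export
phase_peak_positions <- function(phase, q_max = 34.4, q_min = 1) {
  a_nm <- phase$a / 10; c_nm <- phase$c / 10
  d_min <- 2 * pi / q_max
  hmax <- ceiling(2 * a_nm / (sqrt(3) * d_min))
  lmax <- ceiling(c_nm / d_min)
  out <- list()
  for (h in 0:hmax) for (k in 0:h) for (l in 0:lmax) {
    if (h == 0 && k == 0 && l == 0) next
    inv_d2 <- (4 / 3) * (h^2 + h * k + k^2) / a_nm^2 + l^2 / c_nm^2
    d <- 1 / sqrt(inv_d2)
    q <- 2 * pi / d
    if (q > q_max || q < q_min) next
    if (phase$system == "rhombohedral" && !.rhomb_allowed(h, k, l)) next
    out[[length(out) + 1L]] <- c(h, k, l, d, q, l * d / c_nm)
  }
  if (!length(out))
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      d_nm = numeric(0), q_nm = numeric(0),
                      cos_phi = numeric(0)))
  m <- do.call(rbind, out)
  df <- data.frame(h = m[, 1], k = m[, 2], l = m[, 3], d_nm = m[, 4],
                   q_nm = m[, 5], cos_phi = pmin(m[, 6], 1))
  df <- df[order(df$q_nm, df$l, df$h), ]
  df <- df[!duplicated(round(df$q_nm, 8)), ]
  rownames(df) <- NULL
  df
}

#' Anisotropic domain size along a reflection direction
#'
#' Two-direction model interpolating between the [00l] and [hk0] sizes:
#' 1/D(phi) = cos^2(phi)/D_ax + sin^2(phi)/D_eq, with phi the angle between
#' the scattering vector and the c axis.
#'
#' @param phase a \code{phase_model}.
#' @param cos_phi cosine(s) of the angle to the c axis.
#' @return domain size(s), Angstrom.
#' @export
domain_size_hkl <- function(phase, cos_phi) {
  1 / (cos_phi^2 / phase$domain_ax + (1 - cos_phi^2) / phase$domain_eq)
}

#' Scherrer width in q of a size-broadened peak
#'
#' In momentum transfer the Scherrer relation is angle-independent:
#' FWHM_q = 2 pi K / D (the cos-theta factors of the 2-theta form cancel).
#'
#' @param D domain size, Angstrom.
#' @param K Scherrer constant.
#' @return FWHM in nm^-1.
#' @export
scherrer_width_q <- function(D, K = 0.9) 2 * pi * K / (D / 10)

#' Domain size from a Scherrer width in q
#' @param beta_q FWHM in nm^-1 (size contribution only).
#' @param K Scherrer constant.
#' @return domain size, Angstrom.
#' @export
scherrer_domain <- function(beta_q, K = 0.9) 10 * 2 * pi * K / beta_q

# unit-area pseudo-Voigt
.pseudo_voigt <- function(x, x0, fwhm, eta = 0.5) {
  u <- (x - x0) / fwhm
  L <- (2 / (pi * fwhm)) / (1 + 4 * u^2)
  G <- (2 * sqrt(log(2) / pi) / fwhm) * exp(-4 * log(2) * u^2)
  eta * L + (1 - eta) * G
}

# design matrix of unit-area peaks for a set of phases on grid q
.peak_design <- function(q, phases, eta, instr_fwhm) {
  cols <- list(); meta <- list()
  for (p in seq_along(phases)) {
    ph <- phases[[p]]
    refl <- phase_peak_positions(ph, q_max = max(q) + 1, q_min = min(q) - 1)
    refl <- refl[refl$q_nm > min(q) & refl$q_nm < max(q), , drop = FALSE]
    if (!nrow(refl)) next
    D <- domain_size_hkl(ph, refl$cos_phi)
    bq <- sqrt(scherrer_width_q(D, ph$K)^2 +
                 (if (is.function(instr_fwhm)) instr_fwhm(refl$q_nm)
                  else instr_fwhm)^2)
    for (r in seq_len(nrow(refl))) {
      cols[[length(cols) + 1L]] <- .pseudo_voigt(q, refl$q_nm[r], bq[r], eta)
      meta[[length(meta) + 1L]] <- data.frame(
        phase = ph$name, h = refl$h[r], k = refl$k[r], l = refl$l[r],
        q_nm = refl$q_nm[r], fwhm_q = bq[r])
    }
  }
  list(X = if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(q), 0), meta = if (length(meta))
      do.call(rbind, meta) else NULL)
}

#' Synthesize a powder profile from phase models
#'
#' Sum of unit-area pseudo-Voigt peaks at the phases' reflection positions
#' with anisotropic Scherrer widths, free intensity scalars, optional
#' instrumental broadening (added in quadrature) and additive background.
#'
#' @param phases list of \code{phase_model}.
#' @param q grid, nm^-1.
#' @param intensities list (per phase) of reflection intensities, or NULL for
#'   a deterministic default pattern.
#' @param eta pseudo-Voigt mixing (0 Gaussian .. 1 Lorentzian).
#' @param instr_fwhm instrumental FWHM in q: scalar or function of q.
#' @param background additive background (scalar or vector).
#' @return a \code{waxs_profile} with attribute \code{peaks} (data frame of
#'   per-reflection metadata and intensities).
#' @export
synth_profile <- function(phases, q = seq(5, 35, by = 0.02),
                          intensities = NULL, eta = 0.5, instr_fwhm = 0.05,
                          background = 0) {
  if (inherits(phases, "phase_model")) phases <- list(phases)
  des <- .peak_design(q, phases, eta, instr_fwhm)
  if (is.null(intensities)) {
    # deterministic varied default intensities, decaying with q
    m <- des$meta
    intens <- (1 + (7 * m$h + 5 * m$k + 3 * m$l) %% 11) / 11 *
      exp(-m$q_nm / 25) * 100
  } else intens <- unlist(intensities)
  stopifnot(length(intens) == ncol(des$X))
  y <- as.numeric(des$X %*% intens) + background
  prof <- waxs_profile(q, y)
  attr(prof, "peaks") <- cbind(des$meta, intensity = intens)
  prof
}

#' Whole-pattern refinement of cell and domain sizes
#'
#' Least-squares refinement of a 1D profile against pseudo-Voigt peaks at the
#' reflection positions of one or more phases. Free parameters per phase are
#' the cell (a, c) and the two anisotropic domain sizes; reflection
#' intensities are free linear parameters solved by non-negative least
#' squares at every step (variable projection); the background is fixed
#' (linear interpolation through anchor points, never refined); instrumental
#' broadening is removed in quadrature via the supplied resolution function.
#'
#' @param profile a \code{waxs_profile} (or list with q, intensity).
#' @param phases list of starting \code{phase_model}s (values perturbed from
#'   the truth converge to it on clean data).
#' @param background fixed background: scalar, vector on the profile grid, or
#'   data frame of (q, intensity) anchors interpolated linearly.
#' @param eta pseudo-Voigt mixing parameter (fixed).
#' @param instr_fwhm instrumental resolution in q: scalar or function of q.
#' @param min_peaks minimum resolved reflections required per phase.
#' @return object of class \code{waxs_refinement}: refined \code{phases},
#'   \code{intensities} (per-reflection table), \code{rss}, \code{converged},
#'   \code{start}, \code{fitted}.
#' @export
refine_profile <- function(profile, phases, background = 0, eta = 0.5,
                           instr_fwhm = 0.05, min_peaks = 3) {
  if (inherits(phases, "phase_model")) phases <- list(phases)
  q <- profile$q; y <- profile$intensity
  bg <- if (is.data.frame(background))
    stats::approx(background[[1]], background[[2]], xout = q, rule = 2)$y
  else rep(background, length.out = length(q))
  yc <- y - bg
  for (ph in phases) {
    n_in <- sum(phase_peak_positions(ph, max(q), min(q))$q_nm > min(q))
    if (n_in < min_peaks)
      stop("phase ", ph$name, " has fewer than ", min_peaks,
           " reflections in range")
  }
  np <- length(phases)
  par0 <- unlist(lapply(phases, function(p)
    log(c(p$a, p$c, p$domain_ax, p$domain_eq))))
  rebuild <- function(par) {
    lapply(seq_len(np), function(i) {
      v <- exp(par[(i - 1) * 4 + 1:4])
      ph <- phases[[i]]
      ph$a <- v[1]; ph$c <- v[2]; ph$domain_ax <- v[3]; ph$domain_eq <- v[4]
      ph
    })
  }
  resid_fn <- function(par) {
    phs <- rebuild(par)
    des <- .peak_design(q, phs, eta, instr_fwhm)
    if (!ncol(des$X)) return(yc)
    sol <- pracma::lsqnonneg(des$X, yc)
    yc - as.numeric(des$X %*% sol$x)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                    ptol = 1e-13)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn, control = ctl)
  phs <- rebuild(fit$par)
  des <- .peak_design(q, phs, eta, instr_fwhm)
  sol <- pracma::lsqnonneg(des$X, yc)
  fitted <- as.numeric(des$X %*% sol$x) + bg
  structure(list(phases = stats::setNames(phs, vapply(phs, `[[`, "", "name")),
                 intensities = cbind(des$meta, intensity = sol$x),
                 rss = sum((y - fitted)^2),
                 converged = fit$info %in% 1:4, info = fit$info,
                 message = fit$message, start = phases, fitted = fitted,
                 profile = profile, background = bg),
            class = "waxs_refinement")
}

#' @export
print.waxs_refinement <- function(x, ...) {
  cat("<waxs_refinement>", if (x$converged) "converged" else
    paste("NOT converged (info", x$info, ")"), " rss =", signif(x$rss, 4), "\n")
  for (ph in x$phases)
    cat(sprintf("  %s: a = %.4f A, c = %.4f A, D[00l] = %.1f A, D[hk0] = %.1f A\n",
                ph$name, ph$a, ph$c, ph$domain_ax, ph$domain_eq))
  invisible(x)
}

#' @export
coef.waxs_refinement <- function(object, ...) {
  do.call(rbind, lapply(object$phases, function(p)
    data.frame(phase = p$name, a = p$a, c = p$c, domain_ax = p$domain_ax,
               domain_eq = p$domain_eq, row.names = NULL)))
}

#' @export
fitted.waxs_refinement <- function(object, ...) object$fitted

#' @export
residuals.waxs_refinement <- function(object, ...)
  object$profile$intensity - object$fitted

#' @export
plot.waxs_refinement <- function(x, ...) {
  graphics::plot(x$profile$q, x$profile$intensity, pch = 16, cex = 0.3,
                 xlab = "q (nm^-1)", ylab = "intensity", ...)
  graphics::lines(x$profile$q, x$fitted, col = "red")
  invisible(x)
}

# boxcar smoothing with edge handling by shrinking window
.boxcar <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- window %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (window - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Least-correlated-profile classification
#'
#' Greedy extraction of representative profiles from a stack: profiles are
#' boxcar-smoothed and restricted to a q range; the first representative is
#' the profile of highest intensity variance, and each further representative
#' is the profile minimizing its maximum correlation with those already
#' selected. Every profile is then assigned to the representative it
#' correlates best with. Component labels are renumbered by increasing
#' integrated intensity of the representative, so component 0 is the
#' background-like family.
#'
#' @param profiles matrix (profiles in rows) or list of \code{waxs_profile}.
#' @param q q grid matching the columns.
#' @param q_range classification range, nm^-1 (default 5.75--34.4).
#' @param smooth_window boxcar window in grid points (default 4).
#' @param n_components number of representatives to extract.
#' @param var_floor representative candidates must have a smoothed intensity
#'   variance of at least this fraction of the maximum; keeps counting-noise
#'   profiles from being selected as "least correlated" representatives.
#' @param background_component if TRUE (default) the profile of lowest
#'   integrated intensity is always included as a representative; after
#'   relabelling it becomes component 0, the background family.
#' @return object of class \code{waxs_classification}: \code{components}
#'   (matrix of representatives on the restricted grid), \code{labels}
#'   (0-based), \code{rep_index}, \code{q}, parameters used.
#' @export
classify_profiles <- function(profiles, q, q_range = c(5.75, 34.4),
                              smooth_window = 4, n_components = 2,
                              var_floor = 0.02, background_component = TRUE) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    q <- profiles[[1]]$q
    profiles <- do.call(rbind, lapply(profiles, function(p) p$intensity))
  }
  stopifnot(ncol(profiles) == length(q), nrow(profiles) >= 1)
  sel <- q >= q_range[1] & q <= q_range[2]
  if (!any(sel)) stop("q_range outside the profile grid")
  S <- t(apply(profiles[, sel, drop = FALSE], 1, .boxcar,
               window = smooth_window))
  n <- nrow(S)
  if (n_components > n) {
    warning("n_components exceeds number of profiles; returning ", n)
    n_components <- n
  }
  vr <- apply(S, 1, stats::var)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  eligible <- which(vr >= var_floor * max(vr))
  reps <- which.max(vr)
  if (background_component) {
    bg <- which.min(rowSums(S))
    reps <- unique(c(reps, bg))
  }
  while (length(reps) < n_components) {
    cand <- setdiff(eligible, reps)
    if (!length(cand)) {
      warning("no eligible candidate profiles left; returning ",
              length(reps), " components")
      break
    }
    maxcor <- vapply(cand, function(i)
      max(vapply(reps, function(r) abs(safe_cor(S[i, ], S[r, ])), numeric(1))),
      numeric(1))
    if (min(maxcor) > 1 - 1e-9) {
      warning("number of requested components exceeds distinct profiles; ",
              "returning ", length(reps))
      break
    }
    reps <- c(reps, cand[which.min(maxcor)])
  }
  # assign every profile to its best-correlated representative
  corm <- vapply(reps, function(r)
    vapply(seq_len(n), function(i) safe_cor(S[i, ], S[r, ]), numeric(1)),
    numeric(n))
  corm <- matrix(corm, nrow = n)
  assign_raw <- apply(corm, 1, which.max)
  # renumber by integrated intensity of representative (background first)
  ord <- order(rowSums(S[reps, , drop = FALSE]))
  relabel <- integer(length(reps)); relabel[ord] <- seq_along(reps) - 1L
  structure(list(components = S[reps[ord], , drop = FALSE],
                 labels = relabel[assign_raw], rep_index = reps[ord],
                 q = q[sel], q_range = q_range,
                 smooth_window = smooth_window,
                 n_components = length(reps)),
            class = "waxs_classification")
}

#' @export
print.waxs_classification <- function(x, ...) {
  cat("<waxs_classification>", x$n_components, "components, q",
      x$q_range[1], "-", x$q_range[2], "nm^-1, window",
      x$smooth_window, "\n")
  print(table(component = x$labels))
  invisible(x)
}

#' Collagen axial D-spacing from SAXS orders
#'
#' Detects the equally spaced diffraction orders q_n = 2 pi n / D of fibrillar
#' collagen and fits D by weighted linear regression of q on order through the
#' origin. Missing intermediate orders are tolerated.
#'
#' @param profile a \code{waxs_profile} restricted to the SAXS range.
#' @param max_order highest order considered.
#' @param min_prominence peak detection threshold relative to the strongest
#'   peak.
#' @return D in nm with attributes \code{se_nm}, \code{orders},
#'   \code{peaks_q}.
#' @export
collagen_d_spacing <- function(profile, max_order = 6, min_prominence = 0.02) {
  q <- profile$q; y <- profile$intensity
  pk <- pracma::findpeaks(y, minpeakheight = min_prominence * max(y),
                          minpeakdistance = 3)
  if (is.null(pk) || nrow(pk) < 2)
    stop("need at least 2 detected diffraction orders")
  qp <- q[pk[, 2]]; hp <- pk[, 1]
  ord <- order(qp); qp <- qp[ord]; hp <- hp[ord]
  # spacing estimate robust to missing orders: minimal consistent spacing
  dq0 <- min(diff(c(0, qp)))
  n_i <- round(qp / dq0)
  keep <- n_i >= 1 & n_i <= max_order
  qp <- qp[keep]; n_i <- n_i[keep]; hp <- hp[keep]
  if (length(qp) < 2) stop("need at least 2 detected diffraction orders")
  slope <- sum(hp * n_i * qp) / sum(hp * n_i^2)
  D <- 2 * pi / slope
  res <- qp - slope * n_i
  se_slope <- if (length(qp) > 2)
    sqrt(sum(hp * res^2) / ((length(qp) - 1) * sum(hp * n_i^2))) else 0
  structure(D, se_nm = 2 * pi * se_slope / slope^2, orders = n_i,
            peaks_q = qp)
}

#' Azimuthal integration of a 2D detector frame
#'
#' Converts pixel radii to momentum transfer q = (4 pi / lambda) sin(theta)
#' with 2 theta = atan(r / L) and averages intensity in q bins, overall and in
#' azimuthal segments.
#'
#' @param frame numeric matrix (detector image; rows = y, cols = x).
#' @param center beam center c(x, y) in pixel units; must lie inside frame.
#' @param distance_mm sample--detector distance.
#' @param wavelength_nm X-ray wavelength.
#' @param pixel_mm pixel pitch.
#' @param n_segments azimuthal segments (default 16).
#' @param n_qbins number of q bins.
#' @return list with \code{average} (a \code{waxs_profile}),
#'   \code{segments} (list of per-segment profiles), \code{q}.
#' @export
azimuthal_integrate <- function(frame, center, distance_mm, wavelength_nm,
                                pixel_mm = 0.172, n_segments = 16,
                                n_qbins = 200) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny)
    stop("beam center outside frame")
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) - center[1]
  ys <- matrix(rep(seq_len(ny), nx), ny, nx) - center[2]
  r_mm <- sqrt(xs^2 + ys^2) * pixel_mm
  theta <- atan2(r_mm, distance_mm) / 2
  qv <- (4 * pi / wavelength_nm) * sin(theta)
  phi <- atan2(ys, xs) %% (2 * pi)
  seg <- pmin(floor(phi / (2 * pi / n_segments)), n_segments - 1L)
  qmax <- max(qv)
  edges <- seq(0, qmax, length.out = n_qbins + 1)
  qbin <- pmin(findInterval(qv, edges, rightmost.closed = TRUE), n_qbins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx_all <- qbin
  avg <- tapply(as.numeric(frame), idx_all, mean)
  q_avg <- centers[as.integer(names(avg))]
  keep <- is.finite(avg)
  average <- waxs_profile(q_avg[keep], as.numeric(avg)[keep])
  segments <- lapply(0:(n_segments - 1L), function(s) {
    m <- seg == s
    v <- tapply(as.numeric(frame)[m], qbin[m], mean)
    qs <- centers[as.integer(names(v))]
    ok <- is.finite(v)
    waxs_profile(qs[ok], as.numeric(v)[ok], segment = s)
  })
  list(average = average, segments = segments, q = centers)
}
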