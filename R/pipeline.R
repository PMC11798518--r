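# Orchestration and plain-text I/O: run the three per-sample analyses on a
# scene and produce tables, maps and a machine-readable summary.

#' Run the full three-modality analysis on a phantom scene
#'
#' Executes the complete chain: transmission to effective-thickness map, XRF
#' cube fits at the quantification energies with per-pixel thickness
#' constraint, thickness binning (Mg and P trends), the carbonate-dilution
#' model, a XANES line scan with grouped species fractions, and WAXS
#' classification of per-pixel profiles. Emits CSV tables, map images and a
#' JSON summary when \code{outdir} is given. Deterministic for a fixed scene
#' and seed.
#'
#' @param scene a \code{phantom_scene} (or a preset name).
#' @param seed RNG seed for all rendering noise.
#' @param outdir output directory, or NULL for no files.
#' @param flux_time XRF counts scale per pixel.
#' @param bin_edges thickness bin edges, um.
#' @param mask_um interpretation threshold on effective thickness.
#' @param fit_maps if TRUE also produce per-pixel mass-fraction maps (slower);
#'   binned quantification always runs.
#' @return object of class \code{mc_report}: list of stage results plus a
#'   \code{summary} list with the headline flags
#'   (\code{rim_Mg_enhanced}, \code{whit_rim}).
#' @export
run_all <- function(scene = "benign", seed = 1, outdir = NULL,
                    flux_time = 2e6,
                    bin_edges = c(0.3, 0.5, 1, 1.5, 2, 3, 4, 5.5),
                    mask_um = 0.5, fit_maps = FALSE) {
  if (is.character(scene)) scene <- build_scene(scene, seed = seed)
  det <- detector_model()
  geom <- geometry_model()
  stages <- list()

  # thickness from the 2.5 keV scan (used as constraint for all energies)
  cube25 <- render_xrf_cube(scene, E_in = 2.5, det = det, geom = geom,
                            flux_time = flux_time, seed = seed + 101)
  thick <- effective_thickness_map(cube25, "HAP_B")
  stages$thickness <- thick

  cube42 <- render_xrf_cube(scene, E_in = 4.2, det = det, geom = geom,
                            flux_time = flux_time, seed = seed + 102)
  cube21 <- render_xrf_cube(scene, E_in = 2.1, det = det, geom = geom,
                            flux_time = flux_time, seed = seed + 103)

  bins25 <- bin_by_thickness(cube25, thick, edges = bin_edges)
  bins42 <- bin_by_thickness(cube42, thick, edges = bin_edges)
  bins21 <- bin_by_thickness(cube21, thick, edges = bin_edges,
                             line_set = c("O", "Na", "Mg", "Si", "Sr", "Y"))
  stages$bins <- list(`2.5` = bins25, `4.2` = bins42, `2.1` = bins21)

  carb <- tryCatch(carbonate_dilution_model(bins42),
                   error = function(e) NULL)
  stages$carbonate <- carb

  if (fit_maps) {
    stages$maps_25 <- fit_cube(cube25, thick, mask_um = mask_um)
    stages$maps_21 <- fit_cube(cube21, thick, mask_um = mask_um,
                               line_set = c("O", "Na", "Mg", "Si", "Sr", "Y"))
    stages$trace_rescaled <- rescale_trace_fractions(
      stages$maps_21$w, stages$maps_25$w$Mg)
  }

  # XANES line scan across the deposit
  xa <- render_xanes(scene, noise_sd = 0.01, seed = seed + 104)
  specs <- lapply(xa$spectra, function(s)
    if (s$normalized) s else normalize_xanes(s))
  scan <- line_scan_lcf(specs, positions = seq_along(specs), refs = xa$refs,
                        t_eff = xa$t_eff, region = xa$region)
  stages$xanes <- scan

  # WAXS classification; one representative refined per run is left to the
  # user (refine_profile), classification is the mapping product
  wx <- render_waxs(scene, seed = seed + 105)
  cls <- classify_profiles(wx$profiles, wx$q, n_components = 4)
  stages$waxs <- list(classification = cls, region = wx$region, q = wx$q)

  # headline flags
  mg_slope <- mg_rel_drop <- NA_real_
  ok <- is.finite(bins25$w_Mg)
  if (sum(ok) >= 3) {
    mg_slope <- stats::coef(stats::lm(bins25$w_Mg[ok] ~ bins25$t_mean[ok]))[2]
    # effect size: fraction of the mean Mg level lost across the t range
    mg_rel_drop <- -mg_slope * diff(range(bins25$t_mean[ok])) /
      mean(bins25$w_Mg[ok])
  }
  rim_scan <- scan[scan$region == "rim" & is.finite(scan$WHIT_share), ]
  core_scan <- scan[scan$region == "core" & is.finite(scan$WHIT_share), ]
  whit_lcf <- nrow(rim_scan) > 0 && nrow(core_scan) > 0 &&
    mean(rim_scan$WHIT_share) > mean(core_scan$WHIT_share)
  whit_waxs <- .whit_component_in_rim(cls, wx$region, scene)
  summary <- list(
    preset = scene$preset, seed = seed,
    n_pixels = scene$nx * scene$ny,
    mg_bin_slope = unname(mg_slope),
    mg_rel_drop = unname(mg_rel_drop),
    rim_Mg_enhanced = is.finite(mg_rel_drop) && mg_rel_drop > 0.2,
    whit_share_rim = if (nrow(rim_scan)) mean(rim_scan$WHIT_share) else NA,
    whit_share_core = if (nrow(core_scan)) mean(core_scan$WHIT_share) else NA,
    whit_rim_lcf = whit_lcf,
    whit_rim_waxs = whit_waxs,
    whit_rim = whit_lcf && whit_waxs,
    carbonate_slope = if (is.null(carb)) NA else carb$slope)

  rep <- structure(list(scene = scene, stages = stages, summary = summary,
                        seed = seed),
                   class = "mc_report")
  if (!is.null(outdir)) .write_report(rep, outdir)
  rep
}

# is there a classification component whose pixels concentrate in the rim and
# that matches the whitlockite pattern better than the apatite one?
.whit_component_in_rim <- function(cls, region, scene) {
  whit_ref <- synth_profile(mc_phases()$WHIT, q = cls$q, instr_fwhm = 0.05)
  hap_ref <- synth_profile(mc_phases()$HAP_LC, q = cls$q, instr_fwhm = 0.05)
  for (comp in seq_len(cls$n_components) - 1L) {
    rep_prof <- cls$components[comp + 1L, ]
    if (stats::sd(rep_prof) == 0) next
    c_whit <- stats::cor(rep_prof, whit_ref$intensity)
    c_hap <- stats::cor(rep_prof, hap_ref$intensity)
    if (is.na(c_whit) || c_whit <= c_hap) next
    inr <- region[cls$labels == comp] == 3L
    allr <- region == 3L
    if (length(inr) && mean(inr) > mean(allr)) return(TRUE)
  }
  FALSE
}

#' @export
print.mc_report <- function(x, ...) {
  s <- x$summary
  cat("<mc_report>", s$preset, "preset, seed", s$seed, "\n")
  cat(sprintf("  Mg bin slope: %.3g /um -> rim_Mg_enhanced = %s\n",
              s$mg_bin_slope, s$rim_Mg_enhanced))
  cat(sprintf("  WHIT share rim %.3f vs core %.3f -> whit_rim_lcf = %s\n",
              s$whit_share_rim, s$whit_share_core, s$whit_rim_lcf))
  cat(sprintf("  whit_rim_waxs = %s; whit_rim = %s\n",
              s$whit_rim_waxs, s$whit_rim))
  invisible(x)
}

.write_report <- function(rep, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(rep$stages$bins))
    utils::write.csv(as.data.frame(rep$stages$bins[[nm]]),
                     file.path(outdir, paste0("bins_", nm, "keV.csv")),
                     row.names = FALSE)
  utils::write.csv(as.data.frame(rep$stages$xanes),
                   file.path(outdir, "xanes_scan.csv"), row.names = FALSE)
  write_map_csv(unclass(rep$stages$thickness),
                file.path(outdir, "thickness_um.csv"))
  .write_map_png(rep$stages$thickness, file.path(outdir, "thickness.png"))
  jsonlite::write_json(rep$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

.write_map_png <- function(map, path, contours = c(0.3, 0.5, 1.0)) {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  z <- t(map[nrow(map):1, , drop = FALSE])
  graphics::image(z, useRaster = TRUE, axes = FALSE)
  graphics::contour(z, levels = contours, add = TRUE)
  invisible(path)
}

#' Write / read a map as CSV
#' @param map numeric matrix.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Write / read a two-column profile or spectrum text file
#'
#' Plain two-column text with '#' comment lines; readers ignore comments and
#' are the exact inverse of the writers.
#'
#' @param x a \code{waxs_profile} or \code{xanes_spectrum}.
#' @param path file path.
#' @param comment optional comment line(s) written at the top.
#' @return the path.
#' @export
write_profile <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "waxs_profile")) {
    writeLines(c(paste0("# ", c(comment, "q_nm^-1 intensity"))), con)
    utils::write.table(data.frame(x$q, x$intensity), con,
                       row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "xanes_spectrum")) {
    writeLines(paste0("# ", c(comment,
                              paste("mode:", x$mode),
                              paste("normalized:", x$normalized),
                              "energy_eV intensity")), con)
    utils::write.table(data.frame(x$energy_eV, x$intensity), con,
                       row.names = FALSE, col.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

.read_two_col <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 2)
  if (length(bad))
    stop("parse error in ", path, " at data line ", bad[1],
         ": expected two columns")
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("parse error in ", path, ": non-numeric field")
  m
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  m <- .read_two_col(path)
  waxs_profile(m[, 1], m[, 2])
}

#' @rdname write_profile
#' @export
read_xanes <- function(path) {
  lines <- readLines(path)
  mode_line <- grep("^# mode:", lines, value = TRUE)
  norm_line <- grep("^# normalized:", lines, value = TRUE)
  m <- .read_two_col(path)
  xanes_spectrum(m[, 1], m[, 2],
                 mode = if (length(mode_line))
                   trimws(sub("^# mode:", "", mode_line[1])) else
                     "transmission",
                 normalized = length(norm_line) > 0 &&
                   grepl("TRUE", norm_line[1]))
}

#' Write / read a spectrum cube as a plain-text bundle
#'
#' A directory containing \code{meta.json} (calibration, excitation energy,
#' live time, dimensions), \code{counts.tsv} (pixels in rows, channels in
#' columns, row-major over the grid) and \code{transmission.tsv}.
#'
#' @param cube a \code{spectrum_cube}.
#' @param path directory path.
#' @return the path (write) or the cube (read).
#' @export
write_cube <- function(cube, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cube$counts)
  meta <- list(nrow = d[1], ncol = d[2], n_channels = d[3],
               gain = cube$det$gain, offset = cube$det$offset,
               fwhm_noise = cube$det$fwhm_noise,
               fano_k = cube$det$fano_k,
               escape_fraction = cube$det$escape_fraction,
               E_in = cube$E_in, live_time = cube$live_time,
               i0 = cube$i0)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  cmat <- matrix(aperm(cube$counts, c(3, 1, 2)), nrow = d[3])
  utils::write.table(t(cmat), file.path(path, "counts.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cube$transmission, file.path(path, "transmission.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a cube bundle: missing ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cmat <- as.matrix(utils::read.table(file.path(path, "counts.tsv"),
                                      sep = "\t"))
  if (nrow(cmat) != meta$nrow * meta$ncol || ncol(cmat) != meta$n_channels)
    stop("corrupt cube bundle: counts.tsv is ", nrow(cmat), "x", ncol(cmat),
         ", expected ", meta$nrow * meta$ncol, "x", meta$n_channels)
  counts <- aperm(array(t(cmat), c(meta$n_channels, meta$nrow, meta$ncol)),
                  c(2, 3, 1))
  Tr <- as.matrix(utils::read.table(file.path(path, "transmission.tsv"),
                                    sep = "\t"))
  dimnames(Tr) <- NULL
  det <- detector_model(n_channels = meta$n_channels, gain = meta$gain,
                        offset = meta$offset, fwhm_noise = meta$fwhm_noise,
                        escape_fraction = meta$escape_fraction)
  det$fano_k <- meta$fano_k
  spectrum_cube(counts, Tr, i0 = meta$i0, det = det, E_in = meta$E_in,
                live_time = meta$live_time)
}
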