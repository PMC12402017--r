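#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the EEM conditioning chain. Scatter
#' half-widths are in nm around the ridge center lines; the Raman line sits
#' at a wavenumber shift of `raman_shift` cm^-1 below the excitation line.
#' `ife_threshold` is the A254 above which a sample must be diluted before
#' fluorescence measurement (inner-filter screening); the boundary
#' `A254 == threshold` is acceptable. `qsu_reference_intensity` is the raw
#' instrument count of the 0.01 mg/L quinine sulfate standard at
#' ex 350 / em 450 nm, the definition of 1 QSU.
#'
#' @param rayleigh1_halfwidth,rayleigh2_halfwidth Half-widths (nm) of the
#'   first-order (em = ex) and second-order (em = 2 ex) Rayleigh bands.
#' @param raman_shift Raman shift (cm^-1).
#' @param raman_halfwidth Half-width (nm) of the Raman band.
#' @param ife_threshold Inner-filter absorbance threshold (AU), in (0, 1).
#' @param excision_mode `"mask"` (excised cells flagged, left out of later
#'   fits) or `"interpolate"` (excised cells refilled by linear
#'   interpolation along the emission axis).
#' @param qsu_reference_intensity Quinine standard intensity (raw counts).
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(rayleigh1_halfwidth = 15,
                              rayleigh2_halfwidth = 15,
                              raman_shift = 3400,
                              raman_halfwidth = 10,
                              ife_threshold = 0.05,
                              excision_mode = c("mask", "interpolate"),
                              qsu_reference_intensity = 1) {
  excision_mode <- match.arg(excision_mode)
  stopifnot(rayleigh1_halfwidth > 0, rayleigh2_halfwidth > 0,
            raman_halfwidth > 0, qsu_reference_intensity > 0)
  if (ife_threshold <= 0 || ife_threshold >= 1)
    stop("ife_threshold must lie in (0, 1)")
  structure(list(rayleigh1_halfwidth = rayleigh1_halfwidth,
                 rayleigh2_halfwidth = rayleigh2_halfwidth,
                 raman_shift = raman_shift,
                 raman_halfwidth = raman_halfwidth,
                 ife_threshold = ife_threshold,
                 excision_mode = excision_mode,
                 qsu_reference_intensity = qsu_reference_intensity),
            class = "preprocess_config")
}

scatter_mask <- function(ex, em, cfg) {
  m <- matrix(FALSE, length(ex), length(em))
  for (i in seq_along(ex)) {
    m[i, ] <- abs(em - ex[i]) <= cfg$rayleigh1_halfwidth |
      abs(em - 2 * ex[i]) <= cfg$rayleigh2_halfwidth |
      abs(em - raman_emission(ex[i], cfg$raman_shift)) <= cfg$raman_halfwidth
  }
  m
}

#' Excise Rayleigh and Raman scatter from an EEM
#'
#' Masks every cell within the configured half-widths of the first-order
#' Rayleigh line (em = ex), the second-order Rayleigh line (em = 2 ex), or
#' the water Raman line. In `"mask"` mode the cells are flagged in the EEM
#' mask and their values left untouched; in `"interpolate"` mode each masked
#' cell is refilled by 1-D linear interpolation along the emission axis
#' between its nearest unmasked neighbors; a masked run touching an
#' emission edge (so it has a neighbor on one side only) is instead filled
#' along the excitation axis from that emission column's known values. The
#' returned EEM carries no mask (the excised pattern is kept in the
#' `"excised"` attribute).
#'
#' @param x An [eem].
#' @param cfg A [preprocess_config].
#' @return The excised [eem].
#' @export
excise_scatter <- function(x, cfg = preprocess_config()) {
  validate_eem(x)
  m <- scatter_mask(x$ex, x$em, cfg)
  if (cfg$excision_mode == "mask") {
    x$mask <- if (is.null(x$mask)) m else (x$mask | m)
    return(x)
  }
  full <- which(rowSums(!m) == 0)
  if (length(full) > 0)
    stop("cannot interpolate: emission row(s) fully masked at ex = ",
         paste(x$ex[full], collapse = ", "), " nm")
  # pass 1: emission-axis interpolation where a masked run is bracketed by
  # unmasked neighbors on both sides
  filled <- x$intensity
  filled[m] <- NA_real_
  for (i in seq_len(nrow(m))) {
    bad <- m[i, ]
    if (!any(bad)) next
    filled[i, bad] <- stats::approx(x$em[!bad], x$intensity[i, !bad],
                                    xout = x$em[bad], rule = 1)$y
  }
  # pass 2: runs touching an emission edge have no bracketing pair; fill
  # them along the excitation axis from that column's known values
  left <- which(is.na(filled), arr.ind = TRUE)
  for (j in unique(left[, 2])) {
    ok <- !is.na(filled[, j])
    filled[!ok, j] <- stats::approx(x$ex[ok], filled[ok, j],
                                    xout = x$ex[!ok], rule = 2)$y
  }
  x$intensity <- filled
  attr(x, "excised") <- m
  x
}

#' Inner-filter screening decision
#'
#' Flags a sample for dilution when its absorbance at 254 nm exceeds the
#' configured threshold, and suggests the smallest power-of-two dilution
#' that brings A254 at or below it. The boundary `A254 == threshold` needs
#' no dilution. The inner-filter effect is handled by dilution only, not by
#' a mathematical correction.
#'
#' @param uv A [uv_spectrum] covering 254 nm.
#' @param cfg A [preprocess_config].
#' @return List with `needs_dilution` (logical), `suggested_factor`
#'   (power of two, 1 when no dilution is needed) and `a254`.
#' @export
inner_filter_screen <- function(uv, cfg = preprocess_config()) {
  a254 <- extract_uv254(uv)
  if (a254 < 0) stop("negative absorbance at 254 nm")
  thr <- cfg$ife_threshold
  if (a254 <= thr)
    return(list(needs_dilution = FALSE, suggested_factor = 1, a254 = a254))
  factor <- 2^ceiling(log2(a254 / thr))
  # guard against log2 round-off at exact powers of two
  while (a254 / factor > thr) factor <- factor * 2
  while (factor > 1 && a254 / (factor / 2) <= thr) factor <- factor / 2
  list(needs_dilution = TRUE, suggested_factor = factor, a254 = a254)
}

#' Undo a recorded dilution
#'
#' Scales intensities back to the undiluted sample by multiplying with the
#' recorded dilution factor, then resets the factor to 1 (so applying the
#' correction twice is the same as applying it once).
#'
#' @param x An [eem].
#' @return The back-corrected [eem].
#' @export
apply_dilution_correction <- function(x) {
  validate_eem(x)
  x$intensity <- x$intensity * x$dilution_factor
  x$dilution_factor <- 1
  x
}

#' Normalize an EEM to quinine sulfate units
#'
#' Divides raw instrument counts by the intensity of the 0.01 mg/L quinine
#' sulfate standard (ex 350 / em 450 nm), so a raw value equal to the
#' standard's maximum becomes 1 QSU. Refuses to normalize an EEM already in
#' QSU.
#'
#' @param x An [eem] in raw units.
#' @param cfg A [preprocess_config] carrying `qsu_reference_intensity`.
#' @return The [eem] in QSU.
#' @export
qsu_normalize <- function(x, cfg = preprocess_config()) {
  validate_eem(x)
  if (x$units == "QSU") stop("EEM is already in QSU; refusing to normalize twice")
  x$intensity <- x$intensity / cfg$qsu_reference_intensity
  x$units <- "QSU"
  x
}

#' Subtract a blank EEM
#'
#' Elementwise difference against a Milli-Q blank on the same grid and in
#' the same units, clipped at zero (downstream curve resolution requires
#' non-negative data). Masks of sample and blank are unioned.
#'
#' @param x Sample [eem].
#' @param blank Blank [eem] on the identical grid, same units.
#' @return The blank-subtracted [eem].
#' @export
blank_subtract <- function(x, blank) {
  validate_eem(x); validate_eem(blank)
  if (length(x$ex) != length(blank$ex) || length(x$em) != length(blank$em) ||
      any(abs(x$ex - blank$ex) > .grid_tol) ||
      any(abs(x$em - blank$em) > .grid_tol))
    stop("sample and blank grids differ")
  if (x$units != blank$units) stop("sample and blank units differ")
  x$intensity <- pmax(x$intensity - blank$intensity, 0)
  if (!is.null(blank$mask))
    x$mask <- if (is.null(x$mask)) blank$mask else (x$mask | blank$mask)
  x
}
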