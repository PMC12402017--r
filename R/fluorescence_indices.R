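# nearest-grid-point lookup; refuses masked cells so indices can never
# silently use excised scatter regions
eem_value <- function(x, ex, em) {
  i <- which.min(abs(x$ex - ex))
  j <- which.min(abs(x$em - em))
  if (!is.null(x$mask) && x$mask[i, j])
    stop(sprintf("required cell (ex %g, em %g) is masked", x$ex[i], x$em[j]))
  x$intensity[i, j]
}

#' Fluorescence index (FI)
#'
#' Emission intensity ratio I(470 nm) / I(520 nm) at 370 nm excitation
#' (McKnight convention). FI distinguishes microbially derived DOM (higher
#' values) from terrestrially derived DOM (lower values). Wavelengths are
#' taken at the nearest grid points; a masked required cell or a zero
#' denominator is an error.
#'
#' @param x A preprocessed [eem].
#' @param ex Excitation wavelength (nm).
#' @param em_num,em_den Numerator and denominator emission wavelengths (nm).
#' @return The index value.
#' @export
fluorescence_index <- function(x, ex = 370, em_num = 470, em_den = 520) {
  num <- eem_value(x, ex, em_num)
  den <- eem_value(x, ex, em_den)
  if (den == 0) stop("fluorescence index undefined: zero intensity at denominator cell")
  num / den
}

#' Humification index (HIX)
#'
#' Normalized (Ohno) form: the emission area 435--480 nm divided by the sum
#' of the areas 300--345 nm and 435--480 nm, at ~254 nm excitation. On the
#' standard 5 nm excitation grid the nearest point, 255 nm, is used (no
#' interpolation). Sums run over the 1-nm emission grid points, bounds
#' inclusive. The normalized form is bounded in \[0, 1\]; higher values mean
#' more humified (longer-emission) DOM. Set `normalized = FALSE` for the
#' classic unbounded ratio of the two areas.
#'
#' @param x A preprocessed [eem].
#' @param ex Excitation wavelength (nm); 254 targets the 255 nm grid point.
#' @param normalized Use the normalized (0--1) form?
#' @return The index value.
#' @export
humification_index <- function(x, ex = 254, normalized = TRUE) {
  i <- which.min(abs(x$ex - ex))
  long_j <- which(x$em >= 435 & x$em <= 480)
  short_j <- which(x$em >= 300 & x$em <= 345)
  for (j in c(long_j, short_j))
    if (!is.null(x$mask) && x$mask[i, j])
      stop(sprintf("required cell (ex %g, em %g) is masked", x$ex[i], x$em[j]))
  long_sum <- sum(x$intensity[i, long_j])
  short_sum <- sum(x$intensity[i, short_j])
  if (long_sum + short_sum == 0)
    stop("humification index undefined: both emission windows are zero")
  if (normalized) long_sum / (short_sum + long_sum)
  else {
    if (short_sum == 0) stop("humification index undefined: short window is zero")
    long_sum / short_sum
  }
}

#' Biological index (BIX)
#'
#' Emission intensity ratio I(380 nm) / I(430 nm) at 310 nm excitation
#' (Huguet convention); values near or above 1 indicate recently produced,
#' autochthonous DOM.
#'
#' @param x A preprocessed [eem].
#' @param ex Excitation wavelength (nm).
#' @param em_num,em_den Numerator and denominator emission wavelengths (nm).
#' @return The index value.
#' @export
biological_index <- function(x, ex = 310, em_num = 380, em_den = 430) {
  num <- eem_value(x, ex, em_num)
  den <- eem_value(x, ex, em_den)
  if (den == 0) stop("biological index undefined: zero intensity at denominator cell")
  num / den
}

#' Peak C / Peak T ratio
#'
#' Ratio of the maximum intensity in the humic-like Peak C region
#' (ex 320--360, em 420--480 nm) to the maximum in the tryptophan-like
#' Peak T region (ex 270--280, em 330--350 nm), Coble windows. Peaks are
#' window maxima, not fixed cells, because the peak labels denote regions;
#' masked cells are excluded from the maxima.
#'
#' @param x A preprocessed [eem].
#' @param c_ex,c_em Peak C excitation/emission windows (nm, length-2).
#' @param t_ex,t_em Peak T windows (nm, length-2).
#' @return The ratio.
#' @export
peak_ct_ratio <- function(x, c_ex = c(320, 360), c_em = c(420, 480),
                          t_ex = c(270, 280), t_em = c(330, 350)) {
  peak <- function(exw, emw) {
    i <- which(x$ex >= exw[1] & x$ex <= exw[2])
    j <- which(x$em >= emw[1] & x$em <= emw[2])
    if (length(i) == 0 || length(j) == 0)
      stop("EEM grid does not cover the peak window")
    vals <- x$intensity[i, j, drop = FALSE]
    if (!is.null(x$mask)) {
      keep <- !x$mask[i, j, drop = FALSE]
      if (!any(keep)) stop("peak window fully masked")
      vals <- vals[keep]
    }
    max(vals)
  }
  pc <- peak(c_ex, c_em)
  pt <- peak(t_ex, t_em)
  if (pt == 0) stop("Peak C/Peak T undefined: Peak T window maximum is zero")
  pc / pt
}

#' Per-sample fluorescence index table
#'
#' Computes FI, HIX, BIX and Peak C/Peak T for every EEM in a stack and
#' aggregates replicates (mean and sample standard deviation). With a
#' single replicate the sd columns are `NA`. Column order is fixed:
#' `fi, hix, bix, peak_ct` and their `sd_` counterparts.
#'
#' @param stack An [eem_stack] of preprocessed EEMs.
#' @param replicate_map Optional named list mapping a sample id to the
#'   `sample_id`s of its replicate EEMs in the stack; by default EEMs
#'   sharing a `sample_id` are replicates.
#' @return A `data.frame`, one row per sample.
#' @export
index_table <- function(stack, replicate_map = NULL) {
  ids <- vapply(stack$samples, `[[`, character(1), "sample_id")
  if (is.null(replicate_map)) {
    replicate_map <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  } else {
    replicate_map <- lapply(replicate_map, function(r) match(r, ids))
  }
  rows <- lapply(names(replicate_map), function(sid) {
    idx <- replicate_map[[sid]]
    vals <- vapply(idx, function(k) {
      e <- stack$samples[[k]]
      c(fi = fluorescence_index(e), hix = humification_index(e),
        bix = biological_index(e), peak_ct = peak_ct_ratio(e))
    }, numeric(4))
    m <- rowMeans(vals)
    s <- if (length(idx) > 1) apply(vals, 1, stats::sd) else rep(NA_real_, 4)
    data.frame(sample_id = sid, fi = m[1], hix = m[2], bix = m[3],
               peak_ct = m[4], sd_fi = s[1], sd_hix = s[2], sd_bix = s[3],
               sd_peak_ct = s[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
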