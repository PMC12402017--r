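#' Standard excitation and emission grids
#'
#' The canonical acquisition grids used throughout the package: excitation
#' 230--450 nm in 5 nm steps (45 wavelengths) and emission 250--550 nm in
#' 1 nm steps (301 wavelengths). Every EEM on these grids is a 45 x 301
#' matrix with rows indexed by excitation and columns by emission; that
#' orientation is a package-wide convention.
#'
#' @return Numeric vector of wavelengths (nm).
#' @export
std_ex_grid <- function() seq(230, 450, by = 5)

#' @rdname std_ex_grid
#' @export
std_em_grid <- function() seq(250, 550, by = 1)

# tolerance for grid-equality checks (nm, or relative for frequencies)
.grid_tol <- 1e-9

#' Excitation-emission matrix (EEM)
#'
#' Container for one sample's fluorescence landscape. Rows of `intensity`
#' are excitation wavelengths, columns are emission wavelengths. Cells
#' excised during preprocessing are marked in the logical `mask`
#' (`TRUE` = excised).
#'
#' @param sample_id Sample identifier.
#' @param ex,em Strictly increasing wavelength grids (nm).
#' @param intensity Numeric matrix, `length(ex)` x `length(em)`.
#' @param units `"raw"` (instrument counts) or `"QSU"` (quinine sulfate
#'   units).
#' @param dilution_factor Dilution applied before measurement; 1 means
#'   undiluted, must be >= 1.
#' @param mask Optional logical matrix of the same shape; `TRUE` marks
#'   excised cells.
#' @return An object of class `"eem"`.
#' @export
eem <- function(sample_id, ex, em, intensity, units = c("raw", "QSU"),
                dilution_factor = 1, mask = NULL) {
  units <- match.arg(units)
  ex <- as.numeric(ex)
  em <- as.numeric(em)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  dimnames(intensity) <- NULL
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    dimnames(mask) <- NULL
  }
  x <- structure(
    list(sample_id = as.character(sample_id), ex = ex, em = em,
         intensity = intensity, units = units,
         dilution_factor = as.numeric(dilution_factor), mask = mask),
    class = "eem")
  validate_eem(x)
  x
}

validate_eem <- function(x) {
  stopifnot(inherits(x, "eem"))
  if (any(diff(x$ex) <= 0)) stop("excitation grid must be strictly increasing")
  if (any(diff(x$em) <= 0)) stop("emission grid must be strictly increasing")
  if (!identical(dim(x$intensity), c(length(x$ex), length(x$em))))
    stop("intensity must be |ex| x |em| (rows = excitation, cols = emission)")
  if (!is.finite(x$dilution_factor) || x$dilution_factor < 1)
    stop("dilution_factor must be >= 1")
  if (!is.null(x$mask) && !identical(dim(x$mask), dim(x$intensity)))
    stop("mask must have the same dimensions as intensity")
  invisible(x)
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %s: %d ex (%g-%g nm) x %d em (%g-%g nm), units %s, dilution %g\n",
              x$sample_id, length(x$ex), min(x$ex), max(x$ex),
              length(x$em), min(x$em), max(x$em), x$units, x$dilution_factor))
  if (!is.null(x$mask)) cat(sprintf("  masked cells: %d\n", sum(x$mask)))
  invisible(x)
}

#' EIS Bode-phase spectrum
#'
#' @param sample_id Sample identifier.
#' @param freq Frequencies (Hz), strictly positive; stored sorted ascending.
#' @param phase Phase angles (degrees), one per frequency, within
#'   \[-90, 90\].
#' @param magnitude Optional impedance magnitudes (ohm).
#' @param replicate Replicate number (1 or 2 in the standard design).
#' @return An object of class `"eis_spectrum"`.
#' @export
eis_spectrum <- function(sample_id, freq, phase, magnitude = NULL,
                         replicate = 1L) {
  freq <- as.numeric(freq)
  phase <- as.numeric(phase)
  if (length(freq) != length(phase))
    stop("freq and phase must have equal length")
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("frequencies must be positive and finite")
  if (any(abs(phase) > 90 + 1e-9))
    stop("phase angles must lie within [-90, 90] degrees")
  ord <- order(freq)
  freq <- freq[ord]
  phase <- phase[ord]
  if (!is.null(magnitude)) magnitude <- as.numeric(magnitude)[ord]
  if (anyDuplicated(freq)) stop("duplicate frequencies")
  structure(list(sample_id = as.character(sample_id),
                 replicate = as.integer(replicate),
                 freq = freq, phase = phase, magnitude = magnitude),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("<eis_spectrum> %s rep %d: %d points, %.3g-%.5g Hz\n",
              x$sample_id, x$replicate, length(x$freq),
              min(x$freq), max(x$freq)))
  invisible(x)
}

#' UV-Vis absorption spectrum
#'
#' @param sample_id Sample identifier.
#' @param wl Wavelength grid (nm), strictly increasing.
#' @param absorbance Absorbance (1 cm path), one value per wavelength.
#' @return An object of class `"uv_spectrum"`.
#' @export
uv_spectrum <- function(sample_id, wl, absorbance) {
  wl <- as.numeric(wl)
  absorbance <- as.numeric(absorbance)
  if (length(wl) != length(absorbance))
    stop("wl and absorbance must have equal length")
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  structure(list(sample_id = as.character(sample_id), wl = wl,
                 absorbance = absorbance),
            class = "uv_spectrum")
}

# ---- EEM readers/writers ----------------------------------------------------

sidecar_path <- function(path) {
  sub("\\.[^.]+$", "", path) |> paste0(".json")
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

#' Read an EEM from CSV
#'
#' Two dialects are supported. `wide_csv`: the first row holds the emission
#' wavelengths, the first column the excitation wavelengths, and the body the
#' intensities (rows = excitation, the package-wide orientation; transposed
#' files are rejected, not guessed). Empty data fields mark masked cells.
#' `long_csv`: columns `ex,em,intensity`, one row per cell; grid cells absent
#' from the file are masked. Metadata (`sample_id`, `units`,
#' `dilution_factor`) travels in a JSON sidecar named after the CSV
#' (`foo.csv` -> `foo.json`); defaults apply if no sidecar is present.
#'
#' @param path CSV file path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return An [eem] object with sorted, validated grids.
#' @export
read_eem <- function(path, dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sidecar(path)
  sample_id <- meta$sample_id %||% sub("\\.[^.]+$", "", basename(path))
  units <- meta$units %||% "raw"
  dilution <- meta$dilution_factor %||% 1

  if (dialect == "wide_csv") {
    lines <- readLines(path)
    if (length(lines) < 2) stop("malformed wide EEM: fewer than 2 rows")
    header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
    em <- suppressWarnings(as.numeric(header[-1]))
    if (anyNA(em)) stop("malformed header: non-numeric emission wavelength in column ",
                        which(is.na(em))[1] + 1)
    body <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    ex <- suppressWarnings(as.numeric(body[[1]]))
    if (anyNA(ex)) stop("malformed file: non-numeric excitation wavelength in row ",
                        which(is.na(ex))[1] + 1)
    raw <- as.matrix(body[, -1, drop = FALSE])
    mask <- raw == "" | is.na(raw)
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    bad <- which(is.na(num) & !mask, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric intensity at row %d, column %d",
                   bad[1, 1] + 1, bad[1, 2] + 1))
    num[mask] <- 0
    oex <- order(ex); oem <- order(em)
    eem(sample_id, ex[oex], em[oem], num[oex, oem, drop = FALSE],
        units = units, dilution_factor = dilution,
        mask = if (any(mask)) mask[oex, oem, drop = FALSE] else NULL)
  } else {
    df <- utils::read.csv(path, header = TRUE)
    need <- c("ex", "em", "intensity")
    if (!all(need %in% names(df)))
      stop("long EEM CSV must have columns ex,em,intensity")
    if (!is.numeric(df$ex) || !is.numeric(df$em) || !is.numeric(df$intensity))
      stop("non-numeric values in long EEM CSV")
    key <- paste(df$ex, df$em)
    if (anyDuplicated(key))
      stop("duplicate (ex,em) pair: ", key[anyDuplicated(key)])
    ex <- sort(unique(df$ex)); em <- sort(unique(df$em))
    intensity <- matrix(0, length(ex), length(em))
    mask <- matrix(TRUE, length(ex), length(em))
    i <- match(df$ex, ex); j <- match(df$em, em)
    intensity[cbind(i, j)] <- df$intensity
    mask[cbind(i, j)] <- FALSE
    eem(sample_id, ex, em, intensity, units = units,
        dilution_factor = dilution, mask = if (any(mask)) mask else NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an EEM to CSV
#'
#' Inverse of [read_eem]. Masked cells are written as empty fields (wide
#' dialect) or omitted rows (long dialect); metadata goes to a JSON sidecar.
#'
#' @param x An [eem] object.
#' @param path Output CSV path.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return Invisibly, `path`.
#' @export
write_eem <- function(x, path, dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  validate_eem(x)
  if (dialect == "wide_csv") {
    chr <- matrix(format_num(x$intensity), nrow = nrow(x$intensity))
    if (!is.null(x$mask)) chr[x$mask] <- ""
    lines <- c(paste(c("ex_nm", format_num(x$em)), collapse = ","),
               vapply(seq_along(x$ex), function(i)
                 paste(c(format_num(x$ex[i]), chr[i, ]), collapse = ","),
                 character(1)))
    writeLines(lines, path)
  } else {
    keep <- if (is.null(x$mask)) rep(TRUE, length(x$intensity)) else !x$mask
    idx <- which(keep, arr.ind = TRUE)
    df <- data.frame(ex = x$ex[idx[, 1]], em = x$em[idx[, 2]],
                     intensity = x$intensity[idx])
    df <- df[order(df$ex, df$em), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  write_sidecar(path, list(sample_id = x$sample_id, units = x$units,
                           dilution_factor = x$dilution_factor))
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)

# ---- EIS / UV / sample table ------------------------------------------------

#' Read an EIS Bode-phase spectrum from CSV
#'
#' Expects columns `frequency_hz,phase_deg` and optionally `magnitude_ohm`.
#' Rows are sorted by ascending frequency (phase stays paired). A JSON
#' sidecar may carry `sample_id` and `replicate`.
#'
#' @param path CSV file path.
#' @return An [eis_spectrum].
#' @export
read_eis <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("frequency_hz", "phase_deg") %in% names(df)))
    stop("EIS CSV must have columns frequency_hz,phase_deg")
  meta <- read_sidecar(path)
  eis_spectrum(meta$sample_id %||% sub("\\.[^.]+$", "", basename(path)),
               df$frequency_hz, df$phase_deg,
               magnitude = df$magnitude_ohm,
               replicate = meta$replicate %||% 1L)
}

#' @rdname read_eis
#' @param x An [eis_spectrum].
#' @export
write_eis <- function(x, path) {
  df <- data.frame(frequency_hz = x$freq, phase_deg = x$phase)
  if (!is.null(x$magnitude)) df$magnitude_ohm <- x$magnitude
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(sample_id = x$sample_id, replicate = x$replicate))
  invisible(path)
}

#' Read/write a UV-Vis absorption spectrum (CSV columns `wavelength_nm,absorbance`)
#'
#' @param path CSV file path.
#' @return [read_uv] returns a [uv_spectrum].
#' @export
read_uv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df)))
    stop("UV CSV must have columns wavelength_nm,absorbance")
  meta <- read_sidecar(path)
  ord <- order(df$wavelength_nm)
  uv_spectrum(meta$sample_id %||% sub("\\.[^.]+$", "", basename(path)),
              df$wavelength_nm[ord], df$absorbance[ord])
}

#' @rdname read_uv
#' @param x A [uv_spectrum].
#' @export
write_uv <- function(x, path) {
  utils::write.csv(data.frame(wavelength_nm = x$wl, absorbance = x$absorbance),
                   path, row.names = FALSE)
  write_sidecar(path, list(sample_id = x$sample_id))
  invisible(path)
}

#' Read the in-situ sample table
#'
#' CSV with header `sample_id,temperature_c,ph,conductivity_us` holding the
#' physicochemical parameters measured at sampling (temperature in deg C, pH,
#' conductivity in uS/cm). Missing values are kept as `NA` and flagged with a
#' warning, never dropped. pH outside \[0, 14\] or negative conductivity is a
#' validation error.
#'
#' @param path CSV file path.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = c(sample_id = "character"))
  need <- c("sample_id", "temperature_c", "ph", "conductivity_us")
  if (!all(need %in% names(df)))
    stop("sample table must have header sample_id,temperature_c,ph,conductivity_us")
  df <- df[, need]
  validate_sample_table(df)
  df
}

validate_sample_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$ph < 0 | df$ph > 14, na.rm = TRUE))
    stop("pH outside [0, 14] for sample(s): ",
         paste(df$sample_id[which(df$ph < 0 | df$ph > 14)], collapse = ", "))
  if (any(df$conductivity_us < 0, na.rm = TRUE))
    stop("negative conductivity for sample(s): ",
         paste(df$sample_id[which(df$conductivity_us < 0)], collapse = ", "))
  nas <- which(!stats::complete.cases(df))
  if (length(nas) > 0)
    warning("missing values in sample table row(s): ",
            paste(df$sample_id[nas], collapse = ", "))
  invisible(df)
}

#' @rdname read_sample_table
#' @param df Sample table `data.frame`.
#' @export
write_sample_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- model result exports ---------------------------------------------------

#' Export fitted model objects as JSON
#'
#' Serializes an MCR-ALS result or a PCA model to a single JSON file so runs
#' can be archived and compared without R.
#'
#' @param x An `mcr_result` or `pca_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
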