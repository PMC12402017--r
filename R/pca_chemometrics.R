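#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with an odd window. At the
#' edges the window shrinks symmetrically around the evaluated point (the
#' polynomial degree shrinks with it if needed), so the filter stays
#' centered everywhere and a constant signal passes through unchanged.
#' Order 0 is a centered moving average.
#'
#' @param x Numeric signal, at least `window` points long.
#' @param order Polynomial order (default 0).
#' @param window Odd window length (default 15), greater than `order`.
#' @return The smoothed signal, same length as `x`.
#' @export
savitzky_golay <- function(x, order = 0, window = 15) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= order) stop("window must exceed the polynomial order")
  if (n < window) stop("signal shorter than the window")
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    idx <- (i - hi):(i + hi)
    p <- min(order, length(idx) - 1)
    if (p == 0) {
      out[i] <- mean(x[idx])
    } else {
      t <- idx - i
      X <- outer(t, 0:p, `^`)
      out[i] <- qr.coef(qr(X), x[idx])[1]
    }
  }
  out
}

#' Assemble the EIS design matrix
#'
#' Interpolates each Bode-phase spectrum onto a common `n_points`-point
#' log10-spaced frequency grid over `[fmin, fmax]` (linear interpolation in
#' log10 frequency; phase values themselves are untouched) and stacks the
#' spectra as rows, sample-major then by replicate. With the defaults and
#' the five-sample duplicate design this is the 10 x 500 matrix analyzed
#' by PCA. Optionally applies Savitzky-Golay smoothing (0th order, 15
#' points) per row.
#'
#' @param spectra List of [eis_spectrum]; each must cover `[fmin, fmax]`.
#' @param fmin,fmax Frequency range (Hz).
#' @param n_points Number of grid columns.
#' @param smooth Apply Savitzky-Golay smoothing per row?
#' @param sg_order,sg_window Smoothing parameters.
#' @return Numeric matrix with rownames `"<sample>_<replicate>"` and the
#'   target grid in attribute `"freq"`.
#' @export
assemble_eis_matrix <- function(spectra, fmin = 0.1, fmax = 20000,
                                n_points = 500, smooth = FALSE,
                                sg_order = 0, sg_window = 15) {
  target <- 10^seq(log10(fmin), log10(fmax), length.out = n_points)
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  reps <- vapply(spectra, `[[`, integer(1), "replicate")
  ord <- order(match(ids, unique(ids)), reps)
  spectra <- spectra[ord]
  rows <- lapply(spectra, function(s) {
    rel <- 1e-9
    if (min(s$freq) > fmin * (1 + rel) || max(s$freq) < fmax * (1 - rel))
      stop(sprintf("spectrum %s does not cover [%g, %g] Hz",
                   s$sample_id, fmin, fmax))
    y <- stats::approx(log10(s$freq), s$phase, xout = log10(target),
                       rule = 2)$y
    if (smooth) savitzky_golay(y, sg_order, sg_window) else y
  })
  out <- do.call(rbind, rows)
  rownames(out) <- paste0(vapply(spectra, `[[`, character(1), "sample_id"),
                          "_", vapply(spectra, `[[`, integer(1), "replicate"))
  attr(out, "freq") <- target
  out
}

#' Principal component analysis via SVD
#'
#' Fits the bilinear model `D = T P^T + E` after mean-centering or
#' autoscaling (centering plus division by the column sample standard
#' deviation, n-1 denominator). Scores are `U Sigma`, loadings the right
#' singular vectors (orthonormal columns); per-component explained
#' variance is `sigma_i^2 / sum(sigma^2) * 100` over all components of the
#' preprocessed matrix. The sign convention is deterministic: each loading
#' column's largest-magnitude entry is positive (score signs in published
#' plots are convention-dependent, so flip freely when comparing).
#'
#' @param D Numeric matrix, rows = samples (>= 2).
#' @param preprocessing `"center"` or `"autoscale"`.
#' @param nc_kept Number of components to keep.
#' @return An object of class `"pca_model"`: `T` (scores), `P` (loadings),
#'   `explained` (all components, percent, non-increasing),
#'   `total_explained` (kept components), `center`, `scale`,
#'   `preprocessing`, `row_labels`, `var_labels`.
#' @export
fit_pca <- function(D, preprocessing = c("center", "autoscale"),
                    nc_kept = 2) {
  preprocessing <- match.arg(preprocessing)
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("PCA needs at least 2 rows")
  mu <- colMeans(D)
  X <- sweep(D, 2, mu)
  sc <- rep(1, ncol(D))
  if (preprocessing == "autoscale") {
    sc <- apply(D, 2, stats::sd)
    zero <- which(sc == 0)
    if (length(zero) > 0)
      stop("zero-variance column(s) under autoscaling: ",
           paste(colnames(D)[zero] %||% zero, collapse = ", "))
    X <- sweep(X, 2, sc, "/")
  }
  nc_max <- min(dim(X))
  if (nc_kept < 1 || nc_kept > nc_max)
    stop("nc_kept must be between 1 and ", nc_max)
  sv <- svd(X)
  explained <- sv$d^2 / sum(sv$d^2) * 100
  Tm <- sv$u[, seq_len(nc_kept), drop = FALSE] %*%
    diag(sv$d[seq_len(nc_kept)], nc_kept)
  P <- sv$v[, seq_len(nc_kept), drop = FALSE]
  for (j in seq_len(nc_kept)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) {
      P[, j] <- -P[, j]
      Tm[, j] <- -Tm[, j]
    }
  }
  rownames(Tm) <- rownames(D)
  rownames(P) <- colnames(D)
  colnames(Tm) <- colnames(P) <- paste0("PC", seq_len(nc_kept))
  structure(list(T = Tm, P = P, explained = explained,
                 total_explained = sum(explained[seq_len(nc_kept)]),
                 center = mu, scale = sc, preprocessing = preprocessing,
                 row_labels = rownames(D), var_labels = colnames(D)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$T)
  cat(sprintf("<pca_model> %d x %d, %s, %d PCs kept (%.1f%% total: %s)\n",
              nrow(x$T), length(x$center), x$preprocessing, k,
              x$total_explained,
              paste(sprintf("%.1f%%", x$explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Average PCA scores across replicates
#'
#' Collapses replicate rows of a score matrix to per-sample means. Sample
#' order follows first appearance; an unpaired replicate triggers a warning
#' and its single value is used.
#'
#' @param model A [fit_pca] model (or a plain score matrix).
#' @param sample_ids Character vector assigning each score row to a sample;
#'   defaults to the part of the model's row labels before the last `"_"`.
#' @return Matrix of per-sample mean scores.
#' @export
average_replicate_scores <- function(model, sample_ids = NULL) {
  Tm <- if (inherits(model, "pca_model")) model$T else as.matrix(model)
  if (is.null(sample_ids)) {
    if (is.null(rownames(Tm))) stop("sample_ids required when rows are unlabeled")
    sample_ids <- sub("_[^_]*$", "", rownames(Tm))
  }
  if (length(sample_ids) != nrow(Tm))
    stop("sample_ids must label every score row")
  f <- factor(sample_ids, levels = unique(sample_ids))
  counts <- table(f)
  if (any(counts == 1))
    warning("unpaired replicate(s): ",
            paste(names(counts)[counts == 1], collapse = ", "))
  out <- rowsum(Tm, f) / as.vector(counts)
  rownames(out) <- levels(f)
  out
}
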