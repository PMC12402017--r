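#' Gaussian spectral profile
#'
#' Unimodal Gaussian band shape on a wavelength grid, peak-normalized so the
#' grid point nearest `center` has value 1. Shapes are Gaussian in wavelength
#' (not wavenumber), which matches visual EEM peak shapes at this grid
#' resolution.
#'
#' @param center Band center (nm).
#' @param sigma Band standard deviation (nm), > 0.
#' @param grid Wavelength grid (nm).
#' @return Nonnegative vector with maximum 1.
#' @export
gaussian_profile <- function(center, sigma, grid) {
  stopifnot(sigma > 0)
  if (center < min(grid) || center > max(grid))
    warning(sprintf("band center %g nm lies outside grid [%g, %g]",
                    center, min(grid), max(grid)))
  y <- exp(-0.5 * ((grid - center) / sigma)^2)
  peak <- y[which.min(abs(grid - center))]
  if (peak > 0) y / peak else y
}

#' Fluorophore component specification
#'
#' Spectral description of one fluorophore: main excitation band, emission
#' band, and an optional secondary excitation shoulder in the deep UV (the
#' "< 260 nm" shoulder typical of humic and protein-like DOM fluorophores).
#'
#' @param name Component label.
#' @param ex_center,em_center Main band centers (nm); the Stokes shift
#'   `em_center - ex_center` must be positive.
#' @param ex_sigma,em_sigma Band widths (nm), > 0.
#' @param secondary_ex_center Optional secondary excitation center (nm) or
#'   `NULL`; modeled at half the main amplitude.
#' @return An object of class `"component_spec"`.
#' @export
component_spec <- function(name, ex_center, ex_sigma, em_center, em_sigma,
                           secondary_ex_center = NULL) {
  stopifnot(ex_sigma > 0, em_sigma > 0)
  if (em_center <= ex_center)
    stop("Stokes shift must be positive (em_center > ex_center)")
  structure(list(name = name, ex_center = ex_center, ex_sigma = ex_sigma,
                 em_center = em_center, em_sigma = em_sigma,
                 secondary_ex_center = secondary_ex_center),
            class = "component_spec")
}

#' Default six-fluorophore DOM component library
#'
#' Six Gaussian fluorophores at the excitation/emission peak positions of the
#' DOM fractions routinely resolved in river-water EEMs: three humic-like
#' components (C1 340/474, C2 350/430, C3 320/399 nm) and three protein-like
#' components (C4 tryptophan-like 300/354, C5 tryptophan-like 280/338,
#' C6 tyrosine-like 270/294 nm). Each carries a secondary excitation shoulder
#' at 245 nm (half the main amplitude). Default band widths are 20 nm
#' (excitation) and 30 nm (emission).
#'
#' @return List of six [component_spec] objects.
#' @export
default_component_library <- function() {
  centers <- list(C1 = c(340, 474), C2 = c(350, 430), C3 = c(320, 399),
                  C4 = c(300, 354), C5 = c(280, 338), C6 = c(270, 294))
  lapply(names(centers), function(nm)
    component_spec(nm, centers[[nm]][1], 20, centers[[nm]][2], 30,
                   secondary_ex_center = 245)) |>
    stats::setNames(names(centers))
}

#' Spectral profiles of a component library on given grids
#'
#' Builds the common excitation and emission factor matrices implied by a
#' list of [component_spec]s: `S_ex` (|ex| x nc) and `S_em` (nc x |em|),
#' each profile peak-normalized to 1. The secondary excitation shoulder is
#' added as a second Gaussian at half the main amplitude before
#' renormalization.
#'
#' @param components List of [component_spec].
#' @param ex,em Wavelength grids (nm).
#' @return List with elements `S_ex`, `S_em` and `names`.
#' @export
component_profiles <- function(components, ex = std_ex_grid(),
                               em = std_em_grid()) {
  nc <- length(components)
  S_ex <- matrix(0, length(ex), nc)
  S_em <- matrix(0, nc, length(em))
  for (j in seq_len(nc)) {
    cs <- components[[j]]
    p <- gaussian_profile(cs$ex_center, cs$ex_sigma, ex)
    if (!is.null(cs$secondary_ex_center))
      p <- p + 0.5 * suppressWarnings(
        gaussian_profile(cs$secondary_ex_center, cs$ex_sigma, ex))
    S_ex[, j] <- p / max(p)
    S_em[j, ] <- gaussian_profile(cs$em_center, cs$em_sigma, em)
  }
  list(S_ex = S_ex, S_em = S_em,
       names = vapply(components, `[[`, character(1), "name"))
}

#' Ground truth of a synthetic campaign
#'
#' Holds everything needed to reconstruct a noise-free campaign: the
#' component library, the K x nc nonnegative contribution matrix, the noise
#' level, the seed, and per-sample equivalent-circuit parameters for the EIS
#' generator.
#'
#' @param components List of [component_spec].
#' @param C_true Nonnegative K x nc matrix of per-sample contributions
#'   (rownames = sample ids).
#' @param noise_sigma Gaussian noise s.d. in intensity units. The package
#'   default elsewhere is 1% of the clean stack's maximum intensity.
#' @param seed Integer seed.
#' @param eis_params Optional `data.frame` with columns
#'   `sample_id, R_s, R_ct, tau, alpha` (ohm, ohm, s, unitless).
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(components, C_true, noise_sigma = 0, seed = 1L,
                            eis_params = NULL) {
  C_true <- as.matrix(C_true)
  if (ncol(C_true) != length(components))
    stop("C_true must have one column per component")
  if (any(C_true < 0)) stop("C_true must be nonnegative")
  if (!is.null(eis_params) && any(eis_params$alpha <= 0 | eis_params$alpha > 1))
    stop("alpha must lie in (0, 1]")
  structure(list(components = components, C_true = C_true,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 eis_params = eis_params),
            class = "synthetic_truth")
}

#' Add Rayleigh and Raman scatter ridges to an EEM
#'
#' Injects the three scatter features a fluorometer records and a
#' preprocessing chain must excise: first-order Rayleigh (em = ex),
#' second-order Rayleigh (em = 2 ex), and the water Raman band at a
#' wavenumber shift of 3400 cm^-1, i.e. emission satisfying
#' 1/lambda_em = 1/lambda_ex - 3400e-7 nm^-1. Each ridge is a Gaussian in
#' emission around its center line.
#'
#' @param x An [eem].
#' @param rayleigh_width,raman_width Gaussian widths (nm), > 0.
#' @param amplitude Peak ridge intensity added (same units as the EEM).
#' @return The EEM with ridges added.
#' @export
simulate_scatter_ridges <- function(x, rayleigh_width = 4, raman_width = 3,
                                    amplitude = NULL) {
  stopifnot(rayleigh_width > 0, raman_width > 0)
  if (is.null(amplitude))
    amplitude <- max(2 * max(x$intensity), 1)
  ridge <- matrix(0, length(x$ex), length(x$em))
  for (i in seq_along(x$ex)) {
    exi <- x$ex[i]
    ridge[i, ] <- amplitude * (
      exp(-0.5 * ((x$em - exi) / rayleigh_width)^2) +
      0.6 * exp(-0.5 * ((x$em - 2 * exi) / rayleigh_width)^2) +
      0.3 * exp(-0.5 * ((x$em - raman_emission(exi)) / raman_width)^2))
  }
  x$intensity <- x$intensity + ridge
  x
}

#' Emission wavelength of the water Raman band
#'
#' @param ex Excitation wavelength (nm).
#' @param shift Raman shift (cm^-1), 3400 for the water OH stretch.
#' @return Emission wavelength (nm).
#' @export
raman_emission <- function(ex, shift = 3400) {
  1 / (1 / ex - shift * 1e-7)
}

#' Simulate a trilinear EEM stack
#'
#' Builds K sample EEMs from the stored truth according to the trilinear
#' model `D_k = S_ex C_k S_em^T + E_k`: common excitation and emission
#' profiles across samples, sample-specific diagonal contribution matrices.
#' Optionally adds scatter ridges and i.i.d. Gaussian noise (clipped at 0).
#'
#' @param truth A [synthetic_truth].
#' @param add_scatter Add Rayleigh/Raman ridges?
#' @param background Constant instrument background added to every cell
#'   (stray light / dark counts), default 0.
#' @param ex,em Acquisition grids.
#' @param units Units recorded on the generated EEMs.
#' @return List with `stack` (an [eem_stack]) and `truth`.
#' @export
simulate_eem_stack <- function(truth, add_scatter = FALSE, background = 0,
                               ex = std_ex_grid(), em = std_em_grid(),
                               units = "QSU") {
  prof <- component_profiles(truth$components, ex, em)
  K <- nrow(truth$C_true)
  ids <- rownames(truth$C_true) %||% paste0("S", seq_len(K))
  set.seed(truth$seed)
  eems <- lapply(seq_len(K), function(k) {
    D <- prof$S_ex %*% diag(truth$C_true[k, ], nrow = ncol(truth$C_true)) %*%
      prof$S_em + background
    e <- eem(ids[k], ex, em, D, units = units)
    if (add_scatter)
      e <- simulate_scatter_ridges(e)
    if (truth$noise_sigma > 0)
      e$intensity <- e$intensity +
        matrix(stats::rnorm(length(D), 0, truth$noise_sigma), nrow(D))
    e$intensity[e$intensity < 0] <- 0
    e
  })
  list(stack = eem_stack(eems), truth = truth)
}

#' Simulate an EIS Bode-phase spectrum from a Cole-type circuit
#'
#' Single-dispersion Cole element in series with the solution resistance:
#' `Z(w) = R_s + R_ct / (1 + (i w tau)^alpha)`; the reported phase is
#' `arg Z` in degrees, which lies in \[-90, 0\] for positive parameters.
#' The default frequency grid is 500 points log-spaced over 0.1--20,000 Hz.
#'
#' @param R_s Solution (series) resistance (ohm), > 0.
#' @param R_ct Charge-transfer resistance (ohm), > 0.
#' @param tau Dispersion time constant (s), > 0.
#' @param alpha Dispersion exponent in (0, 1]; 1 is an ideal RC.
#' @param freq Frequency grid (Hz); defaults to [eis_default_grid()].
#' @param sample_id,replicate Labels for the returned spectrum.
#' @param noise_sd Gaussian phase noise s.d. (degrees); 0 = noiseless.
#' @return An [eis_spectrum].
#' @export
simulate_eis <- function(R_s, R_ct, tau, alpha, freq = eis_default_grid(),
                         sample_id = "sim", replicate = 1L, noise_sd = 0) {
  if (R_s <= 0 || R_ct <= 0 || tau <= 0)
    stop("R_s, R_ct and tau must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  w <- 2 * pi * freq
  Z <- R_s + R_ct / (1 + (1i * w * tau)^alpha)
  phase <- Arg(Z) * 180 / pi
  if (noise_sd > 0)
    phase <- pmin(pmax(phase + stats::rnorm(length(phase), 0, noise_sd), -90), 90)
  eis_spectrum(sample_id, freq, phase, magnitude = Mod(Z),
               replicate = replicate)
}

#' @rdname simulate_eis
#' @param fmin,fmax Frequency range (Hz).
#' @param n Number of grid points.
#' @export
eis_default_grid <- function(fmin = 0.1, fmax = 20000, n = 500) {
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

#' Simulate a full sampling campaign
#'
#' Generates the complete multi-technique dataset the package analyzes:
#' a K-sample EEM stack obeying the trilinear model (K = `n_rivers` + one
#' DOM-free blank), UV-Vis spectra whose 254 nm absorbance tracks the DOM
#' gradient, an in-situ sample table whose conductivity increases
#' monotonically with DOM load, and duplicate EIS spectra for a five-sample
#' subset (the blank plus four rivers), all tied to a stored ground truth.
#'
#' DOM load drives everything: humic-like contributions scale with load,
#' protein-like contributions scale with load plus a baseline; uv254 is an
#' affine function of load; the Cole-circuit series resistance maps
#' inversely to conductivity and the dispersion exponent alpha decreases
#' with load (DOM-free water is the most ideally capacitive). Samples whose
#' undiluted A254 exceeds `ife_threshold` are "measured diluted": their EEMs
#' carry the dilution factor suggested by [inner_filter_screen] and scaled
#' intensities, for the preprocessing chain to undo. Noise is added to the
#' measured (diluted) stack — its default level, 1% of that stack's clean
#' maximum, is what the instrument sees — while the returned truth stores
#' the undiluted contributions.
#'
#' @param n_rivers Number of river samples (default 9).
#' @param dom_gradient Relative DOM load per river (>= 0); the blank is
#'   appended with load 0. Default: an altitude-like gradient over 9 rivers
#'   in which exactly the three highest-load rivers exceed the inner-filter
#'   threshold.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param noise_sigma EEM noise s.d. (QSU); `NULL` = 1% of the clean stack
#'   maximum.
#' @param add_scatter Add scatter ridges to the EEMs?
#' @param eis_subset Sample ids measured by EIS (default the blank + rivers
#'   3, 5, 6, 9, matching the five-sample study design).
#' @param ife_threshold A254 above which a sample is measured diluted.
#' @return List with `stack`, `uv` (list of [uv_spectrum]), `samples`
#'   (sample table), `eis` (list of [eis_spectrum], 2 replicates per subset
#'   sample), and `truth` (a [synthetic_truth]).
#' @export
simulate_campaign <- function(n_rivers = 9, dom_gradient = NULL, seed = 1L,
                              noise_sigma = NULL, add_scatter = TRUE,
                              eis_subset = NULL, ife_threshold = 0.05) {
  if (is.null(dom_gradient)) {
    base <- c(0.12, 0.16, 0.45, 0.10, 0.17, 0.19, 0.14, 0.95, 1.00)
    dom_gradient <- if (n_rivers == 9) base else
      seq(0.1, 1, length.out = n_rivers)
  }
  if (length(dom_gradient) != n_rivers)
    stop("dom_gradient must have one entry per river")
  if (any(dom_gradient < 0)) stop("dom_gradient must be >= 0")
  ids <- c(paste0("R", seq_len(n_rivers)), "DOMfree")
  dom <- c(dom_gradient, 0)
  K <- n_rivers + 1

  set.seed(seed)
  comps <- default_component_library()
  nc <- length(comps)
  # humic-like components scale with DOM load; protein-like carry a small
  # baseline on top of the load dependence (autochthonous production)
  base_mix <- c(30, 24, 20, 8, 10, 6)
  # distinct load-response exponents per fraction: terrestrial humics scale
  # ~linearly with DOM load, anthropogenic humic/protein material is
  # concentrated in the impacted (high-load) rivers, microbial fractions
  # are ubiquitous (sublinear). Distinct exponents over distinct loads also
  # keep the contribution columns linearly independent, which the trilinear
  # decomposition needs for an essentially unique solution.
  load_exp <- c(1, 1.3, 0.7, 2, 1.6, 0.5)
  C_true <- matrix(0, K, nc, dimnames = list(ids, names(comps)))
  for (k in seq_len(K)) {
    if (dom[k] > 0) {
      # bounded jitter keeps every fraction well above the noise floor
      jitter <- exp(stats::runif(nc, -0.35, 0.35))
      C_true[k, ] <- base_mix * dom[k]^load_exp * jitter
    }
  }

  # physicochemistry: conductivity and uv254 strictly monotone in DOM load
  uv254 <- 0.25 * dom + 0.002
  cond <- 1.7 + 1620 * dom^2
  temp <- round(8 + 6.5 * dom + stats::runif(K, 0, 0.4), 1)
  temp[K] <- 20  # blank measured at room temperature
  ph <- round(pmin(7.8, pmax(6.7, 7.6 - 0.8 * dom +
                               stats::rnorm(K, 0, 0.1))), 1)
  ph[K] <- 7.7
  samples <- data.frame(sample_id = ids, temperature_c = temp, ph = ph,
                        conductivity_us = round(cond, 1))

  # EIS circuit parameters: R_s inversely proportional to conductivity,
  # alpha decreasing with DOM load (blank = most ideal capacitor)
  # R_s tracks ionic conduction, alpha the dispersion broadening by DOM,
  # tau the slower interfacial relaxation of DOM-loaded water; tau gives
  # the spectra a second, composition-driven variance mode
  eis_params <- data.frame(sample_id = ids,
                           R_s = 5e4 / (1 + cond),
                           R_ct = 1e7,
                           tau = 1e-4 * (1 + 3 * dom / max(dom, 1)),
                           alpha = 0.95 - 0.25 * dom / max(dom, 1))

  # UV spectra: exponential CDOM decay anchored at A254 = uv254
  wl <- seq(190, 1100, by = 1)
  uv <- lapply(seq_len(K), function(k)
    uv_spectrum(ids[k], wl, uv254[k] * exp(-0.018 * (wl - 254))))
  names(uv) <- ids

  # samples over the IFE threshold are measured diluted: the fluorometer
  # sees the diluted sample, so dilution scales the contributions before
  # noise is added, and the noise level refers to the measured stack
  cfg <- preprocess_config(ife_threshold = ife_threshold)
  factors <- vapply(seq_len(K), function(k)
    inner_filter_screen(uv[[k]], cfg)$suggested_factor, numeric(1))
  C_meas <- C_true / factors
  prof <- component_profiles(comps)
  clean_max <- max(vapply(seq_len(K), function(k)
    max(prof$S_ex %*% diag(C_meas[k, ], nc) %*% prof$S_em), numeric(1)))
  if (is.null(noise_sigma)) noise_sigma <- 0.01 * clean_max

  truth_meas <- synthetic_truth(comps, C_meas, noise_sigma = noise_sigma,
                                seed = seed, eis_params = eis_params)
  # small instrument background (stray light); the blank keeps it, river
  # samples lose it again through blank subtraction in preprocessing
  sim <- simulate_eem_stack(truth_meas, add_scatter = add_scatter,
                            background = 0.02 * clean_max)
  stack <- sim$stack
  for (k in seq_len(K))
    stack$samples[[k]]$dilution_factor <- factors[k]
  truth <- synthetic_truth(comps, C_true, noise_sigma = noise_sigma,
                           seed = seed, eis_params = eis_params)

  if (is.null(eis_subset)) {
    cand <- intersect(c("R3", "R5", "R6", "R9"), ids)
    eis_subset <- c("DOMfree", cand[seq_len(min(4, length(cand)))])
  }
  eis <- list()
  for (sid in eis_subset) {
    p <- eis_params[eis_params$sample_id == sid, ]
    for (r in 1:2)
      eis[[paste0(sid, "_", r)]] <-
        simulate_eis(p$R_s, p$R_ct, p$tau, p$alpha, sample_id = sid,
                     replicate = r, noise_sd = 0.2)
  }

  list(stack = stack, uv = uv, samples = samples, eis = eis, truth = truth)
}
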