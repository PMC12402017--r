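test_that("scatter excision masks the Rayleigh and Raman bands and nothing else", {
  x <- random_eem(seed = 2)
  cfg <- preprocess_config(excision_mode = "mask")
  y <- excise_scatter(x, cfg)
  ex <- y$ex; em <- y$em
  expect_true(y$mask[ex == 300, em == 300])   # first-order Rayleigh
  expect_true(y$mask[ex == 260, em == 520])   # second-order Rayleigh
  expect_true(y$mask[ex == 350, em == 397])   # Raman (397.3 nm for ex 350)
  expect_false(y$mask[ex == 340, em == 474])  # a genuine fluorescence peak

  # mask mode never alters cell values
  expect_identical(y$intensity, x$intensity)

  # half-width contract: cells just outside the bands stay unmasked
  expect_false(y$mask[ex == 300, em == 316])  # |316-300| = 16 > 15
  expect_true(y$mask[ex == 300, em == 315])
})

test_that("interpolated cells stay within their bracketing neighbors", {
  x <- random_eem(seed = 7)
  cfg_m <- preprocess_config(excision_mode = "mask")
  cfg_i <- preprocess_config(excision_mode = "interpolate")
  m <- excise_scatter(x, cfg_m)$mask
  y <- excise_scatter(x, cfg_i)
  expect_null(y$mask)
  expect_identical(attr(y, "excised"), m)
  # unmasked cells untouched
  expect_identical(y$intensity[!m], x$intensity[!m])

  # every interior masked run is bounded by its bracketing values
  for (i in seq_along(x$ex)) {
    bad <- which(m[i, ])
    if (length(bad) == 0) next
    runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
    for (r in runs) {
      lo <- min(r) - 1; hi <- max(r) + 1
      if (lo < 1 || hi > ncol(m)) next  # edge runs fill along excitation
      bounds <- range(x$intensity[i, c(lo, hi)])
      expect_true(all(y$intensity[i, r] >= bounds[1] - 1e-12 &
                        y$intensity[i, r] <= bounds[2] + 1e-12))
    }
  }
})

test_that("a fully masked emission row errors in interpolate mode only", {
  x <- random_eem(seed = 8)
  wide <- preprocess_config(rayleigh1_halfwidth = 400,
                            excision_mode = "interpolate")
  expect_error(excise_scatter(x, wide), "fully masked")
  wide_mask <- preprocess_config(rayleigh1_halfwidth = 400,
                                 excision_mode = "mask")
  expect_silent(excise_scatter(x, wide_mask))
})

test_that("default excision removes essentially all injected ridge intensity", {
  tr <- truth3(seed = 4, noise_frac = 0)
  clean <- simulate_eem_stack(tr, add_scatter = FALSE)$stack
  dirty <- simulate_eem_stack(tr, add_scatter = TRUE)$stack
  cfg <- preprocess_config(excision_mode = "mask")
  for (k in c(1, 6)) {
    ridge <- dirty$samples[[k]]$intensity - clean$samples[[k]]$intensity
    m <- excise_scatter(dirty$samples[[k]], cfg)$mask
    expect_gte(sum(ridge[m]) / sum(ridge), 0.99)
  }
})

test_that("inner-filter screening suggests the smallest sufficient power-of-two dilution", {
  wl <- 190:400
  mk <- function(a254) uv_spectrum("s", wl, a254 * exp(-0.018 * (wl - 254)))
  cfg <- preprocess_config(ife_threshold = 0.05)

  d <- inner_filter_screen(mk(0.03), cfg)
  expect_false(d$needs_dilution)
  expect_identical(d$suggested_factor, 1)

  # boundary is inclusive: exactly at threshold needs no dilution
  d <- inner_filter_screen(mk(0.05), cfg)
  expect_false(d$needs_dilution)

  # oracle: smallest 2^n with a254 / 2^n <= threshold, by direct search
  for (a254 in c(0.06, 0.11, 0.30, 0.79, 1.6)) {
    f <- 1
    while (a254 / f > 0.05) f <- f * 2
    d <- inner_filter_screen(mk(a254), cfg)
    expect_true(d$needs_dilution)
    expect_identical(d$suggested_factor, f)
  }
  expect_identical(inner_filter_screen(mk(0.30), cfg)$suggested_factor, 8)

  expect_error(inner_filter_screen(mk(-0.1), cfg), "negative")
})

test_that("dilution back-correction rescales once and only once", {
  x <- flat_eem(2.5)
  expect_identical(apply_dilution_correction(x)$intensity, x$intensity)

  x$dilution_factor <- 4
  y <- apply_dilution_correction(x)
  expect_equal(y$intensity[1, 1], 10.0)
  expect_identical(y$dilution_factor, 1)
  expect_identical(apply_dilution_correction(y)$intensity, y$intensity)
})

test_that("QSU normalization divides by the quinine reference and refuses QSU input", {
  raw <- flat_eem(3)
  raw$units <- "raw"
  cfg <- preprocess_config(qsu_reference_intensity = 3)
  q <- qsu_normalize(raw, cfg)
  expect_identical(q$units, "QSU")
  expect_true(all(q$intensity == 1))

  cfg2 <- preprocess_config(qsu_reference_intensity = 2)
  raw1 <- flat_eem(1); raw1$units <- "raw"
  expect_equal(qsu_normalize(raw1, cfg2)$intensity[1, 1], 0.5)

  zero <- flat_eem(0); zero$units <- "raw"
  expect_true(all(qsu_normalize(zero, cfg)$intensity == 0))

  expect_error(qsu_normalize(q, cfg), "already in QSU")

  # scale invariance: scaling sample and reference together cancels
  raw$units <- "raw"
  scaled <- raw; scaled$intensity <- scaled$intensity * 7
  cfg_s <- preprocess_config(qsu_reference_intensity = 3 * 7)
  expect_equal(qsu_normalize(scaled, cfg_s)$intensity,
               qsu_normalize(raw, cfg)$intensity)
})

test_that("blank subtraction clips at zero and unions masks", {
  x <- random_eem(seed = 5)
  expect_true(all(blank_subtract(x, x)$intensity == 0))

  zero <- flat_eem(0)
  expect_identical(blank_subtract(x, zero)$intensity, x$intensity)

  big <- flat_eem(100)
  expect_true(all(blank_subtract(x, big)$intensity == 0))

  bmask <- matrix(FALSE, 45, 301); bmask[3, 3] <- TRUE
  blank <- flat_eem(0.1); blank$mask <- bmask
  y <- blank_subtract(x, blank)
  expect_true(y$mask[3, 3])

  other <- eem("g", seq(230, 450, 5) + 1, 250:550,
               matrix(0, 45, 301), units = "QSU")
  expect_error(blank_subtract(x, other), "grids differ")
})
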