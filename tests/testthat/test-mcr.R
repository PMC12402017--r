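test_that("explained variance follows the residual-ratio definition exactly", {
  set.seed(1)
  D <- matrix(runif(200, 0, 5), 20, 10)
  expect_equal(explained_variance(D, D), 100)
  expect_equal(explained_variance(D, D * 0), 0)
  # residual sum of squares exactly 1% of the total sum of squares
  Dhat <- D * (1 - sqrt(0.01))
  expect_equal(explained_variance(D, Dhat), 99.0)
  # may be negative for models worse than zero, no clipping
  expect_lt(explained_variance(D, -2 * D), 0)
  expect_error(explained_variance(D * 0, D * 0), "zero")

  # masked cells excluded from both sums
  mask <- matrix(FALSE, 20, 10); mask[1, ] <- TRUE
  Dbad <- D; Dbad[1, ] <- 1e6
  expect_equal(explained_variance(Dbad, D, mask = mask), 100)
})

test_that("SVD rank estimation recovers exact ranks and exposes the scree", {
  s3 <- simulate_eem_stack(truth3(seed = 5, noise_frac = 0))$stack
  est <- estimate_rank(s3)
  expect_identical(est$rank, 3L)

  one <- default_component_library()["C1"]
  t1 <- synthetic_truth(one, matrix(1:10, 10, 1), 0, seed = 2)
  s1 <- simulate_eem_stack(t1)$stack
  expect_identical(estimate_rank(s1)$rank, 1L)

  # with 1% noise the three signal values still dominate the scree:
  # a large gap after the third singular value, near-complete variance
  sn <- simulate_eem_stack(truth3(seed = 5, noise_frac = 0.01))$stack
  scree <- estimate_rank(sn)
  d <- scree$singular_values
  expect_gt(d[3] / d[4], 10)
  expect_gt(scree$cumulative[3], 0.95)

  masked <- eem_stack(lapply(s3$samples, excise_scatter,
                             preprocess_config(excision_mode = "mask")))
  expect_error(estimate_rank(masked), "masked")
  zero <- eem_stack(list(flat_eem(0)))
  expect_error(estimate_rank(zero), "all-zero")
})

test_that("purest-variable selection finds orthogonal pure columns deterministically", {
  # 6-column toy: three mutually orthogonal pure columns + three mixtures
  p1 <- c(5, 5, 5, 0, 0, 0, 0, 0, 0)
  p2 <- c(0, 0, 0, 4, 6, 5, 0, 0, 0)
  p3 <- c(0, 0, 0, 0, 0, 0, 6, 4, 5)
  D <- cbind(p1, p2, p3, (p1 + p2) / 2, (p2 + p3) / 2, (p1 + p2 + p3) / 3)

  sel <- purest_variables(D, 3)
  expect_setequal(sel, 1:3)

  # brute-force oracle: of all 3-subsets, the pure triple maximizes the
  # determinant of the unit-normalized Gram submatrix
  U <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  G <- crossprod(U)
  dets <- combn(6, 3, function(s) det(G[s, s]))
  expect_identical(sort(utils::combn(6, 3)[, which.max(dets)]), 1:3)

  # n = 1 picks the dominant-variance pure column
  expect_identical(purest_variables(cbind(p2, p1 * 0.1), 1), 1L)
  # repeated identical call -> identical indices
  expect_identical(purest_variables(D, 3), sel)
  expect_error(purest_variables(D, 7), "exceeds")
})

test_that("fast NNLS agrees with an independent active-set solver", {
  set.seed(99)
  for (i in 1:25) {
    A <- matrix(rnorm(15 * 4), 15, 4)
    b <- rnorm(15)
    x <- domfuse:::fnnls(crossprod(A), drop(crossprod(A, b)))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(x, ref, tolerance = 1e-8)
    expect_true(all(x >= 0))
  }
})

test_that("noise-free trilinear stacks are recovered essentially exactly", {
  tr <- truth3(seed = 5, noise_frac = 0)
  stack <- simulate_eem_stack(tr)$stack
  fit <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3))
  expect_gte(fit$r2, 99.99)
  m <- match_components(fit, tr)
  expect_true(all(m$similarity >= 0.999))
  expect_true(all(fit$S_ex >= 0) && all(fit$S_em >= 0) && all(fit$C >= 0))
  expect_equal(unname(apply(fit$S_ex, 2, max)), rep(1, 3))
  expect_equal(unname(apply(fit$S_em, 1, max)), rep(1, 3))
  # components ordered by descending total contribution
  expect_true(all(diff(colSums(fit$C)) <= 1e-9))
})

test_that("a rank-1 stack factorizes exactly with contributions matching the scales", {
  one <- default_component_library()["C1"]
  t1 <- synthetic_truth(one, matrix(1:10, 10, 1), 0, seed = 2)
  s1 <- simulate_eem_stack(t1)$stack
  fit <- suppressWarnings(fit_mcr_trilinear(s1, nc = 1))
  expect_equal(fit$r2, 100, tolerance = 1e-6)
  expect_equal(fit$C[, 1] / fit$C[1, 1], 1:10 / 1, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("unconstrained ALS is monotone and the trilinear penalty costs < 0.5 points", {
  tr <- truth3(seed = 8, noise_frac = 0.01)
  stack <- simulate_eem_stack(tr)$stack
  free <- suppressWarnings(
    fit_mcr_trilinear(stack, nc = 3, apply_trilinearity = FALSE))
  # explained variance history non-decreasing (= lack of fit non-increasing)
  expect_true(all(diff(free$history) >= -1e-10 * 100))
  tri <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3))
  expect_gte(tri$r2, free$r2 - 0.5)
  expect_lte(tri$r2, free$r2 + 1e-8)
})

test_that("the sample-mode refolding of every component is rank 1 at exit", {
  tr <- truth3(seed = 8, noise_frac = 0.01)
  stack <- simulate_eem_stack(tr)$stack
  fit <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3))
  for (j in 1:3) {
    block <- fit$S_ex[, j] %o% fit$C[, j]  # 45 x K refolded component
    d <- svd(block, nu = 0, nv = 0)$d
    expect_lte(d[2], 1e-8 * d[1])
  }
})

test_that("different valid initializations recover the same subspace on noise-free data", {
  tr <- truth3(seed = 5, noise_frac = 0)
  stack <- simulate_eem_stack(tr)$stack
  f1 <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3))
  f2 <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3, init = "random",
                                           seed = 77))
  principal_angles <- function(A, B) {
    qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
    acos(pmin(1, svd(crossprod(qa, qb))$d))
  }
  expect_lte(max(principal_angles(f1$S_ex, f2$S_ex)), 1e-3)
  expect_lte(max(principal_angles(t(f1$S_em), t(f2$S_em))), 1e-3)
})

test_that("six-component noisy stacks are recovered with high fidelity", {
  tr <- truth6(seed = 11, noise_frac = 0.01)
  stack <- simulate_eem_stack(tr)$stack
  fit <- suppressWarnings(fit_mcr_trilinear(stack, nc = 6))
  expect_gte(fit$r2, 99)
  m <- match_components(fit, tr)
  expect_true(all(m$similarity >= 0.98))
})

test_that("masked stacks are fitted by weighted least squares that ignores masked cells", {
  tr <- truth3(seed = 13, noise_frac = 0)
  stack <- simulate_eem_stack(tr)$stack
  # corrupt a patch, then mask it: the weighted fit must not see it
  corrupted <- stack$samples
  corrupted[[1]]$intensity[10:12, 50:60] <- 500
  mask <- matrix(FALSE, 45, 301); mask[10:12, 50:60] <- TRUE
  corrupted[[1]]$mask <- mask
  fit <- suppressWarnings(fit_mcr_trilinear(eem_stack(corrupted), nc = 3))
  expect_gte(fit$r2, 99.99)
  m <- match_components(fit, tr)
  expect_true(all(m$similarity >= 0.999))
})

test_that("component matching recovers permutations and flags mismatches", {
  tr <- truth3(seed = 5, noise_frac = 0)
  stack <- simulate_eem_stack(tr)$stack
  fit <- suppressWarnings(fit_mcr_trilinear(stack, nc = 3))
  m <- match_components(fit, tr)
  # a valid one-to-one assignment
  expect_setequal(m$permutation, 1:3)

  # swapping the truth components permutes the assignment accordingly
  tr_swap <- tr
  tr_swap$components <- tr$components[c(2, 1, 3)]
  tr_swap$C_true <- tr$C_true[, c(2, 1, 3)]
  m2 <- match_components(fit, tr_swap)
  expect_identical(m2$permutation[m$permutation == 1], 2L)
  expect_identical(m2$permutation[m$permutation == 2], 1L)
  expect_equal(sort(m2$similarity), sort(m$similarity))

  expect_error(match_components(fit, truth6()), "mismatch")
})

test_that("degenerate inputs are rejected", {
  s <- simulate_eem_stack(truth3(seed = 5))$stack
  expect_error(fit_mcr_trilinear(s, nc = 0), "nc")
  expect_error(fit_mcr_trilinear(s, nc = 100), "dimension")
  expect_error(eem_stack(list()), "empty")
})
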