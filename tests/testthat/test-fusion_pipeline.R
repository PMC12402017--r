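# one full end-to-end run shared by several blocks below
pipe <- suppressWarnings(suppressMessages(run_pipeline(list(seed = 4, nc = 6))))

test_that("uv254 extraction interpolates at 254 nm and undoes dilution", {
  uv <- uv_spectrum("s", 190:400, rep(0.12, 211))
  expect_equal(extract_uv254(uv), 0.12)
  expect_equal(extract_uv254(uv, dilution_factor = 2), 0.24)

  coarse <- uv_spectrum("c", c(250, 260), c(0.1, 0.2))
  expect_equal(extract_uv254(coarse), 0.14)  # hand interpolation

  out <- uv_spectrum("o", 300:400, rep(0.1, 101))
  expect_error(extract_uv254(out), "254")
})

test_that("the fused table has the fixed 16-column multi-block layout", {
  fused <- pipe$fused
  expect_identical(dim(fused), c(5L, 16L))
  expect_identical(colnames(fused)[1:10],
                   c("Temp", "pH", "Cond", "EISpc1", "EISpc2", "uv254",
                     "FI", "HIX", "BIX", "PeakCT"))
  expect_identical(colnames(fused)[11:16], paste0("C", 1:6))
  blocks <- attr(fused, "blocks")
  expect_identical(lengths(blocks), c(par = 3L, eis = 2L, uv = 1L,
                                      idx = 4L, frac = 6L))
  expect_setequal(rownames(fused), c("DOMfree", "R3", "R5", "R6", "R9"))
  expect_false(anyNA(as.matrix(fused)))
})

test_that("a sample missing from one block is reported by name", {
  fused <- pipe$fused
  samples <- pipe$campaign$samples
  sub <- samples[samples$sample_id %in% rownames(fused), ]
  idx <- pipe$indices[pipe$indices$sample_id %in% rownames(fused), ]
  uv254 <- pipe$uv254[rownames(fused)]
  frac <- pipe$mcr$C[rownames(fused), ]
  expect_s3_class(build_fused_table(sub, pipe$eis_scores, uv254, idx, frac),
                  "fused_table")
  expect_error(
    build_fused_table(sub, pipe$eis_scores, uv254,
                      idx[idx$sample_id != "R5", ], frac),
    "R5")
})

test_that("the global PCA autoscales the fused table and exports biplot data", {
  g <- pipe$global_pca
  expect_identical(g$model$preprocessing, "autoscale")
  # autoscaled columns: mean 0, sd 1 with the n-1 denominator
  X <- sweep(sweep(as.matrix(pipe$fused), 2, g$model$center), 2,
             g$model$scale, "/")
  expect_equal(unname(colMeans(X)), rep(0, 16), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, stats::sd)), rep(1, 16),
               tolerance = 1e-12)
  expect_identical(nrow(g$biplot$scores), 5L)
  expect_identical(nrow(g$biplot$loadings), 16L)
  # column count contract: 3 + (EIS PCs kept) + 1 + 4 + nc
  expect_identical(ncol(pipe$fused), 3L + 2L + 1L + 4L + 6L)
})

test_that("DOM-load variables load with a common sign on PC1 and the extremes separate", {
  P <- pipe$global_pca$model$P
  load_vars <- c("uv254", "Cond", paste0("C", 1:6))
  signs <- sign(P[load_vars, 1])
  expect_true(all(signs == signs[1]))

  # the blank and the highest-DOM river occupy opposite PC1 extremes
  sc <- pipe$global_pca$model$T[, 1]
  sc_aligned <- sc * signs[1]  # align so DOM load points positive
  expect_identical(names(which.max(sc_aligned)), "R9")
  expect_identical(names(which.min(sc_aligned)), "DOMfree")
})

test_that("global PCA is invariant to the ordering of samples in the blocks", {
  fused <- pipe$fused
  perm <- c(3, 1, 5, 2, 4)
  reordered <- fused[perm, ]
  attr(reordered, "blocks") <- attr(fused, "blocks")
  g1 <- run_global_pca(fused)
  g2 <- run_global_pca(reordered)
  expect_equal(g1$model$explained, g2$model$explained, tolerance = 1e-10)
  expect_equal(g1$model$T[rownames(fused), ], g2$model$T[rownames(fused), ],
               tolerance = 1e-9)
})

test_that("pipeline runs are reproducible and survive a write/read round trip", {
  pipe2 <- suppressWarnings(suppressMessages(run_pipeline(list(seed = 4,
                                                               nc = 6))))
  expect_equal(as.matrix(pipe$fused), as.matrix(pipe2$fused),
               tolerance = 1e-12)
  expect_identical(pipe$mcr$r2, pipe2$mcr$r2)

  # artifacts and campaign round trip
  dir <- withr::local_tempdir()
  write_campaign(pipe$campaign, file.path(dir, "camp"))
  back <- read_campaign(file.path(dir, "camp"))
  expect_equal(stack_matrix(back$stack), stack_matrix(pipe$campaign$stack),
               tolerance = 1e-12)
  expect_identical(back$samples, pipe$campaign$samples)
  expect_length(back$eis, 10)
})

test_that("a campaign without EIS spectra completes with the fusion stage skipped", {
  camp <- simulate_campaign(seed = 4, n_rivers = 3,
                            dom_gradient = c(0.3, 0.6, 1),
                            eis_subset = character(0))
  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  expect_warning(
    out <- suppressMessages(run_pipeline(list(input_dir = dir, nc = 3))),
    "skipped")
  expect_null(out$fused)
  expect_null(out$global_pca)
  expect_identical(nrow(out$indices), 4L)
  expect_identical(ncol(out$mcr$S_ex), 3L)
})

test_that("run artifacts include the fit report and stage log", {
  dir <- withr::local_tempdir()
  domfuse:::write_run_artifacts(pipe, dir)
  expect_true(file.exists(file.path(dir, "indices.csv")))
  expect_true(file.exists(file.path(dir, "fused_table.csv")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_identical(rep$nc, 6L)
  expect_gt(rep$mcr_r2, 99)
  expect_true(any(grepl("MCR-ALS", readLines(file.path(dir, "run.log")))))
})
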