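#' Absorbance at 254 nm
#'
#' Reads A254 off a UV-Vis spectrum (linear interpolation if 254 nm is not
#' a grid point) and multiplies by the dilution factor to report the
#' undiluted value. uv254 is the standard bulk proxy for DOM aromaticity
#' and load.
#'
#' @param uv A [uv_spectrum] whose grid covers 254 nm.
#' @param dilution_factor Dilution applied before measurement.
#' @return Undiluted absorbance at 254 nm.
#' @export
extract_uv254 <- function(uv, dilution_factor = 1) {
  if (min(uv$wl) > 254 || max(uv$wl) < 254)
    stop("UV grid does not cover 254 nm")
  stats::approx(uv$wl, uv$absorbance, xout = 254)$y * dilution_factor
}

#' Build the fused multi-block variable table
#'
#' Horizontally concatenates the five blocks of the data-fusion design into
#' one table with a fixed column order: physicochemical parameters
#' (`Temp, pH, Cond`), averaged EIS PCA scores (`EISpc1, EISpc2`), `uv254`,
#' fluorescence indices (`FI, HIX, BIX, PeakCT`) and the resolved DOM
#' fraction contributions (`C1..Cnc`). With 2 EIS components and 6 MCR
#' components this is the 5 x 16 table (block sizes 3+2+1+4+6) used for
#' the global PCA. All blocks must cover exactly the same samples.
#'
#' @param samples Sample table (`sample_id, temperature_c, ph,
#'   conductivity_us`) for the fused subset; its row order defines the
#'   table's row order.
#' @param eis_scores Matrix of averaged EIS scores, rownames = sample ids.
#' @param uv254 Named numeric vector of undiluted A254 values.
#' @param idx Index table from [index_table].
#' @param frac Contribution matrix `C` from an `mcr_result` (rows named by
#'   sample), or the `mcr_result` itself.
#' @return A `data.frame` of class `"fused_table"` with a `"blocks"`
#'   attribute recording each block's columns.
#' @export
build_fused_table <- function(samples, eis_scores, uv254, idx, frac) {
  if (inherits(frac, "mcr_result")) frac <- frac$C
  ids <- samples$sample_id
  check_cover <- function(block_ids, name) {
    miss <- setdiff(ids, block_ids)
    extra <- setdiff(block_ids, ids)
    if (length(miss) > 0 || length(extra) > 0)
      stop(sprintf("sample mismatch in block '%s': missing [%s], extra [%s]",
                   name, paste(miss, collapse = ", "),
                   paste(extra, collapse = ", ")))
  }
  check_cover(rownames(eis_scores), "eis_scores")
  check_cover(names(uv254), "uv254")
  check_cover(idx$sample_id, "indices")
  check_cover(rownames(frac), "fractions")
  eis_scores <- eis_scores[ids, , drop = FALSE]
  frac <- frac[ids, , drop = FALSE]
  idx <- idx[match(ids, idx$sample_id), ]
  out <- data.frame(Temp = samples$temperature_c, pH = samples$ph,
                    Cond = samples$conductivity_us,
                    EISpc1 = eis_scores[, 1], EISpc2 = eis_scores[, 2],
                    uv254 = unname(uv254[ids]),
                    FI = idx$fi, HIX = idx$hix, BIX = idx$bix,
                    PeakCT = idx$peak_ct,
                    row.names = ids, check.names = FALSE)
  fr <- as.data.frame(frac)
  colnames(fr) <- paste0("C", seq_len(ncol(frac)))
  out <- cbind(out, fr)
  attr(out, "blocks") <- list(par = c("Temp", "pH", "Cond"),
                              eis = c("EISpc1", "EISpc2"),
                              uv = "uv254",
                              idx = c("FI", "HIX", "BIX", "PeakCT"),
                              frac = colnames(fr))
  class(out) <- c("fused_table", "data.frame")
  out
}

#' Global PCA of the fused table
#'
#' Autoscales the fused table (mean 0, sd 1 per column, n-1 denominator)
#' and fits a PCA, returning the model together with biplot data (sample
#' scores and variable loadings on common axes).
#'
#' @param table A [build_fused_table] result.
#' @param nc_kept Number of components, default 2.
#' @return List with `model` (a `pca_model`) and `biplot`
#'   (`scores`, `loadings` data.frames).
#' @export
run_global_pca <- function(table, nc_kept = 2) {
  model <- fit_pca(as.matrix(table), preprocessing = "autoscale",
                   nc_kept = nc_kept)
  list(model = model,
       biplot = list(
         scores = data.frame(sample = rownames(model$T), model$T,
                             row.names = NULL),
         loadings = data.frame(variable = rownames(model$P), model$P,
                               row.names = NULL)))
}

#' Run the full multi-technique pipeline
#'
#' Orchestrates the end-to-end workflow: obtain a campaign (simulate, or
#' load from a directory of canonical CSVs), condition the EEMs (blank
#' subtraction, scatter excision, dilution back-correction), compute the
#' fluorescence indices, decompose the stack by trilinearity-constrained
#' MCR-ALS, assemble and decompose the EIS matrix, extract uv254, build
#' the fused table on the EIS-measured subset, and run the global
#' autoscaled PCA. Every stage is logged; with a fixed seed the run is
#' fully reproducible. If no EIS spectra are available the EIS and fusion
#' stages are skipped with a warning.
#'
#' @param config Configuration list, or path to a YAML/JSON file holding
#'   one. Recognized fields: `simulate` (list passed to
#'   [simulate_campaign]; or `input_dir` to read a campaign written by this
#'   function), `seed`, `nc` (MCR components, default 6),
#'   `excision_mode` (`"mask"` default: excised cells stay flagged and are
#'   excluded from index peaks and MCR residuals; `"interpolate"` refills
#'   them), `eis_smooth` (default
#'   TRUE), `eis_nc` (default 2), `nc_kept` (global PCA, default 2),
#'   `out_dir` (optional; artifacts written there when given).
#' @return Invisibly, a list with every stage's result: `campaign`,
#'   `stack_preprocessed`, `indices`, `mcr`, `eis_matrix`, `eis_pca`,
#'   `eis_scores`, `uv254`, `fused`, `global_pca`, `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(
    list(simulate = list(), input_dir = NULL, seed = 1L, nc = 6,
         excision_mode = "mask", eis_smooth = TRUE, eis_nc = 2,
         nc_kept = 2, out_dir = NULL, blank_id = "DOMfree"),
    config)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[domfuse] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  camp <- stage("load", {
    if (!is.null(cfg$input_dir)) {
      note("loading campaign from %s", cfg$input_dir)
      read_campaign(cfg$input_dir)
    } else {
      note("simulating campaign (seed %d)", as.integer(cfg$seed))
      do.call(simulate_campaign,
              utils::modifyList(list(seed = cfg$seed), cfg$simulate))
    }
  })

  pre_cfg <- preprocess_config(excision_mode = cfg$excision_mode)
  stack <- stage("preprocess", {
    ids <- vapply(camp$stack$samples, `[[`, character(1), "sample_id")
    blank_k <- match(cfg$blank_id, ids)
    blank <- if (!is.na(blank_k)) camp$stack$samples[[blank_k]] else NULL
    eems <- lapply(camp$stack$samples, function(e) {
      if (!is.null(blank) && e$sample_id != cfg$blank_id)
        e <- blank_subtract(e, blank)
      e <- excise_scatter(e, pre_cfg)
      apply_dilution_correction(e)
    })
    note("preprocessed %d EEMs (%s mode)", length(eems), cfg$excision_mode)
    eem_stack(eems)
  })

  indices <- stage("indices", {
    tab <- index_table(stack)
    note("computed indices for %d samples", nrow(tab))
    tab
  })

  mcr <- stage("mcr", {
    fit <- fit_mcr_trilinear(stack, nc = cfg$nc, seed = cfg$seed)
    note("MCR-ALS: nc = %d, r2 = %.3f%%, %d iterations", cfg$nc, fit$r2,
         fit$n_iter)
    fit
  })

  dil <- vapply(camp$stack$samples, `[[`, numeric(1), "dilution_factor")
  names(dil) <- vapply(camp$stack$samples, `[[`, character(1), "sample_id")
  uv254 <- stage("uv254", {
    v <- vapply(camp$uv, function(u)
      extract_uv254(u, dilution_factor = 1), numeric(1))
    names(v) <- vapply(camp$uv, `[[`, character(1), "sample_id")
    v
  })

  eis_matrix <- NULL; eis_pca <- NULL; eis_scores <- NULL
  fused <- NULL; global <- NULL
  if (length(camp$eis) > 0) {
    eis_matrix <- stage("eis", {
      m <- assemble_eis_matrix(camp$eis, smooth = cfg$eis_smooth)
      note("EIS matrix: %d x %d", nrow(m), ncol(m))
      m
    })
    eis_pca <- stage("eis_pca", {
      p <- fit_pca(eis_matrix, preprocessing = "center",
                   nc_kept = cfg$eis_nc)
      note("EIS PCA: %.1f%% in %d PCs (%s)", p$total_explained, cfg$eis_nc,
           paste(sprintf("%.1f", p$explained[seq_len(cfg$eis_nc)]),
                 collapse = "/"))
      p
    })
    eis_scores <- average_replicate_scores(eis_pca)
    fused <- stage("fusion", {
      sub <- rownames(eis_scores)
      tab <- build_fused_table(
        camp$samples[match(sub, camp$samples$sample_id), ],
        eis_scores, uv254[sub],
        indices[indices$sample_id %in% sub, ],
        mcr$C[sub, , drop = FALSE])
      note("fused table: %d x %d", nrow(tab), ncol(tab))
      tab
    })
    global <- stage("global_pca", {
      g <- run_global_pca(fused, nc_kept = cfg$nc_kept)
      note("global PCA: %.1f%% in %d PCs (%s)",
           g$model$total_explained, cfg$nc_kept,
           paste(sprintf("%.1f", g$model$explained[seq_len(cfg$nc_kept)]),
                 collapse = "/"))
      g
    })
  } else {
    warning("no EIS spectra in campaign: EIS and fusion stages skipped")
    note("no EIS spectra: EIS and fusion stages skipped")
  }

  out <- list(campaign = camp, stack_preprocessed = stack,
              indices = indices, mcr = mcr, eis_matrix = eis_matrix,
              eis_pca = eis_pca, eis_scores = eis_scores, uv254 = uv254,
              fused = fused, global_pca = global, log = log)
  if (!is.null(cfg$out_dir)) write_run_artifacts(out, cfg$out_dir)
  invisible(out)
}

#' Write a campaign / read it back
#'
#' On-disk layout: `eem/<id>.csv` (wide dialect + sidecars),
#' `uv/<id>.csv`, `eis/<id>_<rep>.csv`, `samples.csv`, and (write only)
#' `truth.json` with the generator ground truth.
#'
#' @param campaign A [simulate_campaign] result.
#' @param dir Directory.
#' @return `read_campaign()` returns a campaign list (without truth).
#' @export
write_campaign <- function(campaign, dir) {
  for (d in file.path(dir, c("eem", "uv", "eis")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (e in campaign$stack$samples)
    write_eem(e, file.path(dir, "eem", paste0(e$sample_id, ".csv")))
  for (u in campaign$uv)
    write_uv(u, file.path(dir, "uv", paste0(u$sample_id, ".csv")))
  for (s in campaign$eis)
    write_eis(s, file.path(dir, "eis",
                           paste0(s$sample_id, "_", s$replicate, ".csv")))
  write_sample_table(campaign$samples, file.path(dir, "samples.csv"))
  if (!is.null(campaign$truth)) {
    tr <- campaign$truth
    jsonlite::write_json(
      list(components = lapply(tr$components, unclass),
           C_true = tr$C_true, sample_ids = rownames(tr$C_true),
           noise_sigma = tr$noise_sigma, seed = tr$seed,
           eis_params = tr$eis_params),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  eems <- lapply(sort(list.files(file.path(dir, "eem"), "\\.csv$",
                                 full.names = TRUE)), read_eem)
  uv <- lapply(sort(list.files(file.path(dir, "uv"), "\\.csv$",
                               full.names = TRUE)), read_uv)
  names(uv) <- vapply(uv, `[[`, character(1), "sample_id")
  eis <- lapply(sort(list.files(file.path(dir, "eis"), "\\.csv$",
                                full.names = TRUE)), read_eis)
  samples <- read_sample_table(file.path(dir, "samples.csv"))
  ids <- samples$sample_id
  eems <- eems[order(match(vapply(eems, `[[`, character(1), "sample_id"),
                           ids))]
  list(stack = eem_stack(eems), uv = uv[ids], samples = samples, eis = eis,
       truth = NULL)
}

write_run_artifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$indices, file.path(dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(ex_nm = out$mcr$ex, out$mcr$S_ex),
                   file.path(dir, "mcr_S_ex.csv"), row.names = FALSE)
  utils::write.csv(data.frame(em_nm = out$mcr$em, t(out$mcr$S_em)),
                   file.path(dir, "mcr_S_em.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(out$mcr$C), out$mcr$C),
                   file.path(dir, "mcr_C.csv"), row.names = FALSE)
  write_model_json(out$mcr[c("r2", "lof", "n_iter", "converged", "history")],
                   file.path(dir, "mcr_fit.json"))
  if (!is.null(out$eis_pca)) {
    utils::write.csv(data.frame(row = rownames(out$eis_pca$T),
                                out$eis_pca$T),
                     file.path(dir, "eis_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(out$fused),
                     file.path(dir, "fused_table.csv"))
    write_model_json(out$global_pca$model[c("explained", "total_explained",
                                            "preprocessing")],
                     file.path(dir, "global_pca.json"))
  }
  writeLines(out$log, file.path(dir, "run.log"))
  jsonlite::write_json(
    list(n_samples = length(out$campaign$stack$samples),
         nc = ncol(out$mcr$S_ex), mcr_r2 = out$mcr$r2,
         eis_total_explained = if (is.null(out$eis_pca)) NULL else
           out$eis_pca$total_explained,
         global_total_explained = if (is.null(out$global_pca)) NULL else
           out$global_pca$model$total_explained),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
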