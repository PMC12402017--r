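#' Multi-sample EEM stack
#'
#' K EEMs on a common excitation/emission grid, the input of the trilinear
#' decomposition `D_k = S_ex C_k S_em^T + E_k`. The augmented matrix used
#' by the solver is the vertical concatenation of the K excitation-mode
#' matrices (K*|ex| rows x |em| columns), sample-major.
#'
#' @param eems List of [eem] objects on identical grids.
#' @return An object of class `"eem_stack"`.
#' @export
eem_stack <- function(eems) {
  if (length(eems) < 1) stop("empty stack")
  for (e in eems) validate_eem(e)
  ex <- eems[[1]]$ex; em <- eems[[1]]$em
  for (e in eems[-1])
    if (length(e$ex) != length(ex) || length(e$em) != length(em) ||
        any(abs(e$ex - ex) > .grid_tol) || any(abs(e$em - em) > .grid_tol))
      stop("EEMs are not on a common grid (sample ", e$sample_id, ")")
  structure(list(samples = eems, ex = ex, em = em), class = "eem_stack")
}

#' @export
print.eem_stack <- function(x, ...) {
  cat(sprintf("<eem_stack> %d samples, %d x %d grid: %s\n",
              length(x$samples), length(x$ex), length(x$em),
              paste(vapply(x$samples, `[[`, character(1), "sample_id"),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname eem_stack
#' @param x An `eem_stack`.
#' @return `stack_matrix()` returns the augmented (K*|ex|) x |em| matrix;
#'   `stack_mask()` the matching logical mask (or `NULL` if no cell is
#'   masked).
#' @export
stack_matrix <- function(x) {
  do.call(rbind, lapply(x$samples, `[[`, "intensity"))
}

#' @rdname eem_stack
#' @export
stack_mask <- function(x) {
  if (all(vapply(x$samples, function(e) is.null(e$mask), logical(1))))
    return(NULL)
  do.call(rbind, lapply(x$samples, function(e)
    if (is.null(e$mask)) matrix(FALSE, length(e$ex), length(e$em)) else e$mask))
}

#' Explained data variance (R^2)
#'
#' `R2 = 100 * (1 - sum((d - dhat)^2) / sum(d^2))`, the residual-based fit
#' diagnostic of the curve-resolution literature. Masked cells are excluded
#' from both sums. Negative values are possible for models worse than zero
#' and are not clipped.
#'
#' @param D Observed matrix (or augmented stack).
#' @param Dhat Model reconstruction, same dimensions.
#' @param mask Optional logical matrix; `TRUE` cells are excluded.
#' @return Percent explained variance.
#' @export
explained_variance <- function(D, Dhat, mask = NULL) {
  if (!identical(dim(D), dim(Dhat))) stop("D and Dhat dimensions differ")
  keep <- if (is.null(mask)) TRUE else !mask
  tot <- sum(D[keep]^2)
  if (tot == 0) stop("explained variance undefined: sum of squares of D is zero")
  100 * (1 - sum((D[keep] - Dhat[keep])^2) / tot)
}

#' Estimate the chemical rank of an EEM stack by SVD
#'
#' Singular value decomposition of the augmented matrix; the estimated rank
#' is the smallest number of components whose cumulative squared singular
#' values reach `threshold` of the total. Masked cells must have been
#' interpolated first (SVD has no missing-value notion).
#'
#' @param stack An [eem_stack].
#' @param threshold Fraction of total variance, default 0.999.
#' @return List with `rank`, `singular_values`, and `cumulative` (fractions).
#' @export
estimate_rank <- function(stack, threshold = 0.999) {
  D <- stack_matrix(stack)
  if (!is.null(stack_mask(stack)))
    stop("stack has masked cells; excise in interpolate mode before SVD")
  if (all(D == 0)) stop("all-zero stack")
  d <- svd(D, nu = 0, nv = 0)$d
  cum <- cumsum(d^2) / sum(d^2)
  list(rank = which(cum >= threshold)[1], singular_values = d,
       cumulative = cum)
}

#' SIMPLISMA-style purest-variable selection
#'
#' Iteratively picks the `n` columns of a nonnegative matrix that are both
#' "pure" (high standard deviation relative to mean, with a noise allowance
#' added to the mean so near-empty columns are not favored) and mutually
#' independent (each candidate's purity is weighted by the determinant of
#' the correlation submatrix of the already-selected columns plus the
#' candidate, computed on unit-normalized columns; the determinant is 1 for
#' orthogonal columns and 0 for collinear ones). Fully deterministic; ties
#' break toward the lowest column index.
#'
#' @param D Nonnegative matrix.
#' @param n Number of variables to select.
#' @param noise_allowance Percent of the maximum column mean added to each
#'   mean, default 5.
#' @return Integer vector of `n` column indices, in selection order.
#' @export
purest_variables <- function(D, n, noise_allowance = 5) {
  D <- as.matrix(D)
  if (n < 1) stop("n must be >= 1")
  if (n > ncol(D)) stop("n exceeds the number of columns")
  mu <- colMeans(D)
  sdev <- apply(D, 2, stats::sd)
  offset <- noise_allowance / 100 * max(mu)
  purity <- sdev / (mu + offset)
  nrm <- sqrt(colSums(D^2))
  U <- sweep(D, 2, pmax(nrm, .Machine$double.eps), "/")
  G <- crossprod(U)  # cosine-similarity Gram matrix of all columns
  sel <- integer(0)
  for (step in seq_len(n)) {
    w <- vapply(seq_len(ncol(D)), function(j) {
      if (j %in% sel) return(-Inf)
      det(G[c(sel, j), c(sel, j), drop = FALSE])
    }, numeric(1))
    score <- purity * w
    score[sel] <- -Inf
    sel <- c(sel, unname(which.max(score)))  # which.max: lowest index on ties
  }
  sel
}

# ---- nonnegative least squares ----------------------------------------------

# Exact-KKT active-set NNLS on the normal equations (Bro & De Jong's fast
# NNLS): solves min ||Ax - b||, x >= 0, given only AtA and Atb. Keeps ALS
# strictly monotone, unlike clip-after-solve.
fnnls <- function(AtA, Atb, tol = NULL) {
  n <- length(Atb)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(diag(AtA)) * n
  x <- numeric(n)
  P <- logical(n)
  w <- Atb - AtA %*% x
  iter <- 0L
  maxiter <- 30L * n
  while (any(!P) && max(w[!P]) > tol && iter < maxiter) {
    iter <- iter + 1L
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      if (!any(P)) { x <- numeric(n); break }
      s <- numeric(n)
      s[P] <- solve_sym(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) { x <- s; break }
      viol <- which(P & s <= tol)
      alpha <- min(x[viol] / (x[viol] - s[viol] + .Machine$double.eps))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - AtA %*% x
  }
  pmax(x, 0)
}

# symmetric solve with a ridge fallback for numerically singular subproblems
solve_sym <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out))
    out <- solve(A + diag(1e-10 * max(diag(A)), nrow(A)), b)
  drop(out)
}

# Solve min ||A X - B||_F, X >= 0 columnwise from precomputed normal
# equations. Columns whose unconstrained solution is already nonnegative are
# accepted in one batch; only violating columns go through fnnls.
nnls_multi <- function(AtA, AtB) {
  X <- tryCatch(solve(AtA, AtB), error = function(e) NULL)
  if (is.null(X))
    X <- solve(AtA + diag(1e-10 * max(diag(AtA)), nrow(AtA)), AtB)
  bad <- which(apply(X < -1e-12, 2, any))
  X[X < 0] <- 0
  for (j in bad) X[, j] <- fnnls(AtA, AtB[, j])
  X
}

# ---- MCR-ALS with trilinearity ----------------------------------------------

#' MCR-ALS decomposition of an EEM stack with a trilinearity constraint
#'
#' Alternating least squares on the augmented matrix (K samples stacked in
#' the excitation mode) under non-negativity for all factors, with an
#' optional per-component trilinearity constraint that makes the
#' multi-sample solution essentially unique (PARAFAC-like). Each ALS cycle:
#'
#' 1. solve the augmented excitation-mode factor (K*|ex| x nc) given the
#'    emission profiles, by exact active-set nonnegative least squares;
#' 2. trilinearity: refold each component's augmented profile into an
#'    |ex| x K matrix and replace it by its best rank-1 approximation
#'    (leading singular triplet, signs fixed nonnegative, residual
#'    negatives clipped at 0), which yields the common excitation profile
#'    and the per-sample contributions simultaneously;
#' 3. solve the emission profiles given the constrained excitation factor,
#'    again by nonnegative least squares;
#' 4. normalize: excitation columns and emission rows to maximum 1, all
#'    magnitude absorbed into the contributions `C`.
#'
#' Convergence is declared when the relative change in lack of fit over one
#' cycle drops below `tol`, or when the lack of fit itself falls below
#' 1e-8 percent (an exact fit). Components are returned sorted by descending
#' total contribution. Masked stacks are handled by 0/1-weighted least
#' squares (masked cells excluded from all residuals); interpolated stacks
#' use the faster unweighted path.
#'
#' @param stack An [eem_stack].
#' @param nc Number of components, >= 1.
#' @param max_iter Maximum ALS cycles.
#' @param tol Relative lack-of-fit change declaring convergence.
#' @param apply_trilinearity Apply the rank-1 sample-mode constraint?
#' @param init `"simplisma"` (purest emission variables of the augmented
#'   matrix; deterministic) or `"random"`.
#' @param seed Seed for `init = "random"` only.
#' @return An object of class `"mcr_result"`: `S_ex` (|ex| x nc, columns
#'   max-1), `S_em` (nc x |em|, rows max-1), `C` (K x nc contributions),
#'   `r2` (percent, masked cells excluded), `lof` (percent), `n_iter`,
#'   `converged`, `history` (per-iteration r2), `component_names`,
#'   `sample_ids`, grids, and the constraint/initialization settings.
#' @export
fit_mcr_trilinear <- function(stack, nc, max_iter = 200, tol = 1e-6,
                              apply_trilinearity = TRUE,
                              init = c("simplisma", "random"), seed = 1L) {
  init <- match.arg(init)
  D <- stack_matrix(stack)
  K <- length(stack$samples)
  I <- length(stack$ex)
  J <- length(stack$em)
  if (nc < 1) stop("nc must be >= 1")
  if (nc > min(I, J)) stop("nc exceeds the smallest stack dimension")
  if (apply_trilinearity && K < 2)
    stop("trilinear fitting needs at least 2 samples")
  M <- stack_mask(stack)
  weighted <- !is.null(M)
  W <- if (weighted) 1 - M else NULL  # 0/1 weights; 0 = masked
  ids <- vapply(stack$samples, `[[`, character(1), "sample_id")
  Dw <- if (weighted) D * W else D
  tot_ss <- sum(Dw^2)
  if (tot_ss == 0) stop("all-zero stack")

  # initial augmented excitation factor
  if (init == "simplisma") {
    A <- D[, purest_variables(if (weighted) Dw else D, nc), drop = FALSE]
  } else {
    set.seed(seed)
    A <- matrix(stats::runif(nrow(D) * nc), nrow(D), nc)
  }

  refold <- function(A) {
    # per-component rank-1 factorization of the sample-mode refolding
    S_ex <- matrix(0, I, nc)
    C <- matrix(0, K, nc)
    for (j in seq_len(nc)) {
      Mj <- matrix(A[, j], I, K)
      sv <- svd(Mj, nu = 1, nv = 1)
      u <- sv$u[, 1]; v <- sv$v[, 1]
      if (sum(u) < 0) { u <- -u; v <- -v }
      u <- pmax(u, 0); v <- pmax(v, 0)
      S_ex[, j] <- u
      C[, j] <- sv$d[1] * v
    }
    list(S_ex = S_ex, C = C)
  }
  unfold <- function(S_ex, C) {
    A <- matrix(0, I * K, nc)
    for (j in seq_len(nc))
      A[, j] <- as.vector(S_ex[, j] %*% t(C[, j]))
    A
  }

  rf <- refold(A)
  S_ex <- rf$S_ex; C <- rf$C
  if (apply_trilinearity) A <- unfold(S_ex, C)
  S_em <- solve_em(A, D, W, nc)

  lof_prev <- Inf
  history <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- solve_aug(S_em, D, W)
    # revive any component that collapsed to zero (NNLS zero-lock) from the
    # strongest residual column; deterministic, keeps nc effective
    dead <- which(colSums(A) <= 0)
    if (length(dead) > 0) {
      Dres <- D - A %*% S_em
      Dres[Dres < 0] <- 0
      for (j in dead) {
        pick <- which.max(colSums(Dres^2))
        A[, j] <- Dres[, pick]
        Dres[, pick] <- 0
      }
    }
    if (apply_trilinearity) {
      rf <- refold(A)
      S_ex <- rf$S_ex; C <- rf$C
      A <- unfold(S_ex, C)
    }
    S_em <- solve_em(A, D, W, nc)

    Dhat <- A %*% S_em
    res <- if (weighted) (D - Dhat) * W else D - Dhat
    lof <- 100 * sqrt(sum(res^2) / tot_ss)
    history <- c(history, 100 * (1 - sum(res^2) / tot_ss))
    if (lof <= 1e-8 ||
        (is.finite(lof_prev) &&
         abs(lof_prev - lof) <= tol * max(lof_prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  if (!converged)
    warning("MCR-ALS did not converge in ", max_iter, " iterations")

  # model reconstruction at exit; normalization and sorting below only
  # re-parameterize, they do not change the product
  r2 <- explained_variance(D, A %*% S_em, mask = M)

  if (!apply_trilinearity) {
    rf <- refold(A)           # summary factors for reporting only
    S_ex <- rf$S_ex; C <- rf$C
  }
  # normalization convention: profiles max 1, magnitude in C
  for (j in seq_len(nc)) {
    mex <- max(S_ex[, j]); mem <- max(S_em[j, ])
    if (mex > 0) S_ex[, j] <- S_ex[, j] / mex
    if (mem > 0) S_em[j, ] <- S_em[j, ] / mem
    C[, j] <- C[, j] * mex * mem
  }
  ord <- order(colSums(C), decreasing = TRUE)
  S_ex <- S_ex[, ord, drop = FALSE]
  S_em <- S_em[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  rownames(C) <- ids
  structure(list(S_ex = S_ex, S_em = S_em, C = C,
                 r2 = r2, lof = 100 * sqrt(1 - r2 / 100), n_iter = it,
                 converged = converged, history = history,
                 component_names = paste0("C", seq_len(nc)),
                 sample_ids = ids, ex = stack$ex, em = stack$em,
                 trilinear = apply_trilinearity, init = init),
            class = "mcr_result")
}

# step (i): augmented excitation-mode factor given S_em
solve_aug <- function(S_em, D, W) {
  nc <- nrow(S_em)
  if (is.null(W)) {
    AtA <- tcrossprod(S_em)               # S_em S_em^T, nc x nc
    AtB <- S_em %*% t(D)                  # nc x nrow(D)
    t(nnls_multi(AtA, AtB))
  } else {
    A <- matrix(0, nrow(D), nc)
    for (i in seq_len(nrow(D))) {
      w <- W[i, ]
      Sw <- S_em * rep(w, each = nc)
      A[i, ] <- fnnls(tcrossprod(Sw, S_em), drop(Sw %*% D[i, ]))
    }
    A
  }
}

# step (iii): emission profiles given the (constrained) excitation factor
solve_em <- function(A, D, W, nc) {
  if (is.null(W)) {
    nnls_multi(crossprod(A), crossprod(A, D))
  } else {
    S_em <- matrix(0, nc, ncol(D))
    for (j in seq_len(ncol(D))) {
      w <- W[, j]
      Aw <- A * w
      S_em[, j] <- fnnls(crossprod(Aw, A), drop(crossprod(Aw, D[, j])))
    }
    S_em
  }
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<mcr_result> %d components, %d samples, r2 = %.4f%%, lof = %.4f%%\n",
              ncol(x$S_ex), nrow(x$C), x$r2, x$lof))
  cat(sprintf("  %s after %d iterations (%s, trilinearity %s)\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              x$init, if (x$trilinear) "on" else "off"))
  invisible(x)
}

#' Match resolved components to a stored ground truth
#'
#' Finds the one-to-one assignment between resolved and true components
#' maximizing the summed cosine similarity of their concatenated
#' (excitation, emission) profiles — exact over all permutations, which is
#' cheap at the component counts used here. The similarity of a pair is the
#' mean of the excitation-profile and emission-profile cosines.
#'
#' @param result An `mcr_result`.
#' @param truth A [synthetic_truth] with the same number of components.
#' @return List with `permutation` (truth index for each resolved
#'   component) and `similarity` (per resolved component).
#' @export
match_components <- function(result, truth) {
  nc <- ncol(result$S_ex)
  if (nc != length(truth$components))
    stop("component count mismatch between result and truth")
  prof <- component_profiles(truth$components, result$ex, result$em)
  cosine <- function(a, b) {
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }
  sim <- matrix(0, nc, nc)  # resolved x truth
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      sim[i, j] <- (cosine(result$S_ex[, i], prof$S_ex[, j]) +
                      cosine(result$S_em[i, ], prof$S_em[j, ])) / 2
  perms <- all_permutations(nc)
  scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(nc), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  list(permutation = best, similarity = sim[cbind(seq_len(nc), best)])
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n))
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  out
}
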