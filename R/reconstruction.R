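#' Fitting configuration for the voxel-wise parameter estimation
#'
#' @param psi_search_halfwidth half-width of the field-map search interval
#'   in Hz; defaults to the aliasing half-period `1 / (2 delta_te)` so the
#'   multi-start grid covers one full period of the field-map ambiguity.
#' @param psi_grid_points number of field-map grid points in the coarse
#'   multi-start stage.
#' @param r2star_bounds numeric `c(lo, hi)` bounds on R2* in 1/s.
#' @param r2star_grid_points number of R2* values in the coarse grid.
#' @param max_iterations iteration cap for the local refinement.
#' @param convergence_tol relative tolerance of the refinement.
#' @param min_signal_fraction voxels whose mean echo magnitude falls below
#'   this fraction of the slice maximum are skipped as background.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(psi_search_halfwidth = NULL,
                       psi_grid_points = 64L,
                       r2star_bounds = c(0, 500),
                       r2star_grid_points = 4L,
                       max_iterations = 200L,
                       convergence_tol = 1e-8,
                       r2star_grid_max = 300,
                       min_signal_fraction = 0.05) {
  stopifnot(r2star_bounds[1] >= 0, diff(r2star_bounds) > 0,
            convergence_tol > 0, psi_grid_points >= 2L,
            r2star_grid_points >= 1L)
  structure(list(psi_search_halfwidth = psi_search_halfwidth,
                 psi_grid_points = as.integer(psi_grid_points),
                 r2star_bounds = r2star_bounds,
                 r2star_grid_points = as.integer(r2star_grid_points),
                 r2star_grid_max = r2star_grid_max,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 min_signal_fraction = min_signal_fraction),
            class = "fit_config")
}

# Design matrix of the linear subproblem at fixed (psi, r2star): the
# complex exponent is folded into the columns so the least squares is
# solved in the original signal domain (no demodulation reweighting).
vp_design <- function(psi, r2star, basis) {
  e <- exp((1i * 2 * pi * psi - r2star) * basis$t)
  cbind(e, e * basis$p_f, e * basis$p_ndb, e * basis$p_nmidb)
}

#' Linear subproblem of the variable-projection fit
#'
#' At fixed field map and R2*, the signal model is linear in the
#' reparameterized unknowns `W`, `A0 = F f`, `A1 = F f ndb`,
#' `A2 = F f nmidb`. This solves that complex least-squares system exactly
#' and returns the coefficients and the residual norm.
#'
#' @param signal complex vector, one value per echo.
#' @param psi field map in Hz.
#' @param r2star relaxation rate in 1/s.
#' @param acq an `acquisition_spec` or echo-time vector.
#' @param spec a `fat_model_spec`.
#' @param basis optional precomputed [basis_coefficients()].
#' @return list with complex `W`, `A0`, `A1`, `A2` and `residual` (L2 norm
#'   of the misfit in signal units).
#' @export
linear_subfit <- function(signal, psi, r2star, acq = acquisition_spec(),
                          spec = fat_model_spec(), basis = NULL) {
  if (is.null(basis)) basis <- basis_coefficients(acq, spec)
  if (length(signal) < 4L) stop("need at least 4 echoes")
  C <- vp_design(psi, r2star, basis)
  qrC <- qr(C)
  # complex qr() reports no rank; test the R-factor diagonal instead
  rdiag <- abs(diag(qr.R(qrC)))
  if (min(rdiag) <= 1e-10 * max(rdiag))
    stop("design matrix numerically singular (duplicate echo times?)")
  x <- unname(solve(qrC, signal))
  r <- signal - C %*% x
  list(W = x[1L], A0 = x[2L], A1 = x[3L], A2 = x[4L],
       residual = sqrt(sum(Mod(r)^2)))
}

#' Map linear amplitudes back to fat parameters
#'
#' Inverts the reparameterization of the linear subproblem:
#' `ndb = Re(A1 / A0)` clipped to be non-negative, `nmidb = Re(A2 / A0)`
#' clipped to `[0, ndb]`, and the fat amplitude recovered through the
#' proton normalization, `F = |A0| * sum(alpha)`. Voxels whose `A0` is
#' negligible relative to the water amplitude are returned as fat-free
#' rather than dividing by a vanishing number.
#'
#' @param A0,A1,A2 complex amplitudes from [linear_subfit()].
#' @param spec a `fat_model_spec`.
#' @param w_ref reference magnitude used for the degeneracy test
#'   (typically `|W|`); defaults to `|A0|` so the test only trips on exact
#'   zeros.
#' @return list with `F_mag`, `ndb`, `nmidb`, `clipped` (logical),
#'   `degenerate` (logical).
#' @export
nonlinear_map <- function(A0, A1, A2, spec = fat_model_spec(),
                          w_ref = NULL) {
  scale <- max(Mod(A0), if (is.null(w_ref)) 0 else Mod(w_ref))
  if (Mod(A0) <= 1e3 * .Machine$double.eps * scale || Mod(A0) == 0)
    return(list(F_mag = 0, ndb = 0, nmidb = 0, clipped = FALSE,
                degenerate = TRUE))
  ndb <- Re(A1 / A0)
  nmidb <- Re(A2 / A0)
  clipped <- FALSE
  if (ndb < 0) { ndb <- 0; clipped <- TRUE }
  if (nmidb < 0) { nmidb <- 0; clipped <- TRUE }
  if (nmidb > ndb) { nmidb <- ndb; clipped <- TRUE }
  total <- amplitude_total(ndb, spec)
  if (total <= 0) { # beyond the valid composition box; treat as clip to it
    ndb <- (25 + 6 * (spec$chain_length - 4)) / 2
    total <- 0
    clipped <- TRUE
  }
  list(F_mag = Mod(A0) * total, ndb = ndb, nmidb = nmidb,
       clipped = clipped, degenerate = FALSE)
}

# Residual^2 of the projected linear subproblem for one voxel via the
# 4x4 normal equations; A = [1, p_f, p_ndb, p_nmidb] per echo.
vp_resid2 <- function(signal, psi, r2star, A, t) {
  ec <- exp((-1i * 2 * pi * psi - r2star) * t)  # conj of the exponent term
  z <- ec * signal
  b <- crossprod(Conj(A), z)
  w <- exp(-2 * r2star * t)
  G <- crossprod(Conj(A), w * A)
  x <- tryCatch(solve(G, b), error = function(e) NULL)
  if (is.null(x)) return(sum(Mod(signal)^2))
  max(0, sum(Mod(signal)^2) - Re(sum(Conj(b) * x)))
}

principal_psi <- function(psi, delta_te) {
  if (is.na(delta_te)) return(psi)
  p <- psi - round(psi * delta_te) / delta_te
  hw <- 1 / (2 * delta_te)
  if (p <= -hw + 1e-12 * hw) p <- p + 1 / delta_te
  p
}

r2star_grid <- function(cfg) {
  lo <- cfg$r2star_bounds[1]
  hi <- min(cfg$r2star_bounds[2], cfg$r2star_grid_max)
  if (cfg$r2star_grid_points == 1L) return(lo)
  seq(lo, hi, length.out = cfg$r2star_grid_points)
}

psi_grid <- function(cfg, acq) {
  hw <- cfg$psi_search_halfwidth
  if (is.null(hw)) hw <- 1 / (2 * acq$delta_te)
  n <- cfg$psi_grid_points
  -hw + (2 * hw) * seq_len(n) / n   # covers (-hw, hw]
}

refine_voxel <- function(signal, psi0, r20, A, t, cfg, psi_step) {
  obj <- function(par) vp_resid2(signal, par[1L], par[2L], A, t)
  lo <- c(psi0 - 2 * psi_step, cfg$r2star_bounds[1])
  hi <- c(psi0 + 2 * psi_step, cfg$r2star_bounds[2])
  fit <- tryCatch(
    stats::optim(c(psi0, r20), obj, method = "L-BFGS-B",
                 lower = lo, upper = hi,
                 control = list(maxit = cfg$max_iterations,
                                factr = 10, pgtol = 0)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = c(psi0, r20), converged = FALSE))
  # a line-search stall at the numerical floor is a converged fit: the
  # objective can no longer be reduced at machine precision
  stalled <- !is.null(fit$message) &&
    grepl("ABNORMAL_TERMINATION_IN_LNSRCH", fit$message)
  list(par = fit$par, converged = fit$convergence == 0L || stalled)
}

# Coarse grid scores for a batch of voxels: for every field-map grid
# point, the residual^2 minimized over the R2* grid (and the minimizing
# R2* index). Sv is echoes x N.
vp_grid_scores <- function(Sv, A, t, psis, r2s) {
  n_psi <- length(psis)
  N <- ncol(Sv)
  s2 <- colSums(Mod(Sv)^2)
  marg <- matrix(Inf, n_psi, N)
  argr2 <- matrix(1L, n_psi, N)
  for (ri in seq_along(r2s)) {
    w <- exp(-2 * r2s[ri] * t)
    G <- crossprod(Conj(A), w * A)
    for (ip in seq_len(n_psi)) {
      ec <- exp((-2i * pi * psis[ip] - r2s[ri]) * t)
      B <- crossprod(Conj(A), ec * Sv)
      X <- solve(G, B)
      r2v <- pmax(0, s2 - Re(colSums(Conj(B) * X)))
      upd <- r2v < marg[ip, ]
      if (any(upd)) {
        marg[ip, upd] <- r2v[upd]
        argr2[ip, upd] <- ri
      }
    }
  }
  list(marg = marg, argr2 = argr2)
}

# Best grid candidate plus the best candidate from a different field-map
# basin (circular separation of at least min_sep grid steps). Water--fat
# swaps sit in a competing basin about one fat--water shift away; refining
# both and keeping the lower residual resolves the ambiguity.
grid_candidates <- function(marg_col, argr2_col, psis, r2s, min_sep = 4L) {
  n <- length(psis)
  i1 <- which.min(marg_col)
  d <- abs(seq_len(n) - i1)
  far <- pmin(d, n - d) >= min_sep
  cands <- list(c(psis[i1], r2s[argr2_col[i1]]))
  if (any(far)) {
    i2 <- which(far)[which.min(marg_col[far])]
    cands[[2L]] <- c(psis[i2], r2s[argr2_col[i2]])
  }
  cands
}

refine_best <- function(signal, cands, A, t, cfg, psi_step) {
  best <- NULL
  for (cand in cands) {
    ref <- refine_voxel(signal, cand[1L], cand[2L], A, t, cfg, psi_step)
    val <- vp_resid2(signal, ref$par[1L], ref$par[2L], A, t)
    if (is.null(best) || val < best$val)
      best <- list(par = ref$par, converged = ref$converged, val = val)
  }
  best
}

#' Fit the signal model to a single voxel
#'
#' Joint estimation of water, fat, `ndb`, `nmidb`, field map and R2* by
#' variable projection: the four complex amplitudes are eliminated
#' analytically at each trial of the two nonlinear parameters
#' `(psi, r2star)`. A coarse grid over the field-map aliasing interval
#' crossed with a small R2* grid provides multi-start protection against
#' water--fat swaps: the best grid point and the best competitor from a
#' distinct field-map basin are both refined by bounded quasi-Newton
#' iteration and the lower-residual solution is kept. Non-convergence
#' returns the best iterate with `converged = FALSE`, never an error.
#'
#' @param signal complex vector of per-echo measurements.
#' @param acq an `acquisition_spec`.
#' @param spec a `fat_model_spec`.
#' @param cfg a `fit_config`.
#' @return a list (class `voxel_estimate`) with `W_mag`, `F_mag`, `ndb`,
#'   `nmidb`, `psi` (Hz, principal interval), `r2star` (1/s),
#'   `residual_norm`, `converged`, `clipped`, `degenerate`.
#' @export
fit_voxel <- function(signal, acq = acquisition_spec(),
                      spec = fat_model_spec(), cfg = fit_config()) {
  stopifnot(length(signal) == acq$n_echoes, acq$n_echoes >= 4L)
  basis <- basis_coefficients(acq, spec)
  t <- basis$t
  A <- cbind(1 + 0i, basis$p_f, basis$p_ndb, basis$p_nmidb)
  psis <- psi_grid(cfg, acq)
  r2s <- r2star_grid(cfg)
  sc <- vp_grid_scores(matrix(signal, ncol = 1L), A, t, psis, r2s)
  cands <- grid_candidates(sc$marg[, 1L], sc$argr2[, 1L], psis, r2s)
  psi_step <- if (length(psis) > 1L) psis[2L] - psis[1L] else
    1 / (2 * acq$delta_te)
  best <- refine_best(signal, cands, A, t, cfg, psi_step)
  finish_voxel(signal, best$par[1L], best$par[2L], best$converged,
               acq, spec, basis)
}

finish_voxel <- function(signal, psi, r2star, converged, acq, spec, basis) {
  psi <- principal_psi(psi, acq$delta_te)
  lf <- linear_subfit(signal, psi, r2star, acq, spec, basis)
  nl <- nonlinear_map(lf$A0, lf$A1, lf$A2, spec, w_ref = lf$W)
  structure(list(W_mag = unname(Mod(lf$W)), F_mag = unname(nl$F_mag),
                 ndb = unname(nl$ndb),
                 nmidb = unname(nl$nmidb), psi = psi, r2star = r2star,
                 residual_norm = lf$residual, converged = converged,
                 clipped = nl$clipped, degenerate = nl$degenerate),
            class = "voxel_estimate")
}

#' Fit the signal model to every voxel of a multi-echo image
#'
#' Applies the variable-projection estimator voxel-by-voxel. The coarse
#' field-map/R2* grid search is vectorized across all foreground voxels;
#' each voxel is then refined independently. Voxels whose mean echo
#' magnitude is below `min_signal_fraction` of the image maximum are
#' marked invalid and skipped. The procedure is fully deterministic.
#'
#' @param data an `echo_series` (see [read_echo_series()]) or a complex
#'   array with dimensions `rows x cols x slices x echoes`.
#' @param acq an `acquisition_spec`.
#' @param spec a `fat_model_spec`.
#' @param cfg a `fit_config`.
#' @return an object of class `parameter_maps`: arrays `W_mag`, `F_mag`,
#'   `ndb`, `nmidb`, `psi`, `r2star`, `residual`, plus logical `valid`,
#'   `converged`, `clipped` masks (invalid voxels carry `NA`, never silent
#'   zeros), and the grid `affine`.
#' @export
fit_image <- function(data, acq = acquisition_spec(),
                      spec = fat_model_spec(), cfg = fit_config()) {
  affine <- NULL
  if (inherits(data, "echo_series")) { affine <- data$affine; data <- data$data }
  d <- dim(data)
  if (length(d) != 4L || d[4L] != acq$n_echoes)
    stop("echo series dimensions inconsistent with the acquisition: ",
         "expected rows x cols x slices x ", acq$n_echoes)
  n_vox <- prod(d[1:3])
  S <- matrix(data, nrow = n_vox, ncol = d[4L])      # voxels x echoes
  mag <- rowMeans(Mod(S))
  valid <- mag >= cfg$min_signal_fraction * max(mag, 0) & max(mag) > 0
  basis <- basis_coefficients(acq, spec)
  t <- basis$t
  A <- cbind(1 + 0i, basis$p_f, basis$p_ndb, basis$p_nmidb)
  idx <- which(valid)
  maps <- empty_parameter_maps(d[1:3], affine)
  if (length(idx)) {
    Sv <- t(S[idx, , drop = FALSE])                  # echoes x N
    psis <- psi_grid(cfg, acq)
    r2s <- r2star_grid(cfg)
    sc <- vp_grid_scores(Sv, A, t, psis, r2s)
    psi_step <- psis[2L] - psis[1L]
    for (j in seq_along(idx)) {
      sig <- Sv[, j]
      cands <- grid_candidates(sc$marg[, j], sc$argr2[, j], psis, r2s)
      best <- refine_best(sig, cands, A, t, cfg, psi_step)
      est <- finish_voxel(sig, best$par[1L], best$par[2L], best$converged,
                          acq, spec, basis)
      v <- idx[j]
      maps$W_mag[v] <- est$W_mag; maps$F_mag[v] <- est$F_mag
      maps$ndb[v] <- est$ndb; maps$nmidb[v] <- est$nmidb
      maps$psi[v] <- est$psi; maps$r2star[v] <- est$r2star
      maps$residual[v] <- est$residual_norm
      maps$valid[v] <- TRUE
      maps$converged[v] <- est$converged
      maps$clipped[v] <- est$clipped
    }
  }
  maps
}

empty_parameter_maps <- function(dims, affine = NULL) {
  z <- array(NA_real_, dims)
  structure(list(W_mag = z, F_mag = z, ndb = z, nmidb = z, psi = z,
                 r2star = z, residual = z,
                 valid = array(FALSE, dims),
                 converged = array(FALSE, dims),
                 clipped = array(FALSE, dims),
                 affine = affine),
            class = "parameter_maps")
}
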