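# Independent oracles used to cross-check the implementation. These are
# deliberately written as straight-line code, separate from the package's
# own computational paths.

# Multi-echo signal as an explicit sum over the eight fat resonances
# (no linearized basis): the reference path for the forward model.
eq1a_signal <- function(W, F, ndb, nmidb, psi, r2star, t,
                        spec = fat_model_spec()) {
  omega <- 2 * pi * (spec$chemical_shifts - spec$water_shift) *
    spec$gyromagnetic_ratio * spec$field_strength
  alpha <- c(2 * ndb, 4, 2 * nmidb, 6, 4 * (ndb - nmidb), 6,
             6 * (spec$chain_length - 4) - 8 * ndb + 2 * nmidb, 9)
  f <- 1 / sum(alpha)
  vapply(t, function(tt) {
    fat <- sum(alpha * exp(1i * omega * tt))
    (W + F * f * fat) * exp((1i * 2 * pi * psi - r2star) * tt)
  }, complex(1))
}

# Linear least squares by explicit normal equations (complex),
# independent of the QR path used by linear_subfit.
normal_eq_ls <- function(C, y) {
  G <- t(Conj(C)) %*% C
  b <- t(Conj(C)) %*% y
  x <- solve(G, b)
  r <- y - C %*% x
  list(x = as.vector(x), residual = sqrt(sum(Mod(r)^2)))
}

# Exhaustive dense grid search over (psi, r2star, ndb, nmidb) with the
# two remaining complex amplitudes (W, F) solved in closed form per grid
# point. Returns the minimum residual norm per voxel. S is echoes x N.
brute_force_grid_residual <- function(S, acq, spec,
                                      n_psi = 20L, n_r2 = 20L,
                                      n_ndb = 20L, n_nmidb = 20L) {
  basis <- basis_coefficients(acq, spec)
  t <- basis$t
  hw <- 1 / (2 * acq$delta_te)
  psis <- seq(-hw, hw, length.out = n_psi)
  r2s <- seq(0, 300, length.out = n_r2)
  ndbs <- seq(0, 3.4, length.out = n_ndb)
  nmidbs <- seq(0, 1.2, length.out = n_nmidb)
  grid <- expand.grid(ndb = ndbs, nmidb = nmidbs)
  grid <- grid[grid$nmidb <= grid$ndb, ]
  # fat basis column for every composition grid point: echoes x M
  P <- vapply(seq_len(nrow(grid)), function(i)
    basis$p_f + grid$ndb[i] * basis$p_ndb + grid$nmidb[i] * basis$p_nmidb,
    complex(length(t)))
  s2 <- colSums(Mod(S)^2)
  best <- rep(Inf, ncol(S))
  for (r2 in r2s) {
    w <- exp(-2 * r2 * t)
    g11 <- sum(w)
    g12 <- as.vector(crossprod(w, P))              # M complex
    g22 <- as.vector(crossprod(w, Mod(P)^2))       # M real
    det <- g11 * g22 - Mod(g12)^2
    for (psi in psis) {
      ec <- exp((-1i * 2 * pi * psi - r2) * t)
      Z <- ec * S                                  # echoes x N
      b1 <- colSums(Z)                             # N
      B2 <- crossprod(Conj(P), Z)                  # M x N
      # solve the 2x2 Hermitian system per (grid point, voxel)
      X1 <- (outer(g22, b1) - g12 * B2) / det
      X2 <- (g11 * B2 - outer(Conj(g12), b1)) / det
      expl <- Re(Conj(outer(rep(1, nrow(B2)), b1)) * X1 + Conj(B2) * X2)
      res2 <- pmax(0, rep(s2, each = nrow(B2)) - expl)
      best <- pmin(best, apply(matrix(res2, nrow(B2)), 2L, min))
    }
  }
  sqrt(best)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# group assignments (no ties assumed).
ranksum_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  ws <- apply(combos, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all
# sign patterns (no zero or tied absolute differences assumed).
signedrank_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs); p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small phantom settings used across tests (scaled-down grid with a
# proportionally scaled fat ring).
test_phantom_spec <- function(snr = Inf, ...) {
  phantom_spec(matrix_size = c(48L, 64L), sat_thickness = 6,
               fascia_offset = 3, snr = snr, ...)
}

test_acq <- function() acquisition_spec(matrix_size = c(48L, 64L))

# Random valid voxel parameters across the physiological box.
random_voxel_params <- function(n, seed = 1) {
  set.seed(seed)
  ff <- runif(n, 0.3, 1.0)
  tot <- 100
  data.frame(W = (1 - ff) * tot, F = ff * tot,
             ndb = runif(n, 1.5, 3.2),
             nmidb = NA, psi = runif(n, -250, 250),
             r2star = runif(n, 10, 120)) -> p
  p$nmidb <- runif(n, 0.1, pmin(0.9, p$ndb / 2))
  p
}
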