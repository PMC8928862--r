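acq12 <- acquisition_spec()
model <- fat_model_spec()
basis12 <- basis_coefficients(acq12, model)

test_that("linear subfit agrees with an explicit normal-equations oracle", {
  set.seed(21)
  for (rep in 1:20) {
    p <- random_voxel_params(1, seed = 100 + rep)
    s <- forward_signal(p$W, p$F, p$ndb, p$nmidb, p$psi, p$r2star,
                        acq12, model)
    s <- s + complex(real = rnorm(12, sd = 0.5), imaginary = rnorm(12, sd = 0.5))
    lf <- linear_subfit(s, p$psi, p$r2star, acq12, model)
    C <- facmri:::vp_design(p$psi, p$r2star, basis12)
    or <- normal_eq_ls(C, s)
    expect_equal(c(lf$W, lf$A0, lf$A1, lf$A2), or$x, tolerance = 1e-9)
    expect_equal(lf$residual, or$residual, tolerance = 1e-9)
  }
})

test_that("projected residual matches the full linear subfit residual", {
  p <- random_voxel_params(1, seed = 5)
  s <- forward_signal(p$W, p$F, p$ndb, p$nmidb, p$psi, p$r2star, acq12, model)
  s <- s + complex(real = rnorm(12), imaginary = rnorm(12))
  A <- cbind(1 + 0i, basis12$p_f, basis12$p_ndb, basis12$p_nmidb)
  for (psi in c(-100, 0, 150)) for (r2 in c(0, 60)) {
    r2a <- facmri:::vp_resid2(s, psi, r2, A, basis12$t)
    r2b <- linear_subfit(s, psi, r2, acq12, model)$residual^2
    expect_equal(r2a, r2b, tolerance = 1e-8)
  }
})

test_that("noiseless voxels are recovered to high relative accuracy", {
  p <- random_voxel_params(15, seed = 42)
  for (i in seq_len(nrow(p))) {
    s <- forward_signal(p$W[i], p$F[i], p$ndb[i], p$nmidb[i],
                        p$psi[i], p$r2star[i], acq12, model)
    est <- fit_voxel(s, acq12, model)
    expect_true(est$converged)
    expect_equal(est$W_mag, p$W[i], tolerance = 1e-6)
    expect_equal(est$F_mag, p$F[i], tolerance = 1e-6)
    expect_equal(est$ndb, p$ndb[i], tolerance = 1e-6)
    expect_equal(est$nmidb, p$nmidb[i], tolerance = 1e-6)
    expect_equal(est$psi, p$psi[i], tolerance = 1e-6)
    expect_equal(est$r2star, p$r2star[i], tolerance = 1e-6)
  }
})

test_that("field map estimates fold into the principal aliasing interval", {
  hw <- 1 / (2 * acq12$delta_te)
  psi_true <- 90
  s_alias <- forward_signal(20, 80, 2.4, 0.4, psi_true + 2 * hw, 45,
                            acq12, model)
  est <- fit_voxel(s_alias, acq12, model)
  expect_lte(est$psi, hw)
  expect_gt(est$psi, -hw)
  expect_equal(est$psi, psi_true, tolerance = 1e-5)
})

test_that("nonlinear map clips to the valid composition region", {
  nm <- nonlinear_map(1 + 0i, -0.5 + 0i, 0.1 + 0i)
  expect_equal(nm$ndb, 0)
  expect_true(nm$clipped)
  nm2 <- nonlinear_map(1 + 0i, 0.5 + 0i, 2 + 0i)
  expect_equal(nm2$nmidb, nm2$ndb)
  expect_true(nm2$clipped)
  nm3 <- nonlinear_map(1 + 0i, 2.5 + 0i, 0.4 + 0i)
  expect_false(nm3$clipped)
  expect_equal(nm3$F_mag, 104.8 - 2 * 2.5)
})

test_that("fat-free voxels take the degenerate path instead of dividing", {
  nm <- nonlinear_map(0 + 0i, 0 + 0i, 0 + 0i, w_ref = 100 + 0i)
  expect_true(nm$degenerate)
  expect_equal(nm$F_mag, 0)
  s <- forward_signal(100, 0, 0, 0, 40, 30, acq12, model)
  est <- fit_voxel(s, acq12, model)
  expect_equal(est$W_mag, 100, tolerance = 1e-4)
  expect_lt(est$F_mag / est$W_mag, 1e-4)
})

test_that("pure-noise input returns flagged estimates, not an error", {
  set.seed(9)
  s <- complex(real = rnorm(12), imaginary = rnorm(12))
  est <- fit_voxel(s, acq12, model)
  expect_type(est$converged, "logical")
  expect_true(is.finite(est$residual_norm))
})

test_that("degenerate design matrices raise a clear error", {
  acq_dup <- acquisition_spec(echo_times = rep(1.13e-3, 8))
  expect_error(linear_subfit(rep(1 + 0i, 8), 0, 0, acq_dup, model),
               "singular")
})

test_that("image fitting equals independent per-voxel fitting", {
  p <- random_voxel_params(4, seed = 77)
  data <- array(0i, c(2, 2, 1, 12))
  for (i in 1:4) {
    s <- forward_signal(p$W[i], p$F[i], p$ndb[i], p$nmidb[i],
                        p$psi[i], p$r2star[i], acq12, model)
    data[((i - 1) %% 2) + 1, ((i - 1) %/% 2) + 1, 1, ] <- s
  }
  acq_small <- acquisition_spec(matrix_size = c(2L, 2L))
  maps <- fit_image(data, acq_small, model)
  for (i in 1:4) {
    r <- ((i - 1) %% 2) + 1; c <- ((i - 1) %/% 2) + 1
    est <- fit_voxel(data[r, c, 1, ], acq_small, model)
    expect_equal(maps$ndb[r, c, 1], est$ndb, tolerance = 1e-9)
    expect_equal(maps$psi[r, c, 1], est$psi, tolerance = 1e-9)
    expect_equal(maps$r2star[r, c, 1], est$r2star, tolerance = 1e-9)
  }
  expect_true(all(maps$valid))
})

test_that("an all-zero image yields invalid voxels with NA maps", {
  data <- array(0i, c(3, 3, 1, 12))
  maps <- fit_image(data, acquisition_spec(matrix_size = c(3L, 3L)), model)
  expect_false(any(maps$valid))
  expect_true(all(is.na(maps$ndb)))
  expect_true(all(is.na(maps$W_mag)))
})

test_that("background voxels below the signal floor are skipped as NA", {
  p <- random_voxel_params(1, seed = 3)
  s <- forward_signal(p$W, p$F, p$ndb, p$nmidb, p$psi, p$r2star, acq12, model)
  data <- array(0i, c(2, 1, 1, 12))
  data[1, 1, 1, ] <- s
  data[2, 1, 1, ] <- s * 1e-4
  maps <- fit_image(data, acquisition_spec(matrix_size = c(2L, 1L)), model)
  expect_true(maps$valid[1, 1, 1])
  expect_false(maps$valid[2, 1, 1])
  expect_true(is.na(maps$ndb[2, 1, 1]))
})

test_that("fit residual is not worse than a dense brute-force grid search", {
  set.seed(31)
  p <- random_voxel_params(10, seed = 31)
  S <- matrix(0i, 12, nrow(p))
  for (i in seq_len(nrow(p))) {
    s <- forward_signal(p$W[i], p$F[i], p$ndb[i], p$nmidb[i],
                        p$psi[i], p$r2star[i], acq12, model)
    S[, i] <- s + complex(real = rnorm(12, sd = 2),
                          imaginary = rnorm(12, sd = 2))
  }
  oracle <- brute_force_grid_residual(S, acq12, model,
                                      n_psi = 10L, n_r2 = 10L,
                                      n_ndb = 10L, n_nmidb = 10L)
  for (i in seq_len(ncol(S))) {
    est <- fit_voxel(S[, i], acq12, model)
    expect_lte(est$residual_norm, oracle[i] + 1e-8 * sqrt(sum(Mod(S[, i])^2)))
  }
})
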