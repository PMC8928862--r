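test_that("phantom labels partition the grid without overlap", {
  spec <- test_phantom_spec()
  lab <- facmri:::phantom_labels(spec)
  expect_identical(dim(lab), c(48L, 64L))
  counts <- table(lab)
  expect_setequal(as.integer(names(counts)), unname(facmri:::PHANTOM_LABELS))
  # the subcutaneous ring is 4-connected: growing from one SAT voxel on a
  # truth-valued fat-fraction map recovers the whole ring
  sat <- lab %in% facmri:::PHANTOM_LABELS[c("ssat", "dsat")]
  dim(sat) <- dim(lab)
  ff <- matrix(0, nrow(lab), ncol(lab))
  ff[sat] <- 0.95
  seed <- which(sat, arr.ind = TRUE)[1, ]
  expect_identical(region_grow_sat(ff, seed), sat)
})

test_that("phantom geometry validation catches overlaps", {
  expect_error(phantom_spec(fascia_offset = 12, sat_thickness = 10),
               "fascia_offset")
  bad <- test_phantom_spec()
  bad$spine_center <- bad$vat_center  # collide spine with the fat disk
  expect_error(facmri:::phantom_labels(bad), "overlap")
})

test_that("phantom truth maps carry the configured region values", {
  spec <- test_phantom_spec(snr = Inf)
  acq <- test_acq()
  ph <- generate_phantom(spec, acq, fat_model_spec())
  tr <- ph$truth
  vat_idx <- tr$label == facmri:::PHANTOM_LABELS["vat"]
  expect_true(all(tr$ndb[vat_idx] == spec$region_truth$vat$ndb))
  expect_true(all(tr$F[vat_idx] / (tr$W[vat_idx] + tr$F[vat_idx]) ==
                    spec$region_truth$vat$ff))
  expect_true(all(tr$r2star[tr$label == facmri:::PHANTOM_LABELS["spine"]] ==
                    spec$region_truth$spine$r2star))
  expect_identical(dim(ph$echo$data), c(48L, 64L, 1L, 12L))
  expect_s3_class(ph$echo, "echo_series")
  # background voxels are silent in the noiseless phantom
  bg <- tr$label == facmri:::PHANTOM_LABELS["background"]
  expect_true(all(Mod(ph$echo$data[, , 1, 1])[bg] == 0))
})

test_that("phantom signal agrees with the forward model in a known voxel", {
  spec <- test_phantom_spec(snr = Inf)
  acq <- test_acq()
  ph <- generate_phantom(spec, acq, fat_model_spec())
  tr <- ph$truth
  v <- which(tr$label == facmri:::PHANTOM_LABELS["vat"], arr.ind = TRUE)[1, ]
  s_ref <- forward_signal(tr$W[v[1], v[2]], tr$F[v[1], v[2]],
                          tr$ndb[v[1], v[2]], tr$nmidb[v[1], v[2]],
                          tr$psi[v[1], v[2]], tr$r2star[v[1], v[2]],
                          acq, fat_model_spec())
  expect_equal(ph$echo$data[v[1], v[2], 1, ], s_ref, tolerance = 1e-12)
})

test_that("noise generation is seeded and at the configured level", {
  spec <- test_phantom_spec(snr = 50)
  acq <- test_acq()
  ph1 <- generate_phantom(spec, acq, seed = 7)
  ph2 <- generate_phantom(spec, acq, seed = 7)
  ph3 <- generate_phantom(spec, acq, seed = 8)
  expect_identical(ph1$echo$data, ph2$echo$data)
  expect_false(identical(ph1$echo$data, ph3$echo$data))
  clean <- generate_phantom(test_phantom_spec(snr = Inf), acq)
  noise <- ph1$echo$data - clean$echo$data
  sigma_hat <- stats::sd(c(Re(noise), Im(noise)))
  sigma_expected <- max(Mod(clean$echo$data)) / 50
  expect_equal(sigma_hat, sigma_expected, tolerance = 0.02)
})

test_that("the acquisition matrix must match the phantom grid", {
  expect_error(generate_phantom(test_phantom_spec(), acquisition_spec()),
               "matrix size")
})

test_that("cohort specification validates its distribution table", {
  co <- cohort_spec()
  expect_equal(co$n_a, 15L)
  expect_equal(co$n_b, 23L)
  expect_error(cohort_spec(n_a = 1L), "n_a")
  bad <- co$params
  bad$a$sat$ndb <- c(2.2, 2.4, 2.1)  # upper quartile below lower
  expect_error(cohort_spec(params = bad), "IQR")
})

test_that("subject draws are deterministic, valid and correctly sized", {
  co <- cohort_spec(n_a = 4L, n_b = 5L)
  t1 <- draw_subject_fac(co, seed = 3)
  t2 <- draw_subject_fac(co, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), (4 + 5) * 4)
  expect_setequal(unique(t1$depot), c("sat", "vat", "dsat", "ssat"))
  expect_equal(sum(t1$group == "a"), 4 * 4)
  expect_true(all(facmri:::valid_composition(t1$ndb, t1$nmidb)))
  t3 <- draw_subject_fac(co, seed = 4)
  expect_false(identical(t1$ndb, t3$ndb))
})

test_that("simulated cohorts paint subject compositions into the phantom", {
  co <- cohort_spec(n_a = 2L, n_b = 2L)
  subs <- simulate_cohort(co, test_phantom_spec(snr = Inf), test_acq(),
                          master_seed = 11L)
  expect_length(subs, 4L)
  expect_equal(vapply(subs, `[[`, "", "group"), c("a", "a", "b", "b"))
  s <- subs[[3]]
  vat_ndb <- s$true_fac$ndb[s$true_fac$depot == "vat"]
  expect_true(all(s$truth$ndb[s$truth$vat] == vat_ndb))
  # regeneration with the same master seed is identical
  subs2 <- simulate_cohort(co, test_phantom_spec(snr = Inf), test_acq(),
                           master_seed = 11L)
  expect_identical(s$echo$data, subs2[[3]]$echo$data)
  expect_identical(s$true_fac, subs2[[3]]$true_fac)
})

test_that("metadata-only simulation skips image synthesis", {
  co <- cohort_spec(n_a = 2L, n_b = 2L)
  subs <- simulate_cohort(co, test_phantom_spec(), test_acq(),
                          master_seed = 11L, images = FALSE)
  expect_null(subs[[1]]$echo)
  subs_img <- simulate_cohort(co, test_phantom_spec(), test_acq(),
                              master_seed = 11L)
  expect_identical(subs[[1]]$true_fac, subs_img[[1]]$true_fac)
})
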