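# A toy slice: high-fat ring (rows/cols 2..9 border of a 10x10 block)
# around a low-fat interior with one disconnected high-fat blob.
toy_ring <- function() {
  ff <- matrix(0, 12, 12)
  ff[3:10, 3:10] <- 0.2
  ff[3:10, c(3, 10)] <- 0.95
  ff[c(3, 10), 3:10] <- 0.95
  ff[6:7, 6:7] <- 0.95  # disconnected visceral blob
  ff
}

test_that("region growing recovers the ring and nothing else", {
  ff <- toy_ring()
  truth <- ff >= 0.5
  truth[6:7, 6:7] <- FALSE
  grown <- region_grow_sat(ff, seed = c(3, 3))
  expect_identical(grown, truth)
  # Dice coefficient of 1 against the ring truth
  dice <- 2 * sum(grown & truth) / (sum(grown) + sum(truth))
  expect_equal(dice, 1.0)
})

test_that("default seed is the maximum fat-fraction voxel", {
  ff <- toy_ring()
  ff[3, 5] <- 0.99
  expect_identical(region_grow_sat(ff), region_grow_sat(ff, seed = c(3, 5)))
})

test_that("region growing validates its seed", {
  ff <- toy_ring()
  expect_error(region_grow_sat(ff, seed = c(0, 1)), "outside")
  expect_error(region_grow_sat(ff, seed = c(5, 5)), "below the growth threshold")
})

test_that("NA voxels never join the region and can split it", {
  ff <- toy_ring()
  ff[3, 6] <- NA; ff[10, 6] <- NA  # cut the ring into two arcs
  grown <- region_grow_sat(ff, seed = c(3, 3))
  expect_false(any(grown[is.na(ff)]))
  expect_false(grown[3, 10])  # right arc unreachable after the cut
  expect_true(grown[3, 5])
})

test_that("diagonal contact does not connect regions (4-connectivity)", {
  ff <- matrix(0, 4, 4)
  ff[1, 1] <- 0.95; ff[2, 2] <- 0.95
  grown <- region_grow_sat(ff, seed = c(1, 1))
  expect_true(grown[1, 1])
  expect_false(grown[2, 2])
})

test_that("degenerate polygons are rejected", {
  expect_error(facmri:::rasterize_polygon(cbind(c(1, 2), c(1, 2)), c(5, 5)),
               "degenerate")
  expect_error(facmri:::rasterize_polygon(cbind(c(1, 2, 3), c(1, 2, 3)),
                                          c(5, 5)), "zero area")
})

test_that("polygon rasterization uses pixel centers (even-odd rule)", {
  # unit square around pixel centers (2..4, 2..4)
  poly <- cbind(c(1.5, 1.5, 4.5, 4.5), c(1.5, 4.5, 4.5, 1.5))
  m <- facmri:::rasterize_polygon(poly, c(6L, 6L))
  expect_equal(sum(m), 9L)
  expect_true(all(m[2:4, 2:4]))
})

test_that("VAT is inside the cavity outline and excludes SAT", {
  ff <- toy_ring()
  sat <- region_grow_sat(ff, seed = c(3, 3))
  poly <- cbind(c(4.5, 4.5, 8.5, 8.5), c(4.5, 8.5, 8.5, 4.5))
  vat <- delineate_vat(poly, sat, ff)
  expect_true(all(vat[5:8, 5:8] | !vat[5:8, 5:8]))
  expect_false(any(vat & sat))
  expect_true(vat[6, 6])
  expect_false(any(vat[c(1:4, 9:12), ]))
})

test_that("SAT split keeps only the posterior (lower) half", {
  sat <- matrix(TRUE, 8, 6)
  fascia <- cbind(c(0.5, 0.5, 8.5, 8.5), c(0.5, 3.5, 3.5, 0.5))
  sp <- split_sat_depots(sat, fascia)
  expect_false(any(sp$dsat[1:4, ]))  # anterior half excluded
  expect_false(any(sp$ssat[1:4, ]))
  expect_true(all(sp$dsat[5:8, 1:3]))
  expect_true(all(sp$ssat[5:8, 4:6]))
  expect_false(any(sp$dsat & sp$ssat))
})

test_that("a fascia outline outside the grid is rejected", {
  sat <- matrix(TRUE, 4, 4)
  far <- cbind(c(100, 100, 110), c(100, 110, 100))
  expect_error(split_sat_depots(sat, far), "outside the image grid")
})

test_that("ROI refinement applies strict thresholds", {
  mask <- matrix(TRUE, 2, 2)
  ff <- rbind(c(0.95, 0.89), c(0.92, 0.95))
  t2s <- rbind(c(0.025, 0.025), c(0.019, 0.030))
  roi <- refine_roi(mask, ff, t2s)
  expect_identical(roi, rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  # boundary values are excluded (strict inequalities)
  expect_false(any(refine_roi(matrix(TRUE, 1, 1), matrix(0.9, 1, 1),
                              matrix(0.05, 1, 1))))
  expect_false(any(refine_roi(matrix(TRUE, 1, 1), matrix(0.95, 1, 1),
                              matrix(0.020, 1, 1))))
  # NA voxels are excluded
  expect_false(any(refine_roi(matrix(TRUE, 1, 1), matrix(NA_real_, 1, 1),
                              matrix(0.05, 1, 1))))
})

test_that("depot means average valid ROI voxels and reject empty ROIs", {
  maps <- facmri:::empty_parameter_maps(c(2L, 2L, 1L))
  maps$W_mag[] <- 5; maps$F_mag[] <- 95
  maps$ndb[] <- c(2.4, 2.6, 2.4, 2.6); maps$nmidb[] <- 0.3
  maps$r2star[] <- 40; maps$psi[] <- 0; maps$residual[] <- 0
  maps$valid[] <- TRUE
  fac <- fac_maps(maps)
  for (nm in c("fsfa", "fmufa", "fpufa", "fat_fraction", "t2star",
               "ndb", "nmidb", "valid"))
    fac[[nm]] <- facmri:::as_slice(fac[[nm]])
  roi <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  row <- depot_mean_fac(fac, roi)
  expect_equal(row$ndb, 2.5)
  expect_equal(row$n_voxels, 2L)
  expect_equal(row$fpufa, 0.1)
  expect_error(depot_mean_fac(fac, matrix(FALSE, 2, 2)), "empty ROI")
})
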