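#' Region-grow the subcutaneous fat mask
#'
#' Grows a 4-connected region from a seed voxel over all voxels whose fat
#' fraction meets the growth threshold, within a single slice. This
#' reproduces a first-pass subcutaneous adipose tissue (SAT) outline: the
#' subcutaneous ring is the connected high-fat-fraction component touching
#' the body outline, so a single seed anywhere on the ring recovers it
#' without leaking into the visceral compartment (which is separated by
#' the low-fat abdominal-wall muscle).
#'
#' @param ff fat-fraction matrix (rows x cols) or single-slice array.
#'   `NA` voxels never join the region.
#' @param seed integer `c(row, col)` inside the ring; if `NULL`, the
#'   highest-fat-fraction voxel of the slice is used.
#' @param growth_threshold minimum fat fraction for membership
#'   (default 0.5).
#' @return logical matrix, `TRUE` on the grown region.
#' @export
region_grow_sat <- function(ff, seed = NULL, growth_threshold = 0.5) {
  ff <- as_slice(ff)
  eligible <- !is.na(ff) & ff >= growth_threshold
  if (is.null(seed)) {
    seed <- which(ff == max(ff, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  }
  seed <- as.integer(seed)
  if (seed[1L] < 1L || seed[1L] > nrow(ff) || seed[2L] < 1L ||
      seed[2L] > ncol(ff))
    stop("seed outside the image grid")
  if (!eligible[seed[1L], seed[2L]])
    stop("seed voxel fat fraction is below the growth threshold")
  grown <- matrix(FALSE, nrow(ff), ncol(ff))
  grown[seed[1L], seed[2L]] <- TRUE
  repeat {
    nb <- shift_or(grown)
    new <- nb & eligible & !grown
    if (!any(new)) break
    grown <- grown | new
  }
  grown
}

# Union of the four 4-connected neighbour shifts of a logical matrix.
shift_or <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

as_slice <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3L && d[3L] == 1L) return(array(x, d[1:2]))
  stop("expected a 2-D slice (or single-slice 3-D array)")
}

# Pixel-center point-in-polygon rasterization (even-odd rule). Polygons
# are matrices with columns (row, col), 1-based pixel-center coordinates.
rasterize_polygon <- function(polygon, dims) {
  polygon <- as.matrix(polygon)
  if (nrow(unique(polygon)) < 3L) stop("degenerate polygon (< 3 vertices)")
  area2 <- abs(sum(polygon[, 1] * c(polygon[-1, 2], polygon[1, 2]) -
                   polygon[, 2] * c(polygon[-1, 1], polygon[1, 1])))
  if (area2 <= 0) stop("degenerate polygon (zero area)")
  centers <- cbind(rep(seq_len(dims[1L]), times = dims[2L]),
                   rep(seq_len(dims[2L]), each = dims[1L]))
  inside <- mgcv::in.out(rbind(polygon, polygon[1L, , drop = FALSE]),
                         centers)
  matrix(inside, dims[1L], dims[2L])
}

#' Delineate the visceral depot from a manual cavity outline
#'
#' Voxels whose pixel centers fall inside the manually drawn abdominal
#' cavity polygon and that are not part of the subcutaneous mask. The
#' polygon is drawn to exclude the spinal area, mirroring the manual
#' procedure.
#'
#' @param cavity_polygon matrix with columns `(row, col)`, 1-based
#'   pixel-center map coordinates (see [read_polygon()] for the 0-based
#'   file convention).
#' @param sat_mask logical subcutaneous mask on the same grid.
#' @param ff fat-fraction matrix defining the grid (dimensions only).
#' @return logical visceral mask.
#' @export
delineate_vat <- function(cavity_polygon, sat_mask, ff) {
  sat_mask <- as_slice(sat_mask); ff <- as_slice(ff)
  stopifnot(identical(dim(sat_mask), dim(ff)))
  inside <- rasterize_polygon(cavity_polygon, dim(ff))
  inside & !sat_mask
}

#' Split subcutaneous fat into deep and superficial compartments
#'
#' Restricts the SAT mask to the posterior (lower) half of the image rows
#' -- the anterior fascia is not reliably separable -- and labels the
#' remaining SAT voxels as deep (inside the fascia outline, toward the
#' cavity) or superficial (outside it, toward the skin).
#'
#' @param sat_mask logical SAT mask (single slice).
#' @param fascia_polyline fascia outline as a closed polygon, matrix with
#'   columns `(row, col)`; voxels inside it are "deep".
#' @return list of logical masks `dsat`, `ssat`.
#' @export
split_sat_depots <- function(sat_mask, fascia_polyline) {
  sat_mask <- as_slice(sat_mask)
  fascia_polyline <- as.matrix(fascia_polyline)
  # reject an outline whose bounding box misses the grid entirely
  if (all(fascia_polyline[, 1] < 0.5) ||
      all(fascia_polyline[, 1] > nrow(sat_mask) + 0.5) ||
      all(fascia_polyline[, 2] < 0.5) ||
      all(fascia_polyline[, 2] > ncol(sat_mask) + 0.5))
    stop("fascia polyline lies outside the image grid")
  lower <- matrix(FALSE, nrow(sat_mask), ncol(sat_mask))
  lower[seq.int(floor(nrow(sat_mask) / 2) + 1L, nrow(sat_mask)), ] <- TRUE
  deep_side <- rasterize_polygon(fascia_polyline, dim(sat_mask))
  base <- sat_mask & lower
  list(dsat = base & deep_side, ssat = base & !deep_side)
}

#' Refine a depot mask into an analysis ROI
#'
#' Keeps the voxels of a depot mask with fat fraction strictly above
#' `ff_min` (and, optionally, at or below `ff_max`) and T2* strictly above
#' `t2star_min`. Defaults follow the study rule: fat fraction > 0.9 and
#' T2* > 20 ms. Invalid (`NA`) voxels are excluded.
#'
#' @param depot_mask logical mask.
#' @param ff fat-fraction map.
#' @param t2star T2* map in seconds.
#' @param ff_min strict lower fat-fraction bound.
#' @param ff_max inclusive upper fat-fraction clip (`NULL` disables);
#'   the default 1.1 is inert for magnitude-derived fat fractions, which
#'   cannot exceed 1.
#' @param t2star_min strict lower T2* bound in seconds.
#' @return logical ROI mask, a subset of `depot_mask`.
#' @export
refine_roi <- function(depot_mask, ff, t2star, ff_min = 0.9, ff_max = 1.1,
                       t2star_min = 0.020) {
  stopifnot(identical(dim(depot_mask), dim(ff)),
            identical(dim(ff), dim(t2star)))
  keep <- depot_mask & !is.na(ff) & !is.na(t2star) &
    (ff > ff_min) & (t2star > t2star_min)
  if (!is.null(ff_max)) keep <- keep & (ff <= ff_max)
  keep & !is.na(keep)
}

#' Mean fatty-acid composition within an ROI
#'
#' Arithmetic mean of the voxel-wise composition maps over the valid
#' voxels of an ROI. Because the fraction formulas are linear in
#' `(ndb, nmidb)`, averaging fractions voxel-wise equals converting the
#' ROI-mean double-bond counts.
#'
#' @param fac a `fac_maps` object.
#' @param roi_mask logical ROI mask on the same grid.
#' @return one-row `data.frame` with `fsfa`, `fmufa`, `fpufa`, `ndb`,
#'   `nmidb`, `fat_fraction` and `n_voxels`.
#' @export
depot_mean_fac <- function(fac, roi_mask) {
  stopifnot(inherits(fac, "fac_maps"))
  sel <- roi_mask & fac$valid
  n <- sum(sel)
  if (n == 0L) stop("empty ROI: no valid voxels selected")
  data.frame(fsfa = mean(fac$fsfa[sel]), fmufa = mean(fac$fmufa[sel]),
             fpufa = mean(fac$fpufa[sel]), ndb = mean(fac$ndb[sel]),
             nmidb = mean(fac$nmidb[sel]),
             fat_fraction = mean(fac$fat_fraction[sel]), n_voxels = n)
}
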