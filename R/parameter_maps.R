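#' Fatty-acid fractions from double-bond parameters
#'
#' Under the assumption that fatty acids carry at most two double bonds,
#' the saturation fractions follow linearly from the mean double-bond
#' counts:
#' \deqn{f_{SFA} = 1 - (ndb - nmidb)/3,\quad
#'       f_{MUFA} = (ndb - 2\,nmidb)/3,\quad
#'       f_{PUFA} = nmidb/3.}
#' The three fractions sum to one identically. Values falling outside
#' `[0, 1]` (possible only when the inputs violate the at-most-two-double-
#' bonds assumption) are clipped and flagged.
#'
#' @param ndb,nmidb numeric vectors or arrays, `ndb >= 0`,
#'   `0 <= nmidb <= ndb`. `NA`s pass through.
#' @return list of arrays `fsfa`, `fmufa`, `fpufa`, `clipped` (logical).
#' @export
fractions_from_double_bonds <- function(ndb, nmidb) {
  ok <- !is.na(ndb) & !is.na(nmidb)
  if (any(ndb[ok] < 0) || any(nmidb[ok] < 0) || any(nmidb[ok] > ndb[ok]))
    stop("require ndb >= 0 and 0 <= nmidb <= ndb")
  fsfa <- 1 - (ndb - nmidb) / 3
  fmufa <- (ndb - 2 * nmidb) / 3
  fpufa <- nmidb / 3
  clipped <- (fsfa < 0) | (fsfa > 1) | (fmufa < 0) | (fmufa > 1) |
    (fpufa < 0) | (fpufa > 1)
  clipped[is.na(clipped)] <- FALSE
  clamp <- function(x) pmin(pmax(x, 0), 1)
  list(fsfa = clamp(fsfa), fmufa = clamp(fmufa), fpufa = clamp(fpufa),
       clipped = clipped)
}

#' Invert the fraction formulas
#'
#' Exact inverse of [fractions_from_double_bonds()]:
#' `ndb = 3 (fmufa + 2 fpufa)`, `nmidb = 3 fpufa`.
#'
#' @param fsfa,fmufa,fpufa fractions summing to one.
#' @return list with `ndb` and `nmidb`.
#' @export
double_bonds_from_fractions <- function(fsfa, fmufa, fpufa) {
  if (any(abs(fsfa + fmufa + fpufa - 1) > 1e-9, na.rm = TRUE))
    stop("fractions must sum to 1")
  list(ndb = 3 * (fmufa + 2 * fpufa), nmidb = 3 * fpufa)
}

#' Fat fraction
#'
#' The fat share of the total signal, `F / (W + F)`, computed from the
#' magnitudes of the fitted amplitudes. Voxels with no signal at all
#' (`W = F = 0`) return 0 and are reported in the `empty` flag.
#'
#' @param W_mag,F_mag non-negative amplitude magnitudes.
#' @return list with `ff` (in `[0, 1]`) and logical `empty`.
#' @export
fat_fraction <- function(W_mag, F_mag) {
  ok <- !is.na(W_mag) & !is.na(F_mag)
  if (any(W_mag[ok] < 0) || any(F_mag[ok] < 0))
    stop("amplitude magnitudes must be non-negative")
  tot <- W_mag + F_mag
  ff <- ifelse(tot > 0, F_mag / tot, 0)
  empty <- !is.na(tot) & tot == 0
  list(ff = ff, empty = empty)
}

#' T2* map from R2*
#'
#' Reciprocal relaxation time in seconds; an R2* of exactly zero maps to
#' `Inf` (no measurable decay).
#'
#' @param r2star relaxation rates, 1/s, non-negative.
#' @return T2* values in seconds.
#' @export
t2star_map <- function(r2star) {
  if (any(r2star < 0, na.rm = TRUE)) stop("r2star must be non-negative")
  ifelse(!is.na(r2star) & r2star == 0, Inf, 1 / r2star)
}

#' Derive fatty-acid composition maps from fitted parameter maps
#'
#' Converts a `parameter_maps` object into voxel-wise `fsfa`, `fmufa`,
#' `fpufa`, fat-fraction and T2* maps. Fractions are computed voxel-wise
#' (the linear formulas make voxel-wise conversion and ROI averaging
#' commute). Invalid voxels stay `NA`.
#'
#' @param maps a `parameter_maps` object from [fit_image()].
#' @return object of class `fac_maps` with arrays `fsfa`, `fmufa`,
#'   `fpufa`, `fat_fraction`, `t2star`, the `valid` mask and the shared
#'   `affine`.
#' @export
fac_maps <- function(maps) {
  stopifnot(inherits(maps, "parameter_maps"))
  fr <- fractions_from_double_bonds(maps$ndb, maps$nmidb)
  ff <- fat_fraction(maps$W_mag, maps$F_mag)
  ffm <- ff$ff
  ffm[ff$empty] <- NA_real_
  structure(list(fsfa = fr$fsfa, fmufa = fr$fmufa, fpufa = fr$fpufa,
                 fat_fraction = ffm,
                 t2star = t2star_map(maps$r2star),
                 ndb = maps$ndb, nmidb = maps$nmidb,
                 valid = maps$valid & !ff$empty,
                 affine = maps$affine),
            class = "fac_maps")
}
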