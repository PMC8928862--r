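#' Eight-resonance triglyceride fat model specification
#'
#' Defines the spectral model used throughout the package: eight fat
#' resonance groups (A--H) with fixed chemical shifts, a water reference,
#' and amplitude rules parameterized by the mean number of double bonds
#' (`ndb`), the mean number of methylene-interrupted double bonds
#' (`nmidb`) and a fixed mean fatty-acid chain length.
#'
#' The default shifts place the olefinic protons (group A) at 5.28 ppm and
#' the terminal methyl (group H) at 0.90 ppm, with water referenced at
#' 4.70 ppm. The chain length is fixed (default 17.3 carbons) rather than
#' fitted, which removes one nonlinear unknown and stabilizes the
#' voxel-wise estimation; interpersonal variation of chain length in human
#' adipose tissue is small enough for a fixed value to be adequate.
#'
#' @param chemical_shifts named numeric vector of ppm values for the eight
#'   fat groups `A`..`H`; must be strictly decreasing.
#' @param water_shift water reference in ppm.
#' @param chain_length mean fatty-acid carbon chain length (dimensionless,
#'   > 4).
#' @param field_strength main field strength in tesla.
#' @param gyromagnetic_ratio proton gyromagnetic ratio in MHz/T.
#' @return an object of class `fat_model_spec`.
#' @export
fat_model_spec <- function(chemical_shifts = c(A = 5.28, B = 4.22, C = 2.75,
                                               D = 2.25, E = 2.02, F = 1.57,
                                               G = 1.30, H = 0.90),
                           water_shift = 4.70,
                           chain_length = 17.3,
                           field_strength = 3.0,
                           gyromagnetic_ratio = 42.577) {
  stopifnot(length(chemical_shifts) == 8L,
            identical(names(chemical_shifts), LETTERS[1:8]))
  if (any(diff(chemical_shifts) >= 0))
    stop("chemical shifts must be strictly decreasing from A to H")
  if (chain_length <= 4) stop("chain_length must exceed 4")
  if (field_strength <= 0) stop("field_strength must be positive")
  structure(list(chemical_shifts = chemical_shifts,
                 water_shift = water_shift,
                 chain_length = chain_length,
                 field_strength = field_strength,
                 gyromagnetic_ratio = gyromagnetic_ratio),
            class = "fat_model_spec")
}

#' Multi-echo gradient-echo acquisition specification
#'
#' Echo timing and matrix geometry of the monopolar multi-echo protocol.
#' Defaults reproduce the study protocol: 12 echoes, first echo 1.13 ms,
#' spacing 1.56 ms, 96 x 128 matrix at 3 T.
#'
#' @param n_echoes number of echoes (>= 4; the linear subproblem has four
#'   complex unknowns).
#' @param te1 first echo time in seconds.
#' @param delta_te echo spacing in seconds.
#' @param matrix_size integer vector `c(rows, cols)`.
#' @param echo_times optional explicit echo-time vector (seconds),
#'   overriding the uniform `te1 + k * delta_te` grid.
#' @param metadata free-form list (TR, flip angle, FOV, ...) carried along
#'   but not used by the signal model.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_echoes = 12L,
                             te1 = 1.13e-3,
                             delta_te = 1.56e-3,
                             matrix_size = c(96L, 128L),
                             echo_times = NULL,
                             metadata = list()) {
  if (is.null(echo_times)) {
    stopifnot(n_echoes >= 4L, te1 > 0, delta_te > 0)
    echo_times <- te1 + (seq_len(n_echoes) - 1L) * delta_te
  } else {
    n_echoes <- length(echo_times)
    stopifnot(n_echoes >= 4L, all(echo_times > 0))
    te1 <- echo_times[1L]
    delta_te <- if (n_echoes > 1L) echo_times[2L] - echo_times[1L] else NA_real_
  }
  structure(list(n_echoes = as.integer(n_echoes), te1 = te1,
                 delta_te = delta_te, matrix_size = as.integer(matrix_size),
                 echo_times = echo_times, metadata = metadata),
            class = "acquisition_spec")
}

#' Echo times of an acquisition
#' @param acq an `acquisition_spec`.
#' @return numeric vector of echo times in seconds.
#' @export
echo_times <- function(acq) acq$echo_times

#' Water-referenced angular frequencies of the fat resonances
#'
#' Converts the ppm offsets of the eight fat groups relative to water into
#' angular frequencies at the configured field strength:
#' `omega_m = 2 * pi * (delta_m - delta_water) * gamma * B0` with `gamma * B0`
#' in Hz/ppm. Resonances below water in ppm get negative frequencies.
#'
#' @param spec a `fat_model_spec`.
#' @return named numeric vector, rad/s, one entry per fat group A..H.
#' @export
resonance_frequencies <- function(spec) {
  hz_per_ppm <- spec$gyromagnetic_ratio * spec$field_strength  # MHz -> Hz/ppm
  2 * pi * (spec$chemical_shifts - spec$water_shift) * hz_per_ppm
}

#' Resonance amplitudes of the fixed-chain-length triglyceride model
#'
#' Proton-count amplitudes per resonance group:
#' `alpha_A = 2 ndb`, `alpha_B = 4`, `alpha_C = 2 nmidb`, `alpha_D = 6`,
#' `alpha_E = 4 (ndb - nmidb)`, `alpha_F = 6`,
#' `alpha_G = 6 (cl - 4) - 8 ndb + 2 nmidb`, `alpha_H = 9`.
#' With the default chain length 17.3 the methylene constant `6 (cl - 4)`
#' is 79.8 and the total proton count is `104.8 - 2 ndb`.
#'
#' @param ndb mean number of double bonds (>= 0).
#' @param nmidb mean number of methylene-interrupted double bonds
#'   (0 <= nmidb <= ndb).
#' @param spec a `fat_model_spec`.
#' @return list with `alpha` (named vector A..H), `total` (sum of alpha)
#'   and `norm` (the normalization factor `1 / sum(alpha)`).
#' @export
resonance_amplitudes <- function(ndb, nmidb, spec = fat_model_spec()) {
  check_double_bonds(ndb, nmidb)
  cl <- spec$chain_length
  alpha <- c(A = 2 * ndb, B = 4, C = 2 * nmidb, D = 6,
             E = 4 * (ndb - nmidb), F = 6,
             G = 6 * (cl - 4) - 8 * ndb + 2 * nmidb, H = 9)
  if (any(alpha < 0))
    stop("negative resonance amplitude: (ndb, nmidb) = (", ndb, ", ", nmidb,
         ") is not a physical composition at chain length ", cl)
  list(alpha = alpha, total = sum(alpha), norm = 1 / sum(alpha))
}

check_double_bonds <- function(ndb, nmidb) {
  if (any(ndb < 0) || any(nmidb < 0) || any(nmidb > ndb))
    stop("require ndb >= 0 and 0 <= nmidb <= ndb")
  invisible(TRUE)
}

# Total proton count as a function of ndb; linear because the +2ndb of
# group A and +4ndb of group E cancel against -8ndb in G except for -2ndb,
# while all nmidb terms cancel exactly.
amplitude_total <- function(ndb, spec = fat_model_spec()) {
  25 + 6 * (spec$chain_length - 4) - 2 * ndb
}

#' Linearized basis coefficients over the echo times
#'
#' Groups the eight complex resonance phasors `E_m(t) = exp(i omega_m t)`
#' into the three coefficient vectors multiplying F, F*ndb and F*nmidb in
#' the linearized signal model:
#' \deqn{P_F = 4E_B + 6E_D + 6E_F + 6(cl-4)E_G + 9E_H}
#' \deqn{P_{ndb} = 2E_A + 4E_E - 8E_G}
#' \deqn{P_{nmidb} = 2E_C - 4E_E + 2E_G}
#'
#' @param acq an `acquisition_spec` (or numeric vector of echo times in
#'   seconds).
#' @param spec a `fat_model_spec`.
#' @param printed_pf_ea if `TRUE`, add a unit `E_A` term to `P_F`. This
#'   variant matches one published rendering of the coefficient formula
#'   but is inconsistent with the amplitude table (group A carries no
#'   constant term) and breaks the identity that the signal extrapolated
#'   to t = 0 equals W + F; it is exposed only for comparison and is off
#'   by default.
#' @return list of complex vectors `p_f`, `p_ndb`, `p_nmidb`, plus the
#'   echo-time vector `t`.
#' @export
basis_coefficients <- function(acq, spec = fat_model_spec(),
                               printed_pf_ea = FALSE) {
  t <- if (inherits(acq, "acquisition_spec")) acq$echo_times else acq
  omega <- resonance_frequencies(spec)
  E <- exp(1i * outer(t, omega))          # n_echoes x 8, columns A..H
  colnames(E) <- names(omega)
  cG <- 6 * (spec$chain_length - 4)
  p_f <- 4 * E[, "B"] + 6 * E[, "D"] + 6 * E[, "F"] + cG * E[, "G"] +
    9 * E[, "H"]
  if (printed_pf_ea) p_f <- p_f + E[, "A"]
  p_ndb <- 2 * E[, "A"] + 4 * E[, "E"] - 8 * E[, "G"]
  p_nmidb <- 2 * E[, "C"] - 4 * E[, "E"] + 2 * E[, "G"]
  list(p_f = unname(p_f), p_ndb = unname(p_ndb),
       p_nmidb = unname(p_nmidb), t = t)
}

#' Noiseless forward signal of a voxel
#'
#' Evaluates the linearized multi-echo signal model at every echo time:
#' \deqn{S(t) = [W + F f (P_F + P_{ndb} ndb + P_{nmidb} nmidb)]
#'       e^{(i 2\pi \psi - R_2^*) t}}
#' with `f = 1 / sum(alpha)` the proton normalization, `psi` the
#' off-resonance field map in Hz and `r2star` the effective transverse
#' relaxation rate in 1/s.
#'
#' @param W,F complex (or real) water and fat amplitudes, arbitrary units.
#' @param ndb,nmidb triglyceride double-bond parameters.
#' @param psi field map, Hz.
#' @param r2star effective relaxation rate, 1/s (>= 0).
#' @param acq an `acquisition_spec` or echo-time vector (seconds).
#' @param spec a `fat_model_spec`.
#' @param basis optionally a precomputed result of [basis_coefficients()].
#' @return complex vector of per-echo signals.
#' @export
forward_signal <- function(W, F, ndb, nmidb, psi, r2star,
                           acq = acquisition_spec(), spec = fat_model_spec(),
                           basis = NULL) {
  if (r2star < 0) stop("r2star must be non-negative")
  if (is.null(basis)) basis <- basis_coefficients(acq, spec)
  amp <- resonance_amplitudes(ndb, nmidb, spec)
  fat_term <- amp$norm *
    (basis$p_f + basis$p_ndb * ndb + basis$p_nmidb * nmidb)
  (W + F * fat_term) * exp((1i * 2 * pi * psi - r2star) * basis$t)
}
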