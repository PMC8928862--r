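#' Digital abdominal phantom specification
#'
#' Geometry and ground truth of a single-slice abdominal phantom: an
#' elliptical body cross-section with a subcutaneous fat ring (split by a
#' fascia ellipse into deep and superficial compartments), a visceral fat
#' disk inside the abdominal cavity, a posterior spine wedge excluded from
#' the visceral depot, and lean tissue elsewhere in the cavity. Row index
#' increases toward the posterior (supine acquisition), so the "lower
#' half" of the image is the posterior half.
#'
#' All coordinates are `(row, col)` pixel units on the acquisition matrix.
#'
#' @param matrix_size integer `c(rows, cols)`.
#' @param body_center,body_semiaxes outer body ellipse.
#' @param sat_thickness thickness of the subcutaneous ring, pixels.
#' @param fascia_offset depth of the fascia below the skin, pixels
#'   (must be < `sat_thickness`).
#' @param vat_center,vat_semiaxes visceral fat disk.
#' @param spine_center,spine_semiaxes spine wedge (low fat, short T2*).
#' @param region_truth named list of per-region ground truth, each entry a
#'   list with `ff`, `ndb`, `nmidb`, `r2star`. Regions: `ssat`, `dsat`,
#'   `vat`, `cavity`, `spine`. Defaults use a fat fraction of 0.95 in
#'   adipose regions, composition at the high-unsaturation end of the
#'   adult adipose range, and T2* of 25 ms in fat.
#' @param field_coeffs polynomial field-map coefficients (Hz) over
#'   normalized coordinates x, y in `[-1, 1]`:
#'   `c(const, x, y, x^2, y^2, xy)`.
#' @param total_amplitude W + F in body voxels, arbitrary units.
#' @param snr peak signal magnitude divided by the per-channel noise
#'   standard deviation; `Inf` disables noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(96L, 128L),
                         body_center = NULL,
                         body_semiaxes = NULL,
                         sat_thickness = 10,
                         fascia_offset = 5,
                         vat_center = NULL,
                         vat_semiaxes = NULL,
                         spine_center = NULL,
                         spine_semiaxes = NULL,
                         region_truth = NULL,
                         field_coeffs = c(20, 15, -10, 8, -6, 4),
                         total_amplitude = 100,
                         snr = 50) {
  ms <- as.integer(matrix_size)
  ctr <- c((ms[1] + 1) / 2, (ms[2] + 1) / 2)
  if (is.null(body_center)) body_center <- ctr
  if (is.null(body_semiaxes)) body_semiaxes <- round(0.44 * ms) - c(0, 3)
  inner_semi <- body_semiaxes - sat_thickness
  if (is.null(vat_center)) vat_center <- body_center - c(0.09 * ms[1], 0)
  if (is.null(vat_semiaxes)) vat_semiaxes <- pmax(round(0.42 * inner_semi), 4)
  if (is.null(spine_center))
    spine_center <- c(body_center[1] + 0.67 * inner_semi[1], body_center[2])
  if (is.null(spine_semiaxes))
    spine_semiaxes <- pmax(round(0.19 * inner_semi), 2)
  if (fascia_offset >= sat_thickness)
    stop("fascia_offset must be smaller than sat_thickness")
  if (is.null(region_truth))
    region_truth <- list(
      ssat   = list(ff = 0.95, ndb = 2.64, nmidb = 0.54, r2star = 40),
      dsat   = list(ff = 0.95, ndb = 2.56, nmidb = 0.44, r2star = 40),
      vat    = list(ff = 0.95, ndb = 2.49, nmidb = 0.39, r2star = 40),
      cavity = list(ff = 0.10, ndb = 2.50, nmidb = 0.40, r2star = 30),
      spine  = list(ff = 0.20, ndb = 2.50, nmidb = 0.40, r2star = 80))
  stopifnot(all(c("ssat", "dsat", "vat", "cavity", "spine") %in%
                  names(region_truth)), snr > 0)
  structure(list(matrix_size = ms, body_center = body_center,
                 body_semiaxes = body_semiaxes,
                 sat_thickness = sat_thickness,
                 fascia_offset = fascia_offset,
                 vat_center = vat_center, vat_semiaxes = vat_semiaxes,
                 spine_center = spine_center,
                 spine_semiaxes = spine_semiaxes,
                 region_truth = region_truth,
                 field_coeffs = field_coeffs,
                 total_amplitude = total_amplitude, snr = snr),
            class = "phantom_spec")
}

inside_ellipse <- function(rows, cols, center, semiaxes) {
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  ((R - center[1]) / semiaxes[1])^2 + ((C - center[2]) / semiaxes[2])^2 <= 1
}

#' Polygonal outline of an ellipse
#'
#' @param center,semiaxes ellipse in `(row, col)` pixel coordinates.
#' @param n number of vertices.
#' @return matrix with columns `(row, col)`.
#' @export
ellipse_polygon <- function(center, semiaxes, n = 90L) {
  th <- 2 * pi * seq_len(n) / n
  cbind(center[1] + semiaxes[1] * sin(th), center[2] + semiaxes[2] * cos(th))
}

# Region label codes used by the phantom.
PHANTOM_LABELS <- c(background = 0L, ssat = 1L, dsat = 2L, vat = 3L,
                    spine = 4L, cavity = 5L)

phantom_labels <- function(spec) {
  ms <- spec$matrix_size
  rows <- seq_len(ms[1]); cols <- seq_len(ms[2])
  body <- inside_ellipse(rows, cols, spec$body_center, spec$body_semiaxes)
  inner <- inside_ellipse(rows, cols, spec$body_center,
                          spec$body_semiaxes - spec$sat_thickness)
  fascia <- inside_ellipse(rows, cols, spec$body_center,
                           spec$body_semiaxes - spec$fascia_offset)
  vat <- inside_ellipse(rows, cols, spec$vat_center, spec$vat_semiaxes)
  spine <- inside_ellipse(rows, cols, spec$spine_center,
                          spec$spine_semiaxes)
  if (any(vat & spine)) stop("phantom regions overlap: vat and spine")
  if (any(vat & !inner) || any(spine & !inner))
    stop("phantom regions overlap: cavity structures reach the fat ring")
  lab <- matrix(PHANTOM_LABELS["background"], ms[1], ms[2])
  lab[body & !inner & !fascia] <- PHANTOM_LABELS["ssat"]
  lab[body & !inner & fascia] <- PHANTOM_LABELS["dsat"]
  lab[inner] <- PHANTOM_LABELS["cavity"]
  lab[vat] <- PHANTOM_LABELS["vat"]
  lab[spine] <- PHANTOM_LABELS["spine"]
  lab
}

phantom_field_map <- function(spec) {
  ms <- spec$matrix_size
  x <- (seq_len(ms[1]) - (ms[1] + 1) / 2) / ((ms[1] - 1) / 2)
  y <- (seq_len(ms[2]) - (ms[2] + 1) / 2) / ((ms[2] - 1) / 2)
  X <- matrix(x, ms[1], ms[2])
  Y <- matrix(y, ms[1], ms[2], byrow = TRUE)
  k <- spec$field_coeffs
  k[1] + k[2] * X + k[3] * Y + k[4] * X^2 + k[5] * Y^2 + k[6] * X * Y
}

#' Generate a phantom echo series with ground truth
#'
#' Builds per-voxel truth maps from the phantom geometry, synthesizes the
#' noiseless multi-echo signal through the forward model, and adds
#' i.i.d. complex Gaussian noise at the configured SNR (peak magnitude
#' over per-channel standard deviation).
#'
#' @param spec a `phantom_spec`.
#' @param acq an `acquisition_spec`; its matrix size must match the
#'   phantom's.
#' @param model_spec a `fat_model_spec`.
#' @param seed integer seed for the noise draw (ignored when
#'   `spec$snr` is infinite).
#' @return list with `echo` (an `echo_series`: complex array
#'   `rows x cols x 1 x echoes` plus echo times) and `truth` (label
#'   matrix, per-voxel `W`, `F`, `ndb`, `nmidb`, `psi`, `r2star` maps,
#'   depot masks, and the cavity/fascia outlines and a SAT seed voxel for
#'   the segmentation stage).
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             acq = acquisition_spec(),
                             model_spec = fat_model_spec(),
                             seed = 1L) {
  ms <- spec$matrix_size
  if (!identical(as.integer(acq$matrix_size), ms))
    stop("acquisition matrix size does not match the phantom grid")
  lab <- phantom_labels(spec)
  psi <- phantom_field_map(spec)
  z <- matrix(0, ms[1], ms[2])
  W <- z; Fm <- z; ndb <- z; nmidb <- z; r2star <- z
  basis <- basis_coefficients(acq, model_spec)
  nt <- length(basis$t)
  signal <- matrix(0i, nt, prod(ms))
  for (reg in names(PHANTOM_LABELS)[-1]) {
    idx <- which(lab == PHANTOM_LABELS[reg])
    if (!length(idx)) next
    tr <- spec$region_truth[[reg]]
    W[idx] <- (1 - tr$ff) * spec$total_amplitude
    Fm[idx] <- tr$ff * spec$total_amplitude
    ndb[idx] <- tr$ndb; nmidb[idx] <- tr$nmidb; r2star[idx] <- tr$r2star
    amp <- resonance_amplitudes(tr$ndb, tr$nmidb, model_spec)
    fat_term <- amp$norm * (basis$p_f + basis$p_ndb * tr$ndb +
                              basis$p_nmidb * tr$nmidb)
    a <- (1 - tr$ff) * spec$total_amplitude +
      tr$ff * spec$total_amplitude * fat_term     # homogeneous per region
    decay <- exp(outer(basis$t, 1i * 2 * pi * psi[idx] - r2star[idx]))
    signal[, idx] <- a * decay
  }
  if (is.finite(spec$snr)) {
    set.seed(as.integer(seed))
    sigma <- max(Mod(signal)) / spec$snr
    n <- length(signal)
    signal <- signal + complex(real = stats::rnorm(n, sd = sigma),
                               imaginary = stats::rnorm(n, sd = sigma))
  }
  data <- array(0i, c(ms, 1L, nt))
  for (k in seq_len(nt)) data[, , 1L, k] <- matrix(signal[k, ], ms[1], ms[2])
  sat <- lab == PHANTOM_LABELS["ssat"] | lab == PHANTOM_LABELS["dsat"]
  inner_semi <- spec$body_semiaxes - spec$sat_thickness
  cavity_polygon <- ellipse_polygon(
    spec$body_center - c(0.08 * ms[1], 0), 0.72 * inner_semi)
  fascia_polygon <- ellipse_polygon(spec$body_center,
                                    spec$body_semiaxes - spec$fascia_offset)
  seed_voxel <- which(sat, arr.ind = TRUE)[1L, ]
  truth <- list(label = lab, W = W, F = Fm, ndb = ndb, nmidb = nmidb,
                psi = psi, r2star = r2star,
                sat = sat,
                dsat = lab == PHANTOM_LABELS["dsat"],
                ssat = lab == PHANTOM_LABELS["ssat"],
                vat = lab == PHANTOM_LABELS["vat"],
                cavity_polygon = cavity_polygon,
                fascia_polygon = fascia_polygon,
                seed_voxel = as.integer(seed_voxel))
  echo <- echo_series(data, echo_times = basis$t)
  list(echo = echo, truth = truth)
}

#' Two-group cohort specification
#'
#' Depot-level distributions of `(ndb, nmidb)` for two groups. Defaults
#' emulate a two-group abdominal study: group A of 15 subjects with a more
#' saturated adipose composition and group B of 23 subjects with a higher
#' polyunsaturated fraction. Each depot's distribution is normal, centered
#' on the group median with standard deviation `IQR / 1.349`, truncated to
#' the valid composition region (`ndb >= 0`, `0 <= nmidb <= ndb`,
#' fractions in `[0, 1]`).
#'
#' @param n_a,n_b group sizes (>= 2).
#' @param params nested list `params[[group]][[depot]]` with elements
#'   `ndb` and `nmidb`, each `c(median, iqr_lo, iqr_hi)`; groups `a`, `b`
#'   and depots `sat`, `vat`, `dsat`, `ssat`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_a = 15L, n_b = 23L, params = NULL) {
  stopifnot(n_a >= 2L, n_b >= 2L)
  if (is.null(params)) params <- list(
    a = list(  # more saturated group
      sat  = list(ndb = c(2.24, 2.08, 2.33), nmidb = c(0.26, 0.20, 0.33)),
      vat  = list(ndb = c(2.20, 2.09, 2.27), nmidb = c(0.22, 0.18, 0.25)),
      dsat = list(ndb = c(2.14, 2.03, 2.26), nmidb = c(0.22, 0.19, 0.26)),
      ssat = list(ndb = c(2.27, 2.16, 2.34), nmidb = c(0.31, 0.21, 0.39))),
    b = list(  # more polyunsaturated group
      sat  = list(ndb = c(2.56, 2.52, 2.63), nmidb = c(0.48, 0.43, 0.56)),
      vat  = list(ndb = c(2.49, 2.42, 2.61), nmidb = c(0.39, 0.35, 0.46)),
      dsat = list(ndb = c(2.56, 2.49, 2.63), nmidb = c(0.44, 0.42, 0.53)),
      ssat = list(ndb = c(2.64, 2.56, 2.75), nmidb = c(0.54, 0.58, 0.68))))
  for (g in c("a", "b")) {
    stopifnot(all(c("sat", "vat", "dsat", "ssat") %in% names(params[[g]])))
    for (d in names(params[[g]])) {
      p <- params[[g]][[d]]
      if (p$ndb[3] < p$ndb[2] || p$nmidb[3] < p$nmidb[2])
        stop("invalid distribution: IQR upper bound below lower bound")
    }
  }
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 params = params),
            class = "cohort_spec")
}

# sd from IQR width of a normal distribution
iqr_sd <- function(lo, hi) (hi - lo) / (2 * stats::qnorm(0.75))

valid_composition <- function(ndb, nmidb) {
  ndb >= 0 & nmidb >= 0 & nmidb <= ndb & (ndb - nmidb) <= 3 &
    (ndb - 2 * nmidb) >= 0
}

draw_depot_pair <- function(p, n = 1L) {
  out <- matrix(NA_real_, n, 2L)
  need <- seq_len(n)
  for (i in 1:200) {
    ndb <- stats::rnorm(length(need), p$ndb[1], iqr_sd(p$ndb[2], p$ndb[3]))
    nmidb <- stats::rnorm(length(need), p$nmidb[1],
                          iqr_sd(p$nmidb[2], p$nmidb[3]))
    ok <- valid_composition(ndb, nmidb)
    out[need[ok], ] <- cbind(ndb[ok], nmidb[ok])
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) stop("could not draw a valid composition in 200 tries")
  colnames(out) <- c("ndb", "nmidb")
  out
}

#' Draw subject-level depot compositions for a cohort
#'
#' Samples per-subject, per-depot `(ndb, nmidb)` from the group
#' distributions without building images. Deterministic given the seed.
#'
#' @param cohort a `cohort_spec`.
#' @param seed integer master seed.
#' @return `data.frame` with columns `subject`, `group` (`"a"`/`"b"`),
#'   `depot`, `ndb`, `nmidb`.
#' @export
draw_subject_fac <- function(cohort, seed = 1L) {
  set.seed(as.integer(seed))
  depots <- c("sat", "vat", "dsat", "ssat")
  rows <- list()
  sid <- 0L
  for (g in c("a", "b")) {
    n <- if (g == "a") cohort$n_a else cohort$n_b
    for (i in seq_len(n)) {
      sid <- sid + 1L
      for (d in depots) {
        x <- draw_depot_pair(cohort$params[[g]][[d]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%03d", sid), group = g, depot = d,
          ndb = x[1, "ndb"], nmidb = x[1, "nmidb"])
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a two-group imaging cohort
#'
#' Draws per-subject depot compositions from the group distributions and
#' instantiates one phantom per subject with those values painted into the
#' corresponding regions. Per-subject seeds are derived from the master
#' seed by counter, so regeneration with the same master seed is
#' bit-identical and independent of platform.
#'
#' @param cohort a `cohort_spec`.
#' @param phantom_template a `phantom_spec` providing geometry, SNR and
#'   non-adipose truth.
#' @param acq an `acquisition_spec`.
#' @param model_spec a `fat_model_spec`.
#' @param master_seed integer.
#' @param images if `FALSE`, skip image synthesis and return only subject
#'   metadata with true depot compositions (used for statistical
#'   calibration at scale).
#' @return list of subjects, each a list with `id`, `group`, `true_fac`
#'   (per-depot data.frame) and, when `images = TRUE`, `echo` and `truth`
#'   as in [generate_phantom()].
#' @export
simulate_cohort <- function(cohort = cohort_spec(),
                            phantom_template = phantom_spec(),
                            acq = acquisition_spec(),
                            model_spec = fat_model_spec(),
                            master_seed = 1L, images = TRUE) {
  groups <- c(rep("a", cohort$n_a), rep("b", cohort$n_b))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    seed_i <- as.integer(master_seed) + i
    set.seed(seed_i)
    g <- groups[i]
    vals <- lapply(c(sat = "sat", vat = "vat", dsat = "dsat",
                     ssat = "ssat"),
                   function(d) draw_depot_pair(cohort$params[[g]][[d]]))
    true_fac <- do.call(rbind, lapply(names(vals), function(d)
      data.frame(depot = d, ndb = vals[[d]][1, "ndb"],
                 nmidb = vals[[d]][1, "nmidb"])))
    sub <- list(id = sprintf("S%03d", i), group = g, true_fac = true_fac,
                seed = seed_i)
    if (images) {
      spec_i <- phantom_template
      for (d in c("vat", "dsat", "ssat")) {
        spec_i$region_truth[[d]]$ndb <- vals[[d]][1, "ndb"]
        spec_i$region_truth[[d]]$nmidb <- vals[[d]][1, "nmidb"]
      }
      ph <- generate_phantom(spec_i, acq, model_spec, seed = seed_i)
      sub$echo <- ph$echo
      sub$truth <- ph$truth
    }
    subjects[[i]] <- sub
  }
  subjects
}
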