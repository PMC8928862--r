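#' Construct an echo series
#'
#' In-memory container for a complex multi-echo image: a 4-D complex
#' array `rows x cols x slices x echoes` with its echo-time vector and an
#' optional affine.
#'
#' @param data 4-D complex array.
#' @param echo_times numeric vector, seconds, one per echo.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(data, echo_times, affine = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("echo series data must be 4-D")
  if (d[4L] != length(echo_times))
    stop("echo count mismatch: ", d[4L], " volumes vs ",
         length(echo_times), " echo times")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("non-finite values in echo series data")
  structure(list(data = data, echo_times = echo_times, affine = affine),
            class = "echo_series")
}

#' Write an echo series as paired real/imaginary NIfTI volumes
#'
#' Complex data are stored as two 4-D NIfTI files (`<stem>_real.nii.gz`,
#' `<stem>_imag.nii.gz`) -- complex NIfTI datatypes are inconsistently
#' supported across readers -- plus a JSON sidecar `<stem>.json` carrying
#' the echo times in seconds.
#'
#' @param es an `echo_series`.
#' @param stem output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_echo_series <- function(es, stem) {
  stopifnot(inherits(es, "echo_series"))
  paths <- c(real = paste0(stem, "_real.nii.gz"),
             imag = paste0(stem, "_imag.nii.gz"),
             sidecar = paste0(stem, ".json"))
  RNifti::writeNifti(RNifti::asNifti(Re(es$data)), paths["real"])
  RNifti::writeNifti(RNifti::asNifti(Im(es$data)), paths["imag"])
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(list(echo_times = es$echo_times,
                            n_echoes = dim(es$data)[4L]),
                       paths["sidecar"], digits = I(17), auto_unbox = FALSE)
  invisible(paths)
}

#' Read an echo series written by [write_echo_series()]
#'
#' @param stem path prefix used at write time.
#' @return an `echo_series`.
#' @export
read_echo_series <- function(stem) {
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop("missing echo-time sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  re <- RNifti::readNifti(paste0(stem, "_real.nii.gz"))
  im <- RNifti::readNifti(paste0(stem, "_imag.nii.gz"))
  data <- array(complex(real = as.numeric(re), imaginary = as.numeric(im)),
                dim(re))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (dim(data)[4L] != length(meta$echo_times))
    stop("echo count mismatch: ", dim(data)[4L], " volumes vs ",
         length(meta$echo_times), " echo times in sidecar")
  echo_series(data, as.numeric(meta$echo_times),
              affine = structure(RNifti::xform(re), code = NULL))
}

#' Write parameter or composition maps as NIfTI volumes
#'
#' One volume per map plus a JSON sidecar echoing the configuration used
#' (for provenance) and the validity mask.
#'
#' @param maps a `parameter_maps` or `fac_maps` object.
#' @param dir output directory (created if needed).
#' @param stem file-name prefix.
#' @param config optional configuration list echoed into the sidecar.
#' @return invisibly, the written paths.
#' @export
write_maps <- function(maps, dir, stem, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- setdiff(names(maps), "affine")
  paths <- character(0)
  for (nm in fields) {
    x <- maps[[nm]]
    if (!is.array(x) && !is.matrix(x)) next
    p <- file.path(dir, paste0(stem, "_", nm, ".nii.gz"))
    x[is.infinite(x)] <- .Machine$double.xmax  # NIfTI has no Inf
    RNifti::writeNifti(RNifti::asNifti(x * 1), p)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(list(maps = basename(paths),
                            config = config,
                            config_md5 = config_hash(config)),
                       sidecar, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(c(paths, sidecar))
}

#' Read a polygon or polyline from JSON
#'
#' Coordinates are stored 0-based, row-major (`[row, col]` pairs in map
#' index space) and converted to the package's 1-based pixel-center
#' convention.
#'
#' @param path JSON file with a top-level `coordinates` array of
#'   `[row, col]` pairs.
#' @return matrix with columns `(row, col)`, 1-based.
#' @export
read_polygon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- obj$coordinates
  if (is.null(coords) || length(coords) == 0)
    stop("no coordinates in polygon file: ", path)
  as.matrix(coords) + 1
}

#' Write a polygon to JSON (0-based coordinates)
#' @param polygon matrix with columns `(row, col)`, 1-based.
#' @param path output path.
#' @export
write_polygon <- function(polygon, path) {
  jsonlite::write_json(list(coordinates = unname(as.matrix(polygon)) - 1),
                       path, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, digits = NA, auto_unbox = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}

write_table_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline result table
#' @param path CSV written by [run_pipeline()] (first line is a config-hash
#'   comment).
#' @return `data.frame`.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

known_config_keys <- list(
  seed = NULL, out_dir = NULL,
  cohort = c("n_a", "n_b"),
  phantom = c("matrix_size", "snr", "sat_thickness", "fascia_offset",
              "field_coeffs", "total_amplitude"),
  acquisition = c("n_echoes", "te1", "delta_te"),
  model = c("chain_length", "field_strength", "gyromagnetic_ratio"),
  fit = c("psi_grid_points", "r2star_bounds", "min_signal_fraction",
          "max_iterations", "r2star_grid_points"),
  segmentation = c("growth_threshold", "ff_min", "t2star_min"))

#' Validate a pipeline configuration
#'
#' Checks section and key names against the documented schema and fills
#' defaults. Unknown sections or keys are rejected before any computation.
#'
#' @param config nested list (or path to a YAML file).
#' @return validated config list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(known_config_keys))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in setdiff(names(config), c("seed", "out_dir"))) {
    bad <- setdiff(names(config[[sec]]), known_config_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  defaults <- list(seed = 1L, out_dir = "results",
                   cohort = list(n_a = 15L, n_b = 23L),
                   phantom = list(), acquisition = list(), model = list(),
                   fit = list(), segmentation = list())
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages: simulate the two-group cohort, fit every subject's multi-echo
#' images, derive composition maps, segment and refine the depot ROIs,
#' average composition per depot, and compare groups and depots. Each
#' stage logs its parameters; all outputs embed an MD5 hash of the
#' configuration, and reruns with the same configuration are
#' bit-identical.
#'
#' @param config list or YAML path accepted by [pipeline_config()].
#' @return list with the subject table, the comparison tables and the
#'   paths of the written CSV files.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  hash <- config_hash(cfg)
  ph_args <- cfg$phantom
  if (!is.null(ph_args$matrix_size))
    ph_args$matrix_size <- as.integer(unlist(ph_args$matrix_size))
  phspec <- do.call(phantom_spec, ph_args)
  acq <- do.call(acquisition_spec,
                 c(cfg$acquisition, list(matrix_size = phspec$matrix_size)))
  model <- do.call(fat_model_spec, cfg$model)
  fitcfg <- do.call(fit_config, cfg$fit)
  cospec <- do.call(cohort_spec, cfg$cohort)
  message("stage simulate: ", cospec$n_a, " + ", cospec$n_b,
          " subjects, grid ", paste(phspec$matrix_size, collapse = "x"),
          ", snr ", phspec$snr, ", seed ", cfg$seed)
  subjects <- simulate_cohort(cospec, phspec, acq, model,
                              master_seed = cfg$seed)
  rows <- list()
  for (sub in subjects) {
    maps <- fit_image(sub$echo, acq, model, fitcfg)
    fac <- fac_maps(maps)
    seg <- cfg$segmentation
    rows[[sub$id]] <- tryCatch(
      subject_depot_rows(fac, sub$truth, sub$id, sub$group,
        growth_threshold = seg$growth_threshold %||% 0.5,
        ff_min = seg$ff_min %||% 0.9,
        t2star_min = seg$t2star_min %||% 0.020),
      error = function(e) stop("segmentation stage failed for subject ",
                               sub$id, ": ", conditionMessage(e)))
  }
  subject_table <- do.call(rbind, rows)
  rownames(subject_table) <- NULL
  message("stage summarize: ", nrow(subject_table), " depot rows")
  cmp <- depot_comparison_table(subject_table)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subject = write_table_with_hash(subject_table,
      file.path(cfg$out_dir, "subject_depot_table.csv"), hash),
    groups = write_table_with_hash(cmp$group_comparison,
      file.path(cfg$out_dir, "group_comparison.csv"), hash))
  if (!is.null(cmp$depot_comparison))
    paths["depots"] <- write_table_with_hash(cmp$depot_comparison,
      file.path(cfg$out_dir, "depot_comparison.csv"), hash)
  message("stage compare: wrote ", paste(basename(paths), collapse = ", "))
  list(subject_table = subject_table,
       group_comparison = cmp$group_comparison,
       depot_comparison = cmp$depot_comparison,
       paths = paths, config_md5 = hash)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
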