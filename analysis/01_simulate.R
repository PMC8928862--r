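#!/usr/bin/env Rscript
# Stage 1: simulate the two-group imaging cohort.
#
# Draws per-subject depot compositions from the group distributions,
# instantiates one single-slice abdominal phantom per subject at the study
# acquisition settings, and writes the multi-echo images plus the manual
# outlines (cavity and fascia) to results/raw/.
#
# The grid is scaled down from the full 96 x 128 study matrix to keep the
# narrative workflow fast; analysis/00_config.yaml controls everything.

suppressPackageStartupMessages({library(facmri); library(yaml)})

cfg <- pipeline_config("analysis/00_config.yaml")
out <- file.path(cfg$out_dir, "raw")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ph_args <- cfg$phantom
ph_args$matrix_size <- as.integer(unlist(ph_args$matrix_size))
phspec <- do.call(phantom_spec, ph_args)
acq <- do.call(acquisition_spec,
               c(cfg$acquisition, list(matrix_size = phspec$matrix_size)))
cospec <- do.call(cohort_spec, cfg$cohort)

message("simulating ", cospec$n_a + cospec$n_b, " subjects at ",
        paste(phspec$matrix_size, collapse = "x"), ", SNR ", phspec$snr,
        ", master seed ", cfg$seed)
subjects <- simulate_cohort(cospec, phspec, acq, fat_model_spec(),
                            master_seed = cfg$seed)

meta <- list()
for (sub in subjects) {
  stem <- file.path(out, sub$id)
  write_echo_series(sub$echo, stem)
  write_polygon(sub$truth$cavity_polygon, paste0(stem, "_cavity.json"))
  write_polygon(sub$truth$fascia_polygon, paste0(stem, "_fascia.json"))
  meta[[sub$id]] <- list(group = sub$group,
                         seed_voxel = sub$truth$seed_voxel,
                         true_fac = sub$true_fac)
}
jsonlite::write_json(meta, file.path(out, "subjects.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "columns")
message("wrote ", length(subjects), " subjects to ", out)
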