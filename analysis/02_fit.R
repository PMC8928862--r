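#!/usr/bin/env Rscript
# Stage 2: voxel-wise model fitting.
#
# Reads every subject's multi-echo series from results/raw/, runs the
# variable-projection fit jointly estimating (W, F, ndb, nmidb, psi, R2*),
# and writes the parameter maps as NIfTI volumes to results/maps/.

suppressPackageStartupMessages(library(facmri))

cfg <- pipeline_config("analysis/00_config.yaml")
raw <- file.path(cfg$out_dir, "raw")
out <- file.path(cfg$out_dir, "maps")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- jsonlite::read_json(file.path(raw, "subjects.json"),
                            simplifyVector = TRUE)
fitcfg <- do.call(fit_config, cfg$fit)

for (id in names(meta)) {
  es <- read_echo_series(file.path(raw, id))
  acq <- acquisition_spec(echo_times = es$echo_times,
                          matrix_size = dim(es$data)[1:2])
  t0 <- Sys.time()
  maps <- fit_image(es, acq, fat_model_spec(), fitcfg)
  message(id, ": fitted ", sum(maps$valid), " voxels in ",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
          " s; converged ", round(100 * mean(maps$converged[maps$valid]), 1),
          "%")
  write_maps(maps, out, id, config = cfg)
}
message("wrote parameter maps to ", out)
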