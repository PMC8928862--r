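#!/usr/bin/env Rscript
# Stage 3: fatty-acid composition maps.
#
# Converts the fitted parameter maps into voxel-wise fSFA / fMUFA / fPUFA,
# fat-fraction and T2* maps and writes them to results/fac/.

suppressPackageStartupMessages(library(facmri))

cfg <- pipeline_config("analysis/00_config.yaml")
mapdir <- file.path(cfg$out_dir, "maps")
out <- file.path(cfg$out_dir, "fac")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ids <- sub("\\.json$", "", list.files(mapdir, pattern = "^S[0-9]+\\.json$"))
read_map <- function(id, nm)
  as.array(RNifti::readNifti(file.path(mapdir, paste0(id, "_", nm,
                                                      ".nii.gz"))))
for (id in ids) {
  maps <- facmri:::empty_parameter_maps(dim(read_map(id, "ndb")))
  for (nm in c("W_mag", "F_mag", "ndb", "nmidb", "psi", "r2star",
               "residual"))
    maps[[nm]] <- read_map(id, nm)
  maps$valid <- read_map(id, "valid") > 0
  maps$ndb[!maps$valid] <- NA; maps$nmidb[!maps$valid] <- NA
  fac <- fac_maps(maps)
  write_maps(fac, out, id, config = cfg)
}
message("wrote composition maps for ", length(ids), " subjects to ", out)
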