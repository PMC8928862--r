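# facmri

Fatty-acid composition of adipose tissue from multi-echo gradient-echo
MRI: spectral modeling, voxel-wise water–fat–composition estimation,
depot segmentation, synthetic phantoms/cohorts, and two-group
nonparametric statistics.

## What it does

The protons of a triglyceride molecule resonate at eight distinct
chemical shifts, and the relative amplitudes of those resonances are
linear in the mean number of double bonds (`ndb`) and of
methylene-interrupted double bonds (`nmidb`). Sampling the water–fat
interference over 12 echoes lets one estimate, in every voxel,

> water `W`, fat `F`, `ndb`, `nmidb`, the off-resonance field map `psi`,
> and R2\*,

from which saturated / monounsaturated / polyunsaturated fractions
(`fSFA = 1 - (ndb - nmidb)/3`, `fMUFA = (ndb - 2 nmidb)/3`,
`fPUFA = nmidb/3`), fat fraction `F/(W+F)` and T2\* maps follow.
Segmentation (region-grown subcutaneous ring, polygon-delineated
visceral depot, deep/superficial split at the fascia) and the ROI rule
(fat fraction > 0.9, T2\* > 20 ms) reproduce a standard abdominal
analysis, and Wilcoxon rank-sum / signed-rank tests compare groups and
depots.

The estimator is a variable-projection fit: the four complex amplitudes
are solved exactly at each trial of `(psi, R2*)`; a vectorized 64 × 4
multi-start grid over one field-map aliasing period plus two-basin local
refinement protects against water–fat swaps. On a noiseless digital
phantom the round trip recovers all six parameters to better than 1e-6
relative in every voxel.

## Worked example

```r
library(facmri)

# printed adipose compositions -> PUFA fraction
fractions_from_double_bonds(2.56, 0.48)$fpufa   # 0.16
fractions_from_double_bonds(2.20, 0.22)$fpufa   # 0.07333333

# simulate one voxel at the study acquisition and fit it back
acq <- acquisition_spec()        # 12 echoes, TE1 1.13 ms, dTE 1.56 ms, 3 T
s <- forward_signal(W = 5, F = 95, ndb = 2.56, nmidb = 0.48,
                    psi = 40, r2star = 40, acq = acq)
est <- fit_voxel(s, acq)
unlist(est[c("W_mag", "F_mag", "ndb", "nmidb", "psi", "r2star")])
#> W_mag  F_mag    ndb  nmidb    psi r2star
#>     5     95   2.56   0.48     40     40    (to ~1e-7 relative)

# end-to-end synthetic two-group study, written under results/
res <- run_pipeline(list(seed = 7, out_dir = "results",
                         cohort = list(n_a = 15, n_b = 23),
                         phantom = list(matrix_size = c(48, 64),
                                        sat_thickness = 6,
                                        fascia_offset = 3)))
subset(res$group_comparison, depot == "sat" & parameter == "fpufa")
```

## Analysis workflow

The `analysis/` scripts are thin, numbered drivers over the package,
configured by `analysis/00_config.yaml` (scaled-down 48 × 64 grid,
15 + 23 subjects, SNR 50):

| script | writes |
| --- | --- |
| `analysis/01_simulate.R` | multi-echo NIfTI pairs + outlines, `results/raw/` |
| `analysis/02_fit.R` | parameter maps, `results/maps/` |
| `analysis/03_fac_maps.R` | composition maps, `results/fac/` |
| `analysis/04_segment.R` | `results/subject_depot_table.csv` |
| `analysis/05_group_comparison.R` | `results/group_comparison.csv`, `results/depot_comparison.csv` |

Every table embeds an MD5 hash of the configuration; reruns with the
same configuration are bit-identical.

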