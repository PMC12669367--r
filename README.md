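# tractgap

Error assessment for tractography-guided electrode-to-tract distance
measurement in deep brain stimulation (DBS).

When probabilistic tractography guides DBS targeting, the decision-relevant
quantity is the distance (mm) from each electrode contact to a fiber bundle
such as the crossing or non-decussating dentato-rubro-thalamic tract
(c-DRTT / nd-DRTT). That distance inherits error from the processing chain
that produces it. `tractgap` isolates and quantifies three links of that
chain, for methodologists and DBS researchers who need to know how much of
a measured millimeter is signal:

1. **Binarization threshold.** A streamline-count map is binarized at a
   percentage *p* of its robust range (2nd–98th percentile of the
   histogram): the mask keeps voxels with value ≥ *t(p)* where

   *t(p) = r<sub>min</sub> + (p/100) · (r<sub>max</sub> − r<sub>min</sub>)*.

   Sweeping *p* over a candidate set (default 400, 600, 800, 1000%) and
   recording the spread (max − min) of the automated distance per
   contact × tract measures how much the threshold choice alone moves the
   result.
2. **Measurement technique.** Automated distances come from an exact
   anisotropic Euclidean distance transform of the tract mask (each voxel
   stores the mm distance to the nearest tract voxel center), sampled at
   the contact coordinate; distances above 10 mm trigger a one-step
   threshold step-down for that tract. Manual measurement is emulated as
   the distance to the closest tract voxel *visible on the contact's axial
   slice* — a subset-restricted minimum that can only inflate, and is
   sometimes impossible when the tract misses the slice. The per-record
   difference |manual − automated| is the technique error.
3. **Normalization.** An imperfect spatial normalization *T(x) = Ax + w(x)*
   (affine plus smooth residual field) is applied to the electrode tip; the
   error is |‖T(tip) − RN<sub>atlas</sub>‖ − ‖tip − RN<sub>native</sub>‖|,
   the landmark protocol with a red-nucleus-like point. Cases beyond a
   5 mm cutoff are excluded as failed normalizations.

A synthetic phantom generator (tube-shaped probability maps with
heavy-tailed count histograms and low-count spurious branches, bilateral
multi-contact leads, landmarks, per-patient transforms) makes the whole
pipeline runnable and testable without patient data. See the vignette
(`vignettes/error-assessment.Rmd`) for the models, defaults, and their
rationale.

## Worked example

```r
library(tractgap)

res <- run_pipeline(list(n_patients = 3), seed = 7)
print(res$report)
#> Summary of measured errors
#> source                        n   mean +/- sd (mm)     max (mm)
#> threshold choice             48      0.82 +/- 1.30         4.00
#> measurement technique        44      0.81 +/- 0.41         1.53
#> normalization                 3      0.73 +/- 0.35         1.13
```

Three phantom patients give 3 × 2 hemispheres × 4 contacts × 2 tracts = 48
contact×tract measurements. The first row says the threshold choice alone
moved individual distances by 0.82 mm on average (one contact by 4 mm);
the second row is the mean gap between the emulated axial-slice manual
reading and the automated 3D value over the 44 records where a manual
reading was possible (4 tracts were invisible on their contact's slice);
the third row is the landmark distance discrepancy introduced by each
patient's imperfect normalization.

The underlying records are plain data frames:

```r
head(res$measurements, 4)
#>  patient_id hemisphere   tract contact_index p_final d_auto_mm d_manual_mm
#>        P001       left  c-DRTT             0    1000     0.000      0.7874
#>        P001       left nd-DRTT             0    1000     2.828      4.2846
#>        P001       left  c-DRTT             1    1000     2.000      2.5153
#>        P001       left nd-DRTT             1    1000     4.472      5.5999

res$normalization$flagged
#>  patient_id d_native_mm d_norm_mm error_mm excluded
#>        P001       14.28     14.86   0.5732    FALSE
#>        P002       20.10     21.23   1.1284    FALSE
#>        P003       21.82     22.30   0.4809    FALSE
```

Passing `out_dir =` writes `measurements.csv`, `sensitivity_sweep.csv`,
`normerror.csv`, `report.json` and a rendered `report.txt`, each with a
provenance sidecar (config hash, seed, package version). A thin
command-line wrapper over the same functions lives at
`inst/cli/tractgap.R` (`Rscript inst/cli/tractgap.R run --seed 1
--out-dir out/`).

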