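# astroquant

Quantification of confocal microscopy assays used to characterize
astrocytes and glioblastoma-derived cells: where aquaporin-4 (AQP4) water
channels cluster in the plasma membrane, how the cytoskeleton is arranged,
how fast a cell sheet closes a wound, and how quickly cells swell and
recover their volume after a hypo-osmotic challenge. Every stage is paired
with a seeded synthetic-data generator with known ground truth, so the
whole pipeline is verifiable by parameter recovery rather than by eye.

## What it computes

**Plasmalemmal puncta** (AQP4 aggregates, cell-surface plectin
microdomains). 3D objects are detected in a z-stack as connected
components of the supra-threshold voxel set (26-connectivity, minimum 4
voxels; Otsu threshold with a robust background fallback). Counts are
normalized to 100 µm² of cell area, and each punctum is sized by the
full width at half maximum (FWHM) of its intensity profile in the
horizontal and vertical directions of its equatorial plane; the reported
diameter is the mean of the two. For a Gaussian spot of width σ,
FWHM = 2√(2 ln 2) σ ≈ 2.3548 σ.

**Cell regions and occupancy.** From a cell outline and nucleus mask the
package constructs the subplasmalemmal band (between the outline and a
virtual outline shrunk to 80–90% of the cell area) and the perinuclear
region (twice the nuclear area, grown from the nucleus), then reports
occupancy: the percentage of pixels above threshold within a region of the
z-projected image.

**Cytoskeletal architecture.** Filament images are skeletonized and broken
into straight segments at branch points. Metrics: avgTheta, the
length-weighted mean acute angle between segments and the cell long axis;
parallelness, the circular mean resultant length on doubled angles
R = |Σ w·e^(2iθ)|/Σ w ∈ [0, 1]; and bundling, Fisher's skewness
g₁ = m₃/m₂^1.5 of the intensity distribution.

**Wound healing.** The gap area A(t) is fitted linearly over the first
four time points (4-h sampling); the front speed and half-closure time are

    v_migration = |dA/dt| / (2 l),      t_1/2 = A(0) / (2 |dA/dt|)

with l the gap length. Single-cell mobility is the summed step length of
a nucleus track and its average speed.

**Calcein volume dynamics.** A fluorescence trace (1 frame/s, 30 s
baseline, 90 s post-stimulus) is Savitzky–Golay smoothed, photobleaching
is removed by subtracting the slope of a line fitted to the baseline, and
the trace is normalized to percent of baseline (F/F₀ × 100). Swelling is
modeled by the logistic

    F/F0(t) = F_max / (1 + exp(-k (t - t0)))

fitted by nonlinear least squares on the swelling phase; the package
reports F_max, the rate k, the swelling duration t_s,max (onset to peak)
and the half-time of the regulatory volume decrease (RVD) after the peak.

**Statistics.** Mann–Whitney U with exact small-sample p by full
enumeration (normal approximation with tie/continuity correction
otherwise), per-gene z-scoring and pairwise regression of expression
z-scores, and median ± bootstrap SE summaries.

## Worked example

The `analysis/` scripts run a two-group study on synthetic data emulating
plectin-expressing (wt) versus plectin-deficient (ko) astrocytes. Run them
in order from the repository root:

```sh
Rscript analysis/01_simulate_inputs.R     # writes results/simulated/
Rscript analysis/02_quantify_puncta.R
Rscript analysis/03_cytoskeleton.R
Rscript analysis/04_migration.R
Rscript analysis/05_volume_dynamics.R
Rscript analysis/06_expression_regression.R
```

Output of `02_quantify_puncta.R`:

```
Counts exact in 12/12 cells.
Puncta density: wt 20.84 vs ko 6.09 per 100 um^2 (71% reduction, p = 0.005)
Median diameter: wt 0.490 vs ko 0.456 um (7% smaller, p = 0.0649)
```

Every detected count matched the generator's ground truth; the ko group
was simulated with ~70% fewer, slightly smaller puncta and the pipeline
recovers both effects, with the Mann–Whitney p for the density difference
at 0.005. `04_migration.R` likewise reports the simulated ~15% slower
collective migration of ko (`wt 11.7 vs ko 10.1 um/h, p = 0.0286`), and
`05_volume_dynamics.R` the reduced peripheral swelling rate
(`k: wt 0.39 vs ko 0.27 /s, p = 0.00094`). Per-cell and summary tables
are written under `results/`.

A minimal in-session example:

```r
library(astroquant)
geom <- gen_cell_mask("circle", radius = 80, pixel_size = 0.1)
p    <- gen_puncta_stack(geom, n = 12, sigma = 2, noise_sd = 100, seed = 1)
det  <- detect_objects(p$stack)
density_per_100um2(det, geom$cell_area_um2)   # 5.97 per 100 um^2
median(measure_diameters(p$stack, det)$diameter)  # ~0.47 um = 2.3548*sigma*pixel
```

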