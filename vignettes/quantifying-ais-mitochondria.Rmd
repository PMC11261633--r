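---
title: "Quantifying mitochondrial distribution at the axon initial segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial distribution at the axon initial segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismito)
```

## The measurement problem

In *Drosophila* mushroom-body (MB) neurons, mitochondria are not uniformly
distributed along the neuron: in healthy cells they are partially excluded
from the axon initial segment (AIS), the proximal-axon compartment between
the somatodendritic calyx and the axonal lobes, and this exclusion is lost
under genetic perturbations (loss of Cdk5 activity, dominant-interfering
ankyrin fragments) that disrupt the AIS and precede axonal degeneration.
Testing hypotheses about this redistribution requires three quantitative
readouts from two-channel confocal stacks (a mitochondrially targeted
fluorophore plus a structural/AIS marker such as actin or FasII):

1. **Compartment balance** — the ratio of mean mitochondrial intensity in
   the somatodendritic calyx to that in the dorsal/alpha lobe, computed on
   threshold-masked images.
2. **AIS profile** — the binned, max-normalized intensity trace along a
   rectangular ROI laid across the AIS region of the peduncle.
3. **Signal dropout** — the area enclosed between that normalized profile
   and the straight chord joining its values at the AIS edges, plus the
   integrated intensity over the AIS interval.

Because no real image data are distributed with this package, every stage
is validated against a synthetic-stack generator with exact ground truth:
compartment labels per voxel, every punctum's position and amplitude, and
the true AIS interval.

## The synthetic neuron

`compartment_geometry()` describes an idealized MB-like neuron in physical
micrometres: a spherical calyx (radius 8 µm) on the proximal (high-x)
side, a cylindrical peduncle (radius 3 µm, ~42 µm long) containing a
14 µm AIS interval, and a cylindrical lobe (radius 5 µm) on the distal
side. `build_label_volume()` voxelises this into labels
`{background, calyx, ais, axon_proximal, axon_lobe}`; voxel membership is
decided at voxel centres, the AIS arc interval is half-open
`[distal, proximal)`, and overlaps resolve calyx > peduncle > lobe.

Mitochondria are a Poisson point process of Gaussian puncta
(`puncta_model()`, `sample_puncta()`). Key defaults, chosen once as the
study conditions:

* **Density 1.5 puncta/µm³ in every neuronal compartment.** The MB
  peduncle is a fascicle of hundreds of thin axons, so the summed
  mitochondrial signal at confocal resolution is dense and
  quasi-continuous rather than isolated spots; a density of 1.5/µm³
  combined with the effective blur (below) gives mean occupancies of
  several puncta per resolution element, which is what makes the mean
  masked intensity approximately proportional to density (and hence makes
  the compartment ratio recoverable). No real mitochondrial densities are
  implied; these are free parameters of the artifact.
* **AIS exclusion** thins the axonal density inside the AIS to
  `density × (1 − d·w(s))` with depth `d ∈ [0, 1]` and weight `w` over
  the normalized AIS position `s` (0 distal, 1 proximal): `"uniform"`
  (`w = 1`) models depletion throughout the AIS as seen in larvae;
  `"proximal-weighted"` (`w = s`) models the adult pattern of strongest
  depletion at the proximal edge with recovery towards the distal AIS.
  WT-like conditions use `d = 0.8`; KO-like conditions `d = 0`.
* **Punctum amplitude** ~ Normal(10, 2) truncated positive; **punctum
  sigma** 0.4 µm.

`render_stack()` produces the two channels. The mitochondrial channel is
rendered in closed form: convolving a Gaussian punctum with a Gaussian
PSF is again Gaussian, with per-axis
`sigma_eff² = punctum_sigma² + psf_sigma²`, so each punctum is evaluated
directly at voxel centres (windowed at 4 sigma) — no discrete
convolution, which is why a single rendered punctum can be checked
against independent kernel evaluation to 1e-6. The structural-marker
channel fills all neuronal labels at amplitude 100, attenuated 0.3× inside
the AIS; 0.3 gives a trough deep enough that automated boundary detection
has an unambiguous target. The acquisition model defaults are a PSF sigma
of (0.6, 0.25, 0.25) µm (z, y, x) — a 1 µm z-step confocal geometry —
background 5, shot noise at 20 photons per intensity unit (per-voxel
variance ≈ mean/20), and read noise SD 1.

Cohort simulations use a reduced field of view of (18, 32, 80) µm at
(1.0, 0.5, 0.5) µm voxels (`cohort_geometry()`), about 1.8×10^5 voxels
per channel, so that multi-group recovery experiments complete in minutes;
the geometry type itself defaults to finer (1.0, 0.25, 0.25) µm sampling.
Per-stack seeds derive from the master seed by a fixed rule
(`master + 1e5·group + 100·fly + hemisphere`), so extending a cohort never
reshuffles existing stacks.

What the generator deliberately does **not** emulate: axon bifurcation
fine structure, mitochondrial transport dynamics, photobleaching, depth-
dependent attenuation, anatomical variability of the ROI placement (ROI
centres come from ground truth), or segmentation error. Passing recovery
tests therefore demonstrates that the measurement chain is correct and
well calibrated on images whose noise model is known — not that the
biological measurements on real tissue are unbiased.

## Analysis chain and its conventions

**Thresholding** (`threshold_to_missing()`): voxels strictly below the
threshold become missing (`NA`), matching "values below the threshold"
semantics — values equal to the threshold survive. One threshold value is
used for an entire experiment; the default 8 sits at roughly
background + 3 SD of detector noise for the default acquisition model.
The paper's procedure states a threshold but not its value, so it is a
config parameter.

**Compartment ratio** (`somatodendritic_axonal_ratio()`): polygonal ROIs
are applied as prisms across all z-slices (ROIs are drawn once per stack,
not per slice); the mean is the summed intensity of non-missing voxels
divided by their count. "Non-zero area" is read as the non-missing voxel
count, since sub-threshold voxels were set to not-a-number. An ROI left
empty after masking is an explicit error naming the ROI.

**Profiles** (`max_project()`, `extract_profile()`,
`normalize_profile()`): the stack is max-projected (per-pixel max over
non-missing slices), then resampled into the rotated ROI frame by
bilinear interpolation at 4× oversampling, averaged across the ROI width,
then averaged into `round(length/bin_width)` bins — 90 bins for the
37 µm larval ROI at the 0.41 µm bin width. The "intensity histogram" of
the source procedure is implemented as a spatial line profile (bins are
positions, not intensity levels), since the plotted quantity is intensity
versus position across the AIS. Width-averaging before binning was chosen
for determinism; with uniform weights it is equivalent to binning first.
Positions are signed bin centres spanning `[−L/2, +L/2]` with 0 at the
ROI centre (aligned with the approximate AIS centre) and **negative =
distal**. Normalization divides by the profile's own maximum (the
per-image maximum is read as the maximum of that image's profile trace).
By default profiles are *not* threshold-masked (`threshold_profiles:
false`): masking is applied "when configured", and leaving it off avoids
all-missing bins inside a fully excluded AIS; the compartment-ratio stage
always masks.

**Dropout statistics** (`chord_dropout_area()`,
`integrated_ais_intensity()`): with the chord `c(x)` joining the profile
values at the AIS edges, the dropout area is `∫ max(c(x) − y(x), 0) dx`
over the interval. Only the below-chord part counts because the statistic
quantifies a signal depression (the dip a wand-tool selection would
enclose); where the profile crosses above the chord only the below-chord
segments contribute. Both curves are piecewise linear, so the integral is
evaluated exactly on the bin grid refined with the crossing points; the
integrated intensity is the trapezoid integral of `y(x)`. When the
profile is pinned at 1 at both edges and ≤ 1 inside, the two statistics
are complementary: they sum to the interval width.

**AIS interval**: the pipeline default takes the interval from config or
ground truth, mirroring the manual marker/morphology-based practice.
`detect_ais_interval()` automates it for self-tests: the reference level
is the mean of the medians of the flanking 25% of bins on each side, and
the interval is the longest run of bins below 0.6× that reference, at
least 2 µm long (ties: the longest run wins). These parameters are
explicitly arbitrary defaults — the manual criterion they stand in for is
not recoverable — and a failed detection falls back to the manual
interval.

**Statistics** (`collapse_replicates()`, `compare_two_groups()`,
`compare_two_way()`): per-hemisphere measurements of one brain are
technical replicates and are averaged to one value per fly first. The
two-group comparison gates on Kolmogorov–Smirnov normality (estimated
parameters, no Lilliefors correction — the common packaged behaviour,
noted as approximate) at the experiment's alpha: both groups normal →
unpaired t-test (pooled if the F-test of equal variances passes, Welch
otherwise); otherwise Mann–Whitney U (exact when the combined n ≤ 20
without ties — determinism at small n — else normal approximation with
tie correction). Every gate outcome is recorded in `decision_path`. The
genotype × age analysis is a two-way ANOVA with sum-to-zero contrasts and
partial (Type-III) sums of squares, because the cohorts it mirrors are
unbalanced (e.g. N = 24 vs 8) and marginal tests must not depend on
factor order; pairwise genotype-within-age contrasts are Šidák-adjusted,
`p_adj = 1 − (1 − p)^m`, over the whole contrast family. Which t-test
variant and sums-of-squares type the original analysis used is not
stated; these gates are this package's explicit choices.

## A worked run

```{r demo, eval = FALSE}
cfg <- demo_config(n_per_group = 8, seed = 1)   # WT d = 0.8 vs KO d = 0
out <- tempfile("demo")
run_pipeline(cfg, out)
read_table(file.path(out, "comparisons.csv"))[, c("metric", "test_name",
                                                  "adjusted_p")]
```

The expected pattern reproduces the qualitative finding structure the
pipeline was built around: a strongly significant WT/KO difference in
`dropout_area` and `integrated_intensity`, and no significant difference
in the somatodendritic:axonal `ratio` when compartment densities are
matched. `manifest.json` records the config snapshot, master seed, and
MD5 of every output; re-running with the same config and seed is
byte-identical.

## Numerical choices and degenerate inputs

* Intervals along the peduncle are half-open `[distal, proximal)`;
  profile positions are signed with distal negative.
* Bilinear samples with any missing neighbour are missing and are
  excluded from bin averages; a bin with no valid samples is missing.
  Missing bins inside the dropout interval are bridged by linear
  interpolation across non-missing bins.
* `normalize_profile()` on an all-zero or all-missing profile is an
  error; aggregation of a single profile reports SEM 0 with a warning;
  a constant sample gives normality p = 0 (degenerate branch).
* Tie-breaks: trough detection picks the longest qualifying run;
  `round()` (banker's at .5) fixes the bin count.
* On-disk stacks are 32-bit float TIFF (NaN for masked voxels), so
  round trips are bit-exact; voxel size travels in the ImageDescription
  tag as JSON.

## Known limitations

* The chord-dropout statistic is a nonnegative functional of a noisy
  profile, so its expectation under *no* exclusion is small but strictly
  positive (~2–4% of the interval width under the default conditions)
  and scales with profile roughness — it cannot be statistically
  indistinguishable from zero at realistic noise. Comparisons between
  conditions are unaffected (the offset is shared), but the absolute
  area should not be read as a pure exclusion measure near zero.
* The measured compartment ratio compresses slightly towards 1 at
  extreme true density ratios: at low density more voxels fall below
  threshold, biasing that compartment's masked mean upward. At a true
  ratio of 2 the bias is within ~15%; at 4 it is larger but order and
  significance are preserved.
* ROI placement is an input everywhere; no automated anatomical
  segmentation is attempted.
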