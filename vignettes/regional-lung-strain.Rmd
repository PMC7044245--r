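---
title: "Regional lung deformation from periodic 4DCT: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung deformation from periodic 4DCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strain4d)
```

# The problem

Phase-binned ("4D") CT of a mechanically ventilated lung yields a periodic
sequence of N volumetric images $I_n(\mathbf{x}_n)$, $n = 0 \dots N-1$, over
one ventilatory cycle, together with per-phase lung masks and per-phase
spatial transformations $\phi_n(\mathbf{X}) = \mathbf{x}_n$ mapping a common
reference frame $\mathbf{X}$ into each phase frame (these transformations
come from a groupwise, tissue-volume-preserving registration, which this
package consumes, not performs). From those ingredients the package
quantifies how hard and how unevenly each piece of lung parenchyma is worked
by conventional mechanical ventilation (CMV), single-frequency
high-frequency oscillatory ventilation (HFOV, 5 Hz), and multi-frequency
oscillatory ventilation (MFOV, superimposed 5/10/15/20 Hz flows with uniform
amplitudes).

# The analysis chain

**Alignment.** Any phase $n$ is aligned to a chosen reference phase $m$ by
the pullback $T_{n \to m}(\mathbf{x}_m) = \phi_n(\phi_m^{-1}(\mathbf{x}_m))$
(`composePullback()`), with $\phi_m^{-1}$ obtained by damped-free fixed-point
iteration on the displacement field (`invertTransform()`, stopping when the
largest update falls below 0.01 voxel, cap 50 iterations, hard failure if the
round-trip residual exceeds 0.5 voxel anywhere). Images are resampled
trilinearly (`warpImage()`); points leaving the domain are flagged invalid
and excluded from every downstream summary.

**Volume, strain, strain rate.** The Jacobian determinant of the pullback
gives the phase-varying volume of the tissue occupying one reference voxel,
$V_n(\mathbf{x}_0) = \delta V \, |J_{n\to 0}(\mathbf{x}_0)|$. Strain is
referenced per voxel to its minimum inflation state over the cycle,
$\varepsilon_n = (V_n - \min_n V_n)/\min_n V_n$, so $\min_n \varepsilon_n = 0$
and the intratidal strain range is $\Delta\varepsilon = \max_n \varepsilon_n$.
Strain rate uses periodic forward differences,
$\dot\varepsilon_n = (\varepsilon_{(n+1)\bmod N} - \varepsilon_n)/\delta t$
with $\delta t = 1/(f_0 N)$; its range $\Delta\dot\varepsilon$ adds the
fastest inflation and deflation rates, and the rates telescope to zero over a
cycle. Aeration change $\Delta I$ is the per-voxel HU range of the aligned
images.

**Spatial summaries.** Each map is summarised over the analysis mask by its
mean, coefficient of variation (population SD / mean), and per-axis spatial
gradients: three independent univariate OLS slopes of value against world
coordinate (right-left, dorsal-ventral, caudal-rostral), reported signed, as
magnitudes, and mean-normalized. The analysis mask is the reference-phase
lung mask trimmed 6.0 mm from both axial (caudal-rostral) image boundaries
— 10 slices per end at 0.6 mm — and restricted to voxels valid at every
phase with positive determinants.

**Harmonics.** `dftMaps()` decomposes any per-voxel periodic series into
one-sided DFT amplitudes and phases at harmonics $k f_0$, $k = 1 \dots K$
(default $K = 4$, the 5–20 Hz band at a 5 Hz fundamental). Phases are
reported relative to the per-harmonic median phase over lung voxels, wrapped
to $(-\pi, \pi]$; median referencing leaves pairwise phase differences
untouched. The harmonic distortion index is the power fraction above the
fundamental, $\mathrm{HDI} = \sum_{k\ge 2} A_k^2 / \sum_{k \ge 1} A_k^2$;
the root-power variant $\sqrt{\sum_{k\ge2}A_k^2}/A_1$ is available via
`type = "root"`. The power-fraction form is the default because the quantity
of interest is the fraction of oscillatory spectral power carried above the
fundamental. Whether the strain or strain-rate series feeds a
harmonic-correlation analysis is left to the caller — both are exposed on
`VoxelMetricMaps` — since amplitude ratios between harmonics differ by the
factor $k$ between the two series and either choice is defensible.

**Heterogeneity.** `octreeDecompose()` and `supervoxelDecompose()` both
start from one ROI holding the whole mask and recursively subdivide any ROI
whose masked-voxel population SD of the (mean-normalized) strain-range field
is at least 0.3 and whose size is at least 0.2% of the mask. The octree
splits the ROI's own bounding box into eight octants (floor split for odd
extents; axes of extent 1 are not split) — the box is re-fitted per ROI
rather than inherited from the full image so subdivision adapts to the
mask's actual extent. The supervoxel method splits by 2-means on feature
vectors `[wI * z-scored value, (x,y,z)/L]` with `L` the ROI bounding-box
diagonal; `wI = 1/proximityWeight` with default 1 (equal weighting). The
proximity weighting is a genuine free parameter and a sensitivity knob —
smaller weights chase intensity irregularities with more ragged boundaries —
so it is exposed rather than hidden. 2-means runs Lloyd iterations from a
deterministic farthest-pair start (farthest from the centroid, then farthest
from that point), making decompositions reproducible without an RNG.
Degenerate ROIs (identical features, or an empty 2-means cluster) are
treated as below threshold. Heterogeneity is summarised by
$\bar V_\mathrm{ROI}$, the mean ROI size as a fraction of the mask.

**Ventilation and gas exchange.** From airway-opening waveforms and a blood
gas panel: oxygenation index $\mathrm{OI} = \bar P_{aw} \cdot F_iO_2 /
P_aO_2$, ventilatory cost $V_C = V_\mathrm{rms}^2 \cdot P_aCO_2 /
\mathrm{Wt}$, rms and peak-to-peak volume over one breath (CMV) or exactly
1 s (HFOV/MFOV), driving pressure $\Delta P_{aw}$, and dynamic elastance
$E_{rs} = \Delta P_{aw}/V_{pp}$ for CMV records only (for oscillatory
modalities the pressure amplitude is dominated by resistive and inertial
loads, so $E_{rs}$ is reported NA). OI follows the clinical convention with
$F_iO_2$ as a percentage (12 cmH2O, 40%, 100 mmHg gives 4.8); the scaling is
switchable and stamped on the result.

**Respiratory impedance.** `estimateImpedance()` implements Welch averaging
with rectangular windows of 25.6 s and 80% overlap, forming the H1 transfer
estimate $Z = S_{qp}/S_{qq}$ and ordinary coherence, evaluated only at the
nine driving tones of the forcing signal (which must sit on the 1/25.6 Hz
segment grid). The H1 form is the natural choice with noise entering on the
pressure side. `fitConstantPhase()` fits
$\hat Z(f) = R + j 2\pi f I_{aw} + (\eta - j) H/(2\pi f)^\alpha$,
$\alpha = (2/\pi)\arctan(1/\eta)$, by minimising the unweighted sum of
squared complex residuals under non-negativity bounds, from 16 deterministic
data-scaled starts followed by box-constrained quasi-Newton refinement.
Resonant frequency is the smallest in-band root of a cubic spline through
the reactance samples; when the reactance does not change sign in-band (as
happens after severe injury) it is NA with a `defined = FALSE` flag. A
closed-form cross-check, $(2\pi f)^{1+\alpha} = H/I_{aw}$, is provided as
`constantPhaseResonance()`.

**Statistics.** Kruskal-Wallis omnibus tests (tie-corrected, chi-square
reference) for the condition main effect and for modality separately within
each condition; Dunn post hoc z-tests with tie-corrected variance and
Benjamini-Hochberg adjustment within each outcome's three modality pairs
(the per-outcome family mirrors how the post hoc step is applied per
outcome); two-sided comparisons throughout, since no direction is
pre-specified. All-tied inputs return H = 0, p = 1 rather than NaN.

# The synthetic phantom

`makePhantom()` generates the study conditions with exact ground truth. Two
ellipsoidal lungs sit in an elliptic body cylinder; each deforms by a radial
expansion about its hilum,
$u_n(\mathbf{X}) = g_n \, a(\mathbf{X}) (\mathbf{X} - \mathbf{h})$, where
$g_n \in [0,1]$ is the modality volume waveform sampled at the N phases and
$a = A \, m(y) \, \cos^2(\pi\rho/2)$ is a compact-support amplitude field
($\rho$ the elliptic radius, so the lung boundary stays fixed against the
chest wall; $m(y)$ imposes the dorsal-ventral gradient $1 + G\hat y$ and, in
the injured condition, a smooth dorsal consolidation ramp). Because $a$
depends on position only through $\rho$ and $y$, the Jacobian determinant is
closed-form, $\det J = c^2 (c + g\, \nabla a \cdot (\mathbf{X}-\mathbf{h}))$
with $c = 1 + g a$, giving analytic per-voxel volume series. The phase
index is rotated so that phase 1 is the minimum-inflation phase
($g_1 = 0$): the reference transformation is then the identity and the
ground-truth determinants to the reference frame are exact. Intensities
follow the gas/tissue mixture $I = -1000(1 - F) + 40 F$ HU with
$F_n = F_0 / \det J_n$, which conserves per-voxel tissue volume exactly —
the same premise the tissue-volume-preserving registration enforces on real
data. The tissue HU of 40 (soft-tissue range) and aerated tissue fraction
0.2 (about -790 HU) are package choices; consolidated tissue intensity is
governed by the same parameter and reaches 40 HU at full consolidation.

Per-modality default amplitudes emulate the eucapnia-titrated protocol: the
delivered volume rms ratios are fixed at CMV : HFOV : MFOV = 1 : 0.42 : 0.25
(the delivery ratios reported for the titrated animals), starting from a
conventional tidal strain of 0.25 for CMV. This is deliberately *not* a
matched-V_rms comparison: with equal rms a multi-sine with in-phase
components has the larger crest factor and would mechanically produce larger
peak-to-peak strain, inverting the modality contrast the protocol actually
produces. MFOV component phases default to 0 and are configurable.
Additive Gaussian HU noise (default 5 HU) models reconstruction noise;
cardiogenic artifact is not emulated. Blood-gas panels (`makeGasPanel()`)
draw FiO2/PaO2/PaCO2/weight values consistent with the protocol's baseline
and post-injury bands.

What the phantom does *not* emulate — airway trees, vessels, discontinuous
sliding at fissures, cardiogenic oscillation, registration error on real
texture, recruitment/derecruitment — bounds what green tests mean: they
validate the measurement chain on smooth, periodic, tissue-conserving
deformations, not the registration itself.

# Numerical choices

* **Jacobian stencil.** Mapping components are differentiated by central
  finite differences; the interior uses the five-point fourth-order stencil,
  falling back to the three-point stencil beside the boundary and one-sided
  differences at the edge slices. At 0.6 mm resolution the three-point
  truncation error on lung-sized smooth deformations is of order $10^{-3}$
  in the determinant — the same order as the strain signal of interest in
  low-amplitude oscillatory modalities — while the five-point stencil drives
  it below $10^{-3}$ comfortably (the acceptance script reports the measured
  maximum against the analytic phantom truth). `order = 2` restores the
  plain scheme.
* **Interior shells.** Phantom-recovery checks are evaluated on elliptic
  shells of the truth: $\rho \le 0.8$ for determinant error (excluding the
  boundary shell where the taper's curvature is discontinuous) and
  $\rho \le 0.5$ for relative strain-range error (where the true strain is
  bounded away from the crossover band in which the determinant stays near 1
  all cycle and a relative criterion is ill-posed).
* **Inversion.** Fixed-point inversion tolerance 0.01 voxel, 50-iteration
  cap, 0.5-voxel failure threshold; the phantom's own renderer inverts its
  analytic deformation to 1e-6 mm.
* **Trilinear sampling** is edge-clamped for displacement fields (which
  vanish at the phantom boundary) and strict for images (out-of-domain
  samples become NA and invalidate the voxel).
* **CoV** uses the population SD (documented, trivially switchable);
  decomposition SDs likewise.
* **Degenerate inputs.** Zero-mean fields flag normalized gradients NA;
  all-tied samples give H = 0; empty masks and sub-threshold windows error
  early with actionable messages.
* **Problem sizes.** The test suite and acceptance script run phantoms at
  48^3 voxels, 0.6 mm, 21 phases (the densest phase binning of the imaging
  protocol), with smaller 24–32^3 phantoms for structural tests and the
  simulated cohort; these sizes were chosen as the smallest grids on which
  the lung occupies enough voxels (~15,000 masked) for stable spatial
  statistics.

# Limitations

Ground-truth transformations sidestep registration error, which in real
data is the dominant uncertainty in strain maps; the phantom's inter-subject
variability model (lognormal scatter on cell metrics in
`simulateCohort()`) is deliberately simple and shares one phantom
realisation per condition-modality cell; and the harmonic-distortion level
of regional strain in the phantom reflects only the cubic volume-intensity
nonlinearity of the mixture model, far weaker than the tissue nonlinearity
of a real lung, so HDI comparisons across modalities in the phantom are
qualitative only.
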